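test_that("extract_profile reproduces constant and zero fields", {
  img <- tract_image(matrix(7, 50, 80), matrix(7, 50, 80), pixel_size = 0.5)
  prof <- extract_profile(img, reference_line(1, 25, 80, 25))
  expect_true(all(prof$dorsal == 7))
  expect_true(all(prof$ventral == 7))
  expect_true(all(diff(prof$position_um) > 0))
  expect_lte(max(diff(prof$position_um)), img$pixel_size)

  zimg <- tract_image(matrix(0, 50, 80), matrix(0, 50, 80), pixel_size = 0.5)
  zprof <- extract_profile(zimg, reference_line(1, 25, 80, 25))
  expect_true(all(zprof$dorsal == 0))
})

test_that("extract_profile rejects lines outside the image, naming the endpoint", {
  img <- tract_image(matrix(1, 50, 80), matrix(1, 50, 80), pixel_size = 0.5)
  expect_error(extract_profile(img, reference_line(1, 25, 90, 25)), "end point")
  expect_error(extract_profile(img, reference_line(-3, 25, 80, 25)), "start point")
})

test_that("profiles peak at programmed band centers and match a nearest-pixel oracle", {
  fx <- make_tract_image(0.5)
  prof <- extract_profile(fx$image, fx$line)
  # two local maxima at the programmed centers
  for (ctr in fx$truth$band_centers_um) {
    near <- abs(prof$position_um - ctr) < 2
    expect_equal(prof$position_um[which.max(prof$dorsal * near)],
                 prof$position_um[near][which.max(prof$dorsal[near])])
    expect_lt(abs(prof$position_um[near][which.max(prof$dorsal[near])] - ctr), 1)
  }
  # bilinear sampling vs nearest-pixel oracle on 10 random lines, on an
  # image sampled finely relative to the band width (interpolation and
  # nearest-pixel lookup agree to half-pixel discretization error)
  fine <- make_tract_image(0.5, band_sigma = 8, pixel_size = 0.2)
  set.seed(42)
  for (i in 1:10) {
    ln <- reference_line(runif(1, 2, 100), runif(1, 2, 290),
                         runif(1, 400, 499), runif(1, 2, 290))
    p <- extract_profile(fine$image, ln)
    o <- nearest_pixel_profile(fine$image, ln, n = nrow(p))
    expect_lt(max(abs(p$dorsal - o$dorsal)), 0.01 * max(fine$image$dorsal))
    expect_lt(max(abs(p$ventral - o$ventral)), 0.01 * max(fine$image$ventral))
  }
})

test_that("split_branches finds the gap between bands and honors manual splits", {
  prof <- data.frame(position_um = seq(0, 60, by = 0.5), dorsal = 0, ventral = 0)
  prof$dorsal[prof$position_um >= 10 & prof$position_um <= 20] <- 5
  prof$dorsal[prof$position_um >= 40 & prof$position_um <= 50] <- 5
  class(prof) <- c("intensity_profile", "data.frame")
  sp <- split_branches(prof)
  expect_gt(sp$split_position, 20)
  expect_lt(sp$split_position, 40)

  expect_identical(split_branches(prof, manual_split = 30)$split_position, 30)

  # noisy two-band fixture: split near the noiseless valley
  fx0 <- make_tract_image(0.4)
  p0 <- extract_profile(fx0$image, fx0$line)
  tot0 <- p0$dorsal + p0$ventral
  mid <- which(p0$position_um > 35 & p0$position_um < 65)
  oracle <- p0$position_um[mid[which.min(tot0[mid])]]
  fx <- make_tract_image(0.4, noise_sigma = 5, seed = 1)
  p <- extract_profile(fx$image, fx$line)
  expect_lt(abs(split_branches(p)$split_position - oracle), 2)

  # single band: no split detectable
  fx1 <- make_tract_image(0)
  p1 <- extract_profile(fx1$image, fx1$line)
  expect_error(split_branches(p1), "manual_split")
})

test_that("missorting index follows Dm/(Dm+Ds) and its edge cases", {
  pos <- seq(0, 100, by = 0.5)
  mk <- function(d) {
    pr <- data.frame(position_um = pos, dorsal = d, ventral = 0)
    class(pr) <- c("intensity_profile", "data.frame")
    pr
  }
  sp <- structure(list(split_position = 50, dm_side = "high", mode = "manual"),
                  class = "branch_split")
  # all dorsal signal on the Ds (low) side -> mi 0
  expect_equal(missorting_index(mk(ifelse(pos < 50, 4, 0)), sp)$mi, 0)
  # all on the Dm side -> mi 1
  expect_equal(missorting_index(mk(ifelse(pos > 50, 4, 0)), sp)$mi, 1)
  # forced arithmetic: mean_Dm 30, mean_Ds 90 -> 0.25
  res <- missorting_index(mk(ifelse(pos > 50, 30, 90)), sp)
  expect_equal(res$mean_Dm, 30)
  expect_equal(res$mean_Ds, 90)
  expect_equal(res$mi, 0.25)
  # zero denominator is an error, not 0
  expect_error(missorting_index(mk(rep(0, length(pos))), sp), "undefined")
  # scale invariance of the dorsal channel
  d <- ifelse(pos > 50, 3, 7)
  expect_equal(missorting_index(mk(d), sp)$mi,
               missorting_index(mk(d * 13.7), sp)$mi)
})

test_that("missorting index recovers the programmed fraction on noiseless images", {
  for (f in seq(0, 1, by = 0.1)) {
    fx <- make_tract_image(f)
    prof <- extract_profile(fx$image, fx$line)
    sp <- split_branches(prof, manual_split = fx$truth$midpoint_um)
    mi <- missorting_index(prof, sp)$mi
    expect_lte(abs(mi - f), 0.01)
    expect_gte(mi, 0); expect_lte(mi, 1)
  }
})

test_that("projection area counts thresholded pixels times pixel area", {
  z <- matrix(0, 50, 50)
  img <- tract_image(z, z, pixel_size = 0.5)
  expect_equal(projection_area(img, "dorsal", 1), 0)
  d <- z; d[11:20, 11:20] <- 100
  img <- tract_image(d, z, pixel_size = 0.5)
  expect_equal(projection_area(img, "dorsal", 50), 25)
  # brute-force oracle on a programmed mask
  set.seed(3)
  d2 <- matrix(runif(2500, 0, 10), 50, 50)
  img2 <- tract_image(d2, z, pixel_size = 0.4)
  n <- 0L
  for (i in 1:50) for (j in 1:50) if (d2[i, j] >= 5) n <- n + 1L
  expect_equal(projection_area(img2, "dorsal", 5), n * 0.16)
})

test_that("tract TIFF and ROI-line JSON round-trip through the MI pipeline", {
  fx <- make_tract_image(0.3)
  tf <- tempfile(fileext = ".tif")
  write_tract_tiff(fx$image, tf)
  img2 <- read_tract_tiff(tf, pixel_size = fx$image$pixel_size)
  prof <- extract_profile(img2, fx$line)
  sp <- split_branches(prof, manual_split = fx$truth$midpoint_um)
  expect_lt(abs(missorting_index(prof, sp)$mi - 0.3), 0.01)
  expect_error(read_tract_tiff(tf), "pixel_size")

  lf <- tempfile(fileext = ".json")
  writeLines('{"x1": 1, "y1": 60, "x2": 200, "y2": 60}', lf)
  ln <- read_roi_line(lf)
  expect_s3_class(ln, "reference_line")
  expect_equal(ln$offset_from_chiasm, 70)
})
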