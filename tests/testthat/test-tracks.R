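test_that("motion classification applies the strict 2-um excursion rule", {
  t <- 0:60
  expect_equal(classify_motion(granule_track("a", t, rep(5, 61))),
               "static_oscillatory")
  expect_equal(classify_motion(granule_track("b", t, 5 + 3 * t / 60)),
               "anterograde")
  expect_equal(classify_motion(granule_track("c", t, 5 - 3 * t / 60)),
               "retrograde")
  # excursion exactly at the threshold stays static ("more than" is strict)
  expect_equal(classify_motion(granule_track("d", t, 5 + 2 * t / 60)),
               "static_oscillatory")
  # just over the threshold flips the call
  expect_equal(classify_motion(granule_track("e", t, 5 + 2.001 * t / 60)),
               "anterograde")
  # excursion counts even when the endpoint returns to the origin
  osc <- c(seq(0, 2.5, length.out = 31), seq(2.5, 0, length.out = 30))
  expect_equal(classify_motion(granule_track("f", t, osc)), "anterograde")
  expect_error(granule_track("g", c(0, 0, 1), c(0, 1, 2)), "strictly increasing")
})

test_that("classification is shift-invariant and flips under negation", {
  fx <- make_track_fixture("custom", seed = 11, n_confined = 5,
                           n_anterograde = 5, n_retrograde = 5)
  flip <- c(anterograde = "retrograde", retrograde = "anterograde",
            static_oscillatory = "static_oscillatory")
  for (tr in fx$tracks) {
    cls <- classify_motion(tr)
    shifted <- granule_track(tr$granule_id, tr$times, tr$positions + 123.4)
    expect_equal(classify_motion(shifted), cls)
    negated <- granule_track(tr$granule_id, tr$times, -tr$positions)
    expect_equal(classify_motion(negated), unname(flip[cls]))
  }
})

test_that("fixture tracks are classified to their ground-truth labels", {
  fx <- make_track_fixture("fig6b", seed = 7)
  expect_length(fx$tracks, 53)
  expect_true(all(vapply(fx$tracks, function(tr) length(tr$times), numeric(1)) == 61))
  cls <- vapply(fx$tracks, classify_motion, character(1))
  expect_identical(cls, fx$truth$label)
})

test_that("classification accuracy is 100% on 1,000 margin-separated tracks", {
  fx <- make_track_fixture("custom", seed = 99, n_confined = 334,
                           n_anterograde = 333, n_retrograde = 333)
  cls <- vapply(fx$tracks, classify_motion, character(1))
  expect_identical(cls, fx$truth$label)
})

test_that("motion fractions sum to 100 and handle degenerate compositions", {
  t <- 0:60
  one <- list(granule_track("a", t, 3 * t / 60))
  mf1 <- motion_fractions(one)
  expect_equal(mf1$percent[mf1$class == "anterograde"], 100)
  expect_equal(sum(mf1$percent_raw), 100)

  four <- list(granule_track("a", t, 3 * t / 60),
               granule_track("b", t, 3 * t / 60),
               granule_track("c", t, -3 * t / 60),
               granule_track("d", t, -3 * t / 60))
  mf4 <- motion_fractions(four)
  expect_equal(mf4$percent[mf4$class == "anterograde"], 50)
  expect_equal(mf4$percent[mf4$class == "retrograde"], 50)
  expect_error(motion_fractions(list()), ">= 1 track")
})

test_that("domain distribution yields per-bin fractions that sum to one", {
  counts <- data.frame(t_bin_s = c(0, 30, 60),
                       n_central = c(10, 382, 0),
                       n_peripheral = c(0, 118, 0))
  dd <- domain_distribution(counts)
  expect_equal(dd$fraction_peripheral[1], 0)
  expect_equal(dd$fraction_central[2], 0.764)
  expect_equal(dd$fraction_peripheral[2], 0.236)
  expect_true(is.na(dd$fraction_central[3]))
  expect_true(dd$empty[3])
  ok <- !dd$empty
  expect_equal(dd$fraction_central[ok] + dd$fraction_peripheral[ok],
               rep(1, sum(ok)))
})

test_that("contact-aligned fixtures show the programmed occupancy kinetics", {
  het <- make_domain_timecourse("heterotypic", seed = 3)
  dd <- domain_distribution(het$counts)
  late <- het$counts$t_bin_s >= 240
  expect_true(all(dd$fraction_peripheral[late] > het$truth$baseline))
  expect_true(all(abs(dd$fraction_peripheral - het$truth$occupancy) <= 0.03))

  hom <- make_domain_timecourse("homotypic", seed = 3)
  dh <- domain_distribution(hom$counts)
  expect_gt(max(dh$fraction_peripheral), hom$truth$baseline + 0.08)
  end <- hom$counts$t_bin_s >= 480
  expect_true(all(abs(dh$fraction_peripheral[end] - hom$truth$baseline) <= 0.03))
})

test_that("anterograde flux counts boundary crossings and normalizes to mean 1", {
  # one granule crossing the boundary once -> a single unit count in its bin
  tr <- list(granule_track("a", seq(0, 600, by = 10),
                           seq(-35, 26, length.out = 61)))
  fl <- anterograde_flux(tr, duration = 600, bin = 30)
  expect_equal(sum(fl$raw_count), 1)
  expect_equal(fl$t_bin_s[fl$raw_count == 1], 330)  # crosses 0 at t = 350 s
  expect_equal(mean(fl$normalized), 1)

  # constant crossings -> normalized identically 1
  mk_cross <- function(id, t0) granule_track(id, t0 + 0:20, seq(-10, 10, by = 1))
  trs <- unlist(lapply(seq(0, 570, by = 30), function(t0)
    list(mk_cross(paste0("a", t0), t0), mk_cross(paste0("b", t0), t0 + 2))),
    recursive = FALSE)
  fl2 <- anterograde_flux(trs, duration = 600, bin = 30)
  expect_true(all(fl2$raw_count == 2))
  expect_true(all(fl2$normalized == 1))

  # ramping crossings -> normalized nondecreasing, mean exactly 1
  ramp <- unlist(lapply(1:10, function(b) {
    lapply(seq_len(b), function(k)
      granule_track(sprintf("r%d_%d", b, k), (b - 1) * 60 + 0:30 * 0.5,
                    seq(-10, 5, length.out = 31)))
  }), recursive = FALSE)
  fl3 <- anterograde_flux(ramp, duration = 600, bin = 60)
  expect_true(all(diff(fl3$normalized) >= 0))
  expect_equal(mean(fl3$normalized), 1)

  # no crossings -> flagged undefined
  fl4 <- anterograde_flux(list(granule_track("s", 0:60, rep(-10, 61))),
                          duration = 600, bin = 30)
  expect_false(attr(fl4, "defined"))
  expect_true(all(is.na(fl4$normalized)))
})

test_that("track CSV I/O round-trips classifications", {
  fx <- make_track_fixture("custom", seed = 4, n_confined = 3,
                           n_anterograde = 3, n_retrograde = 3)
  f <- tempfile(fileext = ".csv")
  write_tracks_csv(fx$tracks, f)
  back <- read_tracks_csv(f)
  expect_length(back, 9)
  orig <- vapply(fx$tracks, classify_motion, character(1))
  names(orig) <- vapply(fx$tracks, function(x) x$granule_id, character(1))
  got <- vapply(back, classify_motion, character(1))
  expect_identical(got[names(orig)][order(names(orig))],
                   orig[order(names(orig))])
})
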