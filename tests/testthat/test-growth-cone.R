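test_that("domain partition erodes outlines and respects manual tracing", {
  circ <- circle_poly(5)
  p <- partition_domains(circ, erosion_um = 3)
  expect_lt(abs(p$central_area - pi * 4) / (pi * 4), 0.05)
  expect_equal(p$central_area + p$peripheral_area, p$outline_area)

  sq <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
  pm <- partition_domains(circ, central = sq, mode = "manual")
  expect_identical(pm$central, sq)

  star <- star_poly()
  ps <- partition_domains(star, erosion_um = 1.5)
  expect_equal(ps$peripheral_area, polygon_area(star) - ps$central_area)

  expect_error(partition_domains(sq, erosion_um = 3), "smaller erosion_um")
})

test_that("filopodia detection applies the inclusive 2-um threshold exactly", {
  # grid-exact rectangular geometry: 1.9 um is excluded, 2.0 um included
  expect_equal(nrow(detect_filopodia(rect_gc_mask(1.9), 0.1)), 0)
  f2 <- detect_filopodia(rect_gc_mask(2.0), 0.1)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$length_um, 2.0)
  # smooth body without protrusions
  g0 <- make_gc_mask(numeric(0), spike_angles_deg = numeric(0))
  expect_equal(nrow(detect_filopodia(g0$mask, 0.1)), 0)
  expect_error(detect_filopodia(matrix(0, 10, 10), 0.1), "empty")
})

test_that("programmed spikes are recovered with the right count and lengths", {
  lens <- c(0.8, 1.5, 2.0, 2.5, 3.0)
  g <- make_gc_mask(lens, spike_angles_deg = c(40, 130, 0, 220, 310))
  f <- detect_filopodia(g$mask, g$pixel_size)
  expect_equal(nrow(f), 3)
  expect_equal(sort(round(f$length_um, 1)), c(2.0, 2.5, 3.0), tolerance = 0.21)
  all_p <- attr(f, "all_protrusions")
  expect_equal(nrow(all_p), 5)
  expect_true(all(abs(sort(all_p$length_um) - sort(lens)) <= 0.2))
})

test_that("filopodium counts match programmed truth across 50 random fixtures", {
  for (sd in 0:49) {
    set.seed(sd)
    n_sp <- 2 + sd %% 4
    # lengths keep a margin from the 2-um boundary (sub-pixel rasterization
    # at arbitrary angles cannot resolve the boundary itself)
    lens <- ifelse(runif(n_sp) < 0.4, runif(n_sp, 0.6, 1.6), runif(n_sp, 2.4, 4))
    g <- make_gc_mask(lens, seed = sd)
    f <- detect_filopodia(g$mask, g$pixel_size)
    expect_equal(nrow(f), sum(lens >= 2))
  }
})

test_that("raising the length threshold never increases the count", {
  g <- make_gc_mask(c(1.2, 2.2, 2.6, 3.1, 3.8), seed = 17)
  counts <- vapply(seq(0.5, 4.5, by = 0.25), function(thr)
    nrow(detect_filopodia(g$mask, g$pixel_size, min_length_um = thr)),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("dynamics classification scores formation, retraction and stability", {
  n <- 60
  stable <- filopodium_trace("s", rep(3, n))
  formed <- filopodium_trace("f", c(rep(0, 12), rep(3, n - 12)))
  retracting <- filopodium_trace("r", c(seq(2, 6, by = 1), rep(6, 2),
                                        seq(5.5, 0, by = -0.5), rep(0, 41)))
  dyn <- classify_dynamics(list(stable, formed, retracting))
  expect_equal(dyn$n_stable, 1)
  expect_equal(dyn$n_formation, 1)
  expect_equal(dyn$n_retraction, 1)
  d <- dyn$detail
  expect_equal(d$lifetime_s[d$filopodium_id == "s"], 300)
  expect_equal(d$lifetime_s[d$filopodium_id == "f"], 240)
  # 2 -> 6 um over 20 s of growth
  expect_equal(d$elongation_speed[d$filopodium_id == "r"], 0.2)
  expect_equal(d$retraction_speed[d$filopodium_id == "r"], 0.1)
  expect_true(all(d$lifetime_s <= 300, na.rm = TRUE))
  expect_error(classify_dynamics(list(filopodium_trace("x", rep(3, 10)))),
               "missing frames")
})

test_that("dynamics classification matches generator event logs and trace order", {
  fx <- make_gc_sequence(seed = 5, n_filopodia = 6)
  dyn <- classify_dynamics(fx$traces)
  expect_equal(dyn$n_formation, sum(fx$truth$formation))
  expect_equal(dyn$n_retraction, sum(fx$truth$retraction))
  expect_equal(dyn$n_stable, sum(fx$truth$stable))
  d <- dyn$detail[match(fx$truth$filopodium_id, dyn$detail$filopodium_id), ]
  expect_equal(d$lifetime_s, fx$truth$lifetime_s)
  grows <- !is.na(d$elongation_speed) & fx$truth$type %in% c("formation", "transient")
  expect_true(all(abs(d$elongation_speed[grows] -
                        fx$truth$growth_speed[grows]) <= 0.02))
  # invariance to trace ordering
  dyn_rev <- classify_dynamics(rev(fx$traces))
  expect_equal(dyn_rev$n_formation, dyn$n_formation)
  expect_equal(dyn_rev$n_retraction, dyn$n_retraction)
  expect_equal(dyn_rev$n_stable, dyn$n_stable)
  expect_equal(sort(dyn_rev$lifetimes_s), sort(dyn$lifetimes_s))
})

test_that("ROI intensity subtracts a congruent background region", {
  img <- matrix(10, 100, 100)
  img[20:40, 20:40] <- 50
  reg <- cbind(c(2, 4, 4, 2), c(2, 2, 4, 4))
  bg <- cbind(c(6, 8, 8, 6), c(6, 6, 8, 8))
  ri <- roi_intensity(img, reg, bg, pixel_size = 0.1, label = "central")
  expect_equal(ri$mean_intensity, 40)
  expect_equal(roi_intensity(img, bg, cbind(c(6, 8, 8, 6), c(1, 1, 3, 3)),
                             pixel_size = 0.1)$mean_intensity, 0)
  expect_error(roi_intensity(img, reg, reg, pixel_size = 0.1), "overlap")
  # programmed offset over noise is recovered (negative values allowed)
  set.seed(8)
  img2 <- matrix(rnorm(1e4, 100, 5), 100, 100)
  img2[20:40, 20:40] <- img2[20:40, 20:40] + 25
  ri2 <- roi_intensity(img2, reg, bg, pixel_size = 0.1)
  expect_lt(abs(ri2$mean_intensity - 25), 2)
})

test_that("tip accumulation compares distal marker signal to the shaft", {
  g <- make_gc_mask(c(3, 4), seed = 1)
  f <- detect_filopodia(g$mask, g$pixel_size)
  uniform <- matrix(10, nrow(g$mask), ncol(g$mask))
  ta <- tip_accumulation(f, uniform, g$pixel_size)
  expect_true(all(!ta$enriched))
  # marker confined to the distal 1 um
  dmap <- attr(f, "distance_px") * g$pixel_size
  labels <- attr(f, "labels")
  tip_only <- matrix(0, nrow(g$mask), ncol(g$mask))
  for (i in seq_len(nrow(f))) {
    sel <- labels == f$filopodium_id[i] & is.finite(dmap)
    tip_only[sel & dmap >= max(dmap[sel]) - 1] <- 100
  }
  ta2 <- tip_accumulation(f, tip_only, g$pixel_size)
  expect_true(all(ta2$enriched))
  # programmed ratios 2.0 (enriched) and 1.2 (not) at factor 1.5
  for (r in c(2.0, 1.2)) {
    marker <- matrix(0, nrow(g$mask), ncol(g$mask))
    for (i in seq_len(nrow(f))) {
      sel <- labels == f$filopodium_id[i] & is.finite(dmap)
      marker[sel] <- 10
      marker[sel & dmap >= max(dmap[sel]) - 1] <- 10 * r
    }
    ta3 <- tip_accumulation(f, marker, g$pixel_size)
    expect_true(all(ta3$enriched == (r >= 1.5)))
  }
  expect_error(tip_accumulation(f, uniform, g$pixel_size, tip_um = 5),
               "shorter than the tip ROI")
})
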