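# Synthetic-data module: seeded generators for every input type the analysis
# modules consume, each with a machine-readable ground-truth record. Fixture
# compositions named after figures (e.g. 29/13/11 of 53 tracks) are minimal
# integer reconstructions of published summary percentages, not measured
# data; they are labeled as reconstructions in their truth records.

#' Synthetic two-channel optic-tract image
#'
#' Emulates a maximum-projection dual-dye tract image with two brachia as
#' Gaussian intensity bands across the tract. The ventral-dye channel is one
#' band at the ventral-brachium center. The dorsal-dye channel splits its
#' mass between the (correctly sorted) ventral-brachium band and the
#' (missorted) dorsal-brachium band in proportion `missorted_fraction`, so
#' the missorting index of the noiseless image equals `missorted_fraction`
#' by conservation of channel mass.
#'
#' @param missorted_fraction fraction of dorsal-dye mass in the dorsal
#'   brachium, in `[0, 1]`.
#' @param band_centers positions of the ventral and dorsal brachium centers
#'   along the reference line, um.
#' @param band_sigma Gaussian band width, um.
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#' @param seed integer seed.
#' @param pixel_size um/px.
#' @param width_um,height_um image extent, um.
#' @param amplitude peak band intensity.
#' @return list with `image` ([tract_image()]), `line` (full-width
#'   [reference_line()] at mid-height) and `truth` (fraction, band centers,
#'   inter-band midpoint in um).
#' @export
make_tract_image <- function(missorted_fraction, band_centers = c(30, 70),
                             band_sigma = 4, noise_sigma = 0, seed = 1,
                             pixel_size = 0.5, width_um = 100,
                             height_um = 60, amplitude = 100) {
  if (missorted_fraction < 0 || missorted_fraction > 1)
    abort("missorted_fraction must be in [0, 1]")
  if (abs(diff(band_centers)) < 2 * band_sigma)
    warning("brachium bands overlap within 2 sigma; automatic split may be ambiguous")
  nc <- round(width_um / pixel_size); nr <- round(height_um / pixel_size)
  x <- (seq_len(nc) - 0.5) * pixel_size
  band <- function(center) exp(-(x - center)^2 / (2 * band_sigma^2))
  f <- missorted_fraction
  dorsal_row <- amplitude * ((1 - f) * band(band_centers[1L]) +
                               f * band(band_centers[2L]))
  ventral_row <- amplitude * band(band_centers[1L])
  dorsal <- matrix(dorsal_row, nr, nc, byrow = TRUE)
  ventral <- matrix(ventral_row, nr, nc, byrow = TRUE)
  if (noise_sigma > 0) {
    with_seed(seed, {
      dorsal <- pmax(dorsal + matrix(rnorm(nr * nc, 0, noise_sigma), nr, nc), 0)
      ventral <- pmax(ventral + matrix(rnorm(nr * nc, 0, noise_sigma), nr, nc), 0)
    })
  }
  img <- tract_image(dorsal, ventral, pixel_size, orientation = "dorsal_high")
  mid_row <- round(nr / 2)
  list(image = img,
       line = reference_line(1, mid_row, nc, mid_row),
       truth = list(missorted_fraction = f, band_centers_um = band_centers,
                    midpoint_um = mean(band_centers),
                    noise_sigma = noise_sigma))
}

reflect_into <- function(x, lim) {
  # fold a random walk into [-lim, lim] (reflecting boundaries)
  while (any(abs(x) > lim)) {
    x <- ifelse(x > lim, 2 * lim - x, x)
    x <- ifelse(x < -lim, -2 * lim - x, x)
  }
  x
}

#' Synthetic RNP-granule tracks with ground-truth motion labels
#'
#' `profile = "fig6b"` builds the 53-track reconstruction of the published
#' motion-class composition: 29 confined tracks (reflected random walk, step
#' sd 0.2 um, excursion hard-clipped to 1.5 um), 13 retrograde (drift -0.05
#' um/s plus noise sd 0.05 um) and 11 anterograde (+0.05 um/s), each 61
#' samples at 1 Hz. Drift tracks reach 3 um net displacement and confined
#' tracks never exceed 1.5 um, so every track keeps at least a 0.5 um margin
#' from the 2 um decision boundary and the ground-truth labels are recovered
#' exactly for any seed. `profile = "custom"` builds `n_confined` /
#' `n_anterograde` / `n_retrograde` tracks with the same kinematics.
#'
#' @param profile `"fig6b"` or `"custom"`.
#' @param seed integer seed.
#' @param n_confined,n_anterograde,n_retrograde composition for
#'   `"custom"`.
#' @param duration track duration in s (default 60, sampled at 1 Hz).
#' @param drift_speed drift magnitude for directed tracks, um/s.
#' @param step_sigma confined random-walk step sd, um.
#' @param clip confined excursion clip, um.
#' @param noise_sigma positional noise sd for directed tracks, um.
#' @return list with `tracks` (list of [granule_track()]) and `truth`
#'   (data.frame `granule_id`, `label`; plus `reconstruction` flag).
#' @export
make_track_fixture <- function(profile = c("fig6b", "custom"), seed = 7,
                               n_confined = 10, n_anterograde = 10,
                               n_retrograde = 10, duration = 60,
                               drift_speed = 0.05, step_sigma = 0.2,
                               clip = 1.5, noise_sigma = 0.05) {
  profile <- match.arg(profile)
  if (profile == "fig6b") {
    n_confined <- 29L; n_retrograde <- 13L; n_anterograde <- 11L
  }
  t <- seq(0, duration, by = 1)
  comp <- c(rep("static_oscillatory", n_confined),
            rep("retrograde", n_retrograde),
            rep("anterograde", n_anterograde))
  tracks <- with_seed(seed, {
    order_ix <- sample.int(length(comp))
    labels <- comp[order_ix]
    lapply(seq_along(labels), function(i) {
      base <- runif(1, 5, 45)
      pos <- switch(labels[i],
        static_oscillatory = base + c(0, reflect_into(cumsum(rnorm(length(t) - 1L, 0, step_sigma)), clip)),
        anterograde = base + drift_speed * t + c(0, rnorm(length(t) - 1L, 0, noise_sigma)),
        retrograde = base - drift_speed * t + c(0, rnorm(length(t) - 1L, 0, noise_sigma)))
      granule_track(sprintf("g%02d", i), t, pos)
    })
  })
  labels <- with_seed(seed, comp[sample.int(length(comp))])
  list(tracks = tracks,
       truth = data.frame(
         granule_id = vapply(tracks, function(x) x$granule_id, character(1)),
         label = labels),
       reconstruction = profile == "fig6b")
}

# Largest-remainder apportionment of `total` items over quotas `q` (ties in
# the fractional remainders broken by seeded random order).
apportion <- function(q, total, seed) {
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- q - base
    ord <- with_seed(seed, order(frac, runif(length(q)), decreasing = TRUE))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    frac <- q - base
    ord <- with_seed(seed, order(frac, runif(length(q))))
    base[ord[seq_len(-rem)]] <- base[ord[seq_len(-rem)]] - 1L
  }
  as.integer(base)
}

#' Synthetic central/peripheral granule count time course
#'
#' Emulates per-30-s central/peripheral granule counts in a growth cone
#' aligned to a cell contact at T = 0. Baseline peripheral occupancy is
#' 0.236. A heterotypic contact steps the occupancy up to a sustained
#' plateau (0.45 from 3.5 min post-contact through the 10-min window); a
#' homotypic contact produces a transient elevation (0.37 around 3 min)
#' returning to baseline by 8 min. Per-bin peripheral counts are a
#' largest-remainder apportionment of the exact pooled composition — at
#' baseline, 118 peripheral of 500 granules, i.e. 76.4% central — so the
#' pooled fixture statistics are exact by construction (a reconstruction of
#' published pooled fractions, not sampled data).
#'
#' @param contact `"none"`, `"homotypic"` or `"heterotypic"`.
#' @param seed integer seed (breaks apportionment ties only).
#' @param granules_per_bin granules counted per 30-s bin (default 25).
#' @param bin_s bin width, s (default 30).
#' @param duration_s window length, s (default 600 = 10 min; 20 bins).
#' @param baseline baseline peripheral occupancy (default 0.236).
#' @return list with `counts` (data.frame `t_bin_s`, `n_central`,
#'   `n_peripheral`) and `truth` (per-bin programmed occupancy, contact
#'   type, pooled composition, `reconstruction` flag).
#' @export
make_domain_timecourse <- function(contact = c("none", "homotypic", "heterotypic"),
                                   seed = 3, granules_per_bin = 25,
                                   bin_s = 30, duration_s = 600,
                                   baseline = 0.236) {
  contact <- match.arg(contact)
  tb <- seq(0, duration_s - bin_s, by = bin_s)
  minutes <- tb / 60
  occ <- switch(contact,
    none = rep(baseline, length(tb)),
    heterotypic = ifelse(minutes < 1, baseline,
                         pmin(0.45, baseline + (0.45 - baseline) * (minutes - 1) / 2.5)),
    homotypic = {
      peak <- 0.37
      up <- baseline + (peak - baseline) * pmax(0, pmin(1, (minutes - 1) / 2))
      down <- peak - (peak - baseline) * pmax(0, pmin(1, (minutes - 3) / 5))
      ifelse(minutes < 3, up, pmax(baseline, down))
    })
  n_per <- apportion(occ * granules_per_bin,
                     round(sum(occ) * granules_per_bin), seed)
  counts <- data.frame(t_bin_s = tb,
                       n_central = as.integer(granules_per_bin - n_per),
                       n_peripheral = n_per)
  list(counts = counts,
       truth = list(contact = contact, occupancy = occ, t_bin_s = tb,
                    pooled_peripheral = sum(n_per),
                    pooled_total = granules_per_bin * length(tb),
                    baseline = baseline, reconstruction = TRUE))
}

# Rasterize a growth-cone body (ellipse) plus radial spikes.
draw_gc_mask <- function(spike_lengths, spike_angles, pixel_size,
                         body_radii = c(4, 2.5), spike_width = 0.4,
                         margin = NULL) {
  # integer-um margin keeps pixel centers on integer multiples of pixel_size,
  # so axis-aligned geometry is grid-stable regardless of spike lengths
  margin <- margin %||% ceiling(max(c(spike_lengths, 0)) + max(body_radii) + 1)
  half_px <- ceiling(margin / pixel_size)
  n <- 2L * half_px + 1L
  cx <- (half_px + 0.5) * pixel_size
  xs <- (seq_len(n) - 0.5) * pixel_size - cx
  X <- matrix(xs, n, n, byrow = TRUE)   # [row=y, col=x]
  Y <- matrix(xs, n, n, byrow = FALSE)
  mask <- (X / body_radii[1L])^2 + (Y / body_radii[2L])^2 <= 1
  for (k in seq_along(spike_lengths)) {
    L <- spike_lengths[k]
    if (L <= 0) next
    th <- spike_angles[k] * pi / 180
    b <- c(body_radii[1L] * cos(th), body_radii[2L] * sin(th))
    u <- c(cos(th), sin(th))
    a0 <- b - 0.5 * u          # start inside the body to guarantee attachment
    a1 <- b + L * u
    ab <- a1 - a0; len2 <- sum(ab^2)
    tpar <- ((X - a0[1L]) * ab[1L] + (Y - a0[2L]) * ab[2L]) / len2
    px <- a0[1L] + tpar * ab[1L]; py <- a0[2L] + tpar * ab[2L]
    dperp <- sqrt((X - px)^2 + (Y - py)^2)
    # squared-off tip: the protrusion ends exactly at length L from the body
    mask <- mask | (tpar >= 0 & tpar <= 1 & dperp <= spike_width / 2)
  }
  list(mask = mask * 1, center_px = c(half_px + 1L, half_px + 1L))
}

# Seeded spike angles with a minimum angular separation.
spaced_angles <- function(n, min_sep = 30) {
  angles <- numeric(0)
  tries <- 0
  while (length(angles) < n && tries < 10000) {
    cand <- runif(1, 0, 360)
    sep <- function(a, b) pmin(abs(a - b), 360 - abs(a - b))
    if (length(angles) == 0 || all(sep(cand, angles) >= min_sep))
      angles <- c(angles, cand)
    tries <- tries + 1
  }
  if (length(angles) < n) abort("could not place %d spikes with %g deg separation", n, min_sep)
  angles
}

#' Synthetic growth-cone mask with programmed protrusions
#'
#' One binary growth-cone frame: an elliptical body with straight radial
#' spikes of programmed lengths (measured outward from the body boundary) at
#' seeded, well-separated angles.
#'
#' Spike lengths are realized exactly for axis-aligned spikes (angles 0, 90,
#' 180, 270 degrees, where the body boundary falls on a pixel edge); at
#' arbitrary angles rasterization limits length accuracy to about one pixel,
#' so boundary-critical fixtures should use axis-aligned angles.
#'
#' @param spike_lengths_um vector of protrusion lengths, um.
#' @param seed integer seed (spike angles).
#' @param pixel_size um/px (default 0.1).
#' @param body_radii_um ellipse semi-axes, um.
#' @param spike_width_um protrusion width, um.
#' @param spike_angles_deg optional explicit spike angles; default seeded
#'   random angles with at least 30 degrees separation.
#' @return list with `mask` (binary matrix), `pixel_size`, and `truth`
#'   (data.frame `length_um`, `angle_deg`).
#' @export
make_gc_mask <- function(spike_lengths_um, seed = 0, pixel_size = 0.1,
                         body_radii_um = c(4, 2.5), spike_width_um = 0.4,
                         spike_angles_deg = NULL) {
  angles <- spike_angles_deg %||%
    with_seed(seed, spaced_angles(length(spike_lengths_um)))
  if (length(angles) != length(spike_lengths_um))
    abort("spike_angles_deg must match spike_lengths_um in length")
  g <- draw_gc_mask(spike_lengths_um, angles, pixel_size,
                    body_radii = body_radii_um, spike_width = spike_width_um)
  list(mask = g$mask, pixel_size = pixel_size,
       truth = data.frame(length_um = spike_lengths_um, angle_deg = angles))
}

#' Synthetic filopodia length traces with a scripted event log
#'
#' Builds per-frame length traces for a 5-min recording sampled every 5 s
#' from an event schedule, together with the ground-truth event log
#' (formation/retraction/stable calls, lifetimes and active-phase speeds
#' derived from the schedule). Optionally renders the corresponding binary
#' mask stack.
#'
#' @param schedule data.frame with columns `filopodium_id`, `type` (one of
#'   `"stable"`, `"formation"`, `"retraction"`, `"transient"`), `max_len`
#'   (um), `growth_speed`, `retract_speed` (um/s), `t_start` (s; growth
#'   onset for formation/transient, retraction onset for retraction).
#'   `NULL` builds a seeded random schedule of `n_filopodia` events.
#' @param n_filopodia number of filopodia when `schedule` is `NULL`.
#' @param seed integer seed.
#' @param recording recording length, s (default 300).
#' @param frame_interval sampling interval, s (default 5).
#' @param render if `TRUE`, also return a binary mask stack (`[y, x, frame]`)
#'   with the traced lengths as radial spikes.
#' @param pixel_size um/px for rendering.
#' @return list with `traces` (list of [filopodium_trace()]), `truth`
#'   (event log data.frame) and optionally `masks`.
#' @export
make_gc_sequence <- function(schedule = NULL, n_filopodia = 4, seed = 5,
                             recording = 300, frame_interval = 5,
                             render = FALSE, pixel_size = 0.1) {
  n_frames <- round(recording / frame_interval)
  if (is.null(schedule)) {
    schedule <- with_seed(seed, {
      types <- sample(c("stable", "formation", "retraction", "transient"),
                      n_filopodia, replace = TRUE)
      max_len <- runif(n_filopodia, 3.5, 5)
      # speeds quantized so growth/retraction spans a whole number of frames:
      # ramps then hit their extremes exactly on the sampling grid and
      # active-phase speeds are recovered without partial-step bias
      g_steps <- sample(4:8, n_filopodia, replace = TRUE)
      r_steps <- sample(4:8, n_filopodia, replace = TRUE)
      data.frame(filopodium_id = sprintf("f%02d", seq_len(n_filopodia)),
                 type = types,
                 max_len = max_len,
                 growth_speed = max_len / (frame_interval * g_steps),
                 retract_speed = max_len / (frame_interval * r_steps),
                 t_start = frame_interval * sample(5:20, n_filopodia, replace = TRUE))
    })
  }
  times <- frame_interval * (seq_len(n_frames) - 1L)
  build <- function(row) {
    L <- row$max_len
    up <- row$growth_speed; down <- row$retract_speed
    switch(row$type,
      stable = rep(L, n_frames),
      formation = pmin(L, pmax(0, (times - row$t_start) * up)),
      retraction = pmin(L, pmax(0, L - pmax(0, times - row$t_start) * down)),
      transient = {
        g <- pmin(L, pmax(0, (times - row$t_start) * up))
        t_peak <- row$t_start + L / up
        pmax(0, pmin(g, L - pmax(0, times - t_peak - 2 * frame_interval) * down))
      },
      abort("unknown schedule type %s", row$type))
  }
  traces <- lapply(seq_len(nrow(schedule)), function(i) {
    filopodium_trace(schedule$filopodium_id[i], build(schedule[i, ]),
                     frame_interval)
  })
  truth <- do.call(rbind, lapply(seq_len(nrow(schedule)), function(i) {
    lens <- traces[[i]]$lengths
    present <- lens >= 2
    data.frame(filopodium_id = schedule$filopodium_id[i],
               type = schedule$type[i],
               formation = schedule$type[i] %in% c("formation", "transient"),
               retraction = schedule$type[i] %in% c("retraction", "transient"),
               stable = schedule$type[i] == "stable",
               lifetime_s = sum(present) * frame_interval,
               growth_speed = schedule$growth_speed[i],
               retract_speed = schedule$retract_speed[i])
  }))
  out <- list(traces = traces, truth = truth, schedule = schedule)
  if (render) {
    angles <- with_seed(seed, spaced_angles(nrow(schedule)))
    canvas <- ceiling(max(c(schedule$max_len, 0)) + 5)
    frames <- lapply(seq_len(n_frames), function(fi) {
      lens <- vapply(traces, function(tr) tr$lengths[fi], numeric(1))
      draw_gc_mask(lens, angles, pixel_size, margin = canvas)$mask
    })
    out$masks <- array(unlist(frames),
                       dim = c(nrow(frames[[1L]]), ncol(frames[[1L]]), n_frames))
    out$pixel_size <- pixel_size
  }
  out
}

# --- encounter generator ---------------------------------------------------

rigid_transform <- function(xy, angle_deg, shift) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  sweep(as.matrix(xy) %*% t(R), 2L, -shift)
}

# Canonical encounter geometries in a local frame: target path along the
# x axis, contact at T = 0 near the origin, frames every 30 s.
canonical_encounter <- function(class) {
  dt <- 30
  pre_t <- seq(-300, 0, by = dt)
  post_t <- seq(dt, 2700, by = dt)
  lin <- function(from, to, tt) {
    s <- (tt - tt[1L]) / (tt[length(tt)] - tt[1L])
    cbind(from[1L] + s * (to[1L] - from[1L]), from[2L] + s * (to[2L] - from[2L]))
  }
  path <- cbind(seq(-60, 60, by = 10), 0)
  contacts <- data.frame(filopodium_id = integer(), start = numeric(),
                         end = numeric())
  if (class == "fasciculation") {
    pre <- lin(c(-15, -15.3), c(0, -0.3), pre_t)
    post <- lin(c(0.33, -0.3), c(30, -0.3), post_t)
    contacts <- data.frame(filopodium_id = 1L, start = 0, end = 300)
  } else if (class == "crossing") {
    u <- c(cos(pi / 3), sin(pi / 3))
    pre <- lin(c(-10 * u[1L], -0.5 - 10 * u[2L]), c(0, -0.5), pre_t)
    post <- lin(c(0.2 * u[1L], -0.5 + 0.2 * u[2L]),
                c(20 * u[1L], -0.5 + 20 * u[2L]), post_t)
    contacts <- data.frame(filopodium_id = 1L, start = 0, end = 60)
  } else if (class == "tracking") {
    pre <- lin(c(-8, -11.5), c(0, -2), pre_t)
    post <- lin(c(0.28, -2), c(25, -2), post_t)
    contacts <- data.frame(filopodium_id = 1:4,
                           start = c(0, 240, 600, 1200),
                           end = c(120, 420, 900, 1500))
  } else if (class == "retraction") {
    pre <- lin(c(-10, -11), c(0, -1), pre_t)
    post <- lin(c(-0.15, -1.15), c(-12, -13), post_t)
    contacts <- data.frame(filopodium_id = 1L, start = 0, end = 90)
  } else if (class == "stalling") {
    pre <- lin(c(-10, -11.5), c(0, -1.5), pre_t)
    wob <- 0.3 * sin(seq_along(post_t))
    post <- cbind(wob, -1.5 + 0.3 * cos(seq_along(post_t)))
    contacts <- data.frame(filopodium_id = 1L, start = 0, end = 120)
  } else abort("unknown canonical class %s", class)
  list(t = c(pre_t, post_t), xy = rbind(pre, post), path = path,
       contacts = contacts)
}

make_one_encounter <- function(class, origin = NA_character_) {
  g <- canonical_encounter(class)
  angle <- runif(1, 0, 360)
  shift <- runif(2, -50, 50)
  traj <- rigid_transform(g$xy, angle, shift)
  path <- rigid_transform(g$path, angle, shift)
  encounter_event(data.frame(t = g$t, x = traj[, 1L], y = traj[, 2L]),
                  path, contact_time = 0, contacts = g$contacts,
                  observation_end = max(g$t), origin = origin)
}

#' Synthetic encounter events with ground-truth behavior labels
#'
#' Canonical parametric trajectories for each behavior class (target path
#' along a straight axon, contact at T = 0, frames every 30 s, 45-min
#' post-contact observation), placed under a seeded random rigid transform.
#' Every geometry keeps a clear margin from all classifier decision
#' thresholds, so ground-truth labels are recovered exactly for any seed.
#'
#' Named fixtures are integer reconstructions of published compositions:
#' `"fig2c"` is 23 events (11 fasciculation, 7 crossing, 5 tracking);
#' `"fig2i_homo"` is 100 homotypic events (51 fasciculation, 43 crossing, 3
#' stalling, 3 retraction).
#'
#' @param profile one behavior class name, `"fig2c"`, or `"fig2i_homo"`.
#' @param seed integer seed.
#' @return for a class name: list with `event` and `truth`; for a fixture:
#'   list with `events` (list), `truth` (data.frame `event`, `label`) and
#'   `reconstruction = TRUE`.
#' @export
make_encounter <- function(profile, seed = 0) {
  single <- profile %in% BEHAVIOR_CLASSES
  if (single) {
    ev <- with_seed(seed, make_one_encounter(profile))
    return(list(event = ev, truth = list(label = profile)))
  }
  comp <- switch(profile,
    fig2c = c(rep("fasciculation", 11), rep("crossing", 7), rep("tracking", 5)),
    fig2i_homo = c(rep("fasciculation", 51), rep("crossing", 43),
                   rep("stalling", 3), rep("retraction", 3)),
    abort("unknown encounter profile '%s' (use one of %s, fig2c, fig2i_homo)",
          profile, paste(BEHAVIOR_CLASSES, collapse = ", ")))
  origins <- if (profile == "fig2i_homo") {
    rep(c("D->D", "V->V"), length.out = length(comp))
  } else rep(NA_character_, length(comp))
  events <- with_seed(seed, {
    ord <- sample.int(length(comp))
    lapply(ord, function(i) make_one_encounter(comp[i], origins[i]))
  })
  labels <- with_seed(seed, comp[sample.int(length(comp))])
  list(events = events,
       truth = data.frame(event = seq_along(events), label = labels),
       reconstruction = TRUE)
}

#' Synthetic puncta pair fixture with a programmed association fraction
#'
#' Channel-B granules are laid out along an axon shaft; `associated`
#' channel-A puncta are placed within `radius / 2` of a B granule and the
#' remaining `n - associated` at more than twice the radius from every B
#' granule, so the association fraction at `radius` equals
#' `associated / n` exactly for any seed.
#'
#' @param n number of channel-A puncta.
#' @param associated number of them associated (default 84 of 100, the
#'   published-composition reconstruction).
#' @param radius association radius, um (default 0.5).
#' @param seed integer seed.
#' @return list with `setA`, `setB` (data.frames `id`, `x_um`, `y_um`) and
#'   `truth` (`associated` logical vector, programmed fraction,
#'   `reconstruction` flag).
#' @export
make_puncta_fixture <- function(n = 100, associated = 84, radius = 0.5,
                                seed = 13) {
  if (associated < 0 || associated > n)
    abort("associated must be between 0 and n")
  with_seed(seed, {
    xb <- seq(2, by = 2.5 * radius + 2, length.out = n)
    setB <- data.frame(id = seq_len(n), x_um = xb,
                       y_um = rnorm(n, 0, 0.05))
    is_assoc <- seq_len(n) <= associated
    r <- runif(n, 0, radius / 2)
    th <- runif(n, 0, 2 * pi)
    xa <- ifelse(is_assoc, setB$x_um + r * cos(th), setB$x_um)
    ya <- ifelse(is_assoc, setB$y_um + r * sin(th),
                 setB$y_um + 2.5 * radius + runif(n, 0.5, 1.5))
    setA <- data.frame(id = seq_len(n), x_um = xa, y_um = ya)
    list(setA = setA, setB = setB,
         truth = list(associated = is_assoc, fraction = associated / n,
                      radius = radius, reconstruction = TRUE))
  })
}
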