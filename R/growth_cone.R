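# Growth-cone morphometrics: central/peripheral domain partition, filopodia
# detection on binary masks, filopodia dynamics (formation / retraction /
# stable, lifetimes, speeds), background-corrected ROI intensities, and
# marker tip-accumulation calls.

#' Partition a growth-cone outline into central and peripheral domains
#'
#' Manual mode returns the supplied central-domain polygon unchanged
#' (manually traced domains always take precedence). Auto mode is a stand-in
#' for manual tracing: the central domain is the outline eroded by
#' `erosion_um` (computed by rasterizing the polygon and applying a disc
#' erosion), and the peripheral domain is the remainder of the outline.
#'
#' @param outline closed, simple polygon (n x 2 matrix, um).
#' @param central optional manually traced central-domain polygon.
#' @param mode `"manual"` or `"auto"`.
#' @param erosion_um erosion depth in um for auto mode (default 3).
#' @param res raster resolution in um/px for auto mode (default 0.05).
#' @return list with `central` (polygon), `central_area`, `peripheral_area`,
#'   `outline_area` (um^2; peripheral = outline - central by construction)
#'   and `mode`.
#' @export
partition_domains <- function(outline, central = NULL,
                              mode = c("auto", "manual"),
                              erosion_um = 3, res = 0.05) {
  mode <- match.arg(mode)
  outline <- as_poly(outline, "outline")
  if (mode == "manual") {
    if (is.null(central)) abort("manual mode requires a central polygon")
    central <- as_poly(central, "central")
    if (!all(point_in_polygon(central, outline, boundary_tol = 1e-6)))
      abort("central domain must lie inside the outline")
  } else {
    stopifnot_scalar_num(erosion_um, "erosion_um", positive = TRUE)
    r <- rasterize_polygon(outline, res = res, pad = 2 * res)
    radius_px <- round(erosion_um / res)
    brush <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
    eroded <- EBImage::erode(r$mask, brush)
    if (sum(eroded) == 0)
      abort("erosion by %g um annihilates the outline; use a smaller erosion_um",
            erosion_um)
    central <- mask_to_polygon(eroded, r$origin, r$res)
  }
  oa <- polygon_area(outline)
  ca <- polygon_area(central)
  list(central = central, central_area = ca, peripheral_area = oa - ca,
       outline_area = oa, mode = mode)
}

shift_mat <- function(m, dy, dx, fill = Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

# Geodesic distance in pixels from a source set, propagated only through
# `mask` pixels. Uses a 16-neighborhood (unit, diagonal and knight moves
# with Euclidean weights), which tracks true Euclidean arc length to within
# ~3% at any orientation.
geodesic_distance <- function(mask, source) {
  d <- matrix(Inf, nrow(mask), ncol(mask))
  d[source] <- 0
  steps <- expand.grid(dy = -2:2, dx = -2:2)
  keep <- !(steps$dy == 0 & steps$dx == 0) & (abs(steps$dy) + abs(steps$dx) <= 3)
  steps <- steps[keep, ]
  w <- sqrt(steps$dy^2 + steps$dx^2)
  repeat {
    d_old <- d
    for (k in seq_len(nrow(steps))) {
      cand <- shift_mat(d, steps$dy[k], steps$dx[k]) + w[k]
      upd <- mask & cand < d
      d[upd] <- cand[upd]
    }
    if (identical(d, d_old)) break
  }
  d
}

#' Detect filopodia on a binary growth-cone mask
#'
#' A protrusion is a connected component of the mask minus its morphological
#' opening by a disc of radius `r_open_um` (the opening removes thin
#' protrusions and leaves the growth-cone body). The length of a protrusion
#' is the geodesic distance from the body to its tip, computed by chamfer
#' propagation within the protrusion. A protrusion counts as a filopodium if
#' its length is at least `min_length_um` (2 um, inclusive).
#'
#' @param mask binary matrix (`[row = y, col = x]`), nonzero = growth cone.
#' @param pixel_size um per pixel.
#' @param r_open_um opening radius in um (default 0.6); must exceed half the
#'   filopodium width and stay below half the body width.
#' @param min_length_um length threshold in um (default 2, inclusive).
#' @return data.frame with one row per filopodium: `filopodium_id`,
#'   `length_um`, `n_px`, `tip_x`, `tip_y`, `base_x`, `base_y` (pixel
#'   coordinates). All candidate protrusions (including sub-threshold ones)
#'   are kept in attribute `"all_protrusions"`; the geodesic distance map is
#'   kept in attribute `"distance_px"` for downstream tip analysis.
#' @export
detect_filopodia <- function(mask, pixel_size, r_open_um = 0.6,
                             min_length_um = 2.0) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) abort("mask is empty")
  stopifnot_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  radius_px <- max(1L, round(r_open_um / pixel_size))
  brush <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
  body <- EBImage::opening(mask * 1, brush) > 0
  prot <- mask & !body
  labels <- EBImage::bwlabel(prot * 1)
  dmap <- geodesic_distance(mask, body)
  # Euclidean distance to the body, used for the reported length: the tip is
  # located geodesically, but its distance is read from the Euclidean
  # transform so that center-to-center pixel offsets cancel (exact for
  # straight protrusions; a lower bound for strongly curved ones).
  edist <- t(as.matrix(EBImage::distmap(t((!body) * 1), metric = "euclidean")))
  rows <- list()
  ids <- seq_len(max(labels))
  for (id in ids) {
    px <- which(labels == id, arr.ind = TRUE)
    if (nrow(px) < 2L) next
    dd <- dmap[px]
    if (!any(is.finite(dd))) next  # detached speck, not a protrusion
    tip <- px[which.max(ifelse(is.finite(dd), dd, -Inf)), ]
    base <- px[which.min(ifelse(is.finite(dd), dd, Inf)), ]
    len <- edist[tip[1L], tip[2L]] * pixel_size
    rows[[length(rows) + 1L]] <- data.frame(
      filopodium_id = id, length_um = len, n_px = nrow(px),
      tip_x = unname(tip["col"]), tip_y = unname(tip["row"]),
      base_x = unname(base["col"]), base_y = unname(base["row"]))
  }
  all_prot <- if (length(rows)) do.call(rbind, rows) else
    data.frame(filopodium_id = integer(), length_um = numeric(),
               n_px = integer(), tip_x = integer(), tip_y = integer(),
               base_x = integer(), base_y = integer())
  out <- all_prot[all_prot$length_um >= min_length_um, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_protrusions") <- all_prot
  attr(out, "distance_px") <- dmap
  attr(out, "labels") <- labels
  out
}

#' Per-frame length trace of one filopodium
#'
#' @param filopodium_id identifier.
#' @param lengths length in um at each frame of the recording (0 when the
#'   protrusion is absent).
#' @param frame_interval sampling interval in s (default 5).
#' @return object of class `filopodium_trace` with `frames` (0-based) and
#'   `times`.
#' @export
filopodium_trace <- function(filopodium_id, lengths, frame_interval = 5) {
  if (any(lengths < 0)) abort("trace %s: lengths must be >= 0", filopodium_id)
  structure(list(filopodium_id = filopodium_id, lengths = as.numeric(lengths),
                 frames = seq_along(lengths) - 1L,
                 frame_interval = frame_interval),
            class = "filopodium_trace")
}

# Mean rate over the maximal monotone run ending at index `end` going
# backward (strictly increasing if dir > 0, strictly decreasing if dir < 0).
# Plateaus break the run, so only active-phase intervals contribute.
active_phase_speed <- function(lengths, end, dir, interval) {
  s <- end
  while (s > 1L && sign(lengths[s] - lengths[s - 1L]) == dir) s <- s - 1L
  if (s == end) return(NA_real_)
  mean(abs(diff(lengths[s:end]))) / interval
}

#' Classify filopodia dynamics over a recording
#'
#' Scores each per-frame length trace over a 5-min style recording sampled
#' every 5 s. A filopodium is *present* in a frame when its length is at
#' least `threshold` (2 um). Events: *formation* if the first present frame
#' is after frame 0; *retraction* if it drops below the threshold and never
#' returns within the recording ("completely retracted"); *stable* if present
#' in every frame. One trace can count as both formation and retraction.
#' Lifetime is the total time the length stayed at or above the threshold.
#' Elongation speed is the mean per-interval rate over the monotone growth
#' run ending at the maximum length; retraction speed is the analogous rate
#' down to below the threshold (plateaus excluded: active phases only).
#'
#' @param traces list of [filopodium_trace()].
#' @param recording recording duration in s (default 300).
#' @param frame_interval sampling interval in s (default 5).
#' @param threshold presence threshold in um (default 2).
#' @return list of class `dynamics_summary`: counts `n_formation`,
#'   `n_retraction`, `n_stable`, vectors `lifetimes_s`,
#'   `elongation_speeds`, `retraction_speeds` (um/s), and a per-trace
#'   data.frame `detail`.
#' @export
classify_dynamics <- function(traces, recording = 300, frame_interval = 5,
                              threshold = 2.0) {
  n_frames <- round(recording / frame_interval)
  detail <- lapply(traces, function(tr) {
    if (!inherits(tr, "filopodium_trace")) abort("traces must be filopodium_trace objects")
    if (abs(tr$frame_interval - frame_interval) > 1e-6)
      warning(sprintf("trace %s sampled at %g s, expected %g s",
                      tr$filopodium_id, tr$frame_interval, frame_interval))
    if (length(tr$lengths) != n_frames)
      abort("trace %s: expected %d frames (%g s at %g s), got %d — missing frames",
            tr$filopodium_id, n_frames, recording, frame_interval,
            length(tr$lengths))
    present <- tr$lengths >= threshold
    ever <- any(present)
    formation <- ever && !present[1L]
    retraction <- ever && !present[n_frames]
    stable <- all(present)
    lifetime <- sum(present) * frame_interval
    el <- re <- NA_real_
    if (ever) {
      m <- which.max(tr$lengths)
      el <- active_phase_speed(tr$lengths, m, dir = 1, interval = frame_interval)
      below <- which(seq_along(present) > m & !present)
      if (length(below))
        re <- active_phase_speed(tr$lengths, below[1L], dir = -1,
                                 interval = frame_interval)
    }
    data.frame(filopodium_id = tr$filopodium_id, ever_present = ever,
               formation = formation, retraction = retraction,
               stable = stable, lifetime_s = if (ever) lifetime else NA_real_,
               elongation_speed = el, retraction_speed = re)
  })
  detail <- do.call(rbind, detail)
  structure(list(
    n_formation = sum(detail$formation),
    n_retraction = sum(detail$retraction),
    n_stable = sum(detail$stable),
    lifetimes_s = detail$lifetime_s[detail$ever_present],
    elongation_speeds = detail$elongation_speed[!is.na(detail$elongation_speed)],
    retraction_speeds = detail$retraction_speed[!is.na(detail$retraction_speed)],
    detail = detail), class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("filopodia dynamics: %d formation, %d retraction, %d stable; median lifetime %.0f s\n",
              x$n_formation, x$n_retraction, x$n_stable,
              median(x$lifetimes_s)))
  invisible(x)
}

#' Background-corrected mean intensity of a region of interest
#'
#' The mean intensity inside the region minus the mean inside a congruent
#' background ROI placed in an adjacent signal-free area. Negative corrected
#' values are reported, never clipped.
#'
#' @param image intensity matrix (`[row = y, col = x]`).
#' @param region polygon (um) of the measured region.
#' @param background_roi polygon (um) of the background region; must not
#'   overlap `region`.
#' @param pixel_size um per pixel.
#' @param label region label (e.g. `"central"`, `"peripheral"`,
#'   `"shaft_last_10um"`, `"global"`).
#' @return list with `label`, `mean_intensity` (corrected), `mean_raw`,
#'   `mean_background`, `n_px`.
#' @export
roi_intensity <- function(image, region, background_roi, pixel_size,
                          label = "global") {
  image <- as.matrix(image)
  centers <- cbind(
    x = rep((seq_len(ncol(image)) - 0.5) * pixel_size, each = nrow(image)),
    y = rep((seq_len(nrow(image)) - 0.5) * pixel_size, times = ncol(image)))
  in_r <- point_in_polygon(centers, region)
  in_b <- point_in_polygon(centers, background_roi)
  if (any(in_r & in_b)) abort("region and background ROI overlap")
  if (!any(in_r) || !any(in_b))
    abort("region or background ROI contains no pixels")
  mr <- mean(image[in_r]); mb <- mean(image[in_b])
  list(label = label, mean_intensity = mr - mb, mean_raw = mr,
       mean_background = mb, n_px = sum(in_r))
}

#' Marker accumulation at filopodium tips
#'
#' For each detected filopodium, the tip ROI is the distal `tip_um` of the
#' protrusion (pixels whose geodesic distance from the body is within
#' `tip_um` of the tip). The filopodium is called *enriched* in a frame when
#' the mean marker intensity in the tip ROI is at least `enrichment_factor`
#' times the mean over the rest of the protrusion. The factor and tip size
#' are operational choices, surfaced here and echoed in the output.
#'
#' @param filo result of [detect_filopodia()] for one frame.
#' @param marker marker-channel intensity matrix, same shape as the mask.
#' @param pixel_size um per pixel.
#' @param enrichment_factor ratio threshold (default 1.5).
#' @param tip_um tip ROI depth in um (default 1).
#' @return data.frame: `filopodium_id`, `mean_tip`, `mean_shaft`, `ratio`,
#'   `enriched`; attributes `enrichment_factor`, `tip_um`.
#' @export
tip_accumulation <- function(filo, marker, pixel_size,
                             enrichment_factor = 1.5, tip_um = 1.0) {
  dmap <- attr(filo, "distance_px")
  labels <- attr(filo, "labels")
  if (is.null(dmap) || is.null(labels))
    abort("filo must be the unmodified result of detect_filopodia()")
  marker <- as.matrix(marker)
  rows <- lapply(seq_len(nrow(filo)), function(i) {
    id <- filo$filopodium_id[i]
    if (filo$length_um[i] <= tip_um)
      abort("filopodium %s (%.2f um) is shorter than the tip ROI (%g um)",
            id, filo$length_um[i], tip_um)
    sel <- labels == id & is.finite(dmap)
    d_um <- dmap * pixel_size
    tip_sel <- sel & d_um >= (max(d_um[sel]) - tip_um)
    shaft_sel <- sel & !tip_sel
    mt <- mean(marker[tip_sel]); ms <- mean(marker[shaft_sel])
    ratio <- if (ms > 0) mt / ms else Inf
    data.frame(filopodium_id = id, mean_tip = mt, mean_shaft = ms,
               ratio = ratio, enriched = ratio >= enrichment_factor)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(filopodium_id = integer(), mean_tip = numeric(),
               mean_shaft = numeric(), ratio = numeric(), enriched = logical())
  attr(out, "enrichment_factor") <- enrichment_factor
  attr(out, "tip_um") <- tip_um
  out
}
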