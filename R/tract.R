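# Tract-sorting module: dual-dye intensity profiles across the optic tract
# and the missorting index MI = Dm / (Dm + Ds).

#' Two-channel optic-tract image
#'
#' Container for a maximum-projection, two-channel tract image: one channel
#' for the dorsal-retina dye (DiI-style) and one for the ventral-retina dye
#' (DiO-style). Image matrices are indexed `[row, col]` with pixel centers at
#' integer pixel coordinates `(x = col, y = row)`.
#'
#' @param dorsal,ventral numeric matrices of identical dimension,
#'   nonnegative intensities.
#' @param pixel_size pixel size in um/pixel.
#' @param orientation `"dorsal_high"` if the dorsal brachium lies at larger
#'   positions along the reference line, `"dorsal_low"` otherwise.
#' @return an object of class `tract_image`.
#' @export
tract_image <- function(dorsal, ventral, pixel_size,
                        orientation = c("dorsal_high", "dorsal_low")) {
  orientation <- match.arg(orientation)
  dorsal <- as.matrix(dorsal); ventral <- as.matrix(ventral)
  if (!identical(dim(dorsal), dim(ventral)))
    abort("dorsal and ventral channels must have the same shape (%s vs %s)",
          paste(dim(dorsal), collapse = "x"), paste(dim(ventral), collapse = "x"))
  stopifnot_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  if (min(dorsal) < 0 || min(ventral) < 0)
    abort("intensities must be nonnegative")
  structure(list(dorsal = dorsal, ventral = ventral,
                 pixel_size = pixel_size, orientation = orientation),
            class = "tract_image")
}

#' @export
print.tract_image <- function(x, ...) {
  cat(sprintf("tract_image: %d x %d px, %.3g um/px, orientation %s\n",
              nrow(x$dorsal), ncol(x$dorsal), x$pixel_size, x$orientation))
  invisible(x)
}

#' Reference line across the tract
#'
#' The measurement line drawn perpendicular to the tract, spanning the full
#' tract width (both brachia), conventionally 70 um from the chiasm.
#'
#' @param x1,y1,x2,y2 endpoints in pixel coordinates.
#' @param offset_from_chiasm distance of the line from the chiasm in um
#'   (metadata only; default 70).
#' @return an object of class `reference_line`.
#' @export
reference_line <- function(x1, y1, x2, y2, offset_from_chiasm = 70) {
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (!is.finite(len) || len <= 0) abort("reference line must have length > 0")
  structure(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                 offset_from_chiasm = offset_from_chiasm),
            class = "reference_line")
}

# Bilinear interpolation of matrix `m` (pixel centers at integer coords) at
# points (x, y); points must lie within [1, ncol] x [1, nrow].
bilinear <- function(m, x, y) {
  x0 <- pmin(pmax(floor(x), 1L), ncol(m) - 1L)
  y0 <- pmin(pmax(floor(y), 1L), nrow(m) - 1L)
  fx <- x - x0; fy <- y - y0
  idx <- function(r, c) m[cbind(r, c)]
  idx(y0, x0) * (1 - fx) * (1 - fy) +
    idx(y0, x0 + 1L) * fx * (1 - fy) +
    idx(y0 + 1L, x0) * (1 - fx) * fy +
    idx(y0 + 1L, x0 + 1L) * fx * fy
}

#' Extract a dual-channel intensity profile along a reference line
#'
#' Samples both channels by bilinear interpolation at 0.5-pixel steps along
#' the line (so sample spacing never exceeds one pixel).
#'
#' @param image a [tract_image()].
#' @param line a [reference_line()].
#' @return an `intensity_profile`: data.frame with columns `position_um`
#'   (strictly increasing, from the line start), `dorsal`, `ventral`; carries
#'   the image orientation as attribute `orientation`.
#' @export
extract_profile <- function(image, line) {
  if (!inherits(image, "tract_image")) abort("image must be a tract_image")
  if (!inherits(line, "reference_line")) abort("line must be a reference_line")
  nr <- nrow(image$dorsal); nc <- ncol(image$dorsal)
  for (end in list(c("start", line$x1, line$y1), c("end", line$x2, line$y2))) {
    x <- as.numeric(end[2L]); y <- as.numeric(end[3L])
    if (x < 1 || x > nc || y < 1 || y > nr)
      abort("reference line %s point (%.1f, %.1f) lies outside the image (%d x %d px)",
            end[1L], x, y, nc, nr)
  }
  len_px <- sqrt((line$x2 - line$x1)^2 + (line$y2 - line$y1)^2)
  n <- max(2L, ceiling(len_px / 0.5) + 1L)
  t <- seq(0, 1, length.out = n)
  xs <- line$x1 + t * (line$x2 - line$x1)
  ys <- line$y1 + t * (line$y2 - line$y1)
  prof <- data.frame(
    position_um = t * len_px * image$pixel_size,
    dorsal = bilinear(image$dorsal, xs, ys),
    ventral = bilinear(image$ventral, xs, ys)
  )
  attr(prof, "orientation") <- image$orientation
  class(prof) <- c("intensity_profile", "data.frame")
  prof
}

# Simple centered running mean with edge shrinkage; window in samples (odd).
running_mean <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- k %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Two dominant peaks of a smoothed profile: the global maximum plus the
# largest sample separated from it by a prominent valley (the running
# minimum between them must drop below half the smaller of the two).
# Returns NULL when no second peak qualifies.
two_peaks <- function(pos, sm) {
  n <- length(sm)
  i1 <- which.max(sm)
  valley <- rep(Inf, n)
  if (i1 < n) valley[(i1 + 1L):n] <- cummin(sm[i1:(n - 1L)])
  if (i1 > 1L) valley[(i1 - 1L):1L] <- cummin(sm[i1:2L])
  ok <- which(sm > 0 & valley <= 0.5 * pmin(sm, sm[i1]))
  if (length(ok) == 0L) return(NULL)
  i2 <- ok[which.max(sm[ok])]
  sort(c(i1, i2))
}

#' Locate the split between the two brachia on an intensity profile
#'
#' In manual (faithful) mode the supplied split position is used as-is. In
#' automatic mode the profile's two channels are summed, smoothed, the two
#' largest peaks found, and the split placed at the minimum between them.
#'
#' @param profile an intensity profile from [extract_profile()].
#' @param manual_split optional split position in um along the line.
#' @param dm_side which side of the split is the dorsal brachium (where
#'   missorted dorsal axons appear): `"high"`, `"low"`, or `NULL` to take it
#'   from the profile's orientation attribute.
#' @param smooth_um smoothing window for automatic peak/valley detection, um.
#' @return a `branch_split`: list with `split_position` (um) and `dm_side`.
#' @export
split_branches <- function(profile, manual_split = NULL, dm_side = NULL,
                           smooth_um = 2) {
  if (nrow(profile) < 5L) abort("profile needs >= 5 samples")
  pos <- profile$position_um
  if (is.null(dm_side)) {
    ori <- attr(profile, "orientation") %||% "dorsal_high"
    dm_side <- if (identical(ori, "dorsal_low")) "low" else "high"
  }
  dm_side <- match.arg(dm_side, c("high", "low"))
  if (!is.null(manual_split)) {
    if (manual_split <= min(pos) || manual_split >= max(pos))
      abort("manual_split (%g um) must lie strictly inside the profile extent [%g, %g]",
            manual_split, min(pos), max(pos))
    return(structure(list(split_position = manual_split, dm_side = dm_side,
                          mode = "manual"), class = "branch_split"))
  }
  total <- profile$dorsal + profile$ventral
  dx <- mean(diff(pos))
  k <- max(1L, 2L * floor(smooth_um / dx / 2) + 1L)
  sm <- running_mean(total, k)
  two <- two_peaks(pos, sm)
  if (is.null(two))
    abort(paste("could not detect two brachium peaks in the combined profile;",
                "supply manual_split"))
  seg <- seq(two[1L], two[2L])
  # the valley bottom can be a flat plateau under noise; take the center of
  # the near-minimum region rather than an arbitrary argmin within it
  vmin <- min(sm[seg])
  depth <- min(sm[two]) - vmin
  plateau <- seg[sm[seg] <= vmin + 0.25 * depth]
  split_i <- plateau[ceiling(length(plateau) / 2)]
  structure(list(split_position = pos[split_i], dm_side = dm_side,
                 mode = "auto"), class = "branch_split")
}

#' Missorting index from an intensity profile
#'
#' The missorting index is the ratio of mean dorsal-dye intensity in the
#' wrong (dorsal) brachium, Dm, to the total mean dorsal-dye intensity
#' across both brachia: \eqn{MI = Dm / (Dm + Ds)}. It assumes mean signal
#' intensity is proportional to the amount of labeled axons; no correction
#' for dye-loading variability is applied.
#'
#' @param profile an intensity profile from [extract_profile()].
#' @param split a `branch_split` from [split_branches()].
#' @param background scalar background intensity subtracted from the dorsal
#'   channel before averaging (default 0, i.e. off).
#' @return a `missorting_result`: list with `mean_Dm`, `mean_Ds`, `mi`.
#' @export
missorting_index <- function(profile, split, background = 0) {
  if (!inherits(split, "branch_split")) abort("split must come from split_branches()")
  pos <- profile$position_um
  if (split$split_position <= min(pos) || split$split_position >= max(pos))
    abort("split position %g um is outside the profile extent", split$split_position)
  d <- pmax(profile$dorsal - background, 0)
  hi <- pos > split$split_position
  mean_hi <- mean(d[hi]); mean_lo <- mean(d[!hi])
  if (split$dm_side == "high") {
    mean_Dm <- mean_hi; mean_Ds <- mean_lo
  } else {
    mean_Dm <- mean_lo; mean_Ds <- mean_hi
  }
  if (mean_Dm + mean_Ds <= 0)
    abort("missorting index undefined: no dorsal-channel signal on either side")
  structure(list(mean_Dm = mean_Dm, mean_Ds = mean_Ds,
                 mi = mean_Dm / (mean_Dm + mean_Ds)),
            class = "missorting_result")
}

#' @export
print.missorting_result <- function(x, ...) {
  cat(sprintf("missorting index: MI = %.4f (mean Dm = %.3f, mean Ds = %.3f)\n",
              x$mi, x$mean_Dm, x$mean_Ds))
  invisible(x)
}

#' Projection area of one channel above a threshold
#'
#' Area of the thresholded signal mask: number of pixels at or above
#' `threshold`, times the pixel area.
#'
#' @param image a [tract_image()].
#' @param channel `"dorsal"` or `"ventral"`.
#' @param threshold intensity threshold (>= 0).
#' @return area in um^2.
#' @export
projection_area <- function(image, channel = c("dorsal", "ventral"), threshold) {
  channel <- match.arg(channel)
  stopifnot_scalar_num(threshold, "threshold")
  if (threshold < 0) abort("threshold must be >= 0")
  sum(image[[channel]] >= threshold) * image$pixel_size^2
}
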