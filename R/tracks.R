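# Granule-transport module: motion classification of RNP-granule tracks by
# the 2 um unidirectional-displacement rule, motion-class fractions,
# contact-aligned central/peripheral distributions and anterograde flux.

MOTION_CLASSES <- c("anterograde", "retrograde", "static_oscillatory")

#' One-dimensional granule track
#'
#' Position of one RNP granule along the axon axis over time. Positions are
#' arc-length coordinates in um with the anterograde direction (toward the
#' growth cone) positive; projecting 2-D detections onto the axon midline is
#' the caller's concern.
#'
#' @param granule_id identifier.
#' @param times times in seconds, strictly increasing, >= 2 samples.
#' @param positions positions in um, same length as `times`.
#' @return an object of class `granule_track`.
#' @export
granule_track <- function(granule_id, times, positions) {
  if (length(times) < 2L) abort("track %s: needs >= 2 samples", granule_id)
  if (length(times) != length(positions))
    abort("track %s: times and positions differ in length", granule_id)
  if (any(diff(times) <= 0))
    abort("track %s: times must be strictly increasing", granule_id)
  structure(list(granule_id = granule_id, times = as.numeric(times),
                 positions = as.numeric(positions)),
            class = "granule_track")
}

#' Classify one track as anterograde, retrograde or static/oscillatory
#'
#' A granule is classified as anterograde or retrograde transport if it
#' displaces more than `threshold` um in one direction from its origin
#' (strict inequality: an excursion of exactly the threshold is
#' static/oscillatory). The test uses the maximal excursion from the first
#' sample, not the endpoint displacement. If both excursions exceed the
#' threshold, the larger wins; an exact tie goes to anterograde
#' (deterministic tie-break).
#'
#' @param track a [granule_track()].
#' @param threshold displacement threshold in um (default 2).
#' @return one of `"anterograde"`, `"retrograde"`, `"static_oscillatory"`.
#' @export
classify_motion <- function(track, threshold = 2.0) {
  if (!inherits(track, "granule_track")) abort("track must be a granule_track")
  stopifnot_scalar_num(threshold, "threshold", positive = TRUE)
  rel <- track$positions - track$positions[1L]
  d_plus <- max(rel)
  d_minus <- max(-rel)
  if (d_plus > threshold && d_plus >= d_minus) "anterograde"
  else if (d_minus > threshold && d_minus > d_plus) "retrograde"
  else "static_oscillatory"
}

#' Motion-class fractions of a set of tracks
#'
#' @param tracks list of [granule_track()] (or a precomputed character vector
#'   of classes).
#' @param threshold displacement threshold in um passed to
#'   [classify_motion()].
#' @return data.frame with columns `class`, `n`, `percent` (half-up rounded
#'   to 2 decimals; unrounded percentages in `percent_raw` sum to 100).
#' @export
motion_fractions <- function(tracks, threshold = 2.0) {
  if (length(tracks) == 0L) abort("motion_fractions needs >= 1 track")
  classes <- if (is.character(tracks)) tracks
             else vapply(tracks, classify_motion, character(1), threshold = threshold)
  bad <- setdiff(unique(classes), MOTION_CLASSES)
  if (length(bad)) abort("unknown motion class: %s", paste(bad, collapse = ", "))
  n <- vapply(MOTION_CLASSES, function(k) sum(classes == k), integer(1))
  raw <- 100 * n / sum(n)
  data.frame(class = MOTION_CLASSES, n = as.integer(n),
             percent = round_half_up(raw, 2), percent_raw = raw,
             row.names = NULL)
}

#' Central/peripheral granule distribution per time bin
#'
#' Converts per-bin central/peripheral granule counts (counted every 30 s,
#' with `t_bin_s = 0` at the cell-contact point) into per-bin fractions.
#'
#' @param counts data.frame with columns `t_bin_s`, `n_central`,
#'   `n_peripheral`.
#' @return data.frame adding `fraction_central`, `fraction_peripheral`
#'   (summing to 1 per bin) and logical `empty` flagging bins with zero total
#'   (fractions `NA`, never imputed).
#' @export
domain_distribution <- function(counts) {
  req <- c("t_bin_s", "n_central", "n_peripheral")
  if (!all(req %in% names(counts)))
    abort("counts needs columns %s", paste(req, collapse = ", "))
  if (any(counts$n_central < 0 | counts$n_peripheral < 0))
    abort("counts must be >= 0")
  tot <- counts$n_central + counts$n_peripheral
  out <- counts
  out$fraction_central <- ifelse(tot > 0, counts$n_central / tot, NA_real_)
  out$fraction_peripheral <- ifelse(tot > 0, counts$n_peripheral / tot, NA_real_)
  out$empty <- tot == 0
  out
}

#' Anterograde flux of granules entering the growth cone
#'
#' Counts, per time bin, the distinct granules whose track is anterograde
#' within the 50 um segment proximal to the growth cone and whose position
#' crosses the growth-cone boundary (position 0; negative positions are
#' shaft) during that bin. The per-axon series is normalized to its own mean,
#' so a constant-transport axon has a normalized series identically 1.
#'
#' @param tracks list of [granule_track()] with positions relative to the
#'   growth-cone entry point (0 at the boundary, negative in the shaft).
#' @param segment_length length of the scored shaft segment in um
#'   (default 50).
#' @param duration total recording duration in s (default 600).
#' @param bin bin width in s (default 30).
#' @param threshold motion-classification threshold in um.
#' @return a `flux_series`: data.frame with `t_bin_s` (bin start),
#'   `raw_count`, `normalized`; attribute `defined` is `FALSE` when all
#'   counts are zero (normalized left `NA`, flagged not imputed).
#' @export
anterograde_flux <- function(tracks, segment_length = 50, duration = 600,
                             bin = 30, threshold = 2.0) {
  stopifnot_scalar_num(segment_length, "segment_length", positive = TRUE)
  stopifnot_scalar_num(bin, "bin", positive = TRUE)
  starts <- seq(0, duration - bin, by = bin)
  raw <- integer(length(starts))
  for (tr in tracks) {
    in_seg <- any(tr$positions >= -segment_length & tr$positions <= 0)
    if (!in_seg) next
    if (classify_motion(tr, threshold) != "anterograde") next
    cross <- which(tr$positions[-1L] >= 0 & tr$positions[-length(tr$positions)] < 0)
    if (length(cross) == 0L) next
    t_cross <- tr$times[cross[1L] + 1L]
    b <- findInterval(t_cross, c(starts, duration), rightmost.closed = TRUE)
    if (b >= 1L && b <= length(starts)) raw[b] <- raw[b] + 1L
  }
  defined <- any(raw > 0)
  out <- data.frame(t_bin_s = starts, raw_count = raw,
                    normalized = if (defined) raw / mean(raw) else NA_real_)
  attr(out, "defined") <- defined
  class(out) <- c("flux_series", "data.frame")
  out
}

#' Read granule tracks from CSV
#'
#' Expects columns `granule_id`, `t_s`, `pos_um`.
#'
#' @param path CSV file path.
#' @return list of [granule_track()].
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path)
  req <- c("granule_id", "t_s", "pos_um")
  if (!all(req %in% names(df)))
    abort("%s: expected columns %s", path, paste(req, collapse = ", "))
  lapply(split(df, df$granule_id), function(d) {
    d <- d[order(d$t_s), ]
    granule_track(d$granule_id[1L], d$t_s, d$pos_um)
  })
}

#' Write granule tracks to CSV
#'
#' @param tracks list of [granule_track()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(granule_id = tr$granule_id, t_s = tr$times, pos_um = tr$positions)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
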