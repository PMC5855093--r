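# Encounter module: classification of growth-cone / axon encounter events
# into fasciculation, crossing, tracking, stalling and retraction, with
# fraction tables and the group-comparison tests used in figure legends.

BEHAVIOR_CLASSES <- c("fasciculation", "crossing", "tracking",
                      "stalling", "retraction")

#' Growth-cone / axon encounter event
#'
#' @param gc_trajectory data.frame with columns `t` (s), `x`, `y` (um):
#'   growth-cone centroid over time, imaged every 30 s, spanning the contact.
#' @param target_path n x 2 matrix (um): the contacted axon shaft.
#' @param contact_time time of first contact in s (T = 0 convention is the
#'   caller's; any value within the trajectory time span works).
#' @param contacts data.frame of filopodial contact records with columns
#'   `filopodium_id`, `start`, `end` (s); may be empty.
#' @param observation_end end of observation in s.
#' @param origin optional origin pair label (`"D->D"`, `"D->V"`, `"V->D"`,
#'   `"V->V"`).
#' @return object of class `encounter_event`.
#' @export
encounter_event <- function(gc_trajectory, target_path, contact_time,
                            contacts = NULL, observation_end = NULL,
                            origin = NA_character_) {
  req <- c("t", "x", "y")
  if (!all(req %in% names(gc_trajectory)))
    abort("gc_trajectory needs columns %s", paste(req, collapse = ", "))
  gc_trajectory <- gc_trajectory[order(gc_trajectory$t), ]
  if (contact_time < min(gc_trajectory$t) || contact_time > max(gc_trajectory$t))
    abort("trajectory (t in [%g, %g]) does not span contact_time = %g",
          min(gc_trajectory$t), max(gc_trajectory$t), contact_time)
  if (is.null(contacts))
    contacts <- data.frame(filopodium_id = integer(), start = numeric(),
                           end = numeric())
  if (nrow(contacts) && any(contacts$end < contacts$start))
    abort("contact records must have end >= start")
  structure(list(gc_trajectory = gc_trajectory,
                 target_path = as.matrix(target_path),
                 contact_time = contact_time, contacts = contacts,
                 observation_end = observation_end %||% max(gc_trajectory$t),
                 origin = origin),
            class = "encounter_event")
}

#' Geometric tolerances for encounter classification
#'
#' The underlying behavior definitions are observational (merging, crossing,
#' filopodia-guided turning, arrest); these parameters make them operational.
#' All are in um, degrees or minutes and exposed for sensitivity analysis.
#'
#' @param merge_tol max distance to the target path that still counts as
#'   merged (um).
#' @param min_follow arc length that must be traveled while merged for
#'   fasciculation (um).
#' @param cross_dist distance beyond the target path required for crossing
#'   (um).
#' @param cross_max_turn max heading change for a smooth crossing (degrees).
#' @param track_min_turn min turn toward the target tangent for tracking
#'   (degrees).
#' @param track_min_contacts min number of filopodial contacts for tracking.
#' @param retract_tol net retreat along the pre-contact heading that counts
#'   as retraction (um).
#' @param stall_tol max |net advance| that still counts as stalling (um).
#' @param stall_window_min observation window after contact required before
#'   calling stalling (min); encounters are terminated after this window.
#' @return named list of parameters.
#' @export
encounter_params <- function(merge_tol = 1, min_follow = 10, cross_dist = 5,
                             cross_max_turn = 30, track_min_turn = 20,
                             track_min_contacts = 2, retract_tol = 5,
                             stall_tol = 5, stall_window_min = 45) {
  as.list(environment())
}

# Mean heading (degrees) of a trajectory chunk, from first to last point.
chunk_heading <- function(xy) {
  v <- colSums(diff(as.matrix(xy)))
  if (all(v == 0)) return(NA_real_)
  vec_angle(v)
}

# Tangent direction of the target path near a point (segment nearest to it).
path_tangent_at <- function(path, pt) {
  path <- as.matrix(path)
  nseg <- nrow(path) - 1L
  mid <- (path[-1L, , drop = FALSE] + path[-nrow(path), , drop = FALSE]) / 2
  d <- sqrt((mid[, 1L] - pt[1L])^2 + (mid[, 2L] - pt[2L])^2)
  i <- which.min(d)
  vec_angle(path[i + 1L, ] - path[i, ])
}

#' Classify one encounter event
#'
#' Decision cascade applied to the post-contact trajectory:
#' 1. **fasciculation** — the trajectory lies within `merge_tol` of the
#'    target path for at least `min_follow` um of traveled arc;
#' 2. **crossing** — the trajectory crosses the target path and proceeds at
#'    least `cross_dist` um beyond it with a heading change below
#'    `cross_max_turn`;
#' 3. **tracking** — at least `track_min_contacts` filopodial contacts and
#'    the heading turns toward the target tangent by more than
#'    `track_min_turn` degrees while the centroid stays farther than
#'    `merge_tol` from the path;
#' 4. **retraction** — net displacement along the pre-contact heading below
#'    `-retract_tol`;
#' 5. **stalling** — |net advance| below `stall_tol` over the full
#'    `stall_window_min` window.
#' Events matching none of the rules are reported as `"unclassified"`, or
#' `"indeterminate_censored"` when the observation ended before the stall
#' window elapsed.
#'
#' @param event an [encounter_event()].
#' @param params an [encounter_params()] list.
#' @return a single class string.
#' @export
classify_behavior <- function(event, params = encounter_params()) {
  if (!inherits(event, "encounter_event")) abort("event must be an encounter_event")
  tr <- event$gc_trajectory
  path <- event$target_path
  pre <- tr[tr$t <= event$contact_time, c("x", "y"), drop = FALSE]
  post <- tr[tr$t >= event$contact_time, c("x", "y"), drop = FALSE]
  if (nrow(post) < 2L) abort("no post-contact trajectory to classify")
  pre_heading <- if (nrow(pre) >= 2L) chunk_heading(pre) else
    chunk_heading(tr[seq_len(2L), c("x", "y")])
  contact_pt <- as.numeric(post[1L, ])

  # 1. fasciculation: arc traveled while within merge_tol of the path
  post_m <- as.matrix(post)
  dpath <- dist_to_polyline(post_m, path)
  seg_len <- sqrt(rowSums(diff(post_m)^2))
  merged_seg <- dpath[-length(dpath)] <= params$merge_tol &
    dpath[-1L] <= params$merge_tol
  if (sum(seg_len[merged_seg]) >= params$min_follow) return("fasciculation")

  # 2. crossing: crosses the path, proceeds beyond, heading nearly unchanged
  ci <- last_crossing_segment(post_m, path)
  if (ci > 0L) {
    beyond <- post_m[(ci + 1L):nrow(post_m), , drop = FALSE]
    max_beyond <- max(dist_to_polyline(beyond, path))
    post_heading <- chunk_heading(post_m[ci:nrow(post_m), , drop = FALSE])
    if (max_beyond >= params$cross_dist &&
        is.finite(post_heading) && is.finite(pre_heading) &&
        angle_between(post_heading, pre_heading) < params$cross_max_turn)
      return("crossing")
  }

  # 3. tracking: repeated filopodial contacts turn the growth cone to run
  # along the path at a distance
  if (nrow(event$contacts) >= params$track_min_contacts &&
      all(dpath > params$merge_tol)) {
    tangent <- path_tangent_at(path, contact_pt)
    post_heading <- chunk_heading(post_m)
    if (is.finite(post_heading) && is.finite(pre_heading)) {
      turn <- angle_to_line(pre_heading, tangent) -
        angle_to_line(post_heading, tangent)
      if (turn > params$track_min_turn) return("tracking")
    }
  }

  # 4/5. net advance along the pre-contact heading
  disp <- as.numeric(post_m[nrow(post_m), ]) - contact_pt
  advance <- disp[1L] * cos(pre_heading * pi / 180) +
    disp[2L] * sin(pre_heading * pi / 180)
  if (advance < -params$retract_tol) return("retraction")
  observed_min <- (event$observation_end - event$contact_time) / 60
  if (abs(advance) < params$stall_tol) {
    if (observed_min >= params$stall_window_min) return("stalling")
    return("indeterminate_censored")
  }
  if (observed_min < params$stall_window_min) return("indeterminate_censored")
  "unclassified"
}

#' Behavior fractions of a set of encounter events
#'
#' Percentages are computed over all events (unclassified and censored
#' events are reported as their own categories, never dropped). Stalling and
#' retraction are additionally pooled into a `stalling_retraction` row in
#' the summary, with the split retained in the detail counts. When events
#' carry an `origin` label, a per-origin contingency table is attached.
#'
#' @param events list of [encounter_event()] (or a character vector of
#'   precomputed classes).
#' @param params an [encounter_params()] list.
#' @return list with `summary` (class, n, percent, fraction), `detail`
#'   (unpooled counts) and `by_origin` (contingency table or `NULL`).
#' @export
behavior_fractions <- function(events, params = encounter_params()) {
  if (length(events) == 0L) abort("behavior_fractions needs >= 1 event")
  if (is.character(events)) {
    classes <- events
    origins <- rep(NA_character_, length(events))
  } else {
    classes <- vapply(events, classify_behavior, character(1), params = params)
    origins <- vapply(events, function(e) e$origin, character(1))
  }
  lev <- c(BEHAVIOR_CLASSES, "unclassified", "indeterminate_censored")
  n <- vapply(lev, function(k) sum(classes == k), integer(1))
  detail <- data.frame(class = lev, n = as.integer(n),
                       percent = round_half_up(100 * n / sum(n), 2),
                       fraction = round_half_up(n / sum(n), 2),
                       percent_raw = 100 * n / sum(n), row.names = NULL)
  pooled_lev <- c("fasciculation", "crossing", "tracking",
                  "stalling_retraction", "unclassified",
                  "indeterminate_censored")
  np <- c(n[["fasciculation"]], n[["crossing"]], n[["tracking"]],
          n[["stalling"]] + n[["retraction"]], n[["unclassified"]],
          n[["indeterminate_censored"]])
  summary <- data.frame(class = pooled_lev, n = as.integer(np),
                        percent = round_half_up(100 * np / sum(np), 2),
                        fraction = round_half_up(np / sum(np), 2),
                        percent_raw = 100 * np / sum(np), row.names = NULL)
  by_origin <- NULL
  if (any(!is.na(origins))) {
    homo <- ifelse(origins %in% c("D->D", "V->V"), "homotypic",
                   ifelse(origins %in% c("D->V", "V->D"), "heterotypic", NA))
    by_origin <- list(origin = table(origin = origins, class = classes),
                      type = table(type = homo, class = classes))
  }
  list(summary = summary, detail = detail, by_origin = by_origin)
}

#' Per-event filopodial contact statistics
#'
#' @param events list of [encounter_event()].
#' @return data.frame with `event`, `n_contacts`, `mean_duration_min`
#'   (`NA`, flagged by `no_contacts`, when an event has none).
#' @export
contact_stats <- function(events) {
  do.call(rbind, lapply(seq_along(events), function(i) {
    ct <- events[[i]]$contacts
    n <- nrow(ct)
    data.frame(event = i, n_contacts = n,
               mean_duration_min = if (n) mean(ct$end - ct$start) / 60 else NA_real_,
               no_contacts = n == 0L)
  }))
}

#' Two-group comparison tests used in the figure legends
#'
#' Thin wrapper over [stats::fisher.test()], [stats::chisq.test()] and
#' [stats::wilcox.test()] (Mann-Whitney), all two-sided. When chi-square
#' expected counts fall below 5, a note recommending Fisher's exact test is
#' attached.
#'
#' @param a,b for `"fisher"`/`"chi2"`: the two rows (count vectors) of a
#'   contingency table; for `"mannwhitney"`: the two samples.
#' @param test one of `"fisher"`, `"chi2"`, `"mannwhitney"`.
#' @return list with `test`, `statistic`, `p_value`, `note`.
#' @export
compare_groups <- function(a, b, test = c("fisher", "chi2", "mannwhitney")) {
  test <- match.arg(test)
  note <- NA_character_
  if (test == "mannwhitney") {
    ht <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  } else {
    tab <- rbind(a, b)
    if (test == "fisher") {
      ht <- fisher.test(tab, alternative = "two.sided")
    } else {
      ht <- suppressWarnings(chisq.test(tab))
      if (any(ht$expected < 5))
        note <- "chi-square expected counts < 5; consider test = \"fisher\""
    }
  }
  list(test = c(fisher = "Fisher's exact test", chi2 = "chi-square test",
                mannwhitney = "Mann-Whitney test")[[test]],
       statistic = if (!is.null(ht$statistic)) unname(ht$statistic) else NA_real_,
       p_value = ht$p.value, note = note)
}

#' Read an encounter event from JSON
#'
#' Expects `{gc_trajectory: [[t,x,y],...], target_path: [[x,y],...],
#' contact_time, contacts: [{id,start,end},...], observation_end?, origin?}`.
#'
#' @param path JSON file path.
#' @return an [encounter_event()].
#' @export
read_event_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  traj <- as.data.frame(j$gc_trajectory)
  names(traj) <- c("t", "x", "y")
  contacts <- if (!is.null(j$contacts) && length(j$contacts)) {
    ct <- as.data.frame(j$contacts)
    names(ct) <- c("filopodium_id", "start", "end")
    ct
  } else NULL
  encounter_event(traj, as.matrix(j$target_path), j$contact_time,
                  contacts = contacts,
                  observation_end = j$observation_end %||% NULL,
                  origin = j$origin %||% NA_character_)
}

#' Write an encounter event to JSON
#'
#' @param event an [encounter_event()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_event_json <- function(event, path) {
  j <- list(
    gc_trajectory = unname(as.matrix(event$gc_trajectory[, c("t", "x", "y")])),
    target_path = unname(event$target_path),
    contact_time = event$contact_time,
    contacts = if (nrow(event$contacts))
      data.frame(id = event$contacts$filopodium_id,
                 start = event$contacts$start, end = event$contacts$end)
      else list(),
    observation_end = event$observation_end, origin = event$origin)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
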