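# Colocalization module: Manders coefficients on thresholded masks, puncta
# association fractions, and PLA dot counting by growth-cone domain.

#' Manders colocalization coefficients
#'
#' \eqn{M1} is the fraction of channel-1 integrated intensity that lies
#' within the channel-2 mask, restricted to the channel-1 mask:
#' \eqn{M1 = \sum_{mask1 \wedge mask2} ch1 / \sum_{mask1} ch1}; \eqn{M2} is
#' symmetric. When masks are not supplied they are derived by Otsu
#' thresholding of the corresponding channel.
#'
#' @param ch1,ch2 intensity matrices of identical shape.
#' @param mask1,mask2 optional logical matrices; default Otsu threshold of
#'   the channel.
#' @return list with `M1`, `M2` (each in `[0, 1]`, `NA` with `defined =
#'   FALSE` on a zero denominator) and the thresholds used.
#' @export
manders <- function(ch1, ch2, mask1 = NULL, mask2 = NULL) {
  ch1 <- as.matrix(ch1); ch2 <- as.matrix(ch2)
  if (!identical(dim(ch1), dim(ch2))) abort("channels must have the same shape")
  otsu_mask <- function(ch) {
    rng <- range(ch)
    if (rng[1L] == rng[2L]) return(list(mask = ch > rng[1L], thr = rng[1L]))
    sc <- (ch - rng[1L]) / (rng[2L] - rng[1L])
    thr <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
    list(mask = sc > thr, thr = thr * (rng[2L] - rng[1L]) + rng[1L])
  }
  t1 <- t2 <- NA_real_
  if (is.null(mask1)) { o <- otsu_mask(ch1); mask1 <- o$mask; t1 <- o$thr }
  if (is.null(mask2)) { o <- otsu_mask(ch2); mask2 <- o$mask; t2 <- o$thr }
  mask1 <- as.matrix(mask1) > 0; mask2 <- as.matrix(mask2) > 0
  both <- mask1 & mask2
  d1 <- sum(ch1[mask1]); d2 <- sum(ch2[mask2])
  list(M1 = if (d1 > 0) sum(ch1[both]) / d1 else NA_real_,
       M2 = if (d2 > 0) sum(ch2[both]) / d2 else NA_real_,
       defined = c(M1 = d1 > 0, M2 = d2 > 0),
       threshold1 = t1, threshold2 = t2)
}

#' Fraction of puncta associated with a second point set
#'
#' A channel-A punctum is *associated* when its nearest channel-B point lies
#' within `radius`. The radius operationalizes association scored by overlap
#' by eye; it is a configuration choice echoed in the result.
#'
#' @param setA,setB n x 2 matrices of centroids (um); data.frames with
#'   `x_um`, `y_um` columns are accepted.
#' @param radius association radius in um (default 0.5).
#' @return list with `fraction`, `n_associated`, `n`, `radius`.
#' @export
puncta_association <- function(setA, setB, radius = 0.5) {
  stopifnot_scalar_num(radius, "radius", positive = TRUE)
  pts <- function(s) {
    if (is.data.frame(s) && all(c("x_um", "y_um") %in% names(s)))
      s <- s[, c("x_um", "y_um")]
    matrix(as.numeric(as.matrix(s)), ncol = 2L)
  }
  A <- pts(setA)
  if (nrow(A) == 0L) abort("setA is empty")
  B <- pts(setB)
  if (nrow(B) == 0L)
    return(list(fraction = 0, n_associated = 0L, n = nrow(A), radius = radius))
  d2 <- outer(A[, 1L], B[, 1L], "-")^2 + outer(A[, 2L], B[, 2L], "-")^2
  nn <- sqrt(apply(d2, 1L, min))
  n_assoc <- sum(nn <= radius)
  list(fraction = n_assoc / nrow(A), n_associated = as.integer(n_assoc),
       n = nrow(A), radius = radius)
}

#' PLA dot counts by growth-cone domain
#'
#' Assigns each dot to the central domain, the peripheral domain (inside the
#' outline but not central), or outside. Dots on the shared central/outline
#' boundary are assigned to the central domain (deterministic tie-break).
#'
#' @param dots n x 2 matrix of dot centroids (um), or data.frame with
#'   `x_um`, `y_um`.
#' @param outline growth-cone outline polygon (um).
#' @param central central-domain polygon (um), inside the outline.
#' @return list of class `pla_result` with `n_central`, `n_peripheral`,
#'   `n_outside`, `cp_ratio` (`NA`, flagged, when `n_peripheral` is 0) and
#'   per-dot `assignment`.
#' @export
pla_counts <- function(dots, outline, central) {
  if (is.data.frame(dots) && all(c("x_um", "y_um") %in% names(dots)))
    dots <- dots[, c("x_um", "y_um")]
  dots <- matrix(as.numeric(as.matrix(dots)), ncol = 2L)
  in_c <- point_in_polygon(dots, central)
  in_o <- point_in_polygon(dots, outline)
  assignment <- ifelse(in_c, "central", ifelse(in_o, "peripheral", "outside"))
  n_c <- sum(in_c); n_p <- sum(in_o & !in_c); n_out <- sum(!in_o)
  structure(list(n_central = as.integer(n_c), n_peripheral = as.integer(n_p),
                 n_outside = as.integer(n_out),
                 cp_ratio = if (n_p > 0) n_c / n_p else NA_real_,
                 ratio_defined = n_p > 0, assignment = assignment),
            class = "pla_result")
}

#' @export
print.pla_result <- function(x, ...) {
  cat(sprintf("PLA dots: %d central, %d peripheral, %d outside; C/P ratio %s\n",
              x$n_central, x$n_peripheral, x$n_outside,
              if (x$ratio_defined) sprintf("%.3f", x$cp_ratio) else "undefined"))
  invisible(x)
}

#' Read puncta centroids from CSV
#'
#' Expects columns `id`, `x_um`, `y_um` and optionally `intensity`.
#'
#' @param path CSV file path.
#' @return data.frame of centroids.
#' @export
read_puncta_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("x_um", "y_um") %in% names(df)))
    abort("%s: expected columns x_um, y_um", path)
  df
}
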