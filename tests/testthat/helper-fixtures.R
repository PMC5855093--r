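# Shared fixture builders kept deliberately independent of the package's own
# generators where they serve as oracles.

# Rectangular growth-cone body with one horizontal rectangular spike of an
# exact pixel length; geometry is grid-exact so threshold boundary cases are
# deterministic.
rect_gc_mask <- function(spike_len_um, pixel_size = 0.1, spike_width_px = 3) {
  body_w <- 60L; body_h <- 40L; pad <- ceiling(spike_len_um / pixel_size) + 10L
  nr <- body_h + 20L; nc <- body_w + 2L * pad
  m <- matrix(0, nr, nc)
  r0 <- 11L; c0 <- pad + 1L
  m[r0:(r0 + body_h - 1L), c0:(c0 + body_w - 1L)] <- 1
  n_spike <- round(spike_len_um / pixel_size)
  if (n_spike > 0) {
    rows <- r0 + body_h %/% 2 + seq_len(spike_width_px) - 2L
    m[rows, (c0 + body_w):(c0 + body_w + n_spike - 1L)] <- 1
  }
  m
}

# Nearest-pixel line sampling, the independent oracle for extract_profile.
nearest_pixel_profile <- function(image, line, n = 200) {
  t <- seq(0, 1, length.out = n)
  xs <- round(line$x1 + t * (line$x2 - line$x1))
  ys <- round(line$y1 + t * (line$y2 - line$y1))
  list(dorsal = image$dorsal[cbind(ys, xs)],
       ventral = image$ventral[cbind(ys, xs)])
}

circle_poly <- function(r, n = 180, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

star_poly <- function(n_arms = 5, r_out = 8, r_in = 4) {
  th <- seq(0, 2 * pi, length.out = 2 * n_arms + 1)[-(2 * n_arms + 1)]
  r <- rep(c(r_out, r_in), n_arms)
  cbind(r * cos(th), r * sin(th))
}
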