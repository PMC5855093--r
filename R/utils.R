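`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a local random seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random state
#' afterwards, so generators never perturb global RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort("seed must be a single integer, got %s", deparse(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero, matching the 2-decimal percentage style used in
# reports (base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a child seed < 2^31 from a base seed and a stream label.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort("%s must be a single number", name)
  if (positive && x <= 0) abort("%s must be > 0, got %g", name, x)
  invisible(x)
}
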