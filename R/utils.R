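# Shared validation helpers. All user-facing errors go through rlang::abort
# with a class so tests can assert on them.

stop_bad_arg <- function(msg, ...) {
  rlang::abort(msg, class = "chromakit_error", ...)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max || (!allow_zero && x == 0)) {
    stop_bad_arg(sprintf("`%s` = %g is outside the allowed range [%g, %g].",
                         name, x, min, max))
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      length(seed) != 1L || !is.finite(seed)) {
    stop_bad_arg("an explicit integer `seed` is required for every stochastic operation.")
  }
  as.integer(seed)
}

# Deterministic golden-spiral points on the unit sphere (n x 3 matrix).
# Used by the SASA engine and by test oracles at higher density.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
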