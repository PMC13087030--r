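#' Absolute fraction of long-bound molecules
#'
#' The product of the overall bound fraction (amplitude of the slowest
#' diffusion component) with the summed state-spectrum amplitude of all rate
#' components whose residence time `1/k` is at least `threshold` seconds
#' (default 50 s, the conventional cutoff for specifically bound
#' transcription factor molecules).
#'
#' @param fit A `diffusion_fit` (or a single numeric bound fraction).
#' @param spectrum A `rate_spectrum`.
#' @param threshold Residence-time threshold in seconds (default 50).
#' @return The long-bound fraction `f_long` (scalar).
#' @export
long_bound_fraction <- function(fit, spectrum, threshold = 50) {
  f_bound <- if (inherits(fit, "diffusion_fit")) fit$bound_fraction else {
    check_scalar_number(fit, "fit", min = 0, max = 1)
  }
  check_scalar_number(threshold, "threshold", min = 0)
  tb <- if (inherits(spectrum, "rate_spectrum")) spectrum$spectrum else spectrum
  s <- state_spectrum(tb)
  long <- 1 / tb$rate >= threshold
  f_bound * sum(s[long])
}

#' Search time and binding frequency from the long-bound fraction
#'
#' Flux balance over the three-state kinetic model: at steady state the rate
#' of entering the stable (long-bound) state balances the rate of leaving it,
#' so the mean search time -- all time spent not stably bound, i.e. freely
#' diffusing or transiently bound, between two stable binding events -- is
#' \deqn{\tau_{search} = \frac{(1 - f_{long})\,\tau_{long}}{f_{long}},}
#' with \eqn{\tau_{long}} the state-amplitude-weighted mean residence time of
#' the long-bound components. The binding frequency is
#' \eqn{\nu = 1/\tau_{search}}.
#'
#' @param f_long Long-bound fraction from [long_bound_fraction()].
#' @param spectrum A `rate_spectrum` (used for `tau_long`); alternatively
#'   pass `tau_long` directly.
#' @param threshold Residence-time threshold (s), as in
#'   [long_bound_fraction()].
#' @param tau_long Mean long residence time (s); overrides `spectrum`.
#' @param f_bound Optional overall bound fraction carried through to the
#'   result for reporting.
#' @return A `kinetics_result` object (also a tibble) with columns `f_bound`,
#'   `f_long`, `tau_long`, `tau_search`, `nu`.
#' @examples
#' # symmetric case: half the time bound long, 100 s residence
#' binding_frequency(0.5, tau_long = 100)$nu  # 0.01 /s
#' @export
binding_frequency <- function(f_long, spectrum = NULL, threshold = 50,
                              tau_long = NULL, f_bound = NA_real_) {
  check_scalar_number(f_long, "f_long", min = 0, max = 1)
  if (f_long >= 1) {
    stop_bad_arg("f_long = 1 leaves no search phase; binding frequency is undefined.")
  }
  if (is.null(tau_long)) {
    if (is.null(spectrum)) stop_bad_arg("supply either `spectrum` or `tau_long`.")
    tb <- if (inherits(spectrum, "rate_spectrum")) spectrum$spectrum else spectrum
    s <- state_spectrum(tb)
    long <- 1 / tb$rate >= threshold
    if (f_long > 0 && !any(s[long] > 0)) {
      stop_bad_arg("spectrum has no component at or beyond the residence threshold.")
    }
    tau_long <- if (any(s[long] > 0)) {
      sum(s[long] * (1 / tb$rate[long])) / sum(s[long])
    } else NA_real_
  }
  if (f_long == 0) {
    tau_search <- Inf
    nu <- 0
  } else {
    tau_search <- (1 - f_long) * tau_long / f_long
    nu <- 1 / tau_search
  }
  out <- tibble(f_bound = f_bound, f_long = f_long, tau_long = tau_long,
                tau_search = tau_search, nu = nu)
  class(out) <- c("kinetics_result", class(out))
  out
}

#' End-to-end single-molecule kinetics pipeline
#'
#' Convenience wrapper chaining the full inference: jump-distance fit on the
#' fast-scheme tracks (overall bound fraction), survival construction on the
#' slow schemes, global rate-spectrum fit, long-bound fraction and binding
#' frequency.
#'
#' @param fast_tracks,fast_scheme Fast-movie tracks and their scheme.
#' @param slow_tracks List of slow-movie track tibbles.
#' @param slow_schemes List of matching [illumination_scheme()] objects.
#' @param threshold Residence-time threshold in seconds (default 50).
#' @param n_boot_jumps,n_boot_grid Resampling counts for the two fits.
#' @param seed Integer seed.
#' @param ... Passed on to [fit_grid_spectrum()].
#' @return A list with `fit` (diffusion fit), `spectrum` (rate spectrum) and
#'   `kinetics` (a `kinetics_result` row).
#' @export
smt_kinetics <- function(fast_tracks, fast_scheme, slow_tracks, slow_schemes,
                         threshold = 50, n_boot_jumps = 400,
                         n_boot_grid = 500, seed, ...) {
  seed <- check_seed(seed)
  jumps <- jump_distances(fast_tracks, fast_scheme)
  fit <- fit_jump_cdf(jumps, n_boot = n_boot_jumps, seed = seed)
  survs <- Map(build_survival, slow_tracks, slow_schemes)
  spectrum <- fit_grid_spectrum(survs, n_boot = n_boot_grid, seed = seed + 1L,
                                ...)
  f_long <- long_bound_fraction(fit, spectrum, threshold)
  kin <- binding_frequency(f_long, spectrum, threshold,
                           f_bound = fit$bound_fraction)
  list(fit = fit, spectrum = spectrum, kinetics = kin)
}
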