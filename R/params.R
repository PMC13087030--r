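#' Kinetic ground-truth parameters for the three-state track simulator
#'
#' Molecules switch between a freely diffusing state, a transiently bound
#' state and a stably bound state. Transitions follow a continuous-time
#' Markov chain: from `free` a molecule binds transiently at rate `k_bind_T`
#' or stably at rate `k_bind_S`; bound molecules return to `free` at
#' `k_off_T` / `k_off_S`. Bound molecules are immobile up to localization
#' error; free molecules diffuse with `D_free` inside a reflecting nuclear
#' disk.
#'
#' @param D_free Diffusion coefficient of free molecules (um^2/s).
#' @param k_bind_T,k_bind_S Association rates into the transient and stable
#'   bound states (1/s).
#' @param k_off_T,k_off_S Dissociation rates of the two bound states (1/s).
#' @param p_bleach Photobleaching probability per illuminated frame.
#' @param sigma_loc Localization error standard deviation (um). Shared by both
#'   bound states; slow chromatin motion is folded into this term.
#' @param nucleus_radius Confinement radius of the reflecting disk (um).
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' kinetic_params(k_bind_S = 0.002, k_off_S = 0.01)
#' @export
kinetic_params <- function(D_free = 3, k_bind_T = 0.2, k_bind_S = 0.002,
                           k_off_T = 1, k_off_S = 0.01, p_bleach = 0,
                           sigma_loc = 0.03, nucleus_radius = 5) {
  check_scalar_number(D_free, "D_free", min = 1e-12)
  check_scalar_number(k_bind_T, "k_bind_T", min = 0)
  check_scalar_number(k_bind_S, "k_bind_S", min = 0)
  check_scalar_number(k_off_T, "k_off_T", min = 0)
  check_scalar_number(k_off_S, "k_off_S", min = 0)
  check_scalar_number(p_bleach, "p_bleach", min = 0, max = 1)
  check_scalar_number(sigma_loc, "sigma_loc", min = 0)
  check_scalar_number(nucleus_radius, "nucleus_radius", min = 1e-9)
  structure(list(D_free = D_free, k_bind_T = k_bind_T, k_bind_S = k_bind_S,
                 k_off_T = k_off_T, k_off_S = k_off_S, p_bleach = p_bleach,
                 sigma_loc = sigma_loc, nucleus_radius = nucleus_radius),
            class = "kinetic_params")
}

#' Stationary state occupancies of the three-state kinetic model
#'
#' Solves the stationary distribution of the free/transient/stable chain.
#' The chain has star topology around `free`, so the stationary masses are
#' proportional to 1, `k_bind_T/k_off_T` and `k_bind_S/k_off_S`.
#'
#' @param params A [kinetic_params()] object.
#' @return Named numeric vector with elements `free`, `transient`, `stable`.
#' @export
stationary_occupancy <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  wT <- if (params$k_bind_T == 0) 0 else {
    if (params$k_off_T == 0) Inf else params$k_bind_T / params$k_off_T
  }
  wS <- if (params$k_bind_S == 0) 0 else {
    if (params$k_off_S == 0) Inf else params$k_bind_S / params$k_off_S
  }
  if (is.infinite(wT) || is.infinite(wS)) {
    # one absorbing bound state takes all stationary mass
    out <- c(free = 0, transient = 0, stable = 0)
    out[if (is.infinite(wS)) "stable" else "transient"] <- 1
    return(out)
  }
  w <- c(free = 1, transient = wT, stable = wS)
  w / sum(w)
}

#' Association rates reproducing target state occupancies
#'
#' Convenience inverse of [stationary_occupancy()]: given dwell times of the
#' bound states and target stationary occupancies, returns the binding rates
#' that realize them.
#'
#' @param occ_transient,occ_stable Target stationary occupancies.
#' @param k_off_T,k_off_S Dissociation rates (1/s).
#' @inheritParams kinetic_params
#' @return A [kinetic_params()] object.
#' @export
kinetic_params_for_occupancy <- function(occ_transient, occ_stable,
                                         k_off_T = 1, k_off_S = 0.01, ...) {
  check_scalar_number(occ_transient, "occ_transient", min = 0, max = 1)
  check_scalar_number(occ_stable, "occ_stable", min = 0, max = 1)
  occ_free <- 1 - occ_transient - occ_stable
  if (occ_free <= 0) {
    stop_bad_arg("occupancies must leave a positive free fraction.")
  }
  kinetic_params(k_bind_T = occ_transient * k_off_T / occ_free,
                 k_bind_S = occ_stable * k_off_S / occ_free,
                 k_off_T = k_off_T, k_off_S = k_off_S, ...)
}

#' Illumination scheme of a single-molecule movie
#'
#' Three named presets mirror common residence-time imaging practice:
#' `"fast"` (10 ms exposure, no dark time, for jump-distance analysis),
#' `"continuous"` (500 ms exposure, no dark time) and `"timelapse"`
#' (500 ms exposure alternating with a 10 s dark time, cycle 10.5 s).
#'
#' @param name One of `"fast"`, `"continuous"`, `"timelapse"`, or any other
#'   label when `exposure`/`dark_time` are given explicitly.
#' @param exposure Illuminated-frame duration (s).
#' @param dark_time Gap between illuminated frames (s).
#' @param n_frames Illuminated frames per movie.
#' @param tracking_radius Maximum frame-to-frame displacement linked into one
#'   track (um). Defaults emulate 4/3/5 camera pixels of 130 nm for the
#'   fast/continuous/timelapse presets.
#' @return An `illumination_scheme` object with derived `cycle_time`.
#' @examples
#' illumination_scheme("timelapse")$cycle_time  # 10.5 s
#' @export
illumination_scheme <- function(name = c("fast", "continuous", "timelapse"),
                                exposure = NULL, dark_time = NULL,
                                n_frames = NULL, tracking_radius = NULL) {
  name <- if (is.character(name)) name[[1]] else stop_bad_arg("`name` must be a string.")
  presets <- list(
    fast       = list(exposure = 0.010, dark_time = 0,  n_frames = 2500,
                      tracking_radius = 4 * 0.13),
    continuous = list(exposure = 0.500, dark_time = 0,  n_frames = 600,
                      tracking_radius = 3 * 0.13),
    timelapse  = list(exposure = 0.500, dark_time = 10, n_frames = 40,
                      tracking_radius = 5 * 0.13)
  )
  base <- presets[[name]]
  if (is.null(base)) {
    if (is.null(exposure)) {
      stop_bad_arg(sprintf("unknown scheme '%s' and no explicit `exposure`.", name))
    }
    base <- list(exposure = NA_real_, dark_time = 0, n_frames = 1000,
                 tracking_radius = 0.52)
  }
  exposure <- exposure %||% base$exposure
  dark_time <- dark_time %||% base$dark_time
  n_frames <- n_frames %||% base$n_frames
  tracking_radius <- tracking_radius %||% base$tracking_radius
  check_scalar_number(exposure, "exposure", min = 1e-9)
  check_scalar_number(dark_time, "dark_time", min = 0)
  check_scalar_number(n_frames, "n_frames", min = 2)
  check_scalar_number(tracking_radius, "tracking_radius", min = 0)
  structure(list(name = name, exposure = exposure, dark_time = dark_time,
                 n_frames = as.integer(n_frames),
                 cycle_time = exposure + dark_time,
                 tracking_radius = tracking_radius),
            class = "illumination_scheme")
}

#' @export
print.illumination_scheme <- function(x, ...) {
  cat(sprintf("<illumination_scheme '%s'> exposure %.3g s, dark %.3g s, cycle %.3g s, %d frames\n",
              x$name, x$exposure, x$dark_time, x$cycle_time, x$n_frames))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
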