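#' Build fluorescence survival counts from slow-scheme tracks
#'
#' The survival time of a track is `(illuminated frames - 1) * cycle_time`.
#' Returns, for every frame count `n >= 2`, the number of tracks lasting at
#' least `n` illuminated frames. Tracks that reach the final movie frame are
#' right-censored; they are excluded by default.
#'
#' @param tracks Track tibble (from [simulate_tracks()] or read from disk)
#'   with `track_id`, `frame`, `touches_movie_end`; alternatively a tibble
#'   with one row per track and a `frames` column (as produced by
#'   [simulate_survival_events()]).
#' @param scheme The [illumination_scheme()] of the movie (must be a slow
#'   scheme, i.e. not the 10 ms fast preset).
#' @param drop_censored Drop tracks flagged `touches_movie_end` (default TRUE).
#' @return A `survival_data` object: list with `counts` (tibble `n`, `N`),
#'   `cycle_time`, `n_tracks`, `censored`, `scheme_name`, and `frames`
#'   (per-track frame counts retained for resampling).
#' @examples
#' sch <- illumination_scheme("continuous", n_frames = 50)
#' ev <- simulate_survival_events(0.2, 1, sch, 500, seed = 1)
#' build_survival(ev, sch)
#' @export
build_survival <- function(tracks, scheme, drop_censored = TRUE) {
  stopifnot(is.data.frame(tracks), inherits(scheme, "illumination_scheme"))
  if (scheme$name == "fast") {
    stop_bad_arg("survival analysis expects a slow scheme (continuous or timelapse).")
  }
  if ("frames" %in% names(tracks) && !"frame" %in% names(tracks)) {
    per_track <- tibble(frames = as.integer(tracks$frames),
                        censored = if ("touches_movie_end" %in% names(tracks))
                          tracks$touches_movie_end else rep(FALSE, nrow(tracks)))
  } else {
    per_track <- tracks %>%
      group_by(.data$track_id) %>%
      summarise(frames = dplyr::n(),
                censored = any(.data$touches_movie_end), .groups = "drop") %>%
      select("frames", "censored")
  }
  n_censored <- sum(per_track$censored)
  if (drop_censored) per_track <- filter(per_track, !.data$censored)
  frames <- per_track$frames[per_track$frames >= 2L]
  if (!length(frames)) {
    stop_bad_arg("no usable tracks (>= 2 frames) for survival analysis.")
  }
  n_grid <- seq(2L, max(frames))
  counts <- tibble(n = n_grid,
                   N = vapply(n_grid, function(k) sum(frames >= k), integer(1)))
  structure(list(counts = counts, cycle_time = scheme$cycle_time,
                 n_tracks = length(frames), censored = n_censored,
                 scheme_name = scheme$name, frames = frames,
                 n_frames_movie = scheme$n_frames),
            class = "survival_data")
}

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf("<survival_data '%s'> %d tracks (%d censored dropped), cycle %.3g s, max %d frames\n",
              x$scheme_name, x$n_tracks, x$censored, x$cycle_time,
              max(x$counts$n)))
  invisible(x)
}

#' Survival times of individual tracks
#'
#' @param survival A `survival_data` object.
#' @return Numeric vector of per-track survival times in seconds,
#'   `(frames - 1) * cycle_time`.
#' @export
survival_times <- function(survival) {
  stopifnot(inherits(survival, "survival_data"))
  (survival$frames - 1) * survival$cycle_time
}
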