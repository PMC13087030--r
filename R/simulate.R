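#' Simulate single-molecule tracks under a three-state kinetic model
#'
#' Each molecule evolves as a continuous-time Markov chain over
#' free/transient/stable states (see [kinetic_params()]). Free molecules
#' diffuse with `D_free` inside a reflecting disk of radius `nucleus_radius`;
#' bound molecules are immobile up to localization noise. One localization is
#' emitted per illuminated frame (position taken at mid-exposure) with
#' isotropic Gaussian noise `sigma_loc`, and after every illuminated frame the
#' fluorophore bleaches with probability `p_bleach`, truncating the emission.
#' Emitted localizations are linked into tracks exactly as a tracking program
#' would: consecutive frames whose displacement stays within the scheme's
#' `tracking_radius` belong to one track, larger jumps start a new track, and
#' only tracks with at least two localizations are kept.
#'
#' @param params A [kinetic_params()] object (the simulation ground truth).
#' @param scheme An [illumination_scheme()].
#' @param n_molecules Number of independent molecules.
#' @param seed Integer seed; required, the simulation is bit-reproducible.
#' @param n_cells Number of cells the molecules are distributed over
#'   (metadata only).
#' @param initial_state `"stationary"` draws the initial state from the
#'   stationary distribution; alternatively force `"free"`, `"transient"` or
#'   `"stable"`.
#' @param blur_cutoff Motion-blur detection cutoff (um). A freely diffusing
#'   molecule smears over roughly `sqrt(4 D exposure)` during one frame; when
#'   that exceeds the cutoff its localizations are suppressed, emulating how
#'   long exposures blur out movers so that only bound molecules are detected
#'   in slow movies. Bound molecules are always detected, and bleaching still
#'   ticks on every illuminated frame. Set to `Inf` to detect everything.
#' @return An object of class `smt_sim`: a list with `tracks` (tibble with
#'   columns `track_id`, `cell_id`, `frame`, `time_s`, `x_um`, `y_um`,
#'   `true_state`, `touches_movie_end`), `truth` (exact state-sojourn
#'   statistics of the simulated paths, including the realized
#'   stable-association event rate per molecule-second of non-stable time),
#'   `scheme` and `params`.
#' @examples
#' sim <- simulate_tracks(kinetic_params(), illumination_scheme("fast", n_frames = 100),
#'                        n_molecules = 20, seed = 1)
#' head(sim$tracks)
#' sim$truth$occupancy
#' @export
simulate_tracks <- function(params, scheme, n_molecules, seed,
                            n_cells = 1L,
                            initial_state = c("stationary", "free",
                                              "transient", "stable"),
                            blur_cutoff = 0.5) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(scheme, "illumination_scheme"))
  if (!is.numeric(n_molecules) || n_molecules < 1) {
    stop_bad_arg("`n_molecules` must be >= 1.")
  }
  n_molecules <- as.integer(n_molecules)
  seed <- check_seed(seed)
  initial_state <- match.arg(initial_state)

  pi0 <- stationary_occupancy(params)
  frame_times <- (seq_len(scheme$n_frames) - 1) * scheme$cycle_time +
    scheme$exposure / 2
  t_end <- frame_times[length(frame_times)]

  withr::with_seed(seed, {
    pieces <- vector("list", n_molecules)
    occ_time <- c(free = 0, transient = 0, stable = 0)
    stable_entries <- 0
    sojourns <- list(free = numeric(0), transient = numeric(0),
                     stable = numeric(0))

    for (m in seq_len(n_molecules)) {
      path <- sim_ctmc_path(params, t_end, pi0, initial_state)
      occ_time <- occ_time + path$time_in_state
      stable_entries <- stable_entries + path$stable_entries
      for (s in names(sojourns)) {
        sojourns[[s]] <- c(sojourns[[s]], path$sojourns[[s]])
      }
      emitted <- emit_localizations(path, params, scheme, frame_times,
                                    blur_cutoff)
      if (!is.null(emitted)) {
        emitted$molecule <- m
        pieces[[m]] <- emitted
      }
    }

    tracks <- link_tracks(pieces, scheme, n_cells)
  })

  total_time <- sum(occ_time)
  nonstable_time <- occ_time[["free"]] + occ_time[["transient"]]
  truth <- list(
    occupancy = occ_time / total_time,
    stationary = pi0,
    f_bound = unname((occ_time[["transient"]] + occ_time[["stable"]]) / total_time),
    stable_entries = stable_entries,
    nonstable_time = nonstable_time,
    nu_realized = if (nonstable_time > 0) stable_entries / nonstable_time else 0,
    mean_sojourn = vapply(sojourns, function(x) {
      if (length(x)) mean(x) else NA_real_
    }, numeric(1))
  )

  structure(list(tracks = tracks, truth = truth, scheme = scheme,
                 params = params),
            class = "smt_sim")
}

# One molecule's state path over [0, t_end].
sim_ctmc_path <- function(params, t_end, pi0, initial_state) {
  rates_out <- c(free = params$k_bind_T + params$k_bind_S,
                 transient = params$k_off_T,
                 stable = params$k_off_S)
  state <- if (initial_state == "stationary") {
    sample(c("free", "transient", "stable"), 1, prob = pi0)
  } else initial_state

  t_now <- 0
  states <- character(0)
  starts <- numeric(0)
  stable_entries <- 0L
  sojourns <- list(free = numeric(0), transient = numeric(0),
                   stable = numeric(0))

  while (t_now < t_end) {
    r <- rates_out[[state]]
    dwell <- if (r > 0) rexp(1, r) else Inf
    states <- c(states, state)
    starts <- c(starts, t_now)
    t_leave <- t_now + dwell
    if (t_leave >= t_end) {
      t_now <- t_end
      break
    }
    sojourns[[state]] <- c(sojourns[[state]], dwell)
    nxt <- switch(state,
      free = if (runif(1) < params$k_bind_T / r) "transient" else "stable",
      transient = "free",
      stable = "free")
    if (nxt == "stable") stable_entries <- stable_entries + 1L
    state <- nxt
    t_now <- t_leave
  }
  ends <- c(starts[-1], t_end)
  time_in_state <- c(free = 0, transient = 0, stable = 0)
  dt <- ends - starts
  for (s in unique(states)) {
    time_in_state[[s]] <- sum(dt[states == s])
  }
  list(states = states, starts = starts, ends = ends,
       time_in_state = time_in_state, stable_entries = stable_entries,
       sojourns = sojourns)
}

# Cumulative time spent free up to time t (piecewise linear in t).
cumulative_free_time <- function(path, t) {
  idx <- findInterval(t, path$starts)
  free_dur <- ifelse(path$states == "free", path$ends - path$starts, 0)
  cum_before <- c(0, cumsum(free_dur))[idx]
  in_free <- path$states[idx] == "free"
  cum_before + ifelse(in_free, t - path$starts[idx], 0)
}

emit_localizations <- function(path, params, scheme, frame_times,
                               blur_cutoff) {
  n_frames <- length(frame_times)
  n_emit <- if (params$p_bleach > 0) {
    min(n_frames, 1L + rgeom(1, params$p_bleach))
  } else n_frames
  if (n_emit < 2L) {
    return(NULL)
  }
  ft <- frame_times[seq_len(n_emit)]
  state_idx <- findInterval(ft, path$starts)
  states <- path$states[state_idx]

  cf <- cumulative_free_time(path, ft)
  free_dt <- diff(c(cumulative_free_time(path, 0), cf))

  # initial position uniform in the nuclear disk
  repeat {
    p0 <- runif(2, -params$nucleus_radius, params$nucleus_radius)
    if (sum(p0^2) <= params$nucleus_radius^2) break
  }
  pos <- matrix(NA_real_, n_emit, 2)
  cur <- p0
  sdv <- sqrt(2 * params$D_free * pmax(free_dt, 0))
  for (i in seq_len(n_emit)) {
    if (free_dt[i] > 0) {
      cur <- reflect_disk(cur + rnorm(2, 0, sdv[i]), params$nucleus_radius)
    }
    pos[i, ] <- cur
  }
  noise <- matrix(rnorm(2L * n_emit, 0, params$sigma_loc), n_emit, 2)
  out <- tibble(frame = seq_len(n_emit) - 1L, time_s = ft,
                x_um = pos[, 1] + noise[, 1], y_um = pos[, 2] + noise[, 2],
                true_state = states,
                last_movie_frame = seq_len(n_emit) - 1L == n_frames - 1L)
  # motion blur: freely diffusing molecules are not localized when their
  # within-frame smear exceeds the cutoff (long-exposure movies)
  if (sqrt(4 * params$D_free * scheme$exposure) > blur_cutoff) {
    out <- out[out$true_state != "free", , drop = FALSE]
    if (nrow(out) < 2L) return(NULL)
  }
  out
}

reflect_disk <- function(p, radius) {
  r <- sqrt(sum(p^2))
  if (r <= radius) return(p)
  r_new <- 2 * radius - r
  if (r_new < 0) r_new <- radius * abs(r_new / radius) %% 1 # pathological jumps
  p * (r_new / r)
}

# Split each molecule's emission into tracks at jumps beyond tracking_radius,
# keep pieces with >= 2 localizations, assign ids and cells.
link_tracks <- function(pieces, scheme, n_cells) {
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    return(tibble(track_id = character(0), cell_id = integer(0),
                  frame = integer(0), time_s = numeric(0), x_um = numeric(0),
                  y_um = numeric(0), true_state = character(0),
                  touches_movie_end = logical(0)))
  }
  out <- vector("list", length(pieces))
  for (j in seq_along(pieces)) {
    df <- pieces[[j]]
    jump <- sqrt(diff(df$x_um)^2 + diff(df$y_um)^2)
    gap <- diff(df$frame) > 1L
    brk <- c(0, cumsum(jump > scheme$tracking_radius | gap))
    df$piece <- brk
    out[[j]] <- df
  }
  all <- dplyr::bind_rows(out)
  all <- all %>%
    group_by(.data$molecule, .data$piece) %>%
    filter(dplyr::n() >= 2L) %>%
    mutate(touches_movie_end = any(.data$last_movie_frame)) %>%
    ungroup()
  if (!nrow(all)) {
    return(tibble(track_id = character(0), cell_id = integer(0),
                  frame = integer(0), time_s = numeric(0), x_um = numeric(0),
                  y_um = numeric(0), true_state = character(0),
                  touches_movie_end = logical(0)))
  }
  key <- paste(all$molecule, all$piece, sep = "_")
  ids <- match(key, unique(key))
  all$track_id <- sprintf("trk%05d", ids)
  all$cell_id <- ((all$molecule - 1L) %% n_cells) + 1L
  all %>%
    select("track_id", "cell_id", "frame", "time_s", "x_um", "y_um",
           "true_state", "touches_movie_end")
}

#' Simulate fluorescence-survival tracks directly from a rate mixture
#'
#' Track-level generator used to exercise the dissociation-rate spectrum
#' solver without the full spatial simulator. Tracks arise from the two
#' channels a movie of pre-equilibrated molecules produces:
#'
#' * *standing stock*: molecules already bound at the first movie frame.
#'   Their component is drawn length-biased (state amplitudes, `S_k/k_k`)
#'   and, by memorylessness, their residual bound time is exponential.
#' * *binding events*: molecules binding during the movie. Their component
#'   follows the event amplitudes and they enter the frame grid at a uniform
#'   phase of the illumination cycle.
#'
#' At stationarity the binding flux equals occupancy over mean residence
#' time, which fixes the stock share at `tau_bar / (tau_bar + W)` with
#' `tau_bar` the event-weighted mean residence time and `W` the pre-bleach
#' observation window. Durations are additionally truncated by per-frame
#' bleaching; only tracks observed for at least two illuminated frames are
#' returned. With `include_stock = FALSE` every track is a binding event.
#'
#' @param rates Dissociation rates of the mixture components (1/s).
#' @param amplitudes Event amplitudes (will be normalized to sum to 1).
#' @param scheme An [illumination_scheme()]; its `cycle_time` defines the
#'   frame grid and its `n_frames` caps the observable length.
#' @param n_events Number of tracks (before the two-frame filter) to draw.
#' @param p_bleach Bleaching probability per illuminated frame.
#' @param seed Integer seed.
#' @param include_stock Include the standing-stock channel (default TRUE).
#' @return A tibble with one row per observed track: `track_id`, `frames`
#'   (number of illuminated frames), `touches_movie_end`.
#' @export
simulate_survival_events <- function(rates, amplitudes, scheme, n_events,
                                     p_bleach = 0, seed,
                                     include_stock = TRUE) {
  seed <- check_seed(seed)
  stopifnot(length(rates) == length(amplitudes), all(rates > 0),
            all(amplitudes >= 0), sum(amplitudes) > 0,
            inherits(scheme, "illumination_scheme"))
  amplitudes <- amplitudes / sum(amplitudes)
  tau <- scheme$cycle_time
  withr::with_seed(seed, {
    if (include_stock) {
      tau_bar <- sum(amplitudes / rates)
      slots <- if (p_bleach > 0) {
        min(1 / p_bleach, scheme$n_frames - 1)
      } else scheme$n_frames - 1
      p_stock <- tau_bar / (tau_bar + slots * tau)
      stock <- runif(n_events) < p_stock
      s_amp <- (amplitudes / rates) / tau_bar
    } else {
      stock <- rep(FALSE, n_events)
      s_amp <- amplitudes
    }
    comp <- integer(n_events)
    if (any(stock)) {
      comp[stock] <- sample.int(length(rates), sum(stock), replace = TRUE,
                                prob = s_amp)
    }
    comp[!stock] <- sample.int(length(rates), sum(!stock), replace = TRUE,
                               prob = amplitudes)
    dur <- rexp(n_events, rates[comp])
    # stock tracks are detected at frame 0 (phase 0); events enter at a
    # uniform phase. Frames = illuminated instants covered by the interval.
    phase <- ifelse(stock, 0, runif(n_events, 0, tau))
    frames <- ifelse(stock,
                     1L + floor(dur / tau),
                     floor((phase + dur) / tau) - 1L + 1L)
    frames <- pmax(frames, 0L)
    if (p_bleach > 0) {
      frames <- pmin(frames, 1L + rgeom(n_events, p_bleach))
    }
    frames <- pmin(frames, scheme$n_frames)
  })
  keep <- frames >= 2L
  kept_frames <- as.integer(frames[keep])
  tibble(track_id = sprintf("ev%06d", which(keep)),
         frames = kept_frames,
         touches_movie_end = kept_frames >= scheme$n_frames)
}
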