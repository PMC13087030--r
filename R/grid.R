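#' Dissociation-rate spectrum from multi-scheme survival data
#'
#' Decomposes fluorescence survival-time distributions into a non-negative
#' spectrum of dissociation rates over a fixed log-spaced grid, jointly over
#' at least two illumination schemes with distinct cycle times. Fitting both
#' schemes globally separates molecular dissociation (which scales with real
#' time) from photobleaching and tracking loss (which scale with the number
#' of illuminated frames, summarized by the per-frame decay number `a_b`).
#'
#' A binding event of rate component \eqn{k} entering the frame grid of
#' scheme *c* (cycle time \eqn{\tau_c}) at a uniform phase is observed as a
#' track of \eqn{n \ge 2} frames with probability proportional to
#' \eqn{c_{ck} e^{-\lambda_{ck}}} and track-length distribution
#' \eqn{P(\ge n) = e^{-\lambda_{ck}(n-2)}}, where
#' \eqn{\lambda_{ck} = k \tau_c + a_b} and
#' \eqn{c_{ck} = (1 - e^{-k\tau_c})/(k\tau_c)} is the entry-phase truncation
#' factor. For every candidate `a_b` on a coarse scan grid the event
#' amplitudes \eqn{S_k} are estimated by maximum likelihood on this
#' truncated geometric mixture (an EM iteration with inclusion-probability
#' correction, so amplitudes remain comparable across schemes); the scan is
#' refined around the best coarse value. Because the nonparametric maximum
#' likelihood spectrum is discrete, the converged solution is consolidated
#' by likelihood-guided support reduction: contiguous blobs of amplitude are
#' collapsed onto single grid rates whenever that does not reduce the
#' likelihood, recursively splitting blobs that resist collapse. No
#' smoothness penalty is applied; robustness comes from resampling:
#' uncertainties are standard deviations over `n_boot` refits on `boot_frac`
#' of tracks drawn without replacement (with `a_b` re-scanned locally around
#' the point estimate).
#'
#' @param survival_sets List of `survival_data` objects (one per scheme) with
#'   pairwise distinct cycle times; at least two schemes are required,
#'   otherwise `a_b` is unidentifiable.
#' @param rate_grid Log-spaced dissociation-rate grid (1/s). Default: 200
#'   rates from 1e-4 to 10.
#' @param n_boot Resampling refits (default 500). Use 0 to skip errors.
#' @param boot_frac Fraction of tracks per resample (default 0.8).
#' @param seed Integer seed for the resampling.
#' @param ab_scan Coarse scan grid for the per-frame decay number (default 60
#'   values from 0 to 1.5).
#' @param ab_refine Number of refinement points around the best coarse value.
#' @return A `rate_spectrum` object: list with `spectrum` (tibble `rate`,
#'   `event_amp`, `state_amp`, `event_sd`, `state_sd`), `a_b`, `a_b_sd`,
#'   `loglik`, `sse`, `n_tracks`, `schemes`.
#' @export
fit_grid_spectrum <- function(survival_sets,
                              rate_grid = NULL,
                              n_boot = 500, boot_frac = 0.8, seed,
                              ab_scan = seq(0, 1.5, length.out = 60),
                              ab_refine = 15) {
  seed <- check_seed(seed)
  if (inherits(survival_sets, "survival_data")) {
    survival_sets <- list(survival_sets)
  }
  stopifnot(all(vapply(survival_sets, inherits, logical(1), "survival_data")))
  taus <- vapply(survival_sets, `[[`, numeric(1), "cycle_time")
  if (length(survival_sets) < 2 || anyDuplicated(signif(taus, 10))) {
    stop_bad_arg("need >= 2 schemes with distinct cycle times: the per-frame bleaching number is unidentifiable from a single scheme.")
  }
  rate_grid <- rate_grid %||% exp(seq(log(1e-4), log(10), length.out = 200))
  if (!length(rate_grid) || any(rate_grid <= 0)) {
    stop_bad_arg("`rate_grid` must be a non-empty vector of positive rates.")
  }
  rate_grid <- sort(rate_grid)

  pt <- grid_point_fit(survival_sets, rate_grid, ab_scan, ab_refine)
  S <- pt$S
  st <- S / rate_grid
  st <- st / sum(st)

  if (n_boot > 0) {
    ab_local <- grid_refine_ab(pt$a_b, ab_scan, max(ab_refine %/% 2, 5))
    boots <- withr::with_seed(seed, {
      lapply(seq_len(n_boot), function(b) {
        sets_b <- lapply(survival_sets, resample_survival, frac = boot_frac)
        fb <- grid_point_fit(sets_b, rate_grid, ab_local, ab_refine = 0,
                             iters = c(scan = 150, final = 300, polish = 80),
                             n_shortlist = 2)
        Sb <- fb$S
        stb <- Sb / rate_grid
        list(S = Sb, st = stb / sum(stb), a_b = fb$a_b)
      })
    })
    Smat <- vapply(boots, `[[`, numeric(length(rate_grid)), "S")
    stmat <- vapply(boots, `[[`, numeric(length(rate_grid)), "st")
    event_sd <- apply(Smat, 1, sd)
    state_sd <- apply(stmat, 1, sd)
    a_b_sd <- sd(vapply(boots, `[[`, numeric(1), "a_b"))
  } else {
    event_sd <- state_sd <- rep(NA_real_, length(rate_grid))
    a_b_sd <- NA_real_
  }

  structure(list(
    spectrum = tibble(rate = rate_grid, event_amp = S, state_amp = st,
                      event_sd = event_sd, state_sd = state_sd),
    a_b = pt$a_b, a_b_sd = a_b_sd, loglik = pt$ll, sse = pt$sse,
    n_tracks = sum(vapply(survival_sets, `[[`, numeric(1), "n_tracks")),
    schemes = vapply(survival_sets, `[[`, character(1), "scheme_name")),
    class = "rate_spectrum")
}

resample_survival <- function(sv, frac) {
  m <- max(2L, floor(frac * length(sv$frames)))
  frames <- sample(sv$frames, m)
  structure(list(counts = NULL, cycle_time = sv$cycle_time, n_tracks = m,
                 censored = 0L, scheme_name = sv$scheme_name, frames = frames,
                 n_frames_movie = sv$n_frames_movie),
            class = "survival_data")
}

grid_refine_ab <- function(ab_best, ab_scan, n_points) {
  if (length(ab_scan) < 2) return(ab_best)
  step <- diff(sort(unique(ab_scan)))[1]
  seq(max(0, ab_best - step), ab_best + step, length.out = max(n_points, 3))
}

# Per-scheme sufficient statistics for one candidate a_b: counts per track
# length, the conditional geometric pmf rows, and the inclusion weights of
# the two track-origin channels. Tracks arise either from molecules already
# bound when the movie starts (standing stock, length-biased: weight
# S_k/k_k) or from binding events entering the frame grid during the
# pre-bleach observation window (weight S_k c_ck, window proportional to
# cycle_time * expected illuminated frames). Both channels share the same
# geometric survival shape by memorylessness; only the mixture weights
# differ. Their global intensity ratio eta0 (events per second per unit of
# standing stock) is a single nuisance parameter profiled out by maximum
# likelihood.
grid_prep <- function(survival_sets, rate_grid, ab) {
  p_frame <- 1 - exp(-ab)
  lapply(survival_sets, function(sv) {
    tab <- table(sv$frames)
    n <- as.integer(names(tab))
    m <- as.numeric(tab)
    lam <- rate_grid * sv$cycle_time + ab
    ck <- trunc_correction(rate_grid, sv$cycle_time)
    K <- length(rate_grid)
    pmf <- outer(n - 2, lam, function(a, l) exp(-a * l)) *
      matrix(1 - exp(-lam), length(n), K, byrow = TRUE)
    nf <- sv$n_frames_movie %||% (max(sv$frames) * 4)
    slots <- if (p_frame > 0) min(1 / p_frame, nf - 1) else nf - 1
    list(n = n, m = m, N = sum(m),
         stock = exp(-lam) / rate_grid,
         event = ck * exp(-lam),
         window = slots * sv$cycle_time,
         pmf = pmf)
  })
}

# Per-rate track-inclusion weight of scheme b. At stationarity the binding
# event flux equals bound occupancy / mean residence time, which fixes the
# stock:event intensity ratio: w_k = S_k/k_k + W_c S_k c_ck (both channels
# share the detection factor exp(-lambda)). No free channel parameter.
grid_w <- function(b, eta0 = 1) {
  b$stock + eta0 * b$window * b$event
}

grid_loglik <- function(pre, S, eta0 = 1) {
  sum(vapply(pre, function(b) {
    phi <- S * grid_w(b, eta0)
    z <- sum(phi)
    sum(b$m * log(pmax(as.numeric(b$pmf %*% phi) / z, 1e-300)))
  }, numeric(1)))
}

# EM for the truncated two-channel mixture: responsibilities weighted by
# track counts, amplitude update divided by the per-scheme inclusion weight
grid_em <- function(pre, S, eta0 = 1, iters) {
  K <- length(S)
  for (it in seq_len(iters)) {
    num <- numeric(K)
    den <- numeric(K)
    for (b in pre) {
      w <- grid_w(b, eta0)
      phi <- S * w
      z <- sum(phi)
      M <- b$pmf * matrix(phi, length(b$n), K, byrow = TRUE)
      rs <- pmax(rowSums(M), 1e-300)
      num <- num + colSums((b$m / rs) * M)
      den <- den + b$N * w / z
    }
    S <- num / pmax(den, 1e-300)
    S <- S / sum(S)
  }
  S
}


# likelihood-guided support reduction: collapse each contiguous amplitude
# blob onto its best single grid node if that does not cost likelihood;
# blobs that resist are split at their amplitude valley and retried
grid_collapse <- function(pre, S, eta0, tol) {
  sup <- which(S > 1e-4 * max(S))
  for (bl in split(sup, cumsum(c(1, diff(sup) > 1L)))) {
    S <- grid_collapse_blob(pre, S, eta0, bl, tol)
  }
  S / sum(S)
}

grid_collapse_blob <- function(pre, S, eta0, bl, tol) {
  if (length(bl) < 2) return(S)
  mass <- sum(S[bl])
  ll0 <- grid_loglik(pre, S, eta0)
  best_ll <- -Inf
  best <- NULL
  for (node in bl) {
    St <- S
    St[bl] <- 0
    St[node] <- mass
    llt <- grid_loglik(pre, St, eta0)
    if (llt > best_ll) {
      best_ll <- llt
      best <- St
    }
  }
  if (best_ll >= ll0 - tol) return(best)
  w <- S[bl]
  inner <- w[-c(1, length(w))]
  valley <- bl[which.min(inner) + 1L]
  S <- grid_collapse_blob(pre, S, eta0, bl[bl <= valley], tol)
  grid_collapse_blob(pre, S, eta0, bl[bl > valley], tol)
}

# full sharpened fit at one a_b: EM, then alternating support collapse and
# re-seeded EM (the collapse accelerates the slow NPMLE convergence of plain
# EM, so candidate a_b values are compared at near-converged likelihoods)
grid_sharp_fit <- function(survival_sets, rate_grid, ab, n_total,
                           em_iters = 500, polish_iters = 150) {
  K <- length(rate_grid)
  pre <- grid_prep(survival_sets, rate_grid, ab)
  S <- grid_em(pre, rep(1 / K, K), iters = em_iters)
  tol <- 2 + 1e-4 * n_total
  for (r in 1:3) {
    S <- grid_collapse(pre, S, 1, tol)
    S <- 0.98 * S + 0.02 / K # re-seed so support can recover from collapses
    S <- grid_em(pre, S, iters = polish_iters)
  }
  S <- grid_collapse(pre, S, 1, tol)
  list(S = S, a_b = ab, ll = grid_loglik(pre, S))
}

grid_point_fit <- function(survival_sets, rate_grid, ab_scan, ab_refine,
                           iters = c(scan = 200, final = 500, polish = 150),
                           n_shortlist = 6) {
  K <- length(rate_grid)
  uniform <- rep(1 / K, K)
  n_total <- sum(vapply(survival_sets, `[[`, numeric(1), "n_tracks"))
  ll_quick <- function(ab) {
    pre <- grid_prep(survival_sets, rate_grid, ab)
    grid_loglik(pre, grid_em(pre, uniform, iters = iters[["scan"]]))
  }
  sharp <- function(ab) {
    grid_sharp_fit(survival_sets, rate_grid, ab, n_total,
                   em_iters = iters[["final"]],
                   polish_iters = iters[["polish"]])
  }
  lls <- vapply(ab_scan, ll_quick, numeric(1))
  short <- ab_scan[order(-lls)[seq_len(min(n_shortlist, length(ab_scan)))]]
  cands <- lapply(short, sharp)
  best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "ll"))]]
  if (ab_refine > 0 && length(ab_scan) > 2) {
    fine <- setdiff(grid_refine_ab(best$a_b, ab_scan, ab_refine), short)
    if (length(fine)) {
      fcands <- lapply(fine, sharp)
      fbest <- fcands[[which.max(vapply(fcands, `[[`, numeric(1), "ll"))]]
      if (fbest$ll > best$ll) best <- fbest
    }
  }
  best$sse <- grid_cond_sse(survival_sets, rate_grid, best$a_b, best$S, 1)
  best
}

# conditional survival-curve SSE of a given spectrum (diagnostic)
grid_cond_sse <- function(survival_sets, rate_grid, ab, S, eta0 = NULL) {
  pre <- grid_prep(survival_sets, rate_grid, ab)
  sum(unlist(Map(function(sv, b) {
    frames <- sv$frames
    n_grid <- seq(2L, max(frames))
    y <- vapply(n_grid, function(k) sum(frames >= k), numeric(1))
    y <- y / y[[1]]
    lam <- rate_grid * sv$cycle_time + ab
    w <- S * (if (is.null(eta0)) b$event else grid_w(b, eta0))
    surv <- outer(n_grid - 2, lam, function(a, l) exp(-a * l))
    pred <- as.numeric(surv %*% w) / sum(w)
    (y - pred)^2
  }, survival_sets, pre)))
}

# Internal baseline: strict non-negative least squares on the stacked
# conditional survival curves at fixed a_b (no per-scheme scale freedom).
# Used as a convex reference solution in tests.
grid_nnls <- function(survival_sets, rate_grid, ab) {
  rows <- lapply(survival_sets, function(sv) {
    frames <- sv$frames
    n_grid <- seq(2L, max(frames))
    y <- vapply(n_grid, function(k) sum(frames >= k), numeric(1))
    y <- y / y[[1]]
    lam <- rate_grid * sv$cycle_time + ab
    w1 <- trunc_correction(rate_grid, sv$cycle_time) * exp(-lam)
    X <- outer(n_grid - 2, lam, function(a, l) exp(-a * l)) *
      matrix(w1, length(n_grid), length(rate_grid), byrow = TRUE)
    list(X = X, y = y)
  })
  X <- do.call(rbind, lapply(rows, `[[`, "X"))
  y <- unlist(lapply(rows, `[[`, "y"))
  q <- nnls_lawson_hanson(X, y)
  sse <- sum((y - as.numeric(X %*% q))^2)
  list(S = if (sum(q) > 0) q / sum(q) else rep(1 / length(q), length(q)),
       sse = sse)
}

# Lawson-Hanson active-set non-negative least squares. The passive-set
# subproblems are solved through the SVD so that the severely collinear
# columns of a log-spaced exponential design cannot derail the active-set
# walk with a singular triangular solve.
nnls_lawson_hanson <- function(X, y, tol = NULL, max_iter = NULL) {
  n <- ncol(X)
  tol <- tol %||% (10 * .Machine$double.eps * sum(abs(X)) / length(X) * max(dim(X)))
  max_iter <- max_iter %||% (3L * n)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(X, y - X %*% x)
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- lsq_svd(X[, passive, drop = FALSE], y)
      if (min(s[passive]) > 0) break
      idx <- passive & s <= 0
      alpha <- min(x[idx] / (x[idx] - s[idx]))
      x <- x + alpha * (s - x)
      passive[passive & x <= .Machine$double.eps] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- crossprod(X, y - X %*% x)
  }
  x
}

lsq_svd <- function(A, b) {
  sv <- svd(A)
  keep <- sv$d > max(sv$d[1], 0) * 1e-12
  if (!any(keep)) return(numeric(ncol(A)))
  as.numeric(sv$v[, keep, drop = FALSE] %*%
               ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

# uniform-entry-phase truncation factor (1 - exp(-k tau)) / (k tau)
trunc_correction <- function(rates, tau) {
  x <- rates * tau
  ifelse(x < 1e-8, 1 - x / 2, (1 - exp(-x)) / x)
}

#' Residence-time-weighted state amplitudes of a rate spectrum
#'
#' Converts event amplitudes (fraction of binding events per rate) into state
#' amplitudes (instantaneous occupancy of each bound state):
#' \eqn{s_k = (S_k / k_k) / \sum_j (S_j / k_j)}.
#'
#' @param spectrum A `rate_spectrum` object, or a tibble with columns `rate`
#'   and `event_amp`.
#' @return Numeric vector of state amplitudes summing to one.
#' @export
state_spectrum <- function(spectrum) {
  tb <- if (inherits(spectrum, "rate_spectrum")) spectrum$spectrum else spectrum
  stopifnot(all(c("rate", "event_amp") %in% names(tb)))
  if (any(tb$event_amp < 0)) stop_bad_arg("event amplitudes must be >= 0.")
  if (sum(tb$event_amp) <= 0) {
    stop_bad_arg("all-zero spectrum: state amplitudes are undefined.")
  }
  s <- tb$event_amp / tb$rate
  s / sum(s)
}

#' @export
print.rate_spectrum <- function(x, ...) {
  nz <- filter(x$spectrum, .data$event_amp > 1e-6)
  cat(sprintf("<rate_spectrum> %d grid rates, a_b = %.4f (per frame), %d tracks, schemes: %s\n",
              nrow(x$spectrum), x$a_b, x$n_tracks,
              paste(x$schemes, collapse = ", ")))
  print(nz)
  invisible(x)
}

#' @export
tidy.rate_spectrum <- function(x, ...) x$spectrum

#' @export
glance.rate_spectrum <- function(x, ...) {
  tibble(a_b = x$a_b, a_b_sd = x$a_b_sd, loglik = x$loglik, sse = x$sse,
         n_tracks = x$n_tracks, n_rates = nrow(x$spectrum))
}

#' @export
autoplot.rate_spectrum <- function(object, which = c("event", "state"), ...) {
  which <- match.arg(which)
  col <- paste0(which, "_amp")
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$rate, y = .data[[col]])) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$rate, yend = 0),
                          color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dissociation rate (1/s)",
                  y = sprintf("%s amplitude", which),
                  title = sprintf("Dissociation-rate spectrum (a_b = %.3f/frame)",
                                  object$a_b))
}
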