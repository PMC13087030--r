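#' Extract squared frame-to-frame jump distances from tracks
#'
#' Collects squared displacements between localizations in consecutive
#' illuminated frames (lag 1; gap frames are not bridged). Intended for
#' fast-scheme movies, where the jump-distance distribution carries the
#' diffusive information.
#'
#' @param tracks Track tibble as produced by [simulate_tracks()] (columns
#'   `track_id`, `frame`, `x_um`, `y_um`).
#' @param scheme The [illumination_scheme()] the tracks were acquired with.
#' @return A tibble of class `jump_sample` with column `u` (squared jump,
#'   um^2) and attributes `dt` (lag, s) and `n_jumps`.
#' @export
jump_distances <- function(tracks, scheme) {
  stopifnot(is.data.frame(tracks), inherits(scheme, "illumination_scheme"))
  jt <- tracks %>%
    group_by(.data$track_id) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    mutate(du = (.data$x_um - dplyr::lag(.data$x_um))^2 +
                (.data$y_um - dplyr::lag(.data$y_um))^2,
           dframe = .data$frame - dplyr::lag(.data$frame)) %>%
    ungroup() %>%
    filter(!is.na(.data$du), .data$dframe == 1L)
  out <- tibble(u = jt$du)
  attr(out, "dt") <- scheme$cycle_time
  attr(out, "n_jumps") <- nrow(out)
  class(out) <- c("jump_sample", class(out))
  out
}

#' Fit a multi-component diffusion model to the jump-distance CDF
#'
#' Fits \eqn{F(u) = 1 - \sum_i A_i \exp(-u / (4 D_i \Delta t))} to the
#' empirical cumulative distribution of squared jump distances by least
#' squares, evaluated at every observed jump. Amplitudes are constrained to
#' the simplex and diffusion coefficients to be strictly increasing (both by
#' smooth reparameterization); the optimizer is restarted from `n_starts`
#' random initializations and the best solution kept. The amplitude `A_1` of
#' the slowest component is the bound fraction: localization error and slow
#' chromatin motion are absorbed into `D_1` rather than modeled by an
#' explicit noise term. Components whose fitted coefficients collapse onto
#' each other (ratio below `merge_ratio`) are merged, amplitude-weighted, so
#' that amplitude split across duplicated components is reported as one.
#'
#' Uncertainties are standard deviations over `n_boot` refits, each on a
#' `boot_frac` subsample of jumps drawn without replacement and started from
#' the full-data optimum.
#'
#' @param jumps A [jump_distances()] tibble, or any tibble with column `u`
#'   and a `dt` attribute (alternatively pass `dt`).
#' @param n_components Number of apparent diffusion components (default 3).
#' @param n_boot Number of resampling refits for errors (default 400).
#' @param boot_frac Fraction of jumps per resample (default 0.8).
#' @param seed Integer seed for the multi-start and resampling.
#' @param dt Lag time between frames (s); overrides the attribute.
#' @param d_floor Lower bound for the slowest coefficient (um^2/s).
#' @param n_starts Random restarts for the point fit.
#' @param merge_ratio Components with `D[i+1]/D[i]` below this are merged.
#' @return A `diffusion_fit` object: list with `components` (tibble `A`, `D`,
#'   `A_sd`, `D_sd`), `bound_fraction`, `n_jumps`, `dt`, `sse`, `converged`.
#' @examples
#' sch <- illumination_scheme("fast", n_frames = 200)
#' sim <- simulate_tracks(kinetic_params(), sch, n_molecules = 50, seed = 2)
#' fit <- fit_jump_cdf(jump_distances(sim$tracks, sch), n_boot = 20, seed = 3)
#' fit$bound_fraction
#' @export
fit_jump_cdf <- function(jumps, n_components = 3, n_boot = 400,
                         boot_frac = 0.8, seed, dt = NULL, d_floor = 1e-4,
                         n_starts = 10, merge_ratio = 1.15) {
  seed <- check_seed(seed)
  u <- if (is.data.frame(jumps)) jumps$u else as.numeric(jumps)
  dt <- dt %||% attr(jumps, "dt")
  if (is.null(dt)) stop_bad_arg("`dt` is required (attribute or argument).")
  check_scalar_number(dt, "dt", min = 1e-12)
  if (any(!is.finite(u)) || any(u < 0)) {
    stop_bad_arg("squared jumps must be finite and non-negative.")
  }
  n <- length(u)
  if (n < 10 * n_components) {
    stop_bad_arg(sprintf("need at least %d jumps for %d components, got %d.",
                         10 * n_components, n_components, n))
  }

  u_sorted <- sort(u)
  # degenerate: effectively no displacement at all
  if (max(u_sorted) <= .Machine$double.eps) {
    comp <- tibble(A = c(1, rep(0, n_components - 1)),
                   D = d_floor * cumprod(c(1, rep(10, n_components - 1))),
                   A_sd = 0, D_sd = 0)
    return(new_diffusion_fit(comp, n, dt, sse = 0, converged = TRUE))
  }
  f_emp <- seq_len(n) / n

  fit1 <- withr::with_seed(seed, {
    best <- fit_jump_multistart(u_sorted, f_emp, n_components, dt, d_floor,
                                n_starts)
    boots <- replicate(n_boot, {
      idx <- sort(sample.int(n, floor(boot_frac * n)))
      ub <- u_sorted[idx]
      fb <- seq_along(ub) / length(ub)
      fit_jump_once(ub, fb, n_components, dt, d_floor, best$par)$theta
    })
    list(best = best, boots = boots)
  })
  best <- fit1$best

  theta_pt <- decode_jump_theta(best$par, n_components, d_floor)
  if (n_boot > 0) {
    bmat <- matrix(unlist(lapply(seq_len(n_boot), function(b) {
      th <- decode_jump_theta(fit1$boots[, b], n_components, d_floor)
      c(th$A, th$D)
    })), nrow = 2 * n_components)
    A_sd <- apply(bmat[seq_len(n_components), , drop = FALSE], 1, sd)
    D_sd <- apply(bmat[n_components + seq_len(n_components), , drop = FALSE], 1, sd)
  } else {
    A_sd <- D_sd <- rep(NA_real_, n_components)
  }

  comp <- tibble(A = theta_pt$A, D = theta_pt$D, A_sd = A_sd, D_sd = D_sd)
  comp <- merge_components(comp, merge_ratio)
  new_diffusion_fit(comp, n, dt, sse = best$value, converged = best$convergence == 0)
}

new_diffusion_fit <- function(components, n_jumps, dt, sse, converged) {
  structure(list(components = components,
                 bound_fraction = components$A[[1]],
                 n_jumps = n_jumps, dt = dt, sse = sse, converged = converged),
            class = "diffusion_fit")
}

# theta = (logits of A_2..A_K relative to A_1, log(D_1 - floor), log growth
# factors); amplitudes live on the simplex, coefficients strictly ascend.
decode_jump_theta <- function(theta, k, d_floor) {
  la <- c(0, theta[seq_len(k - 1)])
  A <- exp(la - max(la)); A <- A / sum(A)
  g <- theta[k - 1 + seq_len(k)]
  D <- d_floor + cumsum(exp(g))
  list(A = A, D = D)
}

jump_model_cdf <- function(u, A, D, dt) {
  m <- outer(u, 4 * D * dt, function(uu, s) exp(-uu / s))
  1 - as.numeric(m %*% A)
}

jump_objective <- function(theta, u, f_emp, k, dt, d_floor) {
  th <- decode_jump_theta(theta, k, d_floor)
  sum((jump_model_cdf(u, th$A, th$D, dt) - f_emp)^2)
}

# analytic gradient through the simplex/ordering reparameterization
jump_gradient <- function(theta, u, f_emp, k, dt, d_floor) {
  th <- decode_jump_theta(theta, k, d_floor)
  A <- th$A; D <- th$D
  E <- outer(u, 4 * D * dt, function(uu, s) exp(-uu / s)) # n x k
  r <- (1 - as.numeric(E %*% A)) - f_emp
  dA <- -2 * as.numeric(crossprod(E, r))                  # dobj/dA_i
  da <- A[-1] * (dA[-1] - sum(dA * A))                    # softmax chain rule
  dD <- vapply(seq_len(k), function(i) {
    -2 * A[i] * sum(r * E[, i] * u) / (4 * dt * D[i]^2)
  }, numeric(1))
  g <- theta[k - 1 + seq_len(k)]
  dg <- exp(g) * rev(cumsum(rev(dD)))
  c(da, dg)
}

fit_jump_once <- function(u, f_emp, k, dt, d_floor, theta0) {
  o <- optim(theta0, jump_objective, gr = jump_gradient, u = u,
             f_emp = f_emp, k = k, dt = dt, d_floor = d_floor,
             method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  o$theta <- o$par
  o
}

fit_jump_multistart <- function(u, f_emp, k, dt, d_floor, n_starts) {
  # moment-based anchor: spread starts around mean(u)/(4 dt) over decades
  d_hat <- max(mean(u) / (4 * dt), d_floor * 10)
  best <- NULL
  for (s in seq_len(n_starts)) {
    d_lo <- d_hat * 10^runif(1, -3, -0.5)
    ratios <- 10^runif(k, 0.3, 1.5)
    g0 <- log(diff(c(d_floor, d_lo * cumprod(ratios))))
    a0 <- rnorm(k - 1, 0, 1)
    o <- fit_jump_once(u, f_emp, k, dt, d_floor, c(a0, g0))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best
}

# merge adjacent components with nearly identical coefficients
merge_components <- function(comp, merge_ratio) {
  repeat {
    if (nrow(comp) < 2) break
    r <- comp$D[-1] / comp$D[-nrow(comp)]
    i <- which(r < merge_ratio)[1]
    if (is.na(i)) break
    w <- comp$A[i] + comp$A[i + 1]
    comp$D[i] <- if (w > 0) {
      (comp$A[i] * comp$D[i] + comp$A[i + 1] * comp$D[i + 1]) / w
    } else mean(comp$D[i + 0:1])
    comp$A[i] <- w
    comp$A_sd[i] <- sqrt(comp$A_sd[i]^2 + comp$A_sd[i + 1]^2)
    comp <- comp[-(i + 1), ]
  }
  comp
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> %d components, %d jumps, dt = %.4g s\n",
              nrow(x$components), x$n_jumps, x$dt))
  cat(sprintf("  bound fraction (A1): %.3f\n", x$bound_fraction))
  print(x$components)
  invisible(x)
}

#' @export
tidy.diffusion_fit <- function(x, ...) {
  x$components %>%
    mutate(component = row_number(), .before = 1) %>%
    rename(amplitude = "A", diffusion_coef = "D",
           amplitude_sd = "A_sd", diffusion_coef_sd = "D_sd")
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(bound_fraction = x$bound_fraction, n_jumps = x$n_jumps,
         dt = x$dt, sse = x$sse, converged = x$converged)
}

#' @export
autoplot.diffusion_fit <- function(object, jumps = NULL, ...) {
  comps <- tidy(object)
  grid <- tibble(u = seq(0, max(4 * max(comps$diffusion_coef) * object$dt * 3,
                                1e-3), length.out = 400))
  grid$F <- jump_model_cdf(grid$u, comps$amplitude, comps$diffusion_coef,
                           object$dt)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$u, y = .data$F)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = expression(u ~ (mu * m^2)),
                  y = "P(jump² ≤ u)",
                  title = "Jump-distance CDF fit")
  if (!is.null(jumps)) {
    uu <- sort(if (is.data.frame(jumps)) jumps$u else jumps)
    emp <- tibble(u = uu, F = seq_along(uu) / length(uu))
    p <- p + ggplot2::geom_step(data = emp, color = "grey40", alpha = 0.7)
  }
  p
}
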