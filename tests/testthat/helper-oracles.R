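# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: linear algebra for the Markov chain, brute-force
# geometry for SASA, direct nonlinear fits for exponential mixtures.

# stationary distribution of the 3-state chain by solving pi Q = 0
oracle_stationary <- function(params) {
  Q <- matrix(0, 3, 3, dimnames = list(c("free", "transient", "stable"),
                                       c("free", "transient", "stable")))
  Q["free", "transient"] <- params$k_bind_T
  Q["free", "stable"] <- params$k_bind_S
  Q["transient", "free"] <- params$k_off_T
  Q["stable", "free"] <- params$k_off_S
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, 3))
  b <- c(0, 0, 0, 1)
  pi_hat <- qr.solve(A, b)
  setNames(pmax(pi_hat, 0) / sum(pmax(pi_hat, 0)), rownames(Q))
}

# brute-force Shrake-Rupley at arbitrary density: all-pairs occlusion test,
# no spatial binning, independent golden-spiral construction
oracle_sasa_total <- function(atoms, probe, n_points, select = NULL) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rext <- atoms$radius + probe
  idx <- seq_len(nrow(xyz))
  sel <- if (is.null(select)) idx else which(select)
  gold <- function(n) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
    cbind(r * cos(phi), r * sin(phi), z)
  }
  pts <- gold(n_points)
  total <- 0
  for (i in sel) {
    p <- sweep(pts * rext[i], 2, xyz[i, ], `+`)
    occ <- rep(FALSE, n_points)
    for (j in idx[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      occ <- occ | d2 < rext[j]^2
    }
    total <- total + sum(!occ) / n_points * 4 * pi * rext[i]^2
  }
  total
}

# direct nonlinear least-squares fit of one or two exponentials (plus fixed
# bleach) to the stacked conditional survival curves of several schemes
oracle_exp_survival_fit <- function(survival_sets, n_comp, ab = 0) {
  p_frame <- 1 - exp(-ab)
  curves <- lapply(survival_sets, function(sv) {
    n <- seq(2L, max(sv$frames))
    y <- vapply(n, function(k) sum(sv$frames >= k), numeric(1))
    nf <- sv$n_frames_movie
    window <- (if (p_frame > 0) min(1 / p_frame, nf - 1) else nf - 1) *
      sv$cycle_time
    list(n = n, y = y / y[[1]], tau = sv$cycle_time, window = window)
  })
  predict_sse <- function(rates, amps) {
    sum(unlist(lapply(curves, function(cv) {
      lam <- rates * cv$tau + ab
      ck <- (1 - exp(-rates * cv$tau)) / (rates * cv$tau)
      w <- amps * exp(-lam) * (1 / rates + cv$window * ck)
      w <- w / sum(w)
      pred <- vapply(cv$n, function(nn) sum(w * exp(-lam * (nn - 2))),
                     numeric(1))
      (cv$y - pred)^2
    })))
  }
  if (n_comp == 1) {
    o <- optimize(function(lk) predict_sse(exp(lk), 1), c(log(1e-4), log(10)))
    list(rates = exp(o$minimum), amps = 1, sse = o$objective)
  } else {
    obj <- function(th) predict_sse(exp(th[1:2]), c(plogis(th[3]), 1 - plogis(th[3])))
    best <- NULL
    for (start in list(c(log(0.01), log(1), 0), c(log(0.05), log(0.5), 1),
                       c(log(0.002), log(2), -1))) {
      o <- optim(start, obj, control = list(maxit = 2000))
      if (is.null(best) || o$value < best$value) best <- o
    }
    k <- exp(best$par[1:2])
    a <- c(plogis(best$par[3]), 1 - plogis(best$par[3]))
    ord <- order(k)
    list(rates = k[ord], amps = a[ord], sse = best$value)
  }
}

# do two labelings induce the same partition?
same_partition <- function(a, b) {
  ta <- outer(a, a, `==`)
  tb <- outer(b, b, `==`)
  all(ta == tb)
}

# amplitude mass within one multiplicative grid step of a target rate
amp_near <- function(spectrum_tb, rate, n_grid = 200,
                     lo = 1e-4, hi = 10) {
  step <- (log(hi) - log(lo)) / (n_grid - 1)
  sum(spectrum_tb$event_amp[abs(log(spectrum_tb$rate / rate)) <= step + 1e-12])
}
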