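cont <- illumination_scheme("continuous", n_frames = 600)
tl <- illumination_scheme("timelapse", n_frames = 40)

two_scheme_survival <- function(rates, amps, p_bleach, seeds, n = 10000) {
  ev_c <- simulate_survival_events(rates, amps, cont, n, p_bleach = p_bleach,
                                   seed = seeds[1])
  ev_t <- simulate_survival_events(rates, amps, tl, n, p_bleach = p_bleach,
                                   seed = seeds[2])
  list(build_survival(ev_c, cont), build_survival(ev_t, tl))
}

test_that("a single dissociation rate localizes on the grid with negligible bleach term", {
  svs <- two_scheme_survival(0.1, 1, 0, c(7, 8))
  sp <- fit_grid_spectrum(svs, n_boot = 0, seed = 1)
  expect_lte(sp$a_b, 0.02)
  expect_gte(amp_near(sp$spectrum, 0.1), 0.9)
  # oracle: direct single-exponential fit of the same survival curves
  orc <- oracle_exp_survival_fit(svs, 1, ab = sp$a_b)
  peak <- sp$spectrum$rate[which.max(sp$spectrum$event_amp)]
  expect_lt(abs(log(peak / orc$rates)), log(1.15))
})

test_that("two rates with substantial bleaching give state amplitudes near truth", {
  svs <- two_scheme_survival(c(0.02, 1), c(0.3, 0.7), 1 - exp(-0.3), c(5, 6))
  sp <- fit_grid_spectrum(svs, n_boot = 0, seed = 2)
  expect_lt(abs(sp$a_b - 0.3) / 0.3, 0.2)
  s <- state_spectrum(sp)
  s_slow_true <- (0.3 / 0.02) / (0.3 / 0.02 + 0.7 / 1)
  expect_lt(abs(sum(s[sp$spectrum$rate < 0.14]) - s_slow_true), 0.10)
})

test_that("dissociation faster than the grid maximum piles up at the largest rate", {
  # short cycles so that 15/s unbinding still leaves observable tracks
  s1 <- illumination_scheme("continuous", exposure = 0.1, n_frames = 400)
  s2 <- illumination_scheme("continuous", exposure = 0.2, n_frames = 400)
  svs <- list(
    build_survival(simulate_survival_events(15, 1, s1, 20000, seed = 11), s1),
    build_survival(simulate_survival_events(15, 1, s2, 20000, seed = 12), s2))
  sp <- fit_grid_spectrum(svs, n_boot = 0, seed = 3)
  top_rates <- sp$spectrum$rate[sp$spectrum$event_amp > 0.5]
  expect_true(all(top_rates >= max(sp$spectrum$rate) * 0.8))
})

test_that("the spectrum fit validates its inputs", {
  svs <- two_scheme_survival(0.1, 1, 0, c(7, 8), n = 500)
  expect_error(fit_grid_spectrum(svs[1], n_boot = 0, seed = 1),
               class = "chromakit_error") # single scheme: a_b unidentifiable
  expect_error(fit_grid_spectrum(svs, rate_grid = numeric(0), n_boot = 0,
                                 seed = 1),
               class = "chromakit_error")
  expect_error(fit_grid_spectrum(list(svs[[1]], svs[[1]]), n_boot = 0,
                                 seed = 1),
               class = "chromakit_error") # duplicate cycle times
})

test_that("state amplitudes reweight events by residence time", {
  tb <- tibble::tibble(rate = c(0.1, 1), event_amp = c(0.5, 0.5))
  expect_equal(state_spectrum(tb), c(10 / 11, 1 / 11), tolerance = 1e-12)
  single <- tibble::tibble(rate = 0.3, event_amp = 1)
  expect_equal(state_spectrum(single), 1)
  withr::with_seed(13, {
    for (i in 1:20) {
      r <- sort(10^runif(5, -3, 1))
      a <- runif(5)
      expect_equal(sum(state_spectrum(tibble::tibble(rate = r,
                                                     event_amp = a / sum(a)))),
                   1, tolerance = 1e-9)
    }
  })
  expect_error(state_spectrum(tibble::tibble(rate = 1, event_amp = 0)),
               class = "chromakit_error")
})

test_that("the convex NNLS baseline is at least as good as a two-exponential fit in its own objective", {
  rg <- exp(seq(log(1e-4), log(10), length.out = 200))
  # plant the two rates exactly on grid nodes so the comparison is fair
  k1 <- rg[which.min(abs(log(rg / 0.02)))]
  k2 <- rg[which.min(abs(log(rg / 1)))]
  ab_true <- 0.3
  svs <- two_scheme_survival(c(k1, k2), c(0.3, 0.7), 1 - exp(-ab_true),
                             c(15, 16))
  nn <- chromakit:::grid_nnls(svs, rg, ab_true)
  # oracle: direct 2-exponential fit evaluated in the same least-squares
  # objective (event-channel survival curves at the same fixed a_b)
  nnls_obj <- function(rates, amps) {
    sum(unlist(lapply(svs, function(sv) {
      n <- seq(2L, max(sv$frames))
      y <- vapply(n, function(k) sum(sv$frames >= k), numeric(1))
      y <- y / y[[1]]
      lam <- rates * sv$cycle_time + ab_true
      w1 <- (1 - exp(-rates * sv$cycle_time)) / (rates * sv$cycle_time) *
        exp(-lam)
      X <- outer(n - 2, lam, function(a, l) exp(-a * l)) *
        matrix(w1, length(n), length(rates), byrow = TRUE)
      (y - as.numeric(X %*% amps))^2
    })))
  }
  obj <- function(th) nnls_obj(exp(th[1:2]), exp(th[3:4]))
  best <- Inf
  for (start in list(c(log(0.02), log(1), 0, 0), c(log(0.005), log(2), 1, -1))) {
    o <- optim(start, obj, control = list(maxit = 3000))
    best <- min(best, o$value)
  }
  # the oracle's rates are continuous, so it can undercut the grid-constrained
  # NNLS by at most a grid-discretization margin
  expect_lte(nn$sse, best * 1.001)
})

test_that("resampling produces finite uncertainty estimates", {
  svs <- two_scheme_survival(0.1, 1, 0.1, c(21, 22), n = 4000)
  sp <- fit_grid_spectrum(svs, n_boot = 8, seed = 4)
  expect_true(all(is.finite(sp$spectrum$event_sd)))
  expect_gte(sp$a_b_sd, 0)
  expect_s3_class(generics::tidy(sp), "tbl_df")
  expect_equal(generics::glance(sp)$n_tracks, sp$n_tracks)
  expect_s3_class(ggplot2::autoplot(sp), "ggplot")
})
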