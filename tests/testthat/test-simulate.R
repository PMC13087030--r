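test_that("parameter constructors reject invalid values", {
  expect_error(kinetic_params(D_free = -1), class = "chromakit_error")
  expect_error(kinetic_params(p_bleach = 1.5), class = "chromakit_error")
  expect_error(kinetic_params(k_off_S = NaN), class = "chromakit_error")
  expect_error(illumination_scheme("fast", exposure = 0), class = "chromakit_error")
  expect_error(simulate_tracks(kinetic_params(), illumination_scheme("fast"),
                               n_molecules = 10),
               class = "chromakit_error") # missing seed
})

test_that("scheme presets carry the documented timings", {
  expect_equal(illumination_scheme("fast")$exposure, 0.010)
  expect_equal(illumination_scheme("continuous")$cycle_time, 0.5)
  expect_equal(illumination_scheme("timelapse")$cycle_time, 10.5)
  expect_equal(illumination_scheme("timelapse")$dark_time, 10)
})

test_that("no binding pathway yields only free localizations and zero bound fraction", {
  p <- kinetic_params(k_bind_T = 0, k_bind_S = 0)
  sch <- illumination_scheme("fast", n_frames = 60)
  sim <- simulate_tracks(p, sch, 40, seed = 5)
  expect_true(all(sim$tracks$true_state == "free"))
  expect_equal(sim$truth$f_bound, 0)
  expect_equal(sim$truth$occupancy[["stable"]], 0)
})

test_that("an absorbing stable state without bleaching spans the whole movie", {
  p <- kinetic_params(k_off_S = 0, k_bind_S = 0.01, p_bleach = 0)
  sch <- illumination_scheme("continuous", n_frames = 30)
  sim <- simulate_tracks(p, sch, 25, seed = 6, initial_state = "stable")
  sv <- build_survival(sim$tracks, sch, drop_censored = FALSE)
  expect_equal(sv$n_tracks, 25)
  expect_true(all(survival_times(sv) == (30 - 1) * sch$cycle_time))
  expect_true(all(sim$tracks$touches_movie_end))
})

test_that("long-run occupancy matches the stationary distribution of the rate matrix", {
  p <- kinetic_params(D_free = 2, k_bind_T = 0.5, k_bind_S = 0.3,
                      k_off_T = 0.8, k_off_S = 0.4, p_bleach = 0)
  pi_oracle <- oracle_stationary(p)
  expect_equal(unname(stationary_occupancy(p)), unname(pi_oracle),
               tolerance = 1e-10)
  sch <- illumination_scheme("fast", n_frames = 400)
  n_mol <- 150
  sim <- simulate_tracks(p, sch, n_mol, seed = 42)
  # standard error of a time-averaged occupancy across independent molecules
  se <- sqrt(pi_oracle * (1 - pi_oracle) / n_mol)
  for (s in names(pi_oracle)) {
    expect_lt(abs(sim$truth$occupancy[[s]] - pi_oracle[[s]]), 3 * se[[s]] + 0.02)
  }
})

test_that("simulation is bit-reproducible for a fixed seed", {
  p <- kinetic_params(p_bleach = 0.2)
  sch <- illumination_scheme("fast", n_frames = 80)
  s1 <- simulate_tracks(p, sch, 30, seed = 77)
  s2 <- simulate_tracks(p, sch, 30, seed = 77)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_tracks(p, sch, 30, seed = 78)
  expect_false(identical(s1$tracks, s3$tracks))
})

test_that("stable-state sojourns in emitted tracks are exponential with rate k_off_S", {
  # fast frames so discretization is negligible relative to the KS band
  p <- kinetic_params(k_bind_T = 0, k_bind_S = 1.5, k_off_T = 1, k_off_S = 2,
                      p_bleach = 0, sigma_loc = 0.02)
  sch <- illumination_scheme("fast", n_frames = 1800)
  sim <- simulate_tracks(p, sch, 420, seed = 9)
  runs <- sim$tracks %>%
    dplyr::group_by(track_id) %>%
    dplyr::arrange(frame, .by_group = TRUE) %>%
    dplyr::summarise(
      r = list(rle(true_state)), first = dplyr::first(frame),
      .groups = "drop")
  dur <- unlist(lapply(runs$r, function(r) {
    # completed sojourns: drop runs touching either track end
    if (length(r$lengths) <= 2) return(numeric(0))
    keep <- seq_along(r$lengths)[-c(1, length(r$lengths))]
    r$lengths[keep][r$values[keep] == "stable"]
  })) * sch$cycle_time
  expect_gt(length(dur), 5000)
  dur <- dur[seq_len(5000)]
  ks <- suppressWarnings(stats::ks.test(dur, "pexp", rate = 2))
  expect_lt(unname(ks$statistic), 1.628 / sqrt(5000) + 0.01)
})

test_that("doubling the number of molecules shrinks the bound-fraction error by sqrt(2)", {
  p <- kinetic_params(k_bind_T = 0.8, k_bind_S = 0, k_off_T = 1.2,
                      p_bleach = 0)
  sch <- illumination_scheme("fast", n_frames = 40)
  emp_bound <- function(n_mol, seed) {
    sim <- simulate_tracks(p, sch, n_mol, seed = seed)
    mean(sim$tracks$true_state != "free")
  }
  f1 <- vapply(1:24, function(i) emp_bound(150, 100 + i), numeric(1))
  f2 <- vapply(1:24, function(i) emp_bound(300, 200 + i), numeric(1))
  ratio <- sd(f1) / sd(f2)
  expect_gt(ratio, sqrt(2) * 0.7)
  expect_lt(ratio, sqrt(2) * 1.45)
})

test_that("survival-event generator reproduces the per-component geometric decay", {
  sch <- illumination_scheme("continuous", n_frames = 500)
  ev <- simulate_survival_events(0.4, 1, sch, 40000, p_bleach = 0, seed = 3,
                                 include_stock = FALSE)
  sv <- build_survival(ev, sch)
  y <- sv$counts$N / sv$counts$N[[1]]
  lam <- 0.4 * sch$cycle_time
  pred <- exp(-lam * (sv$counts$n - 2))
  expect_lt(max(abs(y - pred)[sv$counts$n <= 12]), 0.02)
})
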