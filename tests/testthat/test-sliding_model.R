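test_that("processivity formula and its inverse agree with hand arithmetic", {
  expect_equal(round(processivity_from_rates(sliding_rates(1.2, 0, 0.01)), 2), 0.99)
  expect_equal(processivity_from_rates(sliding_rates(3)), 1)
  expect_equal(processivity_from_rates(sliding_rates(1, 1, 0)), 0.5)

  expect_equal(round(loss_rate_from_processivity(0.99, 1.2), 2), 0.01)
  expect_equal(loss_rate_from_processivity(1, 5), 0)
})

test_that("processivity <-> loss rate round-trips to machine precision", {
  set.seed(3)
  for (i in 1:30) {
    r <- sliding_rates(runif(1, 0.1, 5), runif(1, 0, 1), runif(1, 0, 0.5))
    P <- processivity_from_rates(r)
    expect_equal(loss_rate_from_processivity(P, r$k_forward),
                 r$k_backward + r$k_dropoff, tolerance = 1e-12)
  }
})

test_that("geometric law predicts bypassing efficiency below the breakpoint", {
  expect_equal(bypassing_from_processivity(processivity_model(1, 0.99), 0), 1)
  expect_equal(bypassing_from_processivity(processivity_model(1, 0.99, breakpoint = 60), 50),
               0.99^50)
  expect_equal(0.99^50, 0.605, tolerance = 1e-3)
  expect_equal(bypassing_from_processivity(processivity_model(0.5, 1, breakpoint = 100), 70),
               0.5)
})

test_that("efficiency is non-increasing in gap length and in the loss rate", {
  m <- processivity_model(1, 0.99, breakpoint = 56, decline = 3e-3)
  eff <- bypassing_from_processivity(m, 0:110)
  expect_true(all(diff(eff) <= 0))
  expect_true(all(diff(eff[1:56]) < 0))  # strictly decreasing while P < 1
  # increasing drop-off reduces per-gap processivity, hence efficiency
  effs <- sapply(c(0.005, 0.02, 0.08), function(kd) {
    P <- processivity_from_rates(sliding_rates(1.2, 0, kd))
    bypassing_from_processivity(processivity_model(1, P), 50)
  })
  expect_true(all(diff(effs) < 0))
})

test_that("beyond the breakpoint efficiency falls below the geometric extrapolation", {
  m <- processivity_model(1, 0.99, breakpoint = 56, decline = 3e-3)
  L <- seq(59, 92, by = 3)
  expect_true(all(bypassing_from_processivity(m, L) < 0.99^L))
})

test_that("per-gap processivity inverts the geometric law", {
  expect_equal(per_gap_processivity(0.605, 1, 50), 0.99, tolerance = 1e-4)
  expect_equal(per_gap_processivity(0.7, 0.7, 33), 1)
  set.seed(5)
  for (i in 1:20) {
    P <- runif(1, 0.9, 0.999); A <- runif(1, 0.5, 1); L <- sample(10:90, 1)
    eff <- bypassing_from_processivity(processivity_model(A, P), L)
    expect_equal(per_gap_processivity(eff, A, L), P, tolerance = 1e-10)
  }
  expect_error(per_gap_processivity(0.8, 0.5, 10), class = "validation_error")
})

test_that("exponential gap fit recovers the generating P", {
  # noiseless: exact recovery
  gs0 <- generate_gap_series(processivity_model(1, 0.99),
                             gaps = seq(38, 56, 3), sigma = 0, replicates = 1)
  f0 <- fit_exponential_gap_model(gs0$data, fix_A = 1)
  expect_equal(f0$P, 0.99, tolerance = 1e-8)
  # seeded noise: within half a percentage point
  gs <- generate_gap_series(processivity_model(1, 0.99),
                            gaps = seq(38, 56, 3), sigma = 0.02, seed = 21)
  f <- fit_exponential_gap_model(gs$data, fix_A = 1)
  expect_lt(abs(f$P - 0.99), 0.005)
  # free-A fit on noiseless data also recovers both parameters
  gsA <- generate_gap_series(processivity_model(0.8, 0.985),
                             gaps = seq(38, 92, 3), sigma = 0, replicates = 1)
  fA <- fit_exponential_gap_model(gsA$data)
  expect_equal(fA$A, 0.8, tolerance = 1e-4)
  expect_equal(fA$P, 0.985, tolerance = 1e-5)
})

test_that("efficiency increasing with gap length flags a non-physical fit", {
  gs <- data.frame(gap_nt = seq(40, 60, 5),
                   efficiency_frac = c(0.3, 0.35, 0.42, 0.5, 0.6))
  expect_warning(f <- fit_exponential_gap_model(gs),
                 class = "nonphysical_warning")
  expect_gt(f$P, 1)
  expect_error(fit_exponential_gap_model(
    data.frame(gap_nt = c(40, 50), efficiency_frac = c(0.6, 0.5))),
    class = "under_determined_error")
})

test_that("breakpoint fit finds the regime change at 56 nt", {
  gs0 <- generate_gap_series(sigma = 0, replicates = 1)
  b0 <- fit_breakpoint(gs0$data)
  expect_equal(b0$regime, "two_regime")
  expect_equal(b0$breakpoint, 56)
  expect_equal(b0$P, 0.99, tolerance = 1e-4)
  # single-regime data must not produce a spurious breakpoint
  gs1 <- generate_gap_series(processivity_model(1, 0.99), sigma = 0.02,
                             replicates = 2, seed = 9)
  expect_equal(fit_breakpoint(gs1$data)$regime, "single_regime")
  expect_error(fit_breakpoint(data.frame(gap_nt = c(40, 45, 50, 55),
                                         efficiency_frac = c(.6, .5, .45, .4))),
               class = "under_determined_error")
})

test_that("breakpoint recovery is stable under seeded noise", {
  hits <- 0
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    gs <- generate_gap_series(sigma = 0.02, replicates = 2, seed = 4000 + s)
    b <- fit_breakpoint(gs$data)
    if (b$regime == "two_regime" && abs(b$breakpoint - 56) <= 3) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("exact first passage reproduces the closed form without backward steps", {
  expect_equal(first_passage_exact(sliding_rates(1.2, 0, 0.0121), 0),
               list(reach_prob = 1, mean_time = 0))
  r <- sliding_rates(1.2, 0, 0.0121)
  fp <- first_passage_exact(r, 50)
  expect_equal(fp$reach_prob, (1.2 / 1.2121)^50, tolerance = 1e-10)
  expect_equal(fp$reach_prob, 0.6056, tolerance = 2e-4)
  # successful trajectories wait Exp(kf + kd) at each of the L positions
  expect_equal(fp$mean_time, 50 / 1.2121, tolerance = 1e-10)
})

test_that("exact reach probability dominates the loss-counting approximation", {
  # treating backward steps as loss (the headline P formula) understates
  # the true reach probability, since backward excursions can recover
  set.seed(17)
  for (i in 1:10) {
    r <- sliding_rates(runif(1, 0.5, 2), runif(1, 0.1, 1), runif(1, 0.005, 0.05))
    L <- sample(5:40, 1)
    approx <- processivity_from_rates(r)^L
    expect_gte(first_passage_exact(r, L)$reach_prob, approx)
  }
  # and agrees exactly when backward stepping is absent
  r0 <- sliding_rates(1.5, 0, 0.02)
  expect_equal(first_passage_exact(r0, 20)$reach_prob,
               processivity_from_rates(r0)^20, tolerance = 1e-10)
})

test_that("Gillespie ensembles agree with the exact solve within Monte Carlo error", {
  set.seed(29)
  for (i in 1:20) {
    r <- sliding_rates(runif(1, 0.5, 2), runif(1, 0, 0.8), runif(1, 0.01, 0.08))
    L <- sample(5:30, 1)
    fp <- first_passage_exact(r, L)
    sim <- simulate_sliding(r, L, n = 50000, seed = 600 + i)
    se <- sqrt(fp$reach_prob * (1 - fp$reach_prob) / 50000)
    expect_lt(abs(sim$reach_prob - fp$reach_prob), 4 * se + 1e-12)
  }
})

test_that("loss-free sliding reaches the landing site in Erlang mean time", {
  sim <- simulate_sliding(sliding_rates(1.2), L = 50, n = 20000, seed = 2)
  expect_equal(sim$reach_prob, 1)
  expect_equal(sim$mean_time, 50 / 1.2, tolerance = 0.01)
  expect_equal(sum(sim$dropoff_hist), 0)
})

test_that("identical seeds give identical ensembles", {
  r <- sliding_rates(1.2, 0.3, 0.02)
  s1 <- simulate_sliding(r, 30, 5000, seed = 77)
  s2 <- simulate_sliding(r, 30, 5000, seed = 77)
  expect_identical(s1, s2)
  s3 <- simulate_sliding(r, 30, 5000, seed = 78)
  expect_false(identical(s1$mean_time, s3$mean_time))
})

test_that("drop-off histogram accounts for all lost trajectories", {
  sim <- simulate_sliding(sliding_rates(1.2, 0, 0.05), 40, 20000, seed = 8)
  expect_equal(sum(sim$dropoff_hist) + round(sim$reach_prob * sim$n), sim$n)
})

test_that("fitting per-gap-reconstructed noiseless data returns the same P", {
  m <- processivity_model(1, 0.985, breakpoint = 70)
  L <- seq(38, 68, 3)
  eff <- bypassing_from_processivity(m, L)
  Ppg <- per_gap_processivity(eff, 1, L)
  expect_equal(Ppg, rep(0.985, length(L)), tolerance = 1e-10)
  refit <- fit_exponential_gap_model(
    data.frame(gap_nt = L, efficiency_frac = eff), fix_A = 1)
  expect_equal(refit$P, 0.985, tolerance = 1e-8)
})
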