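test_that("bypassing efficiency is the ORF1+2 share of the reporter bands", {
  expect_equal(bypassing_efficiency(c(ORF1 = 51, "ORF1+2" = 49)), 0.49)
  expect_equal(bypassing_efficiency(c(ORF1 = 10, "ORF1+2" = 0)), 0)
  expect_equal(bypassing_efficiency(c(ORF1 = 0, "ORF1+2" = 7)), 1)
})

test_that("bypassing efficiency is invariant to densitometry scale", {
  set.seed(41)
  for (i in 1:20) {
    d <- c(ORF1 = runif(1, 1, 100), "ORF1+2" = runif(1, 1, 100))
    base <- bypassing_efficiency(d)
    for (c_mult in c(0.01, 3, 1e4)) {
      expect_equal(bypassing_efficiency(d * c_mult), base)
    }
  }
})

test_that("degenerate band densities raise classed errors", {
  expect_error(bypassing_efficiency(c(ORF1 = 0, "ORF1+2" = 0)),
               class = "undefined_efficiency_error")
  expect_error(bypassing_efficiency(c(ORF1 = -1, "ORF1+2" = 2)),
               class = "validation_error")
  expect_error(bypassing_efficiency(c(ORF1 = 5)), class = "validation_error")
})

test_that("band-length calibration interpolates ladder borders", {
  lad <- generate_ladder()
  # pause-intermediate band at 21 +/- 3 aa
  b <- lad$bands[1, ]
  r <- calibrate_band_length(b$upper_mobility, b$lower_mobility, lad$ladder)
  expect_equal(r$length_aa, 21)
  expect_equal(r$bounds, c(18, 24), tolerance = 1e-9)
  # band collapsed onto a single ladder point is exact
  m31 <- lad$ladder$mobility[lad$ladder$length_aa == 31]
  r31 <- calibrate_band_length(m31, m31, lad$ladder)
  expect_equal(r31$length_raw, 31, tolerance = 1e-9)
  expect_equal(r31$bounds, c(31, 31), tolerance = 1e-9)
})

test_that("calibration inverts the generator's mobility law at arbitrary lengths", {
  lad <- generate_ladder()
  mobility_of <- function(len) 2 - 0.45 * log(len)  # generator's law
  for (len in c(13.7, 21, 28.2, 36, 40.5)) {
    r <- calibrate_band_length(mobility_of(len), mobility_of(len), lad$ladder)
    expect_equal(r$length_raw, len, tolerance = 1e-3)
  }
})

test_that("calibration is monotone: nested bands give nested lengths", {
  lad <- generate_ladder()
  mobility_of <- function(len) 2 - 0.45 * log(len)
  outer <- calibrate_band_length(mobility_of(30), mobility_of(14), lad$ladder)
  inner <- calibrate_band_length(mobility_of(26), mobility_of(18), lad$ladder)
  expect_gt(inner$length_raw, outer$bounds[1])
  expect_lt(inner$length_raw, outer$bounds[2])
})

test_that("calibration refuses extrapolation and non-monotone ladders", {
  lad <- generate_ladder()
  expect_error(calibrate_band_length(10, 10, lad$ladder),
               class = "extrapolation_error")
  bad <- lad$ladder
  bad$mobility[3] <- bad$mobility[1]  # breaks strict monotonicity
  expect_error(calibrate_band_length(bad$mobility[5], bad$mobility[6], bad),
               class = "validation_error")
})

test_that("completion time reports t0 + 2*tau of a delayed exponential rise", {
  t <- seq(0, 200, by = 2)
  y <- ifelse(t <= 10, 0, 0.5 * (1 - exp(-(t - 10) / 20)))
  ct <- completion_time(t, y)
  expect_equal(ct$completion_s, 50, tolerance = 1e-3)
  expect_equal(ct$t0, 10, tolerance = 1e-3)
  expect_equal(ct$tau, 20, tolerance = 1e-3)
  # ideal step function
  expect_equal(completion_time(t, as.numeric(t >= 30))$completion_s, 30,
               tolerance = 0.02)
  # policy multiplier is exposed
  expect_equal(completion_time(t, y, multiplier = 3)$completion_s, 70,
               tolerance = 1e-2)
})

test_that("completion time of a chain product tracks the analytic 86% crossing", {
  m <- hifi_chain()
  t <- seq(0, 600, by = 5)
  orf12 <- chain_occupancies(t, m)[, "ORF1_2"]
  ct <- completion_time(t, orf12)
  # oracle: root-find the exact Bateman solution for the time at which the
  # product reaches 1 - exp(-2) of its plateau
  plateau <- m$f_byp
  target <- plateau * (1 - exp(-2))
  oracle <- uniroot(function(tt) chain_occupancies(tt, m)[, "ORF1_2"] - target,
                    c(1, 600))$root
  expect_lt(abs(ct$completion_s - oracle) / oracle, 0.15)
})

test_that("completion time rejects unconverged or decreasing trajectories", {
  t <- seq(0, 50, by = 2)
  rising <- 1 - exp(-t / 100)           # far from plateau at t = 50
  expect_error(completion_time(t, rising), class = "nonconvergence_error")
  expect_error(completion_time(t, exp(-t / 10)), class = "validation_error")
})

test_that("timing decomposition and derived rates follow the arithmetic", {
  expect_equal(bypassing_time(153, 53), 100)
  expect_equal(bypassing_time(76, 32), 44)
  expect_equal(bypassing_time(60, 60), 0)
  expect_error(bypassing_time(50, 60), class = "negative_time_error")

  expect_equal(sliding_velocity(50, 41.7), 1.199, tolerance = 1e-3)
  expect_equal(sliding_velocity(50, 50), 1)
  for (v in c(0.3, 1.2, 5)) expect_equal(sliding_velocity(50, 50 / v), v)
  expect_error(sliding_velocity(0, 10), class = "validation_error")

  expect_equal(round(average_elongation_rate(114, 25), 1), 4.6)
  expect_equal(average_elongation_rate(114, 37), 3.081, tolerance = 1e-3)
  expect_equal(average_elongation_rate(10, 10), 1)
  expect_error(average_elongation_rate(10, 0), class = "validation_error")
})

test_that("additivity: bypassing time plus gap-less time reconstructs the total", {
  t_full <- 153; t_dgap <- 53
  expect_equal(bypassing_time(t_full, t_dgap) + t_dgap, t_full)
})

test_that("rank correlation matches the exhaustive rank formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rank_correlation(x, x^3), 1)
  expect_equal(rank_correlation(x, rev(x)), -1)
  # all permutations up to n = 6, against the explicit d^2 formula
  for (n in 3:6) {
    perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), , drop = FALSE]
    for (i in seq_len(nrow(perms))) {
      y <- as.numeric(perms[i, ])
      expect_equal(rank_correlation(seq_len(n), y),
                   spearman_bruteforce(seq_len(n), y))
    }
  }
})

test_that("rank correlation rejects constant and short series", {
  expect_error(rank_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "undefined_correlation_error")
  expect_error(rank_correlation(1:2, 2:1), class = "validation_error")
})
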