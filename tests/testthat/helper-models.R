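# Shared fixtures and independent oracles used across the test files.

hifi_chain <- function() chain_model(k = c(0.5, 0.25, 0.25, 0.2, 0.015), f_byp = 0.49)

# Random chain models with well-separated rates (the analytic solution's
# documented precondition); rates log-uniform over [0.01, 2] 1/s.
random_chain <- function() {
  repeat {
    k <- exp(stats::runif(5, log(0.01), log(2)))
    if (min(abs(diff(sort(k))) / sort(k)[-1]) > 1e-4) break
  }
  chain_model(k = k, f_byp = stats::runif(1, 0.05, 0.95))
}

# Independent ODE oracle for the branched chain (straight deSolve call,
# not the package's own "ode" code path).
ode_oracle <- function(t, model, rtol = 1e-10) {
  k <- model$k; f <- model$f_byp
  rhs <- function(tt, y, p) {
    list(c(-k[1] * y[1],
           k[1] * y[1] - k[2] * y[2],
           k[2] * y[2] - k[3] * y[3],
           k[3] * y[3] - k[4] * y[4],
           f * k[4] * y[4] - k[5] * y[5],
           (1 - f) * k[4] * y[4],
           k[5] * y[5]))
  }
  tt <- unique(sort(c(0, t)))
  sol <- deSolve::ode(c(1, 0, 0, 0, 0, 0, 0), tt, rhs, NULL,
                      rtol = rtol, atol = 1e-13)
  sol <- sol[match(t, tt), -1, drop = FALSE]
  cbind(sol[, 1:4, drop = FALSE], sol[, 5] + sol[, 6], sol[, 7])
}

# Spearman's rho by the explicit rank-difference formula (no ties).
spearman_bruteforce <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
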