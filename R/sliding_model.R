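#' Per-nucleotide sliding rate constants
#'
#' @param k_forward Forward sliding rate (nt/s), > 0.
#' @param k_backward Backward sliding rate (nt/s), >= 0.
#' @param k_dropoff Drop-off (track loss) hazard per position (1/s), >= 0.
#' @return An object of class `sliding_rates`.
#' @export
sliding_rates <- function(k_forward, k_backward = 0, k_dropoff = 0) {
  check_positive(k_forward, "k_forward")
  check_nonneg(k_backward, "k_backward")
  check_nonneg(k_dropoff, "k_dropoff")
  structure(list(k_forward = k_forward, k_backward = k_backward,
                 k_dropoff = k_dropoff), class = "sliding_rates")
}

#' Processivity coefficient from sliding rates
#'
#' The probability that a sliding ribosome advances by one nucleotide
#' rather than stepping back or dropping off the mRNA track:
#' `P = k_forward / (k_forward + k_dropoff + k_backward)`. Note this
#' headline model counts a backward step as loss; see
#' [first_passage_exact()] for the exact birth-death treatment in which
#' backward steps are recoverable.
#'
#' @param r A [sliding_rates()] object.
#' @return Processivity coefficient `P` in `(0, 1]`.
#' @examples
#' processivity_from_rates(sliding_rates(1.2, 0, 0.01))  # ~0.99
#' @export
processivity_from_rates <- function(r) {
  stopifnot(inherits(r, "sliding_rates"))
  r$k_forward / (r$k_forward + r$k_dropoff + r$k_backward)
}

#' Combined loss rate from a processivity coefficient
#'
#' Algebraic inverse of [processivity_from_rates()]: given `P` and the
#' forward rate, returns `k_dropoff + k_backward = k_forward * (1 - P) / P`.
#'
#' @param P Processivity coefficient in `(0, 1]`.
#' @param k_forward Forward sliding rate (nt/s).
#' @return Combined loss rate (nt/s).
#' @export
loss_rate_from_processivity <- function(P, k_forward) {
  check_positive(k_forward, "k_forward")
  if (!is.numeric(P) || any(P <= 0) || any(P > 1)) {
    rs_stop("`P` must lie in (0, 1]", "validation_error")
  }
  k_forward * (1 - P) / P
}

#' Two-regime processivity model of bypassing efficiency
#'
#' Below the breakpoint the efficiency follows the geometric law
#' `A * P^L` (take-off/landing probability `A` times the per-nucleotide
#' continuation probability to the power of the gap length). Beyond the
#' breakpoint the per-nucleotide probability declines linearly by `decline`
#' per additional nucleotide, capturing the loss of mRNA-element support on
#' long gaps.
#'
#' @param A Combined take-off and landing probability, in `[0, 1]`.
#' @param P Sub-breakpoint processivity coefficient, in `(0, 1]`.
#' @param breakpoint Gap length `L*` (nt) where the regime changes;
#'   `Inf` for a single-regime model.
#' @param decline Per-nucleotide decrease of `P` beyond the breakpoint
#'   (>= 0). The default 0 gives the single-regime law at all lengths.
#' @return An object of class `processivity_model`.
#' @export
processivity_model <- function(A = 1, P = 0.99, breakpoint = Inf, decline = 0) {
  check_fraction(A, "A")
  if (!is.numeric(P) || P <= 0 || P > 1) rs_stop("`P` must lie in (0, 1]", "validation_error")
  if (!is.numeric(breakpoint) || breakpoint < 0) rs_stop("`breakpoint` must be >= 0", "validation_error")
  check_nonneg(decline, "decline")
  structure(list(A = A, P = P, breakpoint = breakpoint, decline = decline),
            class = "processivity_model")
}

#' @export
print.processivity_model <- function(x, ...) {
  cat(sprintf("Processivity model: A = %.3f, P = %.4f", x$A, x$P))
  if (is.finite(x$breakpoint)) {
    cat(sprintf(", breakpoint = %g nt, decline = %.2e /nt", x$breakpoint, x$decline))
  }
  cat("\n")
  invisible(x)
}

#' Bypassing efficiency predicted by a processivity model
#'
#' For `L <= breakpoint` returns `A * P^L`; beyond the breakpoint each
#' additional nucleotide `j` contributes a factor
#' `max(P - decline * (j - L*), 0)`.
#'
#' @param m A [processivity_model()].
#' @param L Gap lengths (nt), >= 0; vectorised.
#' @return Efficiencies in `[0, 1]`.
#' @export
bypassing_from_processivity <- function(m, L) {
  stopifnot(inherits(m, "processivity_model"))
  check_nonneg(L, "L")
  Ls <- as.numeric(L)
  bp <- m$breakpoint
  short <- m$A * m$P^pmin(Ls, bp)
  if (!is.finite(bp) || m$decline == 0) {
    if (m$decline == 0) return(m$A * m$P^Ls)
  }
  excess <- pmax(0, floor(Ls) - bp)
  max_ex <- max(excess)
  if (max_ex == 0) return(short)
  steps <- pmax(m$P - m$decline * seq_len(max_ex), 0)
  cum <- cumprod(steps)
  mult <- ifelse(excess > 0, cum[pmax(excess, 1)], 1)
  short * mult
}

#' Per-gap-length processivity coefficient
#'
#' Inverts the geometric law for a single gap length:
#' `P(L) = (efficiency / A)^(1/L)`, the quantity plotted per gap length to
#' reveal regime changes.
#'
#' @param efficiency Observed bypassing efficiency, `0 < efficiency <= A`.
#' @param A Combined take-off/landing probability.
#' @param L Gap length (nt), > 0.
#' @return `P(L)` in `(0, 1]`.
#' @export
per_gap_processivity <- function(efficiency, A = 1, L) {
  check_positive(L, "L")
  check_fraction(A, "A")
  if (any(efficiency <= 0)) rs_stop("`efficiency` must be > 0", "validation_error")
  if (any(efficiency > A + 1e-12)) {
    rs_stop("`efficiency` exceeds the take-off/landing probability `A`", "validation_error")
  }
  (pmin(efficiency, A) / A)^(1 / L)
}

#' Exponential fit of bypassing efficiency versus gap length
#'
#' Least-squares fit of `A * P^L` to a gap series, on the linear scale by
#' default. `A` may be fixed (conventionally at 1, since nearly all
#' ribosomes take off and land).
#'
#' @param gs Data frame with columns `gap_nt` and `efficiency_frac`
#'   (alias `efficiency`).
#' @param fix_A Fix `A` at this value instead of fitting it (e.g. `1`);
#'   `NULL` fits `A`.
#' @param transform `"linear"` (default) fits on the efficiency scale;
#'   `"log"` fits on log efficiency (weights small efficiencies more).
#' @param max_gap Use only gaps `<= max_gap` (the sub-breakpoint range).
#' @return List with `A`, `P`, asymptotic standard error and 95% interval
#'   for `P`, and the residual sum of squares. A fitted `P > 1` triggers a
#'   non-physical warning.
#' @export
fit_exponential_gap_model <- function(gs, fix_A = NULL,
                                      transform = c("linear", "log"),
                                      max_gap = Inf) {
  transform <- match.arg(transform)
  gs <- as_gap_series(gs)
  gs <- gs[gs$gap_nt <= max_gap, , drop = FALSE]
  L <- gs$gap_nt
  y <- gs$efficiency_frac
  if (length(unique(L)) < 3L) {
    rs_stop("need at least 3 distinct gap lengths", "under_determined_error")
  }
  # log-linear regression provides the starting values (and the log fit)
  ly <- log(pmax(y, 1e-9))
  lf <- stats::lm(ly ~ L)
  P0 <- min(exp(stats::coef(lf)[2]), 1.5)
  A0 <- if (is.null(fix_A)) min(exp(stats::coef(lf)[1]), 1) else fix_A

  if (transform == "log") {
    if (is.null(fix_A)) {
      A <- exp(stats::coef(lf)[[1]]); P <- exp(stats::coef(lf)[[2]])
      seP <- P * summary(lf)$coefficients[2, 2]
    } else {
      A <- fix_A
      lp <- stats::lm(I(ly - log(A)) ~ 0 + L)
      P <- exp(stats::coef(lp)[[1]])
      seP <- P * summary(lp)$coefficients[1, 2]
    }
    rss <- sum((y - A * P^L)^2)
  } else {
    resfun <- function(par) {
      A <- if (is.null(fix_A)) stats::plogis(par[1]) else fix_A
      P <- exp(par[length(par)])
      y - A * P^L
    }
    par0 <- if (is.null(fix_A)) c(stats::qlogis(min(max(A0, 1e-3), 1 - 1e-3)), log(P0)) else log(P0)
    fit <- minpack.lm::nls.lm(par = par0, fn = resfun,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    P <- exp(fit$par[length(fit$par)])
    A <- if (is.null(fix_A)) stats::plogis(fit$par[1]) else fix_A
    rss <- fit$deviance
    # delta-method SE for P from the Jacobian
    seP <- tryCatch({
      cv <- tryCatch(solve(fit$hessian) * rss / max(1, length(y) - length(fit$par)),
                     error = function(e) NULL)
      if (is.null(cv)) NA_real_ else P * sqrt(cv[length(fit$par), length(fit$par)])
    }, error = function(e) NA_real_)
  }
  if (P > 1) {
    rs_warn(sprintf("fitted P = %.4f exceeds 1: non-physical (efficiency increasing with gap length)", P),
            "nonphysical_warning")
  }
  list(A = A, P = P, se_P = seP,
       ci_P = if (is.finite(seP)) c(P - 1.96 * seP, P + 1.96 * seP) else c(NA_real_, NA_real_),
       rss = rss, n = length(y), transform = transform)
}

# Piecewise (two-regime) SSE for a fixed integer breakpoint candidate.
two_regime_fit <- function(L, y, bp, fix_A = 1) {
  resfun <- function(par) {
    P <- stats::plogis(par[1])
    d <- exp(par[2])
    m <- processivity_model(A = fix_A, P = P, breakpoint = bp, decline = d)
    y - bypassing_from_processivity(m, L)
  }
  # starting values: geometric fit below bp, mild decline
  below <- L <= bp
  P0 <- if (sum(below) >= 2) {
    exp(stats::coef(stats::lm(log(pmax(y[below], 1e-9)) ~ 0 + L[below],
                              data = data.frame()))[[1]])
  } else 0.99
  P0 <- min(max(P0, 0.5), 0.999)
  fit <- minpack.lm::nls.lm(par = c(stats::qlogis(P0), log(5e-4)), fn = resfun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  list(P = stats::plogis(fit$par[1]), decline = exp(fit$par[2]), sse = fit$deviance)
}

#' Breakpoint (two-regime) analysis of a gap series
#'
#' Detects the gap length at which sliding switches from the constant
#' high-processivity regime to the declining long-gap regime. Integer
#' candidate breakpoints are scanned; for each, a constant-`P` law is fit
#' below and a linearly declining per-nucleotide probability above, and the
#' candidate minimising total squared error wins. If the two-regime model
#' does not improve on the single-regime fit (F-ratio below
#' `f_threshold`'s critical value) a single-regime result is returned.
#'
#' @param gs Gap series data frame (`gap_nt`, `efficiency_frac`).
#' @param fix_A Take-off/landing probability, fixed (default 1).
#' @param candidates Integer candidate breakpoints; defaults to the range
#'   of observed gaps leaving at least two distinct lengths on each side.
#' @param f_threshold Significance level of the F-test against the
#'   single-regime model.
#' @return List with `regime` (`"two_regime"` or `"single_regime"`),
#'   `breakpoint`, sub-breakpoint `P`, `decline`, the SSE profile over
#'   candidates, and the single-regime fit for reference.
#' @export
fit_breakpoint <- function(gs, fix_A = 1, candidates = NULL, f_threshold = 0.05) {
  gs <- as_gap_series(gs)
  L <- gs$gap_nt
  y <- gs$efficiency_frac
  ug <- sort(unique(L))
  if (length(ug) < 6L) {
    rs_stop("need at least 6 distinct gap lengths spanning both regimes",
            "under_determined_error")
  }
  if (is.null(candidates)) {
    candidates <- seq(ceiling(ug[2]), floor(ug[length(ug) - 1L]))
  }
  single <- fit_exponential_gap_model(gs, fix_A = fix_A)
  prof <- data.frame(breakpoint = candidates, sse = NA_real_,
                     P = NA_real_, decline = NA_real_)
  for (i in seq_along(candidates)) {
    f <- two_regime_fit(L, y, candidates[i], fix_A = fix_A)
    prof$sse[i] <- f$sse
    prof$P[i] <- f$P
    prof$decline[i] <- f$decline
  }
  best <- which.min(prof$sse)
  n <- length(y)
  extra_par <- 2L  # breakpoint + decline
  df2 <- n - 3L
  if (prof$sse[best] < 1e-12 && single$rss > 1e-10) {
    # noiseless two-regime data: the piecewise model fits exactly
    Fstat <- Inf
    pval <- 0
  } else {
    Fstat <- ((single$rss - prof$sse[best]) / extra_par) / (prof$sse[best] / df2)
    pval <- stats::pf(Fstat, extra_par, df2, lower.tail = FALSE)
  }
  if (!is.finite(pval) || pval > f_threshold) {
    return(list(regime = "single_regime", breakpoint = NA_real_,
                P = single$P, decline = 0, profile = prof,
                single_fit = single, f_stat = Fstat, p_value = pval))
  }
  list(regime = "two_regime", breakpoint = prof$breakpoint[best],
       P = prof$P[best], decline = prof$decline[best], profile = prof,
       single_fit = single, f_stat = Fstat, p_value = pval)
}

#' Exact first-passage analysis of the sliding random walk
#'
#' Solves the birth--death chain of a ribosome sliding over an `L`-nt gap:
#' from each position it steps forward (`k_forward`), backward
#' (`k_backward`) or irreversibly leaves the track (`k_dropoff`); the
#' landing site at `L` absorbs. Reach probabilities and conditional mean
#' traversal times come from the standard tridiagonal linear systems. At
#' position 0 a reflecting boundary is used by default (refolded mRNA
#' behind the ribosome blocks backward motion); a backward self-loop at 0
#' is distributionally identical to removing the backward hazard there, and
#' is implemented that way. With `boundary = "absorb"` a backward step at 0
#' loses the ribosome.
#'
#' @param r A [sliding_rates()] object.
#' @param L Gap length (nt), integer >= 0.
#' @param boundary `"reflect"` (default) or `"absorb"` at position 0.
#' @return List with `reach_prob` and `mean_time` (mean traversal time of
#'   successful trajectories, s).
#' @export
first_passage_exact <- function(r, L, boundary = c("reflect", "absorb")) {
  stopifnot(inherits(r, "sliding_rates"))
  boundary <- match.arg(boundary)
  check_nonneg(L, "L")
  L <- as.integer(round(L))
  if (L == 0L) return(list(reach_prob = 1, mean_time = 0))
  kf <- r$k_forward; kb <- r$k_backward; kd <- r$k_dropoff
  # transient positions 0..L-1
  n <- L
  M <- matrix(0, n, n)
  rhs_u <- numeric(n)
  for (i in seq_len(n)) {
    pos <- i - 1L
    back <- if (pos == 0L) { if (boundary == "reflect") 0 else kb } else kb
    tot <- kf + kd + back
    M[i, i] <- tot
    if (pos > 0L) M[i, i - 1L] <- -kb
    if (i < n) M[i, i + 1L] <- -kf else rhs_u[i] <- kf  # absorbed at L
  }
  u <- solve(M, rhs_u)                       # reach probabilities
  h <- solve(M, u)                           # E[T * 1{reach}] from each position
  list(reach_prob = u[1], mean_time = if (u[1] > 0) h[1] / u[1] else NA_real_)
}

#' Stochastic (Gillespie) simulation of ribosome sliding
#'
#' Continuous-time Markov simulation of the sliding walk described for
#' [first_passage_exact()]: exponential waiting times with total hazard
#' `k_forward + k_backward + k_dropoff`, landing at `L` absorbs, position 0
#' reflects backward steps by default. All trajectories are advanced in a
#' vectorised sweep, so ensembles of 1e5 trajectories are fast. The same
#' seed always reproduces the identical summary.
#'
#' @param r A [sliding_rates()] object.
#' @param L Gap length (nt), >= 0.
#' @param n Number of trajectories, >= 1.
#' @param seed Integer seed (recorded in the output).
#' @param boundary `"reflect"` (default) or `"absorb"` at position 0.
#' @param max_events Safety cap on simulation sweeps.
#' @return An object of class `sliding_ensemble`: `n`, `reach_prob`,
#'   `mean_time` and `sd_time` of successful trajectories, a drop-off
#'   position histogram (`dropoff_hist`, counts at positions `0..L-1`),
#'   and the seed.
#' @examples
#' simulate_sliding(sliding_rates(1.2, 0, 0.0121), L = 50, n = 1000, seed = 1)
#' @export
simulate_sliding <- function(r, L, n, seed = 1L,
                             boundary = c("reflect", "absorb"),
                             max_events = 1e7) {
  stopifnot(inherits(r, "sliding_rates"))
  boundary <- match.arg(boundary)
  check_nonneg(L, "L")
  if (n < 1) rs_stop("`n` must be >= 1", "validation_error")
  L <- as.integer(round(L)); n <- as.integer(n)
  kf <- r$k_forward; kb <- r$k_backward; kd <- r$k_dropoff

  res <- with_seed(seed, {
    pos <- integer(n)
    tim <- numeric(n)
    landed_time <- numeric(0)
    drop_pos <- integer(0)
    if (L == 0L) {
      landed_time <- numeric(n)
      pos <- integer(0)
    }
    sweeps <- 0L
    while (length(pos) > 0L) {
      sweeps <- sweeps + 1L
      if (sweeps > max_events) rs_stop("simulation exceeded max_events", "simulation_error")
      at0 <- pos == 0L
      back_hazard <- if (boundary == "reflect") ifelse(at0, 0, kb) else kb
      tot <- kf + kd + back_hazard
      tim <- tim + stats::rexp(length(pos), tot)
      u <- stats::runif(length(pos)) * tot
      fwd <- u < kf
      bwd <- !fwd & (u < kf + back_hazard)
      drop <- !fwd & !bwd
      # under "absorb", a backward move from 0 is loss at position 0
      if (boundary == "absorb") {
        lost_bwd <- bwd & at0
        drop <- drop | lost_bwd
        bwd <- bwd & !at0
      }
      pos[fwd] <- pos[fwd] + 1L
      pos[bwd] <- pos[bwd] - 1L
      done_land <- pos == L & !drop
      landed_time <- c(landed_time, tim[done_land])
      drop_pos <- c(drop_pos, pos[drop])
      keep <- !done_land & !drop
      pos <- pos[keep]
      tim <- tim[keep]
    }
    list(landed_time = landed_time, drop_pos = drop_pos)
  })

  hist_counts <- if (L > 0) tabulate(res$drop_pos + 1L, nbins = L) else integer(0)
  names(hist_counts) <- if (L > 0) as.character(0:(L - 1L)) else character(0)
  structure(list(
    n = n,
    reach_prob = length(res$landed_time) / n,
    mean_time = if (length(res$landed_time)) mean(res$landed_time) else NA_real_,
    sd_time = if (length(res$landed_time) > 1) stats::sd(res$landed_time) else NA_real_,
    dropoff_hist = hist_counts,
    rates = r, gap_nt = L, boundary = boundary, seed = seed
  ), class = "sliding_ensemble")
}

#' @export
print.sliding_ensemble <- function(x, ...) {
  cat(sprintf("Sliding ensemble: n = %d over %d nt (seed %s)\n", x$n, x$gap_nt, x$seed))
  cat(sprintf("  reach probability: %.4f\n", x$reach_prob))
  cat(sprintf("  traversal time of successful trajectories: %.2f +/- %.2f s\n",
              x$mean_time, x$sd_time))
  invisible(x)
}
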