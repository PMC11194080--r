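#' Five-step irreversible translation chain with a bypassing branch
#'
#' Constructs the minimal kinetic model of ORF1 translation and bypassing:
#' five consecutive irreversible first-order steps
#' (initiation state -> INT1 -> INT2 -> INT3 -> take-off state -> ORF1+2),
#' with the outflow of the take-off state split by a branch fraction
#' `f_byp`: that fraction of ribosomes completes bypassing and ORF2
#' synthesis (rate `k[5]`), the remainder accumulates as terminated ORF1
#' product.
#'
#' @param k Numeric vector of the five step rate constants (1/s), all > 0,
#'   ordered from the initiation step to the bypassing/ORF2 step.
#' @param f_byp Fraction of ribosomes at the take-off state that go on to
#'   produce ORF1+2 (the bypassing branch), in `[0, 1]`.
#' @return An object of class `chain_model`.
#' @examples
#' m <- chain_model(k = c(0.5, 0.25, 0.25, 0.2, 0.015), f_byp = 0.49)
#' chain_occupancies(c(0, 10, 100), m)
#' @export
chain_model <- function(k, f_byp = 0.5) {
  if (length(k) != 5L) rs_stop("`k` must hold exactly 5 rate constants", "validation_error")
  check_positive(k, "k")
  check_fraction(f_byp, "f_byp")
  structure(list(k = as.numeric(k), f_byp = as.numeric(f_byp)), class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat("Five-step translation chain\n")
  cat(sprintf("  k1..k5 (1/s): %s\n", paste(signif(x$k, 4), collapse = ", ")))
  cat(sprintf("  bypassing branch fraction: %.3f\n", x$f_byp))
  invisible(x)
}

# Bateman occupancies of a linear irreversible chain X0 -> X1 -> ... -> Xn
# with rates[i] taking X_{i-1} to X_i. Returns length(t) x (n + 1) matrix of
# the transient states X0..X_{n-1} plus the absorbed pool X_n.
# Near-degenerate rates are perturbed by 1e-6 relative (distinct multiples)
# before evaluation to avoid catastrophic cancellation in the partial
# fraction expansion.
bateman_occupancies <- function(t, rates) {
  check_nonneg(t, "t")
  n <- length(rates)
  lam <- as.numeric(rates)
  # deterministic perturbation of (near-)equal rates
  for (i in seq_len(n)) {
    while (any(abs(lam[-i] - lam[i]) < 1e-6 * lam[i])) {
      lam[i] <- lam[i] * (1 + 1e-6 * i)
    }
  }
  out <- matrix(0, nrow = length(t), ncol = n + 1L)
  for (m in 0:(n - 1L)) {
    idx <- seq_len(m + 1L)           # states' exit rates lam[1..m+1]
    pref <- prod(lam[seq_len(m)])    # product of the m rates traversed
    acc <- 0
    for (j in idx) {
      denom <- prod(lam[setdiff(idx, j)] - lam[j])
      acc <- acc + exp(-lam[j] * t) / denom
    }
    out[, m + 1L] <- pref * acc
  }
  out[out < 0 & out > -1e-12] <- 0
  out[, n + 1L] <- pmax(0, 1 - rowSums(out[, seq_len(n), drop = FALSE]))
  out
}

#' Occupancies of the translation chain over time
#'
#' Evaluates the closed-form (Bateman) solution of the five-step chain at
#' the requested times. The take-off state is treated as a branch point:
#' the cohort `f_byp` proceeds with rate `k[5]` to the ORF1+2 product while
#' the cohort `1 - f_byp` is absorbed as terminated ORF1. The observable
#' ORF1 gel band conflates ribosomes paused at the take-off state with the
#' terminated product, so by default both are reported as one `ORF1`
#' column; set `collapse_orf1 = FALSE` to keep them separate.
#'
#' @param t Times (s), >= 0.
#' @param model A [chain_model()].
#' @param collapse_orf1 Report the take-off-state occupancy and the
#'   terminated pool as a single observable `ORF1` column (default) or as
#'   separate `take_off` and `ORF1_term` columns.
#' @param method `"analytic"` (Bateman, default) or `"ode"` (adaptive
#'   numerical integration via [deSolve::ode()]), provided as a fallback
#'   and cross-check.
#' @return Matrix with one row per time point; columns are species
#'   fractions which sum to 1 at every time.
#' @export
chain_occupancies <- function(t, model, collapse_orf1 = TRUE,
                              method = c("analytic", "ode")) {
  stopifnot(inherits(model, "chain_model"))
  method <- match.arg(method)
  check_nonneg(t, "t")
  k <- model$k
  f <- model$f_byp
  if (method == "analytic") {
    # The perturbed partial-fraction expansion is accurate for a single
    # near-equal pair, but multi-way degeneracies cancel catastrophically;
    # those fall back to stiff-safe numerical integration.
    rel_gaps <- abs(diff(sort(k))) / sort(k)[-1]
    if (sum(rel_gaps < 1e-4) >= 2) method <- "ode"
  }
  if (method == "analytic") {
    b5 <- bateman_occupancies(t, k)        # full chain, absorbing ORF1+2
    trans4 <- b5[, 1:4, drop = FALSE]      # shared states S0..S3
    take_off <- f * b5[, 5]
    orf12 <- f * b5[, 6]
    terminated <- (1 - f) * pmax(0, 1 - rowSums(trans4))
  } else {
    rhs <- function(tt, y, p) {
      dy <- c(-k[1] * y[1],
              k[1] * y[1] - k[2] * y[2],
              k[2] * y[2] - k[3] * y[3],
              k[3] * y[3] - k[4] * y[4],
              f * k[4] * y[4] - k[5] * y[5],   # take-off state, byp cohort
              (1 - f) * k[4] * y[4],           # terminated ORF1
              k[5] * y[5])                     # ORF1+2
      list(dy)
    }
    tt <- unique(sort(c(0, t)))
    sol <- deSolve::ode(y = c(1, 0, 0, 0, 0, 0, 0), times = tt, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
    sol <- sol[match(t, tt), -1, drop = FALSE]
    trans4 <- sol[, 1:4, drop = FALSE]
    take_off <- sol[, 5]
    terminated <- sol[, 6]
    orf12 <- sol[, 7]
  }
  if (collapse_orf1) {
    out <- cbind(trans4, take_off + terminated, orf12)
    colnames(out) <- SPECIES_LEVELS
  } else {
    out <- cbind(trans4, take_off, terminated, orf12)
    colnames(out) <- c(SPECIES_LEVELS[1:4], "take_off", "ORF1_term", "ORF1_2")
  }
  rownames(out) <- NULL
  out
}

#' Local elongation rates implied by the chain steps
#'
#' Each first-order step of the chain coarse-grains translation of a
#' contiguous mRNA segment; the mean elongation rate over that segment is
#' the segment length times the step rate constant.
#'
#' @param model A [chain_model()].
#' @param segment_lengths Codons translated in each step (e.g. the
#'   distances between consecutive pause sites); one per rate, positive.
#' @return Named numeric vector of per-segment elongation rates (aa/s).
#' @export
local_rates <- function(model, segment_lengths) {
  stopifnot(inherits(model, "chain_model"))
  if (length(segment_lengths) != length(model$k)) {
    rs_stop("`segment_lengths` must match the number of chain steps", "validation_error")
  }
  check_positive(segment_lengths, "segment_lengths")
  r <- segment_lengths * model$k
  names(r) <- paste0("segment", seq_along(r))
  r
}

# Predicted fractions for the observed (time, species) design; species must
# already be normalized to SPECIES_LEVELS.
chain_predict <- function(times, species, model) {
  tt <- sort(unique(times))
  occ <- chain_occupancies(tt, model)
  occ[cbind(match(times, tt), match(species, SPECIES_LEVELS))]
}

theta_to_model <- function(theta) {
  chain_model(k = exp(theta[1:5]), f_byp = stats::plogis(theta[6]))
}

model_to_theta <- function(model) {
  f <- min(max(model$f_byp, 1e-6), 1 - 1e-6)
  c(log(model$k), stats::qlogis(f))
}

#' Global fit of the translation chain to band time courses
#'
#' Weighted nonlinear least squares over all species simultaneously, as
#' done for gel time courses of translation intermediates and products.
#' Rates are fitted on the log scale and the branch fraction on the logit
#' scale; optimisation uses Levenberg--Marquardt ([minpack.lm::nls.lm()])
#' from multiple random starts, and parameter uncertainty is assessed by a
#' residual bootstrap.
#'
#' @param tc Data frame with columns `time_s`, `species`, `fraction` and
#'   optionally `replicate`. Species labels are matched against
#'   `pre_INT1, INT1, INT2, INT3, ORF1, ORF1_2` (gel aliases such as
#'   `"ORF1+2"` are accepted).
#' @param init Optional [chain_model()] used as the first start.
#' @param starts Number of multi-starts; additional starts are drawn
#'   log-uniformly over `[1e-3, 10]` 1/s.
#' @param seed Seed controlling the random starts and the bootstrap.
#' @param n_boot Bootstrap resamples for the 95% intervals (0 disables).
#' @param weights `"auto"` uses inverse per-species standard deviation when
#'   replicates are present, otherwise uniform; `"uniform"` forces uniform.
#' @return An object of class `chain_fit`: point estimates (`model`),
#'   residual sum of squares (`rss`), bootstrap 2.5/97.5% bounds
#'   (`ci`), convergence and under-determination flags, and the seed.
#' @export
global_fit <- function(tc, init = NULL, starts = 20, seed = 1203,
                       n_boot = 100, weights = c("auto", "uniform")) {
  weights <- match.arg(weights)
  tc <- as.data.frame(tc)
  if (!all(c("time_s", "species", "fraction") %in% names(tc))) {
    rs_stop("time course needs columns time_s, species, fraction", "validation_error")
  }
  sp <- normalize_species(tc$species)
  if (!all(sp %in% SPECIES_LEVELS)) {
    rs_stop(sprintf("unknown species: %s",
                    paste(unique(sp[!sp %in% SPECIES_LEVELS]), collapse = ", ")),
            "validation_error")
  }
  times <- as.numeric(tc$time_s)
  y <- as.numeric(tc$fraction)
  check_nonneg(times, "time_s")

  under_determined <- length(unique(times)) < 8L
  if (under_determined) {
    rs_warn("fewer than 8 distinct time points: the chain fit is under-determined",
            "under_determined_warning")
  }

  w <- rep(1, length(y))
  has_reps <- "replicate" %in% names(tc) &&
    anyDuplicated(paste(times, sp)) > 0L
  if (weights == "auto" && has_reps) {
    sds <- tapply(y, sp, function(v) stats::sd(v))
    sds[!is.finite(sds) | sds <= 0] <- mean(sds[is.finite(sds) & sds > 0], na.rm = TRUE)
    if (all(is.finite(sds)) && all(sds > 0)) w <- 1 / sds[sp]
  }

  residual_fn <- function(theta, yy) {
    m <- tryCatch(theta_to_model(theta), error = function(e) NULL)
    if (is.null(m)) return(rep(1e6, length(yy)))
    w * (yy - chain_predict(times, sp, m))
  }

  fit_one <- function(theta0, yy) {
    tryCatch(
      minpack.lm::nls.lm(par = theta0, fn = residual_fn, yy = yy,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  res <- with_seed(seed, {
    starts_list <- list()
    if (!is.null(init)) {
      stopifnot(inherits(init, "chain_model"))
      starts_list[[1]] <- model_to_theta(init)
    }
    while (length(starts_list) < max(1L, starts)) {
      starts_list[[length(starts_list) + 1L]] <-
        c(log(exp(stats::runif(5, log(1e-3), log(10)))), stats::rnorm(1, 0, 1))
    }
    best <- NULL
    for (th in starts_list) {
      f <- fit_one(th, y)
      if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) best <- f
    }
    if (is.null(best)) {
      rs_stop("chain fit failed to converge from every start", "fit_error")
    }
    est_theta <- best$par
    est_model <- theta_to_model(est_theta)
    pred <- chain_predict(times, sp, est_model)
    resid <- y - pred

    ci <- NULL
    boot_par <- NULL
    if (n_boot > 0) {
      # Cluster wild bootstrap: one Gaussian multiplier per gel lane
      # (time point x replicate). Band fractions within a lane are
      # renormalised together, so their residuals are correlated and
      # heteroscedastic; perturbing whole lanes preserves both.
      lane <- if ("replicate" %in% names(tc)) {
        interaction(times, tc$replicate, drop = TRUE)
      } else {
        factor(times)
      }
      # HC2 leverage correction: residuals at high-leverage observations
      # (few time points informing a rate) systematically underestimate
      # the noise; rescale by 1/sqrt(1 - h) before perturbing.
      J <- matrix(0, length(y), 6L)
      eps <- 1e-6
      base_pred <- chain_predict(times, sp, est_model)
      for (p in 1:6) {
        thp <- est_theta
        thp[p] <- thp[p] + eps
        J[, p] <- (chain_predict(times, sp, theta_to_model(thp)) - base_pred) / eps
      }
      h <- tryCatch({
        JtJ_inv <- solve(crossprod(J))
        rowSums((J %*% JtJ_inv) * J)
      }, error = function(e) rep(0, length(y)))
      scaled <- resid / sqrt(pmax(1 - h, 0.05))
      boot_par <- matrix(NA_real_, nrow = n_boot, ncol = 6L)
      for (b in seq_len(n_boot)) {
        v <- stats::rnorm(nlevels(lane))[as.integer(lane)]
        yb <- pred + scaled * v
        fb <- fit_one(est_theta, yb)
        if (!is.null(fb)) boot_par[b, ] <- fb$par
      }
      boot_par <- boot_par[stats::complete.cases(boot_par), , drop = FALSE]
      nat <- cbind(exp(boot_par[, 1:5, drop = FALSE]),
                   stats::plogis(boot_par[, 6]))
      ci <- apply(nat, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
      colnames(ci) <- c(paste0("k", 1:5), "f_byp")
      rownames(ci) <- c("lower", "upper")
    }
    list(model = est_model, rss = best$deviance, ci = ci,
         converged = best$info %in% 1:4, resid = resid)
  })

  structure(list(model = res$model, rss = res$rss, ci = res$ci,
                 converged = res$converged,
                 under_determined = under_determined,
                 seed = seed, n_obs = length(y)),
            class = "chain_fit")
}

#' @export
print.chain_fit <- function(x, ...) {
  cat("Global chain fit\n")
  print(x$model)
  cat(sprintf("  RSS: %.4g   converged: %s%s\n", x$rss, x$converged,
              if (x$under_determined) "   (under-determined)" else ""))
  if (!is.null(x$ci)) {
    cat("  bootstrap 95% intervals:\n")
    print(signif(x$ci, 4))
  }
  invisible(x)
}
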