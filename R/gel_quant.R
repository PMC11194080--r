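#' Bypassing efficiency from band densities
#'
#' The ratio of the density of the full bypassing product band (ORF1+2) to
#' the sum of the ORF1 and ORF1+2 band densities in a lane.
#'
#' @param densities Named numeric vector of band densities (arbitrary
#'   units, >= 0); must contain `ORF1` and `ORF1_2` (gel-style aliases
#'   such as `"ORF1+2"` are accepted).
#' @return Efficiency fraction in `[0, 1]`.
#' @examples
#' bypassing_efficiency(c(ORF1 = 51, "ORF1+2" = 49))  # 0.49
#' @export
bypassing_efficiency <- function(densities) {
  if (is.null(names(densities))) {
    rs_stop("`densities` must be a named vector of band densities", "validation_error")
  }
  names(densities) <- normalize_species(names(densities))
  check_nonneg(densities, "densities")
  if (!all(c("ORF1", "ORF1_2") %in% names(densities))) {
    rs_stop("both ORF1 and ORF1+2 densities are required", "validation_error")
  }
  d1 <- unname(densities[["ORF1"]])
  d12 <- unname(densities[["ORF1_2"]])
  if (d1 + d12 == 0) {
    rs_stop("both reporter bands have zero density: efficiency undefined",
            "undefined_efficiency_error")
  }
  d12 / (d1 + d12)
}

#' Peptide length of a gel band from a ladder calibration
#'
#' Interpolates the upper and lower mobility borders of a band against a
#' peptide-marker ladder and reports the midpoint as the length estimate
#' with the two interpolated borders as bounds. Interpolation is
#' piecewise-linear in log length versus mobility by default (the
#' conventional gel calibration); `method = "linear"` interpolates length
#' directly.
#'
#' @param upper_mobility,lower_mobility Gel mobility of the band borders
#'   (unitless coordinate; order does not matter).
#' @param ladder Data frame with columns `mobility` and `length_aa`
#'   (lengths > 0, mobility strictly monotone in length).
#' @param method `"log"` (default) or `"linear"` interpolation.
#' @return List with `length_aa` (estimate rounded to integer amino
#'   acids), `length_raw`, and `bounds` (the two border lengths, sorted).
#' @export
calibrate_band_length <- function(upper_mobility, lower_mobility, ladder,
                                  method = c("log", "linear")) {
  method <- match.arg(method)
  ladder <- as.data.frame(ladder)
  if (!all(c("mobility", "length_aa") %in% names(ladder)) || nrow(ladder) < 2L) {
    rs_stop("ladder needs >= 2 rows with columns mobility and length_aa",
            "validation_error")
  }
  check_positive(ladder$length_aa, "ladder$length_aa")
  o <- order(ladder$mobility)
  mob <- ladder$mobility[o]
  len <- ladder$length_aa[o]
  dl <- diff(len)
  if (any(diff(mob) <= 0) || !(all(dl > 0) || all(dl < 0))) {
    rs_stop("ladder mobility must be strictly monotone in length", "validation_error")
  }
  borders <- c(upper_mobility, lower_mobility)
  if (any(borders < min(mob)) || any(borders > max(mob))) {
    rs_stop("band border outside the ladder range: refusing to extrapolate",
            "extrapolation_error")
  }
  interp_len <- function(x) {
    if (method == "log") {
      exp(stats::approx(mob, log(len), xout = x)$y)
    } else {
      stats::approx(mob, len, xout = x)$y
    }
  }
  bl <- sort(vapply(borders, interp_len, numeric(1)))
  raw <- mean(bl)
  list(length_aa = round(raw), length_raw = raw, bounds = bl)
}

#' Completion time of a product trajectory
#'
#' Fits a delayed single-exponential rise
#' `amplitude * (1 - exp(-(t - t0) / tau))` (zero before `t0`) to a
#' product time course and reports `t0 + multiplier * tau` as the
#' completion time; the default multiplier of 2 corresponds to ~86% of
#' the plateau. The trajectory must have reached a plateau (the final 20%
#' of samples varying by less than 5% of the maximum).
#'
#' @param time_s Sampling times (s), strictly increasing.
#' @param fraction Product fraction at each time.
#' @param multiplier Completion-time policy: completion is declared at
#'   `t0 + multiplier * tau`. Exposed rather than hard-coded because the
#'   extraction convention for "synthesis time" is not standardised.
#' @return List with `completion_s`, the fit parameters `t0`, `tau`,
#'   `amplitude`, and the policy `multiplier`.
#' @export
completion_time <- function(time_s, fraction, multiplier = 2) {
  if (length(time_s) != length(fraction) || length(time_s) < 5L) {
    rs_stop("need >= 5 paired samples", "validation_error")
  }
  if (any(diff(time_s) <= 0)) rs_stop("`time_s` must be strictly increasing", "validation_error")
  check_positive(multiplier, "multiplier")
  y <- as.numeric(fraction)
  if (y[length(y)] < y[1] || all(diff(y) <= 0)) {
    rs_stop("trajectory decreases: not a product accumulation curve", "validation_error")
  }
  tailn <- max(2L, ceiling(0.2 * length(y)))
  tail_y <- y[(length(y) - tailn + 1L):length(y)]
  if (diff(range(tail_y)) > 0.05 * max(y)) {
    rs_stop("trajectory has not reached a plateau: completion time undefined",
            "nonconvergence_error")
  }
  amp0 <- mean(tail_y)
  t0_0 <- max(0, time_s[which(y >= 0.05 * amp0)[1]] - 1e-3)
  i50 <- which(y >= 0.5 * amp0)[1]
  tau0 <- max((time_s[i50] - t0_0) / log(2), 1e-3)
  resfun <- function(par) {
    t0 <- exp(par[1]); tau <- exp(par[2]); amp <- par[3]
    pred <- ifelse(time_s <= t0, 0, amp * (1 - exp(-(time_s - t0) / tau)))
    y - pred
  }
  fit <- minpack.lm::nls.lm(par = c(log(max(t0_0, 1e-4)), log(tau0), amp0),
                            fn = resfun,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  t0 <- exp(fit$par[1]); tau <- exp(fit$par[2]); amp <- fit$par[3]
  list(completion_s = t0 + multiplier * tau, t0 = t0, tau = tau,
       amplitude = amp, multiplier = multiplier)
}

#' Time spent in take-off, sliding and landing
#'
#' The difference between the completion time on the full (gap-containing)
#' mRNA and on the gap-less fusion construct isolates the time cost of
#' bypassing.
#'
#' @param t_full Completion time on the bypassing mRNA (s).
#' @param t_dgap Completion time on the gap-less construct (s).
#' @return Bypassing time (s), `t_full - t_dgap`.
#' @examples
#' bypassing_time(153, 53)  # 100 s
#' @export
bypassing_time <- function(t_full, t_dgap) {
  check_positive(t_dgap, "t_dgap")
  if (any(t_full < t_dgap)) {
    rs_stop("`t_full` must be >= `t_dgap`: negative bypassing time", "negative_time_error")
  }
  t_full - t_dgap
}

#' Average sliding velocity over the non-coding gap
#'
#' @param gap_nt Gap length (nt), > 0.
#' @param t_byp Bypassing time (s), > 0.
#' @return Velocity in nt/s.
#' @export
sliding_velocity <- function(gap_nt, t_byp) {
  check_positive(gap_nt, "gap_nt")
  check_positive(t_byp, "t_byp")
  gap_nt / t_byp
}

#' Average elongation rate
#'
#' @param aa_count Amino acids translated, > 0.
#' @param time_s Time taken (s), > 0.
#' @return Rate in aa/s.
#' @examples
#' average_elongation_rate(114, 25)  # ~4.6 aa/s
#' @export
average_elongation_rate <- function(aa_count, time_s) {
  check_positive(aa_count, "aa_count")
  check_positive(time_s, "time_s")
  aa_count / time_s
}

#' Spearman rank correlation
#'
#' @param x,y Paired numeric series, >= 3 points, neither constant.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    rs_stop("need >= 3 paired points", "validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rs_stop("constant series: rank correlation undefined", "undefined_correlation_error")
  }
  stats::cor(x, y, method = "spearman")
}
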