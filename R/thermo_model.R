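#' Energy-unit configuration for the free-energy transform
#'
#' By default free energies are expressed in units of the thermal energy
#' `kT` (so `kT = 1`); supply `temp_k` with `unit = "kJ/mol"` to convert
#' using the gas constant at the experiment temperature.
#'
#' @param kT Thermal energy in the chosen unit, > 0. Ignored when
#'   `temp_k` is given.
#' @param unit Unit label, `"kT"` or `"kJ/mol"`.
#' @param temp_k Absolute temperature (K) used for the kJ/mol conversion.
#' @return An object of class `thermo_config`.
#' @export
thermo_config <- function(kT = 1, unit = c("kT", "kJ/mol"), temp_k = NULL) {
  unit <- match.arg(unit)
  if (!is.null(temp_k)) {
    check_positive(temp_k, "temp_k")
    kT <- 8.31446261815324e-3 * temp_k  # R in kJ/(mol K)
    unit <- "kJ/mol"
  }
  check_positive(kT, "kT")
  structure(list(kT = kT, unit = unit), class = "thermo_config")
}

#' Temperature-shift model of the bypassing curve
#'
#' As temperature drops below the 37 degC reference, the bypassing
#' efficiency-versus-gap-length curve shifts toward shorter gaps by
#' `delta_nt(T)` nucleotides. The shift is stored per fitted temperature
#' and summarised by a linear law `delta_nt = slope * (ref_temp - T)`.
#'
#' @param P_ref Processivity coefficient at the reference temperature.
#' @param A Amplitude (take-off/landing probability), default 1.
#' @param slope Linear shift per degree of cooling (nt/degC), >= 0.
#' @param intercept Intercept of the linear shift law (nt), default 0 so
#'   that `delta_nt(ref_temp) = 0`.
#' @param ref_temp Reference temperature (degC), default 37.
#' @param shifts Optional data frame `(temperature_c, delta_nt)` of
#'   per-temperature fitted shifts; used in preference to the linear law
#'   for temperatures it covers.
#' @return An object of class `temp_shift_model`.
#' @export
temp_shift_model <- function(P_ref = 0.99, A = 1, slope = 1.5, intercept = 0,
                             ref_temp = 37, shifts = NULL) {
  if (!is.numeric(P_ref) || P_ref <= 0 || P_ref > 1) {
    rs_stop("`P_ref` must lie in (0, 1]", "validation_error")
  }
  check_fraction(A, "A")
  check_nonneg(slope, "slope")
  if (!is.null(shifts)) {
    shifts <- as.data.frame(shifts)
    stopifnot(all(c("temperature_c", "delta_nt") %in% names(shifts)))
  }
  structure(list(P_ref = P_ref, A = A, slope = slope, intercept = intercept,
                 ref_temp = ref_temp, shifts = shifts),
            class = "temp_shift_model")
}

#' @export
print.temp_shift_model <- function(x, ...) {
  cat(sprintf("Temperature-shift model (reference %g degC)\n", x$ref_temp))
  cat(sprintf("  P_ref = %.4f, A = %.3f\n", x$P_ref, x$A))
  cat(sprintf("  shift: %.3f nt/degC (intercept %.3f nt)\n", x$slope, x$intercept))
  if (!is.null(x$shifts)) {
    cat("  fitted per-temperature shifts:\n")
    print(x$shifts, row.names = FALSE)
  }
  invisible(x)
}

#' Temperature-dependent leftward shift of the bypassing curve
#'
#' The number of nucleotides by which the efficiency-versus-gap-length
#' curve moves toward shorter gaps at temperature `T` relative to the
#' reference: positive when cooling, 0 at the reference temperature.
#'
#' @param m A [temp_shift_model()].
#' @param temp_c Temperatures (degC).
#' @param use_table Use the per-temperature fitted table when available
#'   (default); otherwise the linear law.
#' @return Shifts in nt (0 at the reference temperature).
#' @export
delta_nt <- function(m, temp_c, use_table = TRUE) {
  stopifnot(inherits(m, "temp_shift_model"))
  out <- m$intercept + m$slope * (m$ref_temp - temp_c)
  out[temp_c == m$ref_temp] <- 0
  if (use_table && !is.null(m$shifts)) {
    idx <- match(temp_c, m$shifts$temperature_c)
    out[!is.na(idx)] <- m$shifts$delta_nt[idx[!is.na(idx)]]
  }
  pmax(out, ifelse(temp_c <= m$ref_temp, 0, -Inf))
}

#' Bypassing efficiency from the recurrent temperature-shift formula
#'
#' The efficiency-versus-gap-length curve at temperature `T` is the
#' reference curve translated leftward (toward shorter gaps) by
#' `delta_nt(T)` nucleotides:
#' `byp(T, L) = A * P_ref^max(L + delta_nt(T), 0)`, clamped to `[0, 1]`.
#' Cooling therefore both lowers the curve at every length and lowers its
#' maximum (the value at zero gap), as seen in temperature-series
#' bypassing data. Temperatures outside the range of the fitted shift
#' table raise an extrapolation warning (not an error).
#'
#' @param m A [temp_shift_model()].
#' @param temp_c Temperature (degC); scalar or vector recycled against `L`.
#' @param L Gap lengths (nt), >= 0.
#' @return Efficiencies in `[0, 1]`.
#' @export
recurrent_bypassing <- function(m, temp_c, L) {
  stopifnot(inherits(m, "temp_shift_model"))
  check_nonneg(L, "L")
  if (!is.null(m$shifts) && length(m$shifts$temperature_c)) {
    rng <- range(c(m$shifts$temperature_c, m$ref_temp))
    if (any(temp_c < rng[1] | temp_c > rng[2])) {
      rs_warn("temperature outside the fitted range: extrapolating the shift law",
              "extrapolation_warning")
    }
  }
  shift <- delta_nt(m, temp_c)
  eff <- m$A * m$P_ref^pmax(L + shift, 0)
  pmin(pmax(eff, 0), 1)
}

#' Fit the temperature-shift model to a multi-temperature gap series
#'
#' First fits the reference-temperature sub-series with the geometric law
#' (`A` fixed at 1 by default) to obtain `P_ref`, then estimates one shift
#' `delta_nt` per remaining temperature by 1-D least squares against the
#' shifted reference curve, and finally regresses the shifts on
#' `(ref_temp - T)` to obtain the linear slope in nt/degC.
#'
#' @param gs Gap series data frame with columns `gap_nt`,
#'   `efficiency_frac` and `temperature_c`.
#' @param P_ref Optional known reference processivity; required if the
#'   reference temperature is absent from the data.
#' @param ref_temp Reference temperature (degC), default 37.
#' @param fix_A Fix the amplitude at this value (default 1); `NULL` refits
#'   `A` on the reference sub-series.
#' @return A [temp_shift_model()] with the fitted per-temperature shift
#'   table and linear slope.
#' @export
fit_temp_shift <- function(gs, P_ref = NULL, ref_temp = 37, fix_A = 1) {
  gs <- as_gap_series(gs)
  if (!"temperature_c" %in% names(gs) || all(is.na(gs$temperature_c))) {
    rs_stop("gap series must carry a temperature column", "validation_error")
  }
  temps <- sort(unique(gs$temperature_c), decreasing = TRUE)
  if (length(temps) < 2L) {
    rs_stop("need at least 2 temperatures to fit a shift", "under_determined_error")
  }
  A <- if (is.null(fix_A)) NA_real_ else fix_A
  if (is.null(P_ref)) {
    if (!ref_temp %in% temps) {
      rs_stop("reference temperature absent and `P_ref` not supplied",
              "configuration_error")
    }
    ref_fit <- fit_exponential_gap_model(gs[gs$temperature_c == ref_temp, ],
                                         fix_A = fix_A)
    P_ref <- ref_fit$P
    A <- ref_fit$A
  } else if (is.null(fix_A)) {
    A <- 1
  }

  others <- setdiff(temps, ref_temp)
  shift_of <- function(tt) {
    sub <- gs[gs$temperature_c == tt, ]
    obj <- function(d) {
      pred <- pmin(pmax(A * P_ref^pmax(sub$gap_nt + d, 0), 0), 1)
      sum((sub$efficiency_frac - pred)^2)
    }
    lo <- if (tt < ref_temp) 0 else -max(sub$gap_nt)
    stats::optimize(obj, interval = c(lo, 3 * max(sub$gap_nt)), tol = 1e-8)$minimum
  }
  shifts <- vapply(others, shift_of, numeric(1))
  tab <- data.frame(temperature_c = c(ref_temp, others),
                    delta_nt = c(0, shifts))
  tab <- tab[order(-tab$temperature_c), ]
  cooling <- ref_temp - tab$temperature_c
  reg <- stats::lm(delta_nt ~ cooling, data = tab)
  temp_shift_model(P_ref = P_ref, A = A,
                   slope = stats::coef(reg)[["cooling"]],
                   intercept = stats::coef(reg)[["(Intercept)"]],
                   ref_temp = ref_temp, shifts = tab)
}

#' Standard free energy of bypassing
#'
#' The logistic free-energy transform
#' `dG = -kT * ln(byp / (1 - byp))`: zero at 50% efficiency, negative when
#' bypassing is favourable (efficiency above one half).
#'
#' @param efficiency Bypassing efficiencies strictly inside `(0, 1)`.
#' @param cfg A [thermo_config()]; defaults to units of `kT`.
#' @return Free energies in the configured unit.
#' @examples
#' delta_g(0.5)               # 0
#' delta_g(exp(1) / (1 + exp(1)))  # -1 kT
#' @export
delta_g <- function(efficiency, cfg = thermo_config()) {
  stopifnot(inherits(cfg, "thermo_config"))
  if (!is.numeric(efficiency) || any(!is.finite(efficiency))) {
    rs_stop("`efficiency` must be finite", "validation_error")
  }
  if (any(efficiency <= 0 | efficiency >= 1)) {
    dir <- if (any(efficiency >= 1)) "fully efficient (dG -> -Inf)" else "fully inefficient (dG -> +Inf)"
    rs_stop(sprintf("efficiency at 0 or 1 has infinite free energy: %s", dir),
            "infinite_energy_error")
  }
  out <- -cfg$kT * log(efficiency / (1 - efficiency))
  out + 0  # normalise IEEE negative zero at exactly half efficiency
}

#' Free-energy profile of a bypassing model over gap lengths
#'
#' Maps model efficiencies at each gap length through [delta_g()] and
#' reports where the profile crosses zero (the length at which bypassing
#' stops being favourable). Efficiencies are clamped to
#' `[1e-6, 1 - 1e-6]` before conversion, with a truncation warning when
#' the clamp is active.
#'
#' @param m A [processivity_model()] or [temp_shift_model()].
#' @param L Gap lengths (nt) at which to evaluate.
#' @param temp_c Temperature for a [temp_shift_model()] (default its
#'   reference temperature).
#' @param cfg A [thermo_config()].
#' @return Data frame `(gap_nt, efficiency_frac, deltaG)` with attribute
#'   `zero_crossing_nt`, the interpolated length at which `dG = 0`
#'   (`NA` if the profile does not cross zero).
#' @export
delta_g_profile <- function(m, L, temp_c = NULL, cfg = thermo_config()) {
  check_nonneg(L, "L")
  eff <- if (inherits(m, "processivity_model")) {
    bypassing_from_processivity(m, L)
  } else if (inherits(m, "temp_shift_model")) {
    recurrent_bypassing(m, if (is.null(temp_c)) m$ref_temp else temp_c, L)
  } else {
    rs_stop("`m` must be a processivity_model or temp_shift_model", "validation_error")
  }
  clamped <- eff < 1e-6 | eff > 1 - 1e-6
  if (any(clamped)) {
    rs_warn("efficiency saturates at 0 or 1 on part of the range: profile truncated there",
            "range_truncation_warning")
  }
  eff_c <- pmin(pmax(eff, 1e-6), 1 - 1e-6)
  dg <- delta_g(eff_c, cfg)
  out <- data.frame(gap_nt = L, efficiency_frac = eff, deltaG = dg)
  zc <- NA_real_
  s <- sign(dg)
  flip <- which(diff(s) != 0 & s[-length(s)] != 0)
  if (length(flip)) {
    i <- flip[1]
    zc <- L[i] + (0 - dg[i]) * (L[i + 1] - L[i]) / (dg[i + 1] - dg[i])
  } else if (any(dg == 0)) {
    zc <- L[which(dg == 0)[1]]
  }
  attr(out, "zero_crossing_nt") <- zc
  names(out)[3] <- if (cfg$unit == "kT") "deltaG_kT" else "deltaG_kJ_mol"
  out
}
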