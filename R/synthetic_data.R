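# Synthetic-data generators. These emulate the densitometry-level tables a
# gel quantification would produce -- band-fraction time courses, bypassing
# efficiency versus gap length (optionally per temperature) and peptide
# ladder calibrations -- from the package's own kinetic models plus simple
# noise, so every analysis stage can be validated end to end without
# laboratory data. Each generator returns the data frame together with a
# machine-readable `truth` record of the generating parameters and seed.

default_chain_model <- function() {
  # Scenario defaults chosen so that ORF1 completes within 10-15 s, the
  # intermediates peak successively, the ORF1+2 product plateaus near 49%
  # on a ~80 s time scale, mirroring the qualitative shape of reconstituted
  # high-fidelity translation of the bypassing mRNA.
  chain_model(k = c(0.5, 0.25, 0.25, 0.2, 0.015), f_byp = 0.49)
}

default_gap_model <- function() {
  # Constant P = 0.99 up to the 56-nt breakpoint. Beyond it the per-nt
  # continuation probability declines linearly; the slope is calibrated so
  # that the per-gap-length processivity coefficient (efficiency^(1/L)) at
  # the longest gap, 92 nt, equals 1.2/(1.2 + 0.04) -- i.e. the combined
  # loss rate rises from 0.01 to 0.04 nt/s (at k_forward = 1.2 nt/s)
  # across the long-gap range, and efficiency collapses to ~5% at 92 nt.
  target <- 92 * log(1.2 / 1.24) - 56 * log(0.99)
  d <- stats::uniroot(function(d) sum(log(0.99 - d * (1:36))) - target,
                      c(1e-4, 5e-3), tol = 1e-12)$root
  processivity_model(A = 1, P = 0.99, breakpoint = 56, decline = d)
}

default_temp_model <- function() {
  temp_shift_model(P_ref = 0.99, A = 1, slope = 1.5, ref_temp = 37)
}

#' Synthetic band-fraction time courses from the translation chain
#'
#' Evaluates [chain_occupancies()] on a time grid, maps the states to the
#' observable gel bands (the ORF1 band pools the take-off state with the
#' terminated product), and perturbs each band with multiplicative
#' log-normal noise before renormalising each lane to total signal 1.
#'
#' @param model Generating [chain_model()]; default emulates fast
#'   high-fidelity translation with a 49% bypassing branch.
#' @param times Sampling grid (s).
#' @param sigma Log-normal noise sigma on band densities (0 = noiseless).
#' @param replicates Independent replicate lanes per time point.
#' @param seed Integer seed, recorded in the truth record.
#' @return List with `data` (columns `time_s, species, fraction,
#'   replicate`) and `truth` (generating parameters).
#' @export
generate_timecourse <- function(model = default_chain_model(),
                                times = c(2, 5, 10, 15, 20, 30, 45, 60, 90, 120, 180, 240),
                                sigma = 0.05, replicates = 2, seed = 1L) {
  stopifnot(inherits(model, "chain_model"))
  check_nonneg(sigma, "sigma")
  occ <- chain_occupancies(times, model)
  clipped <- 0L
  data <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(replicates), function(rep) {
      dens <- occ
      if (sigma > 0) {
        dens <- occ * matrix(stats::rlnorm(length(occ), -sigma^2 / 2, sigma),
                             nrow = nrow(occ))
      }
      frac <- dens / pmax(rowSums(dens), .Machine$double.eps)
      data.frame(time_s = rep(times, times = ncol(frac)),
                 species = rep(colnames(occ), each = length(times)),
                 fraction = as.vector(frac),
                 replicate = rep)
    }))
  })
  list(data = data,
       truth = list(scenario = "timecourse", k = model$k, f_byp = model$f_byp,
                    sigma = sigma, replicates = replicates, seed = seed,
                    clipped = clipped))
}

#' Synthetic bypassing-efficiency series over gap lengths
#'
#' Evaluates the two-regime processivity model on a gap-length grid and
#' adds additive Gaussian noise, truncating to `[0, 1]`.
#'
#' @param model Generating [processivity_model()]; the default has
#'   `A = 1`, `P = 0.99`, a 56-nt breakpoint and a per-nt decline beyond
#'   it matching a loss rate rising from 0.01 to 0.04 nt/s.
#' @param gaps Gap lengths (nt); default 38 to 92 in steps of 3.
#' @param sigma Additive Gaussian noise on efficiencies.
#' @param replicates Replicates per gap length.
#' @param temperature_c Optional temperature annotation copied to the
#'   output (the model itself is temperature-free).
#' @param seed Integer seed.
#' @return List with `data` (columns `gap_nt, efficiency_frac,
#'   temperature_c, replicate`) and `truth`.
#' @export
generate_gap_series <- function(model = default_gap_model(),
                                gaps = seq(38, 92, by = 3),
                                sigma = 0.02, replicates = 2,
                                temperature_c = NA_real_, seed = 1L) {
  stopifnot(inherits(model, "processivity_model"))
  check_nonneg(sigma, "sigma")
  eff <- bypassing_from_processivity(model, gaps)
  clipped <- 0L
  data <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(replicates), function(rep) {
      e <- eff
      if (sigma > 0) e <- e + stats::rnorm(length(e), 0, sigma)
      clipped <<- clipped + sum(e < 0 | e > 1)
      data.frame(gap_nt = gaps, efficiency_frac = pmin(pmax(e, 0), 1),
                 temperature_c = temperature_c, replicate = rep)
    }))
  })
  list(data = data,
       truth = list(scenario = "gap", A = model$A, P = model$P,
                    breakpoint = model$breakpoint, decline = model$decline,
                    sigma = sigma, replicates = replicates, seed = seed,
                    clipped = clipped))
}

#' Synthetic temperature x gap-length efficiency grid
#'
#' Evaluates [recurrent_bypassing()] on the full temperature-by-length
#' grid (default: the twelve temperatures from 37 to 10 degC used in
#' temperature-series bypassing assays) and adds Gaussian noise.
#'
#' @param model Generating [temp_shift_model()] (default: `P_ref = 0.99`,
#'   `A = 1`, shift slope 1.5 nt/degC).
#' @param temps Temperatures (degC).
#' @param gaps Gap lengths (nt).
#' @param sigma Additive Gaussian noise on efficiencies.
#' @param replicates Replicates per (temperature, length) cell.
#' @param seed Integer seed.
#' @return List with `data` (gap-series columns incl. `temperature_c`)
#'   and `truth`.
#' @export
generate_temperature_grid <- function(model = default_temp_model(),
                                      temps = c(37, 33, 30, 28, 26, 24, 22, 20, 18, 16, 13, 10),
                                      gaps = seq(38, 92, by = 3),
                                      sigma = 0.02, replicates = 2, seed = 1L) {
  stopifnot(inherits(model, "temp_shift_model"))
  check_nonneg(sigma, "sigma")
  grid <- expand.grid(gap_nt = gaps, temperature_c = temps)
  eff <- recurrent_bypassing(model, grid$temperature_c, grid$gap_nt)
  clipped <- 0L
  data <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(replicates), function(rep) {
      e <- eff
      if (sigma > 0) e <- e + stats::rnorm(length(e), 0, sigma)
      clipped <<- clipped + sum(e < 0 | e > 1)
      data.frame(gap_nt = grid$gap_nt, efficiency_frac = pmin(pmax(e, 0), 1),
                 temperature_c = grid$temperature_c, replicate = rep)
    }))
  })
  list(data = data,
       truth = list(scenario = "tempgrid", P_ref = model$P_ref, A = model$A,
                    slope = model$slope, ref_temp = model$ref_temp,
                    sigma = sigma, replicates = replicates, seed = seed,
                    clipped = clipped))
}

#' Synthetic peptide ladder and band fixtures
#'
#' Emits a monotone mobility-versus-length calibration table (log-linear
#' mobility, the usual gel behaviour) and band fixtures placed at known
#' peptide lengths with configurable border half-widths, for exercising
#' [calibrate_band_length()].
#'
#' @param lengths Marker peptide lengths (aa); default 11 to 41.
#' @param bands Data frame `(length_aa, half_width_aa)` of band centres
#'   and border half-widths; defaults to the three pausing-intermediate
#'   lengths 21 +/- 3, 31 +/- 2 and 38.5 +/- 2.5 aa.
#' @return List with `ladder` (`mobility`, `length_aa`), `bands` (the
#'   fixture table with upper/lower border mobilities), and `truth`.
#' @export
generate_ladder <- function(lengths = 11:41,
                            bands = data.frame(length_aa = c(21, 31, 38.5),
                                               half_width_aa = c(3, 2, 2.5))) {
  check_positive(lengths, "lengths")
  mobility_of <- function(len) 2 - 0.45 * log(len)
  ladder <- data.frame(mobility = mobility_of(lengths), length_aa = lengths)
  bands <- as.data.frame(bands)
  stopifnot(all(c("length_aa", "half_width_aa") %in% names(bands)))
  bands$upper_mobility <- mobility_of(bands$length_aa + bands$half_width_aa)
  bands$lower_mobility <- mobility_of(bands$length_aa - bands$half_width_aa)
  list(ladder = ladder, bands = bands,
       truth = list(scenario = "ladder", mobility_intercept = 2,
                    mobility_slope = -0.45, lengths = range(lengths)))
}
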