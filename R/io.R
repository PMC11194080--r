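# CSV schemas: required columns, accepted aliases and range checks for the
# plain-text table dialects used throughout. All numeric outputs carry
# units in their column names (time_s, gap_nt, efficiency_frac, ...).

SCHEMAS <- list(
  gap_series = list(
    required = c("gap_nt", "efficiency_frac"),
    aliases = c(efficiency = "efficiency_frac", temperature = "temperature_c"),
    optional = c("temperature_c", "replicate"),
    checks = list(
      gap_nt = function(x) x >= 0,
      efficiency_frac = function(x) x >= 0 & x <= 1
    )
  ),
  timecourse = list(
    required = c("time_s", "species", "fraction"),
    aliases = c(),
    optional = "replicate",
    checks = list(
      time_s = function(x) x >= 0,
      fraction = function(x) x >= 0 & x <= 1
    )
  ),
  lanes = list(
    required = c("lane_id", "time_s", "species", "density"),
    aliases = c(),
    optional = character(),
    checks = list(
      time_s = function(x) x >= 0,
      density = function(x) x >= 0
    )
  ),
  ladder = list(
    required = c("mobility", "length_aa"),
    aliases = c(length = "length_aa"),
    optional = character(),
    checks = list(length_aa = function(x) x > 0)
  ),
  timing = list(
    required = c("construct", "time_s"),
    aliases = c(),
    optional = c("buffer", "gap_nt"),
    checks = list(
      time_s = function(x) x > 0,
      gap_nt = function(x) x >= 0
    )
  )
)

#' Validate a table against one of the package's CSV schemas
#'
#' Checks column presence (after applying aliases), numeric types and
#' value ranges (fractions in `[0, 1]`, times >= 0, ...). On failure the
#' error message names every offending row and column.
#'
#' @param x A data frame, or path to a comma-separated file with a header
#'   row.
#' @param schema One of `"gap_series"`, `"timecourse"`, `"lanes"`,
#'   `"ladder"`, `"timing"`.
#' @return The validated (alias-normalised) data frame, invisibly usable
#'   downstream.
#' @export
validate_inputs <- function(x, schema) {
  if (!schema %in% names(SCHEMAS)) {
    rs_stop(sprintf("unknown schema '%s'", schema), "validation_error")
  }
  sc <- SCHEMAS[[schema]]
  if (is.character(x)) {
    if (!file.exists(x)) rs_stop(sprintf("file not found: %s", x), "validation_error")
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  for (a in names(sc$aliases)) {
    if (a %in% names(x) && !(sc$aliases[[a]] %in% names(x))) {
      names(x)[names(x) == a] <- sc$aliases[[a]]
    }
  }
  missing_cols <- setdiff(sc$required, names(x))
  if (length(missing_cols)) {
    rs_stop(sprintf("schema '%s': missing column(s) %s", schema,
                    paste(missing_cols, collapse = ", ")),
            "validation_error")
  }
  if (nrow(x) == 0L) {
    rs_stop(sprintf("schema '%s': file contains a header but no rows", schema),
            "empty_file_error")
  }
  problems <- character(0)
  for (col in names(sc$checks)) {
    if (!col %in% names(x)) next
    v <- x[[col]]
    if (!is.numeric(v)) {
      problems <- c(problems, sprintf("column '%s' is not numeric", col))
      next
    }
    bad <- which(!is.finite(v) | !sc$checks[[col]](v))
    if (length(bad)) {
      problems <- c(problems,
                    sprintf("column '%s' out of range at row(s) %s", col,
                            paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  if (length(problems)) {
    rs_stop(sprintf("schema '%s': %s", schema, paste(problems, collapse = "; ")),
            "validation_error")
  }
  x
}

# Internal coercion used by the fitting functions.
as_gap_series <- function(gs) {
  validate_inputs(gs, "gap_series")
}

#' Bypassing efficiencies from a tidy lanes table
#'
#' Applies [bypassing_efficiency()] per `(lane_id, time_s)` group of a
#' densitometry lanes table.
#'
#' @param lanes Data frame or CSV path with columns
#'   `lane_id, time_s, species, density`.
#' @return Data frame `(lane_id, time_s, efficiency_frac)`.
#' @export
lane_efficiencies <- function(lanes) {
  lanes <- validate_inputs(lanes, "lanes")
  lanes$species <- normalize_species(lanes$species)
  key <- interaction(lanes$lane_id, lanes$time_s, drop = TRUE)
  out <- do.call(rbind, lapply(split(lanes, key), function(g) {
    dens <- stats::setNames(g$density, g$species)
    data.frame(lane_id = g$lane_id[1], time_s = g$time_s[1],
               efficiency_frac = bypassing_efficiency(dens))
  }))
  rownames(out) <- NULL
  out[order(out$lane_id, out$time_s), , drop = FALSE]
}

#' Run the full synthetic-data / fitting pipeline
#'
#' Generates the three synthetic scenarios (chain time course, gap-length
#' series, temperature grid) from a single seed, runs the corresponding
#' fits, and writes a JSON run report plus tidy CSVs to `out_dir`.
#' Identical configuration and seed reproduce an identical bundle.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level seed governing every stochastic stage.
#' @param sigma_timecourse,sigma_series Noise levels passed to the
#'   generators (set to 0 for the noiseless self-consistency check).
#' @param starts Multi-starts for the chain fit.
#' @param n_boot Bootstrap resamples for the chain fit intervals.
#' @return The run report (named list), invisibly; written as
#'   `report.json` alongside `timecourse.csv`, `gap_series.csv`,
#'   `temperature_grid.csv`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, sigma_timecourse = 0.05,
                         sigma_series = 0.02, starts = 8, n_boot = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tc <- generate_timecourse(sigma = sigma_timecourse, seed = seed)
  gap <- generate_gap_series(sigma = sigma_series, seed = seed + 1L)
  grid <- generate_temperature_grid(sigma = sigma_series, replicates = 3,
                                    seed = seed + 2L)

  utils::write.csv(tc$data, file.path(out_dir, "timecourse.csv"), row.names = FALSE)
  utils::write.csv(gap$data, file.path(out_dir, "gap_series.csv"), row.names = FALSE)
  utils::write.csv(grid$data, file.path(out_dir, "temperature_grid.csv"),
                   row.names = FALSE)

  chain_fit <- global_fit(tc$data, init = default_chain_model(),
                          starts = starts, seed = seed, n_boot = n_boot)
  gap_fit <- fit_exponential_gap_model(gap$data, fix_A = 1, max_gap = 56)
  bp_fit <- fit_breakpoint(gap$data)
  ts_fit <- fit_temp_shift(grid$data)
  profile <- delta_g_profile(default_gap_model(), L = seq(38, 92))

  report <- list(
    package = "riboslide",
    version = as.character(utils::packageVersion("riboslide")),
    seed = seed,
    stages = list(
      chain = list(truth = tc$truth,
                   estimate = list(k = chain_fit$model$k,
                                   f_byp = chain_fit$model$f_byp,
                                   rss = chain_fit$rss,
                                   converged = chain_fit$converged,
                                   ci = chain_fit$ci)),
      gap = list(truth = gap$truth,
                 estimate = list(A = gap_fit$A, P = gap_fit$P,
                                 breakpoint = bp_fit$breakpoint,
                                 decline = bp_fit$decline,
                                 regime = bp_fit$regime)),
      temperature = list(truth = grid$truth,
                         estimate = list(P_ref = ts_fit$P_ref,
                                         slope_nt_per_c = ts_fit$slope,
                                         shifts = ts_fit$shifts)),
      free_energy = list(zero_crossing_nt = attr(profile, "zero_crossing_nt"))
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(ts_fit$shifts, file.path(out_dir, "temperature_shifts.csv"),
                   row.names = FALSE)
  utils::write.csv(profile, file.path(out_dir, "deltaG_profile.csv"),
                   row.names = FALSE)
  invisible(report)
}
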