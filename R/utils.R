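#' @keywords internal
"_PACKAGE"

# Classed errors so callers can distinguish bad input from numerical failure.
rs_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "riboslide_error", "error", "condition")))
}

rs_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "riboslide_warning", "warning", "condition")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    rs_stop(sprintf("`%s` must be finite and > 0", name), "validation_error")
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    rs_stop(sprintf("`%s` must be finite and >= 0", name), "validation_error")
  }
  invisible(x)
}

check_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) {
    rs_stop(sprintf("`%s` must lie in %s", name, if (open) "(0, 1)" else "[0, 1]"),
            "validation_error")
  }
  invisible(x)
}

# Evaluate `code` under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Canonical species labels used throughout: gel band names with CSV-safe
# aliases ("ORF1+2" -> "ORF1_2", "pre-INT1" -> "pre_INT1").
SPECIES_LEVELS <- c("pre_INT1", "INT1", "INT2", "INT3", "ORF1", "ORF1_2")

normalize_species <- function(x) {
  x <- gsub("\\+", "_", gsub("-", "_", as.character(x)))
  x[x == "ORF1_ORF2"] <- "ORF1_2"
  x
}
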