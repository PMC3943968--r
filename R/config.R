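# Run configuration: thresholds and simulation settings with validated
# defaults. The defaults are the study's published values; a config file only
# needs to name what it overrides.

#' High-abundance plasma proteins targeted by 14-protein immunodepletion
#'
#' Names of the fourteen proteins removed by multi-affinity depletion of
#' plasma/CSF before deep proteome analysis. Proteins on this list are
#' conventionally excluded from quantitative conclusions in depleted-workflow
#' data because their residual levels no longer reflect the sample.
#'
#' @format Character vector of 14 protein names.
#' @export
mars14_proteins <- c(
  "Serum albumin", "Immunoglobulin gamma", "Alpha-1-antitrypsin",
  "Immunoglobulin alpha", "Serotransferrin", "Haptoglobin", "Fibrinogen",
  "Alpha-2-macroglobulin", "Alpha-1-acid glycoprotein", "Immunoglobulin mu",
  "Apolipoprotein A-I", "Apolipoprotein A-II", "Complement C3",
  "Transthyretin"
)

csf_config_defaults <- function() {
  list(
    fc_affected = 1.5,        # fold-change at/above which a protein is affected
    fc_unaffected = 1.2,      # fold-change below which a protein is unaffected
    r2_low = 0.3,             # R^2 below which no gradient is credited
    r2_high = 0.7,            # R^2 above which linearity is sufficient
    suppression_fold = 2,     # >= 2-fold decrease at the high spike flags suppression
    band_low = 0.2,           # plasma/CSF ratio below which the band is "low"
    band_high = 0.4,          # plasma/CSF ratio above which the band is "high"
    noise_cv = 0.20,          # technical coefficient of variation
    dialect = "generic",
    xlsx_sheet = NULL,
    depletion_list = mars14_proteins,
    seed = NULL               # mandatory for simulation; no silent default
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML key/value file of thresholds and simulation settings. Every
#' key is optional; omitted keys take the package defaults (fold-change
#' thresholds 1.5 and 1.2, R-squared bands 0.3/0.7, 2-fold suppression flag,
#' plasma/CSF ratio bands 0.2/0.4, 20% technical CV). Unknown keys and
#' out-of-range values are rejected with an error naming the offending keys.
#' `seed` has no default: simulation entry points refuse to run without an
#' explicit one.
#'
#' @param path Path to a YAML config file, or `NULL` for all defaults.
#' @return A validated named list of class `"csf_config"`.
#' @export
load_config <- function(path = NULL) {
  cfg <- csf_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      abort(sprintf(
        "unknown config key(s): %s", paste(unknown, collapse = ", ")
      ))
    }
    cfg[names(user)] <- user
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  bad <- character()
  num_pos <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) bad <<- c(bad, key)
  }
  num_pos("fc_affected"); num_pos("fc_unaffected"); num_pos("suppression_fold")
  num_pos("band_low"); num_pos("band_high")
  if (!is.numeric(cfg$noise_cv) || cfg$noise_cv < 0) bad <- c(bad, "noise_cv")
  for (key in c("r2_low", "r2_high")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) bad <- c(bad, key)
  }
  if (length(bad) == 0) {
    if (cfg$fc_affected <= cfg$fc_unaffected) bad <- c(bad, "fc_affected")
    if (cfg$r2_low >= cfg$r2_high) bad <- c(bad, "r2_low")
    if (cfg$band_low >= cfg$band_high) bad <- c(bad, "band_low")
  }
  if (!is.null(cfg$seed) &&
      (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))) {
    bad <- c(bad, "seed")
  }
  if (!cfg$dialect %in% names(csf_dialects)) bad <- c(bad, "dialect")
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid config value(s) for: %s", paste(unique(bad), collapse = ", ")
    ))
  }
  structure(cfg, class = "csf_config")
}

#' @export
print.csf_config <- function(x, ...) {
  cat("<csf_config>\n")
  for (key in names(x)) {
    v <- x[[key]]
    cat(sprintf("  %-18s %s\n", key,
                if (is.null(v)) "NULL"
                else paste(utils::head(v, 3), collapse = ", ")))
  }
  invisible(x)
}
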