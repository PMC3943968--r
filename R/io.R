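# Reading and writing protein report tables.
#
# A "protein report" on disk is a wide table: one row per protein, a protein
# accession column, one abundance column per sample, and optionally
# "protein_name" and per-sample unique-peptide-count columns named
# "n_unique_peptides_<sample_id>". In memory the package works in long, tidy
# form: one row per (accession, sample) with the sample-role metadata joined
# on, so every downstream verb is an ordinary dplyr operation.

# Column-name conventions of the supported report dialects. Dialect mapping is
# a documented column-name translation only; vendor binary formats are out of
# scope.
csf_dialects <- list(
  generic      = list(accession = "accession",        name = "protein_name"),
  progenesis   = list(accession = "Accession",        name = "Description"),
  spectrummill = list(accession = "accession_number", name = "entry_name"),
  pd           = list(accession = "Accession",        name = "Description")
)

#' Describe the samples of a study design
#'
#' Builds the sample-role metadata table that accompanies every protein
#' report. Each sample has a role and only the role's fields are meaningful:
#' `spike_fraction` for spiked samples, `rcg_point` for rostro-caudal gradient
#' collection points, `patient_id`/`fluid` for paired plasma/CSF samples.
#'
#' @param sample_id Character vector of sample identifiers (must match the
#'   abundance column names of the report file).
#' @param role One of `"reference"`, `"spiked"`, `"rcg_point"`,
#'   `"patient_fluid"` per sample.
#' @param spike_fraction Volume fraction of whole blood in `[0, 1]`; `NA`
#'   unless `role == "spiked"`.
#' @param centrifuged Logical; whether the sample was centrifuged before
#'   freezing (`NA` where irrelevant).
#' @param rcg_point Integer collection point `1..7` (1 = lumbar-most, i.e.
#'   first millilitres drawn); `NA` unless `role == "rcg_point"`.
#' @param patient_id,fluid Patient identifier and fluid (`"CSF"` or
#'   `"plasma"`) for paired-fluid designs.
#' @return A tibble with one row per sample.
#' @export
sample_meta <- function(sample_id,
                        role,
                        spike_fraction = NA_real_,
                        centrifuged = NA,
                        rcg_point = NA_integer_,
                        patient_id = NA_character_,
                        fluid = NA_character_) {
  roles <- c("reference", "spiked", "rcg_point", "patient_fluid")
  if (!all(role %in% roles)) {
    abort(sprintf("`role` must be one of: %s", paste(roles, collapse = ", ")))
  }
  meta <- tibble(
    sample_id = as.character(sample_id),
    role = role,
    spike_fraction = as.numeric(spike_fraction),
    centrifuged = as.logical(centrifuged),
    rcg_point = as.integer(rcg_point),
    patient_id = as.character(patient_id),
    fluid = as.character(fluid)
  )
  validate_sample_meta(meta)
}

validate_sample_meta <- function(meta) {
  assert_cols(meta, c("sample_id", "role"), "sample metadata")
  if (anyDuplicated(meta$sample_id)) {
    abort("sample_id values must be unique in sample metadata.")
  }
  bad_spike <- meta$role == "spiked" & is.na(meta$spike_fraction)
  if (any(bad_spike)) {
    abort(sprintf(
      "spiked sample(s) without spike_fraction: %s",
      paste(meta$sample_id[bad_spike], collapse = ", ")
    ))
  }
  if (any(meta$spike_fraction < 0 | meta$spike_fraction > 1, na.rm = TRUE)) {
    abort("spike_fraction must lie in [0, 1].")
  }
  bad_rcg <- meta$role == "rcg_point" & is.na(meta$rcg_point)
  if (any(bad_rcg)) {
    abort(sprintf(
      "rcg_point sample(s) without rcg_point index: %s",
      paste(meta$sample_id[bad_rcg], collapse = ", ")
    ))
  }
  if ("fluid" %in% names(meta)) {
    ok <- is.na(meta$fluid) | meta$fluid %in% c("CSF", "plasma")
    if (!all(ok)) abort("fluid must be \"CSF\" or \"plasma\" (or NA).")
  }
  meta
}

# Internal: validate a long abundance tibble (the in-memory AbundanceMatrix).
validate_abundance <- function(df, what = "abundance table") {
  assert_cols(df, c("accession", "sample_id", "abundance"), what)
  if (any(df$abundance < 0, na.rm = TRUE)) {
    abort(sprintf("%s contains negative abundances.", what))
  }
  key <- paste(df$accession, df$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df$accession[duplicated(key)][1]
    abort(sprintf("duplicate (accession, sample) rows in %s: %s", what, dup))
  }
  invisible(df)
}

#' Read a protein report into a tidy abundance table
#'
#' Reads a wide protein report (TSV/CSV, or XLSX via readxl) and returns a
#' long tibble with one row per (protein, sample), the sample-role metadata
#' joined on, and per-sample unique-peptide counts where the file carries
#' `n_unique_peptides_<sample_id>` columns. Cells that cannot be parsed as
#' numbers become explicit missing values; they are counted and reported in a
#' warning, never silently dropped.
#'
#' @param path Path to the report file (`.tsv`/`.txt`, `.csv`, or `.xlsx`).
#' @param meta Sample metadata from [sample_meta()]; every `sample_id` must be
#'   a column of the file.
#' @param dialect Column-name convention of the export:
#'   `"generic"` (accession column `accession`), `"progenesis"` / `"pd"`
#'   (`Accession`), or `"spectrummill"` (`accession_number`).
#' @param sheet For XLSX input, the sheet to read (default first).
#' @return A tibble with columns `accession`, `protein_name` (if present),
#'   `sample_id`, `abundance`, `n_peptides` (if present), plus the metadata
#'   columns of `meta`.
#' @export
read_protein_report <- function(path, meta,
                                dialect = c("generic", "progenesis",
                                            "spectrummill", "pd"),
                                sheet = NULL) {
  dialect <- arg_match(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  meta <- validate_sample_meta(meta)

  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("XLSX input requires the readxl package.")
    }
    readxl::read_excel(path, sheet = sheet %||% 1, col_types = "text")
  } else if (ext == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }

  acc_col <- csf_dialects[[dialect]]$accession
  if (!acc_col %in% names(raw)) {
    abort(sprintf(
      "missing accession column \"%s\" expected by the %s dialect.",
      acc_col, dialect
    ))
  }
  raw <- rename(raw, accession = dplyr::all_of(acc_col))
  name_col <- csf_dialects[[dialect]]$name
  if (name_col %in% names(raw) && name_col != "accession") {
    raw <- rename(raw, protein_name = dplyr::all_of(name_col))
  }

  dup <- unique(raw$accession[duplicated(raw$accession)])
  if (length(dup) > 0) {
    abort(sprintf(
      "duplicate accession row(s): %s", paste(utils::head(dup, 5), collapse = ", ")
    ))
  }

  absent <- setdiff(meta$sample_id, names(raw))
  if (length(absent) > 0) {
    abort(sprintf(
      "sample(s) declared in metadata but absent from file: %s",
      paste(absent, collapse = ", ")
    ))
  }

  id_cols <- intersect(c("accession", "protein_name"), names(raw))
  long <- tidyr::pivot_longer(
    raw[, c(id_cols, meta$sample_id)],
    cols = dplyr::all_of(meta$sample_id),
    names_to = "sample_id", values_to = ".raw"
  )
  parsed <- suppressWarnings(as.numeric(long$.raw))
  n_bad <- sum(!is.na(long$.raw) & long$.raw != "" & is.na(parsed))
  if (n_bad > 0) {
    warn(sprintf(
      "%d abundance cell(s) could not be parsed as numbers and were set to missing.",
      n_bad
    ))
  }
  long$abundance <- parsed
  long$.raw <- NULL

  # unique-peptide-count columns, generic convention
  pep_cols <- grep("^n_unique_peptides_", names(raw), value = TRUE)
  if (length(pep_cols) > 0) {
    peps <- tidyr::pivot_longer(
      raw[, c("accession", pep_cols)],
      cols = dplyr::all_of(pep_cols),
      names_to = "sample_id", values_to = "n_peptides",
      names_prefix = "n_unique_peptides_"
    )
    peps$n_peptides <- suppressWarnings(as.integer(peps$n_peptides))
    long <- left_join(long, peps, by = c("accession", "sample_id"))
  }

  out <- left_join(long, meta, by = "sample_id")
  validate_abundance(out)
  out
}

#' Write a tidy abundance table as a generic protein report
#'
#' Inverse of [read_protein_report()] for the generic dialect: tab-separated,
#' first column `accession`, one column per sample in first-appearance order,
#' missing values written as empty cells, `n_unique_peptides_<sample>` columns
#' appended when the table carries peptide counts.
#'
#' @param df Long abundance tibble with `accession`, `sample_id`, `abundance`
#'   (and optionally `n_peptides`) columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_report <- function(df, path) {
  validate_abundance(df)
  sample_order <- unique(df$sample_id)
  wide <- tidyr::pivot_wider(
    df[, c("accession", "sample_id", "abundance")],
    names_from = "sample_id", values_from = "abundance"
  )
  wide <- wide[, c("accession", sample_order), drop = FALSE]
  if ("n_peptides" %in% names(df)) {
    peps <- tidyr::pivot_wider(
      df[, c("accession", "sample_id", "n_peptides")],
      names_from = "sample_id", values_from = "n_peptides",
      names_prefix = "n_unique_peptides_"
    )
    wide <- left_join(wide, peps, by = "accession")
  }
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}
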