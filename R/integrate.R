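# Cross-experiment integration: accession-keyed outer join of all
# per-experiment results, plasma/CSF ratio bands, candidate cross-referencing
# and a cross-experiment consistency report.

#' Align per-experiment result tables into a combined overview
#'
#' Outer-joins any number of per-experiment result tables on the leading
#' protein accession. Columns other than `accession` are prefixed with the
#' experiment name (the list names), so e.g. the contamination category
#' becomes `contamination_category`. An optional accession-group mapping
#' re-keys member accessions to their leading accession before the join
#' (protein-grouping alignment); group members are recorded in a
#' `group_members` column, and any `shared_peptide` flag is OR-combined
#' across experiments. An accession that appears both as a leading accession
#' of one group and a member of another is a conflict and raises an error
#' naming the accessions involved.
#'
#' @param tables Named list of tibbles, each with an `accession` column.
#' @param groups Optional tibble with `leading` and `member` columns mapping
#'   member accessions to their group leader.
#' @return A tibble of class `"csf_overview"`, one row per leading accession;
#'   the column-to-experiment provenance map is attached as the
#'   `"provenance"` attribute.
#' @export
align_accessions <- function(tables, groups = NULL) {
  if (!is.list(tables) || length(tables) == 0 || is.null(names(tables)) ||
      any(names(tables) == "")) {
    abort("`tables` must be a non-empty named list of result tibbles.")
  }
  purrr::walk(tables, assert_cols, cols = "accession", what = "result table")

  relabel <- function(acc) acc
  group_note <- NULL
  if (!is.null(groups)) {
    assert_cols(groups, c("leading", "member"), "group mapping")
    # a leading accession listed as a member of a *different* group conflicts
    conflict <- groups$member[groups$member %in% groups$leading &
                                groups$member != groups$leading]
    if (length(conflict) > 0) {
      abort(sprintf(
        "accession(s) both leading and member of different groups: %s",
        paste(unique(conflict), collapse = ", ")
      ))
    }
    map <- setNames(groups$leading, groups$member)
    relabel <- function(acc) {
      hit <- acc %in% names(map)
      acc[hit] <- map[acc[hit]]
      acc
    }
    group_note <- groups %>%
      filter(.data$leading != .data$member) %>%
      group_by(accession = .data$leading) %>%
      summarise(group_members = paste(sort(unique(.data$member)), collapse = ";"),
                .groups = "drop")
  }

  shared_cols <- character()
  prefixed <- purrr::imap(tables, function(tbl, label) {
    tbl <- as_tibble(tbl)
    tbl$accession <- relabel(tbl$accession)
    if (anyDuplicated(tbl$accession)) {
      abort(sprintf(
        "experiment \"%s\" has duplicate rows per leading accession after grouping.",
        label
      ))
    }
    keep <- setdiff(names(tbl), "accession")
    # drop list-columns from the flat overview
    keep <- keep[!purrr::map_lgl(tbl[keep], is.list)]
    out <- tbl[, c("accession", keep), drop = FALSE]
    names(out)[-1] <- paste(label, keep, sep = "_")
    out
  })

  overview <- purrr::reduce(prefixed, full_join, by = "accession")
  sp_cols <- grep("_shared_peptide$", names(overview), value = TRUE)
  if (length(sp_cols) > 0) {
    overview$shared_peptide <- purrr::reduce(
      overview[sp_cols], function(a, b) (!is.na(a) & a) | (!is.na(b) & b)
    )
  }
  if (!is.null(group_note)) {
    overview <- left_join(overview, group_note, by = "accession")
  }
  provenance <- tibble(
    column = unlist(purrr::imap(
      prefixed, function(tbl, label) setdiff(names(tbl), "accession")
    ), use.names = FALSE),
    experiment = rep(names(prefixed),
                     vapply(prefixed, function(tbl) ncol(tbl) - 1L, 1L))
  )
  attr(overview, "provenance") <- provenance
  class(overview) <- c("csf_overview", class(overview))
  overview
}

#' Band a plasma/CSF ratio
#'
#' Assigns equal-protein plasma/CSF mean ratios to interpretation bands:
#' above 0.4 the protein behaves like a plasma-dominant protein (`"high"`),
#' below 0.2 like a CNS-dominant one (`"low"`), between the two `"mid"`;
#' missing ratios give `"none"`. Exact 0.2 and 0.4 fall in `"mid"`.
#'
#' @param mean_ratio Numeric vector of non-negative ratios (NA allowed).
#' @param low,high Band boundaries (defaults 0.2, 0.4).
#' @return A factor with levels `high`, `mid`, `low`, `none`.
#' @export
annotate_ratio_band <- function(mean_ratio, low = 0.2, high = 0.4) {
  if (any(mean_ratio < 0, na.rm = TRUE)) {
    abort("plasma/CSF ratios must be >= 0.")
  }
  band <- dplyr::case_when(
    is.na(mean_ratio) ~ "none",
    mean_ratio > high ~ "high",
    mean_ratio < low ~ "low",
    TRUE ~ "mid"
  )
  factor(band, levels = c("high", "mid", "low", "none"))
}

#' Cross-reference a candidate list against the combined overview
#'
#' Counts how many externally supplied candidate proteins (e.g. a biomarker
#' candidate list) fall in each contamination category of the overview, plus
#' the number of candidates not present in the overview at all.
#'
#' @param candidates Character vector of accessions (non-empty).
#' @param overview A [align_accessions()] result.
#' @param category_col Category column to tabulate (default
#'   `"contamination_category"`).
#' @return A tibble `category`, `n` (including an `"unmatched"` row).
#' @export
cross_reference <- function(candidates, overview,
                            category_col = "contamination_category") {
  if (length(candidates) == 0) abort("the candidate list is empty.")
  assert_cols(overview, c("accession", category_col), "overview")
  matched <- overview %>%
    filter(.data$accession %in% candidates)
  counts <- count_categories(matched, category_col)
  bind_rows(
    counts,
    tibble(category = "unmatched",
           n = length(setdiff(candidates, overview$accession)))
  )
}

#' Cross-experiment consistency report
#'
#' Summarises how well the independent experiments agree on which proteins
#' plasma shapes: contingency tables of contamination category against
#' plasma/CSF ratio band and against gradient category, the fraction of
#' high-band proteins called contamination-affected, and the fraction of
#' proteins on which the contamination and gradient calls agree exactly.
#' Requires at least two populated experiment blocks.
#'
#' @param overview A [align_accessions()] result containing at least two of:
#'   a `contamination_category`, an `rcg_category`, and a
#'   `plasma_csf_mean_ratio` column.
#' @return An object of class `"csf_consistency"` with elements `tables`
#'   (named list of contingency tables) and `stats` (tibble of agreement
#'   fractions); [tidy()] returns `stats`.
#' @export
consistency_report <- function(overview) {
  if (nrow(overview) == 0) abort("the overview is empty.")
  have_contam <- "contamination_category" %in% names(overview)
  have_rcg <- "rcg_category" %in% names(overview)
  have_ratio <- "plasma_csf_mean_ratio" %in% names(overview)
  if (sum(have_contam, have_rcg, have_ratio) < 2) {
    abort("need results from at least two experiments to assess consistency.")
  }
  tables <- list()
  stats <- tibble(statistic = character(), value = numeric(), n = integer())
  if (have_contam && have_ratio) {
    band <- annotate_ratio_band(overview$plasma_csf_mean_ratio)
    contam <- as.character(overview$contamination_category)
    tables$contamination_by_band <- table(contamination = contam, band = band)
    hi <- !is.na(contam) & band == "high" & contam != "not_evaluable"
    stats <- bind_rows(stats, tibble(
      statistic = "high_band_affected_fraction",
      value = if (sum(hi) > 0) mean(contam[hi] == "affected") else NA_real_,
      n = sum(hi)
    ))
  }
  if (have_contam && have_rcg) {
    contam <- as.character(overview$contamination_category)
    rcg <- as.character(overview$rcg_category)
    ok <- !is.na(contam) & !is.na(rcg) &
      contam != "not_evaluable" & rcg != "not_evaluable"
    tables$contamination_by_rcg <- table(
      contamination = contam[ok], rcg = rcg[ok]
    )
    stats <- bind_rows(stats, tibble(
      statistic = "contamination_rcg_agreement",
      value = if (sum(ok) > 0) mean(contam[ok] == rcg[ok]) else NA_real_,
      n = sum(ok)
    ))
  }
  structure(list(tables = tables, stats = stats), class = "csf_consistency")
}

#' @export
print.csf_consistency <- function(x, ...) {
  cat("Cross-experiment consistency report\n\n")
  for (label in names(x$tables)) {
    cat(label, ":\n", sep = "")
    print(x$tables[[label]])
    cat("\n")
  }
  print(x$stats)
  invisible(x)
}

#' @rdname consistency_report
#' @param x A `csf_consistency` object.
#' @param ... Unused.
#' @method tidy csf_consistency
#' @export
tidy.csf_consistency <- function(x, ...) {
  x$stats
}
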