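# Three-way categorisation of proteins (affected / uncertain / unaffected)
# for each pre-analytical factor, and the cross-experiment category merge.
#
# Boundary conventions (the printed inequalities leave exact ties open; these
# choices make every rule a total function and are applied consistently):
#   * contamination: fc exactly 1.5 -> affected; fc exactly 1.2 -> uncertain.
#   * gradient: r2 exactly 0.7 and exactly 0.3 fall in the middle 0.3-0.7
#     band; fc exactly 1.2 with a mid r2 -> unaffected; fc exactly 1.5 with
#     high r2 -> affected.
#   * centrifugation: fc exactly 1.5 -> uncertain (the rule is "> 1.5"),
#     fc exactly 1.2 -> uncertain.

csf_categories <- c("affected", "uncertain", "unaffected", "not_evaluable")

as_category <- function(x) {
  factor(x, levels = csf_categories)
}

#' Classify proteins by blood-contamination response
#'
#' Applies the spike-in rules to directional (spiked/reference) fold changes
#' at the low (0.5%) and high (2%) blood levels: an increase of at least
#' 1.5-fold at either level makes a protein affected; increases below
#' 1.2-fold at every available level make it unaffected; anything between is
#' uncertain. A protein halved or worse at the high spike is additionally
#' flagged as suppressed (ion-suppression/degradation signature), which is a
#' flag, not a category. Single-level designs are allowed: missing levels are
#' simply not consulted; proteins missing both are not evaluable.
#'
#' @param df Tibble with directional fold-change columns.
#' @param fc_low_col,fc_high_col Column names (defaults `"fc_low"`,
#'   `"fc_high"`).
#' @param fc_affected,fc_unaffected Category thresholds (defaults 1.5, 1.2).
#' @param suppression_fold Decrease factor flagging suppression (default 2,
#'   i.e. directional fold change at the high spike <= 0.5).
#' @return The input with `category` (factor) and `suppressed` (logical)
#'   columns added, plus `experiment = "blood_spike"`.
#' @export
classify_contamination <- function(df, fc_low_col = "fc_low",
                                   fc_high_col = "fc_high",
                                   fc_affected = 1.5, fc_unaffected = 1.2,
                                   suppression_fold = 2) {
  assert_cols(df, c(fc_low_col, fc_high_col), "fold-change table")
  lo <- df[[fc_low_col]]
  hi <- df[[fc_high_col]]
  any_ge <- function(threshold) {
    (!is.na(lo) & lo >= threshold) | (!is.na(hi) & hi >= threshold)
  }
  all_lt <- function(threshold) {
    (is.na(lo) | lo < threshold) & (is.na(hi) | hi < threshold)
  }
  category <- dplyr::case_when(
    is.na(lo) & is.na(hi) ~ "not_evaluable",
    any_ge(fc_affected) ~ "affected",
    all_lt(fc_unaffected) ~ "unaffected",
    TRUE ~ "uncertain"
  )
  df %>% mutate(
    category = as_category(category),
    suppressed = !is.na(hi) & hi <= 1 / suppression_fold,
    experiment = "blood_spike"
  )
}

#' Classify proteins by rostro-caudal gradient response
#'
#' Combines the symmetric end-to-end fold change with the linearity of the
#' per-protein fit: sufficient linearity (R-squared above 0.7) with at least
#' a 1.5-fold change makes a protein affected by the gradient; sufficient
#' linearity with a smaller change, or intermediate linearity (0.3-0.7) with
#' more than a 1.2-fold change, is uncertain; everything else — including any
#' protein with R-squared below 0.3, whatever its fold change — is
#' unaffected.
#'
#' @param df Tibble with fold-change and R-squared columns, e.g. a
#'   [fit_gradient()] result.
#' @param fc_col,r2_col Column names (defaults `"fc_1_7"`, `"r_squared"`).
#' @param fc_affected,fc_unaffected,r2_high,r2_low Thresholds (defaults 1.5,
#'   1.2, 0.7, 0.3).
#' @return The input with `category` and `experiment = "rcg"` columns added.
#' @export
classify_rcg <- function(df, fc_col = "fc_1_7", r2_col = "r_squared",
                         fc_affected = 1.5, fc_unaffected = 1.2,
                         r2_high = 0.7, r2_low = 0.3) {
  assert_cols(df, c(fc_col, r2_col), "gradient-fit table")
  fc <- df[[fc_col]]
  r2 <- df[[r2_col]]
  not_eval <- is.na(fc) | is.na(r2)
  if ("evaluable" %in% names(df)) not_eval <- not_eval | !df$evaluable
  category <- dplyr::case_when(
    not_eval ~ "not_evaluable",
    r2 > r2_high & fc >= fc_affected ~ "affected",
    r2 > r2_high ~ "uncertain",
    r2 >= r2_low & fc > fc_unaffected ~ "uncertain",
    r2 >= r2_low ~ "unaffected",
    TRUE ~ "unaffected"
  )
  df %>% mutate(category = as_category(category), experiment = "rcg")
}

#' Classify proteins by centrifugation response
#'
#' Compares a not-centrifuged against a centrifuged blood-contaminated
#' sample: proteins increased more than 1.5-fold in the not-centrifuged
#' sample are affected by (the omission of) centrifugation, below 1.2-fold
#' unaffected, between the two uncertain. Increases above 10-fold — the
#' signature of cell-associated proteins such as hemoglobin and carbonic
#' anhydrases — get a `strong` flag.
#'
#' @param df Tibble with a directional not-centrifuged/centrifuged
#'   fold-change column.
#' @param fc_col Column name (default `"fc"`).
#' @param fc_affected,fc_unaffected,fc_strong Thresholds (defaults 1.5, 1.2,
#'   10).
#' @return The input with `category`, `strong` and
#'   `experiment = "centrifugation"` columns added.
#' @export
classify_centrifugation <- function(df, fc_col = "fc", fc_affected = 1.5,
                                    fc_unaffected = 1.2, fc_strong = 10) {
  assert_cols(df, fc_col, "fold-change table")
  fc <- df[[fc_col]]
  category <- dplyr::case_when(
    is.na(fc) ~ "not_evaluable",
    fc > fc_affected ~ "affected",
    fc < fc_unaffected ~ "unaffected",
    TRUE ~ "uncertain"
  )
  df %>% mutate(
    category = as_category(category),
    strong = !is.na(fc) & fc > fc_strong,
    experiment = "centrifugation"
  )
}

#' Merge two categories from different experiments or platforms
#'
#' The cross-platform reconciliation rules: identical calls keep themselves;
#' affected + unaffected = uncertain; affected + uncertain = affected;
#' unaffected + uncertain = unaffected; a not-evaluable call acts as the
#' identity element (the single available category passes through). The
#' operation is commutative and idempotent. Vectorised, so it works inside
#' `mutate()`.
#'
#' @param a,b Character or factor vectors of categories.
#' @return A factor of merged categories.
#' @examples
#' merge_categories("affected", "unaffected") # uncertain
#' merge_categories("affected", "uncertain")  # affected
#' @export
merge_categories <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  a[is.na(a)] <- "not_evaluable"
  b[is.na(b)] <- "not_evaluable"
  bad <- setdiff(unique(c(a, b)), csf_categories)
  if (length(bad) > 0) {
    abort(sprintf("unknown category value(s): %s", paste(bad, collapse = ", ")))
  }
  out <- dplyr::case_when(
    a == b ~ a,
    a == "not_evaluable" ~ b,
    b == "not_evaluable" ~ a,
    (a == "affected" & b == "unaffected") |
      (a == "unaffected" & b == "affected") ~ "uncertain",
    (a == "affected" & b == "uncertain") |
      (a == "uncertain" & b == "affected") ~ "affected",
    (a == "unaffected" & b == "uncertain") |
      (a == "uncertain" & b == "unaffected") ~ "unaffected"
  )
  as_category(out)
}

#' Count proteins per category
#'
#' Tabulates a classification result into per-category counts. The three
#' evaluable categories partition the evaluable proteins; not-evaluable
#' proteins are counted separately.
#'
#' @param df Tibble with a `category` column (or a bare vector).
#' @param category_col Column name (default `"category"`).
#' @return A tibble `category`, `n` over all four categories (zero-filled),
#'   with `n_evaluable` and `n_total` attributes and columns in a one-row
#'   summary accessible via `attr(x, "totals")`.
#' @export
count_categories <- function(df, category_col = "category") {
  x <- if (is.data.frame(df)) {
    assert_cols(df, category_col, "classification result")
    df[[category_col]]
  } else {
    df
  }
  x <- as_category(as.character(x))
  tab <- table(x)
  out <- tibble(
    category = names(tab),
    n = as.integer(tab)
  )
  attr(out, "totals") <- tibble(
    n_evaluable = sum(out$n[out$category != "not_evaluable"]),
    n_total = sum(out$n)
  )
  out
}

#' Drop depletion-list proteins before classification
#'
#' Removes proteins on the immunodepletion list from a depleted-workflow
#' table: their residual quantitative data do not reflect the sample and are
#' omitted from conclusions.
#'
#' @param df Tibble with an `accession` and/or `protein_name` column.
#' @param depletion_list Character vector of names/accessions to drop
#'   (default [mars14_proteins]).
#' @return The filtered tibble; removed rows attached as the `"excluded"`
#'   attribute.
#' @export
drop_depleted <- function(df, depletion_list = mars14_proteins) {
  cols <- intersect(c("accession", "protein_name"), names(df))
  if (length(cols) == 0) {
    abort("need an `accession` or `protein_name` column to match the depletion list.")
  }
  hit <- Reduce(`|`, lapply(cols, function(cc) df[[cc]] %in% depletion_list))
  out <- df[!hit, , drop = FALSE]
  attr(out, "excluded") <- df[hit, , drop = FALSE]
  out
}
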