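# Reference-ratio quantification, fold changes, gradient linearity, MRM
# transition selection and peptide-to-protein rollup.

#' Ratios of every sample (or condition) to a reference
#'
#' Divides each protein's abundance in every sample by its abundance in the
#' designated reference, after averaging duplicate channels of the same
#' condition (arithmetic mean on the linear scale). Ratios are missing where
#' either operand is missing or the reference abundance is zero; missingness
#' propagates, it is never imputed.
#'
#' @param df Long abundance tibble (`accession`, `sample_id`, `abundance`).
#' @param reference_id Condition label of the reference (a `sample_id`, or a
#'   value of `average_by` when averaging).
#' @param average_by Optional column name identifying the condition that
#'   duplicate channels share (e.g. `"rcg_point"`); `NULL` treats every
#'   `sample_id` as its own condition. Rows with a missing condition value
#'   other than the reference are dropped.
#' @return A tibble `accession`, `sample_id` (the condition label),
#'   `ratio`; the reference-to-itself row is present with ratio 1.
#' @export
ratio_to_reference <- function(df, reference_id, average_by = NULL) {
  validate_abundance(df)
  if (!is.null(average_by)) {
    assert_cols(df, average_by, "abundance table")
    cond <- as.character(df[[average_by]])
    # the reference channel itself typically has no condition value
    if ("role" %in% names(df)) {
      cond[is.na(cond) & df$role == "reference"] <- reference_id
    }
    df$.condition <- cond
    df <- filter(df, !is.na(.data$.condition))
  } else {
    df$.condition <- df$sample_id
  }
  if (!reference_id %in% df$.condition) {
    abort(sprintf("reference \"%s\" not found among samples/conditions.", reference_id))
  }

  averaged <- df %>%
    group_by(.data$accession, .data$.condition) %>%
    summarise(abundance = mean(.data$abundance), .groups = "drop")

  ref <- averaged %>%
    filter(.data$.condition == reference_id) %>%
    select("accession", ref_abundance = "abundance")
  if (all(is.na(ref$ref_abundance))) {
    abort("reference sample is entirely missing; cannot form ratios.")
  }

  averaged %>%
    left_join(ref, by = "accession") %>%
    mutate(ratio = if_else(
      is.na(.data$abundance) | is.na(.data$ref_abundance) |
        .data$ref_abundance == 0,
      NA_real_,
      .data$abundance / .data$ref_abundance
    )) %>%
    select("accession", sample_id = ".condition", "ratio")
}

#' Fold change between two abundances or ratios
#'
#' The magnitude of change between two positive quantities. With
#' `symmetric = TRUE` (the default used for classification) the result is
#' `max(a/b, b/a)`, so a halving and a doubling both give 2 and the direction
#' is carried separately; with `symmetric = FALSE` the plain ratio `a/b` is
#' returned. Non-positive or missing inputs give a missing result with a
#' warning.
#'
#' @param a,b Numeric vectors (recycled).
#' @param symmetric Return the symmetric magnitude (default `TRUE`)?
#' @return Numeric vector of fold changes.
#' @examples
#' fold_change(0.675, 0.414) # 1.63: the lumbar/ventricular total-protein change
#' @export
fold_change <- function(a, b, symmetric = TRUE) {
  n <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  bad <- (!is.na(a) & a <= 0) | (!is.na(b) & b <= 0)
  if (any(bad)) {
    warn(sprintf("%d non-positive input(s) to fold_change; returning NA.", sum(bad)))
  }
  out <- a / b
  if (symmetric) out <- pmax(out, 1 / out)
  out[bad | is.na(a) | is.na(b)] <- NA_real_
  out
}

# Closed-form simple linear regression of y on x; returns slope, intercept,
# and R^2 with the convention that zero total variance (a constant series,
# which cannot exhibit a gradient) gives R^2 = 0.
ols_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n = n))
  }
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  ss_tot <- sum((y - ybar)^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r_squared = r2, n = n)
}

#' Per-protein linear fit of ratio against gradient point
#'
#' Ordinary least squares of the reference ratio against the integer
#' collection-point index, per protein: slope, intercept, coefficient of
#' determination, and the symmetric fold changes between the first and last
#' point (`fc_1_7`) and second and last point (`fc_2_7`, robust to
#' erythrocyte contamination of the first millilitres). Fold changes use the
#' observed point ratios by default; `use_fitted = TRUE` uses the fitted-line
#' endpoints instead. Proteins with fewer than 3 non-missing points are
#' marked not evaluable and excluded from downstream gradient classification.
#'
#' @param ratios Tibble with `accession`, a point column and a ratio column
#'   (e.g. from [ratio_to_reference()] with `average_by = "rcg_point"`).
#' @param point_col,ratio_col Column names (defaults `"sample_id"` parsed as
#'   integers if no `rcg_point` column exists, else `"rcg_point"`; and
#'   `"ratio"`).
#' @param use_fitted Use fitted-line endpoints for the fold changes?
#' @return A tibble of class `"csf_gradient_fits"`: `accession`, `slope`,
#'   `intercept`, `r_squared`, `fc_1_7`, `fc_2_7`, `direction` (+1 if the
#'   ratio increases toward the lumbar point 1), `n_points`, `evaluable`.
#' @export
fit_gradient <- function(ratios, point_col = NULL, ratio_col = "ratio",
                         use_fitted = FALSE) {
  if (is.null(point_col)) {
    point_col <- if ("rcg_point" %in% names(ratios)) "rcg_point" else "sample_id"
  }
  assert_cols(ratios, c("accession", point_col, ratio_col), "ratio table")
  pts <- suppressWarnings(as.integer(as.character(ratios[[point_col]])))
  if (all(is.na(pts))) abort(sprintf("column %s is not interpretable as point indices.", point_col))
  work <- tibble(
    accession = ratios$accession,
    point = pts,
    ratio = ratios[[ratio_col]]
  ) %>% filter(!is.na(.data$point))

  fits <- work %>%
    group_by(.data$accession) %>%
    summarise(
      .fit = list(ols_fit(.data$point, .data$ratio)),
      .first = .data$ratio[which.min(.data$point)][1],
      .second = {
        p <- sort(unique(.data$point[!is.na(.data$ratio)]))
        if (length(p) >= 2) .data$ratio[match(p[2], .data$point)] else NA_real_
      },
      .last = .data$ratio[which.max(.data$point)][1],
      .pmin = min(.data$point), .pmax = max(.data$point),
      .groups = "drop"
    )

  out <- fits %>%
    mutate(
      slope = purrr::map_dbl(.data$.fit, "slope"),
      intercept = purrr::map_dbl(.data$.fit, "intercept"),
      r_squared = purrr::map_dbl(.data$.fit, "r_squared"),
      n_points = purrr::map_int(.data$.fit, "n"),
      first = if (use_fitted) .data$intercept + .data$slope * .data$.pmin else .data$.first,
      second = .data$.second,
      last = if (use_fitted) .data$intercept + .data$slope * .data$.pmax else .data$.last,
      fc_1_7 = suppressWarnings(fold_change(.data$first, .data$last, symmetric = TRUE)),
      fc_2_7 = suppressWarnings(fold_change(.data$second, .data$last, symmetric = TRUE)),
      direction = sign(.data$first - .data$last),
      evaluable = .data$n_points >= 3
    ) %>%
    select("accession", "slope", "intercept", "r_squared", "fc_1_7", "fc_2_7",
           "direction", "n_points", "evaluable")
  n_dropped <- sum(!out$evaluable)
  if (n_dropped > 0) {
    inform(sprintf(
      "%d protein(s) with fewer than 3 non-missing points marked not evaluable.",
      n_dropped
    ))
  }
  class(out) <- c("csf_gradient_fits", class(out))
  out
}

#' Choose the quantifier transition and compute MRM peptide ratios
#'
#' For each peptide of a stable-isotope-dilution MRM run, the most intense
#' transition (by SIS peak area) that is free of interference becomes the
#' quantifier, and the peptide ratio is the endogenous over SIS peak area of
#' that transition. Peptides whose transitions are all flagged for
#' interference are excluded and reported.
#'
#' @param mrm Long tibble with columns `peptide`, `transition`,
#'   `endogenous_area`, `sis_area` and logical `interference`; an optional
#'   `accession` column is carried through. Peptides are expected to carry at
#'   least three monitored transitions (fewer draws a warning).
#' @return A tibble with one row per quantifiable peptide: `peptide`,
#'   `chosen_transition`, `endogenous_area`, `sis_area`, `ratio`,
#'   `n_transitions`; excluded peptides are attached as the
#'   `"excluded"` attribute and reported via a message.
#' @export
select_quantifier_transition <- function(mrm) {
  assert_cols(mrm, c("peptide", "transition", "endogenous_area", "sis_area",
                     "interference"), "MRM table")
  few <- mrm %>% count(.data$peptide) %>% filter(.data$n < 3)
  if (nrow(few) > 0) {
    warn(sprintf(
      "%d peptide(s) monitored with fewer than 3 transitions.", nrow(few)
    ))
  }
  keep_cols <- intersect(c("accession", "peptide"), names(mrm))
  chosen <- mrm %>%
    group_by(dplyr::across(dplyr::all_of(keep_cols))) %>%
    summarise(
      n_transitions = n(),
      .i = {
        ok <- which(!.data$interference)
        if (length(ok) == 0) NA_integer_ else ok[which.max(.data$sis_area[ok])]
      },
      chosen_transition = if (is.na(.i[1])) NA_character_
                          else as.character(.data$transition[.i[1]]),
      endogenous_area = if (is.na(.i[1])) NA_real_ else .data$endogenous_area[.i[1]],
      sis_area = if (is.na(.i[1])) NA_real_ else .data$sis_area[.i[1]],
      .groups = "drop"
    ) %>%
    select(-".i") %>%
    mutate(ratio = .data$endogenous_area / .data$sis_area)
  excluded <- filter(chosen, is.na(.data$chosen_transition))
  if (nrow(excluded) > 0) {
    inform(sprintf(
      "%d peptide(s) excluded: all transitions flagged for interference (%s).",
      nrow(excluded), paste(utils::head(excluded$peptide, 5), collapse = ", ")
    ))
  }
  out <- filter(chosen, !is.na(.data$chosen_transition))
  attr(out, "excluded") <- excluded
  out
}

#' Roll peptide ratios up to protein ratios
#'
#' The protein ratio is the median of its peptide ratios (robust to a single
#' interfered or mis-assigned peptide); the contributing peptide count is
#' recorded.
#'
#' @param peptides Tibble with `accession` and `ratio` columns (one row per
#'   peptide), e.g. from [select_quantifier_transition()].
#' @return A tibble `accession`, `ratio`, `n_peptides`.
#' @export
rollup_peptides <- function(peptides) {
  assert_cols(peptides, c("accession", "ratio"), "peptide table")
  peptides %>%
    filter(!is.na(.data$ratio)) %>%
    group_by(.data$accession) %>%
    summarise(
      n_peptides = n(),
      ratio = stats::median(.data$ratio),
      .groups = "drop"
    ) %>%
    select("accession", "ratio", "n_peptides")
}

#' Filter proteins by peptide support across contexts
#'
#' Retains proteins quantified with at least `min_unique_peptides` unique
#' peptides in at least `min_contexts` contexts (patients or samples),
#' mirroring the "two or more peptides in two or more patients" rule. The
#' removed proteins and the reason each failed are returned alongside the
#' retained data.
#'
#' @param df Long abundance tibble with an `n_peptides` column; the context
#'   is `patient_id` where present, else `sample_id`.
#' @param min_unique_peptides Minimum unique peptides per context (default 2).
#' @param min_contexts Minimum number of contexts meeting the peptide
#'   threshold (default 2).
#' @return A list with elements `data` (the filtered tibble) and `exclusions`
#'   (tibble `accession`, `n_qualifying_contexts`, `reason`).
#' @export
filter_quantifiable <- function(df, min_unique_peptides = 2, min_contexts = 2) {
  assert_cols(df, c("accession", "n_peptides"), "abundance table")
  context_col <- if ("patient_id" %in% names(df)) "patient_id" else "sample_id"
  support <- df %>%
    group_by(.data$accession, context = .data[[context_col]]) %>%
    summarise(
      ok = any(!is.na(.data$n_peptides) &
                 .data$n_peptides >= min_unique_peptides &
                 !is.na(.data$abundance)),
      .groups = "drop"
    ) %>%
    group_by(.data$accession) %>%
    summarise(n_qualifying_contexts = sum(.data$ok), .groups = "drop")
  keep <- support$accession[support$n_qualifying_contexts >= min_contexts]
  exclusions <- support %>%
    filter(!.data$accession %in% keep) %>%
    mutate(reason = sprintf(
      "only %d context(s) with >= %d unique peptides (need %d)",
      .data$n_qualifying_contexts, min_unique_peptides, min_contexts
    ))
  list(
    data = filter(df, .data$accession %in% keep),
    exclusions = exclusions
  )
}
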