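test_that("reference ratios: identity, simple division, duplicate-channel averaging", {
  df <- tibble::tibble(
    accession = rep(c("A", "B"), each = 4),
    sample_id = rep(c("ref", "s1", "d1", "d2"), 2),
    abundance = c(4, 8, 3, 5, 2, 1, 2, 2),
    rcg_point = rep(c(NA, 1L, 2L, 2L), 2),
    role = rep(c("reference", "rcg_point", "rcg_point", "rcg_point"), 2)
  )
  # per-sample ratios
  r <- ratio_to_reference(df, "ref")
  expect_equal(r$ratio[r$accession == "A" & r$sample_id == "ref"], 1)
  expect_equal(r$ratio[r$accession == "A" & r$sample_id == "s1"], 2)
  # duplicate channels 3 and 5 average to 4 -> ratio 1 (mean before ratio)
  ravg <- ratio_to_reference(df, "ref", average_by = "rcg_point")
  expect_equal(ravg$ratio[ravg$accession == "A" & ravg$sample_id == "2"], 1)

  # missingness and zero reference propagate to missing ratios
  df2 <- tibble::tibble(
    accession = c("A", "A", "B", "B"),
    sample_id = rep(c("ref", "s"), 2),
    abundance = c(4, NA, 0, 5)
  )
  r2 <- ratio_to_reference(df2, "ref")
  expect_true(is.na(r2$ratio[r2$accession == "A" & r2$sample_id == "s"]))
  expect_true(is.na(r2$ratio[r2$accession == "B" & r2$sample_id == "s"]))

  # entirely missing reference is an error
  df3 <- tibble::tibble(
    accession = c("A", "A"), sample_id = c("ref", "s"), abundance = c(NA, 1)
  )
  expect_error(ratio_to_reference(df3, "ref"), "entirely missing")
  expect_error(ratio_to_reference(df3, "nope"), "not found")
})

test_that("fold change: identity, symmetry, worked total-protein example", {
  expect_equal(fold_change(3, 3), 1)
  expect_equal(fold_change(2, 8), 4)
  expect_equal(fold_change(8, 2), 4)
  expect_equal(fold_change(2, 8, symmetric = FALSE), 0.25)
  # lumbar vs ventricular total protein concentration
  expect_equal(fold_change(0.675, 0.414), 1.63, tolerance = 5e-3)
  expect_warning(out <- fold_change(c(-1, 2), c(1, 0)), "non-positive")
  expect_true(all(is.na(out)))
})

test_that("gradient fit: worked examples and degenerate conventions", {
  # perfectly linear increasing series
  lin <- tibble::tibble(accession = "A", rcg_point = 1:7,
                        ratio = seq(1.0, 1.6, by = 0.1))
  fit <- fit_gradient(lin)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$fc_1_7, 1.6, tolerance = 1e-12)
  expect_equal(fit$direction, -1) # increases toward the ventricular end

  # decreasing series: slope -0.1 per point, symmetric fc still 1.6
  dec <- tibble::tibble(accession = "A", rcg_point = 1:7,
                        ratio = seq(1.6, 1.0, by = -0.1))
  fdec <- fit_gradient(dec)
  expect_equal(fdec$slope, -0.1, tolerance = 1e-12)
  expect_equal(fdec$fc_1_7, 1.6, tolerance = 1e-12)
  expect_equal(fdec$direction, 1)

  # constant ratios: zero total variance -> r_squared defined as 0
  const <- tibble::tibble(accession = "A", rcg_point = 1:7, ratio = 2)
  expect_equal(fit_gradient(const)$r_squared, 0)

  # fewer than 3 points -> not evaluable, counted
  short <- tibble::tibble(accession = c("A", "A", "B", "B", "B"),
                          rcg_point = c(1L, 7L, 1L, 4L, 7L),
                          ratio = c(1, 2, 1, 1.5, 2))
  expect_message(fshort <- fit_gradient(short), "not evaluable")
  expect_false(fshort$evaluable[fshort$accession == "A"])
  expect_true(fshort$evaluable[fshort$accession == "B"])

  # fitted-endpoint alternative for the fold change
  noisy <- tibble::tibble(accession = "A", rcg_point = 1:7,
                          ratio = c(1.62, 1.48, 1.41, 1.33, 1.18, 1.09, 1.0))
  obs <- fit_gradient(noisy)
  fitd <- fit_gradient(noisy, use_fitted = TRUE)
  expect_equal(obs$fc_1_7, 1.62)
  expect_false(isTRUE(all.equal(obs$fc_1_7, fitd$fc_1_7)))
})

test_that("closed-form OLS agrees with the lm oracle on random 7-point inputs", {
  withr::with_seed(42, {
    for (i in 1:200) {
      y <- exp(rnorm(7, 0, 0.5))
      fit <- fit_gradient(tibble::tibble(accession = "X", rcg_point = 1:7,
                                         ratio = y))
      oracle <- stats::lm(y ~ x, data = data.frame(x = 1:7, y = y))
      expect_equal(fit$slope, unname(stats::coef(oracle)[2]), tolerance = 1e-10)
      expect_equal(fit$r_squared, summary(oracle)$r.squared, tolerance = 1e-10)
    }
  })
})

test_that("noise-free simulated gradient recovers the catalog amplitude exactly", {
  catl <- tiny_catalog()
  rc <- simulate_rcg_series(catl, noise_cv = 0, seed = 4)
  fit <- ratio_to_reference(rc, "reference", average_by = "rcg_point") |>
    fit_gradient()
  joined <- dplyr::left_join(fit, catl, by = "accession")
  expect_equal(joined$fc_1_7, joined$gradient_amp, tolerance = 1e-9)
  sloped <- dplyr::filter(joined, gradient_amp > 1)
  expect_equal(sloped$r_squared, rep(1, nrow(sloped)), tolerance = 1e-9)
  flat <- dplyr::filter(joined, gradient_amp == 1)
  expect_equal(flat$r_squared, rep(0, nrow(flat)))
})

test_that("percent CV: worked value, degenerate cases, scale invariance", {
  expect_equal(percent_cv(c(2, 2, 2)), 0)
  expect_equal(percent_cv(c(1, 1, 1, 1, 2)), 100 * sd(c(1, 1, 1, 1, 2)) / 1.2)
  expect_equal(percent_cv(c(1, 1, 1, 1, 2)), 37.27, tolerance = 1e-3)
  expect_true(is.na(percent_cv(3)))
  withr::with_seed(1, {
    x <- runif(20, 1, 5)
    expect_equal(percent_cv(7.3 * x), percent_cv(x), tolerance = 1e-12)
  })
})

test_that("quantifier transition: most intense interference-free SIS wins", {
  mrm <- tibble::tibble(
    peptide = rep(c("PEP1", "PEP2", "PEP3"), each = 3),
    transition = rep(c("y4", "y5", "y6"), 3),
    endogenous_area = c(80, 150, 40, 90, 210, 60, 10, 20, 30),
    sis_area = c(100, 200, 50, 100, 200, 50, 100, 200, 50),
    interference = c(FALSE, FALSE, FALSE,  # PEP1: top transition clean
                     FALSE, TRUE, FALSE,   # PEP2: top transition flagged
                     TRUE, TRUE, TRUE)     # PEP3: nothing usable
  )
  expect_message(out <- select_quantifier_transition(mrm), "excluded")
  expect_equal(out$chosen_transition[out$peptide == "PEP1"], "y5")
  expect_equal(out$ratio[out$peptide == "PEP1"], 150 / 200)
  # next-most-intense clean transition
  expect_equal(out$chosen_transition[out$peptide == "PEP2"], "y4")
  expect_equal(out$ratio[out$peptide == "PEP2"], 90 / 100)
  expect_false("PEP3" %in% out$peptide)
  expect_equal(attr(out, "excluded")$peptide, "PEP3")

  expect_warning(
    select_quantifier_transition(tibble::tibble(
      peptide = "P", transition = c("a", "b"),
      endogenous_area = c(150, 1), sis_area = c(100, 1),
      interference = FALSE
    )),
    "fewer than 3"
  )
})

test_that("peptide rollup is the median with the peptide count recorded", {
  peps <- tibble::tibble(
    accession = c("A", "B", "B", "B", "C", "C"),
    ratio = c(2.0, 1.0, 1.2, 5.0, 1.0, 1.4)
  )
  out <- rollup_peptides(peps)
  expect_equal(out$ratio[out$accession == "A"], 2.0)   # single peptide
  expect_equal(out$ratio[out$accession == "B"], 1.2)   # robust to the outlier
  expect_equal(out$ratio[out$accession == "C"], 1.2)   # even-count median
  expect_equal(out$n_peptides, c(1L, 3L, 2L))
})

test_that("quantifiability filter applies both thresholds and reports exclusions", {
  df <- tidyr::expand_grid(
    accession = c("keep", "few_peps", "few_pats"),
    patient_id = sprintf("P%d", 1:5)
  )
  df$sample_id <- paste(df$accession, df$patient_id)
  df$abundance <- 1
  df$n_peptides <- dplyr::case_when(
    df$accession == "keep" ~ ifelse(df$patient_id %in% c("P1", "P2"), 2L, 1L),
    df$accession == "few_peps" ~ 1L,
    TRUE ~ ifelse(df$patient_id == "P1", 5L, 1L)
  )
  out <- filter_quantifiable(df, 2, 2)
  expect_equal(unique(out$data$accession), "keep")
  expect_setequal(out$exclusions$accession, c("few_peps", "few_pats"))
  expect_match(out$exclusions$reason, "context", all = TRUE)
  # zero thresholds are the identity filter
  all_kept <- filter_quantifiable(df, 0, 0)
  expect_equal(nrow(all_kept$data), nrow(df))
  expect_equal(nrow(all_kept$exclusions), 0)
})
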