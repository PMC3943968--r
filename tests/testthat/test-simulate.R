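test_that("catalog and simulators are bit-reproducible given the same seed", {
  spec <- sim_spec(n_cns = 30, n_plasma_liver = 30, seed = 5)
  expect_identical(generate_catalog(spec), generate_catalog(spec))
  catl <- generate_catalog(spec)
  expect_identical(
    simulate_blood_spike(catl, noise_cv = 0.2, seed = 9),
    simulate_blood_spike(catl, noise_cv = 0.2, seed = 9)
  )
  expect_identical(
    simulate_rcg_series(catl, noise_cv = 0.2, seed = 9),
    simulate_rcg_series(catl, noise_cv = 0.2, seed = 9)
  )
  expect_identical(
    simulate_plasma_csf_pairs(catl, noise_cv = 0.2, seed = 9),
    simulate_plasma_csf_pairs(catl, noise_cv = 0.2, seed = 9)
  )
  # and different seeds differ
  expect_false(identical(
    simulate_blood_spike(catl, noise_cv = 0.2, seed = 9),
    simulate_blood_spike(catl, noise_cv = 0.2, seed = 10)
  ))
})

test_that("catalog respects origin-class invariants and the albumin sentinel", {
  catl <- tiny_catalog()
  cns <- dplyr::filter(catl, origin == "cns")
  expect_true(all(cns$gradient_amp == 1))
  expect_true(all(cns$cell_assoc_frac == 0))
  expect_true(all(cns$r_volume <= 5))
  blood <- dplyr::filter(catl, origin == "blood_cellular")
  expect_true(all(blood$cell_assoc_frac >= 0.9))
  plasma <- dplyr::filter(catl, origin == "plasma_liver")
  expect_true(all(plasma$r_volume >= 50))
  expect_true(all(catl$gradient_amp >= 1))

  alb <- dplyr::filter(catl, accession == "ALB_SYN")
  expect_equal(alb$r_volume, 177)
  expect_true(alb$depleted)

  cns_only <- generate_catalog(sim_spec(
    n_cns = 10, n_leptomeningeal = 0, n_plasma_liver = 0,
    n_blood_cellular = 0, n_mixed = 0, seed = 3
  ))
  expect_true(all(dplyr::filter(cns_only, origin == "cns")$gradient_amp == 1))
  expect_error(generate_catalog(sim_spec(
    n_cns = 0, n_leptomeningeal = 0, n_plasma_liver = 0,
    n_blood_cellular = 0, n_mixed = 0, seed = 1
  )), "at least one protein")
})

test_that("noise-free spike-in equals the closed-form forward model exactly", {
  catl <- tiny_catalog()
  fc <- spike_fold_changes(catl, noise_cv = 0, seed = 1)
  # independent arithmetic, not predict_spike_fc(): fc = (1-f) + f * r for
  # proteins without a cellular component
  plain <- dplyr::filter(fc, cell_assoc_frac == 0)
  expect_equal(plain$fc_high, 0.98 + 0.02 * plain$r_volume, tolerance = 1e-12)
  expect_equal(plain$fc_low, 0.995 + 0.005 * plain$r_volume, tolerance = 1e-12)
  # albumin-like sentinel: the canonical 4.52-fold increase at 2% blood
  expect_equal(fc$fc_high[fc$accession == "ALB_SYN"], 4.52, tolerance = 1e-12)

  # f = 0 reproduces the clean concentration
  sp0 <- simulate_blood_spike(catl, fractions = numeric(0), noise_cv = 0, seed = 1)
  expect_equal(sp0$abundance, catl$c_csf, tolerance = 1e-12)

  expect_error(simulate_blood_spike(catl, fractions = -0.01, seed = 1), ">= 0")
  expect_error(simulate_blood_spike(catl, fractions = 0.5, seed = 1), "10%")
})

test_that("centrifugation strips most of the cellular payload only", {
  catl <- tiny_catalog()
  not_cfg <- simulate_blood_spike(catl, fractions = 0.005, centrifuged = FALSE,
                                  noise_cv = 0, seed = 1)
  cfg <- simulate_blood_spike(catl, fractions = 0.005, centrifuged = TRUE,
                              noise_cv = 0, seed = 1)
  spiked <- function(x) dplyr::filter(x, role == "spiked")
  ratio <- spiked(not_cfg)$abundance / spiked(cfg)$abundance
  blood <- catl$cell_assoc_frac >= 0.9
  expect_true(all(ratio[blood] > 5))           # cell-associated: large removal
  expect_equal(ratio[catl$cell_assoc_frac == 0], # plasma-phase: untouched
               rep(1, sum(catl$cell_assoc_frac == 0)), tolerance = 1e-12)
})

test_that("noise-free gradient series is linear with the catalog amplitude", {
  catl <- tiny_catalog()
  rc <- simulate_rcg_series(catl, noise_cv = 0, seed = 2)
  wide <- tidyr::pivot_wider(
    dplyr::filter(rc, role == "rcg_point"),
    id_cols = "accession", names_from = "sample_id", values_from = "abundance"
  )
  wide <- dplyr::left_join(wide, catl, by = "accession")
  # flat proteins identical at all points
  flat <- dplyr::filter(wide, gradient_amp == 1)
  expect_equal(flat$rcg1_a, flat$rcg7_a, tolerance = 1e-12)
  # end-to-end ratio equals the amplitude; duplicates agree noise-free
  expect_equal(wide$rcg1_a / wide$rcg7_a, wide$gradient_amp, tolerance = 1e-12)
  expect_equal(wide$rcg1_a, wide$rcg1_b, tolerance = 1e-12)
  expect_equal(wide$rcg7_a, wide$rcg7_b, tolerance = 1e-12)
  # reference channel is the mean of the 7 noise-free point values
  pts <- as.matrix(wide[, sprintf("rcg%d_a", 1:7)])
  ref <- dplyr::filter(rc, role == "reference")
  expect_equal(ref$abundance[match(wide$accession, ref$accession)],
               rowMeans(pts), tolerance = 1e-12)

  expect_error(simulate_rcg_series(catl, n_points = 2, seed = 1), ">= 3")
})

test_that("point-1 erythrocyte spike raises cell-associated proteins at point 1 only", {
  catl <- tiny_catalog()
  clean <- simulate_rcg_series(catl, noise_cv = 0, seed = 2)
  spiked <- simulate_rcg_series(catl, noise_cv = 0, seed = 2,
                                hb_point1_fraction = 0.01)
  joined <- dplyr::inner_join(
    clean, spiked, by = c("accession", "sample_id"),
    suffix = c("_clean", "_hb")
  )
  blood_acc <- catl$accession[catl$cell_assoc_frac >= 0.9]
  p1 <- dplyr::filter(joined, sample_id == "rcg1_a", accession %in% blood_acc)
  p7 <- dplyr::filter(joined, sample_id == "rcg7_a", accession %in% blood_acc)
  expect_true(all(p1$abundance_hb > p1$abundance_clean))
  expect_equal(p7$abundance_hb, p7$abundance_clean, tolerance = 1e-12)
})

test_that("paired plasma/CSF simulation honours the rescaling algebra", {
  catl <- tiny_catalog()
  pc <- simulate_plasma_csf_pairs(catl, noise_cv = 0, seed = 3,
                                  patient_sigma = 0)
  # equal-volume ratio is r_volume exactly (no noise, no patient effect)
  rv <- plasma_csf_ratio(pc, basis = "equal_volume")
  expect_equal(rv$mean_ratio[match(catl$accession, rv$accession)],
               catl$r_volume, tolerance = 1e-12)
  # equal-protein basis: a protein whose r_volume equals the total-protein
  # concentration ratio has ratio ~ 1
  ev <- dplyr::filter(pc, basis == "equal_volume", patient_id == "P1")
  tot <- sum(ev$abundance[ev$fluid == "plasma"]) /
    sum(ev$abundance[ev$fluid == "CSF"])
  rp <- plasma_csf_ratio(pc, basis = "equal_protein")
  joined <- dplyr::left_join(rp, catl, by = "accession")
  expect_equal(joined$mean_ratio, joined$r_volume / tot, tolerance = 1e-12)
})

test_that("technical noise is calibrated: empirical CV matches the nominal 20%", {
  big <- generate_catalog(sim_spec(
    n_cns = 1000, n_leptomeningeal = 0, n_plasma_liver = 0,
    n_blood_cellular = 0, n_mixed = 0, seed = 17
  ))
  cvs <- vapply(1:5, function(s) {
    sim <- simulate_blood_spike(big, fractions = numeric(0), noise_cv = 0.2,
                                seed = s)
    factors <- sim$abundance / big$c_csf
    stats::sd(factors) / mean(factors)
  }, numeric(1))
  expect_true(all(cvs >= 0.18 & cvs <= 0.22))
})
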