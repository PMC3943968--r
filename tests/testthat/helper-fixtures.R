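# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from outside the package.

# A small catalog covering every origin class, deterministic.
tiny_catalog <- function(seed = 101, ...) {
  generate_catalog(sim_spec(
    n_cns = 20, n_leptomeningeal = 5, n_plasma_liver = 15,
    n_blood_cellular = 5, n_mixed = 5, seed = seed, ...
  ))
}

# Write a generic protein report TSV for the given wide tibble; returns path.
write_report_file <- function(wide, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(wide, path, na = "")
  path
}

# Wide fold-change table from a simulated spike experiment (noise optional).
spike_fold_changes <- function(catalog, noise_cv = 0, seed = 1) {
  sp <- simulate_blood_spike(catalog, noise_cv = noise_cv, seed = seed)
  ratio_to_reference(sp, "reference") |>
    tidyr::pivot_wider(names_from = sample_id, values_from = ratio) |>
    dplyr::rename(fc_low = "spike_0.5", fc_high = "spike_2") |>
    dplyr::left_join(
      dplyr::select(catalog, "accession", "origin", "r_volume",
                    "cell_assoc_frac"),
      by = "accession"
    )
}

# Synthetic supplement-style ratio table with a known category composition
# (counts chosen at build time, independent of the classifier under test):
# n_affected proteins get a high-spike ratio >= 1.5, n_unaffected get both
# ratios < 1.2, n_uncertain get a maximum ratio in [1.2, 1.5).
synthetic_supplement <- function(n_affected = 26, n_unaffected = 40,
                                 n_uncertain = 15, n_suppressed = 5,
                                 seed = 11) {
  withr::with_seed(seed, {
    tibble::tibble(
      accession = sprintf("SUP_%03d", seq_len(n_affected + n_unaffected +
                                                n_uncertain + n_suppressed)),
      fc_low = c(
        runif(n_affected, 0.9, 1.4),
        runif(n_unaffected, 0.85, 1.19),
        runif(n_uncertain, 1.0, 1.19),
        runif(n_suppressed, 0.8, 1.1)
      ),
      fc_high = c(
        runif(n_affected, 1.5, 60),
        runif(n_unaffected, 0.85, 1.19),
        runif(n_uncertain, 1.2, 1.499),
        runif(n_suppressed, 0.1, 0.5)
      ),
      truth = rep(
        c("affected", "unaffected", "uncertain", "unaffected"),
        c(n_affected, n_unaffected, n_uncertain, n_suppressed)
      )
    )
  })
}
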