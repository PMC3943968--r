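# Ground-truthed synthetic data: a protein catalog with known origins,
# plasma/CSF ratios and gradient amplitudes, plus generators for the four
# study designs (blood spike-in +/- centrifugation, seven-point rostro-caudal
# gradient with a pooled reference channel, paired plasma/CSF patients).
#
# The forward model for a CSF sample contaminated with whole-blood volume
# fraction f is, per protein:
#
#   E[abundance] = (1 - f) * c_csf
#                + f * [ (1 - caf) * r_volume * c_csf          (plasma phase)
#                      + caf * payload_ratio * c_csf * keep ]  (cellular phase)
#
# where caf is the cell-associated fraction, payload_ratio the cellular
# enrichment relative to the CSF concentration, and keep = 1 - removal for a
# centrifuged sample (centrifugation strips most of the cellular payload but
# none of the plasma phase). Technical noise is multiplicative log-normal at a
# stated %CV, mean-preserving.

#' Simulation settings for the synthetic study designs
#'
#' @param n_cns,n_leptomeningeal,n_plasma_liver,n_blood_cellular,n_mixed
#'   Protein counts per origin class. The defaults give a 500-protein study:
#'   brain-derived (flat gradient, negligible plasma ratio), leptomeningeal,
#'   liver-secreted plasma proteins (high plasma/CSF ratio, 1.6-fold
#'   gradient), blood-cell-associated proteins (cellular payload removed by
#'   centrifugation), and mixed-origin proteins.
#' @param noise_cv Technical coefficient of variation of the multiplicative
#'   log-normal noise (default 0.20).
#' @param seed Integer seed; mandatory, recorded in the outputs.
#' @param gradient_amp_plasma End-to-end (lumbar/ventricular) fold change of
#'   plasma-derived proteins along the gradient (default 1.6).
#' @param spike_fractions Whole-blood volume fractions for the contamination
#'   design (default 0.5% and 2%).
#' @param centrifugation_removal Fraction of the cell-associated payload
#'   removed by centrifugation before freezing (default 0.95).
#' @param n_rcg_points Number of gradient collection points (default 7;
#'   point 1 is lumbar-most).
#' @param n_patients Number of paired plasma/CSF patients (default 5).
#' @param patient_sigma Log-scale SD of per-patient biological variation in
#'   the paired-fluid design (default 0.3, giving between-patient %CV of
#'   roughly 30%).
#' @param hb_point1_fraction Optional whole-blood volume fraction added to
#'   gradient point 1 only, emulating puncture erythrocytes contaminating the
#'   first millilitres (default 0 = off).
#' @return A validated list of class `"sim_spec"`.
#' @export
sim_spec <- function(n_cns = 200, n_leptomeningeal = 50, n_plasma_liver = 150,
                     n_blood_cellular = 50, n_mixed = 50,
                     noise_cv = 0.20, seed = NULL,
                     gradient_amp_plasma = 1.6,
                     spike_fractions = c(0.005, 0.02),
                     centrifugation_removal = 0.95,
                     n_rcg_points = 7, n_patients = 5,
                     patient_sigma = 0.3,
                     hb_point1_fraction = 0) {
  spec <- list(
    n_per_class = c(
      cns = n_cns, leptomeningeal = n_leptomeningeal,
      plasma_liver = n_plasma_liver, blood_cellular = n_blood_cellular,
      mixed = n_mixed
    ),
    noise_cv = noise_cv, seed = seed,
    gradient_amp_plasma = gradient_amp_plasma,
    spike_fractions = spike_fractions,
    centrifugation_removal = centrifugation_removal,
    n_rcg_points = n_rcg_points, n_patients = n_patients,
    patient_sigma = patient_sigma,
    hb_point1_fraction = hb_point1_fraction
  )
  if (any(spec$n_per_class < 0)) abort("protein counts must be >= 0.")
  if (sum(spec$n_per_class) == 0) abort("the catalog must contain at least one protein.")
  if (noise_cv < 0) abort("noise_cv must be >= 0.")
  if (any(spike_fractions < 0 | spike_fractions > 0.1)) {
    abort("spike_fractions must lie in [0, 0.1].")
  }
  if (centrifugation_removal < 0 || centrifugation_removal > 1) {
    abort("centrifugation_removal must lie in [0, 1].")
  }
  if (gradient_amp_plasma < 1) abort("gradient_amp_plasma must be >= 1.")
  if (n_rcg_points < 3) abort("n_rcg_points must be >= 3.")
  if (n_patients < 2) abort("n_patients must be >= 2.")
  if (hb_point1_fraction < 0) abort("hb_point1_fraction must be >= 0.")
  structure(spec, class = "sim_spec")
}

#' Generate a ground-truth protein catalog
#'
#' Draws a per-protein ground truth for simulation: true CSF concentration,
#' equal-volume plasma/CSF concentration ratio (`r_volume`), cell-associated
#' fraction and cellular enrichment (`payload_ratio`), gradient amplitude,
#' and membership of the 14-protein depletion list. Ratios are drawn
#' log-uniformly per origin class: CNS and leptomeningeal 0.05-5,
#' liver-secreted plasma proteins 50-15000, mixed-origin 5-50;
#' blood-cell-associated proteins have a near-zero plasma phase but a large
#' cellular payload. An albumin-like sentinel (`accession "ALB_SYN"`,
#' equal-volume plasma/CSF ratio 177) is always present.
#'
#' @param spec A [sim_spec()] (the `seed` is mandatory).
#' @return A tibble of class `"csf_catalog"`, one row per protein, columns
#'   `accession`, `origin`, `c_csf`, `r_volume`, `cell_assoc_frac`,
#'   `payload_ratio`, `gradient_amp`, `depleted`.
#' @export
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_per_class
  with_rng(spec$seed, {
    draw <- function(class, n_class) {
      if (n_class == 0) return(NULL)
      acc <- sprintf("SYN_%s_%03d", toupper(substr(class, 1, 4)), seq_len(n_class))
      tibble(
        accession = acc,
        origin = class,
        c_csf = runif_log(n_class, 1, 1000),
        r_volume = switch(class,
          cns            = runif_log(n_class, 0.05, 5),
          leptomeningeal = runif_log(n_class, 0.05, 5),
          plasma_liver   = runif_log(n_class, 50, 15000),
          blood_cellular = runif_log(n_class, 0.05, 1),
          mixed          = runif_log(n_class, 5, 50)
        ),
        cell_assoc_frac = if (class == "blood_cellular") {
          runif(n_class, 0.9, 1)
        } else {
          rep(0, n_class)
        },
        payload_ratio = if (class == "blood_cellular") {
          runif_log(n_class, 1e3, 1e5)
        } else {
          rep(0, n_class)
        },
        gradient_amp = switch(class,
          cns            = rep(1, n_class),
          leptomeningeal = rep(1, n_class),
          plasma_liver   = rep(spec$gradient_amp_plasma, n_class),
          blood_cellular = rep(1, n_class),
          mixed          = runif(n_class, 1, spec$gradient_amp_plasma)
        ),
        depleted = FALSE
      )
    }
    cat_tbl <- bind_rows(purrr::imap(as.list(n), function(n_class, class) {
      draw(class, n_class)
    }))
    sentinel <- tibble(
      accession = "ALB_SYN", origin = "plasma_liver",
      c_csf = 200, r_volume = 177, cell_assoc_frac = 0, payload_ratio = 0,
      gradient_amp = spec$gradient_amp_plasma, depleted = TRUE
    )
    out <- bind_rows(sentinel, cat_tbl)
    class(out) <- c("csf_catalog", class(out))
    attr(out, "seed") <- spec$seed
    out
  })
}

# Noise-free expected abundance under the contamination forward model.
spike_expectation <- function(catalog, fraction, centrifuged, removal) {
  keep <- 1 - removal * as.numeric(centrifuged)
  (1 - fraction) * catalog$c_csf +
    fraction * ((1 - catalog$cell_assoc_frac) * catalog$r_volume * catalog$c_csf +
                  catalog$cell_assoc_frac * catalog$payload_ratio * catalog$c_csf * keep)
}

#' Simulate the blood spike-in contamination design
#'
#' Generates a reference CSF sample (no added blood) plus one sample per
#' requested (spike fraction, centrifugation) condition, under the
#' contamination forward model with multiplicative log-normal technical
#' noise. At `noise_cv = 0` abundances equal the closed-form expectation
#' exactly; e.g. a pure plasma protein with equal-volume ratio 177 shows a
#' `0.98 + 0.02 * 177 = 4.52`-fold increase at a 2% spike.
#'
#' @param catalog A [generate_catalog()] tibble.
#' @param fractions Blood volume fractions in `[0, 0.1]` (default 0.5%, 2%).
#' @param centrifuged Logical, recycled against `fractions`: whether each
#'   spiked sample was centrifuged before freezing.
#' @param noise_cv Technical CV (default 0.20).
#' @param seed Integer seed (mandatory).
#' @param centrifugation_removal Fraction of cell-associated payload removed
#'   by centrifugation (default 0.95).
#' @return Long abundance tibble with sample metadata columns (`role`,
#'   `spike_fraction`, `centrifuged`) joined on; the reference sample has
#'   `role = "reference"`.
#' @export
simulate_blood_spike <- function(catalog, fractions = c(0.005, 0.02),
                                 centrifuged = FALSE, noise_cv = 0.20,
                                 seed = NULL, centrifugation_removal = 0.95) {
  stopifnot(inherits(catalog, "csf_catalog"))
  if (any(fractions < 0)) abort("spike fractions must be >= 0.")
  if (any(fractions > 0.1)) abort("spike fractions above 10% are not supported.")
  centrifuged <- rep_len(as.logical(centrifuged), length(fractions))

  design <- tibble(
    sample_id = c("reference", sprintf(
      "spike_%g%s", 100 * fractions, if_else(centrifuged, "_cfg", "")
    )),
    role = c("reference", rep("spiked", length(fractions))),
    spike_fraction = c(0, fractions),
    centrifuged = c(NA, centrifuged)
  )

  with_rng(seed, {
    out <- purrr::pmap(design, function(sample_id, role, spike_fraction, centrifuged) {
      mu <- spike_expectation(
        catalog, spike_fraction,
        isTRUE(centrifuged), centrifugation_removal
      )
      tibble(
        accession = catalog$accession,
        sample_id = sample_id,
        abundance = mu * lognormal_factor(nrow(catalog), noise_cv)
      )
    })
    out <- bind_rows(out)
    out <- left_join(out, design, by = "sample_id")
    attr(out, "seed") <- seed
    out
  })
}

# Noise-free expected abundance at gradient point k (1 = lumbar, K =
# ventricular): linear in k from gradient_amp * c_csf at k = 1 down to c_csf
# at k = K.
rcg_expectation <- function(catalog, k, n_points) {
  frac <- (n_points - k) / (n_points - 1)
  catalog$c_csf * (1 + (catalog$gradient_amp - 1) * frac)
}

#' Simulate the rostro-caudal gradient design
#'
#' Generates abundances at `n_rcg_points` collection points (point 1 =
#' lumbar-most, point K = ventricular-most), linear in the point index per
#' protein, plus a pooled reference channel equal to the mean of the
#' noise-free point expectations (emulating a reference made from equal
#' amounts of every point). Points 1 and K get duplicate channels, to be
#' averaged downstream before ratio computation. An optional erythrocyte
#' spike adds cellular payload to point 1 only.
#'
#' @param catalog A [generate_catalog()] tibble.
#' @param n_points Number of gradient points (default 7, >= 3).
#' @param noise_cv Technical CV (default 0.20).
#' @param seed Integer seed (mandatory).
#' @param hb_point1_fraction Whole-blood volume fraction contaminating point 1
#'   only (default 0 = off); affects the cellular payload of
#'   blood-cell-associated proteins.
#' @return Long abundance tibble with `rcg_point` metadata (NA for the
#'   reference channel) and `role` of `"rcg_point"` or `"reference"`.
#' @export
simulate_rcg_series <- function(catalog, n_points = 7, noise_cv = 0.20,
                                seed = NULL, hb_point1_fraction = 0) {
  stopifnot(inherits(catalog, "csf_catalog"))
  if (n_points < 3) abort("n_points must be >= 3.")
  if (any(catalog$gradient_amp < 1)) {
    abort("gradient_amp must be >= 1 for every protein (increase toward lumbar).")
  }

  mu_by_point <- vapply(
    seq_len(n_points),
    function(k) rcg_expectation(catalog, k, n_points),
    numeric(nrow(catalog))
  ) # proteins x points
  if (hb_point1_fraction > 0) {
    mu_by_point[, 1] <- mu_by_point[, 1] +
      hb_point1_fraction * catalog$cell_assoc_frac *
        catalog$payload_ratio * catalog$c_csf
  }
  mu_ref <- rowMeans(mu_by_point)

  # duplicate channels for the two end points
  channels <- tibble(rcg_point = sort(c(seq_len(n_points), 1L, n_points))) %>%
    group_by(.data$rcg_point) %>%
    mutate(channel = letters[row_number()]) %>%
    ungroup()
  channels$sample_id <- sprintf("rcg%d_%s", channels$rcg_point, channels$channel)

  with_rng(seed, {
    point_rows <- purrr::pmap(channels, function(rcg_point, channel, sample_id) {
      tibble(
        accession = catalog$accession,
        sample_id = sample_id,
        abundance = mu_by_point[, rcg_point] *
          lognormal_factor(nrow(catalog), noise_cv),
        role = "rcg_point",
        rcg_point = as.integer(rcg_point)
      )
    })
    ref_rows <- tibble(
      accession = catalog$accession,
      sample_id = "reference",
      abundance = mu_ref * lognormal_factor(nrow(catalog), noise_cv),
      role = "reference",
      rcg_point = NA_integer_
    )
    out <- bind_rows(c(point_rows, list(ref_rows)))
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate paired plasma/CSF patient samples
#'
#' For each patient, CSF abundance is the catalog concentration and plasma
#' abundance is `r_volume * c_csf`, each multiplied by a per-(protein,
#' patient) log-normal biological factor (`patient_sigma` on the log scale)
#' and technical noise. Both the equal-volume abundances and the
#' equal-total-protein rescaling (each sample divided by its summed
#' abundance, emulating equal protein loads per fluid) are emitted.
#'
#' @param catalog A [generate_catalog()] tibble.
#' @param n_patients Number of patients (default 5, >= 2).
#' @param noise_cv Technical CV (default 0.20).
#' @param seed Integer seed (mandatory).
#' @param patient_sigma Log-scale SD of patient-level biological variation
#'   (default 0.3).
#' @return Long tibble with columns `accession`, `sample_id`, `patient_id`,
#'   `fluid`, `basis` (`"equal_volume"` or `"equal_protein"`), `abundance`,
#'   `role = "patient_fluid"`.
#' @export
simulate_plasma_csf_pairs <- function(catalog, n_patients = 5, noise_cv = 0.20,
                                      seed = NULL, patient_sigma = 0.3) {
  stopifnot(inherits(catalog, "csf_catalog"))
  if (n_patients < 2) abort("n_patients must be >= 2.")

  with_rng(seed, {
    out <- purrr::map(seq_len(n_patients), function(p) {
      bio <- exp(rnorm(nrow(catalog), 0, patient_sigma))
      csf <- catalog$c_csf * bio * lognormal_factor(nrow(catalog), noise_cv)
      pla <- catalog$r_volume * catalog$c_csf * bio *
        lognormal_factor(nrow(catalog), noise_cv)
      bind_rows(
        tibble(
          accession = catalog$accession,
          sample_id = sprintf("P%d_CSF", p),
          patient_id = sprintf("P%d", p), fluid = "CSF", abundance = csf
        ),
        tibble(
          accession = catalog$accession,
          sample_id = sprintf("P%d_plasma", p),
          patient_id = sprintf("P%d", p), fluid = "plasma", abundance = pla
        )
      )
    })
    out <- bind_rows(out)
    out$role <- "patient_fluid"
    equal_vol <- mutate(out, basis = "equal_volume")
    equal_prot <- out %>%
      group_by(.data$sample_id) %>%
      mutate(abundance = .data$abundance / sum(.data$abundance, na.rm = TRUE)) %>%
      ungroup() %>%
      mutate(basis = "equal_protein")
    res <- bind_rows(equal_vol, equal_prot)
    attr(res, "seed") <- seed
    res
  })
}
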