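#' Outcome model for synthetic cohorts
#'
#' The probability that a synthetic patient is `TILsum_High` is
#' `plogis(intercept + sum(coef * log1p(x)))`, where each coefficient is
#' attached either to a `"class:region"` lesion volume (mm^3, as produced by
#' the Exp7 feature set of the 7-class scheme) or to a clinical covariate
#' (`age`, `gcs`, `map`, `hb`, `antiaggregants`). This is how a known effect
#' — e.g. subdural blood over the parietal lobe driving therapeutic
#' intensity — is planted for recovery testing of the whole pipeline.
#'
#' @param intercept Real; `intercept = 0` with no coefficients gives a 50%
#'   High prevalence.
#' @param coefficients Named numeric vector, e.g.
#'   `c("SDH:Parietal Lobe" = 2)`.
#' @return A `tbq_outcome_spec`.
#' @export
outcome_model_spec <- function(intercept = 0, coefficients = numeric()) {
  cls <- scheme_seven()$labels
  valid <- c(
    as.character(outer(cls, atlas_region_names(), paste, sep = ":")),
    "age", "gcs", "map", "hb", "antiaggregants"
  )
  bad <- setdiff(names(coefficients), valid)
  if (length(bad)) {
    stop("invalid outcome-model feature name(s): ", paste(bad, collapse = ", "),
         " (use \"class:region\" pairs or clinical covariate names)")
  }
  structure(list(intercept = intercept, coefficients = coefficients),
            class = "tbq_outcome_spec")
}

# daily TIL series consistent with a drawn outcome: High patients get at
# least one day at >= 11 within the 8-day window, Low patients never do.
#' @noRd
sample_til_series <- function(high) {
  base <- sample(0:9, 8L, replace = TRUE, prob = stats::dpois(0:9, 4))
  if (high) {
    ndays <- sample(1:3, 1L)
    days <- sample.int(8L, ndays)
    base[days] <- sample(11:28, ndays, replace = TRUE)
  } else {
    base <- pmin(base, 10L)
  }
  as.integer(base)
}

# CT findings coupled to the realized lesion volumes (midline shift and
# cistern status are not derivable from label maps, so severity is randomly
# generated but driven by total volume; epidural and IVH/tSAH flags are read
# off the segmentation).
#' @noRd
sample_findings <- function(vols_mm3) {
  total_cm3 <- sum(vols_mm3) / 1000
  mass_cm3 <- max(vols_mm3[c("IPH", "SDH", "EDH")], 0) / 1000 * stats::runif(1, 0.8, 1.2)
  shift <- max(0, stats::rnorm(1, mean = 1.5 * total_cm3, sd = 2))
  sev <- total_cm3 + shift / 3
  cist <- sample(c("normal", "compressed", "absent"), 1L,
                 prob = c(1, stats::plogis(sev - 3), stats::plogis(sev - 6)))
  evac <- mass_cm3 > 10 && stats::runif(1) < stats::plogis((mass_cm3 - 25) / 8)
  ct_findings(
    cistern_status = cist,
    midline_shift_mm = round(shift, 1),
    mass_lesion_volume_cm3 = round(mass_cm3, 1),
    evacuated = evac,
    epidural_mass_present = vols_mm3[["EDH"]] > 0,
    ivh_or_tsah_present = vols_mm3[["IVH"]] > 0 || vols_mm3[["SAH"]] > 0
  )
}

#' Generate a synthetic TBI cohort
#'
#' Simulates `n` patients: a 7-class ground-truth lesion volume per patient
#' on a shared synthetic atlas (one admission scan each), clinical covariates
#' in severe-TBI admission ranges (age 18-80, GCS 3-15, MAP, Hb,
#' antiaggregant flag), CT findings coupled to lesion load, Marshall and
#' Rotterdam scores, an 8-day TILsum series consistent with the outcome, and
#' the `TILsum_High`/`TILsum_Low` label drawn from the logistic outcome model
#' on log1p lesion volumes. Optionally, degraded "automatic" segmentation
#' variants at given target Dice levels are produced per patient.
#'
#' @param n Number of patients, >= 1.
#' @param lesion_spec A [lesion_gen_spec()].
#' @param outcome_spec An [outcome_model_spec()].
#' @param seed Integer RNG seed; the cohort is reproducible bit-for-bit.
#' @param atlas Optional shared `tbq_atlas`; generated from `shape` and
#'   `seed` when missing.
#' @param shape Grid dimensions of the generated atlas.
#' @param degrade Optional named numeric vector of target overall Dice values,
#'   e.g. `c(cnn_ft = 0.8, cnn_raw = 0.5)`: per patient, each variant is a
#'   degraded copy of the truth, quantified into a `quant_<name>` list-column.
#' @param keep_volumes Keep the 3D volumes as list-columns? Set `FALSE` for
#'   large cohorts where only the quantified features matter.
#' @return A cohort tibble, one row per patient: `id`, clinical columns, CT
#'   findings, `marshall`, `rotterdam`, `til_series` (list), `outcome`,
#'   `quant` (list of `tbq_quant`), and optionally `truth_seg` /
#'   `seg_<variant>` list-columns. The atlas rides along as attribute
#'   `"atlas"`.
#' @examples
#' coh <- generate_cohort(6, seed = 1, shape = c(32, 32, 32))
#' dplyr::count(coh, outcome)
#' @export
generate_cohort <- function(n, lesion_spec = lesion_gen_spec(),
                            outcome_spec = outcome_model_spec(),
                            seed = 1L, atlas = NULL,
                            shape = c(48, 48, 48), degrade = NULL,
                            keep_volumes = n <= 50) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (is.null(atlas)) atlas <- generate_atlas(shape, seed = seed)
  clin_names <- c("age", "gcs", "map", "hb", "antiaggregants")
  rows <- vector("list", n)
  with_seed(seed + 1L, {
    patient_seeds <- sample.int(2L^30L, n)
  })
  for (i in seq_len(n)) {
    ps <- patient_seeds[i]
    truth <- generate_lesions(atlas, lesion_spec, seed = ps)
    q <- region_lesion_volumes(truth, atlas, scan_id = sprintf("pt%03d", i))
    feats <- build_features(q, exp = "Exp7")
    per_class <- build_features(q, exp = "Exp4")
    rows[[i]] <- with_seed(ps + 1L, {
      clin <- list(
        age = round(stats::runif(1, 18, 80)),
        gcs = sample(3:15, 1L),
        map = round(min(max(stats::rnorm(1, 88, 16), 40), 130)),
        hb = round(min(max(stats::rnorm(1, 125, 25), 40), 180)),
        antiaggregants = stats::runif(1) < 0.15,
        sex = sample(c("M", "F"), 1L, prob = c(0.72, 0.28)),
        weight = round(min(max(stats::rnorm(1, 73, 12), 45), 110)),
        height = round(min(max(stats::rnorm(1, 175, 9), 150), 200))
      )
      x <- c(feats, vapply(clin[clin_names], as.numeric, numeric(1)))
      cf <- outcome_spec$coefficients
      eta <- outcome_spec$intercept +
        sum(cf * log1p(x[names(cf)]))
      high <- stats::runif(1) < stats::plogis(eta)
      til <- sample_til_series(high)
      fnd <- sample_findings(per_class)
      tibble::tibble(
        id = sprintf("pt%03d", i),
        !!!clin,
        cistern_status = fnd$cistern_status,
        midline_shift_mm = fnd$midline_shift_mm,
        mass_lesion_volume_cm3 = fnd$mass_lesion_volume_cm3,
        evacuated = fnd$evacuated,
        epidural_mass_present = fnd$epidural_mass_present,
        ivh_or_tsah_present = fnd$ivh_or_tsah_present,
        marshall = marshall(fnd),
        rotterdam = rotterdam(fnd),
        til_series = list(til),
        outcome = til_outcome(til),
        p_high = stats::plogis(eta),
        quant = list(q),
        truth_seg = if (keep_volumes) list(truth) else list(NULL)
      )
    })
    if (!is.null(degrade)) {
      for (v in names(degrade)) {
        dv <- degrade_segmentation(truth, target_dice = degrade[[v]],
                                   seed = ps + 2L + match(v, names(degrade)))
        rows[[i]][[paste0("quant_", v)]] <-
          list(region_lesion_volumes(dv, atlas, scan_id = sprintf("pt%03d", i)))
        if (keep_volumes) rows[[i]][[paste0("seg_", v)]] <- list(dv)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!keep_volumes) out$truth_seg <- NULL
  attr(out, "atlas") <- atlas
  class(out) <- c("tbq_cohort", class(out))
  out
}

#' Patient-level stratified cohort split
#'
#' Splits a cohort into train/validation/test at the patient level (all scans
#' of a patient stay together), stratified by outcome, with per-stratum sizes
#' allocated by largest remainder so totals match the proportions to
#' rounding. 30 patients at the conventional 60/20/20 proportions give
#' 18/6/6.
#'
#' @param cohort A cohort tibble with `id` and `outcome`.
#' @param proportions Positive, summing to 1; default `c(0.6, 0.2, 0.2)`.
#' @param seed Integer RNG seed.
#' @return The cohort with a `split` factor column
#'   (`train`/`validation`/`test`).
#' @export
split_cohort <- function(cohort, proportions = c(train = 0.6, validation = 0.2, test = 0.2),
                         seed = 1L) {
  if (any(proportions <= 0) || abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must be positive and sum to 1")
  }
  nm <- names(proportions)
  if (is.null(nm)) nm <- c("train", "validation", "test")[seq_along(proportions)]
  split <- character(nrow(cohort))
  with_seed(seed, {
    for (lv in unique(cohort$outcome)) {
      idx <- which(cohort$outcome == lv)
      if (length(idx) < length(proportions)) {
        stop("outcome stratum '", lv, "' has fewer patients (", length(idx),
             ") than splits (", length(proportions), ")")
      }
      idx <- idx[sample.int(length(idx))]
      exact <- length(idx) * proportions
      sizes <- floor(exact)
      rem <- exact - sizes
      short <- length(idx) - sum(sizes)
      if (short > 0) {
        bump <- order(rem, decreasing = TRUE)[seq_len(short)]
        sizes[bump] <- sizes[bump] + 1
      }
      assign_to <- rep(nm, times = sizes)
      split[idx] <- assign_to
    }
  })
  cohort$split <- factor(split, levels = nm)
  cohort
}
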