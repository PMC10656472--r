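#' Pipeline run configuration
#'
#' The three pipeline stages ([pipeline_simulate()], [pipeline_quantify()],
#' [pipeline_evaluate()]) communicate only via files under `outdir`, so any
#' stage can be rerun in isolation and real segmentations from any tool can
#' enter at the quantify stage. Every stage writes a provenance block
#' (config hash, seed, package version) next to its outputs; reruns with
#' unchanged inputs reproduce outputs bit-identically.
#'
#' @param outdir Output directory.
#' @param n Number of synthetic patients.
#' @param seed Master seed.
#' @param shape Atlas grid dimensions.
#' @param degrade Named numeric vector of degraded segmentation variants
#'   (target overall Dice each).
#' @param schemes Schemes to quantify under: subset of `c("seven", "four")`.
#' @param experiments Experiment ids to build and evaluate.
#' @param cv A [cv_config()].
#' @param path YAML file for `read_run_config()`.
#' @return A `tbq_run_config` list.
#' @export
run_config <- function(outdir, n = 20L, seed = 1L, shape = c(48L, 48L, 48L),
                       degrade = c(cnn = 0.6), schemes = c("seven", "four"),
                       experiments = 1:7, cv = cv_config(seed = seed)) {
  structure(
    list(outdir = outdir, n = as.integer(n), seed = as.integer(seed),
         shape = as.integer(shape), degrade = degrade,
         schemes = match.arg(schemes, c("seven", "four"), several.ok = TRUE),
         experiments = if (is.numeric(experiments)) paste0("Exp", experiments) else experiments,
         cv = cv),
    class = "tbq_run_config"
  )
}

#' @rdname run_config
#' @export
read_run_config <- function(path, outdir = dirname(path)) {
  y <- yaml::read_yaml(path)
  cv_args <- y$cv %||% list()
  run_config(
    outdir = y$outdir %||% outdir,
    n = y$n %||% 20L,
    seed = y$seed %||% 1L,
    shape = unlist(y$shape %||% c(48L, 48L, 48L)),
    degrade = unlist(y$degrade %||% c(cnn = 0.6)),
    schemes = unlist(y$schemes %||% c("seven", "four")),
    experiments = unlist(y$experiments %||% paste0("Exp", 1:7)),
    cv = do.call(cv_config, cv_args)
  )
}

#' @noRd
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  slim <- config[setdiff(names(config), "outdir")]
  jsonlite::write_json(slim, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' @noRd
write_provenance <- function(config, stage, dir) {
  jsonlite::write_json(
    list(stage = stage, seed = config$seed, config_hash = config_hash(config),
         package = "tbiquant",
         version = as.character(utils::packageVersion("tbiquant"))),
    file.path(dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE
  )
}

#' Simulate a cohort to disk
#'
#' Writes the atlas, per-patient ground-truth and degraded segmentations
#' (NIfTI + scheme sidecars), and a manifest CSV (one row per patient:
#' clinical covariates, CT findings, Marshall/Rotterdam, the daily TILsum
#' series, the outcome label, the train/validation/test split and file
#' paths). Idempotent for a fixed config: rerunning reproduces the manifest
#' byte-identically.
#'
#' @param config A [run_config()].
#' @return The manifest tibble, invisibly.
#' @export
pipeline_simulate <- function(config) {
  if (config$n < 1L) stop("n must be >= 1")
  dir <- file.path(config$outdir, "sim")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(
    config$n, seed = config$seed, shape = config$shape,
    degrade = config$degrade, keep_volumes = TRUE
  )
  cohort <- split_cohort(cohort, seed = config$seed)
  atlas <- attr(cohort, "atlas")
  write_atlas(atlas, file.path(dir, "atlas.nii.gz"))

  paths <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    id <- cohort$id[i]
    tp <- file.path(dir, paste0(id, "_truth.nii.gz"))
    write_label_volume(cohort$truth_seg[[i]], tp)
    row <- tibble::tibble(truth_path = tp)
    for (v in names(config$degrade)) {
      vp <- file.path(dir, paste0(id, "_", v, ".nii.gz"))
      write_label_volume(cohort[[paste0("seg_", v)]][[i]], vp)
      row[[paste0(v, "_path")]] <- vp
    }
    row
  })

  til <- do.call(rbind, cohort$til_series)
  colnames(til) <- paste0("til_d", 1:8)
  manifest <- dplyr::bind_cols(
    cohort[, c("id", "age", "sex", "weight", "height", "gcs", "map", "hb",
               "antiaggregants", "cistern_status", "midline_shift_mm",
               "mass_lesion_volume_cm3", "evacuated", "epidural_mass_present",
               "ivh_or_tsah_present")],
    tibble::as_tibble(til),
    tibble::tibble(
      marshall = as.character(cohort$marshall),
      rotterdam = cohort$rotterdam,
      outcome = cohort$outcome,
      split = as.character(cohort$split)
    ),
    paths
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  write_provenance(config, "simulate", dir)
  message("simulated ", config$n, " patients -> ", dir)
  invisible(manifest)
}

#' Quantify simulated (or externally supplied) segmentations
#'
#' Reads the manifest and volumes written by the simulate stage, quantifies
#' every segmentation variant against the atlas, and writes one tidy
#' quantification CSV per variant plus one feature CSV per variant, scheme
#' and experiment (columns: id, label, then the experiment's metrics).
#' Degraded variants carry 7-class labels, so both schemes apply to all
#' variants.
#'
#' @param config A [run_config()].
#' @return Invisibly, the named list of feature-file paths.
#' @export
pipeline_quantify <- function(config) {
  sim <- file.path(config$outdir, "sim")
  dir <- file.path(config$outdir, "features")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- readr::read_csv(file.path(sim, "manifest.csv"),
                              show_col_types = FALSE)
  atlas <- read_atlas(file.path(sim, "atlas.nii.gz"))
  variants <- c("truth", names(config$degrade))

  cohort <- manifest
  cohort$outcome <- factor(manifest$outcome,
                           levels = c("TILsum_Low", "TILsum_High"))
  cohort$marshall <- factor(manifest$marshall,
                            levels = c("I", "II", "III", "IV", "V", "VI"),
                            ordered = TRUE)
  written <- list()
  for (v in variants) {
    qs <- purrr::map2(manifest[[paste0(v, "_path")]], manifest$id, function(p, id) {
      region_lesion_volumes(read_label_volume(p), atlas, scan_id = id)
    })
    readr::write_csv(dplyr::bind_rows(qs), file.path(dir, paste0("quant_", v, ".csv")))
    cohort[[paste0("quant_", v)]] <- qs
    for (sch in config$schemes) {
      qcol <- paste0("quant_", v)
      if (sch == "four") {
        qcol4 <- paste0(qcol, "_four")
        if (!qcol4 %in% names(cohort)) {
          cohort[[qcol4]] <- purrr::map(cohort[[qcol]], merge_quant,
                                        target = scheme_four())
        }
        qcol <- qcol4
      }
      for (e in config$experiments) {
        ft <- build_feature_table(cohort, exp = e, quant_col = qcol)
        stopifnot(ncol(ft) - 2L == experiment_spec(e, sch)$n_metrics)
        f <- file.path(dir, sprintf("features_%s_%s_%s.csv", v, sch, e))
        readr::write_csv(ft, f)
        written[[sprintf("%s_%s_%s", v, sch, e)]] <- f
      }
    }
  }
  write_provenance(config, "quantify", dir)
  message("wrote ", length(written), " feature tables -> ", dir)
  invisible(written)
}

#' Evaluate segmentations and classifiers from disk
#'
#' Two reports from the files of the previous stages: (1) segmentation
#' evaluation — per-scan, per-class Dice of every degraded variant against
#' the ground truth, with summaries and paired Wilcoxon comparisons between
#' variants; (2) classification — nested CV over the experiment grid on the
#' train+validation patients, and accuracy of each scheme's best (Exp7)
#' refit model applied to every variant's features of the held-out test
#' patients.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `dice`, `grid` (tidy AUC table),
#'   `comparisons`, and `accuracy` tibbles.
#' @export
pipeline_evaluate <- function(config) {
  sim <- file.path(config$outdir, "sim")
  fdir <- file.path(config$outdir, "features")
  dir <- file.path(config$outdir, "reports")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- readr::read_csv(file.path(sim, "manifest.csv"),
                              show_col_types = FALSE)

  # --- segmentation evaluation -------------------------------------------
  dice_all <- purrr::map_dfr(names(config$degrade), function(v) {
    purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
      rep <- dice_report(
        read_label_volume(manifest[[paste0(v, "_path")]][i]),
        read_label_volume(manifest$truth_path[i]),
        scan_id = manifest$id[i]
      )
      dplyr::mutate(rep, variant = v)
    })
  })
  if (nrow(dice_all)) {
    readr::write_csv(dice_all, file.path(dir, "dice_per_scan.csv"))
    readr::write_csv(
      dice_all |> dplyr::group_by(.data$variant) |>
        dplyr::group_modify(~ dice_summary(.x)) |> dplyr::ungroup(),
      file.path(dir, "dice_summary.csv")
    )
  }

  # --- classification ----------------------------------------------------
  train_ids <- manifest$id[manifest$split != "test"]
  test_ids <- manifest$id[manifest$split == "test"]
  variants <- c("truth", names(config$degrade))
  read_ft <- function(v, sch, e) {
    ft <- readr::read_csv(
      file.path(fdir, sprintf("features_%s_%s_%s.csv", v, sch, e)),
      show_col_types = FALSE
    )
    ft$label <- factor(ft$label, levels = c("TILsum_Low", "TILsum_High"))
    ft
  }
  grid <- tidyr::expand_grid(variant = variants, scheme = config$schemes,
                             experiment = config$experiments)
  results <- purrr::pmap(grid, function(variant, scheme, experiment) {
    ft <- read_ft(variant, scheme, experiment)
    nested_cv(ft[ft$id %in% train_ids, ], config = config$cv)
  })
  auc_tbl <- dplyr::mutate(
    grid,
    mean_auc = vapply(results, function(r) mean(r$auc), numeric(1)),
    sd_auc = vapply(results, function(r) stats::sd(r$auc), numeric(1)),
    n_folds = vapply(results, function(r) length(r$auc), integer(1))
  )
  readr::write_csv(auc_tbl, file.path(dir, "auc_grid.csv"))

  comps <- NULL
  if ("Exp7" %in% config$experiments && length(variants) > 1L) {
    e7 <- which(grid$experiment == "Exp7")
    pairs <- utils::combn(e7, 2L, simplify = FALSE)
    pairs <- Filter(function(p) grid$scheme[p[1L]] == grid$scheme[p[2L]], pairs)
    comps <- purrr::map_dfr(pairs, function(p) {
      dplyr::bind_cols(
        tibble::tibble(scheme = grid$scheme[p[1L]],
                       variant_a = grid$variant[p[1L]],
                       variant_b = grid$variant[p[2L]]),
        compare_auc(results[[p[1L]]]$auc, results[[p[2L]]]$auc)
      )
    })
    readr::write_csv(comps, file.path(dir, "auc_comparisons.csv"))
  }

  # best Exp7 model per scheme, applied to the test patients of each variant
  accuracy <- NULL
  if ("Exp7" %in% config$experiments && length(test_ids) >= 2L) {
    accuracy <- purrr::map_dfr(config$schemes, function(sch) {
      i_best <- which(grid$scheme == sch & grid$experiment == "Exp7" &
                        grid$variant == "truth")
      model <- results[[i_best]]
      purrr::map_dfr(variants, function(v) {
        ft <- read_ft(v, sch, "Exp7")
        ft <- ft[ft$id %in% test_ids, ]
        if (length(unique(ft$label)) < 2L) return(NULL)
        dplyr::bind_cols(
          tibble::tibble(classification_model = paste0(sch, "-class"),
                         applied_segmentation = v),
          apply_model(model, ft)
        )
      })
    })
    if (!is.null(accuracy) && nrow(accuracy)) {
      readr::write_csv(accuracy, file.path(dir, "accuracy.csv"))
    }
  }
  write_provenance(config, "evaluate", dir)
  message("reports -> ", dir)
  invisible(list(dice = dice_all, grid = auc_tbl, comparisons = comps,
                 accuracy = accuracy))
}
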