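#' Lesion volume per type and atlas region
#'
#' The core quantification step: for a segmentation and an atlas on the same
#' grid, every lesion voxel is ascribed to its atlas region, giving a lesion
#' class x region table of volumes in mm^3 (4 x 11 or 7 x 11). Lesion voxels
#' falling outside the atlas head (atlas code 0) are not silently lost: they
#' are returned in an "(unassigned)" spill column, flagged, and a diagnostic
#' warning is raised when the spill exceeds 1% of the lesion volume. The
#' spill is excluded from downstream feature sets.
#'
#' @param seg A `tbq_label_volume`.
#' @param atlas A `tbq_atlas` on the same grid (shape and spacing).
#' @param scan_id Identifier carried into the output.
#' @return A `tbq_quant` tibble with columns `scan_id`, `class`, `region`,
#'   `volume_mm3` (one row per class x region cell, zeros included, plus
#'   spill rows with `region == "(unassigned)"`); attributes `scheme` and
#'   `spill_mm3`.
#' @examples
#' atl <- generate_atlas(c(48, 48, 48), seed = 1)
#' seg <- generate_lesions(atl, seed = 2)
#' q <- region_lesion_volumes(seg, atl)
#' dplyr::count(q, class, wt = volume_mm3)
#' @export
region_lesion_volumes <- function(seg, atlas, scan_id = "scan") {
  check_same_grid(seg, atlas)
  vv <- voxel_volume(seg)
  nz <- seg$grid != 0L
  tab <- table(
    factor(seg$grid[nz], levels = seg$scheme$codes),
    factor(atlas$grid[nz], levels = 0:11)
  )
  vols <- matrix(as.numeric(tab) * vv, nrow = nrow(tab),
                 dimnames = list(seg$scheme$labels, c("(unassigned)", atlas$regions)))
  spill <- sum(vols[, "(unassigned)"])
  total <- sum(vols)
  if (total > 0 && spill / total > 0.01) {
    warning(sprintf(
      "%.1f%% of the lesion volume falls outside the atlas head (unassigned)",
      100 * spill / total
    ))
  }
  out <- tibble::tibble(
    scan_id = scan_id,
    class = rep(rownames(vols), times = ncol(vols)),
    region = rep(colnames(vols), each = nrow(vols)),
    volume_mm3 = as.numeric(vols)
  )
  out <- out[order(match(out$class, seg$scheme$labels),
                   match(out$region, colnames(vols))), ]
  out <- out[out$region != "(unassigned)" | out$volume_mm3 > 0, ]
  class(out) <- c("tbq_quant", class(out))
  attr(out, "scheme") <- seg$scheme$name
  attr(out, "spill_mm3") <- spill
  out
}

# class x region matrix view of a tbq_quant (spill dropped)
#' @noRd
quant_matrix <- function(q) {
  scheme <- get_scheme(attr(q, "scheme"))
  q <- q[q$region != "(unassigned)", ]
  m <- matrix(0, length(scheme$labels), 11,
              dimnames = list(scheme$labels, atlas_region_names()))
  m[cbind(match(q$class, rownames(m)), match(q$region, colnames(m)))] <- q$volume_mm3
  m
}

#' Merge a quantification table onto a coarser scheme
#'
#' Sums sibling class rows through the scheme merge map (e.g. SDH + EDH +
#' SAH volumes become the EAH row). Quantifying a merged volume and merging
#' a quantification commute, so either route gives the same table.
#'
#' @param q A `tbq_quant`.
#' @param target Target `tbq_scheme`.
#' @return A `tbq_quant` on the target scheme.
#' @export
merge_quant <- function(q, target) {
  from <- get_scheme(attr(q, "scheme"))
  m <- merge_map(from, target)
  to_label <- target$labels[match(m[as.character(from$codes)], target$codes)]
  names(to_label) <- from$labels
  scan <- q$scan_id[1L]
  out <- q |>
    dplyr::mutate(class = unname(to_label[.data$class])) |>
    dplyr::group_by(.data$class, .data$region) |>
    dplyr::summarise(volume_mm3 = sum(.data$volume_mm3), .groups = "drop")
  regions <- c(atlas_region_names(), "(unassigned)")
  out <- out[order(match(out$class, target$labels), match(out$region, regions)), ]
  out <- tibble::tibble(scan_id = scan, out)
  class(out) <- c("tbq_quant", class(out))
  attr(out, "scheme") <- target$name
  attr(out, "spill_mm3") <- attr(q, "spill_mm3")
  out
}

#' Experiment feature-set definitions
#'
#' The seven nested feature sets used to probe what predicts extreme
#' therapeutic intensity: Exp1 clinical covariates (age, GCS, MAP, Hb,
#' antiaggregants; 5 metrics); Exp2 adds the Marshall and Rotterdam CT scores
#' (7); Exp3 the global lesion volume (1); Exp4 volume per lesion type (4 or
#' 7); Exp5 volume per atlas region (11); Exp6 the concatenation of Exp4 and
#' Exp5 (15 or 18); Exp7 volume per type and region, the flattened class x
#' region table (44 or 77).
#'
#' @param id Experiment id, `"Exp1"`..`"Exp7"` (or 1..7).
#' @param scheme_name `"four"` or `"seven"`; only relevant for Exp4/6/7.
#' @return List with `id` and the expected metric count `n_metrics`.
#' @export
experiment_spec <- function(id, scheme_name = "seven") {
  if (is.numeric(id)) id <- paste0("Exp", id)
  id <- match.arg(id, paste0("Exp", 1:7))
  k <- if (identical(scheme_name, "four")) 4L else 7L
  n <- switch(id,
    Exp1 = 5L, Exp2 = 7L, Exp3 = 1L, Exp4 = k, Exp5 = 11L,
    Exp6 = k + 11L, Exp7 = k * 11L
  )
  list(id = id, scheme = scheme_name, n_metrics = n)
}

#' Build the feature vector of one experiment
#'
#' Deterministic feature ordering: volume features are named
#' `"class:region"` in class-major order (scheme class order, then atlas
#' region order), so model inputs and importances are stable across runs.
#'
#' @param q A `tbq_quant` (required for Exp3-Exp7).
#' @param clinical Named list/one-row data frame with `age`, `gcs`, `map`,
#'   `hb`, `antiaggregants` (required for Exp1-Exp2).
#' @param scores Named list with `marshall` (I-VI or 1-6) and `rotterdam`
#'   (required for Exp2).
#' @param exp An [experiment_spec()] or its id.
#' @return Named numeric vector whose length matches the experiment's metric
#'   count.
#' @export
build_features <- function(q = NULL, clinical = NULL, scores = NULL,
                           exp = "Exp7") {
  if (!is.list(exp) || is.data.frame(exp)) {
    exp <- experiment_spec(exp, scheme_name = if (!is.null(q)) attr(q, "scheme") else "seven")
  }
  need_clin <- exp$id %in% c("Exp1", "Exp2")
  if (need_clin) {
    if (is.null(clinical)) stop(exp$id, " needs clinical covariates")
    fields <- c("age", "gcs", "map", "hb", "antiaggregants")
    miss <- fields[!fields %in% names(clinical)]
    if (length(miss)) stop("missing clinical field(s): ", paste(miss, collapse = ", "))
    v <- vapply(fields, function(f) as.numeric(clinical[[f]]), numeric(1))
    if (exp$id == "Exp2") {
      if (is.null(scores)) stop("Exp2 needs Marshall and Rotterdam scores")
      v <- c(v,
             marshall = as.numeric(as.integer(scores$marshall)),
             rotterdam = as.numeric(scores$rotterdam))
    }
    return(v)
  }
  if (is.null(q)) stop(exp$id, " needs a quantification table")
  m <- quant_matrix(q)
  switch(exp$id,
    Exp3 = c(total_volume = sum(m)),
    Exp4 = rowSums(m),
    Exp5 = colSums(m),
    Exp6 = c(rowSums(m), colSums(m)),
    Exp7 = {
      v <- as.numeric(t(m)) # class-major: all regions of class 1, then class 2...
      names(v) <- as.character(outer(colnames(m), rownames(m),
                                     function(r, cl) paste0(cl, ":", r)))
      v
    }
  )
}

#' Feature table for a cohort
#'
#' Maps [build_features()] over a cohort tibble, returning one row per
#' patient with an `id` column, the outcome `label`, and the experiment's
#' features — ready for [nested_cv()].
#'
#' @param cohort A cohort tibble from [generate_cohort()] (needs a `quant`
#'   list-column for Exp3-7; clinical columns for Exp1-2).
#' @param exp Experiment id.
#' @param quant_col Name of the list-column of `tbq_quant` tables to use
#'   (default `"quant"`; degraded variants store theirs under other names).
#' @return A tibble: `id`, `label`, then feature columns.
#' @export
build_feature_table <- function(cohort, exp = "Exp7", quant_col = "quant") {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    q <- if (quant_col %in% names(cohort)) cohort[[quant_col]][[i]] else NULL
    clin <- list(
      age = cohort$age[i], gcs = cohort$gcs[i], map = cohort$map[i],
      hb = cohort$hb[i], antiaggregants = as.numeric(cohort$antiaggregants[i])
    )
    scores <- if (all(c("marshall", "rotterdam") %in% names(cohort))) {
      list(marshall = cohort$marshall[i], rotterdam = cohort$rotterdam[i])
    }
    build_features(q = q, clinical = clin, scores = scores, exp = exp)
  })
  feat <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(tibble::tibble(id = cohort$id, label = cohort$outcome), feat)
}
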