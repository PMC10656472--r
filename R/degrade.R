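#' Degrade a reference segmentation to a target Dice
#'
#' Emulates an automatic segmenter of controllable quality without training
#' one: the reference mask is eroded from its boundary inwards (keeping the
#' deepest voxels), whole connected components may drop out, a thin shell of
#' false-positive voxels is dilated back onto the boundary, and kept voxels
#' can be relabelled between classes at given confusion rates. The number of
#' kept and false-positive voxels is solved so the overall-lesion ("All")
#' Dice against the reference hits `target_dice`; a bounded bisection (at
#' most 20 steps) then verifies and, if needed, nudges the kept count until
#' the measured Dice is within +/- 0.05 of target. Class confusion changes
#' per-class Dice but never the "All" Dice.
#'
#' @param truth A `tbq_label_volume` (the reference).
#' @param target_dice Target overall-lesion Dice in (0, 1].
#' @param confusion Optional named list: source class label -> named numeric
#'   vector of relabelling probabilities (e.g. `list(SDH = c(EDH = 0.3))`).
#' @param seed Integer RNG seed.
#' @param dropout Probability that each connected lesion component is dropped
#'   entirely (default 0).
#' @param fp_fraction False-positive voxels to add, as a fraction of the
#'   reference lesion volume; default `0.15 * (1 - target_dice)`.
#' @return A `tbq_label_volume` on the same scheme; attribute
#'   `"achieved_dice"` holds the measured overall Dice.
#' @export
degrade_segmentation <- function(truth, target_dice, confusion = NULL,
                                 seed = 1L, dropout = 0,
                                 fp_fraction = 0.15 * (1 - target_dice)) {
  if (!is.numeric(target_dice) || target_dice <= 0 || target_dice > 1) {
    stop("target_dice must lie in (0, 1]")
  }
  all_mask <- truth$grid != 0L
  V <- sum(all_mask)
  if (V == 0L) return(truth)
  if (target_dice == 1) {
    if (length(confusion) || dropout > 0 || fp_fraction > 0) {
      stop("target Dice 1.0 is unreachable with confusion, dropout or false positives")
    }
    attr(truth, "achieved_dice") <- 1
    return(truth)
  }
  dm <- dim(truth$grid)
  with_seed(seed, {
    candidates <- all_mask
    if (dropout > 0) {
      comp <- label_components(all_mask)
      ncomp <- max(comp)
      drop <- which(stats::runif(ncomp) < dropout)
      if (length(drop) == ncomp) drop <- drop[-sample.int(ncomp, 1L)] # keep one
      candidates[comp %in% drop] <- FALSE
    }
    R <- sum(candidates)
    F_n <- as.integer(round(fp_fraction * V))
    dice_of <- function(K) 2 * K / (K + V + F_n)
    K <- as.integer(round(target_dice * (V + F_n) / (2 - target_dice)))
    K <- min(max(K, 1L), R)
    if (dice_of(R) < target_dice - 0.05) {
      stop(sprintf(
        "target Dice %.2f unreachable: at most %.2f after component dropout",
        target_dice, dice_of(R)
      ))
    }
    # keep the K deepest voxels of the candidate mask (erosion-like loss);
    # random tie-break inside a depth shell
    depth <- boundary_depth(candidates)
    cand_idx <- which(candidates)
    ord <- order(depth[cand_idx] + stats::runif(length(cand_idx)), decreasing = TRUE)
    pick_kept <- function(K) cand_idx[ord[seq_len(K)]]
    # bounded bisection on K against the measured Dice (exact by construction,
    # so this normally converges on the first iteration)
    lo <- 1L; hi <- R
    for (step in seq_len(20L)) {
      d <- dice_of(K)
      if (abs(d - target_dice) <= 0.05) break
      if (d < target_dice) lo <- K else hi <- K
      K <- as.integer((lo + hi) / 2)
    }
    kept <- pick_kept(K)

    out <- array(0L, dm)
    out[kept] <- truth$grid[kept]

    # false positives: dilate shells of background voxels outward from the
    # reference lesion boundary, labelled by an adjacent reference class
    if (F_n > 0L) {
      sel <- logical(length(out))
      sel[all_mask] <- TRUE
      added <- 0L
      frontier <- which(all_mask)
      for (shell in 1:5) {
        if (added >= F_n || !length(frontier)) break
        nb <- unique(neighbors6(frontier, dm))
        nb <- nb[!sel[nb]]
        if (!length(nb)) break
        sel[nb] <- TRUE
        take <- if (length(nb) > F_n - added) nb[sample.int(length(nb), F_n - added)] else nb
        # class from an adjacent labelled voxel (max over 6 shifted class grids)
        cls <- integer(length(take))
        for (ax in 1:3) for (s in c(-1L, 1L)) {
          ai <- arrayInd(take, dm)
          ai[, ax] <- ai[, ax] + s
          ok <- ai[, ax] >= 1L & ai[, ax] <= dm[ax]
          v <- integer(length(take))
          v[ok] <- truth$grid[lin_index(ai[ok, , drop = FALSE], dm)]
          cls <- pmax(cls, v)
        }
        cls[cls == 0L] <- truth$grid[kept[1L]]
        out[take] <- cls
        added <- added + length(take)
        frontier <- nb
      }
    }

    # class confusion on labelled voxels (leaves the All mask untouched)
    if (length(confusion)) {
      labs <- truth$scheme$labels
      for (from in names(confusion)) {
        from_code <- truth$scheme$codes[match(from, labs)]
        if (is.na(from_code)) stop("unknown class in confusion map: ", from)
        rates <- confusion[[from]]
        idx <- which(out == from_code)
        if (!length(idx)) next
        u <- stats::runif(length(idx))
        cum <- 0
        for (to in names(rates)) {
          to_code <- truth$scheme$codes[match(to, labs)]
          if (is.na(to_code)) stop("unknown class in confusion map: ", to)
          hit <- u >= cum & u < cum + rates[[to]]
          out[idx[hit]] <- to_code
          cum <- cum + rates[[to]]
        }
      }
    }

    res <- label_volume(out, spacing = truth$spacing, scheme = truth$scheme,
                        affine = truth$affine)
    attr(res, "achieved_dice") <- dice(res$grid != 0L, all_mask)
    res
  })
}
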