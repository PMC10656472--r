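#' Dice overlap between two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`. When both masks are empty the score is
#' undefined and `NA` is returned (neither 0 nor 1), so that absent lesion
#' classes do not distort per-class averages.
#'
#' @param a,b Logical (or 0/1) arrays of identical shape.
#' @return Dice in \[0, 1\], or `NA` when both masks are empty.
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1:2, 1, 1] <- TRUE
#' dice(m, m) # 1
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shape mismatch")
  a <- a != 0
  b <- b != 0
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

#' Per-class and overall Dice report
#'
#' Compares an automatic segmentation against a reference on the same grid
#' and scheme: one Dice per lesion class, plus the overall-lesion "All" Dice
#' computed after merging every class into a single lesional-tissue mask.
#' Classes absent from both masks get an undefined (NA) Dice with
#' `defined = FALSE`; the count of such exclusions is visible in the report
#' so aggregated tables stay interpretable.
#'
#' @param auto,ref `tbq_label_volume`s on the same grid and scheme.
#' @param scan_id Identifier carried into the report.
#' @return A `tbq_dice_report` tibble: `scan_id`, `class` (the scheme's
#'   classes then `"All"`), `dice`, `defined`.
#' @export
dice_report <- function(auto, ref, scan_id = "scan") {
  if (!identical(auto$scheme$name, ref$scheme$name)) {
    stop("scheme mismatch: '", auto$scheme$name, "' vs '", ref$scheme$name, "'")
  }
  check_same_grid(auto, ref)
  per_class <- vapply(auto$scheme$codes, function(cc) {
    dice(auto$grid == cc, ref$grid == cc)
  }, numeric(1))
  all_d <- dice(auto$grid != 0L, ref$grid != 0L)
  out <- tibble::tibble(
    scan_id = scan_id,
    class = c(auto$scheme$labels, "All"),
    dice = c(per_class, all_d),
    defined = !is.na(c(per_class, all_d))
  )
  class(out) <- c("tbq_dice_report", class(out))
  out
}

#' Summarise Dice reports over scans
#'
#' Mean and standard error per class over the scans where the class's Dice is
#' defined, with the number of excluded (both-empty) scans, mirroring
#' mean-and-standard-error barplots of segmentation comparisons.
#'
#' @param reports A `tbq_dice_report` (possibly row-bound over scans).
#' @return Tibble: `class`, `mean_dice`, `se_dice`, `n`, `n_undefined`.
#' @export
dice_summary <- function(reports) {
  reports |>
    dplyr::group_by(class = factor(.data$class, levels = unique(.data$class))) |>
    dplyr::summarise(
      mean_dice = mean(.data$dice[.data$defined]),
      se_dice = stats::sd(.data$dice[.data$defined]) /
        sqrt(max(sum(.data$defined), 1L)),
      n = sum(.data$defined),
      n_undefined = sum(!.data$defined),
      .groups = "drop"
    )
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided comparison of paired samples (e.g. per-scan Dice of two
#' segmentation variants). Zero differences are dropped; the null
#' distribution is exact for n <= 25 effective pairs without ties in the
#' absolute differences, and a tie-corrected normal approximation otherwise.
#' When every difference is zero the test is undefined and reported as such
#' rather than fabricating a p-value.
#'
#' @param x,y Equal-length paired numeric vectors; at least 5 nonzero
#'   differences are required.
#' @return Tibble: `statistic` (V), `p_value`, `n_effective`, `method`
#'   (`"exact"`, `"normal"`, or `"degenerate"` with `NA` p).
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n_effective = 0L, method = "degenerate"))
  }
  if (length(d) < 5L) stop("fewer than 5 nonzero differences; test unreliable")
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- length(d) <= 25L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = !exact)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_effective = length(d),
    method = if (exact) "exact" else "normal"
  )
}
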