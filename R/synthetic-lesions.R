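#' Specification of the synthetic lesion mix
#'
#' One row per lesion class of the 7-class scheme: prevalence (probability the
#' class is present in a scan), a log-normal volume distribution
#' (median mm^3 and log-sd of the total class volume when present), placement
#' weights over the 11 atlas regions, and a range for the number of connected
#' components the class volume is split into.
#'
#' Defaults emulate a severe-TBI admission-scan lesion mix scaled to the small
#' synthetic head: contusional IPH and oedema are common and bulky, SDH and
#' SAH common and thinner, EDH rarer, petechiae small and multiple, IVH
#' confined to the ventricular (rest-of-brain) compartment.
#'
#' @param prevalence,vol_median_mm3,vol_log_sd Named numeric vectors over the
#'   7 class labels; partial overrides are merged into the defaults.
#' @param region_weights Named list class -> length-11 weight vector over
#'   [atlas_region_names()] (rows are normalised to sum to 1).
#' @param n_components Named list class -> integer range `c(lo, hi)`.
#' @return A `tbq_lesion_spec` tibble with one row per class.
#' @export
lesion_gen_spec <- function(prevalence = NULL, vol_median_mm3 = NULL,
                            vol_log_sd = NULL, region_weights = NULL,
                            n_components = NULL) {
  cls <- scheme_seven()$labels
  prev <- c(IPH = 0.6, SDH = 0.5, EDH = 0.15, SAH = 0.5, Pe = 0.3, Od = 0.6, IVH = 0.3)
  med <- c(IPH = 2000, SDH = 1500, EDH = 600, SAH = 800, Pe = 150, Od = 2500, IVH = 400)
  lsd <- c(IPH = 0.6, SDH = 0.6, EDH = 0.6, SAH = 0.5, Pe = 0.5, Od = 0.6, IVH = 0.5)
  rn <- atlas_region_names()
  lobes <- c(4, 3, 1, 2, rep(0.2, 5), 0.3, 0) # lobe-heavy placement
  surface <- c(3, 3, 2, 2, rep(0, 5), 0, 1) # convexity collections
  vent <- c(rep(0.25, 9), 8, 0) # ventricular system
  w <- list(
    IPH = lobes, SDH = surface, EDH = surface, SAH = surface,
    Pe = lobes, Od = lobes, IVH = vent
  )
  nc <- list(
    IPH = c(1L, 2L), SDH = c(1L, 1L), EDH = c(1L, 1L), SAH = c(1L, 2L),
    Pe = c(1L, 4L), Od = c(1L, 2L), IVH = c(1L, 1L)
  )
  override <- function(def, usr) {
    if (!is.null(usr)) def[names(usr)] <- usr
    def
  }
  prev <- override(prev, prevalence)
  med <- override(med, vol_median_mm3)
  lsd <- override(lsd, vol_log_sd)
  if (!is.null(region_weights)) w[names(region_weights)] <- region_weights
  if (!is.null(n_components)) nc[names(n_components)] <- n_components
  stopifnot(all(prev >= 0 & prev <= 1), all(med > 0), all(lsd >= 0))
  w <- lapply(w, function(v) {
    stopifnot(length(v) == 11L, all(v >= 0), sum(v) > 0)
    v <- v / sum(v)
    names(v) <- rn
    v
  })
  out <- tibble::tibble(
    class = cls,
    code = scheme_seven()$codes,
    prevalence = unname(prev[cls]),
    vol_median_mm3 = unname(med[cls]),
    vol_log_sd = unname(lsd[cls]),
    region_weights = w[cls],
    n_components = nc[cls]
  )
  class(out) <- c("tbq_lesion_spec", class(out))
  out
}

#' Generate a synthetic 7-class lesion volume on an atlas
#'
#' For each lesion class: presence is Bernoulli(prevalence); the total class
#' volume is log-normal (median `vol_median_mm3`, log-sd `vol_log_sd`); the
#' volume is split over 1 or more connected components; each component is
#' grown as a connected blob by seeded breadth-first region growing from a
#' random voxel of an atlas region drawn from the class's placement weights,
#' and never crosses the region boundary. Components that cannot reach their
#' target size inside the remaining free space of their region are truncated
#' with a warning. Deterministic given `seed`.
#'
#' @param atlas A `tbq_atlas`.
#' @param spec A [lesion_gen_spec()].
#' @param seed Integer RNG seed.
#' @return A 7-class `tbq_label_volume`; attribute `"realized"` holds a tibble
#'   of realized per-component volumes (class, region, target and realized
#'   mm^3).
#' @export
generate_lesions <- function(atlas, spec = lesion_gen_spec(), seed = 1L) {
  vv <- voxel_volume(atlas)
  dm <- dim(atlas$grid)
  with_seed(seed, {
    grid <- array(0L, dm)
    rows <- list()
    for (i in seq_len(nrow(spec))) {
      if (stats::runif(1) > spec$prevalence[i]) next
      total_mm3 <- stats::rlnorm(1, meanlog = log(spec$vol_median_mm3[i]),
                                 sdlog = spec$vol_log_sd[i])
      ncr <- spec$n_components[[i]]
      ncomp <- if (ncr[1L] == ncr[2L]) ncr[1L] else sample(ncr[1L]:ncr[2L], 1L)
      shares <- stats::runif(ncomp)
      shares <- shares / sum(shares)
      for (k in seq_len(ncomp)) {
        target_vox <- max(1L, as.integer(round(total_mm3 * shares[k] / vv)))
        wts <- spec$region_weights[[i]]
        # weight-driven placement, re-drawn (up to 5 tries) when the target
        # volume exceeds the region's free capacity, so truncation stays rare
        for (try in 1:5) {
          region <- sample.int(11L, 1L, prob = wts)
          free <- atlas$grid == region & grid == 0L
          cand <- which(free)
          if (length(cand) >= target_vox) break
        }
        if (!length(cand)) {
          warning("no free voxels left in region '", atlas$regions[region],
                  "' for class ", spec$class[i], "; component skipped")
          next
        }
        start <- cand[sample.int(length(cand), 1L)]
        blob <- grow_blob(free, start, target_vox, dm)
        if (length(blob) < target_vox) {
          warning(
            "component of class ", spec$class[i], " truncated in region '",
            atlas$regions[region], "': ", length(blob), "/", target_vox, " voxels"
          )
        }
        grid[blob] <- spec$code[i]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          class = spec$class[i], region = atlas$regions[region],
          target_mm3 = target_vox * vv, realized_mm3 = length(blob) * vv
        )
      }
    }
    out <- label_volume(grid, spacing = atlas$spacing, scheme = scheme_seven())
    attr(out, "realized") <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(class = character(), region = character(),
                     target_mm3 = numeric(), realized_mm3 = numeric())
    out
  })
}
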