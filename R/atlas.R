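#' Atlas parcellations
#'
#' A `tbq_atlas` assigns every voxel of the head to one of 11 named regions
#' (four lobes, five deep grey structures, the rest of the brain -- mainly
#' the ventricles -- and the extra-cerebral space); 0 marks voxels outside
#' the head. Region codes 1-11 follow [atlas_region_names()].
#'
#' @param grid 3D integer array of region codes in 0..11.
#' @param spacing Voxel size (mm), length 3, strictly positive.
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return A `tbq_atlas`.
#' @export
atlas_parcellation <- function(grid, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(length(dim(grid)) == 3L)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (!is.integer(grid)) {
    if (any(grid != round(grid))) stop("atlas grid contains non-integer values")
    storage.mode(grid) <- "integer"
  }
  if (any(grid < 0L) || any(grid > 11L)) stop("atlas codes must lie in 0..11")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(
    list(grid = grid, spacing = spacing, affine = affine,
         regions = atlas_region_names()),
    class = "tbq_atlas"
  )
}

#' @export
print.tbq_atlas <- function(x, ...) {
  cat(
    "<atlas parcellation> ", paste(dim(x$grid), collapse = "x"),
    " voxels @ ", paste(signif(x$spacing, 3), collapse = "x"),
    " mm, ", length(unique(x$grid[x$grid != 0L])), " regions present\n",
    sep = ""
  )
  invisible(x)
}

# error unless a segmentation and an atlas share grid shape and spacing;
# registration is deliberately out of scope, so mismatches are never resampled
# silently.
#' @noRd
check_same_grid <- function(a, b) {
  if (!identical(dim(a$grid), dim(b$grid))) {
    stop("grid shape mismatch: ", paste(dim(a$grid), collapse = "x"), " vs ",
         paste(dim(b$grid), collapse = "x"),
         " (volumes must be registered to a common grid upstream)")
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-6) {
    stop("voxel spacing mismatch between paired volumes")
  }
  invisible(TRUE)
}

#' Generate a synthetic 11-region atlas
#'
#' Builds an ellipsoidal head inside `shape`: an outer shell is the
#' extra-cerebral space, a small central ellipsoid is the rest-of-brain
#' compartment (standing in for the ventricles and unlabelled parenchyma),
#' and the remaining brain tissue is partitioned into the four lobes,
#' caudate, cerebellum, insula, putamen and thalamus by a Voronoi tessellation
#' around anatomically placed, seed-jittered generator points. All 11 regions
#' are guaranteed nonempty; the result is deterministic given `seed`.
#'
#' @param shape Integer length-3 grid dimensions, each >= 32.
#' @param seed Integer RNG seed.
#' @param spacing Voxel size, mm.
#' @return A `tbq_atlas`.
#' @examples
#' atl <- generate_atlas(c(48, 48, 48), seed = 1)
#' table(atl$grid[atl$grid != 0])
#' @export
generate_atlas <- function(shape, seed = 1L, spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L)) {
    stop("shape must have 3 dimensions, each >= 32, to hold 11 nonempty regions")
  }
  with_seed(seed, {
    ctr <- (shape + 1) / 2
    semi_head <- 0.46 * shape
    semi_brain <- 0.85 * semi_head
    # normalised squared radii
    x <- (seq_len(shape[1L]) - ctr[1L])
    y <- (seq_len(shape[2L]) - ctr[2L])
    z <- (seq_len(shape[3L]) - ctr[3L])
    r2 <- function(semi) {
      outer(outer((x / semi[1L])^2, (y / semi[2L])^2, `+`), (z / semi[3L])^2, `+`)
    }
    in_head <- r2(semi_head) <= 1
    in_brain <- r2(semi_brain) <= 1
    in_vent <- r2(semi_brain * c(0.16, 0.32, 0.16)) <= 1

    grid <- array(0L, shape)
    grid[in_head] <- 11L                      # extra-cerebral space
    grid[in_brain] <- 10L                     # rest-of-brain, refined below

    # generator points for the 9 named structures, in brain-normalised coords
    # (x: left-right, y: posterior-anterior, z: inferior-superior)
    pts <- rbind(
      `Frontal Lobe`   = c(0.00,  0.55,  0.30),
      `Parietal Lobe`  = c(0.00, -0.15,  0.65),
      `Occipital Lobe` = c(0.00, -0.65,  0.15),
      `Temporal Lobe`  = c(0.60,  0.10, -0.25),
      Caudate          = c(0.15,  0.22,  0.12),
      Cerebellum       = c(0.00, -0.50, -0.55),
      Insula           = c(0.45,  0.12,  0.00),
      Putamen          = c(0.30,  0.08, -0.02),
      Thalamus         = c(0.10, -0.12,  0.05)
    )
    pts <- pts + matrix(stats::runif(length(pts), -0.04, 0.04), nrow(pts), 3L)

    tissue <- which(in_brain & !in_vent)
    ai <- arrayInd(tissue, shape)
    # normalised coordinates of tissue voxels
    nc <- cbind(
      (ai[, 1L] - ctr[1L]) / semi_brain[1L],
      (ai[, 2L] - ctr[2L]) / semi_brain[2L],
      (ai[, 3L] - ctr[3L]) / semi_brain[3L]
    )
    d2 <- matrix(0, length(tissue), nrow(pts))
    for (k in seq_len(nrow(pts))) {
      d2[, k] <- (nc[, 1L] - pts[k, 1L])^2 + (nc[, 2L] - pts[k, 2L])^2 +
        (nc[, 3L] - pts[k, 3L])^2
    }
    grid[tissue] <- max.col(-d2, ties.method = "first")

    present <- sort(unique(grid[grid != 0L]))
    if (!identical(present, 1:11)) {
      stop("shape too small to realise 11 nonempty regions (got ",
           length(present), ")")
    }
    atlas_parcellation(grid, spacing = spacing)
  })
}

#' @rdname read_label_volume
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  atlas_parcellation(array(as.integer(as.vector(img)), dim(img)),
                     spacing = RNifti::pixdim(img))
}

#' @rdname read_label_volume
#' @param atlas A `tbq_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  img <- RNifti::asNifti(atlas$grid)
  RNifti::pixdim(img) <- atlas$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
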