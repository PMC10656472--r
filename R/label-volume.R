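#' Multiclass lesion label volumes
#'
#' A `tbq_label_volume` wraps a 3D integer grid of lesion class codes together
#' with its voxel spacing (mm), a voxel-to-world affine (RAS+, NIfTI
#' convention) and the label scheme the codes refer to. Every nonzero code in
#' the grid must appear in the scheme; 0 is background.
#'
#' @param grid 3D integer array of class codes.
#' @param spacing Numeric length-3 voxel size in mm, strictly positive.
#' @param scheme A [label_scheme()].
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to
#'   `diag(c(spacing, 1))`.
#' @return A `tbq_label_volume`.
#' @examples
#' g <- array(0L, c(8, 8, 8)); g[3:4, 3:4, 3:4] <- 1L
#' label_volume(g, c(1, 1, 1), scheme_seven())
#' @export
label_volume <- function(grid, spacing = c(1, 1, 1), scheme = scheme_seven(),
                         affine = NULL) {
  stopifnot(length(dim(grid)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive values (mm)")
  }
  if (!is.integer(grid)) {
    if (any(grid != round(grid))) stop("label grid contains non-integer values")
    storage.mode(grid) <- "integer"
  }
  present <- sort(unique(grid[grid != 0L]))
  bad <- setdiff(present, scheme$codes)
  if (length(bad)) {
    counts <- vapply(bad, function(b) sum(grid == b), integer(1))
    stop(
      "label codes not in scheme '", scheme$name, "': ",
      paste0(bad, " (", counts, " voxels)", collapse = ", ")
    )
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(
    list(grid = grid, spacing = spacing, affine = affine, scheme = scheme),
    class = "tbq_label_volume"
  )
}

#' @export
print.tbq_label_volume <- function(x, ...) {
  cat(
    "<label volume> ", paste(dim(x$grid), collapse = "x"),
    " voxels @ ", paste(signif(x$spacing, 3), collapse = "x"),
    " mm, scheme '", x$scheme$name, "', ",
    sum(x$grid != 0L), " lesion voxels\n",
    sep = ""
  )
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param vol A `tbq_label_volume` or `tbq_atlas`.
#' @return Scalar mm^3 per voxel.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Read and write label volumes as NIfTI
#'
#' Volumes travel as `.nii`/`.nii.gz` with a JSON sidecar (`<path>.json`)
#' recording the scheme name and class table, so that integer codes stay
#' interpretable outside the package. `read_label_volume()` validates the data
#' on the way in: non-integer voxel data and codes absent from the scheme are
#' errors (the offender reported with its voxel count).
#'
#' @param path File path to a NIfTI image.
#' @param scheme Scheme to validate against; if `NULL`, the sidecar's scheme
#'   is used (an error if neither is available).
#' @return `read_label_volume()` a `tbq_label_volume`; `write_label_volume()`
#'   the path, invisibly.
#' @export
read_label_volume <- function(path, scheme = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (is.null(scheme)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("no scheme given and no sidecar found at ", sidecar)
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    scheme <- label_scheme(meta$scheme$name, meta$scheme$codes, meta$scheme$labels)
    if (identical(scheme$name, "seven")) scheme <- scheme_seven()
    if (identical(scheme$name, "four")) scheme <- scheme_four()
  }
  if (length(dim(img)) != 3L) stop("expected a 3D image, got ", length(dim(img)), "D")
  vals <- as.vector(img)
  if (any(vals != round(vals))) stop("label image contains non-integer data")
  grid <- array(as.integer(vals), dim(img))
  label_volume(grid, spacing = RNifti::pixdim(img), scheme = scheme,
               affine = unclass(RNifti::xform(img)))
}

#' @rdname read_label_volume
#' @param vol A `tbq_label_volume`.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(scheme = list(name = vol$scheme$name, codes = vol$scheme$codes,
                       labels = vol$scheme$labels)),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' Merge a label volume onto a coarser scheme
#'
#' Voxelwise recoding through the merge map between the two schemes (e.g.
#' 7-class to 4-class sends SDH/EDH/SAH to EAH and Pe to IPH), or onto the
#' single-class "All" scheme representing lesional tissue of any type.
#' Background stays background and the set of nonzero voxels is unchanged.
#'
#' @param vol A `tbq_label_volume`.
#' @param target Target `tbq_scheme` (must be reachable via a merge map, or
#'   be the "All" scheme).
#' @return A `tbq_label_volume` on the target scheme.
#' @export
merge_classes <- function(vol, target) {
  m <- merge_map(vol$scheme, target)
  lut <- integer(max(vol$scheme$codes) + 1L) # 0 -> 0
  lut[as.integer(names(m)) + 1L] <- as.integer(m)
  grid <- array(lut[vol$grid + 1L], dim(vol$grid))
  label_volume(grid, spacing = vol$spacing, scheme = target, affine = vol$affine)
}

#' Resample a label volume to an isotropic grid
#'
#' Nearest-neighbour resampling of label codes onto an isotropic grid at
#' `target_spacing` mm, matching the preprocessing convention of resampling
#' CT label maps to 1 mm^3. The label set of the output is always a subset of
#' the input's; a volume already at the target spacing comes back unchanged.
#'
#' @param vol A `tbq_label_volume`.
#' @param target_spacing Positive scalar, mm.
#' @return A `tbq_label_volume` at isotropic spacing.
#' @export
resample_iso <- function(vol, target_spacing = 1) {
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      !is.finite(target_spacing) || target_spacing <= 0) {
    stop("target_spacing must be a positive scalar (mm)")
  }
  if (all(vol$spacing == target_spacing)) return(vol)
  dm <- dim(vol$grid)
  idx <- lapply(1:3, function(ax) {
    n_out <- max(1L, as.integer(round(dm[ax] * vol$spacing[ax] / target_spacing)))
    centers <- (seq_len(n_out) - 0.5) * target_spacing # world coord along axis
    src <- ceiling(centers / vol$spacing[ax])
    pmin(pmax(src, 1L), dm[ax])
  })
  grid <- vol$grid[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  label_volume(grid, spacing = rep(target_spacing, 3), scheme = vol$scheme)
}
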