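# Low-level 3D grid helpers shared by the atlas generator, the lesion grower,
# the segmentation degrader and the resampler. All masks are logical arrays,
# all voxel sets are 1-based linear indices into the array.

#' @noRd
lin_index <- function(ijk, dm) {
  (ijk[, 1L] - 1L) + (ijk[, 2L] - 1L) * dm[1L] + (ijk[, 3L] - 1L) * dm[1L] * dm[2L] + 1L
}

# 6-connected neighbours of a set of linear indices, out-of-bounds dropped.
#' @noRd
neighbors6 <- function(idx, dm) {
  ai <- arrayInd(idx, dm)
  out <- vector("list", 6L)
  k <- 0L
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      k <- k + 1L
      ni <- ai
      ni[, ax] <- ni[, ax] + s
      ok <- ni[, ax] >= 1L & ni[, ax] <= dm[ax]
      out[[k]] <- lin_index(ni[ok, , drop = FALSE], dm)
    }
  }
  unlist(out, use.names = FALSE)
}

# Zero-padded shift of a logical array by one voxel along one axis.
#' @noRd
shift1 <- function(a, ax, s) {
  dm <- dim(a)
  out <- array(FALSE, dm)
  n <- dm[ax]
  if (n <= 1L) return(out)
  src <- if (s > 0) 1:(n - 1L) else 2:n
  dst <- if (s > 0) 2:n else 1:(n - 1L)
  ix <- list(seq_len(dm[1L]), seq_len(dm[2L]), seq_len(dm[3L]))
  jx <- ix
  ix[[ax]] <- dst
  jx[[ax]] <- src
  out[ix[[1L]], ix[[2L]], ix[[3L]]] <- a[jx[[1L]], jx[[2L]], jx[[3L]]]
  out
}

# One pass of 6-connected binary erosion (voxels keeping all 6 neighbours inside).
#' @noRd
erode_once <- function(mask) {
  out <- mask
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) out <- out & shift1(mask, ax, s)
  }
  out
}

# Depth of each voxel from the mask boundary: 1 on the outermost shell,
# increasing inwards, 0 outside the mask.
#' @noRd
boundary_depth <- function(mask) {
  depth <- array(0L, dim(mask))
  cur <- mask
  d <- 0L
  while (any(cur)) {
    d <- d + 1L
    depth[cur] <- d
    cur <- erode_once(cur)
  }
  depth
}

# Seeded breadth-first growth of a connected blob of ~target_n voxels inside
# `allowed`. Frontier additions are shuffled so blobs stay roughly isotropic.
# Returns linear indices; may return fewer than target_n if the region fills up.
#' @noRd
grow_blob <- function(allowed, start, target_n, dm = dim(allowed)) {
  sel <- logical(length(allowed))
  sel[start] <- TRUE
  n <- 1L
  frontier <- start
  while (n < target_n && length(frontier)) {
    nb <- unique(neighbors6(frontier, dm))
    nb <- nb[allowed[nb] & !sel[nb]]
    if (!length(nb)) break
    if (length(nb) > 1L) nb <- nb[sample.int(length(nb))]
    if (n + length(nb) > target_n) nb <- nb[seq_len(target_n - n)]
    sel[nb] <- TRUE
    n <- n + length(nb)
    frontier <- nb
  }
  which(sel)
}

# 6-connected component labelling of a logical mask. Returns an integer array,
# 0 outside the mask, components numbered from 1.
#' @noRd
label_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  todo <- which(mask)
  comp <- 0L
  while (length(todo)) {
    comp <- comp + 1L
    frontier <- todo[1L]
    lab[frontier] <- comp
    while (length(frontier)) {
      nb <- unique(neighbors6(frontier, dm))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- comp
      frontier <- nb
    }
    todo <- todo[lab[todo] == 0L]
  }
  lab
}

# Evaluate an expression with a private, restorable RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
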