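# Label volumes: NIfTI round-trips, validation, class merging, resampling.

test_that("label volumes round-trip through NIfTI exactly", {
  set.seed(1)
  for (scheme in list(scheme_seven(), scheme_four())) {
    v <- random_label_volume(c(10L, 12L, 8L), scheme = scheme)
    f <- withr::local_tempfile(fileext = ".nii.gz")
    write_label_volume(v, f)
    r <- read_label_volume(f, scheme = scheme)
    expect_identical(r$grid, v$grid)
    expect_equal(r$spacing, v$spacing)
    # sidecar alone is enough to reconstruct the scheme
    r2 <- read_label_volume(f)
    expect_identical(r2$scheme$labels, scheme$labels)
  }
  # background-only volume is valid with an empty lesion set
  z <- label_volume(array(0L, c(8, 8, 8)))
  expect_equal(sum(z$grid), 0)
})

test_that("validation rejects out-of-scheme codes and non-integer data", {
  g <- array(0L, c(6, 6, 6))
  g[1:3] <- 9L
  expect_error(label_volume(g, scheme = scheme_seven()), "9 \\(3 voxels\\)")
  expect_error(label_volume(array(0.5, c(4, 4, 4))), "non-integer")
  expect_error(label_volume(array(0L, c(4, 4, 4)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(read_label_volume(tempfile()), "no such file")
  # a file written with an alien code fails on read under the 7-class scheme
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(g)
  RNifti::writeNifti(img, f)
  expect_error(read_label_volume(f, scheme = scheme_seven()), "9")
})

test_that("merging classes follows the 7-to-4 map and conserves lesion voxels", {
  g <- array(0L, c(8, 8, 8))
  g[1] <- 2L # SDH
  g[2] <- 4L # SAH
  v <- label_volume(g, scheme = scheme_seven())
  m <- merge_classes(v, scheme_four())
  expect_equal(sum(m$grid == 2L), 2) # both became EAH
  expect_identical(which(m$grid != 0L), which(v$grid != 0L))

  # merge to "All" gives a binary mask with identical support
  a <- merge_classes(v, scheme_all())
  expect_setequal(unique(as.vector(a$grid)), c(0L, 1L))
  expect_identical(a$grid != 0L, v$grid != 0L)

  # nonzero voxel count conserved on random volumes (brute-force voxel loop)
  set.seed(2)
  for (i in 1:5) {
    v <- random_label_volume()
    m <- merge_classes(v, scheme_four())
    lut <- merge_map(scheme_seven(), scheme_four())
    expected <- vapply(seq_along(v$grid), function(j) {
      if (v$grid[j] == 0L) 0L else unname(lut[as.character(v$grid[j])])
    }, integer(1))
    expect_identical(as.vector(m$grid), expected)
  }

  # composition: 7 -> 4 -> All equals direct 7 -> All
  v <- random_label_volume()
  expect_identical(
    merge_classes(merge_classes(v, scheme_four()), scheme_all())$grid,
    merge_classes(v, scheme_all())$grid
  )
  expect_error(merge_classes(merge_classes(v, scheme_all()), scheme_four()),
               "no merge map")
})

test_that("nearest-neighbour resampling preserves labels and volume", {
  # identity resample
  v <- random_label_volume(c(10L, 10L, 10L))
  expect_identical(resample_iso(v, 1)$grid, v$grid)

  # a 2 mm cube of 10^3 lesion voxels is 8000 mm^3; at 1 mm it stays within
  # one voxel-shell of that
  g <- array(0L, c(16, 16, 16))
  g[4:13, 4:13, 4:13] <- 1L
  v2 <- label_volume(g, spacing = c(2, 2, 2))
  r <- resample_iso(v2, 1)
  vol <- sum(r$grid != 0L) * 1
  shell <- 6 * 20^2 + 12 * 20 + 8 # one-voxel shell of a 20-cube
  expect_lte(abs(vol - 8000), shell)
  expect_equal(dim(r$grid), c(32L, 32L, 32L))

  # no new label codes appear on random volumes
  set.seed(3)
  for (sp in c(0.5, 2, 3)) {
    v <- random_label_volume(c(9L, 9L, 9L))
    r <- resample_iso(v, sp)
    expect_true(all(unique(as.vector(r$grid)) %in% unique(as.vector(v$grid))))
  }
  expect_error(resample_iso(v, -1), "positive")
})
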