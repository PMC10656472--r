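# Regional volume quantification and the seven experiment feature sets.

test_that("a lesion confined to one region lands in exactly one cell", {
  atl <- small_atlas()
  vox <- which(atl$grid == 1L)[1:300] # 300 voxels of Frontal Lobe
  g <- array(0L, dim(atl$grid))
  g[vox] <- 1L # IPH
  q <- region_lesion_volumes(label_volume(g), atl)
  expect_equal(q$volume_mm3[q$class == "IPH" & q$region == "Frontal Lobe"], 300)
  expect_equal(sum(q$volume_mm3), 300)

  # empty segmentation gives the all-zero table
  q0 <- region_lesion_volumes(label_volume(array(0L, dim(atl$grid))), atl)
  expect_true(all(q0$volume_mm3 == 0))
  expect_equal(nrow(q0), 77)
})

test_that("the volume table matches a brute-force per-voxel census", {
  atl <- small_atlas()
  set.seed(31)
  seg <- random_label_volume(dim(atl$grid), p_lesion = 0.05)
  q <- suppressWarnings(region_lesion_volumes(seg, atl))
  expect_equal(sum(q$volume_mm3), sum(seg$grid != 0L) * voxel_volume(seg))
  # per-cell check against an explicit voxel loop
  for (cc in c(1L, 4L, 7L)) {
    for (rr in c(1L, 10L, 11L)) {
      expected <- sum(seg$grid == cc & atl$grid == rr) * voxel_volume(seg)
      got <- q$volume_mm3[q$class == seg$scheme$labels[cc] &
                            q$region == atl$regions[rr]]
      expect_equal(got, expected)
    }
  }
  # spill: random labels cover atlas code 0, so the unassigned rows + warning
  expect_warning(region_lesion_volumes(seg, atl), "outside the atlas")
  spill <- q$volume_mm3[q$region == "(unassigned)"]
  expect_equal(sum(spill),
               sum(seg$grid != 0L & atl$grid == 0L) * voxel_volume(seg))
  expect_error(
    region_lesion_volumes(random_label_volume(c(8L, 8L, 8L)), atl),
    "mismatch"
  )
})

test_that("merging and quantification commute", {
  atl <- small_atlas()
  seg <- generate_lesions(atl, seed = 32)
  q7 <- region_lesion_volumes(seg, atl)
  route_a <- merge_quant(q7, scheme_four())
  route_b <- region_lesion_volumes(merge_classes(seg, scheme_four()), atl)
  expect_equal(route_a$volume_mm3, route_b$volume_mm3)
  expect_equal(route_a$class, route_b$class)
})

test_that("translation within a region leaves the table unchanged", {
  atl <- small_atlas()
  inside <- which(atl$grid == 1L & shift1(atl$grid == 1L, 1L, -1L))
  vox <- inside[1:40]
  ai <- arrayInd(vox, dim(atl$grid))
  ai[, 1L] <- ai[, 1L] + 1L # translated copy, still in Frontal Lobe
  g1 <- array(0L, dim(atl$grid)); g1[vox] <- 1L
  g2 <- array(0L, dim(atl$grid)); g2[lin_index(ai, dim(atl$grid))] <- 1L
  q1 <- region_lesion_volumes(label_volume(g1), atl)
  q2 <- region_lesion_volumes(label_volume(g2), atl)
  expect_equal(q1$volume_mm3, q2$volume_mm3)
})

test_that("the seven experiments have their prescribed metric counts", {
  atl <- small_atlas()
  seg <- generate_lesions(atl, seed = 33)
  q7 <- region_lesion_volumes(seg, atl)
  q4 <- merge_quant(q7, scheme_four())
  clin <- list(age = 50, gcs = 7, map = 90, hb = 120, antiaggregants = 0)
  scores <- list(marshall = marshall(ct_findings()), rotterdam = 3)

  counts7 <- c(Exp1 = 5, Exp2 = 7, Exp3 = 1, Exp4 = 7, Exp5 = 11, Exp6 = 18, Exp7 = 77)
  counts4 <- c(Exp1 = 5, Exp2 = 7, Exp3 = 1, Exp4 = 4, Exp5 = 11, Exp6 = 15, Exp7 = 44)
  for (e in names(counts7)) {
    f7 <- build_features(q7, clinical = clin, scores = scores, exp = e)
    f4 <- build_features(q4, clinical = clin, scores = scores, exp = e)
    expect_length(f7, counts7[[e]])
    expect_length(f4, counts4[[e]])
    expect_equal(experiment_spec(e, "seven")$n_metrics, unname(counts7[[e]]))
    expect_equal(experiment_spec(e, "four")$n_metrics, unname(counts4[[e]]))
  }

  # marginal-sum identity: Exp4 and Exp5 both sum to the Exp3 scalar
  expect_equal(sum(build_features(q7, exp = "Exp4")),
               unname(build_features(q7, exp = "Exp3")))
  expect_equal(sum(build_features(q7, exp = "Exp5")),
               unname(build_features(q7, exp = "Exp3")))

  # fixed class-major feature order on Exp7
  f7 <- build_features(q7, exp = "Exp7")
  expect_identical(names(f7)[1:2], c("IPH:Frontal Lobe", "IPH:Parietal Lobe"))
  expect_identical(names(f7)[12], "SDH:Frontal Lobe")

  expect_error(build_features(q7, clinical = list(age = 1), exp = "Exp1"),
               "gcs")
  expect_error(build_features(clinical = clin, exp = "Exp3"), "quantification")
})
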