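# Synthetic atlas, lesion generation and the segmentation degrader.

test_that("the generated atlas has 11 nonempty regions and is deterministic", {
  atl <- generate_atlas(c(48, 48, 48), seed = 1)
  counts <- table(atl$grid[atl$grid != 0L])
  expect_identical(sort(as.integer(names(counts))), 1:11)
  expect_true(all(counts >= 1))
  # region voxel counts partition the head exactly
  expect_equal(sum(counts), sum(atl$grid != 0L))
  atl2 <- generate_atlas(c(48, 48, 48), seed = 1)
  expect_identical(atl$grid, atl2$grid)
  expect_false(identical(atl$grid, generate_atlas(c(48, 48, 48), seed = 2)$grid))
  expect_error(generate_atlas(c(16, 16, 16), seed = 1), "32")
})

test_that("lesion generation respects prevalence and placement weights", {
  atl <- small_atlas()
  empty <- lesion_gen_spec(prevalence = c(IPH = 0, SDH = 0, EDH = 0, SAH = 0,
                                          Pe = 0, Od = 0, IVH = 0))
  v <- generate_lesions(atl, empty, seed = 1)
  expect_equal(sum(v$grid), 0)

  # IVH fully weighted on Rest-of-brain never escapes that region
  ivh_only <- lesion_gen_spec(
    prevalence = c(IPH = 0, SDH = 0, EDH = 0, SAH = 0, Pe = 0, Od = 0, IVH = 1),
    region_weights = list(IVH = c(rep(0, 9), 1, 0)),
    vol_median_mm3 = c(IVH = 200)
  )
  for (s in 1:5) {
    v <- generate_lesions(atl, ivh_only, seed = s)
    lesioned <- which(v$grid != 0L)
    expect_gt(length(lesioned), 0)
    expect_true(all(atl$grid[lesioned] == 10L))
    expect_true(all(v$grid[lesioned] == 7L))
  }

  expect_identical(generate_lesions(atl, seed = 9)$grid,
                   generate_lesions(atl, seed = 9)$grid)
})

test_that("realized lesion volumes follow the log-normal target", {
  atl <- small_atlas(c(48L, 48L, 48L), seed = 3L)
  spec <- lesion_gen_spec(
    prevalence = c(IPH = 0, SDH = 1, EDH = 0, SAH = 0, Pe = 0, Od = 0, IVH = 0),
    vol_median_mm3 = c(SDH = 1200), vol_log_sd = c(SDH = 0.5)
  )
  vols <- vapply(1:200, function(s) {
    v <- suppressWarnings(generate_lesions(atl, spec, seed = s))
    sum(v$grid != 0L) * voxel_volume(v)
  }, numeric(1))
  # median of 200 log-normal draws (log-sd 0.5): ~±10% sampling error
  expect_gt(stats::median(vols) / 1200, 0.82)
  expect_lt(stats::median(vols) / 1200, 1.22)
})

test_that("the degrader hits its target Dice and confusion spares the All mask", {
  atl <- small_atlas()
  truth <- generate_lesions(atl, seed = 4)

  identity <- degrade_segmentation(truth, 1.0, fp_fraction = 0)
  expect_identical(identity$grid, truth$grid)
  expect_error(
    degrade_segmentation(truth, 1.0, confusion = list(SDH = c(EDH = 0.5))),
    "unreachable"
  )

  for (td in c(0.3, 0.5, 0.8)) {
    deg <- degrade_segmentation(truth, td, seed = 5)
    rep <- dice_report(deg, truth)
    measured <- rep$dice[rep$class == "All"]
    expect_gte(measured, td - 0.05)
    expect_lte(measured, td + 0.05)
  }

  # relabelling within lesion classes cannot change the overall Dice
  spec <- lesion_gen_spec(prevalence = c(SDH = 1))
  truth2 <- suppressWarnings(generate_lesions(atl, spec, seed = 6))
  base <- degrade_segmentation(truth2, 0.7, seed = 7)
  conf <- degrade_segmentation(truth2, 0.7, seed = 7,
                               confusion = list(SDH = c(EDH = 0.5)))
  r_base <- dice_report(base, truth2)
  r_conf <- dice_report(conf, truth2)
  expect_equal(r_conf$dice[r_conf$class == "All"],
               r_base$dice[r_base$class == "All"])
  expect_lt(r_conf$dice[r_conf$class == "SDH"],
            r_base$dice[r_base$class == "SDH"])
})
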