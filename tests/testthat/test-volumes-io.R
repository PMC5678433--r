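# NIfTI IO, region schemes and volumetrics.

test_that("label volumes round-trip through NIfTI", {
  lv <- small_folded_lv(a = 1)
  f <- tempfile(fileext = ".nii.gz")
  write_label_volume(lv, f)
  back <- read_label_volume(f)
  expect_identical(back$voxels, lv$voxels)
  expect_equal(back$spacing_mm, lv$spacing_mm)
})

test_that("float-stored integral data are accepted, non-integer rejected", {
  arr <- array(0, c(6, 6, 6))
  arr[3:4, 3:4, 3:4] <- 2
  f <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(arr)  # double storage
  RNifti::writeNifti(img, f, datatype = "float")
  lv <- read_label_volume(f)
  expect_identical(unique(as.vector(lv$voxels)), c(0L, 2L))

  arr[2, 2, 2] <- 0.5
  RNifti::writeNifti(RNifti::asNifti(arr), f, datatype = "float")
  expect_error(read_label_volume(f), "non-integer")
})

test_that("4D and missing inputs are rejected with clear messages", {
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1L, c(4, 4, 4, 3))), f)
  expect_error(read_label_volume(f), "4D|3D")
  expect_error(read_label_volume(tempfile()), "no such file")
})

test_that("region scheme round-trips through CSV and validates", {
  sc <- phantom_region_scheme()
  f <- tempfile(fileext = ".csv")
  write_region_scheme(sc, f)
  back <- read_region_scheme(f)
  expect_equal(as.data.frame(back), as.data.frame(sc))
  expect_error(region_scheme(1, "cortex", "frontal"), "tissue")
  expect_error(region_scheme(c(1, 1), c("cGM", "WM"), c("frontal", "none")),
               "duplicate")
})

test_that("tissue volumes count voxels in physical units", {
  arr <- array(0L, c(20, 20, 20))
  arr[1:10, 1:10, 1:10] <- 1L  # 1000 voxels
  lv <- label_volume(arr, c(1, 1, 1))
  sc <- region_scheme(1, "cGM", "frontal")
  vols <- tissue_volumes(lv, sc)
  expect_equal(vols$volume_ml[vols$region == "cortical_grey_matter"], 1.000)
  # empty regions report 0 ml without error
  expect_equal(vols$volume_ml[vols$region == "cerebellum"], 0)
  # anisotropic spacing: voxel volume is the product of spacings
  lv2 <- label_volume(arr, c(0.5, 1, 2))
  expect_equal(tissue_volumes(lv2, sc)$volume_ml[2], 1.000)
})

test_that("whole-brain volume of the phantom matches the analytic solid", {
  lv <- small_folded_lv(a = 0)
  vols <- tissue_volumes(lv, phantom_region_scheme())
  wb <- vols$volume_ml[vols$region == "whole_brain"]
  expect_equal(wb, 4 / 3 * pi * 30^3 / 1000, tolerance = 0.02)
})

test_that("volumes agree with a brute-force label histogram", {
  lv <- small_folded_lv(a = 2)
  sc <- phantom_region_scheme()
  vols <- tissue_volumes(lv, sc)
  counts <- table(factor(as.vector(lv$voxels), levels = 0:8))
  vv <- prod(lv$spacing_mm) / 1000
  expect_equal(vols$volume_ml[vols$region == "cortical_grey_matter"],
               sum(counts[as.character(1:4)]) * vv)
  # additivity: lobar cGM volumes sum exactly to total cGM
  lobar <- vols$volume_ml[grepl("_grey_matter$", vols$region) &
                          vols$region != "cortical_grey_matter"]
  expect_identical(sum(lobar), vols$volume_ml[vols$region == "cortical_grey_matter"])
})

test_that("unmapped labels are reported by name", {
  arr <- array(0L, c(4, 4, 4))
  arr[2, 2, 2] <- 9L
  lv <- label_volume(arr, c(1, 1, 1))
  expect_error(tissue_volumes(lv, phantom_region_scheme()), "9")
})

test_that("combine_regions: additivity, monotonicity, partition", {
  lv <- small_folded_lv(a = 2)
  sc <- phantom_region_scheme()
  all_mask <- combine_regions(lv, sc, c("cGM", "WM"))
  cgm <- combine_regions(lv, sc, "cGM")
  wm <- combine_regions(lv, sc, "WM")
  expect_equal(sum(all_mask), sum(cgm) + sum(wm))

  fr <- combine_regions(lv, sc, "cGM", "frontal")
  expect_true(all(cgm[fr]))

  lobes <- c("frontal", "parietal", "temporal", "occipital")
  masks <- lapply(lobes, function(lb) combine_regions(lv, sc, c("cGM", "WM"), lb))
  expect_equal(Reduce(`+`, lapply(masks, sum)), sum(all_mask))
  for (i in 1:3) {
    for (j in (i + 1):4) expect_false(any(masks[[i]] & masks[[j]]))
  }
  expect_error(combine_regions(lv, sc, character(0)), "empty selection")
})
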