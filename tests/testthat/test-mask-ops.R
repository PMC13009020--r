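slab_masks <- function() {
  breast <- array(0L, dim = c(10, 4, 4)); breast[1:10, 2:3, 2:3] <- 1L
  fgt <- breast
  mask_set(breast, fgt)
}

test_that("laterality split divides a slab at the bounding-box midpoint", {
  lat <- split_laterality(slab_masks(), axis = 1)
  # coordinates 1..10, midpoint 5.5: 1-5 lower-index side, 6-10 other
  expect_equal(sum(lat$left), 5 * 4)
  expect_equal(sum(lat$right), 5 * 4)
  expect_true(all(which(lat$left == 1L, arr.ind = TRUE)[, 1] <= 5))
  expect_true(all(which(lat$right == 1L, arr.ind = TRUE)[, 1] >= 6))
})

test_that("midpoint voxels go to the lower-index side", {
  breast <- array(0L, dim = c(9, 3, 3)); breast[1:9, 2, 2] <- 1L  # midpoint 5
  lat <- split_laterality(mask_set(breast, breast), axis = 1)
  expect_equal(sum(lat$left), 5)   # coords 1..5 inclusive of the midpoint
  expect_equal(sum(lat$right), 4)
})

test_that("disjoint ellipsoids land wholly on one side each and sides partition the breast", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  lat <- split_laterality(ph$masks)
  expect_equal(sum(lat$left), ph$truth$per_side$left$n_breast)
  expect_equal(sum(lat$right), ph$truth$per_side$right$n_breast)
  # partition property
  expect_identical(array(as.integer(lat$left | lat$right), dim = dim(lat$left)),
                   ph$masks$breast)
  expect_equal(sum(lat$left * lat$right), 0)
  expect_error(split_laterality(mask_set(array(0L, dim = c(4, 4, 4)),
                                         array(0L, dim = c(4, 4, 4)))),
               "empty breast")
})

test_that("contralateral selection follows the tumor: unilateral, bilateral, tie", {
  ms <- slab_masks()
  # tumor only on the right half
  tum <- array(0L, dim = c(10, 4, 4)); tum[8, 2, 2] <- 1L
  lat <- split_laterality(mask_set(ms$breast, ms$fgt, tum))
  expect_equal(select_analysis_side(lat, "contralateral")$analysis_side, "left")
  expect_equal(select_analysis_side(lat, "ipsilateral")$analysis_side, "right")
  # bilateral: smaller tumor volume wins (left 1 voxel, right 3)
  tum2 <- tum; tum2[8, 2, 3] <- 1L; tum2[8, 3, 2] <- 1L; tum2[2, 2, 2] <- 1L
  lat2 <- split_laterality(mask_set(ms$breast, ms$fgt, tum2))
  expect_equal(select_analysis_side(lat2, "contralateral")$analysis_side, "left")
  # exact tie: lower-index side, with a warning
  tum3 <- array(0L, dim = c(10, 4, 4)); tum3[2, 2, 2] <- 1L; tum3[8, 2, 2] <- 1L
  lat3 <- split_laterality(mask_set(ms$breast, ms$fgt, tum3))
  expect_warning(sel <- select_analysis_side(lat3, "contralateral"), "tie|equal")
  expect_equal(sel$analysis_side, "left")
})

test_that("tumor-free studies pick the larger-FGT side; modes are complementary", {
  breast <- array(0L, dim = c(10, 4, 4)); breast[1:10, 2:3, 2:3] <- 1L
  fgt <- array(0L, dim = c(10, 4, 4)); fgt[6:10, 2:3, 2:3] <- 1L  # FGT only right
  lat <- split_laterality(mask_set(breast, fgt))
  expect_message(sel <- select_analysis_side(lat, "contralateral"), "tumor-free")
  expect_equal(sel$analysis_side, "right")
  sel_ipsi <- suppressMessages(select_analysis_side(lat, "ipsilateral"))
  expect_false(sel$analysis_side == sel_ipsi$analysis_side)
})

test_that("FGT refinement subtracts the tumor and matches a voxel count oracle", {
  set.seed(42)
  dims <- c(8, 8, 8)
  breast <- array(1L, dim = dims)
  fgt <- array(0L, dim = dims)
  fgt[sample(prod(dims), 100)] <- 1L
  tum <- array(0L, dim = dims)
  tum[sample(which(fgt == 1L), 30)] <- 1L  # 30 overlap voxels
  ms <- refine_fgt(mask_set(breast, fgt, tum))
  expect_equal(sum(ms$refined_fgt), 70)
  expect_true(all(ms$refined_fgt <= fgt))
  expect_equal(sum(ms$refined_fgt * tum), 0)
  # disjoint tumor: identity
  tum2 <- array(0L, dim = dims); tum2[which(fgt == 0L)[1:10]] <- 1L
  expect_identical(refine_fgt(mask_set(breast, fgt, tum2))$refined_fgt, fgt)
  # tumor covering all FGT: empty result is legal
  expect_message(ms3 <- refine_fgt(mask_set(breast, fgt, fgt)), "empty")
  expect_equal(sum(ms3$refined_fgt), 0)
})

test_that("refinement is idempotent and monotone in the dilation margin", {
  ph <- generate_phantom(phantom_spec(seed = 9,
    tumor_spec = list(side = "right", center = c(24, 12, 8), radius = 3,
                      amplitude = 120)))
  m0 <- refine_fgt(ph$masks, margin_mm = 0)
  expect_identical(refine_fgt(m0, margin_mm = 0)$refined_fgt, m0$refined_fgt)
  prev <- sum(m0$refined_fgt)
  for (margin in c(1, 2, 4)) {
    cur <- sum(refine_fgt(ph$masks, margin_mm = margin)$refined_fgt)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("mask dilation respects anisotropic spacing", {
  m <- array(0L, dim = c(7, 7, 7)); m[4, 4, 4] <- 1L
  d <- dilate_mask(m, margin_mm = 1, spacing = c(1, 1, 2))
  # 1 mm reaches one voxel in x and y, none in z
  expect_equal(sum(d), 5)
  expect_equal(d[3, 4, 4] + d[5, 4, 4] + d[4, 3, 4] + d[4, 5, 4], 4L)
  expect_equal(d[4, 4, 3], 0L)
})
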