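test_that("zero-magnitude divergence warp is the identity", {
  sp <- small_phantom()
  img <- sp$case$contrast; msk <- sp$case$truth$label_mask
  fld <- warp_field(matrix(c(16, 16, 13), 1), 0, 15)
  w <- divergence_warp(img, msk, fld)
  expect_equal(w$img$data, img$data, tolerance = 1e-12)
  expect_identical(w$mask$data, msk$data)
})

test_that("a positive bump dilates the structure and matches a brute-force warp", {
  sp <- small_phantom()
  img <- sp$case$contrast; msk <- sp$case$truth$label_mask
  fld <- warp_field(matrix(c(16, 16, 13), 1), 5, 15)
  w <- divergence_warp(img, msk, fld)
  expect_gt(sum(w$mask$data == 1L), sum(msk$data == 1L))
  expect_true(all(unique(as.vector(w$mask$data)) %in%
                    unique(as.vector(msk$data))))
  # background fraction changes by < 20 %
  expect_lt(abs(mean(w$mask$data == 0L) / mean(msk$data == 0L) - 1), 0.2)
  # independently coded per-voxel backward warp
  expect_identical(w$mask$data,
                   array(as.integer(bf_divergence_warp(msk, c(16, 16, 13),
                                                       5, 15, TRUE)),
                         dim(msk$data)))
  expect_equal(w$img$data,
               bf_divergence_warp(img, c(16, 16, 13), 5, 15, FALSE),
               tolerance = 1e-9)
  # geometry mismatch rejected
  bad <- label_mask(msk$data[1:10, 1:10, 1:10], msk$spacing)
  expect_error(divergence_warp(img, bad, fld), "share")
})

test_that("offline augmentation sizes, provenance and ratio-0 behaviour", {
  sp <- small_phantom()
  aug <- offline_augment(list(sp$case, sp$case), ratio = 3, seed = 9)
  expect_length(aug, 8)
  expect_false(aug[[1]]$augmented)
  expect_true(aug[[2]]$augmented)
  expect_s3_class(aug[[2]]$warp, "warp_field")
  expect_true(is.numeric(aug[[2]]$seed))
  expect_identical(aug[[1]]$img$data, sp$case$contrast$data)  # original kept
  only <- offline_augment(list(sp$case), ratio = 0)
  expect_length(only, 1)
  expect_error(offline_augment(list(sp$case), ratio = -1), "ratio")
  # reproducibility
  aug2 <- offline_augment(list(sp$case, sp$case), ratio = 3, seed = 9)
  expect_identical(aug[[4]]$mask$data, aug2[[4]]$mask$data)
})

test_that("random affine parameters respect the documented ranges", {
  set.seed(42)
  for (i in 1:1000) {
    p <- draw_affine_params(c(100, 100, 100))
    expect_true(p$angle_deg >= 0 && p$angle_deg <= 15)
    expect_true(p$scale >= 0.7 && p$scale <= 1.3)
    expect_true(all(abs(p$translation_mm) <= 10))
  }
})

test_that("affine warp: identity, scale volume ratio, determinism", {
  sph <- array(0L, c(48, 48, 48))
  ctr <- 24.5
  for (k in 1:48) for (j in 1:48) for (i in 1:48)
    if ((i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= 100) sph[i, j, k] <- 1L
  sm <- label_mask(sph)
  sv <- ct_volume(sph * 100)
  idp <- list(angle_deg = 0, axis = c(0, 0, 1), scale = 1,
              translation_mm = c(0, 0, 0))
  af <- random_affine_3d(sv, sm, params = idp)
  expect_identical(af$mask$data, sm$data)
  expect_equal(af$img$data, sv$data, tolerance = 1e-9)
  big <- random_affine_3d(sv, sm, params = modifyList(idp, list(scale = 1.3)))
  expect_lt(abs(sum(big$mask$data) / sum(sph) - 1.3^3), 0.05 * 1.3^3)
  a1 <- random_affine_3d(sv, sm, seed = 7)
  a2 <- random_affine_3d(sv, sm, seed = 7)
  expect_identical(a1$mask$data, a2$mask$data)
})

test_that("image and mask stay aligned through a divergence warp", {
  # threshold the warped contrast image at the lumen/wall midpoint and
  # compare with the warped lumen label
  sp <- bulge_phantom()
  img <- sp$case$contrast; msk <- sp$case$truth$label_mask
  set.seed(3)
  fld <- aortaseg:::draw_warp_field(msk, 3, 5, 15)
  w <- divergence_warp(img, msk, fld)
  ints <- sp$spec$intensity_model
  thr <- (ints$lumen_contrast + ints$wall) / 2
  est <- label_mask(array(as.integer(w$img$data > thr), dim(w$img$data)),
                    img$spacing)
  lum <- label_mask(array(as.integer(w$mask$data == 1L), dim(w$mask$data)),
                    img$spacing)
  expect_gt(dice_score(est, lum, 1L), 0.95)
})
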