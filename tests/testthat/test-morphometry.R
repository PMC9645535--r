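test_that("Dice score identities, hand count and symmetry", {
  a <- array(0L, c(4, 4, 2)); b <- array(0L, c(4, 4, 2))
  a[1:4, 1, 1] <- 1L          # |A| = 4
  b[3:4, 1, 1] <- 1L; b[1:2, 2, 1] <- 1L  # |B| = 4, overlap 2
  ma <- label_mask(a); mb <- label_mask(b)
  expect_equal(dice_score(ma, mb, 1L), 0.5)
  expect_equal(dice_score(ma, ma, 1L), 1)
  expect_equal(dice_score(mb, ma, 1L), dice_score(ma, mb, 1L))
  disj <- label_mask(array(0L, c(4, 4, 2))); disj$data[1, 3, 2] <- 1L
  expect_equal(dice_score(ma, disj, 1L), 0)
  expect_equal(dice_score(ma, mb, 2L), 1)  # both empty
  expect_error(dice_score(ma, label_mask(array(0L, c(2, 2, 2)))), "share")
})

test_that("class volumes count voxels times voxel volume", {
  m <- label_mask(array(0L, c(10, 10, 10)))
  expect_equal(class_volumes(m)$lumen_mm3, 0)
  m$data[1:10, 1:10, 1:10] <- 1L
  expect_equal(class_volumes(m)$lumen_mm3, 1000)
  tp <- tube_phantom()
  v <- class_volumes(tp$case$truth$label_mask)
  expect_lt(abs(v$lumen_mm3 / (pi * 100 * 60) - 1), 0.02)
})

test_that("axial diameters: cylinder, single voxel, oblique ellipse vs scan", {
  tp <- tube_phantom()
  di <- axial_diameters(tp$case$truth$label_mask, 1L)
  expect_true(all(abs(di$ap_mm - 20) <= 1))
  expect_true(all(abs(di$transverse_mm - 20) <= 1))
  one <- label_mask(array(0L, c(8, 8, 2)), spacing = c(0.7, 0.8, 1))
  one$data[3, 5, 1] <- 1L
  d1 <- axial_diameters(one, 1L)
  expect_equal(d1$ap_mm, 0.8)
  expect_equal(d1$transverse_mm, 0.7)
  # 45-degree elongated ellipse: against an exhaustive index-scan oracle
  el <- array(0L, c(40, 40, 1))
  for (j in 1:40) for (i in 1:40) {
    u <- ((i - 20) + (j - 20)) / sqrt(2)
    v <- ((i - 20) - (j - 20)) / sqrt(2)
    if ((u / 15)^2 + (v / 5)^2 <= 1) el[i, j, 1] <- 1L
  }
  me <- label_mask(el, spacing = c(1, 1, 1))
  de <- axial_diameters(me, 1L)
  w <- which(el[, , 1] == 1L, arr.ind = TRUE)
  expect_equal(de$ap_mm, max(w[, 2]) - min(w[, 2]) + 1)
  expect_equal(de$transverse_mm, max(w[, 1]) - min(w[, 1]) + 1)
})

test_that("three-slice protocol: symmetry, bulge apex, truncation flag", {
  tp <- tube_phantom()
  pr <- three_slice_protocol(tp$case$truth$label_mask, "foreground")
  expect_true(pr$complete)
  expect_equal(nrow(pr$measurements), 3)
  expect_true(all(abs(pr$measurements$ap_mm - 24) <= 1))
  expect_true(all(abs(pr$measurements$transverse_mm - 24) <= 1))
  bp <- bulge_phantom()
  prb <- three_slice_protocol(bp$case$truth$label_mask, "foreground")
  apex_z <- bp$case$truth$centerline$points[
    which.max(bp$case$truth$radius(bp$case$truth$centerline$arc)), 3]
  expect_lte(abs(prb$max_ap_slice - (apex_z / 1 + 1)), 2)
  # mask shorter than the +/- 10 mm span is flagged
  short <- label_mask(array(0L, c(20, 20, 8)))
  short$data[8:12, 8:12, 4:5] <- 1L
  prs <- three_slice_protocol(short, 1L)
  expect_false(prs$complete)
})

test_that("max axial area: cylinder value, empty mask, dilation monotonicity", {
  tp <- tube_phantom()
  a <- max_axial_area(tp$case$truth$label_mask, 1L)
  expect_lt(abs(a / (pi * 100) - 1), 0.03)
  expect_equal(max_axial_area(label_mask(array(0L, c(4, 4, 4)))), 0)
  grown <- tp$case$truth$label_mask
  grown$data[grown$data == 2L] <- 1L  # superset of the lumen
  expect_gte(max_axial_area(grown, 1L), a)
})

test_that("centerline extraction recovers straight and curved tube axes", {
  tp <- tube_phantom()
  cl <- extract_centerline(tp$case$truth$label_mask, "foreground")
  ax <- sqrt((cl$points[, 1] - 24)^2 + (cl$points[, 2] - 24)^2)
  expect_lt(max(ax), 1)  # within one voxel of the true axis
  expect_true(all(diff(cl$arc) > 0))
  expect_gte(cl$points[1, 3], cl$points[nrow(cl$points), 3])  # superior first
  bp <- bulge_phantom()
  cl2 <- extract_centerline(bp$case$truth$label_mask, "foreground")
  D <- aortaseg:::cross_dist(cl2$points, bp$case$truth$centerline$points)
  expect_lt(mean(apply(D, 1, min)), 1.5)
  one <- label_mask(array(0L, c(6, 6, 6)), spacing = c(2, 2, 2))
  one$data[3, 4, 5] <- 1L
  cl3 <- extract_centerline(one, 1L)
  expect_equal(unname(as.vector(cl3$points)), c(4, 6, 8))
  expect_error(extract_centerline(label_mask(array(0L, c(4, 4, 4)))), "absent")
})

test_that("centerline deviation and Hausdorff distance match brute force", {
  A <- cbind(0, 0, seq(0, 50, by = 1))
  B <- cbind(3, 4, seq(0, 50, by = 1))  # parallel, offset 5 mm
  expect_equal(as.numeric(centerline_deviation(A, A)), 0)
  expect_equal(hausdorff_distance(A, A), 0)
  expect_equal(as.numeric(centerline_deviation(A, B)), 5)
  expect_equal(hausdorff_distance(A, B), 5)
  # line vs its subsampled half, against the all-pairs oracle
  half <- A[seq(1, nrow(A), by = 2), ]
  bf <- bf_closest_stats(A, half)
  expect_equal(as.numeric(centerline_deviation(A, half)), bf$mean_sym,
               tolerance = 1e-12)
  expect_equal(hausdorff_distance(A, half), bf$hausdorff, tolerance = 1e-12)
  # upper-bound property on random pairs
  set.seed(8)
  for (i in 1:200) {
    P <- matrix(runif(30, 0, 40), ncol = 3)
    Q <- matrix(runif(24, 0, 40), ncol = 3)
    expect_gte(hausdorff_distance(P, Q) + 1e-12,
               as.numeric(centerline_deviation(P, Q)))
  }
  expect_error(centerline_deviation(A[0, , drop = FALSE], B), "empty")
})

test_that("orthogonal diameter profile: cylinder constant, bulge maximum", {
  tp <- tube_phantom()
  m <- tp$case$truth$label_mask
  cl <- extract_centerline(m, "foreground")
  prof <- orthogonal_diameter_profile(m, cl, step_mm = 2)
  expect_true(all(diff(prof$arc_length_mm) > 0))
  mid <- prof$diameter_mm[prof$arc_length_mm > 10 &
                            prof$arc_length_mm < max(prof$arc_length_mm) - 10]
  expect_true(all(abs(mid - 24) <= 1))  # 2(r + wall) within one spacing
  bp <- bulge_phantom()
  clb <- extract_centerline(bp$case$truth$label_mask, "foreground")
  pb <- orthogonal_diameter_profile(bp$case$truth$label_mask, clb, step_mm = 2)
  expect_lt(abs(max(pb$diameter_mm, na.rm = TRUE) - 44) / 44, 0.05)
})

test_that("profile comparison: identities, constant offset, hand arithmetic", {
  p1 <- data.frame(arc_length_mm = c(0, 10, 20), diameter_mm = c(20, 30, 25))
  expect_equal(compare_profiles(p1, p1), list(rmse_mm = 0, pct_diff = 0))
  p2 <- p1; p2$diameter_mm <- p1$diameter_mm + 2
  cp <- compare_profiles(p1, p2)
  expect_equal(cp$rmse_mm, 2, tolerance = 1e-9)
  # hand computation on 3 samples: |d1-d2| = c(2,2,2); means = c(21,31,26)
  expect_equal(cp$pct_diff, mean(2 / c(21, 31, 26)) * 100, tolerance = 1e-6)
  p3 <- data.frame(arc_length_mm = c(100, 110), diameter_mm = c(1, 1))
  expect_error(compare_profiles(p1, p3), "overlap")
})

test_that("straightened view recentres the vessel and counts slices", {
  bp <- bulge_phantom()
  m <- bp$case$truth$label_mask
  cl <- extract_centerline(m, "foreground")
  sv <- straightened_view(ct_volume((m$data > 0L) * 1.0, m$spacing), cl,
                          half_width_mm = 30, step_mm = 2)
  pts_s <- aortaseg:::smooth_moving_average(cl$points, 5L)
  Ls <- sum(sqrt(rowSums(diff(pts_s)^2)))
  expect_equal(dim(sv$data)[3], floor(Ls / 2) + 1)
  # lumen centred in every straightened slice away from the ends
  d <- dim(sv$data)
  ctr <- (d[1:2] + 1) / 2
  for (k in seq(3, d[3] - 2, by = 4)) {
    sl <- sv$data[, , k]
    if (sum(sl) == 0) next
    w <- which(sl > 0.5, arr.ind = TRUE)
    expect_lt(sqrt(sum((colMeans(w) - ctr)^2)), 2 / min(m$spacing[1:2]) + 2)
  }
})

test_that("agreement statistics: identities, offset, ICC against aov", {
  x <- c(10, 12, 14, 16, 18)
  st <- agreement_stats(x, x)
  expect_equal(st$bias, 0)
  expect_equal(st$pct_cv, 0)
  expect_equal(st$spearman_r, 1)
  expect_equal(diff(st$loa), 0)
  st2 <- agreement_stats(x + 3, x)
  expect_equal(st2$bias, 3)
  expect_equal(diff(st2$loa), 0)  # SD of differences is 0
  # ICC(A,1) cross-checked against an independent aov decomposition
  y <- c(11, 11, 15, 15, 19)
  st3 <- agreement_stats(x, y)
  df <- data.frame(val = c(x, y),
                   subj = factor(rep(1:5, 2)),
                   rater = factor(rep(1:2, each = 5)))
  ms <- summary(stats::aov(val ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_ref <- (msr - mse) / (msr + mse + 2 / 5 * (msc - mse))
  expect_equal(st3$icc, unname(icc_ref), tolerance = 1e-12)
  expect_error(agreement_stats(1:2, 2:3), "at least 3")
})

test_that("morphometry and agreement reports assemble and serialize", {
  bp <- bulge_phantom()
  rep <- morphometry_report(bp$case$truth$label_mask)
  expect_s3_class(rep, "morphometry_report")
  v <- rep$volumes
  expect_gte(v$total_mm3, v$lumen_mm3)
  expect_gte(v$total_mm3, v$ws_ilt_mm3)
  expect_gt(rep$max_ap_diameter_mm, 0)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "report.json")
  write_report(rep, f)
  expect_true(file.exists(f))
  expect_true(file.exists(file.path(dir, "report_profile.csv")))
  parsed <- jsonlite::read_json(f)
  expect_true(is.numeric(parsed$max_ap_diameter_mm))
})

test_that("mask-vs-mask agreement report computes all fields", {
  bp <- bulge_phantom()
  truth <- bp$case$truth$label_mask
  pred <- truth
  # perturb: drop a thin superior slab and erode one boundary column
  pred$data[, , 78:80] <- 0L
  rep <- suppressMessages(compare_masks(pred, truth))
  expect_s3_class(rep, "agreement_report")
  expect_true(all(rep$dice >= 0 & rep$dice <= 1))
  expect_gt(rep$dice[["foreground"]], 0.9)
  expect_gte(rep$centerline_hausdorff_mm, rep$centerline_mean_euclidean_mm)
  expect_gte(rep$profile_rmse_mm, 0)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "agreement.json")
  write_report(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_true(is.numeric(parsed$centerline_mean_euclidean_mm))
})
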