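test_that("phantom generation is deterministic and labels are well-formed", {
  tp <- tube_phantom()
  again <- generate_phantom(tp$spec)
  expect_identical(again$contrast$data, tp$case$contrast$data)
  expect_identical(again$noncontrast$data, tp$case$noncontrast$data)
  expect_identical(again$truth$label_mask$data, tp$case$truth$label_mask$data)
  expect_true(all(tp$case$truth$label_mask$data %in% 0:2))
  # lumen is a single connected component
  m <- bulge_phantom()$case$truth$label_mask
  lab <- aortaseg:::cc_label_cpp(array(as.integer(m$data == 1L), dim(m$data)), 26L)
  expect_equal(max(lab), 1L)
})

test_that("without thrombus no wall voxel intrudes into the lumen", {
  tp <- tube_phantom()
  m <- tp$case$truth$label_mask
  truth <- tp$case$truth
  w2 <- which(m$data == 2L, arr.ind = TRUE)
  pts <- sweep((w2 - 1) %*% diag(m$spacing), 2, m$origin, `+`)
  D <- aortaseg:::cross_dist(pts, truth$centerline$points)
  dmin <- apply(D, 1, min)
  r <- truth$radius(0)
  # all class-2 voxels live in the wall annulus [r, r + wall]
  expect_true(all(dmin > r - 1e-6))
  expect_true(all(dmin <= r + truth$wall_thickness + 1e-6))
})

test_that("tube lumen volume matches the analytic and sub-voxel oracles", {
  tp <- tube_phantom()
  nl <- sum(tp$case$truth$label_mask$data == 1L)
  expect_lt(abs(nl / (pi * 10^2 * 60) - 1), 0.02)
  orc <- oracle_volumes(tp$spec, subdiv = 5)
  expect_lt(abs(nl * prod(tp$spec$spacing) / orc$lumen_mm3 - 1), 0.02)
})

test_that("contrast lumen is bright and non-contrast lumen iso-intense", {
  tp <- tube_phantom()
  truth <- tp$case$truth
  # sample pure-lumen intensities along the centerline, background at a corner
  on_axis <- function(v) {
    pts <- truth$centerline$points
    aortaseg:::sample_points_cpp(v$data * 1.0, v$spacing, v$origin, pts, TRUE)
  }
  sd0 <- tp$spec$noise_sd
  bg_c <- mean(tp$case$contrast$data[1:6, 1:6, ])
  bg_n <- mean(tp$case$noncontrast$data[1:6, 1:6, ])
  expect_gt(abs(mean(on_axis(tp$case$contrast)) - bg_c), 10 * sd0)
  expect_lt(abs(mean(on_axis(tp$case$noncontrast)) - bg_n), 2 * sd0)
})

test_that("a grid too small for the geometry is rejected", {
  spec <- phantom_spec(grid_shape = c(16, 16, 20), spacing = c(1, 1, 1),
                       centerline_control_points =
                         cbind(8, 8, seq(0, 20, length.out = 3)),
                       lumen_radius_profile = cbind(c(0, 1), c(10, 10)),
                       wall_thickness = 2, thrombus_fraction = 0)
  expect_error(generate_phantom(spec), "too small")
})

test_that("analytic profile reports the tube and bulge geometry", {
  tp <- tube_phantom()
  prof <- analytic_profile(tp$case$truth, step = 2)
  expect_true(all(abs(prof$outer_diameter_mm - 24) < 1e-9))
  expect_true(all(abs(prof$lumen_diameter_mm - 20) < 1e-9))
  # profile integral of the lumen area matches the analytic volume within 3%
  al <- pi * (prof$lumen_diameter_mm / 2)^2
  vol <- sum((al[-1] + al[-length(al)]) / 2 * diff(prof$arc_length_mm))
  expect_lt(abs(vol / tp$case$truth$volumes$lumen_mm3 - 1), 0.03)

  bp <- bulge_phantom()
  pb <- analytic_profile(bp$case$truth, step = 1)
  apex <- pb$arc_length_mm[which.max(pb$outer_diameter_mm)]
  expect_lt(abs(apex / bp$case$truth$length_mm - 0.5), 0.05)
  expect_error(analytic_profile(tp$case$truth, step = 1000), "step")
})

test_that("cohort generation validates n, is reproducible, and sizes correctly", {
  base <- phantom_spec(grid_shape = c(32, 32, 32), spacing = c(2, 2, 2))
  expect_error(generate_cohort(0, base), "n must be")
  c1 <- generate_cohort(3, base, seed = 5)
  c2 <- generate_cohort(3, base, seed = 5)
  expect_length(c1, 3)
  for (i in 1:3) {
    expect_identical(c1[[i]]$truth$spec$lumen_radius_profile,
                     c2[[i]]$truth$spec$lumen_radius_profile)
    expect_identical(c1[[i]]$contrast$data, c2[[i]]$contrast$data)
  }
  single <- generate_cohort(1, base, seed = 9)
  expect_length(single, 1)
  expect_identical(single[[1]]$truth$spec$grid_shape, base$grid_shape)
})
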