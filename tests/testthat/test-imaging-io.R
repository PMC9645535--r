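test_that("NIfTI round trip preserves data, spacing and origin", {
  dir <- withr::local_tempdir()
  v <- ct_volume(array(rnorm(8 * 7 * 6), c(8, 7, 6)),
                 spacing = c(1, 1, 2.5), origin = c(-10, 5, 2))
  f <- file.path(dir, "v.nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$data, v$data, tolerance = 1e-6)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)
  # mask round trip through the mask reader
  m <- label_mask(array(sample(0:2, 60, TRUE), c(5, 4, 3)), c(1, 1, 2.5))
  fm <- file.path(dir, "m.nii.gz")
  write_volume(m, fm)
  m2 <- read_volume(fm, mask = TRUE)
  expect_identical(m2$data, m$data)
})

test_that("non-3D payloads and malformed inputs are rejected", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "flat.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1:20, 4)), f)
  expect_error(read_volume(f), "3D")
  expect_error(read_volume(file.path(dir, "absent.nii.gz")), "no such file")
  expect_error(ct_volume(matrix(1, 2, 2)), "3D")
  expect_error(label_mask(array(5L, c(2, 2, 2))), "outside")
})

test_that("isotropic resampling preserves extent and label sets", {
  set.seed(1)
  m <- label_mask(array(sample(0:2, 20^2 * 8, TRUE), c(20, 20, 8)),
                  spacing = c(1, 1, 2.5))
  iso <- resample_isotropic(m, 1)
  expect_equal(dim(iso$data), c(20L, 20L, 20L))
  expect_true(all(unique(as.vector(iso$data)) %in% unique(as.vector(m$data))))
  # brute-force per-voxel nearest-neighbour oracle
  oracle <- bf_resample_nearest(m, c(20, 20, 20), c(1, 1, 1), m$origin)
  expect_identical(iso$data, array(as.integer(oracle), c(20, 20, 20)))
  # extent within one target voxel per axis
  expect_true(all(abs(volume_extent(iso) - volume_extent(m)) <= 1))
  # identity on already-isotropic input
  v <- ct_volume(array(rnorm(10^3), c(10, 10, 10)))
  expect_equal(resample_isotropic(v, 1)$data, v$data, tolerance = 1e-12)
  expect_error(resample_isotropic(v, 0), "positive")
  expect_error(resample_isotropic(m, 1, interpolation = "linear"), "nearest")
})

test_that("ROI down-sampling follows the round-half-up dimension rule", {
  thin <- ct_volume(array(0, c(512, 512, 6)))
  low <- downsample_for_roi(thin, 3.2)
  expect_equal(dim(low$data)[1:2], c(160L, 160L))
  mid <- ct_volume(array(0, c(320, 320, 4)))
  expect_equal(dim(downsample_for_roi(mid, 3.2)$data)[1:2], c(100L, 100L))
  expect_error(downsample_for_roi(thin, 1.0), "factor")
})

test_that("intensity normalization maps the window to [0, 1]", {
  v <- function(x) ct_volume(array(x, c(2, 2, 2)))
  expect_true(all(normalize_intensity(v(-100))$data == 0))
  expect_true(all(normalize_intensity(v(400))$data == 1))
  expect_true(all(normalize_intensity(v(150))$data == 0.5))
  expect_true(all(normalize_intensity(v(1e4))$data == 1))  # clipped
  expect_error(normalize_intensity(v(0), c(5, 5)), "low < high")
})
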