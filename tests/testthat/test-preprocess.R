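test_that("isotropic resampling follows the shape arithmetic and preserves extent", {
  set.seed(2)
  v <- volume(array(rnorm(64^3), c(64, 64, 64)), spacing = c(3, 3, 3))
  r <- resample_isotropic(v, 1.5)
  expect_equal(dim(r), c(128L, 128L, 128L))
  expect_equal(r$spacing, rep(1.5, 3))
  # physical extent preserved to within one voxel per axis
  expect_true(all(abs(dim(r) * 1.5 - dim(v) * 3) <= 1.5))

  # anisotropic input
  va <- volume(array(rnorm(20 * 30 * 10), c(20, 30, 10)), spacing = c(1, 2, 4))
  ra <- resample_isotropic(va, 2)
  expect_equal(dim(ra), c(10L, 30L, 20L))

  expect_error(resample_isotropic(volume(array(0, c(2, 2, 2)), c(0.1, 0.1, 0.1)),
                                  1000), "collapse")
})

test_that("resampling at the native spacing is the identity", {
  set.seed(3)
  v <- volume(array(rnorm(10^3), c(10, 10, 10)), spacing = rep(1.5, 3))
  r <- resample_isotropic(v, 1.5)
  expect_equal(r$data, v$data)
})

test_that("resampling a constant volume is exact in both directions", {
  v <- volume(array(7, c(12, 12, 12)), spacing = c(3, 3, 3))
  r <- resample_isotropic(v, 1.5)
  expect_true(all(r$data == 7))
  back <- resample_isotropic(r, 3)
  expect_equal(dim(back), dim(v))
  expect_true(all(back$data == 7))
})

test_that("nearest-neighbour resampling keeps label values intact", {
  set.seed(4)
  lab <- array(sample(0:3, 8^3, replace = TRUE), c(8, 8, 8))
  r <- resample_isotropic(volume(lab, c(2, 2, 2)), 1.2, "nearest")
  expect_true(all(r$data %in% 0:3))
})

test_that("intensity scaling is an exact min-max map and is idempotent", {
  v <- volume(array(c(0, 5, 10, 5, 5, 0, 10, 5), c(2, 2, 2)), c(1, 1, 1))
  s <- scale_intensity(v, 0, 1)
  expect_equal(sort(unique(as.vector(s$data))), c(0, 0.5, 1))

  set.seed(5)
  vr <- volume(array(rnorm(6^3), c(6, 6, 6)), c(1, 1, 1))
  sr <- scale_intensity(vr, 0, 1)
  expect_equal(min(sr$data), 0)
  expect_equal(max(sr$data), 1)
  expect_equal(scale_intensity(sr, 0, 1)$data, sr$data)

  expect_warning(sc <- scale_intensity(volume(array(3, c(4, 4, 4)), c(1, 1, 1))),
                 "constant")
  expect_true(all(sc$data == 0))
})

test_that("center crop offsets, identity case, and symmetric zero padding", {
  set.seed(6)
  big <- array(rnorm(32 * 32 * 20), c(32, 32, 20))
  v <- volume(big, c(1, 1, 1))
  cr <- center_crop(v, c(28, 28, 16))      # offsets (2, 2, 2)
  expect_equal(dim(cr), c(28L, 28L, 16L))
  expect_equal(cr$data, big[3:30, 3:30, 3:18])

  expect_equal(center_crop(v, dim(v))$data, v$data)

  small <- volume(array(1, c(8, 12, 12)), c(1, 1, 1))
  pd <- center_crop(small, c(12, 12, 12))  # axis 1 padded 2 each side
  expect_equal(dim(pd), c(12L, 12L, 12L))
  expect_true(all(pd$data[1:2, , ] == 0))
  expect_true(all(pd$data[11:12, , ] == 0))
  expect_true(all(pd$data[3:10, , ] == 1))

  expect_equal(center_crop(cr, c(28, 28, 16))$data, cr$data)
})

test_that("crop offsets match the canonical 256x256x160 -> 224x224x128 case", {
  # use a sparse marker volume to keep memory small: check that the voxel at
  # input position (17,17,17) lands at output (1,1,1), i.e. offsets (16,16,16)
  x <- array(0, c(256, 256, 160))
  x[17, 17, 17] <- 1
  x[17 + 223, 17 + 223, 17 + 127] <- 2
  cr <- center_crop(volume(x, c(1.5, 1.5, 1.5)), c(224, 224, 128))
  expect_equal(dim(cr), c(224L, 224L, 128L))
  expect_equal(cr$data[1, 1, 1], 1)
  expect_equal(cr$data[224, 224, 128], 2)
})

test_that("the composed preprocessing contract holds", {
  v <- generate_phantom("AD", shape = c(24, 24, 24), spacing_mm = 2,
                        noise_sd = 0.05, seed = 1)
  f <- tempfile(fileext = ".nii")
  write_volume(v, f)
  cfg <- preprocess_config(crop_shape = c(20L, 20L, 20L))
  out <- preprocess_volume(f, cfg)
  expect_equal(dim(out), c(20L, 20L, 20L))
  expect_gte(min(out$data), 0)
  expect_lte(max(out$data), 1)

  # fixed point: already isotropic at target, right shape, full [0,1] range
  set.seed(7)
  d <- array(runif(10^3), c(10, 10, 10))
  d[1] <- 0; d[2] <- 1
  vfix <- volume(d, spacing = rep(1.5, 3))
  out2 <- preprocess_volume(vfix, preprocess_config(crop_shape = c(10, 10, 10)))
  expect_equal(out2$data, d)

  # 3 mm input at half the crop shape: resampling alone reaches the target
  v3 <- volume(array(runif(12^3), c(12, 12, 12)), spacing = rep(3, 3))
  out3 <- preprocess_volume(v3, preprocess_config(crop_shape = c(24, 24, 24)))
  expect_equal(dim(out3), c(24L, 24L, 24L))
})
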