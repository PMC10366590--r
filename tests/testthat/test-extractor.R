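test_that("extractor initialisation is deterministic and structured per design", {
  p1 <- init_extractor(seed = 0)
  p2 <- init_extractor(seed = 0)
  expect_identical(p1, p2)

  p3 <- init_extractor(seed = 1)
  expect_false(identical(p1$stem$w, p3$stem$w))

  expect_length(p1$module1, 3L)
  expect_length(p1$module2, 4L)
  expect_equal(dim(p1$stem$w), c(7L, 7L, 7L, 1L, 64L))
  expect_equal(dim(p1$module1[[1]]$w3)[5], 256L)
  expect_equal(dim(p1$module2[[4]]$w3)[5], 512L)

  expect_error(init_extractor(seed = 0, init_scheme = "glorot"), "unknown")
})

test_that("compiled 3D convolution matches the nested-loop oracle", {
  set.seed(10)
  cases <- list(
    list(d = c(5, 4, 3, 1), k = c(3, 3, 3, 1, 2), s = 1L),
    list(d = c(6, 6, 6, 2), k = c(3, 3, 3, 2, 3), s = c(2L, 2L, 2L)),
    list(d = c(6, 5, 4, 3), k = c(1, 1, 1, 3, 2), s = c(1L, 2L, 2L)),
    list(d = c(4, 4, 4, 2), k = c(5, 3, 1, 2, 2), s = c(2L, 1L, 2L)),
    list(d = c(3, 3, 3, 1), k = c(7, 7, 7, 1, 1), s = c(2L, 2L, 2L))
  )
  for (cs in cases) {
    x <- array(rnorm(prod(cs$d)), cs$d)
    w <- array(rnorm(prod(cs$k)), cs$k)
    b <- rnorm(cs$k[5])
    expect_equal(conv3d(x, w, b, cs$s), conv3d_oracle(x, w, b, cs$s),
                 tolerance = 1e-10)
  }
})

test_that("a centered 1x1x1 identity kernel reproduces the input", {
  set.seed(11)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  w <- array(1, c(1, 1, 1, 1, 1))
  expect_equal(conv3d(x, w), x)
})

test_that("compiled average pooling matches the nested-loop oracle", {
  set.seed(12)
  for (cs in list(list(d = c(6, 6, 6, 2), k = 3L, s = 2L),
                  list(d = c(5, 4, 6, 1), k = c(3L, 2L, 3L), s = c(2L, 2L, 1L)),
                  list(d = c(4, 4, 4, 3), k = 2L, s = 2L))) {
    x <- array(rnorm(prod(cs$d)), cs$d)
    expect_equal(avgpool3d(x, cs$k, cs$s), avgpool3d_oracle(x, cs$k, cs$s),
                 tolerance = 1e-12)
  }
  # constants survive pooling because padding is excluded from the mean
  expect_true(all(avgpool3d(array(5, c(7, 7, 7, 1)), 3L, 2L) == 5))
})

test_that("global average pooling equals the double-loop mean", {
  x <- array(c(1, 3, 2, 6), c(2, 1, 1, 2))
  expect_equal(global_avg_pool(x), c(2, 4))

  set.seed(13)
  t4 <- array(rnorm(4 * 3 * 2 * 16), c(4, 3, 2, 16))
  ref <- vapply(1:16, function(c) {
    acc <- 0
    for (i in 1:4) for (j in 1:3) for (k in 1:2) acc <- acc + t4[i, j, k, c]
    acc / 24
  }, numeric(1))
  expect_equal(global_avg_pool(t4), ref)

  expect_equal(global_avg_pool(array(3.5, c(2, 2, 2, 5))), rep(3.5, 5))
})

test_that("zero input with zero biases propagates to zero features", {
  p <- test_extractor()
  z <- array(0, c(12, 12, 12))
  f <- extract_features(z, p)
  expect_equal(f$x_d, rep(0, 32))
  expect_equal(f$x_e, rep(0, 64))
})

test_that("the stem is scale-equivariant for non-negative scalings", {
  p <- test_extractor()
  set.seed(14)
  x <- array(rnorm(10^3), c(10, 10, 10))
  expect_equal(conv_pool_stem(2.5 * x, p), 2.5 * conv_pool_stem(x, p),
               tolerance = 1e-12)
})

test_that("bottleneck blocks validate channels and agree with the oracle path", {
  p <- test_extractor()
  set.seed(15)
  bad <- array(rnorm(4^3 * 5), c(4, 4, 4, 5))
  expect_error(bottleneck_block(bad, p$module1[[1]]), "channel mismatch")

  # direct composition of oracle convolutions on a tiny tensor
  blk <- p$module1[[1]]
  x <- array(rnorm(4^3 * 8), c(4, 4, 4, 8))
  r <- function(a) { a[a < 0] <- 0; a }
  h <- r(conv3d_oracle(x, blk$w1, blk$b1, 1L))
  h <- r(conv3d_oracle(h, blk$w2, blk$b2, blk$stride))
  h <- conv3d_oracle(h, blk$w3, blk$b3, 1L)
  s <- conv3d_oracle(x, blk$proj, blk$bproj, blk$stride)
  expect_equal(bottleneck_block(x, blk), r(h + s), tolerance = 1e-10)

  # block output channel counts follow the module width
  expect_equal(dim(bottleneck_block(x, blk))[4], 32L)
})

test_that("feature extraction is deterministic and has the contracted lengths", {
  p <- test_extractor()
  v <- generate_phantom("MCI", shape = c(12, 12, 12), seed = 3)
  f1 <- extract_features(v, p)
  f2 <- extract_features(v, p)
  expect_identical(f1, f2)
  expect_length(f1$x_d, 32L)
  expect_length(f1$x_e, 64L)
  expect_true(all(is.finite(c(f1$x_d, f1$x_e))))
})
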