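# Independent brute-force references used to validate the fast paths.

# Direct nested-loop 3D convolution with "same" padding (pad_total =
# max((out-1)*stride + k - in, 0), floor-first split), accumulating per
# output voxel. Intentionally naive; only for tiny tensors.
conv3d_oracle <- function(x, w, bias = NULL, stride = 1L) {
  d <- dim(x); K <- dim(w)
  stride <- rep(stride, length.out = 3L)
  out_dim <- ceiling(d[1:3] / stride)
  pad <- pmax((out_dim - 1) * stride + K[1:3] - d[1:3], 0) %/% 2
  if (is.null(bias)) bias <- numeric(K[5])
  out <- array(0, c(out_dim, K[5]))
  for (co in 1:K[5]) for (oz in 1:out_dim[3]) for (oy in 1:out_dim[2])
    for (ox in 1:out_dim[1]) {
      acc <- bias[co]
      for (ci in 1:K[4]) for (kz in 1:K[3]) for (ky in 1:K[2])
        for (kx in 1:K[1]) {
          ix <- (ox - 1) * stride[1] + kx - pad[1]
          iy <- (oy - 1) * stride[2] + ky - pad[2]
          iz <- (oz - 1) * stride[3] + kz - pad[3]
          if (ix >= 1 && ix <= d[1] && iy >= 1 && iy <= d[2] &&
              iz >= 1 && iz <= d[3])
            acc <- acc + x[ix, iy, iz, ci] * w[kx, ky, kz, ci, co]
        }
      out[ox, oy, oz, co] <- acc
    }
  out
}

# Nested-loop average pooling; padded voxels excluded from the divisor.
avgpool3d_oracle <- function(x, kernel = 3L, stride = 2L) {
  d <- dim(x)
  kernel <- rep(kernel, length.out = 3L)
  stride <- rep(stride, length.out = 3L)
  out_dim <- ceiling(d[1:3] / stride)
  pad <- pmax((out_dim - 1) * stride + kernel - d[1:3], 0) %/% 2
  out <- array(0, c(out_dim, d[4]))
  for (c in 1:d[4]) for (oz in 1:out_dim[3]) for (oy in 1:out_dim[2])
    for (ox in 1:out_dim[1]) {
      xs <- ((ox - 1) * stride[1] - pad[1] + 1):((ox - 1) * stride[1] - pad[1] + kernel[1])
      ys <- ((oy - 1) * stride[2] - pad[2] + 1):((oy - 1) * stride[2] - pad[2] + kernel[2])
      zs <- ((oz - 1) * stride[3] - pad[3] + 1):((oz - 1) * stride[3] - pad[3] + kernel[3])
      xs <- xs[xs >= 1 & xs <= d[1]]
      ys <- ys[ys >= 1 & ys <= d[2]]
      zs <- zs[zs >= 1 & zs <= d[3]]
      out[ox, oy, oz, c] <- mean(x[xs, ys, zs, c])
    }
  out
}

# Explicit dense ridge pseudo-inverse / output-weight solve.
ridge_pinv_oracle <- function(G, lam) solve(lam * diag(ncol(G)) + t(G) %*% G) %*% t(G)
fit_weights_oracle <- function(G, Y, lam) ridge_pinv_oracle(G, lam) %*% Y

# Tiny helper shared across files: a phantom dataset in a fresh temp dir.
make_phantom_manifest <- function(n_per_class, classes = c("AD", "NC"),
                                  shape = c(16L, 16L, 16L), effect_size = 1,
                                  noise_sd = 0.05, seed = 0L,
                                  scans_per_subject = 1L) {
  dir <- file.path(tempfile("phantoms"), "data")
  mp <- generate_dataset(dir, n_per_class = n_per_class, classes = classes,
                         shape = shape, effect_size = effect_size,
                         noise_sd = noise_sd, seed = seed,
                         scans_per_subject = scans_per_subject)
  read_manifest(mp)
}

# Cheap extractor used throughout the tests.
test_extractor <- function(seed = 7L)
  init_extractor(seed = seed, channels = c(stem = 8L, module1 = 32L, module2 = 64L))

test_precfg <- function(shape = c(16L, 16L, 16L))
  preprocess_config(crop_shape = shape)
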