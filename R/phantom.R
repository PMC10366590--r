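# Synthetic 3D phantoms: an ellipsoidal "brain" of high intensity carrying a
# central low-intensity spherical cavity whose radius grows with class
# severity (NC < MCI < AD), a crude but directionally correct stand-in for
# ventricular enlargement / atrophy. Deterministic in its seeds, so every
# downstream stage is testable without any image download.

PHANTOM_SEVERITY <- c(NC = 1, MCI = 2, AD = 3)

#' Generate one labelled phantom volume
#'
#' The ellipsoid has semi-axes 0.4 x grid shape and intensity 1 over a zero
#' background; the cavity is a central sphere of intensity 0.1 with radius
#' `0.15 * severity * effect_size` times the smallest semi-axis, where
#' severity is 1/2/3 for NC/MCI/AD. The whole structure is jittered by up to
#' one voxel (drawn from `seed`, independent of the class) so repeated
#' subjects differ spatially without changing the class-mean intensity
#' ordering. I.i.d. Gaussian noise of sd `noise_sd` (drawn from `scan_seed`)
#' is added and the result clipped to be non-negative.
#'
#' With `effect_size = 0` the cavity vanishes for every class, so phantoms of
#' different classes with equal seeds are identical — the generator's null
#' configuration.
#'
#' @param class_label `"NC"`, `"MCI"` or `"AD"`.
#' @param shape Grid size in voxels (default 32^3; the full-scale model input
#'   is 224 x 224 x 128).
#' @param spacing_mm Isotropic voxel size; deliberately not 1.5 mm by default
#'   so the resampling stage does real work.
#' @param effect_size Non-negative dial on class separation.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Seed for the subject morphology (jitter).
#' @param scan_seed Seed for the additive noise; defaults to `seed`. Distinct
#'   scan seeds under one morphology seed emulate repeat scans of a subject.
#' @param id Identifier stored in the volume.
#' @return A [volume()].
#' @export
generate_phantom <- function(class_label = c("NC", "MCI", "AD"),
                             shape = c(32L, 32L, 32L), spacing_mm = 2,
                             effect_size = 1, noise_sd = 0.05,
                             seed = 0L, scan_seed = NULL, id = NULL) {
  class_label <- match.arg(class_label)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L), noise_sd >= 0,
            effect_size >= 0, spacing_mm > 0)
  semi <- 0.4 * shape
  cavity_r <- 0.15 * PHANTOM_SEVERITY[[class_label]] * effect_size * min(semi)
  if (cavity_r >= min(semi))
    stop("cavity radius (", signif(cavity_r, 4), ") exceeds the ellipsoid (",
         signif(min(semi), 4), "); reduce effect_size")

  center <- (shape + 1) / 2 +
    with_local_seed(seed, runif(3, -1, 1))

  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - center[a]) / semi[a])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  data <- array(0, shape)
  data[r2 <= 1] <- 1
  if (cavity_r > 0) {
    cx <- lapply(1:3, function(a) (seq_len(shape[a]) - center[a])^2)
    d2 <- outer(outer(cx[[1]], cx[[2]], "+"), cx[[3]], "+")
    data[d2 <= cavity_r^2] <- 0.1
  }
  if (noise_sd > 0) {
    noise <- with_local_seed(scan_seed %||% seed,
                             rnorm(length(data), 0, noise_sd))
    data <- data + array(noise, shape)
    data[data < 0] <- 0
  }
  volume(data, spacing = rep(spacing_mm, 3),
         id = id %||% paste0(class_label, "_", seed))
}

#' Generate a labelled phantom dataset on disk
#'
#' Writes `n_per_class * scans_per_subject` NIfTI files per class plus a CSV
#' manifest with columns `path,label,subject`. Each synthetic subject has its
#' own morphology seed; its scans share that morphology and differ only in
#' noise, so subject-level grouped splitting is genuinely exercised.
#' Regeneration with the same seed reproduces identical volumes.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_per_class Subjects per class (>= 1).
#' @param classes Class labels to generate.
#' @param scans_per_subject Scans per subject (default 1).
#' @param shape,spacing_mm,effect_size,noise_sd,seed Passed to
#'   [generate_phantom()]; `seed` offsets every subject/scan seed.
#' @return Path of the manifest file, invisibly; the manifest data frame as
#'   attribute `"manifest"`.
#' @export
generate_dataset <- function(out_dir, n_per_class = 40L,
                             classes = c("AD", "MCI", "NC"),
                             scans_per_subject = 1L,
                             shape = c(32L, 32L, 32L), spacing_mm = 2,
                             effect_size = 1, noise_sd = 0.05, seed = 0L) {
  stopifnot(n_per_class >= 1L, scans_per_subject >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  subj_idx <- 0L
  for (cl in classes) {
    for (s in seq_len(n_per_class)) {
      subj_idx <- subj_idx + 1L
      subject <- sprintf("%s_s%03d", cl, s)
      subj_seed <- as.integer(seed) + 1009L * subj_idx
      for (k in seq_len(scans_per_subject)) {
        v <- generate_phantom(cl, shape = shape, spacing_mm = spacing_mm,
                              effect_size = effect_size, noise_sd = noise_sd,
                              seed = subj_seed, scan_seed = subj_seed + k - 1L,
                              id = sprintf("%s_scan%d", subject, k))
        fn <- sprintf("%s_scan%d.nii", subject, k)
        write_volume(v, file.path(out_dir, fn))
        rows[[length(rows) + 1L]] <- data.frame(path = fn, label = cl,
                                                subject = subject)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  attr(mpath, "manifest") <- manifest
  invisible(mpath)
}
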