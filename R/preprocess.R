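#' Preprocessing configuration
#'
#' Bundles the three preprocessing steps applied to every input volume before
#' feature extraction: resampling to isotropic voxels, min-max intensity
#' normalisation, and center cropping to a fixed grid. Defaults follow the
#' model's canonical input: 1.5 mm isotropic voxels, intensities in (0, 1),
#' and a 224 x 224 x 128 grid (336 x 336 x 192 mm).
#'
#' @param target_spacing_mm Isotropic target voxel size in mm (> 0).
#' @param intensity_range Length-2 `(lo, hi)` with `lo < hi`.
#' @param crop_shape Length-3 positive integer vector, the output grid.
#' @param interpolation `"trilinear"` (default) or `"nearest"` (for label
#'   maps).
#' @param clip_percentiles Optional length-2 percentiles (e.g. `c(0.5, 99.5)`)
#'   to clip intensities before min-max scaling; `NULL` (default) disables
#'   clipping.
#' @param canonical If `TRUE`, reorient volumes to RAS on load; by default
#'   volumes are used in their native voxel order.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing_mm = 1.5,
                              intensity_range = c(0, 1),
                              crop_shape = c(224L, 224L, 128L),
                              interpolation = c("trilinear", "nearest"),
                              clip_percentiles = NULL,
                              canonical = FALSE) {
  stopifnot(is.numeric(target_spacing_mm), target_spacing_mm > 0)
  if (length(intensity_range) != 2L || intensity_range[1] >= intensity_range[2])
    stop("intensity_range must be (lo, hi) with lo < hi")
  crop_shape <- as.integer(crop_shape)
  if (length(crop_shape) != 3L || any(is.na(crop_shape)) || any(crop_shape < 1L))
    stop("crop_shape must be 3 positive integers")
  structure(list(target_spacing_mm = target_spacing_mm,
                 intensity_range = as.numeric(intensity_range),
                 crop_shape = crop_shape,
                 interpolation = match.arg(interpolation),
                 clip_percentiles = clip_percentiles,
                 canonical = isTRUE(canonical)),
            class = "preprocess_config")
}

#' Resample a volume to isotropic voxels
#'
#' The output grid has `round(shape * spacing / target)` voxels per axis, so
#' the physical extent is preserved to within one voxel. Voxel centers are
#' aligned between the two grids; intensities are interpolated trilinearly
#' (or by nearest neighbour for label maps) with edge clamping.
#'
#' @param v A [volume()].
#' @param target_spacing_mm Target isotropic voxel size in mm.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return A [volume()] with spacing `(t, t, t)`.
#' @export
resample_isotropic <- function(v, target_spacing_mm,
                               interpolation = c("trilinear", "nearest")) {
  v <- as_volume(v)
  interpolation <- match.arg(interpolation)
  t <- as.numeric(target_spacing_mm)
  stopifnot(length(t) == 1L, is.finite(t), t > 0)
  in_shape <- dim(v$data)
  out_shape <- as.integer(round(in_shape * v$spacing / t))
  if (any(out_shape < 1L))
    stop("resampling to ", t, " mm would collapse an axis (input ",
         paste(in_shape, collapse = "x"), " at ",
         paste(v$spacing, collapse = "x"), " mm)")
  scale <- t / v$spacing                      # output-voxel steps in input voxels
  data <- cpp_resample3d(v$data, out_shape, scale,
                         if (interpolation == "nearest") 1L else 0L)
  # voxel-center alignment: input coord u = a*i + (a-1)/2 for output index i
  map <- diag(c(scale, 1))
  map[1:3, 4] <- (scale - 1) / 2
  volume(data, spacing = rep(t, 3), affine = v$affine %*% map, id = v$id)
}

#' Rescale intensities to a fixed range by global min-max mapping
#'
#' Applies the affine map sending the volume's global minimum to `lo` and
#' maximum to `hi`. A constant-valued volume cannot be scaled; it is returned
#' as all-`lo` with a warning rather than producing NaN.
#'
#' @param v A [volume()].
#' @param lo,hi Target range, `lo < hi`.
#' @param clip_percentiles Optional percentiles (0-100) to clip at before
#'   scaling.
#' @return A [volume()] with the same grid and metadata.
#' @export
scale_intensity <- function(v, lo = 0, hi = 1, clip_percentiles = NULL) {
  v <- as_volume(v)
  stopifnot(lo < hi)
  x <- v$data
  if (!is.null(clip_percentiles)) {
    q <- stats::quantile(x, clip_percentiles / 100, names = FALSE)
    x[x < q[1]] <- q[1]
    x[x > q[2]] <- q[2]
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant-valued volume; returning all-lo output")
    x[] <- lo
  } else {
    x <- lo + (x - rng[1]) * (hi - lo) / (rng[2] - rng[1])
  }
  volume(x, spacing = v$spacing, affine = v$affine, id = v$id)
}

#' Center-crop (and zero-pad) a volume to a fixed shape
#'
#' The crop window is centered on the grid center with offsets
#' `floor((in - out) / 2)` per axis. Axes smaller than the target are
#' symmetrically zero-padded, so the function is total on inputs of any size.
#'
#' @param v A [volume()].
#' @param crop_shape Length-3 positive integer target shape.
#' @return A [volume()] with shape exactly `crop_shape`.
#' @export
center_crop <- function(v, crop_shape) {
  v <- as_volume(v)
  crop_shape <- as.integer(crop_shape)
  stopifnot(length(crop_shape) == 3L, all(crop_shape >= 1L))
  in_shape <- dim(v$data)
  offset <- floor((in_shape - crop_shape) / 2)   # negative => padding
  out <- array(0, crop_shape)
  # overlap of the centered window with the input grid, per axis
  idx_in <- idx_out <- vector("list", 3L)
  for (a in 1:3) {
    i0 <- max(0L, offset[a])
    o0 <- max(0L, -offset[a])
    n <- min(in_shape[a] - i0, crop_shape[a] - o0)
    idx_in[[a]] <- seq.int(i0 + 1L, length.out = n)
    idx_out[[a]] <- seq.int(o0 + 1L, length.out = n)
  }
  out[idx_out[[1]], idx_out[[2]], idx_out[[3]]] <-
    v$data[idx_in[[1]], idx_in[[2]], idx_in[[3]]]
  affine <- v$affine
  affine[, 4] <- v$affine %*% c(offset, 1)
  volume(out, spacing = v$spacing, affine = affine, id = v$id)
}

#' Run the full preprocessing chain on one volume
#'
#' Composition, in order: [resample_isotropic()], [scale_intensity()],
#' [center_crop()]. The output has shape `cfg$crop_shape` and intensities
#' inside `cfg$intensity_range` (zero-padded margins sit at the range floor
#' when `lo <= 0`).
#'
#' @param x A file path, 3D array, or [volume()].
#' @param cfg A [preprocess_config()].
#' @return A preprocessed [volume()].
#' @export
preprocess_volume <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  v <- as_volume(x)
  if (cfg$canonical) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$spacing
    RNifti::sform(img) <- structure(v$affine, code = 2L)
    RNifti::orientation(img) <- "RAS"
    v <- volume(as.array(img), spacing = abs(RNifti::pixdim(img))[1:3],
                affine = unclass(RNifti::xform(img)), id = v$id)
  }
  v <- resample_isotropic(v, cfg$target_spacing_mm, cfg$interpolation)
  v <- scale_intensity(v, cfg$intensity_range[1], cfg$intensity_range[2],
                       cfg$clip_percentiles)
  center_crop(v, cfg$crop_shape)
}
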