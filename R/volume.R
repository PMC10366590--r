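#' Construct a 3D volume
#'
#' A `volume` bundles a 3D array of scalar intensities with its voxel spacing
#' (mm/voxel), the 4x4 voxel-to-world affine, and an identifier. It is the raw
#' input type of the preprocessing and feature-extraction stages.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Numeric length-3 vector of voxel sizes in mm, all positive.
#' @param affine 4x4 voxel-to-world transform; defaults to a diagonal scaling
#'   by `spacing`.
#' @param id Optional scan/subject identifier.
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL, id = NULL) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 axes, got ", length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- matrix(as.numeric(affine), 4, 4)
  structure(list(data = data, spacing = spacing, affine = affine, id = id),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume", if (!is.null(x$id)) paste0(" '", x$id, "'"), "> ",
      paste(dim(x$data), collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm, range [",
      signif(min(x$data), 4), ", ", signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Read a NIfTI file as a volume
#'
#' Loads a NIfTI-1/NIfTI-2 image in its native voxel order, retaining the
#' header affine and voxel spacing. Only 3D images are accepted; 4D time
#' series are rejected.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param id Identifier stored in the volume; defaults to the file name.
#' @return A [volume()].
#' @export
load_volume <- function(path, id = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop("'", path, "' is not a 3D image (found ", length(d),
         " axes); 4D time series are not supported")
  spacing <- abs(RNifti::pixdim(img))[1:3]
  affine <- unclass(RNifti::xform(img))
  volume(as.array(img), spacing = spacing, affine = affine,
         id = id %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
}

#' Write a volume to a NIfTI file
#'
#' @param v A [volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

as_volume <- function(x) {
  if (inherits(x, "volume")) return(x)
  if (is.character(x) && length(x) == 1L) return(load_volume(x))
  if (is.array(x) && length(dim(x)) == 3L) return(volume(x))
  stop("cannot interpret object of class '", class(x)[1], "' as a volume")
}
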