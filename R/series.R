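#' 4D diffusion-weighted image series
#'
#' Binds a 4D intensity array (x, y, z, volume) to its voxel geometry and a
#' [gradient_scheme()]. Intensities must be finite and non-negative and the
#' number of volumes must equal the scheme length.
#'
#' @param data 4D numeric array.
#' @param scheme a `gradient_scheme` of matching length.
#' @param voxel_size mm per axis (length 3 or scalar).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a
#'   diagonal map with the image centre at the world origin.
#' @return An object of class `dwi_series` with fields `data`,
#'   `voxel_size`, `affine`, `scheme`.
#' @export
dwi_series <- function(data, scheme, voxel_size = c(2, 2, 2),
                       affine = NULL) {
  if (length(dim(data)) != 4) stopf("data must be a 4D array")
  if (dim(data)[4] == 0) stopf("series has no volumes")
  if (!inherits(scheme, "gradient_scheme"))
    stopf("scheme must be a gradient_scheme")
  if (dim(data)[4] != length(scheme))
    stopf("volume/gradient count mismatch: %d volumes but %d scheme entries",
          dim(data)[4], length(scheme))
  if (!all(is.finite(data))) stopf("intensities must be finite")
  if (min(data) < 0) stopf("intensities must be non-negative")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stopf("voxel sizes must be strictly positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -(dim(data)[1:3] - 1) / 2 * voxel_size
  }
  structure(list(data = data, voxel_size = voxel_size,
                 affine = unname(as.matrix(affine)), scheme = scheme),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI series: %d x %d x %d voxels, %d volumes, voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size), collapse = " x ")))
  print(x$scheme)
  invisible(x)
}

#' @export
dim.dwi_series <- function(x) dim(x$data)

#' Read a DWI series from NIfTI + gradient files
#'
#' @param image_path path to a 4D NIfTI-1 image (optionally gzipped).
#' @param gradient_paths see [read_gradients()].
#' @param dialect gradient dialect, `"fsl"` or `"mrtrix"`.
#' @return a [dwi_series()].
#' @export
read_dwi <- function(image_path, gradient_paths, dialect = c("fsl", "mrtrix")) {
  dialect <- match.arg(dialect)
  img <- RNifti::readNifti(image_path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1)
  if (length(dim(data)) != 4) stopf("expected a 4D NIfTI image")
  affine <- RNifti::xform(img)
  attributes(affine) <- list(dim = dim(affine))
  scheme <- read_gradients(gradient_paths, dialect, affine = affine)
  if (length(scheme) != dim(data)[4])
    stopf("volume/gradient count mismatch: image has %d volumes, gradients %d",
          dim(data)[4], length(scheme))
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))  # mm per voxel axis
  dwi_series(data, scheme, voxel_size = voxel_size, affine = affine)
}

#' Write a DWI series to NIfTI + gradient files
#'
#' @param series a [dwi_series()].
#' @param image_path output NIfTI path (`.nii` or `.nii.gz`).
#' @param gradient_paths see [write_gradients()].
#' @param dialect gradient dialect, `"fsl"` or `"mrtrix"`.
#' @return the image path, invisibly.
#' @export
write_dwi <- function(series, image_path, gradient_paths,
                      dialect = c("fsl", "mrtrix")) {
  dialect <- match.arg(dialect)
  if (!inherits(series, "dwi_series")) stopf("not a dwi_series")
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- series$voxel_size
  # pixdim assignment rescales existing transforms, so set the sform after
  RNifti::sform(img) <- structure(series$affine, code = 2L)
  RNifti::writeNifti(img, image_path)
  write_gradients(series$scheme, gradient_paths, dialect,
                  affine = series$affine)
  invisible(image_path)
}

#' Write a motion trace as TSV
#'
#' Columns: `volume` (1-based index), `tx`, `ty`, `tz` (mm), `rx`, `ry`,
#' `rz` (degrees), written with 6 decimals so the round trip is lossless at
#' that precision.
#'
#' @param trace a [motion_trace()] or 6-column matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_motion_trace <- function(trace, path) {
  trace <- unclass(trace)
  if (is.null(dim(trace))) trace <- matrix(trace, nrow = 1)
  df <- data.frame(volume = seq_len(nrow(trace)),
                   formatC(trace, format = "f", digits = 6))
  names(df) <- c("volume", "tx", "ty", "tz", "rx", "ry", "rz")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motion trace written by [write_motion_trace()]
#'
#' @param path TSV path.
#' @return a [motion_trace()].
#' @export
read_motion_trace <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  motion_trace(as.matrix(df[, c("tx", "ty", "tz", "rx", "ry", "rz")]))
}

#' Export a weight set
#'
#' Slice weights go to a TSV (`volume`, `slice`, `weight`); voxel weights,
#' when present, to a 4D NIfTI image.
#'
#' @param weights a `weight_set`.
#' @param slice_path TSV output path for slice weights (or `NULL`).
#' @param voxel_path NIfTI output path for voxel weights (or `NULL`).
#' @param voxel_size mm per axis for the voxel-weight image.
#' @return invisibly, the paths written.
#' @export
write_weights <- function(weights, slice_path = NULL, voxel_path = NULL,
                          voxel_size = c(2, 2, 2)) {
  written <- character()
  if (!is.null(slice_path) && !is.null(weights$slice)) {
    w <- weights$slice
    df <- data.frame(volume = rep(seq_len(ncol(w)), each = nrow(w)),
                     slice = rep(seq_len(nrow(w)), times = ncol(w)),
                     weight = as.vector(w))
    write.table(df, slice_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, slice_path)
  }
  if (!is.null(voxel_path) && !is.null(weights$voxel)) {
    img <- RNifti::asNifti(weights$voxel, pixdim = c(rep_len(voxel_size, 3), 1))
    RNifti::writeNifti(img, voxel_path)
    written <- c(written, voxel_path)
  }
  invisible(written)
}
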