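#' Rigid-body motion parameters
#'
#' A motion trace holds one rigid transform per volume of a series:
#' translations `tx, ty, tz` in millimetres and Euler rotations
#' `rx, ry, rz` in degrees, applied intrinsically in z-y-x order
#' (i.e. the rotation matrix is `Rz %*% Ry %*% Rx`). The centre of
#' rotation is the image centre. A trace is stored in the convention of
#' the forward motion: it maps the reference (motion-free) pose to the
#' acquired pose, so an all-zero row is the identity.
#'
#' @param parameters numeric matrix with 6 columns
#'   (`tx, ty, tz, rx, ry, rz`) and one row per volume, or a vector of
#'   length 6 for a single volume.
#' @return An object of class `motion_trace`: the parameter matrix with
#'   column names.
#' @export
motion_trace <- function(parameters) {
  if (is.null(dim(parameters))) parameters <- matrix(parameters, nrow = 1)
  parameters <- as.matrix(parameters)
  if (ncol(parameters) != 6)
    stopf("a motion trace needs 6 columns (tx, ty, tz, rx, ry, rz), got %d",
          ncol(parameters))
  if (!all(is.finite(parameters)))
    stopf("motion parameters must be finite")
  colnames(parameters) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(parameters, class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("Rigid motion trace: %d volume(s)\n", nrow(x)))
  cat(sprintf("  |t| range %.2f-%.2f mm, |r| range %.2f-%.2f deg\n",
              min(abs(x[, 1:3])), max(abs(x[, 1:3])),
              min(abs(x[, 4:6])), max(abs(x[, 4:6]))))
  invisible(x)
}

#' Euler angles to rotation matrix
#'
#' Intrinsic z-y-x Euler convention: `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)`,
#' angles in degrees.
#'
#' @param angles numeric vector `c(rx, ry, rz)` in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_rotation <- function(angles) {
  a <- angles * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotation matrix to Euler angles (intrinsic z-y-x)
#'
#' Inverse of [euler_to_rotation()]; returns angles in degrees. At gimbal
#' lock (|ry| = 90 deg) the rx/rz split is resolved by setting rx = 0.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric vector `c(rx, ry, rz)` in degrees.
#' @export
rotation_to_euler <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(abs(sy) - 1) < 1e-12) {
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2])
  } else {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  }
  c(rx, ry, rz) * 180 / pi
}

#' Rigid transform as a 4x4 homogeneous matrix (mm, about the origin)
#'
#' @param mu length-6 parameter vector `c(tx, ty, tz, rx, ry, rz)`.
#' @return 4x4 matrix `[R t; 0 1]`.
#' @export
rigid_matrix <- function(mu) {
  T <- diag(4)
  T[1:3, 1:3] <- euler_to_rotation(mu[4:6])
  T[1:3, 4] <- mu[1:3]
  T
}

#' Invert a rigid parameter vector
#'
#' Returns the parameters of the inverse transform: rotation transposed,
#' translation `-R^T t`.
#'
#' @param mu length-6 parameter vector.
#' @return length-6 parameter vector of the inverse transform.
#' @export
invert_rigid <- function(mu) {
  R <- euler_to_rotation(mu[4:6])
  c(-crossprod(R, mu[1:3]), rotation_to_euler(t(R)))
}

#' Compose two rigid parameter vectors
#'
#' `compose_rigid(a, b)` returns the parameters of `T(a) %*% T(b)`
#' (apply `b` first, then `a`).
#'
#' @param a,b length-6 parameter vectors.
#' @return length-6 parameter vector.
#' @export
compose_rigid <- function(a, b) {
  T <- rigid_matrix(a) %*% rigid_matrix(b)
  c(T[1:3, 4], rotation_to_euler(T[1:3, 1:3]))
}

interp_code <- function(interpolation) {
  switch(match.arg(interpolation, c("trilinear", "nearest", "cubic")),
         nearest = 0L, trilinear = 1L, cubic = 3L)
}

#' Resample a volume under a rigid transform
#'
#' Moves the image content by the rigid transform `mu` (rotation about the
#' image centre, then translation in mm): the output at position `x` is the
#' input sampled at `T(mu)^{-1} x`. With `invert = TRUE` the inverse
#' transform is applied, undoing a previous `apply_rigid()` up to
#' interpolation error. Out-of-field voxels are set to 0.
#'
#' @param volume 3D numeric array.
#' @param mu length-6 rigid parameters (`tx, ty, tz` mm; `rx, ry, rz` deg).
#' @param voxel_size mm per axis (length 3, or scalar).
#' @param interpolation one of `"trilinear"`, `"nearest"`, `"cubic"`
#'   (Catmull-Rom).
#' @param invert apply the inverse transform instead.
#' @return resampled 3D array of the same dimensions.
#' @export
apply_rigid <- function(volume, mu, voxel_size = c(1, 1, 1),
                        interpolation = "trilinear", invert = FALSE) {
  dm <- dim(volume)
  if (length(dm) != 3) stopf("apply_rigid expects a 3D volume")
  voxel_size <- rep_len(voxel_size, 3)
  if (all(mu == 0) && interpolation %in% c("nearest", "trilinear"))
    return(volume)

  T <- rigid_matrix(mu)
  if (!invert) T <- solve(T)
  # voxel index -> centred mm coordinates
  S <- diag(c(voxel_size, 1))
  S[1:3, 4] <- -(dm - 1) / 2 * voxel_size
  M <- solve(S) %*% T %*% S

  out <- .resample_affine_cpp(as.double(volume), as.integer(dm), M,
                              interp_code(interpolation))
  array(out, dm)
}
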