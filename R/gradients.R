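#' Multi-shell gradient sampling scheme
#'
#' Container for a whole acquisition's diffusion encoding: one b-value and
#' one unit direction per volume, the temporal (acquisition) order, and the
#' phase-encode axis. Directions are stored in the image coordinate frame
#' (FSL bvec convention); rows are stored in acquisition order and
#' `temporal_order` records the permutation that produced that order
#' (identity for a freshly constructed scheme). Volumes with
#' b < 50 s/mm^2 are treated as unweighted (b = 0) and may
#' carry a zero direction.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param directions N x 3 matrix of directions; unit norm required where
#'   b > 0 (renormalized with a warning beyond tolerance 1e-3).
#' @param temporal_order permutation of `seq_len(N)`; defaults to identity.
#' @param pe_axis phase-encode axis label, one of `"x"`, `"y"`, `"z"`.
#' @return An object of class `gradient_scheme` with fields `bvals`,
#'   `directions`, `temporal_order`, `pe_axis`.
#' @export
gradient_scheme <- function(bvals, directions, temporal_order = NULL,
                            pe_axis = "y") {
  bvals <- as.numeric(bvals)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3)
    stopf("directions must be an N x 3 matrix")
  n <- length(bvals)
  if (nrow(directions) != n)
    stopf("gradient count mismatch: %d b-values but %d directions",
          n, nrow(directions))
  if (any(bvals < 0)) stopf("b-values must be non-negative")
  pe_axis <- match.arg(pe_axis, c("x", "y", "z"))

  dw <- bvals >= B0_THRESHOLD
  nrm <- sqrt(rowSums(directions^2))
  if (any(dw & nrm == 0))
    stopf("zero direction vector on a diffusion-weighted volume (b = %g)",
          bvals[which(dw & nrm == 0)[1]])
  if (any(dw & abs(nrm - 1) > 1e-3))
    warnf("%d direction(s) deviate from unit norm by more than 1e-3; renormalizing",
          sum(dw & abs(nrm - 1) > 1e-3))
  directions[dw, ] <- directions[dw, , drop = FALSE] / nrm[dw]
  directions[!dw & nrm > 0, ] <-
    directions[!dw & nrm > 0, , drop = FALSE] / nrm[!dw & nrm > 0]

  temporal_order <- temporal_order %||% seq_len(n)
  if (!identical(sort(as.integer(temporal_order)), seq_len(n)))
    stopf("temporal_order must be a permutation of 1..%d", n)

  structure(list(bvals = bvals, directions = unname(directions),
                 temporal_order = as.integer(temporal_order),
                 pe_axis = pe_axis),
            class = "gradient_scheme")
}

#' @export
length.gradient_scheme <- function(x) length(x$bvals)

#' @export
print.gradient_scheme <- function(x, ...) {
  sh <- shell_table(x)
  cat(sprintf("Gradient scheme: %d volumes (%d b=0), pe axis %s\n",
              length(x), sum(is_b0(x)), x$pe_axis))
  for (i in seq_len(nrow(sh)))
    cat(sprintf("  shell b=%g: %d directions\n", sh$b[i], sh$n[i]))
  invisible(x)
}

#' Identify unweighted volumes
#'
#' @param scheme a `gradient_scheme`.
#' @return logical vector, `TRUE` where b < 50 s/mm^2.
#' @export
is_b0 <- function(scheme) scheme$bvals < B0_THRESHOLD

#' Shell membership of each volume
#'
#' Groups diffusion-weighted volumes by rounded b-value; unweighted volumes
#' form their own group labelled `b = 0`.
#'
#' @param scheme a `gradient_scheme`.
#' @return integer vector of shell ids (1-based); id 1 is the b = 0 group
#'   when present.
#' @export
shell_ids <- function(scheme) {
  b <- ifelse(is_b0(scheme), 0, round(scheme$bvals))
  match(b, sort(unique(b)))
}

shell_table <- function(scheme) {
  b <- ifelse(is_b0(scheme), 0, round(scheme$bvals))
  tb <- table(b)
  data.frame(b = as.numeric(names(tb)), n = as.integer(tb))
}

#' Rotate a gradient table by per-volume rigid transforms
#'
#' Replaces each direction u_v by `R_v %*% u_v` where `R_v` is the rotation
#' component of the v-th rigid transform in `trace`. b-values and temporal
#' order are unchanged. The motion-correction engine passes the realignment
#' (inverse-motion) trace here so that rotated directions match the
#' realigned volumes.
#'
#' @param scheme a `gradient_scheme`.
#' @param trace a `motion_trace` (or 6-column matrix) with one row per
#'   volume.
#' @return a new `gradient_scheme` with rotated directions.
#' @export
rotate_gradient_table <- function(scheme, trace) {
  trace <- unclass(trace)
  if (is.null(dim(trace))) trace <- matrix(trace, nrow = 1)
  if (nrow(trace) != length(scheme))
    stopf("trace has %d rows but the scheme has %d volumes",
          nrow(trace), length(scheme))
  dirs <- scheme$directions
  for (v in seq_len(nrow(trace))) {
    R <- euler_to_rotation(trace[v, 4:6])
    if (abs(det(R) - 1) > 1e-6)
      stopf("rotation for volume %d is not orthonormal (det = %g)",
            v, det(R))
    dirs[v, ] <- R %*% dirs[v, ]
  }
  out <- scheme
  out$directions <- dirs
  out
}

#' q-space sample points of a scheme
#'
#' Maps each volume to a q-space point `q = sqrt(b) * u` (the diffusion
#' timing scale is absorbed into the SHORE scale parameter zeta; this is a
#' unit convention, not physics). b = 0 volumes map to the origin.
#'
#' @param scheme a `gradient_scheme`.
#' @return N x 3 matrix of q-space points.
#' @export
q_points <- function(scheme) {
  q <- sqrt(pmax(scheme$bvals, 0))
  q[is_b0(scheme)] <- 0
  scheme$directions * q
}

# ---- gradient-table files ---------------------------------------------------

#' Read a gradient table
#'
#' Supports the FSL dialect (a `bval` file with one row of N values and a
#' `bvec` file with three rows of N components, image frame) and the MRtrix
#' dialect (one N x 4 file `x y z b`, scanner frame; converted to the image
#' frame through the affine's rotation).
#'
#' @param paths for `dialect = "fsl"` a character vector
#'   `c(bval = ..., bvec = ...)` (order bval, bvec if unnamed); for
#'   `"mrtrix"` a single path.
#' @param dialect `"fsl"` or `"mrtrix"`.
#' @param affine 4x4 voxel-to-world matrix; required to convert the MRtrix
#'   dialect (defaults to identity orientation).
#' @return a `gradient_scheme`.
#' @export
read_gradients <- function(paths, dialect = c("fsl", "mrtrix"),
                           affine = diag(4)) {
  dialect <- match.arg(dialect)
  if (dialect == "fsl") {
    bval_path <- paths[["bval"]] %||% paths[[1]]
    bvec_path <- paths[["bvec"]] %||% paths[[2]]
    bvals <- scan(bval_path, quiet = TRUE)
    bvec <- as.matrix(read.table(bvec_path))
    if (nrow(bvec) != 3)
      stopf("a bvec file must have 3 rows, got %d", nrow(bvec))
    if (ncol(bvec) != length(bvals))
      stopf("gradient count mismatch: %d b-values but %d b-vectors",
            length(bvals), ncol(bvec))
    gradient_scheme(bvals, t(bvec))
  } else {
    g <- as.matrix(read.table(paths[[1]]))
    if (ncol(g) != 4)
      stopf("an MRtrix grad file must have 4 columns, got %d", ncol(g))
    Rw <- affine_rotation(affine)
    dirs <- g[, 1:3, drop = FALSE] %*% Rw  # world -> image: d_i = R^T d_w
    gradient_scheme(g[, 4], dirs)
  }
}

#' Write a gradient table
#'
#' @param scheme a `gradient_scheme`.
#' @param paths as in [read_gradients()].
#' @param dialect `"fsl"` or `"mrtrix"`.
#' @param affine 4x4 voxel-to-world matrix (MRtrix dialect conversion).
#' @return the paths, invisibly.
#' @export
write_gradients <- function(scheme, paths, dialect = c("fsl", "mrtrix"),
                            affine = diag(4)) {
  dialect <- match.arg(dialect)
  fmt <- function(x) formatC(x, format = "g", digits = 10)
  if (dialect == "fsl") {
    bval_path <- paths[["bval"]] %||% paths[[1]]
    bvec_path <- paths[["bvec"]] %||% paths[[2]]
    writeLines(paste(fmt(scheme$bvals), collapse = " "), bval_path)
    writeLines(apply(t(scheme$directions), 1,
                     function(r) paste(fmt(r), collapse = " ")), bvec_path)
  } else {
    Rw <- affine_rotation(affine)
    dirs <- scheme$directions %*% t(Rw)  # image -> world
    tab <- cbind(dirs, scheme$bvals)
    writeLines(apply(tab, 1, function(r) paste(fmt(r), collapse = " ")),
               paths[[1]])
  }
  invisible(paths)
}

# rotation component of an affine: columns normalized to unit length
affine_rotation <- function(affine) {
  A <- affine[1:3, 1:3]
  sweep(A, 2, sqrt(colSums(A^2)), "/")
}
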