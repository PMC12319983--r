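# Three-tier outlier weighting: modified Z-score on slice means (no
# prediction needed), Gaussian-mixture weighting of slice RMSE against the
# model prediction, and voxel-wise standardized residuals. All weights are
# diagonal entries of the W matrix of the weighted SHORE fit.

# Mclust resolves `mclustBIC` in the calling frame, so it must be imported
# alongside Mclust for the fit to work from within the package namespace.
#' @importFrom mclust Mclust mclustBIC
NULL

weight_set <- function(slice = NULL, voxel = NULL, method = "none") {
  structure(list(slice = slice, voxel = voxel, method = method),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("Weight set (%s):", x$method))
  if (!is.null(x$slice))
    cat(sprintf(" %d slices x %d volumes, %.0f%% < 0.5;",
                nrow(x$slice), ncol(x$slice), 100 * mean(x$slice < 0.5)))
  if (!is.null(x$voxel)) cat(" voxel weights present;")
  cat("\n")
  invisible(x)
}

series_data <- function(x) if (inherits(x, "dwi_series")) x$data else x

# slice summary statistic over the mask; returns n_slices x n_volumes,
# NA where a slice has no mask voxels
slice_stat <- function(data, mask, fun) {
  d <- dim(data)
  out <- matrix(NA_real_, d[3], d[4])
  for (s in seq_len(d[3])) {
    m <- mask[, , s]
    if (!any(m)) next
    sl <- matrix(data[, , s, ], ncol = d[4])[m, , drop = FALSE]
    out[s, ] <- fun(sl)
  }
  out
}

default_mask <- function(data, mask) {
  if (is.null(mask)) array(TRUE, dim(data)[1:3]) else (mask > 0)
}

#' Slice weights from the modified Z-score of slice means
#'
#' Within each b-value shell the slice-mean intensities (over the brain
#' mask when given, else the full slice) are reduced to modified Z-scores
#' `Z = |mean - shell median| / (1.4826 * MAD)` and converted to weights by
#' the soft ramp `w = 1 - (Z - eta_l) / (eta_u - eta_l)`, clamped to
#' `[0, 1]`: slices at or below `eta_l` keep weight 1, slices at or above
#' `eta_u` drop to 0. A shell whose MAD is zero (all slice means equal)
#' gets all weights 1.
#'
#' @param series a [dwi_series()] (or 4D array with `scheme` given).
#' @param scheme the gradient scheme; defaults to `series$scheme`.
#' @param eta_l,eta_u lower and upper Z thresholds, `eta_u > eta_l >= 0`.
#' @param mask optional 3D brain mask (logical or 0/1).
#' @return a `weight_set` with slice weights (slices x volumes).
#' @export
zscore_slice_weights <- function(series, scheme = NULL, eta_l = 3,
                                 eta_u = 10, mask = NULL) {
  if (!(eta_u > eta_l) || eta_l < 0)
    stopf("need eta_u > eta_l >= 0 (got %g, %g)", eta_l, eta_u)
  data <- series_data(series)
  scheme <- scheme %||% series$scheme
  mask <- default_mask(data, mask)
  means <- slice_stat(data, mask, colMeans)
  # slices with no voxels in the mask carry no evidence: weight 1 and
  # excluded from the shell statistics (without a mask a zero-intensity
  # slice has mean 0 and is down-weighted naturally)

  w <- matrix(1, nrow(means), ncol(means))
  sid <- shell_ids(scheme)
  for (s in unique(sid)) {
    vols <- which(sid == s)
    vals <- means[, vols]
    ok <- is.finite(vals)
    if (!any(ok)) next
    resid <- vals - median(vals[ok])
    madv <- median(abs(resid[ok] - median(resid[ok])))
    if (madv == 0) {
      message(sprintf("shell %d: zero MAD of slice means; all weights 1", s))
      next
    }
    Z <- abs(resid) / (1.4826 * madv)
    wk <- clamp01(1 - (Z - eta_l) / (eta_u - eta_l))
    wk[!ok] <- 1
    w[, vols] <- wk
  }
  weight_set(slice = w, method = "zscore")
}

#' Slice weights from a Gaussian mixture on prediction residuals
#'
#' Per shell, computes the root-mean-squared error between the acquired
#' and predicted series for every slice, fits a Gaussian mixture to the
#' log-RMSE values with model selection over one or two components (BIC),
#' and uses the posterior probability of the lower-mean (inlier) component
#' as the slice weight. When one component explains the residuals (clean
#' data), or a shell has fewer than 4 scoreable slices, all weights are 1.
#' The procedure is deterministic.
#'
#' @param series acquired [dwi_series()] (or 4D array with `scheme`).
#' @param predicted predicted series aligned with `series` (same dims).
#' @param scheme gradient scheme; defaults to `series$scheme`.
#' @param mask optional 3D brain mask.
#' @param rel_floor slices whose RMSE is below this fraction of their mean
#'   signal are inliers regardless of the mixture: residuals at the level
#'   of the reconstruction accuracy itself are not artifacts. Without the
#'   floor, near-noiseless data would have its (tiny, heterogeneous)
#'   model-misfit residuals split into two clusters and clean slices
#'   down-weighted.
#' @param seed unused (the fit is deterministic); kept for interface
#'   stability.
#' @return a `weight_set` with slice weights.
#' @export
gmm_slice_weights <- function(series, predicted, scheme = NULL, mask = NULL,
                              rel_floor = 0.02, seed = NULL) {
  data <- series_data(series)
  pred <- series_data(predicted)
  if (!identical(dim(data), dim(pred)))
    stopf("acquired and predicted series have different dimensions")
  scheme <- scheme %||% series$scheme
  mask <- default_mask(data, mask)

  resid2 <- (data - pred)^2
  rmse <- sqrt(slice_stat(resid2, mask, colMeans))
  level <- slice_stat(data, mask, colMeans)

  w <- matrix(1, nrow(rmse), ncol(rmse))
  sid <- shell_ids(scheme)
  for (s in unique(sid)) {
    vols <- which(sid == s)
    vals <- rmse[, vols]
    ok <- is.finite(vals)
    if (sum(ok) < 4) {
      message(sprintf("shell %d: fewer than 4 scoreable slices; all weights 1", s))
      next
    }
    le <- log(pmax(vals[ok], .Machine$double.eps))
    if (sd(le) < 1e-10) next  # identical residuals: single cluster
    fit <- tryCatch(
      Mclust(le, G = 1:2, modelNames = "V", verbose = FALSE),
      error = function(e) {
        message(sprintf("shell %d: mixture fit failed (%s); all weights 1",
                        s, conditionMessage(e)))
        NULL
      })
    if (is.null(fit) || fit$G == 1) next
    mu <- fit$parameters$mean
    if (abs(diff(mu)) < 1e-8) next
    ws <- fit$z[, which.min(mu)]
    wk <- matrix(1, nrow(rmse), length(vols))
    wk[ok] <- ws
    wk[ok & vals < rel_floor * level[, vols]] <- 1
    w[, vols] <- wk
  }
  weight_set(slice = w, method = "gmm")
}

#' Voxel weights from standardized prediction residuals
#'
#' Per volume, residuals `E - Ehat` over the brain voxels are standardized
#' by `1.4826 * MAD` and converted to weights `w = 1 / (z^2 + 1)^2`, a
#' smooth redescending function: z = 0 gives 1, z = 1 gives 1/4, z = 3
#' gives 1/100. A volume with zero residual MAD keeps all weights 1.
#'
#' @param series acquired [dwi_series()] (or 4D array).
#' @param predicted predicted series of the same dimensions.
#' @param mask optional 3D brain mask; weights outside the mask are 1.
#' @return a `weight_set` with a 4D voxel-weight array.
#' @export
voxel_weights <- function(series, predicted, mask = NULL) {
  data <- series_data(series)
  pred <- series_data(predicted)
  if (!identical(dim(data), dim(pred)))
    stopf("acquired and predicted series have different dimensions")
  mask <- default_mask(data, mask)

  d <- dim(data)
  w <- array(1, d)
  for (v in seq_len(d[4])) {
    resid <- data[, , , v][mask] - pred[, , , v][mask]
    madv <- median(abs(resid - median(resid)))
    if (madv == 0) {
      message(sprintf("volume %d: zero residual MAD; all voxel weights 1", v))
      next
    }
    z <- resid / (1.4826 * madv)
    wv <- array(1, d[1:3])
    wv[mask] <- 1 / (z^2 + 1)^2
    w[, , , v] <- wv
  }
  weight_set(voxel = w, method = "voxel")
}

# expand slice (and optional voxel) weights into per-(voxel, volume) fit
# weights for the masked voxels: rows = volumes, cols = masked voxels
fit_weight_matrix <- function(wset, dims, mask) {
  vox <- which(mask)
  zidx <- arrayInd(vox, dims[1:3])[, 3]
  nvol <- dims[4]
  W <- matrix(1, nvol, length(vox))
  if (!is.null(wset$slice))
    W <- W * t(wset$slice[zidx, , drop = FALSE])
  if (!is.null(wset$voxel)) {
    voxw <- matrix(wset$voxel, prod(dims[1:3]), nvol)[vox, , drop = FALSE]
    W <- W * t(voxw)
  }
  W
}
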