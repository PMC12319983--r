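# The iterative motion-correction engine: alternates outlier weighting,
# weighted regularized SHORE fitting in the current (rotated) q-space,
# signal prediction in the original q-space, rigid registration of each
# acquired volume to its same-contrast prediction, and gradient-table
# rotation, over a fixed number of epochs.

#' Configuration of the motion-correction engine
#'
#' The default schedule follows the five-epoch design: modified Z-score
#' slice weighting in the initialization epoch (no prediction needed yet),
#' Gaussian-mixture slice weighting against the current prediction in the
#' middle epochs, and voxel-wise weighting added in the final epoch.
#' Trilinear interpolation is used while iterating and cubic spline for
#' the final resampling.
#'
#' @param n_epochs number of epochs (>= 1; default 5).
#' @param order SHORE truncation order (even; default 6, 72 functions).
#' @param zeta SHORE scale parameter (default 700, with q = sqrt(b) u and
#'   b in s/mm^2).
#' @param lambda_l,lambda_n angular/radial regularization strengths
#'   (default 1e-8).
#' @param eta_l,eta_u modified Z-score ramp thresholds.
#' @param registration settings from [register_settings()].
#' @param interpolation resampling during iterations.
#' @param final_interpolation resampling of the final corrected series.
#' @param max_translation,max_rotation divergence bounds (mm, degrees); a
#'   registration outside them flags the volume and zeroes its weights.
#' @param seed seed forwarded to stochastic sub-steps (the engine itself
#'   is deterministic).
#' @param verbose print per-epoch progress.
#' @return a list of class `moco_config`.
#' @export
moco_config <- function(n_epochs = 5, order = 6, zeta = 700,
                        lambda_l = 1e-8, lambda_n = 1e-8,
                        eta_l = 3, eta_u = 10,
                        registration = register_settings(),
                        interpolation = "trilinear",
                        final_interpolation = "cubic",
                        max_translation = 50, max_rotation = 60,
                        seed = 1, verbose = FALSE) {
  if (n_epochs < 1) stopf("n_epochs must be at least 1")
  structure(list(n_epochs = n_epochs, order = order, zeta = zeta,
                 lambda_l = lambda_l, lambda_n = lambda_n,
                 eta_l = eta_l, eta_u = eta_u, registration = registration,
                 interpolation = interpolation,
                 final_interpolation = final_interpolation,
                 max_translation = max_translation,
                 max_rotation = max_rotation, seed = seed,
                 verbose = verbose),
            class = "moco_config")
}

realign_trace <- function(mu) t(apply(mu, 1, invert_rigid))

realign_series <- function(data, mu, voxel_size, interpolation) {
  out <- data
  for (v in seq_len(dim(data)[4]))
    out[, , , v] <- apply_rigid(data[, , , v], mu[v, ], voxel_size,
                                interpolation, invert = TRUE)
  out
}

#' Motion-correct a DWI series
#'
#' Runs the iterative engine on a (pre-processed) series. Each epoch:
#' (1) slice/voxel outlier weights — modified Z-score in epoch 1,
#' Gaussian-mixture weights comparing the realigned data with the current
#' prediction afterwards, voxel-wise weights added in the final epoch;
#' (2) a weighted regularized SHORE fit in the basis evaluated on the
#' motion-rotated q-space points; (3) prediction of every volume's
#' contrast at its current (rotated) q-space point, so that prediction and
#' acquired volume share the same diffusion sensitization; (4) rigid
#' registration of each acquired volume to its same-contrast prediction
#' (skipped in the final epoch); (5) rotation of the gradient table by the
#' per-volume realignment rotations. The returned `prediction` is the
#' model reconstruction evaluated in the nominal (as-designed) q-space. Transforms always map the original acquired
#' volumes, so resampling error does not compound across epochs. A
#' registration leaving the divergence bounds flags the volume and forces
#' its weights to zero; processing continues.
#'
#' @param series a [dwi_series()], intensity-corrected.
#' @param config a [moco_config()].
#' @param mask optional 3D brain mask; derived by thresholding the mean
#'   b = 0 volume at 10 percent of its maximum when omitted.
#' @return An object of class `moco_result`: list with `corrected`
#'   (realigned series carrying the rotated gradient table), `trace`
#'   (estimated per-volume forward motion), `weights` (final
#'   `weight_set`), `coefficients` (final SHORE fit over the masked
#'   voxels), `prediction` (model prediction in the original q-space),
#'   `rotated_scheme`, `flagged` (divergent volumes), and `log`
#'   (per-epoch weighted RMSE).
#' @export
correct_motion <- function(series, config = moco_config(), mask = NULL) {
  if (!inherits(series, "dwi_series")) stopf("series must be a dwi_series")
  data <- series$data
  d <- dim(data)
  vs <- series$voxel_size
  scheme0 <- series$scheme
  n <- d[4]
  K <- config$n_epochs

  if (is.null(mask)) {
    b0 <- which(is_b0(scheme0))
    ref <- if (length(b0)) apply(data[, , , b0, drop = FALSE], 1:3, mean)
           else apply(data, 1:3, mean)
    mask <- ref > 0.1 * max(ref)
  } else mask <- mask > 0
  # dilate for fitting: the model must cover the partial-volume halo
  # around the brain, otherwise the predictions are zero where the data
  # still has signal and the registration metric is biased at the
  # boundary (the registration support is derived from the prediction)
  mask <- mask | (smooth_gauss3(mask * 1, 1.5, renormalize = FALSE) > 0.02)
  vox <- which(mask)
  if (length(vox) == 0) stopf("empty brain mask")
  zidx <- arrayInd(vox, d[1:3])[, 3]

  index_set <- shore_index_set(config$order)
  reg <- regularization_operators(index_set, config$lambda_l, config$lambda_n)
  Phi0 <- build_basis(index_set, q_points(scheme0), config$zeta)

  mu <- matrix(0, n, 6)
  flagged <- rep(FALSE, n)
  prediction <- NULL
  scheme_k <- scheme0
  fit <- NULL
  wset <- NULL
  log_rows <- list()

  for (k in seq_len(K)) {
    final <- k == K
    if (k == 1) {
      data_k <- data
    } else {
      interp <- if (final) config$final_interpolation else config$interpolation
      data_k <- pmax(realign_series(data, mu, vs, interp), 0)
    }

    if (k == 1) {
      wset <- zscore_slice_weights(data_k, scheme0, config$eta_l,
                                   config$eta_u, mask)
    } else {
      wset <- gmm_slice_weights(data_k, prediction, scheme0, mask,
                                seed = config$seed)
      if (final) {
        vset <- voxel_weights(data_k, prediction, mask)
        wset <- weight_set(slice = wset$slice, voxel = vset$voxel,
                           method = "gmm+voxel")
      }
    }
    if (any(flagged)) wset$slice[, flagged] <- 0

    if (k > 1) {
      scheme_k <- rotate_gradient_table(scheme0, realign_trace(mu))
      basis_k <- build_basis(index_set, q_points(scheme_k), config$zeta)
    } else basis_k <- Phi0

    E <- t(matrix(data_k, prod(d[1:3]), n)[vox, , drop = FALSE])  # Q x V
    W <- fit_weight_matrix(wset, d, mask)
    fit <- fit_shore(E, basis_k, W, reg)

    # internal prediction lives in the CURRENT (rotated) q-space: volume v
    # of the prediction then has the same diffusion sensitization as the
    # acquired volume v, which is what makes registration-to-prediction
    # valid; the nominal-q-space reconstruction is produced at the end
    pred_vals <- basis_k$design %*% fit$coefficients
    prediction <- array(0, d)
    pm <- matrix(prediction, prod(d[1:3]), n)
    pm[vox, ] <- t(pmax(pred_vals, 0))
    prediction <- array(pm, d)

    wrmse <- sqrt(sum(W * (E - pred_vals)^2) / sum(W))
    log_rows[[k]] <- data.frame(epoch = k, weighted_rmse = wrmse)
    if (config$verbose)
      message(sprintf("epoch %d: weighted RMSE %.4f", k, wrmse))

    if (!final) {
      prev <- NULL
      for (v in seq_len(n)) {
        fixedv <- prediction[, , , v]
        movingv <- data[, , , v]
        if (sd(fixedv) == 0 || sd(movingv) == 0) {
          flagged[v] <- TRUE
          next
        }
        inits <- unique(c(list(mu[v, ]), list(rep(0, 6)),
                          if (!is.null(prev)) list(prev)))
        res <- rigid_register(movingv, fixedv, vs, config$registration,
                              inits = inits)
        if (max(abs(res$mu[1:3])) > config$max_translation ||
            max(abs(res$mu[4:6])) > config$max_rotation) {
          flagged[v] <- TRUE
          warnf("volume %d: registration diverged; flagged", v)
        } else {
          mu[v, ] <- res$mu
          prev <- res$mu
        }
      }
    }
  }

  scheme_final <- rotate_gradient_table(scheme0, realign_trace(mu))
  # reconstruction in the nominal (as-designed) q-space
  recon_vals <- Phi0$design %*% fit$coefficients
  recon <- matrix(0, prod(d[1:3]), n)
  recon[vox, ] <- t(pmax(recon_vals, 0))
  structure(list(
    corrected = dwi_series(data_k, scheme_final, voxel_size = vs,
                           affine = series$affine),
    trace = motion_trace(mu),
    weights = wset,
    coefficients = fit,
    prediction = dwi_series(array(recon, d), scheme0, voxel_size = vs,
                            affine = series$affine),
    rotated_scheme = scheme_final,
    flagged = flagged,
    mask = mask,
    log = do.call(rbind, log_rows)), class = "moco_result")
}

#' @export
print.moco_result <- function(x, ...) {
  cat(sprintf("Motion correction: %d epochs, %d volumes (%d flagged)\n",
              nrow(x$log), nrow(x$trace), sum(x$flagged)))
  cat(sprintf("  weighted RMSE %.4f -> %.4f\n",
              x$log$weighted_rmse[1],
              x$log$weighted_rmse[nrow(x$log)]))
  invisible(x)
}
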