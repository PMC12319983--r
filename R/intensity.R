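# Rician bias correction of magnitude data and B1 bias-field combination.

#' Rician correction factor xi(theta)
#'
#' `xi(theta) = 2 + theta^2 - (pi/8) exp(-theta^2/2) *
#'  [(2 + theta^2) I0(theta^2/4) + theta^2 I1(theta^2/4)]^2`,
#' where theta is the signal-to-noise ratio eta/sigma. The bracketed term
#' is `(8/pi) * (mean/sigma)^2` of a Rician variable at SNR theta, so
#' `xi(0) = 2 - pi/2` (Rayleigh) and `xi -> 1` as theta grows. Evaluated
#' with exponentially scaled Bessel functions, which keeps the expression
#' stable at large theta; beyond theta = 1e4 the limit 1 is returned
#' (the remaining correction is below 1e-8).
#'
#' @param theta non-negative SNR value(s).
#' @return xi evaluated elementwise.
#' @export
xi_factor <- function(theta) {
  if (any(theta < 0)) stopf("theta must be non-negative")
  x <- theta^2 / 4
  # exp(-theta^2/2) I_k(theta^2/4) = exp(-x) * besselI(x, k, scaled)
  # exp(-theta^2/2) * I_k(theta^2/4)^2 terms: the scaling factors cancel,
  # exp(-2x) * (I_k(x) e^{x})^2 = I_k(x)^2 with x = theta^2/4
  i0 <- besselI(x, 0, expon.scaled = TRUE)
  i1 <- besselI(x, 1, expon.scaled = TRUE)
  mean_over_sigma2 <- (pi / 8) * ((2 + theta^2) * i0 + theta^2 * i1)^2
  xi <- 2 + theta^2 - mean_over_sigma2
  xi[theta > 1e4] <- 1
  xi
}

# Rician mean / sigma at SNR theta (same stable evaluation)
rician_mean_factor <- function(theta) {
  x <- theta^2 / 4
  sqrt(pi / 8) * ((2 + theta^2) * besselI(x, 0, expon.scaled = TRUE) +
                  theta^2 * besselI(x, 1, expon.scaled = TRUE))
}

#' Correct the Rician bias of mean magnitude intensities
#'
#' Magnitude MRI at low SNR overestimates the underlying signal. Given the
#' measured mean magnitude `<M>` and the noise standard deviation sigma,
#' the true intensity `E_c` solves the moment identity
#' `E_c^2 = <M>^2 + (xi(theta) - 2) sigma^2` with `theta = E_c / sigma`,
#' iterated to a relative tolerance of 1e-6. `sigma = 0` returns `<M>`
#' unchanged; pure-noise inputs (`<M>` at or below the Rayleigh mean
#' `sigma sqrt(pi/2)`) collapse to 0.
#'
#' @param mean_magnitude non-negative measured mean magnitude(s); any
#'   numeric array.
#' @param sigma noise standard deviation: a scalar or an array matching
#'   `mean_magnitude`.
#' @param max_iter iteration cap; exceeding it raises an error reporting
#'   the residual.
#' @return corrected intensities, same shape as `mean_magnitude`.
#' @export
rician_correct <- function(mean_magnitude, sigma, max_iter = 100) {
  if (any(sigma < 0)) stopf("sigma must be non-negative")
  if (any(mean_magnitude < 0)) stopf("mean magnitude must be non-negative")
  M <- mean_magnitude
  s <- if (length(sigma) == 1) rep(sigma, length(M)) else sigma
  if (length(s) != length(M))
    stopf("sigma must be scalar or match mean_magnitude")

  Ec <- as.numeric(M)
  live <- s > 0 & M > 0
  for (it in seq_len(max_iter)) {
    if (!any(live)) break
    theta <- Ec[live] / s[live]
    Ec2 <- M[live]^2 + (xi_factor(theta) - 2) * s[live]^2
    new <- sqrt(pmax(Ec2, 0))
    delta <- abs(new - Ec[live]) / pmax(new, s[live] * 1e-3)
    Ec[live] <- new
    conv <- delta < 1e-6
    live[live] <- !conv
  }
  if (any(live))
    stopf("Rician fixed point did not converge after %d iterations (max residual %g)",
          max_iter, max(abs(M[live] - rician_mean_factor(Ec[live] / s[live]) * s[live])))
  out <- M
  out[] <- Ec
  out
}

#' B1 bias-field object
#'
#' Multiplicative receive-field `beta` with the mean b = 0 intensities
#' before and after bias-field correction of the averaged b = 0 image,
#' used to renormalize the global intensity scale.
#'
#' @param beta 3D array of multiplicative field values (positive inside
#'   the mask).
#' @param mean_b0_raw,mean_b0_corrected scalar mean intensities of the
#'   averaged b = 0 image before/after field correction.
#' @return an object of class `bias_field`.
#' @export
bias_field <- function(beta, mean_b0_raw, mean_b0_corrected) {
  if (mean_b0_raw == 0) stopf("mean b = 0 intensity must be nonzero")
  structure(list(beta = beta, mean_b0_raw = mean_b0_raw,
                 mean_b0_corrected = mean_b0_corrected),
            class = "bias_field")
}

#' Apply a B1 bias-field correction to a series
#'
#' Divides every volume by the field `beta` voxel-wise and rescales by the
#' ratio of corrected to raw mean b = 0 intensity:
#' `E_c(q) = E(q) * mean_b0_corrected / (beta * mean_b0_raw)`. With
#' `beta = 1` everywhere and equal means the series is unchanged. The
#' operation is exactly inverted by multiplying back.
#'
#' @param series a [dwi_series()] or 4D array.
#' @param field a [bias_field()].
#' @param mask optional 3D mask; `beta` must be positive inside it (the
#'   whole grid when omitted).
#' @return corrected series of the same class as the input.
#' @export
b1_correct <- function(series, field, mask = NULL) {
  data <- series_data(series)
  mask <- default_mask(data, mask)
  if (any(field$beta[mask] <= 0))
    stopf("bias field must be positive inside the mask")
  scale <- field$mean_b0_corrected / field$mean_b0_raw
  corr <- data * rep(scale / field$beta, dim(data)[4])
  if (inherits(series, "dwi_series")) {
    series$data <- corr
    series
  } else corr
}

#' Estimate the noise standard deviation from b = 0 volumes
#'
#' Fallback estimator when no noise map is supplied: half-differences of
#' consecutive b = 0 volumes cancel anatomy, leaving noise whose robust
#' spread `1.4826 * MAD / sqrt(2)` estimates sigma.
#'
#' @param series a [dwi_series()].
#' @param mask optional 3D brain mask.
#' @return scalar sigma estimate.
#' @export
estimate_sigma <- function(series, mask = NULL) {
  b0 <- which(is_b0(series$scheme))
  if (length(b0) < 2)
    stopf("need at least two b = 0 volumes to estimate sigma")
  mask <- default_mask(series$data, mask)
  d <- vapply(seq_len(length(b0) - 1), function(i) {
    diff <- (series$data[, , , b0[i + 1]] - series$data[, , , b0[i]])[mask]
    1.4826 * median(abs(diff - median(diff))) / sqrt(2)
  }, numeric(1))
  median(d)
}
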