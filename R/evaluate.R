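# Image-quality and motion-trace scoring: SSIM (slice-wise by default),
# PSNR, and per-volume rigid-trace errors.

# valid-region uniform box sums via integral images (2D)
box_sum_2d <- function(x, w) {
  cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  n1 <- nrow(x) - w + 1; n2 <- ncol(x) - w + 1
  P <- rbind(0, cbind(0, cs))
  P[(1:n1) + w, (1:n2) + w, drop = FALSE] -
    P[(1:n1), (1:n2) + w, drop = FALSE] -
    P[(1:n1) + w, (1:n2), drop = FALSE] +
    P[(1:n1), (1:n2), drop = FALSE]
}

ssim_2d <- function(a, b, w, C1, C2) {
  n <- w * w
  mu_a <- box_sum_2d(a, w) / n
  mu_b <- box_sum_2d(b, w) / n
  va <- box_sum_2d(a^2, w) / n - mu_a^2
  vb <- box_sum_2d(b^2, w) / n - mu_b^2
  cab <- box_sum_2d(a * b, w) / n - mu_a * mu_b
  m <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(m)
}

#' Structural similarity index
#'
#' SSIM with the standard constants (K1 = 0.01, K2 = 0.03) and a 7-voxel
#' uniform window, the dynamic range taken from the image pair unless
#' given. 3D inputs are scored slice-wise along `slice_axis` and averaged
#' (set `aggregate = FALSE` for the per-slice values); `method = "3d"`
#' scores whole volumes with a cubic window. Symmetric in its arguments;
#' identical images score 1.
#'
#' @param image_a,image_b arrays of identical shape (2D or 3D).
#' @param window window width in voxels.
#' @param data_range dynamic range; default `max - min` over the pair.
#' @param method `"slice"` or `"3d"`.
#' @param slice_axis axis for slice-wise scoring.
#' @param aggregate return the mean (`TRUE`) or per-slice values.
#' @return scalar in `[-1, 1]`, or a per-slice vector.
#' @export
ssim <- function(image_a, image_b, window = 7, data_range = NULL,
                 method = c("slice", "3d"), slice_axis = 3,
                 aggregate = TRUE) {
  method <- match.arg(method)
  if (!identical(dim(image_a), dim(image_b)))
    stopf("images must have identical shapes")
  R <- data_range %||% (max(image_a, image_b) - min(image_a, image_b))
  if (R == 0) return(1)  # both images constant and equal
  C1 <- (0.01 * R)^2; C2 <- (0.03 * R)^2

  if (is.null(dim(image_a)) || length(dim(image_a)) == 2 ||
      method == "3d") {
    if (method == "3d" && length(dim(image_a)) == 3)
      return(ssim_3d(image_a, image_b, window, C1, C2))
    a <- as.matrix(image_a); b <- as.matrix(image_b)
    return(ssim_2d(a, b, min(window, dim(a)), C1, C2))
  }
  ns <- dim(image_a)[slice_axis]
  vals <- vapply(seq_len(ns), function(s) {
    a <- slice_along(image_a, slice_axis, s)
    b <- slice_along(image_b, slice_axis, s)
    ssim_2d(a, b, min(window, dim(a)), C1, C2)
  }, numeric(1))
  if (aggregate) mean(vals) else vals
}

slice_along <- function(x, axis, s) {
  switch(axis, x[s, , ], x[, s, ], x[, , s])
}

ssim_3d <- function(a, b, w, C1, C2) {
  n <- w^3
  cum1 <- function(x) array(apply(x, c(2, 3), cumsum), dim(x))
  cum_along <- function(x, ax) {
    if (ax == 1) return(cum1(x))
    p <- c(ax, setdiff(1:3, ax))
    aperm(cum1(aperm(x, p)), order(p))
  }
  bs <- function(x) {
    cs <- cum_along(cum_along(cum_along(x, 1), 2), 3)
    d <- dim(cs)
    P <- array(0, d + 1)
    P[-1, -1, -1] <- cs
    i <- function(k, nd) (1:(nd - w + 1)) + k
    n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
    P[i(w, n1), i(w, n2), i(w, n3), drop = FALSE] -
      P[i(0, n1), i(w, n2), i(w, n3), drop = FALSE] -
      P[i(w, n1), i(0, n2), i(w, n3), drop = FALSE] -
      P[i(w, n1), i(w, n2), i(0, n3), drop = FALSE] +
      P[i(0, n1), i(0, n2), i(w, n3), drop = FALSE] +
      P[i(0, n1), i(w, n2), i(0, n3), drop = FALSE] +
      P[i(w, n1), i(0, n2), i(0, n3), drop = FALSE] -
      P[i(0, n1), i(0, n2), i(0, n3), drop = FALSE]
  }
  mu_a <- bs(a) / n; mu_b <- bs(b) / n
  va <- bs(a^2) / n - mu_a^2
  vb <- bs(b^2) / n - mu_b^2
  cab <- bs(a * b) / n - mu_a * mu_b
  m <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(m)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(range^2 / MSE)`; identical images return `Inf`.
#'
#' @param image_a,image_b arrays of identical shape.
#' @param data_range dynamic range; default `max - min` over the pair.
#' @return PSNR in dB.
#' @export
psnr <- function(image_a, image_b, data_range = NULL) {
  if (!identical(dim(image_a), dim(image_b)))
    stopf("images must have identical shapes")
  mse <- mean((image_a - image_b)^2)
  if (mse == 0) return(Inf)
  R <- data_range %||% (max(image_a, image_b) - min(image_a, image_b))
  if (R <= 0) stopf("data_range must be positive")
  10 * log10(R^2 / mse)
}

#' Per-volume motion-trace errors
#'
#' Translation error is the Euclidean norm of the translation difference
#' (mm); rotation error is the geodesic angle of `R_true %*% t(R_est)`
#' (degrees). Both traces must use the same composition convention.
#'
#' @param true_trace,estimated_trace [motion_trace()] objects (or
#'   6-column matrices) of equal length.
#' @return An object of class `trace_error_report`: data.frame with
#'   columns `volume`, `translation_mm`, `rotation_deg`, plus a `summary`
#'   attribute (median and IQR of each).
#' @export
trace_error <- function(true_trace, estimated_trace) {
  a <- unclass(true_trace); b <- unclass(estimated_trace)
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  if (nrow(a) != nrow(b))
    stopf("traces have different lengths (%d vs %d)", nrow(a), nrow(b))
  terr <- sqrt(rowSums((a[, 1:3, drop = FALSE] - b[, 1:3, drop = FALSE])^2))
  rerr <- vapply(seq_len(nrow(a)), function(v) {
    Rd <- euler_to_rotation(a[v, 4:6]) %*% t(euler_to_rotation(b[v, 4:6]))
    acos(max(-1, min(1, (sum(diag(Rd)) - 1) / 2))) * 180 / pi
  }, numeric(1))
  out <- data.frame(volume = seq_len(nrow(a)), translation_mm = terr,
                    rotation_deg = rerr)
  attr(out, "summary") <- list(
    median_translation_mm = median(terr), iqr_translation_mm = stats::IQR(terr),
    median_rotation_deg = median(rerr), iqr_rotation_deg = stats::IQR(rerr))
  class(out) <- c("trace_error_report", "data.frame")
  out
}

#' @export
print.trace_error_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "Trace error over %d volumes: median %.3f mm (IQR %.3f), median %.3f deg (IQR %.3f)\n",
    nrow(x), s$median_translation_mm, s$iqr_translation_mm,
    s$median_rotation_deg, s$iqr_rotation_deg))
  invisible(x)
}
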