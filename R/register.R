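# Rigid volume registration: normalized cross-correlation over a
# multiresolution pyramid, derivative-free (Nelder-Mead) local refinement.

# block-average downsampling by an integer factor
downsample_volume <- function(volume, factor) {
  if (factor == 1) return(volume)
  d <- dim(volume)
  nd <- floor(d / factor)
  v <- volume[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
              seq_len(nd[3] * factor), drop = FALSE]
  a <- array(v, c(factor, nd[1], factor, nd[2], factor, nd[3]))
  apply(a, c(2, 4, 6), mean)
}

ncc <- function(a, b) {
  av <- a - mean(a); bv <- b - mean(b)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(0)
  sum(av * bv) / den
}

#' Registration settings
#'
#' @param levels integer downsampling factors of the pyramid, coarse to
#'   fine.
#' @param maxit Nelder-Mead iteration caps, one per level.
#' @param reltol optimizer relative tolerance.
#' @param refine number of full-resolution polish passes with cubic
#'   interpolation (restarted Nelder-Mead); trilinear resampling in the
#'   objective low-pass filters the moving image and biases the optimum by
#'   about a degree, which the cubic passes remove.
#' @param refine_maxit iteration cap of each polish pass.
#' @param smooth_sigma Gaussian pre-smoothing (voxels) of both images
#'   before the metric is evaluated; suppresses the noise-induced shift of
#'   the correlation optimum while biasing both images identically.
#' @return a list of settings for [rigid_register()].
#' @export
register_settings <- function(levels = c(4, 2, 1), maxit = c(200, 120, 100),
                              reltol = 1e-8, refine = 2, refine_maxit = 150,
                              smooth_sigma = 0.8) {
  list(levels = levels, maxit = rep_len(maxit, length(levels)),
       reltol = reltol, refine = refine, refine_maxit = refine_maxit,
       smooth_sigma = smooth_sigma)
}

#' Rigid registration by normalized cross-correlation
#'
#' Finds the rigid transform T such that `apply_rigid(moving, mu,
#' invert = TRUE)` best matches `fixed` (equivalently: `moving` is
#' approximately `fixed` moved by T). The global normalized
#' cross-correlation metric is maximized with Nelder-Mead over a 3-level
#' multiresolution pyramid; the search is deterministic for fixed settings
#' and initializations.
#'
#' @param moving,fixed 3D arrays on the same grid.
#' @param voxel_size mm per axis.
#' @param settings from [register_settings()].
#' @param inits list of length-6 starting parameter vectors; the best
#'   scoring start at the coarsest level seeds the refinement.
#' @param support optional logical array marking the voxels the polish
#'   metric is evaluated on (e.g. a brain mask in the fixed image's
#'   space); defaults to the support of the fixed image.
#' @return list with `mu` (length-6 parameters), `metric` (final NCC) and
#'   `converged`.
#' @export
rigid_register <- function(moving, fixed, voxel_size = c(1, 1, 1),
                           settings = register_settings(),
                           inits = list(rep(0, 6)), support = NULL) {
  if (!identical(dim(moving), dim(fixed)))
    stopf("moving and fixed images must share a grid")
  if (sd(moving) == 0 || sd(fixed) == 0)
    stopf("cannot register a flat (zero-variance) image")
  voxel_size <- rep_len(voxel_size, 3)
  if ((settings$smooth_sigma %||% 0) > 0) {
    # plain zero-padded smoothing: edge renormalization would brighten
    # clipped borders of a displaced volume and bias large motions
    moving <- smooth_gauss3(moving, settings$smooth_sigma, renormalize = FALSE)
    fixed <- smooth_gauss3(fixed, settings$smooth_sigma, renormalize = FALSE)
  }

  supp_full <- if (is.null(support)) fixed > 0.02 * max(fixed) else support > 0
  if (sum(supp_full) < 64) supp_full <- array(TRUE, dim(fixed))

  pyramid <- lapply(settings$levels, function(f)
    list(moving = downsample_volume(moving, f),
         fixed = downsample_volume(fixed, f),
         vs = voxel_size * f))

  objective <- function(level, interpolation = "trilinear") {
    force(level); force(interpolation)
    function(par) {
      res <- apply_rigid(level$moving, par, level$vs, interpolation,
                         invert = TRUE)
      -ncc(res, level$fixed)
    }
  }

  # choose the best init at the coarsest level
  f0 <- objective(pyramid[[1]])
  mu <- inits[[which.min(vapply(inits, f0, numeric(1)))]]
  value <- NA_real_
  for (i in seq_along(pyramid)) {
    fit <- optim(mu, objective(pyramid[[i]]), method = "Nelder-Mead",
                 control = list(maxit = settings$maxit[i],
                                reltol = settings$reltol))
    mu <- fit$par
    value <- fit$value
  }
  # full-resolution polish: cubic interpolation, metric restricted to the
  # support of the fixed image; voxels where the model predicts nothing
  # carry no signal information and would otherwise bias the optimum
  supp <- supp_full
  fsup <- fixed[supp]
  fcub <- function(par) {
    res <- apply_rigid(moving, par, voxel_size, "cubic", invert = TRUE)
    -ncc(res[supp], fsup)
  }
  for (p in seq_len(settings$refine %||% 0)) {
    fit <- optim(mu, fcub, method = "Nelder-Mead",
                 control = list(maxit = settings$refine_maxit,
                                reltol = settings$reltol))
    mu <- fit$par
    value <- fit$value
  }
  list(mu = mu, metric = -value, converged = TRUE)
}
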