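# Synthetic multi-tensor phantom: an ellipsoidal "brain" with isotropic,
# single-fiber and crossing-fiber regions, plus a corruption model (rigid
# motion, slice dropouts, spin-history hyperintensities, Rician noise,
# opposed-blip distortion) that realizes the forward model the correction
# engine inverts.

#' Phantom specification
#'
#' Describes a multi-tensor diffusion phantom on a regular grid: an
#' ellipsoidal brain containing an isotropic core, two single-fiber lobes
#' (principal axes along x and y) and, optionally, a crossing-fiber band
#' where both populations mix 50/50. Eigenvalues are in mm^2/s.
#'
#' @param shape grid dimensions (length 3).
#' @param voxel_size mm per axis (scalar or length 3).
#' @param semi_axes ellipsoid semi-axes in mm.
#' @param s0 baseline unweighted intensity inside the brain.
#' @param background intensity outside the brain.
#' @param fiber_evals eigenvalues of the fiber tensor (mm^2/s,
#'   descending).
#' @param iso_diffusivity diffusivity of the isotropic matrix (mm^2/s).
#' @param csf_diffusivity diffusivity of the core (mm^2/s).
#' @param include_crossing include the crossing-fiber band.
#' @param smoothing partial-volume smoothing of the tensor field and
#'   intensity map, as a Gaussian sigma in voxels (0 disables; region
#'   boundaries are then voxel-sharp).
#' @param seed RNG seed for any stochastic simulation built on this spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), voxel_size = 2.5,
                         semi_axes = c(20, 17, 14), s0 = 100,
                         background = 0,
                         fiber_evals = c(1.8e-3, 0.3e-3, 0.3e-3),
                         iso_diffusivity = 1.0e-3,
                         csf_diffusivity = 2.5e-3,
                         include_crossing = TRUE, smoothing = 0.8,
                         seed = 1) {
  if (any(fiber_evals <= 0) || iso_diffusivity <= 0 || csf_diffusivity <= 0)
    stopf("diffusion tensor eigenvalues must be positive")
  structure(list(shape = as.integer(rep_len(shape, 3)),
                 voxel_size = rep_len(voxel_size, 3),
                 semi_axes = rep_len(semi_axes, 3), s0 = s0,
                 background = background, fiber_evals = fiber_evals,
                 iso_diffusivity = iso_diffusivity,
                 csf_diffusivity = csf_diffusivity,
                 include_crossing = isTRUE(include_crossing),
                 smoothing = smoothing, seed = seed),
            class = "phantom_spec")
}

# separable Gaussian smoothing (sigma in voxels, zero-padded with edge
# renormalization); smoothing the tensor field keeps it positive
# semidefinite (convex combinations) and makes the phantom resemble the
# partial-volume smoothness of real brain data
smooth_gauss3 <- function(x, sigma = 0.8, renormalize = TRUE) {
  if (sigma <= 0) return(x)
  r <- max(1, ceiling(2 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  shift3 <- function(a, o, ax) {
    d <- dim(a)
    out <- array(0, d)
    src <- lapply(d, seq_len); dst <- src
    n <- d[ax]
    if (o >= 0) { dst[[ax]] <- seq_len(n - o) + o; src[[ax]] <- seq_len(n - o) }
    else { dst[[ax]] <- seq_len(n + o); src[[ax]] <- seq_len(n + o) - o }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  norm <- array(1, dim(x))
  for (ax in 1:3) {
    xa <- array(0, dim(x)); na <- array(0, dim(x))
    for (o in (-r):r) {
      xa <- xa + w[o + r + 1] * shift3(x, o, ax)
      na <- na + w[o + r + 1] * shift3(norm, o, ax)
    }
    x <- xa; norm <- na
  }
  if (!renormalize) return(x)
  x / pmax(norm, .Machine$double.eps)
}

# diagonal tensor rotated to axis: returns 6-vector (xx, yy, zz, xy, xz, yz)
tensor_along <- function(evals, axis) {
  e1 <- axis / sqrt(sum(axis^2))
  ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- ref - sum(ref * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  D <- evals[1] * outer(e1, e1) + evals[2] * outer(e2, e2) +
       evals[3] * outer(e3, e3)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Build the tensor-field phantom volume
#'
#' Deterministic for a fixed spec. Returns the per-voxel mixture of up to
#' two diffusion tensors with volume fractions, the unweighted intensity
#' map, and the brain mask.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `dmri_phantom` with fields `s0` (3D array),
#'   `fractions` (x, y, z, 2), `tensors` (x, y, z, 2, 6; components xx,
#'   yy, zz, xy, xz, yz), `mask`, `voxel_size`, `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  d <- spec$shape
  vs <- spec$voxel_size
  cx <- (d - 1) / 2
  X <- (slice.index(array(0, d), 1) - 1 - cx[1]) * vs[1]
  Y <- (slice.index(array(0, d), 2) - 1 - cx[2]) * vs[2]
  Z <- (slice.index(array(0, d), 3) - 1 - cx[3]) * vs[3]
  r <- sqrt((X / spec$semi_axes[1])^2 + (Y / spec$semi_axes[2])^2 +
            (Z / spec$semi_axes[3])^2)
  mask <- r <= 1

  s0 <- array(spec$background, d)
  fractions <- array(0, c(d, 2)); fractions[, , , 1] <- 1
  tensors <- array(0, c(d, 2, 6))

  Dx <- tensor_along(spec$fiber_evals, c(1, 0, 0))
  Dy <- tensor_along(spec$fiber_evals, c(0, 1, 0))
  Diso <- c(rep(spec$iso_diffusivity, 3), 0, 0, 0)
  Dcsf <- c(rep(spec$csf_diffusivity, 3), 0, 0, 0)

  xn <- X / spec$semi_axes[1]  # normalized left-right coordinate
  # core offset from centre: breaks the phantom's symmetry so that rigid
  # registration is well conditioned for rotations
  rc <- sqrt(((X - 0.12 * spec$semi_axes[1]) / spec$semi_axes[1])^2 +
             ((Y + 0.10 * spec$semi_axes[2]) / spec$semi_axes[2])^2 +
             (Z / spec$semi_axes[3])^2)
  core <- mask & rc < 0.35
  lobe_x <- mask & rc >= 0.35 & xn > 0.15
  lobe_y <- mask & rc >= 0.35 & xn < -0.15
  band <- mask & rc >= 0.35 & abs(xn) <= 0.15

  assign_region <- function(sel, s0val, D1, D2 = NULL, f1 = 1) {
    s0[sel] <<- s0val
    for (k in 1:6) {
      t1 <- tensors[, , , 1, k]; t1[sel] <- D1[k]; tensors[, , , 1, k] <<- t1
      if (!is.null(D2)) {
        t2 <- tensors[, , , 2, k]; t2[sel] <- D2[k]; tensors[, , , 2, k] <<- t2
      }
    }
    fr1 <- fractions[, , , 1]; fr1[sel] <- f1; fractions[, , , 1] <<- fr1
    fr2 <- fractions[, , , 2]; fr2[sel] <- 1 - f1; fractions[, , , 2] <<- fr2
  }

  # smooth intensity gradient gives registration texture inside regions
  shade <- 1.1 - 0.25 * r^2
  assign_region(core, spec$s0 * 1.3, Dcsf)
  assign_region(lobe_x, spec$s0 * 0.9, Dx)
  assign_region(lobe_y, spec$s0 * 0.9, Dy)
  if (spec$include_crossing) {
    assign_region(band, spec$s0 * 0.95, Dx, Dy, f1 = 0.5)
  } else {
    assign_region(band, spec$s0, Diso)
  }
  s0[mask] <- s0[mask] * shade[mask]
  # gentle smooth texture: registration cues inside homogeneous regions
  texture <- 1 + 0.08 * sin(2 * pi * X / 23) * sin(2 * pi * Y / 19) +
             0.05 * sin(2 * pi * Z / 17)
  s0[mask] <- s0[mask] * texture[mask]

  if (spec$smoothing > 0) {
    s0 <- smooth_gauss3(s0, spec$smoothing)
    for (p in 1:2) {
      fractions[, , , p] <- smooth_gauss3(fractions[, , , p], spec$smoothing)
      for (k in 1:6)
        tensors[, , , p, k] <- smooth_gauss3(tensors[, , , p, k],
                                             spec$smoothing)
    }
  }

  structure(list(s0 = s0, fractions = fractions, tensors = tensors,
                 mask = mask, voxel_size = vs, spec = spec),
            class = "dmri_phantom")
}

#' Noise-free multi-tensor signal of the phantom
#'
#' `S(b, u) = S0 * sum_k f_k exp(-b u' D_k u)` per voxel.
#'
#' @param phantom a [make_phantom()] result.
#' @param b b-value in s/mm^2.
#' @param u unit direction (ignored for b = 0).
#' @return 3D intensity array.
#' @export
phantom_signal <- function(phantom, b, u) {
  if (b < B0_THRESHOLD) return(phantom$s0)
  u <- u / sqrt(sum(u^2))
  quad <- function(k) {
    Tk <- phantom$tensors[, , , k, ]
    Tk[, , , 1] * u[1]^2 + Tk[, , , 2] * u[2]^2 + Tk[, , , 3] * u[3]^2 +
      2 * (Tk[, , , 4] * u[1] * u[2] + Tk[, , , 5] * u[1] * u[3] +
           Tk[, , , 6] * u[2] * u[3])
  }
  att <- phantom$fractions[, , , 1] * exp(-b * quad(1)) +
         phantom$fractions[, , , 2] * exp(-b * quad(2))
  phantom$s0 * att
}

#' Corruption specification for a simulated acquisition
#'
#' @param trace a [motion_trace()] (per-volume forward motion) or `NULL`
#'   for a motion-free series.
#' @param dropouts `NULL` or data.frame with columns `volume`, `slice`,
#'   `factor` (attenuation in (0, 1)).
#' @param hyper `NULL` or data.frame with columns `volume`, `slice`,
#'   `gain` (> 1), the spin-history stand-in.
#' @param sigma Rician noise standard deviation (>= 0).
#' @param fieldmap `NULL` or 3D field inhomogeneity map (Hz) used by
#'   [simulate_blip_pair()].
#' @param readout_scaling voxel displacement per Hz for the distortion
#'   model.
#' @param seed RNG seed for the noise draw.
#' @return an object of class `corruption_spec`.
#' @export
corruption_spec <- function(trace = NULL, dropouts = NULL, hyper = NULL,
                            sigma = 0, fieldmap = NULL,
                            readout_scaling = 0.02, seed = 1) {
  if (sigma < 0) stopf("sigma must be non-negative")
  if (!is.null(dropouts) &&
      (any(dropouts$factor <= 0) || any(dropouts$factor >= 1)))
    stopf("dropout attenuation factors must lie in (0, 1)")
  if (!is.null(hyper) && any(hyper$gain <= 1))
    stopf("hyperintensity gains must exceed 1")
  structure(list(trace = trace, dropouts = dropouts, hyper = hyper,
                 sigma = sigma, fieldmap = fieldmap,
                 readout_scaling = readout_scaling, seed = seed),
            class = "corruption_spec")
}

#' Simulate a motion-corrupted multi-shell acquisition
#'
#' For each volume the multi-tensor signal is evaluated along the
#' motion-rotated gradient direction (`R^T u` for head rotation `R`), the
#' volume is rigidly moved by the per-volume motion, slice corruptions
#' (dropout attenuation, spin-history gain) are applied, and Rician noise
#' is added in the complex domain (`|S + n1 + i n2|`, `n ~ N(0, sigma)`).
#' Deterministic for a fixed corruption seed. The clean motion-free,
#' noise-free series is returned alongside as ground truth.
#'
#' @param phantom a [make_phantom()] result.
#' @param scheme a [gradient_scheme()].
#' @param corruption a [corruption_spec()].
#' @return list with `series` (corrupted [dwi_series()]), `clean`
#'   (motion-free noiseless series), `trace` (ground-truth
#'   [motion_trace()]), `corruption`, and `mask`.
#' @export
simulate_series <- function(phantom, scheme, corruption = corruption_spec()) {
  d <- dim(phantom$s0)
  n <- length(scheme)
  trace <- corruption$trace %||% motion_trace(matrix(0, n, 6))
  if (nrow(trace) != n)
    stopf("motion trace has %d rows for %d volumes", nrow(trace), n)

  clean <- array(0, c(d, n))
  corrupted <- array(0, c(d, n))
  for (v in seq_len(n)) {
    b <- scheme$bvals[v]; u <- scheme$directions[v, ]
    clean[, , , v] <- phantom_signal(phantom, b, u)
    R <- euler_to_rotation(trace[v, 4:6])
    ueff <- if (b >= B0_THRESHOLD) drop(crossprod(R, u)) else u
    vol <- phantom_signal(phantom, b, ueff)
    vol <- apply_rigid(vol, trace[v, ], phantom$voxel_size, "trilinear")
    corrupted[, , , v] <- vol
  }
  if (!is.null(corruption$dropouts))
    for (i in seq_len(nrow(corruption$dropouts))) {
      r <- corruption$dropouts[i, ]
      corrupted[, , r$slice, r$volume] <-
        corrupted[, , r$slice, r$volume] * r$factor
    }
  if (!is.null(corruption$hyper))
    for (i in seq_len(nrow(corruption$hyper))) {
      r <- corruption$hyper[i, ]
      corrupted[, , r$slice, r$volume] <-
        corrupted[, , r$slice, r$volume] * r$gain
    }
  if (corruption$sigma > 0)
    corrupted <- with_seed(corruption$seed, {
      n1 <- array(rnorm(length(corrupted), sd = corruption$sigma),
                  dim(corrupted))
      n2 <- array(rnorm(length(corrupted), sd = corruption$sigma),
                  dim(corrupted))
      sqrt((corrupted + n1)^2 + n2^2)
    })

  list(series = dwi_series(corrupted, scheme,
                           voxel_size = phantom$voxel_size),
       clean = dwi_series(clean, scheme, voxel_size = phantom$voxel_size),
       trace = motion_trace(unclass(trace)), corruption = corruption,
       mask = phantom$mask)
}

#' Piecewise burst motion trace
#'
#' A slowly varying baseline punctuated by a few short bursts of rapid
#' motion, the pattern seen in moving-subject acquisitions: translations
#' up to `max_translation` mm and rotations up to `max_rotation` degrees
#' (one burst reaches the maxima; the others draw a fraction of them).
#'
#' @param n_volumes series length.
#' @param n_bursts number of motion bursts.
#' @param max_translation,max_rotation burst amplitude caps (mm, degrees).
#' @param baseline_translation,baseline_rotation slow-drift amplitudes.
#' @param seed RNG seed.
#' @return a [motion_trace()].
#' @export
burst_motion_trace <- function(n_volumes, n_bursts = 3,
                               max_translation = 20, max_rotation = 24,
                               baseline_translation = 4,
                               baseline_rotation = 4, seed = 1) {
  with_seed(seed, {
    t <- seq(0, 1, length.out = n_volumes)
    baseline <- function(amp) {
      ph <- runif(3, 0, 2 * pi)
      amp * (0.6 * sin(2 * pi * t + ph[1]) + 0.4 * sin(4 * pi * t + ph[2]))
    }
    mu <- cbind(baseline(baseline_translation),
                baseline(baseline_translation),
                baseline(baseline_translation * 0.5),
                baseline(baseline_rotation),
                baseline(baseline_rotation),
                baseline(baseline_rotation * 0.5))
    starts <- sort(sample(seq(3, n_volumes - 8), n_bursts))
    tmag <- max_translation * c(1, runif(n_bursts - 1, 0.3, 0.8))
    rmag <- max_rotation * c(1, runif(n_bursts - 1, 0.3, 0.8))
    for (k in seq_len(n_bursts)) {
      len <- sample(4:7, 1)
      vols <- starts[k]:min(starts[k] + len - 1, n_volumes)
      tdir <- rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
      rdir <- rnorm(3); rdir <- rdir / sqrt(sum(rdir^2))
      mu[vols, 1:3] <- mu[vols, 1:3] + rep(tmag[k] * tdir, each = length(vols))
      mu[vols, 4:6] <- mu[vols, 4:6] + rep(rmag[k] * rdir, each = length(vols))
    }
    motion_trace(mu)
  })
}

#' Random slice dropouts
#'
#' Samples a fraction of all (volume, slice) pairs from the given slices
#' and assigns them a common attenuation factor.
#'
#' @param n_volumes series length.
#' @param slices candidate slice indices (use slices crossing the brain).
#' @param fraction fraction of candidate pairs to corrupt.
#' @param attenuation multiplicative dropout factor in (0, 1).
#' @param seed RNG seed.
#' @return data.frame with columns `volume`, `slice`, `factor`.
#' @export
random_dropouts <- function(n_volumes, slices, fraction = 0.1,
                            attenuation = 0.2, seed = 1) {
  with_seed(seed, {
    all_pairs <- expand.grid(volume = seq_len(n_volumes), slice = slices)
    k <- max(1, round(fraction * nrow(all_pairs)))
    sel <- all_pairs[sample(nrow(all_pairs), k), ]
    sel$factor <- attenuation
    rownames(sel) <- NULL
    sel
  })
}

#' Simulate an opposed-blip distortion pair
#'
#' Displaces voxels along the phase-encode axis by `+d` and `-d` voxels,
#' `d = fieldmap * readout_scaling`, with mass-preserving (Jacobian
#' modulated) resampling: susceptibility stretching in one blip appears as
#' signal pile-up in the other, and total intensity is conserved.
#'
#' @param volume 3D array.
#' @param fieldmap 3D field inhomogeneity map (Hz) on the same grid.
#' @param pe_axis phase-encode axis, `"x"`, `"y"` or `"z"`.
#' @param readout_scaling voxel displacement per Hz.
#' @return list with `plus` and `minus` distorted volumes.
#' @export
simulate_blip_pair <- function(volume, fieldmap, pe_axis = "y",
                               readout_scaling = 0.02) {
  if (!identical(dim(volume), dim(fieldmap)))
    stopf("volume and fieldmap must share a grid")
  ax <- match(match.arg(pe_axis, c("x", "y", "z")), c("x", "y", "z"))
  disp <- fieldmap * readout_scaling
  if (max(abs(disp)) > dim(volume)[ax] / 2)
    stopf("displacement exceeds half the field of view along the PE axis")
  list(plus = pushforward_1d(volume, disp, ax),
       minus = pushforward_1d(volume, -disp, ax))
}

# mass-preserving 1D pushforward along axis `ax`: each voxel's intensity is
# distributed linearly between the two voxels bracketing its displaced
# position (out-of-field mass is dropped)
pushforward_1d <- function(volume, disp, ax) {
  d <- dim(volume)
  perm <- c(ax, setdiff(1:3, ax))
  v <- aperm(volume, perm)
  dsp <- aperm(disp, perm)
  dp <- dim(v)
  idx <- slice.index(v, 1)
  target <- idx + dsp
  f <- floor(target)
  frac <- target - f
  lin <- function(i1)  # linear index for position i1 along axis 1
    i1 + dp[1] * (slice.index(v, 2) - 1) +
    dp[1] * dp[2] * (slice.index(v, 3) - 1)
  out <- numeric(prod(dp))
  add <- function(pos, val) {
    keep <- pos >= 1 & pos <= dp[1] & val != 0
    if (!any(keep)) return()
    acc <- rowsum(val[keep], lin(pos)[keep])
    out[as.integer(rownames(acc))] <<- out[as.integer(rownames(acc))] + acc
  }
  add(f, as.vector(v * (1 - frac)))
  add(f + 1, as.vector(v * frac))
  array(aperm(array(out, dp), order(perm)), d)
}
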