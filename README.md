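# dwimotion

Retrospective motion correction and model-free reconstruction for
multi-shell diffusion MRI of moving subjects, with fetal brain imaging as
the motivating application.

Diffusion MRI acquires one 3D volume per diffusion encoding (b-value b and
unit direction u). A moving subject displaces every volume by a different
rigid transform and corrupts individual slices (signal dropouts,
spin-history hyperintensities), all at low SNR with Rician noise. Because
each volume carries a different contrast, registering everything to a
single reference volume does not work. `dwimotion` instead:

1. represents the per-voxel signal E(q), q = sqrt(b)·u, in an orthonormal
   SHORE basis (generalized-Laguerre radial functions times real
   even-degree spherical harmonics; 72 functions at order 6, scale
   ζ = 700),
2. fits coefficients by weighted ℓ2-regularized least squares
   `argmin_c ||W(Φc − E)||² + λ_l||Lc||² + λ_n||Nc||²`, with
   `diag(L) = l(l+1)`, `diag(N) = n(n+1)`, λ = 1e-8,
3. down-weights unreliable data with three tiers: modified Z-scores of
   slice means, a Gaussian mixture on slice log-RMSE against the model
   prediction, and voxel-wise redescending weights `1/(z²+1)²`,
4. registers each acquired volume rigidly to its own same-contrast model
   prediction (multiresolution normalized cross-correlation) and rotates
   its gradient direction accordingly,
5. iterates 1–4 for five epochs, rebuilding the basis on the rotated
   q-space points each time.

The package also designs multi-shell gradient schemes (antipodal
electrostatic-repulsion energy, balanced per-shell/global, with
incremental temporal ordering), performs Rician bias correction via the
ξ(θ) moment fixed point and B1 bias-field correction, simulates a
multi-tensor phantom with known motion/dropouts/noise/opposed-blip
distortion, and scores results with SSIM, PSNR and motion-trace errors.

## Worked example

Design the recommended two-shell fetal protocol, simulate a corrupted
acquisition from the built-in phantom, and correct it:

```r
library(dwimotion)

scheme <- order_incrementally(
  design_scheme(n_b0 = 11, shells = list(c(400, 28), c(900, 56)), seed = 3))
scheme
#> Gradient scheme: 95 volumes (11 b=0), pe axis y
#>   shell b=0: 11 directions
#>   shell b=400: 28 directions
#>   shell b=900: 56 directions

phantom <- make_phantom()
trace <- burst_motion_trace(length(scheme), n_bursts = 3,
                            max_translation = 20, max_rotation = 24,
                            seed = 5)
sim <- simulate_series(phantom, scheme,
                       corruption_spec(trace = trace, sigma = 5, seed = 9))

res <- correct_motion(sim$series, moco_config(), mask = phantom$mask)
res
#> Motion correction: 5 epochs, 95 volumes (0 flagged)
#>   weighted RMSE 11.0798 -> 1.5854

trace_error(sim$trace, res$trace)
#> Trace error over 95 volumes: median 0.726 mm (IQR 0.388), median 3.063 deg (IQR 3.167)
```

The weighted RMSE is the residual between the model prediction and the
(re)aligned data under the current outlier weights; it drops sevenfold as
the volumes are realigned. The trace error compares the estimated
per-volume rigid motion with the simulation's ground truth: burst motion
spanning 20 mm / 24° is recovered to well under a millimetre in
translation; rotational recovery plateaus at about three degrees median
on this smooth phantom, which carries far less rotational information
than real anatomy (see the methods vignette for the analysis).
`res$corrected` is the realigned series carrying the rotated gradient
table, `res$weights` holds the final slice/voxel weights, and
`res$prediction` the model reconstruction.

A thin command-line front end over the same functions is installed at
`inst/cli/dwimotion.R` (subcommands `design-scheme`, `simulate`,
`fit-shore`, `weights`, `rician-correct`, `b1-correct`, `correct`,
`evaluate`).

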