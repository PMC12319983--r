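---
title: "Model-based motion correction for multi-shell diffusion MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based motion correction for multi-shell diffusion MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Diffusion MRI of a moving subject — the fetus being the extreme case —
produces a 4D series in which every volume may be displaced by a different
rigid transform, individual slices may be degraded by signal dropout or
spin-history hyperintensities, and the whole series sits at low SNR with
Rician (magnitude) noise statistics. Because every volume carries a
*different* diffusion contrast (its b-value and encoding direction), the
standard trick of registering everything to one reference volume fails:
volumes are not supposed to look alike.

`dwimotion` implements the model-based alternative: represent the diffusion
signal per voxel in a smooth q-space basis, predict from that model what
each acquired volume *should* look like, register each acquired volume to
its own same-contrast prediction, down-weight slices and voxels that the
model cannot explain, and iterate.

# The signal model

Per voxel, the normalized diffusion signal E(q) over the q-space point
q = q·u is expanded in a simple-harmonic-oscillator (SHORE) basis

E(q) = Σ_{l even} Σ_{n=l..N} Σ_{m=-l..l} c_{nlm} X_{nl}(q, ζ) Y_{lm}(u),

with radial functions built from generalized Laguerre polynomials,

X_{nl}(q) = κ_{nl} (q²/ζ)^{l/2} e^{-q²/(2ζ)} L_{n-l}^{l+1/2}(q²/ζ),

and real even-degree spherical harmonics Y_{lm}. The normalization
κ_{nl} = sqrt(2 (n-l)! / (ζ^{3/2} Γ(n+3/2))) makes the basis orthonormal
under the measure q² dq dΩ, which the test suite verifies by numerical
quadrature. The radial index runs over the *full* range n = l..N: at order
N = 6 this yields 72 basis functions (1, 8, 29 at orders 0, 2, 4). The
alternative truncation n ≤ (N+l)/2, which yields 50 functions at order 6,
is deliberately not used — the larger set is the point of this basis.

Coefficients are estimated by weighted ℓ2-regularized least squares,

c* = argmin_c ‖W(Φc − E)‖² + λ_l ‖Lc‖² + λ_n ‖Nc‖²,

with diagonal penalties diag(L) = l(l+1) and diag(N) = n(n+1) on the
angular and radial frequencies, solved per voxel by Cholesky on the normal
equations with Jacobi equilibration and two steps of iterative refinement
(the design matrix is at most ~100 × 72, so dense solves are cheap).
Voxels that share a weight vector — all voxels of a slice, under
slice-wise weighting — share one factorization.

**Units.** q = sqrt(b)·u with b in s/mm², and the diffusion-time scale is
absorbed into ζ. This is a unit convention, not physics: ζ = 700 (the
default) is calibrated for this mapping. With two shells plus b = 0 the
radial direction of the basis is underdetermined (three distinct |q|
magnitudes, seven radial orders); the small default penalties
λ_l = λ_n = 1e-8 select a well-behaved interpolant, and predictions are
only ever evaluated at sampled |q| shells inside the engine. Unregularized
fits demand a sampling with at least as many distinct radial magnitudes as
radial orders; the coefficient-recovery tests use ten shells out to
b = 6000 s/mm² for that reason.

# Outlier weighting

Three complementary tiers populate the diagonal weight matrix W:

1. **Modified Z-score on slice means** (initialization; needs no
   prediction). Per b-shell, slice-mean intensities are scored as
   Z = |mean − median| / (1.4826·MAD) and mapped through the soft ramp
   w = 1 − (Z − η_l)/(η_u − η_l), clamped to [0, 1]. The thresholds
   default to η_l = 3 (the conventional modified-Z outlier cut, softened)
   and η_u = 10. Slices with no voxels in the brain mask carry no
   evidence: they get weight 1 and are excluded from the shell statistics
   (without a mask, an empty slice has mean 0 and is down-weighted
   naturally).
2. **Gaussian mixture on prediction residuals** (middle epochs). Per
   shell, the log of each slice's RMSE against the current prediction is
   modelled with a Gaussian mixture; model selection (BIC, one vs two
   components) decides whether an outlier population exists at all, and
   the posterior probability of the lower-mean component is the slice
   weight. Two guards keep this honest: a shell with fewer than 4
   scoreable slices, or a degenerate single cluster, keeps all weights 1;
   and slices whose RMSE is below 2% of their mean signal are inliers by
   construction — residuals at the level of the reconstruction accuracy
   itself are not artifacts, and without this floor near-noiseless data
   would have its tiny model-misfit residuals split into two clusters.
3. **Voxel-wise weights** (final epoch). Standardized residuals
   z = (E − Ê)/(1.4826·MAD) per volume map to the smooth redescending
   weight w = 1/(z² + 1)² (1 at z = 0, 1/4 at z = 1, 1/100 at z = 3).

# Registration to prediction

Each acquired volume is registered rigidly to its own model prediction —
fixed and moving images share diffusion sensitization by construction.
The metric is global normalized cross-correlation over a 3-level
multiresolution pyramid (block-averaged by factors 4, 2, 1) with
Nelder-Mead, followed by full-resolution polish passes.

Numerical choices that mattered, found during development and locked in:

* **Cubic polish.** Trilinear interpolation inside the objective low-pass
  filters the moving image by an amount that varies with the transform,
  biasing the optimum by up to a degree; two restarted Nelder-Mead passes
  with Catmull-Rom interpolation at full resolution remove this.
* **Metric pre-smoothing.** Both images are smoothed (Gaussian, 0.8
  voxels) before the metric: this suppresses the noise-induced shift of
  the correlation optimum while biasing both images identically. The
  smoothing is plain zero-padded convolution — renormalizing at the array
  edge would brighten the clipped border of a strongly displaced volume
  and bias exactly the large motions that matter.
* **Support-restricted polish.** The polish metric is evaluated on the
  support of the fixed image (prediction > 2% of max): voxels where the
  model predicts nothing carry no information. For the same reason the
  engine dilates the brain mask by about two voxels before fitting, so
  the model covers the partial-volume halo around the brain; a prediction
  that is zero where the data still has signal biases the metric at the
  boundary.
* **Capture range.** The coarse pyramid level with full-volume NCC finds
  20 mm / 24° displacements reliably on brain-sized objects; each volume
  is additionally seeded with its previous-epoch estimate and its
  temporal neighbour's current estimate.

Registration is volume-to-volume only. Within-volume (inter-slice and
intra-slice) motion is not corrected geometrically; it is handled by the
weighting tiers, which is the design point of the whole framework.

# The iterative engine

`correct_motion()` runs a fixed number of epochs (default 5):

* **Epoch 1** — modified-Z slice weights (no prediction exists yet),
  weighted SHORE fit in the original q-space basis, prediction of every
  volume's contrast, registration of each acquired volume to its
  prediction, rotation of each gradient direction by its volume's
  realignment rotation.
* **Epochs 2–4** — realign the *original* volumes with the current
  inverse transforms (trilinear), mixture slice weights against the
  current prediction, rebuild the basis on the rotated q-space points
  Φ(q^(k)), refit, re-predict, re-register, re-rotate. Internal
  predictions are evaluated at each volume's *current rotated* q-space
  point: the reference image for volume v then has exactly the diffusion
  sensitization of the acquired volume v, which is the property that
  makes registration-to-prediction valid (predicting at the nominal,
  unrotated direction would hand a burst volume a reference whose
  contrast belongs to a direction tens of degrees away). Only the
  returned reconstruction is evaluated in the nominal q-space.
* **Final epoch** — final realignment with cubic interpolation,
  voxel-wise weights added to the slice weights, final fit in the rotated
  basis, final prediction in the original sampling scheme.

Transforms always map the original acquired volumes, so resampling error
never compounds. A registration outside ±50 mm / ±60° flags the volume
and forces its weights to zero; processing continues without it. The
engine is deterministic: every stochastic-looking component (mixture fit,
optimizer) is run with fixed, deterministic initialization.

On an already-aligned noiseless series the estimated trace stays at zero
to well under 0.1 mm / 0.1° when the full two-shell protocol is sampled
(the residual is prediction misfit, which shrinks with angular coverage);
note that the weighted RMSE of the *final* epoch compares the prediction
with data that has been resampled once, so on pristine input it can sit
slightly above the epoch-1 value even though nothing was "worsened" — on
motion-corrupted input it drops several-fold.

# Sampling scheme design

The acquisition designer minimizes an antipodally symmetric Coulomb
energy E(S) = Σ_{i<j} 1/‖u_i−u_j‖ + 1/‖u_i+u_j‖, combined as
0.5·E(pooled) + 0.5·mean-per-shell E — balancing whole-set and per-shell
angular uniformity — with multi-start projected gradient descent on the
sphere (20 restarts by default, deterministic per seed). Degenerate
(coincident/antipodal) configurations get the largest finite energy so
the optimizer can escape them rather than aborting.

The temporal ordering interleaves the b = 0 volumes evenly, keeps every
temporal prefix of diffusion-weighted volumes within one volume of the
overall shell ratio (largest-deficit quota rule), and places directions
within each shell by greedy farthest-point selection against the already
placed ones. Any contiguous segment of the acquisition therefore samples
both shells and covers the sphere nearly uniformly, which is what makes
partial data usable when motion corrupts a stretch of the scan. The
recommended fetal protocol is 11 interleaved b = 0 volumes plus 28
directions at b = 400 and 56 at b = 900 s/mm² — 95 volumes.

The even-spacing rule for the b = 0 volumes is a choice (the protocol
specifies "interleaved" without a rule); round(seq(1, N, length.out = 11))
is used.

# Intensity corrections

**Rician bias.** The measured magnitude mean ⟨M⟩ overestimates the true
intensity η at low SNR. With ξ(θ) = 2 + θ² − (π/8)e^{−θ²/2}[(2+θ²)I₀(θ²/4)
+ θ²I₁(θ²/4)]² and θ = η/σ, the corrected intensity solves the fixed
point E_c² = ⟨M⟩² + (ξ(E_c/σ) − 2)σ², iterated to 1e-6 relative
tolerance. The sign convention is fixed by the moment identity — the
bracketed term is exactly (8/π)(⟨M⟩/σ)² of a Rician at SNR θ, so the
fixed point is mean-matching and E_c ≤ ⟨M⟩ always; a Monte-Carlo oracle
(10⁶ draws) confirms recovery of η within 1% at θ = 5 and within 2% down
to θ = 1. Everything is evaluated with exponentially scaled Bessel
functions, which is stable at any θ; note 1 − ξ(θ) ≈ 1/(2θ²), so ξ is
within 1e-3 of its limit from θ ≈ 23 upward. σ is accepted as a map or
scalar; a fallback estimator from half-differences of consecutive b = 0
volumes (1.4826·MAD/√2) is provided.

**B1 receive field.** Given a multiplicative field β (estimated
externally, e.g. by N4), the series is corrected as
E_c(q) = E(q) · mean_b0_corrected / (β · mean_b0_raw), an exact rescaling
that is trivially invertible.

# The synthetic phantom

The test surface for everything above is a multi-tensor phantom: an
ellipsoidal "brain" (semi-axes 20 × 17 × 14 mm, 2.5 mm isotropic voxels
on a 32³ grid by default) containing a CSF-like isotropic core
(2.5e-3 mm²/s) deliberately offset from centre so that no rigid rotation
maps the phantom onto itself, two single-fiber lobes (principal axes
along x and y, eigenvalues 1.8/0.3/0.3 ×10⁻³ mm²/s), a 50/50
crossing-fiber band between them, a smooth intensity shade plus a gentle
sinusoidal texture (registration cues inside homogeneous regions), and
Gaussian partial-volume smoothing of the tensor field (0.8 voxels) so
that region boundaries resemble imaging data rather than voxel art.

The corruption model applies, in order: per-volume rigid motion (the
signal is evaluated along the motion-rotated encoding direction R^T u,
then the volume is moved by the forward transform), multiplicative slice
dropouts (attenuation in (0,1)) and spin-history hyperintensities
(gain > 1), and complex-domain Rician noise |S + n₁ + i n₂|. Susceptibility
distortion is simulated separately as an opposed-blip pair: displacement
±(fieldmap × readout scaling) along the phase-encode axis with a
mass-preserving 1D pushforward, so stretching in one blip appears as
pile-up in the other and total intensity is conserved.

Default study conditions (used by the acceptance script and the heavier
tests): the 95-volume protocol above; burst motion — a slow sinusoidal
baseline (±4 mm / ±4°) punctuated by three 4–7 volume bursts, the largest
reaching 20 mm / 24°, matching the strongest motion observed in moving
subjects; Rician σ = 5 at S0 = 100 (b = 0 SNR 20, a realistic fetal
value — the b = 900 shell then sits at SNR 4–12, which is the hard part);
dropout attenuation 0.2 on 10% of brain-crossing slices.

What the phantom does *not* emulate: realistic anatomy and its
partial-volume complexity, eddy-current distortions, intra-volume
(slice-level) motion, spatially varying noise from parallel imaging, and
maternal tissue surrounding the brain. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as
designed under controlled corruption — not that clinical fetal data of
arbitrary quality will reach the same numbers.

# Evaluation

SSIM uses the standard constants (K1 = 0.01, K2 = 0.03), a 7-voxel
uniform window evaluated on interior (valid) windows via integral images,
the dynamic range taken from the image pair, computed slice-wise and
averaged (a 3D windowed variant is available). PSNR is
10·log10(range²/MSE) with an infinite sentinel for identical images.
Motion-trace error reports per-volume translation error (Euclidean norm)
and rotation error (geodesic angle of R_true R_est^T, in degrees), with
median/IQR summaries.

# Problem sizes

The heavier checks run the full engine on the 95-volume protocol at 32³
(motion recovery, SSIM improvement) and 24³ (dropout recall); these take
a few minutes each on a single core, dominated by the ~380 rigid
registrations of the five-epoch loop. The compact 30-volume scheme used
in the faster unit tests leaves the order-6 angular model underdetermined
(16 directions against 28 angular terms on the outer shell), so its
quantitative bounds are intentionally loose; the protocol-level bounds
are asserted under the full study conditions.

# Known limitations

* Rotational recovery is prediction-limited. On the default phantom study
  (b = 0 SNR 20) translations are recovered to well under a millimetre
  (median), but per-volume rotations plateau at roughly 2–3° median: the
  single-volume information floor for registering one b = 900 volume
  (SNR ≈ 7) to a perfect reference is already about 1.2° on this phantom,
  and the alternating loop converges to a self-consistent reconstruction
  that retains a residual rotational distortion of a degree or two
  (registering volumes to the converged reconstruction drifts by that
  much even when started at the true transform, and noiseless runs show
  the same plateau). Richer image structure — real anatomy — carries more
  rotational information than a smooth phantom, so this is a conservative
  setting for rotations.
* Volume-level registration only; severe intra-volume motion is
  down-weighted, not corrected.
* The two-shell protocol leaves the radial basis direction regularization-
  determined; coefficients are not individually interpretable there, only
  predictions at sampled shells are.
* Field-map estimation is out of scope: the opposed-blip distortion model
  is a simulation tool, and correction assumes an externally supplied
  field/bias map.
* The registration metric is global NCC; pathological intensity artifacts
  that survive weighting could in principle bias it.
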