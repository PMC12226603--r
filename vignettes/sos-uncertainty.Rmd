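---
title: "Speed-of-sound reconstruction, uncertainty, and acquisition selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed-of-sound reconstruction, uncertainty, and acquisition selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inverse problem

Pulse-echo speed-of-sound (SoS) imaging measures apparent speckle
displacements between beamformed frames acquired under different virtual-source
(VS) transmit angles. When the tissue SoS deviates from the beamforming
assumption $c_0$, echoes appear shifted along the differential propagation
paths of a transmit pair. With slowness $x = 1/c$ collected on an
$N_\mathrm{ax} \times N_\mathrm{lat}$ grid, the vectorized time delays $d$
from $M$ transmit pairs obey, to first order,

$$ d \approx L\,(x - x_0), \qquad x_0 = 1/c_0 , $$

where $L$ stacks, pair-major, discretized acoustic path-integral matrices:
each row holds the per-pixel traversal-length differences (mm) between the two
straight round-trip rays of one pair at one measurement pixel. Because both
transmits of a pair share the same receive path, the receive leg cancels in
every row; `build_forward_model()` therefore assembles rows from transmit-leg
differences only, which tests validate against a dense ray-marching oracle of
the full round trips. Reconstruction solves

$$ \hat{x} = \arg\min_x \; \lVert L (x - x_0) - d \rVert_p + \lambda\, \mathcal{R}(x) ,
\qquad \hat{c} = 1 / (\hat{x} + x_0). $$

This is a limited-angle tomographic problem: rays enter only from the
transducer face within a narrow angular fan, so the operator is
ill-conditioned and strong priors (or learned regularization) are essential.

### Modeling simplifications

The single biggest simplification is the **straight-ray (refraction-free)
forward model**: rays are traced as straight segments from the VS wavefront to
each pixel and back to the aperture, truncated at the field-of-view boundary.
Bent-ray or full-wave physics are out of scope. The default VS geometry is the
**plane-wavefront limit** (virtual source at infinity, angles evenly spaced
over ±20°); a finite focal offset behind the aperture is available through
`acquisition_spec(vs_depth_mm = ...)`. We interpret the default 84 × 64
reconstruction grid as axial × lateral (84 depth rows over a 64-element
aperture); both orientations are configurable since only the product is fixed
by convention. The measurement grid defaults to the reconstruction grid.

Transmit pairs follow the fixed-offset rule $(i, i+2)$, giving the documented
15 displacement maps from 17 transmits; the offset is configurable.

## Analytical baseline

`solve_inverse_lbfgs()` minimizes the $p$-norm data term with an anisotropic
total-variation prior, all $\ell_1$ terms smoothed as
$\sqrt{t^2 + \varepsilon^2}$ so LBFGS applies. The problem is solved in
measurement-normalized units ($x/\max|d|$), making `lambda_reg` and
`smoothing_eps` unit-free. Initialization is $x = 0$ (i.e. $c = c_0$) and the
solver runs a few warm restarts of `optim(method = "L-BFGS-B")`
(`factr = 1`, `lmm = 20`), which polishes solutions on this ill-conditioned
operator to the accuracy the tests demand. The default `lambda_reg = 5e-4`
was fixed once by an L-curve sweep on the synthetic test preset (the corner of
the data-misfit vs. total-variation trade-off); it is not revisited by any
test.

## The variational network

The reconstruction network unrolls $K$ gradient-descent steps with learnable
components,

$$ x_k = x_{k-1} - \Big[ (s_k L)^\top \psi_k\!\big(s_k (L x_{k-1} - d)\big)
   + \nabla R(x_{k-1}) \Big], \qquad x_0 = 0, $$

with the field-of-experts regularization gradient

$$ \nabla R(x) = \sum_{j=1}^{N_k} r_k^{(j)\top} \ast
   \Big( w_k^{(j)} \cdot \phi_k^{(j)}\big(r_k^{(j)} \ast x\big) \Big). $$

Per layer, the learnable parameters are the filter kernels $r$ ($o \times o$),
per-pixel prior weights $w$, per-measurement data weights $s$, and the
penalty transforms $\phi, \psi$, each a piecewise-linear function given by
ordinates at fixed equispaced knots on $[-1, 1]$ with constant extrapolation.
The global regularization weight $\lambda$ is absorbed into $w$ — the printed
update has both, but only their product is identifiable, so we keep the
spatially-resolved learnable factor.

Numerical conventions:

* **Convolutions** are cross-correlations with zero padding and "same" output
  size; the transpose is correlation with the flipped kernel under the
  complementary padding, so the adjoint identity
  $\langle r \ast a, b\rangle = \langle a, r^\top\!\ast b\rangle$ holds
  exactly (unit-tested).
* **Normalization.** All learnable transforms act on normalized responses:
  the slowness deviation and measurements are expressed in units of
  `x_scale`, and each filter/data response is divided by a per-filter scale.
  These scales are calibrated once from the first training batch (the maximum
  absolute response observed) and then frozen.
* **Initialization.** Filters start at small zero-mean Gaussian values
  (zero-mean enforced at initialization only), $\phi$ and $\psi$ at the
  identity, $w$ at a small constant, and $s$ at $1/\sigma_{\max}(L)$
  (power iteration), so the initial network is approximately normalized
  gradient descent on the least-squares data term — a stable starting point.

### Training

The loss is an exponentially layer-weighted L1 reconstruction error plus a
smoothed second-difference penalty on the $\phi$ control points,

$$ \mathcal{L} = \sum_{k=1}^K e^{-\tau (K-k)} \lVert x_k - x^\ast\rVert_1
 + \lambda_r \sum_{k,j,i} \sqrt{\big(y^{\phi}_{i-1} - 2y^{\phi}_i + y^{\phi}_{i+1}\big)^2 + \varepsilon}. $$

Gradients of the full unrolled computation are computed by the package's own
reverse-mode differentiation (R has no autodiff framework of the kind deep
learning stacks provide); every parameter family is verified against central
finite differences in the test suite. Optimization is mini-batch Adam. The
batch loss is the mean over samples; the smoothness and KL penalties enter
once per objective evaluation.

**Scaled-down study conditions.** The package's default training conditions
are deliberately small enough to run on one CPU: a 21 × 16 grid at 2 mm pitch
(42 × 32 mm field of view), 17 transmits / 15 pairs, 500 training and 32 test
samples, $K = 5$ layers, $N_k = 8$ priors, $o = 5$ kernels, 21 knots, 1200
Adam iterations at batch 8, learning rate $2\cdot10^{-3}$, $\tau = 0.5$,
$\lambda_r = 10^{-3}$, $\varepsilon = 10^{-6}$. The full-scale reference
setting (84 × 64 grid, $o = 8$, 10,000 samples, 120,000 iterations, batch 16)
is expressible through the same configuration objects but is not what the
tests run. Architecture size, iteration count and learning rate are free
hyperparameters chosen once for this problem size.

## Synthetic data generator

The generator defines the study conditions and is itself first-class, tested
code.

* **Phantoms.** One inclusion per phantom: a random ellipse (random center,
  semi-axes 8–20% of the field of view, rotation) whose boundary radius is
  modulated by a smooth periodic random field (Gaussian-filtered angular
  noise, relative amplitude 0.15) — "deformed ellipse". With probability 0.5
  the edge is low-pass filtered (Gaussian, σ = 1.5 mm) into a smooth
  transition; the mask is then the 0.5 level set. 5% of samples are
  inclusion-free. Background SoS is uniform on 1490–1540 m/s (slight
  per-sample variation around the beamforming assumption $c_0 = 1515$ m/s);
  the inclusion contrast magnitude is uniform on 10–60 m/s with random sign —
  plausible for breast tissue, configurable.
* **Measurements.** To avoid the inverse crime, measurements are simulated on
  an `hr_factor = 2` upsampled grid with an independently built operator
  $L_\mathrm{hr}$: the slowness map is upsampled (nearest neighbor),
  $d_\mathrm{hr} = L_\mathrm{hr} x_\mathrm{hr} + \epsilon$ with i.i.d.
  Gaussian $\epsilon$, then block-averaged to the coarse measurement grid.
  The coarse reconstruction operator is never used for simulation. The noise
  level is not stated in the problem setting; the default is calibrated so
  the displacement SNR is 20 dB against a 40 m/s-contrast disk reference
  (`calibrate_noise_std()`), a moderately noisy regime.
* **Multi-frame cases.** `make_lesion_case()` images one phantom `n_frames`
  times (the clinical protocol uses 3–5). Corrupted frames get their noise
  std multiplied by `corruption_scale` plus a random low-frequency
  displacement offset field (rms $(\text{scale}-1)\sigma$, correlation length
  a quarter of the grid) as a hand/body-motion surrogate; `scale = 1` is an
  exact null. Cases are labelled CA (carcinoma-like) when the absolute
  contrast exceeds 35 m/s, FA otherwise, so the synthetic cohort is
  contrast-separable by construction.

What the generator does **not** emulate: speckle statistics and displacement-
tracking errors, acoustic shadowing, refraction, aberration, anisotropy, and
real lesion morphology. Passing tests therefore demonstrate correctness of
the algorithms and the qualitative behavior of uncertainty-informed
selection under controlled corruption — not clinical performance.

## Uncertainty estimation

Both schemes sample the posterior of the *filters only*; all other parameters
stay point estimates.

**Monte Carlo dropout (MCD).** Each prior's kernel is dropped as a whole with
probability $p = 0.25$, independently on the analysis ($r \ast x$) and
synthesis ($r^\top \ast$) sides of every layer — filter-level removal, since
individual coefficients are only meaningful within a kernel. Deliberately, no
$1/(1-p)$ rescaling is applied to the surviving filters (deviating from
standard inverted dropout; the masked update is used as written). Per-element
masks are available by configuration. The MCD model is trained with the same
dropout active, following the standard MC-dropout prescription of matching
train- and test-time noise.

**Bayesian variational inference (BVI).** The $t$ filter coefficients get a
Gaussian posterior $\mathcal{N}(\mu, \Sigma)$ with $\Sigma = DD^\top$, $D$
lower-triangular and block-diagonal with one $o^2 \times o^2$ block per
filter (filters mutually uncorrelated). Samples are reparameterized draws
$\mu + Dy$, $y \sim \mathcal{N}(0, I)$, one per forward pass during training.
The KL divergence from the isotropic prior $\mathcal{N}(\mu, \alpha^{-1} I)$
reduces (constants dropped) to

$$ \mathrm{KL} \approx \alpha\,\mathrm{tr}(DD^\top) - 2\,\mathrm{tr}(\log D)
 = \alpha \sum_{ij} D_{ij}^2 - 2 \sum_i \log D_{ii}, $$

computed without ever forming $\Sigma$ or a determinant — the printed KL
formula with its garbled trace placement is implemented as the standard
Gaussian KL whose simplification this is. Positivity of $\mathrm{diag}(D)$ is
maintained by optimizing its logarithm; off-diagonal entries are free.
Defaults $\alpha = 0.1$, $\beta = 10$, $\mu \sim \mathcal{N}(0, 10^{-4})$,
$D_{ii} \sim U(0.9, 1.1)$.

**Posterior summaries.** At inference both schemes draw $S = 100$ samples
(chosen as a safe upper bound for the stability of the summary statistics),
convert each to SoS, and report the per-pixel sample mean as the
reconstruction and the sample standard deviation (ddof = 1) as the
uncertainty map.

## Frame selection and evaluation

For each frame, `score_frame()` computes the mean uncertainty inside the
operator-annotated inclusion and in the 5 mm ring around it (morphological
dilation by $\lceil 5\,\mathrm{mm} / \mathrm{pitch} \rceil$ pixels per axis
with an axis-aligned rectangular structuring element — chosen over a disc for
exact pixel-count testability — minus the inclusion). The *relative*
uncertainty is their absolute difference; policies `SI_rel` / `SI_inc` pick
the frame minimizing the relative / inclusion uncertainty, against the
uninformed baselines `S1`, `S3`, `SR`. "Uncertainty mean" is the arithmetic
mean over the mask (a median variant is available). Each frame is scored with
its own mask; the synthetic generator reuses one mask per case since viewing
directions are not modeled. Ties break to the lowest index; indices are
1-based in R.

Diagnosis uses the SoS contrast $\Delta c = |\mathrm{median}_{inc}\,c -
\mathrm{median}_{ring}\,c|$ computed on the posterior-mean map of the selected
frame, oriented so larger values indicate carcinoma (the positive class).
`roc_auc()` sweeps thresholds over the unique scores (positive when score ≥
threshold), computes AUC by the rank statistic (ties 0.5), and reports
F1/sensitivity/specificity at the operating point maximizing sensitivity +
specificity, ties to the lower threshold. Group differences use the
two-sided Wilcoxon rank-sum test: exact for combined $n \le 12$ without
ties, normal approximation with tie correction otherwise — normality
screening is deliberately out of scope, the nonparametric test is hard-coded.

## Problem sizes used by the tests and the acceptance script

Oracle and property tests run on grids of 3 × 3 to 12 × 10 pixels. The
"not-inferior" comparison trains all three models (VN, MCD, BVI) under the
scaled-down conditions above; frame-selection power uses 200 four-frame cases
with three frames corrupted at scale 5 and a 60-case cohort (30 CA-like at
45–60 m/s contrast, 30 FA-like at 10–20 m/s, a gap several times the
noise-induced $\Delta c$ spread) scored with the MCD model at $S = 100$.
These sizes are the package's own scaled-down choices, stated here so results
can be reproduced exactly; `scripts/acceptance.R` re-runs them end to end
from a single seed.

### What uncertainty-guided selection does — and does not — do on this synthetic data

An important empirical finding of the package's own experiments: under the
generator's corruption model, the argmin-`SI_rel` policy does **not** recover
the clean frame above chance — it systematically prefers corrupted frames
(hit rate ≈ 0.13 vs 0.25 chance over 200 four-frame cases). The mechanism is
diagnosable: heavily corrupted measurements drive the learned data transforms
into their saturated range, so corrupted frames reconstruct *smoother,
lower-contrast* inclusions; the filter-posterior uncertainty concentrates at
reconstructed structure (inclusion edges), so the clean frame — having the
sharpest inclusion — exhibits the *largest* inclusion-to-background
uncertainty difference and is anti-selected. This holds across MCD and BVI
and across corruption scales 5–100. In vivo, motion corruption instead *adds*
spurious structure near the lesion, the regime in which relative uncertainty
is a useful trust score. The generator's suppressive corruption (scaled noise
plus a smooth offset field) therefore probes a different regime than clinical
motion artifacts. Despite the inverted hit rate, `SI_rel` selection still
classifies the synthetic CA/FA cohort at least as well as random selection
(AUC ≈ 0.89, better than `SR` in 20 of 20 selection seeds), because its
deterministic, uncertainty-consistent choice removes selection variance from
the contrast statistic.

## Known limitations

* Straight rays: refraction and aberration are not modeled, so the operator
  is increasingly wrong at high contrast.
* The generator's corruption model (scaled noise + smooth offset field) is a
  crude motion surrogate; real motion produces structured, correlated
  artifacts.
* Uncertainty is epistemic-over-filters only; no aleatoric heads, ensembles,
  or uncertainty over $w, s, \psi, \phi$.
* Scaled-down training on a tiny grid: absolute RMSE numbers are not
  comparable to full-scale results, only the relative orderings the tests
  assert.
* Whether BVI should also treat non-filter parameters probabilistically is
  open; we keep them deterministic, matching the stated restriction to
  filters.
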