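---
title: "Threshold-free activation mapping with lisar: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-free activation mapping with lisar: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

Voxelwise tests on fMRI contrast maps face a severe multiple-comparison
problem: at ~10^5 voxels, uncorrected thresholds flood the map with false
positives, while familywise corrections on independent voxels discard the
spatial coherence that real activations exhibit.  Cluster-extent methods
exploit that coherence but require an arbitrary cluster-defining threshold
and report inference at cluster, not voxel, resolution.

`lisar` implements LISA, a threshold-free alternative built from three
components:

1. an uncorrected voxelwise **z-map** (one-sample, two-sample, or
   single-subject GLM contrast, quantile-transformed from t to z);
2. an **edge-preserving bilateral filter applied after the test**, which
   strengthens spatially coherent signal without blurring activation
   borders;
3. **permutation-based FDR control** on the filtered map via a conservative
   two-component mixture model, since filtered values are no longer
   standardized and classical Benjamini–Hochberg no longer applies.

The null hypothesis at every voxel is one-sided: *the effect is not
positive*.  Negative effects are probed by negating the contrast and
re-running, not by two-sided scoring.

## The bilateral filter

For voxel $i$ with value $z_i$ and neighbourhood $\Omega_i$,

$$\lambda_i = \frac{1}{W_i} \sum_{j \in \Omega_i} z_j\,
  f_r(\lVert z_i - z_j\rVert)\, g_s(d(i,j)), \qquad
  W_i = \sum_{j \in \Omega_i} f_r(\lVert z_i - z_j\rVert)\, g_s(d(i,j)),$$

with Gaussian kernels in the calibrated parameterisation
$f_r(x) = \exp(-x^2/\sigma_r)$ and $g_s(x) = \exp(-x^2/\sigma_s)$ — note the
single $\sigma$ in the denominator, not $2\sigma^2$; the defaults
$\sigma_s = \sigma_r = 2.0$ are calibrated to this form.  The spatial
kernel favours near neighbours; the range kernel suppresses neighbours with
dissimilar values, which is what preserves edges.  A neighbour average with
$z_i$ rather than $z_j$ inside the sum would cancel against $W_i$ and
return the input unchanged, so the filter uses the standard form with
$z_j$.

**Neighbourhood.** $\Omega_i$ is the 5×5×5 cube of offsets minus its 8
corners — exactly **117 voxels**, the unique natural set of that size
(an exact Chebyshev or Euclidean ball of radius 2 would contain 125 or 33
voxels respectively).  Geometry is computed in voxel units by default
(`distance = "voxel"`), because the filter parameters are stated in voxels;
`distance = "mm"` measures $d(i,j)$ physically for strongly anisotropic
acquisitions.  At radius 1 the same cube-minus-corners construction yields
the 19-voxel set (centre plus 18 face/edge neighbours) that the boundary
rule below uses.

**Scaling.** $\sigma_r$ only makes sense relative to the spread of the map
values, so the observed and all permuted maps are divided by one common
factor: the standard deviation of the *pooled* in-mask values of the first
30 permuted maps.  Pooling (rather than averaging per-map SDs) was chosen
as the simpler estimator; with ≥ 30 × (number of in-mask voxels) values the
difference is negligible.  Only the first 30 maps enter, so the factor is
identical no matter how many permutations follow.

**Boundary rule.** A voxel that keeps at least $\lceil 117/2 \rceil = 59$
of its stencil in the mask is filtered normally over the in-mask members.
Below that, the filter falls back to a **median** over the in-mask
18-neighbourhood provided at least 9 of those 18 neighbours are in-mask;
otherwise the voxel is **discarded**.  Two conventions the original
formulation leaves open are fixed here: the centre voxel joins the median
(ties resolved toward evaluation rather than discard throughout), and the
median of an even count is the mean of the two middle values.  Discarded
voxels are excluded from all pooling, treated as out-of-mask by subsequent
iterations, reported with FDR = 1, and flagged in a companion evaluability
mask — "discarded" is otherwise unrepresentable in a scalar volume.

**Iterations.** The filter is applied twice by default, each pass consuming
the previous output.  Because the fallback/discard decision depends only on
mask geometry, evaluability is identical for every map filtered with the
same mask — a property the permutation machinery relies on.

## The permutation null

Exchangeability dictates the scheme:

* **one-sample group mode** — each subject's contrast map is negated as a
  whole with probability ½ (sign flips preserve within-map spatial
  autocorrelation).  Draws are i.i.d., so repeats and the identity draw can
  occur; the observed statistic is *not* added to the null ensemble.
* **two-sample group mode** — every map is reassigned to one of the two
  groups with probability ½; assignments leaving a group with fewer than
  two maps are redrawn.
* **single-subject mode** — task labels are permuted *within runs only*
  (volumes themselves are not exchangeable under temporal autocorrelation).
  The default preserves each run's label multiset, the exchangeable
  reading; `resample_labels = TRUE` draws labels independently from the
  run's pool for users who prefer the literal resampling formulation.
  Drift regressors are not permuted.

Each permutation is pushed through the *identical* pipeline as the observed
data — statistic, scale factor, filter parameters — and the in-mask
evaluable filtered values are pooled into the null ensemble, the empirical
estimate of $F_0$.  The ensemble stores exact values up to a memory cap
(2×10^7 by default) and falls back to a fixed 10,000-bin histogram beyond
that; at desk scale the exact path is always taken.  Permuted maps are
processed in a stream, so peak memory is roughly two volumes plus the
ensemble.

## FDR from the two-component mixture

With prior null probability $p_0$ and component distributions $F_0$
(permutation null) and $F_1$ (non-null, never estimated directly), the
mixture is $F_z = p_0 F_0 + p_1 F_1$ and the tail-area false discovery
rate at threshold $\lambda$ is

$$\mathrm{Fdr}(\lambda) = p_0\, F_0(\lambda)\, /\, F_z(\lambda).$$

Because estimating $p_0$ is error-prone, it is fixed at **1**, the most
conservative choice: every reported score is an upper bound on the
corresponding score under any $p_0 < 1$.

Both distributions are estimated empirically, with no histogram binning or
density smoothing: $F_0$ from the pooled null values, $F_z$ from the
observed filtered map itself.  Since the method detects *positive*
activations, both enter as right-tail exceedance proportions
$S(\lambda) = \Pr(X \ge \lambda)$ (ties inclusive); a literal left-sided
CDF ratio tends to $p_0$ at large $\lambda$ and cannot flag activations,
so the left-tail form is kept only as an audit option (`tail = "left"`).
The observed voxel itself counts in $S_z$, so the denominator never
vanishes.

Raw ratios are clipped to $[0,1]$ and monotonised q-value style: each voxel
receives the smallest clipped ratio attained at any threshold no larger
than its own $\lambda$ (a cumulative minimum in ascending $\lambda$ order).
Scores are therefore monotone non-increasing in $\lambda$, rank-based
(invariant under any strictly monotone relabelling applied to observed and
null values alike), and thresholding at any level `q` selects a single
$\lambda$ cutoff.

## Single-subject model

The first-level GLM uses boxcar regressors convolved with the canonical
double-gamma HRF (peak 6 s, undershoot 16 s, amplitude ratio 1/6, no
derivative terms), one shared regressor per condition across runs, plus a
per-run intercept and polynomial drift (order 3 by default).  Fitting is
ordinary least squares; the contrast t statistic is mapped to z by the
quantile transform.  No temporal prewhitening is applied by default —
inference rests on the label permutations, not on a noise model — but an
AR(1) Cochrane–Orcutt option (`ar1 = TRUE`) is available.  Rank-deficient
designs abort with the names of the collinear columns.

## Numerical choices

* **t→z mapping**: $z = \Phi^{-1}(T_\nu(t))$, capped at $|z| = 8.2$ to keep
  maps finite — a numerical, not statistical, choice.  For odd integer
  degrees of freedom (every one-sample test on an even group size) the t
  CDF is evaluated by its elementary arctan series, which is exact to
  rounding and fast; tail probabilities below $10^{-8}$, and all other
  degrees of freedom, use the log-probability route so the mapping does
  not saturate before the cap.  Voxels with zero sample variance are set
  to $\pm 8.2$ with a warning.
* **Degenerate inputs**: an empty mask, fewer than 30 permutations (the
  scale factor needs 30 permuted maps), or a zero-variance null are fatal
  errors rather than silent defaults.
* **Determinism**: every random choice derives from the user seed; two runs
  with identical configuration produce bit-identical outputs.  Internal
  sub-seeds stay below 2^31.
* **Performance**: the filter engine visits each symmetric offset pair
  once and keeps its hot loops branch-free so the compiler can vectorise
  the `exp()` evaluations; out-of-mask neighbours are excluded exactly by
  multiplying each pair weight with the validity of both endpoints.  A
  full study-scale analysis (20 maps, 24³ grid, 500 permutations) takes a
  few seconds on one core.

## The synthetic-data module

`simulate_noise()` draws stationary Gaussian fields by spectral synthesis:
the FFT of the target autocorrelation kernel is clipped at zero (periodising
a truncated ACF can create a little negative spectral mass; a warning fires
if clipping exceeds 0.1% of the total), square-rooted, used to modulate
white noise, and normalised to exact unit marginal variance.  The target
ACF is the mixed Gaussian/exponential model used for realistic fMRI noise,

$$\mathrm{ACF}(r) = a\, e^{-r^2/(2b^2)} + (1-a)\, e^{-r/c},$$

whose exponential term produces the heavy tails that distinguish real fMRI
noise from Gaussian-smoothed noise.  The defaults $a = 0.5$, $b = c = 2$
voxels were chosen to give clearly visible non-Gaussian ACF tails on a
desk-scale grid; the validity checks depend on the shape of the model, not
on these particular values, and all three are configurable.  Signals are
spheres (closed Euclidean balls over voxel centres — radius 2 gives 33
voxels) or 1-voxel-thick sticks (axis-aligned or diagonal), injected at an
amplitude expressed in units of the noise SD; study-mode amplitudes lie in
[0.4, 1.0].  `simulate_group()` defaults to 26 maps, a typical group-study
sample size.

What the generator deliberately does *not* emulate: non-stationary
smoothness, physiological artefacts, between-subject anatomical
variability, and non-Gaussian marginals.  Passing validation on these
simulations therefore demonstrates correctness of the statistical
machinery under its stated assumptions, not robustness to every property
of real data.

## Validation harnesses and study conditions

Two harnesses reproduce the package's validation studies at desk scale; the
problem sizes below are the package's committed study conditions.

**False positives** (`run_fpr_harness()`): 100 signal-free datasets of 20
maps on 24³ grids, 500 permutations each, threshold FDR < 0.05.  Under the
global null any detection is false, so FDR control implies the
any-detection rate stays at 5% (weak FWER control); the harness reports it
with its binomial Monte-Carlo error.

**Power** (`run_power_harness()`): paired comparison of four pipelines on
identical simulated data — post-test bilateral (LISA), post-test Gaussian
(same machinery, range kernel disabled), pre-test Gaussian (inputs smoothed
with a conventional fwhm = 6 mm kernel at the default 3 mm voxel size, no
post-test filter), and no filter — all sharing the permutation-FDR
machinery.  The expected ranking, and the package's acceptance surface, is
the *ordering* bilateral ≥ post-Gauss ≥ pre-Gauss ≥ none on a medium,
moderate-SNR signal (sphere of radius 4 at SNR 0.7 over 50 replicates, 100
permutations each); the absolute true-positive rates depend on signal
geometry and are not fixed reference values.  The small-signal scenarios —
a 5-voxel stick at SNR 1.0 and a radius-2 sphere at SNR 0.7 — probe the
regime where spatial context matters most; there the bilateral pipeline is
expected to beat unfiltered voxelwise FDR outright.

## Known limitations

* Inference is one-sided by design; run the negated contrast for
  deactivations.
* The two-group test assumes pooled variance; no Welch option.
* Group tests ignore within-subject variance (no mixed-effects weighting).
* Exchangeability structure is limited to runs (single-subject) and
  subjects (group); no general exchangeability blocks.
* The filtered statistic has no closed-form null; all inference is
  conditional on the permutation ensemble, so very small permutation
  counts (near the 30 minimum) give coarse FDR resolution.
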