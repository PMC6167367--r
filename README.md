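# lisar

Threshold-free statistical inference for brain activation maps.

Voxelwise tests on fMRI contrast maps must correct for ~10^5 simultaneous
comparisons. Cluster-extent methods buy power by pooling neighbours, but
need an arbitrary cluster-defining threshold and lose voxel-level
precision. `lisar` implements **LISA**: a pipeline that converts the group
(or single-subject) test statistic into an uncorrected z-map, applies an
**edge-preserving bilateral filter after the test**, and controls the
false discovery rate on the filtered map with a permutation null and a
conservative two-component mixture model. It is aimed at neuroimaging
researchers who want voxel-resolution inference with the power of spatial
pooling — including on high-resolution (7T) data where smoothing is
unacceptable.

## The method in brief

1. **z-map** — a one-sample t-test across subject contrast maps (or a
   two-sample test, or a single-subject GLM contrast), quantile-transformed
   to z: `z = Φ⁻¹(T_ν(t))`. The null at each voxel is one-sided: the effect
   is not positive.
2. **Bilateral filter** — for voxel *i* with neighbourhood Ω_i (the
   117-voxel 5×5×5-minus-corners stencil),

   λ_i = Σ_j z_j f_r(|z_i−z_j|) g_s(d(i,j)) / W_i,

   with Gaussian kernels f_r(x) = exp(−x²/σ_r), g_s(x) = exp(−x²/σ_s),
   σ_r = σ_s = 2.0, two iterations. Maps are first scaled by the pooled SD
   of the first 30 permuted maps so σ_r is meaningful. Mask-boundary voxels
   fall back to an 18-neighbourhood median or are discarded.
3. **Permutation FDR** — sign flips (one-sample), group shuffles
   (two-sample) or within-run label shuffles (single subject) generate
   permuted maps that traverse the *identical* pipeline; their pooled
   filtered values estimate the null F₀. With p₀ = 1 (conservative), each
   voxel's score is Fdr(λ) = F₀(λ)/F_z(λ) in right-tail exceedance form,
   monotonised q-value style. Voxels with Fdr < 0.05 are reported
   significant.

A generic mode accepts any user-supplied observed map plus permuted maps
computed with the same statistic (e.g. MVPA weight maps).

## Worked example

Simulate a 20-subject group with a spherical activation (SNR 0.7, radius 4
voxels) in autocorrelated noise, then run the group analysis:

```r
library(lisar)

sig <- signal_spec("sphere", amplitude = 0.7, center = c(12, 12, 12), radius = 4)
grp <- simulate_group(n_maps = 20, noise = noise_spec(grid = c(24, 24, 24)),
                      signals = list(sig), seed = 46)
res <- lisa_group(grp, n_permutations = 500, fdr_q = 0.05, seed = 1)
res
#> <lisa_result> mode group1, 500 permutations, kernel bilateral
#>   scale factor 1.004; 13792 evaluable voxels
#>   240 voxels significant at FDR < 0.05

truth <- attr(grp, "truth")
c(tpr = mean(res$significant[truth]),
  false_positives = sum(res$significant & !truth))
#>             tpr false_positives 
#>       0.9338521       0.0000000
```

240 of the 257 true sphere voxels are recovered (TPR 0.93 at FDR < 0.05)
with no false positives; only the sphere's outermost shell, where the
signal meets the noise floor, is missed. The `scale factor` line reports
the null-SD calibration of the range kernel, and 13,792 of the 13,824
grid voxels are evaluable (the 32 grid-corner voxels fail the boundary
rule and are flagged, not silently dropped). Per-dataset TPR at this
moderate SNR is variable — across repeated simulations it ranges from
near 0.1 on unlucky noise draws to above 0.9 — which is why the
validation harnesses average over many replicates.

For comparison, the same data without any spatial filter
(`kernel = "none"`) recovers almost nothing:

```r
sum(lisa_group(grp, n_permutations = 500, seed = 1, kernel = "none")$significant)
#> 17
```

A command-line wrapper is installed with the package
(`<library>/lisar/exec/lisa`):

```sh
lisa simulate --n-maps 20 --grid 24 --snr 0.7 --shape sphere --size 4 \
     --seed 42 --out-dir sim/
lisa group --maps 'sim/map_*.nii' --perms 500 --q 0.05 --seed 1 -o fdr.nii
```

which writes the FDR-score volume, an evaluability mask, and a JSON
provenance log (seed, parameters, scale factor).

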