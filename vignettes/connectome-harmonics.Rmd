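---
title: "Connectome-harmonic decomposition: model, choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-harmonic decomposition: model, choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The package treats the cortex as an undirected graph: vertices are
cortical-surface nodes (two hemispheres, left block first), edges are the
union of *local* connections (triangle edges of the surface mesh) and
*long-range* connections (white-matter fiber endpoint pairs, supplied as a
vertex-pair list or synthesized). A single subject's adjacency is binary;
a group connectome is the entrywise mean of subject adjacencies, giving
fractional weights in [0, 1] that are used as-is (an optional
binarize-at-threshold switch exists but is off by default, since nothing
in the method requires it).

On this graph the symmetric normalized Laplacian
`Δ_G = D^{-1/2}(D − A)D^{-1/2}` is formed with (weighted) degrees; its
eigenvalues lie in [0, 2], with one zero eigenvalue per connected
component. The eigenvectors — connectome harmonics ψ_k, ordered by
ascending eigenvalue and indexed by wavenumber k — play the role of a
Fourier basis adapted to the connectivity. "Frequency" throughout means
spatial wavenumber, never temporal Hz.

A vertex-mapped functional series `F(v, t)` is projected with the plain
Euclidean inner product, `α_k(t) = ⟨F_t, ψ_k⟩`; no area or degree
weighting is applied, matching the stated projection formula. Derived
quantities are power `P = |α|`, energy `E = |α|² λ²`, and total energy per
time point, which equals the squared Laplacian norm `‖Δ_G F_t‖²` when the
basis is complete — an identity the tests verify to 1e−8 and which anchors
the whole decomposition path.

## Numerical choices

**Eigensolver.** Dense symmetric `eigen()` for graphs up to 2,000 vertices
or when all modes are requested; otherwise a partial ARPACK solve. No R
shift-invert sparse solver is assumed: because the spectrum is confined to
[0, 2], the smallest eigenpairs of Δ_G are the largest of `2I − Δ_G`, so a
plain largest-eigenvalue ARPACK iteration on the flipped operator suffices
and needs no factorization. Agreement between the two paths is tested to
1e−8 on eigenvalues and 1e−6 on subspace principal angles.

**Degeneracy and signs.** Icosphere-like symmetric graphs have degenerate
eigenspaces, so individual eigenvectors are not identifiable; all
vector-level tests compare subspaces by principal angles. For
reproducibility only, each eigenvector's largest-magnitude entry is made
positive (ties broken by lowest vertex index).

**Isolated vertices** make `D^{-1/2}` undefined and are pruned before the
eigenproblem, with an explicit original-to-retained index map. This is a
declared choice: the source analysis reports a spectrum shorter than its
vertex count without stating the exclusion rule.

**Indices** are 1-based in memory (idiomatic R); on-disk formats keep
their conventional 0-based indices (OFF/PLY faces, the long-edge TSV).

**Logarithmic binning** (default 100 bins) reports per-bin geometric means
of both x and y — arithmetic means in log10 space. With an arithmetic mean
of y, a pure power law would drift off the fitted line by ~1e−4 in slope;
with the geometric mean the exactness anchor (β exact, ε = 0 at machine
precision on exact power laws) holds, and multiplicative log-normal noise
remains unbiased in the fitting space. Zero-power harmonics are excluded
before the log with a reported count. The fit itself is unweighted OLS of
log10 y on log10 x; β is the literal slope (negative for decaying
spectra), ε the RMSE of residuals in log10 units.

**Spectrum quantization** uses edges `10^linspace(0, log10 m, L+1)` with
half-open bins (last closed); "energy of a bin" defaults to the sum over
member harmonics (conserving the spectrum total), with a mean-per-harmonic
mode available since the aggregator is not pinned down by the method
description.

**Band notation.** Fractional ranges of the spectrum, band `(lo, hi)`
selecting wavenumbers `⌈lo·m⌉+1 … ⌊hi·m⌋`; defaults (0,.01], (.01,.1],
(.1,.2], (.2,1]. The percent labels used in the source figures are read as
fractions, the only reading consistent with equating k < 2·10² with the
first band of an ~18,700-mode spectrum.

**Permutation testing.** "Monte-Carlo" significance is implemented as a
paired within-subject sign-flip test on the mean difference with the
add-one rule. When `2^n_pairs ≤ n_perm` the test enumerates all sign
patterns and reports the exact p. This matters: at 12 pairs the exact
floor is 2/4096 ≈ 4.9e−4, which clears a Bonferroni-corrected 0.01/15
threshold, whereas the Monte-Carlo add-one estimate of the same pattern
(~1e−3 at n_perm = 2000) cannot — so exhaustive enumeration is the
estimator, not merely the test oracle, for small designs. Calibration
(type-I within Monte-Carlo error of nominal) is asserted over 200 null
replicates.

**Gaussian fits** to histograms (repertoire distributions) are
least-squares fits of `a·exp(−(x−μ)²/2σ²)` to bin densities with common
breaks across conditions; both the fitted height `a` and the width σ are
reported, since the source describes μ as the "height" of the normal
curve. Histogram resolution defaults to 100 bins over the pooled observed
range. Normalization maxima are per harmonic over all pooled baseline
scans; harmonics with zero baseline maximum are excluded with a count.

**Indirect multiple correlation** re-represents each observation-space
vector by its correlations with per-harmonic energy-change vectors and
computes the multiple correlation in that space, with `n_harmonics` as the
nominal sample dimension. This mirrors the described procedure; because
harmonic correlates are not independent observations, every result carries
a warning and the p-value should be read as nominal.

## The synthetic world

The generator states, once, the world the tests run in:

- **Connectome**: two order-2 icospheres (162 vertices each; order 5
  reproduces the 10,242-per-hemisphere resolution of real surface graphs),
  radius 70 mm, 10 mm gap; 200 long-range edges sampled without
  replacement with probability ∝ exp(−d/30 mm), 10% forced
  inter-hemispheric.
- **Coefficients**: zero-mean normal with SD `amplitude · k^(−0.5)` — a
  shallow, near-critical spectrum. The exponent and the vertex-noise SD
  (0.01 at unit amplitude) are the two free parameters the method
  description leaves open; they were fixed on physical grounds (a steep
  k^(−1) profile would bury the top-band signal below any appreciable
  noise floor, making the stated high-k effect undetectable in principle)
  and not revisited.
- **Design**: 12 subjects, paired conditions, T = 210 (~7 min at TR 2 s),
  per-subject lognormal amplitude (sdlog 0.2). Condition B applies ×0.8 to
  the lowest 1% of wavenumbers and ×1.3 to the top 80%, and couples the
  top band through a shared latent time course (mixing weight 0.6, i.e.
  pairwise latent correlation 0.36). The coupling is needed because
  Pearson correlations are scale-invariant: an amplitude-only modulation
  is invisible to the cross-frequency analysis.
- **Repertoire widening is emergent**, not a separate dial: the band
  modulations alone widen the pooled baseline-normalized coefficient
  distribution by a predictable factor `sqrt(mean(f_k²))` (≈1.24 at the
  defaults), which the tests verify against the fitted σ to ±5%. Planting
  an extra global widening factor would partially cancel the low-k
  suppression and muddy the stated effect pattern.

What the generator does **not** emulate: hemodynamics, temporal
autocorrelation, physiological noise and motion, geometry of real
cortical folding, and tractography biases. A green planted-effect test
therefore establishes that the analysis chain recovers effects of the
stated kind and size under exchangeable Gaussian noise — not that it would
detect them in real fMRI at real effect sizes.

## Degenerate inputs and tie-breaks

Self-pair long edges are rejected; long pairs duplicating mesh edges are
counted once and flagged local. Constant vertex time courses z-score to
zero with a count. Zero-variance coefficient rows propagate as missing
through the cross-frequency matrix and are excluded from aggregates with
counts. Degenerate t-tests return p = 1 when both groups are constant and
equal, p → 0 (flagged) when constant and unequal. Identical permutation
groups give p = 1; permutation p never falls below 1/(n_perm+1) on the
Monte-Carlo path. All-zero coefficient sets make the repertoire fit fail
loudly rather than return a meaningless σ.

## Known limitations

- Full spectra are dense-solved up to n = 2,000; beyond that only partial
  bases are practical, and all spectral summaries record the m used.
- The basis container is R-native serialization (no HDF5 dependency in
  the supported stack); it is bit-exact and fingerprint-checked but not
  language-neutral.
- GIFTI/NIfTI/CIFTI adapters are not included; functional input is
  assumed already vertex-mapped (TSV or in-memory matrices).
- The indirect multiple-correlation p-value inherits the source
  procedure's assumption that harmonic correlates act as samples; it is
  reported with a permanent warning, not endorsed.
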