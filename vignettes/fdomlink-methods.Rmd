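---
title: "fdomlink: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fdomlink: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`fdomlink` implements the computational chain of a paired DOM-optics /
16S-community study: EEM preprocessing and PARAFAC on the spectroscopy
side; diversity, phylogenetic null models, the Sloan neutral model,
co-occurrence networks and linkage statistics on the community side; and
synthetic-data generators that produce every input with known ground truth.
This vignette records the models, their assumptions, the tunable parameters
that matter, and the choices we made where the design was genuinely open.

## 1. EEM preprocessing

An EEM is a fluorescence intensity surface over emission (rows) and
excitation (columns), carried with an append-only set of correction flags.
The pipeline applies, in order: blank subtraction, inner-filter correction,
Raman normalization, scatter excision, wavelength trimming, grid
harmonization. Re-applying any correction is an error, which protects
against double processing.

**Inner-filter correction.** We use the standard absorbance-based form
$F_{corr} = F_{obs}\,10^{(A_{ex}+A_{em})/2}$, with decadic absorbance
interpolated linearly to the EEM wavelengths and rescaled to a 1 cm path.
The method is unreliable above roughly A = 1.5; we warn (and flag the
result) rather than refuse, since the threshold is a guideline, not a hard
physical limit.

**Raman normalization.** The divisor is the trapezoidal area of the
blank's emission scan at 350 nm excitation over 371-428 nm emission, the
community-standard band for water Raman scatter; both the reference
excitation and the band are configurable because instruments differ. The
operation is scale-equivariant: multiplying sample and blank by the same
constant leaves the normalized EEM unchanged.

**Negative intensities** after blank subtraction are kept, not clamped, so
preprocessing stays invertible; `fit_parafac(floor_negatives = TRUE)`
(the default) floors them at the last possible moment.

**Scatter excision.** First/second-order Rayleigh (half-widths 10 nm) and
first-order Raman (5 nm) ridges are removed and refilled by 1-D linear
interpolation along emission, with *linear* (not constant) extrapolation at
grid edges so that smooth surfaces are refilled consistently at the
boundary. The sub-Rayleigh region (`em < ex − w`) is physically signal-free
and is zero-filled rather than interpolated. Wavelength comparisons use a
1e-6 nm tolerance throughout.

**Trimming** defaults to emission ≤ 600 nm and excitation ≥ 250 nm —
long-emission DOM signal is negligible and short-excitation channels are
noisy on common instruments. Both bounds are exposed because grids differ;
whether a particular instrument grid contains, say, a 248 nm channel is not
something the package should assume.

## 2. PARAFAC

The stack is fitted as a nonnegative trilinear model by hierarchical
alternating least squares (HALS): each factor column in turn is updated by
a closed-form nonnegative least-squares step sharing one Gram matrix per
mode. HALS is a block nonnegative-LS scheme with a guaranteed monotone
non-increasing loss, and it is fully vectorizable in R, which is why we
chose it over per-row Lawson-Hanson updates (identical fixed points, far
cheaper). Defaults: 5 random starts, relative SSE tolerance 1e-8, at most
2500 iterations; best start by SSE; deterministic given `seed`.

Missing cells (excised scatter that could not be refilled, masked regions)
are handled by expectation-maximization: they are imputed from the current
model each iteration and excluded from the reported SSE. A dead component
(zero column) is reseeded with small random values rather than left stuck.

**Per-sample normalization** (default on) scales each sample slab to unit
sum of squares before fitting, so bright samples do not dominate the
loadings; scores are un-normalized afterwards. Loadings are returned in the
unit-maximum convention with all intensity scale absorbed into the scores,
which makes the scores equal to Fmax. Components are ordered by ascending
emission peak.

**Validation.** Split-half validation partitions samples into random
halves (default 2 independent halvings rather than the S4C6T3 scheme —
simpler and configurable), fits each half, matches components greedily by
the product of excitation and emission Tucker congruence, and passes at
congruence ≥ 0.95 — a conventional threshold; the studies this mirrors
report validated component counts but not their thresholds. Core
consistency is computed from the least-squares Tucker core
(`100 (1 − ||G − T||² / K)`); it can be NA above the true rank when the
extra loading columns make the factor matrices numerically rank-deficient,
which is itself diagnostic.

**Classification** of components by peak position uses literature
conventions: emission peak < 320 nm tyrosine-like, < 380 nm
tryptophan-like, otherwise humic-like, split at 260 nm excitation into
terrestrial vs microbial. The boundaries live in a config object
(`classification_rules()`) and can be overridden. `match_reference()`
performs the same congruence matching against a user-supplied spectral
library, entirely offline.

## 3. Optical indices

FI uses the corrected-instrument emission pair 470/520 nm at 370 nm
excitation (the legacy 450/500 pair is available by argument). BIX is
380/430 at 310. HIX defaults to the unbounded Zsolnay form H/L (H: em
435-480, L: em 300-345, at ex 254), with the Ohno form H/(H+L) selectable;
band sums interpolate to a 1 nm comb so the index does not depend on the
instrument grid. SUVA254 is `(A254/path) × 100 / DOC` in L mg⁻¹ m⁻¹.
Spectral slopes regress `ln a` on wavelength (a the Napierian absorption
coefficient) over 275-295 and 350-400 nm; SR is their ratio. One
literature ambiguity is worth noting: some studies describe SR loosely as a
ratio of absorbances while citing the slope-ratio literature; we implement
the slope ratio, which is the quantity with the documented molecular-weight
interpretation, and say so rather than guess at any particular study's
arithmetic. All EEM-based indices are exactly invariant to global intensity
scaling, and indices whose wavelengths were trimmed away raise a typed
error instead of silently returning NaN.

## 4. Diversity and ordination

Chao1, Shannon, Gini-Simpson and Pielou are computed from first
principles, with the bias-corrected Chao1 branch when no doubletons exist.
Shannon defaults to **base 2**: reported Shannon values near 9.7 for
~2000-taxon sediment communities are only attainable in bits, so that is
the convention the package mirrors. Simpson is reported as Gini-Simpson
(1 − Σp²). No rarefaction is applied by default; a `subsample()` utility
exists but is opt-in. Bray-Curtis is the default (and assumed) NMDS
distance; NMDS itself is vegan's `monoMDS` (Kruskal stress-1, monotone
regression) wrapped with seeded multi-start. Group comparisons offer Welch
t, Mann-Whitney and one-way ANOVA, with the zero-variance/equal-means
degenerate case defined as statistic 0, p 1.

## 5. Community assembly (βMNTD/βNTI)

βMNTD is abundance-weighted by default. The null shuffles tip labels
across the whole phylogeny — Stegen's "taxa shuffle", implemented as a
joint row/column permutation of the cophenetic matrix — with 999 draws by
default; an exhaustive-permutation mode exists for small trees and is used
by the tests to verify the sampled null is unbiased. Pairs with zero null
standard deviation (e.g. identical single-taxon communities) are flagged
`NA`, never fabricated. `assembly_fractions()` counts |βNTI| < 2 as
stochastic, with values exactly at 2 counted deterministic. The pipeline
runs βNTI separately per matrix type (water/sediment), since pooling
habitats with disjoint communities would conflate between-habitat turnover
with assembly mechanism; this is a documented default, not a claim about
any particular study's pooling.

## 6. Sloan neutral community model

Predicted occurrence frequency is `1 − I(d; Nmp, Nm(1−p))`. N is the mean
sample read total (median selectable), the detection limit defaults to
d = 1/N (the smallest observable relative abundance; Sloan's original used
instrument detection limits, hence configurable), and m is estimated by
least squares over a log-spaced grid refined by golden-section search. The
95% band is a Wilson binomial interval at n = number of samples, chosen for
robustness at frequencies near 0 and 1.

One honest caveat, visible in our own calibration tests: on data generated
from the stationary beta marginal followed by multinomial read sampling,
the fitted Nm is biased upward by roughly 20-25%, because real detection in
N reads is `1 − (1−π)^N` rather than the threshold `π > 1/N` the fitted
curve assumes. This is a property of the standard fitting convention, not
of our implementation; the parameter-recovery acceptance test passes within
its ±25% band with this bias included, and we report it rather than tune
d to cancel it.

## 7. Networks and linkage

Co-occurrence networks use all pairwise Spearman correlations
(t-approximation p for n ≥ 10, exact distribution below), BH correction
across all tested pairs, and edges at |ρ| ≥ 0.6, q ≤ 0.05 — standard
literature thresholds, recorded in the output metadata because published
node counts are rarely reproducible without knowing the unstated filters.
Constant variables are skipped and logged. Average path length is the mean
shortest-path length within the largest connected component (a single
summary number implies a connected summary); it is reported as undefined
for an edgeless network. The prevalence filter (≥ 50% of samples by
default) is applied before network construction.

The linkage stage correlates |βNTI| with the 1-D Euclidean distance matrix
of each DOM component (Fmax by default; percent composition selectable) by
Spearman over upper triangles, with significance from a Mantel permutation
of sample labels, `p = (1 + #{|ρ_perm| ≥ |ρ_obs|})/(1 + n_perm)`. A naive
pairwise p is also emitted, labelled anti-conservative, because treating
n(n−1)/2 pairs as independent observations overstates evidence.

## 8. What the synthetic data emulates — and what it does not

The generators are the package's stated world:

* **EEMs**: Gaussian excitation/emission loadings at literature-typical
  peak positions for four fluorophores (terrestrial humic-like with a dual
  excitation peak, microbial humic-like, tyrosine-like, tryptophan-like),
  mixed with Gamma-distributed weights at SNR 50 by default, optionally with
  Rayleigh/Raman ridges. Real loadings are neither Gaussian nor exactly
  trilinear; a green recovery test establishes that the algorithm recovers
  a true trilinear structure, not that any instrument's data are trilinear.
* **Absorbance**: piecewise double-exponential with exact band slopes, so
  SR ground truth is the slope ratio by construction.
* **Phylogeny**: forward Yule simulation, unit rate, ultrametric.
* **Neutral communities**: Dirichlet(Nmp) relative abundances (the Sloan
  stationary marginals) then multinomial reads — deliberately the model the
  NCM fits, making recovery a clean inverse problem. The log-series
  metacommunity is randomly assigned to tips so it carries no phylogenetic
  signal; an earlier index-ordered assignment measurably inflated |βNTI|
  on supposedly neutral data, which is worth remembering when building
  null fixtures.
* **Niche communities**: Brownian optima on the tree (phylogenetically
  conserved), selection `exp(−s(opt − env)²)` times the metacommunity, then
  multinomial reads. Optima are standardized to unit SD by default so `env`
  and `s` are in trait-SD units and independent of tree height. A single
  Brownian draw on a ~300-tip Yule tree does not reliably concentrate trait
  extremes in one clade, so the strong-filtering regime (the world in which
  within-habitat βNTI < −2 dominates) uses a 1000-taxon pool with s = 4 and
  habitats at ±2 SD; this regime was verified stable across independent
  tree and community seeds, not tuned to one seed.
* **Study-like bundle**: 16 sites (6 high-disturbance HH, 6 low-disturbance
  LH, 4 river R) × water/sediment; sediment protein-dominated under high
  disturbance (~69% target) and humic-dominated under low (~63%), water
  humic-dominated throughout, DOC and environmental covariates lognormal,
  water communities neutral, sediment communities niche-filtered along the
  disturbance contrast. Observed EEMs are built backwards through the
  measurement chain (inner-filter attenuation, blank with a water Raman
  ridge, scatter, noise) so preprocessing is exercised for real.

Not emulated: sequencing error, chimeras, compositional artifacts, vendor
binary formats, or instrument drift. A green end-to-end test therefore
establishes correctness of the analysis chain on data obeying the stated
models, not robustness to every artifact of real instruments.

## 9. Numerical conventions and degenerate inputs

Seeds are explicit everywhere randomness exists, and every randomized
result is bit-reproducible given its seed. Typed conditions
(`fdomlink_*_error`) distinguish format, shape, domain, state and numeric
failures; the pipeline wraps them with the failing stage's name and the CLI
maps them to exit codes (2 config, 3 data, 4 numeric). Division-by-zero
style cases (zero-denominator indices, zero-variance distance matrices,
empty communities, all-zero samples) raise typed errors rather than
returning NaN. Wilson intervals are clipped to [0, 1]; βNTI pairs with
zero null SD are NA; r² is reported unclamped and may be negative.

## 10. Known limitations

* PARAFAC multi-start does not guarantee the global optimum; degenerate
  two-component cancellation is mitigated by nonnegativity but not
  impossible.
* The NCM Nm bias discussed in §6.
* Mantel permutation p-values have resolution 1/(n_perm + 1).
* The co-occurrence network is plain Spearman + FDR; it makes no claim of
  compositionality-awareness (no SparCC/SPIEC-EASI) and the documented
  thresholds materially affect node/edge counts.
* The exhaustive βNTI null is limited to ≤ 8 taxa (factorial growth).
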