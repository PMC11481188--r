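---
title: "Methods: trajectory and tipping-point analysis of an aging transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory and tipping-point analysis of an aging transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agecourse)
```

## The question the pipeline answers

In a cross-sectional cohort whose samples span the adult lifespan, gene
expression need not drift at a constant rate: a transcript can hold steady
for years and then change direction at a specific age. `agecourse` treats
age as a continuous covariate and estimates, for groups of co-expressed
transcripts, *when* such changes of direction — tipping points — occur, and
assembles them into an ordered molecular timeline together with
histology-derived events such as the onset of glycosaminoglycan (GAG)
accumulation in the extracellular matrix.

The pipeline assumes one measurement per animal (no repeated measures), ages
densely covering the range of interest, and bulk RNA-seq counts as input.

## Models and procedures

### Normalization

Transcripts whose total count over all samples is below 30 are removed
(strict `<`), then TMM scaling factors are computed (reference sample by the
75th-percentile rule; 30% of M values and 5% of A values trimmed;
inverse-variance weights) and expression is taken as
`log2((count + 0.5) / (lib_size × factor) × 1e6)`. The pseudocount of 0.5
avoids minus infinity at zero counts; the CPM scale is a convention only,
since every downstream statistic (correlation, standardized trajectories) is
location/scale invariant per transcript.

### Co-expression modules

The network stage follows the weighted-correlation-network recipe with
deliberately simple, fully specified components:

* unsigned adjacency `|r|^β`, β = 12 — a soft threshold that keeps the
  network weighted while suppressing weak correlations. An unsigned network
  groups anti-correlated transcripts together; direction is reintroduced
  later at the module–age-correlation step.
* topological overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij) /
  (min(k_i,k_j) + 1 − a_ij)`, so that two transcripts are close when they
  share neighbours, not merely when they are directly correlated.
* average-linkage clustering of `1 − TOM`, cut at the **static height**
  `0.99·max(h) − deep_split · 0.05 · range(h)`. This is a documented
  simplification of dynamic hybrid tree cutting: larger `deep_split` cuts
  deeper and splits more finely. It behaves well when planted structure is
  present (the tests verify exact recovery of planted blocks) but it is less
  adaptive than the dynamic algorithm on real dendrograms with very uneven
  merge heights.
* clusters below `min_module_size` (30) are left unassigned (label 0, the
  "grey" convention), module eigengenes are first principal components of
  the standardized module submatrix (sign-aligned to the module mean
  profile, unit variance), and modules whose eigengene dissimilarity
  `1 − r` is below 0.25 are merged iteratively, recomputing eigengenes
  after each merge.
* a module is *age-correlated* when its eigengene has Pearson `|r| ≥ 0.30`
  and `p ≤ 0.05` against age (t-transform, n − 2 df). Both signs are kept;
  the sign becomes the default per-gene direction.

### Directional enrichment

Age-associated genes inherit a direction (±1, encoded as fold-change ±2)
from their module's correlation sign; genes whose own trajectory is
quadratic override this with the post-vertex slope sign, i.e. `sign(B2)`.
Pathways (GMT input) are tested by the two-tailed Fisher exact test against
the universe of all transcripts that passed the count filter, corrected with
Benjamini–Hochberg (adjusted p ≤ 0.05). Pathway directionality is the
activation z-score

`z = Σ_i x_i / √N`,

the standardized net direction of the `N` pathway members observed. The
printed form of this statistic is typographically ambiguous between `Σx·N`,
`Σx/N` and `Σx/√N`; the package adopts `√N`, the standard activation
z-score convention under which `z` is approximately standard normal for
random directions and `|z| = √N` exactly at unanimity. The denominator is
configurable (`activation_zscore(..., denominator = "n")`). Category skew
(e.g. "are downregulated pathways disproportionately metabolic?") uses the
exact two-tailed binomial test, summing all outcome probabilities no larger
than the observed one.

### Trajectories and tipping points

Each transcript (and each pathway's per-sample mean standardized profile)
is fitted with both `y = B0 + B1·x` and `y = B0 + B1·x + B2·x²`. The
quadratic is preferred when the extra sum-of-squares F test
`F = (SSE_lin − SSE_quad) / (SSE_quad / (n − 3))` gives `p ≤ 0.05`; the age
effect is then the coefficient t test of `B1` (linear) or `B2` (quadratic),
equivalent under OLS to comparing against the null-impact-of-age model. For
quadratic winners the vertex `−B1/(2·B2)` is the tipping age. Numerical
tie-break: when both models fit essentially perfectly (quadratic improvement
below `1e−10 ×` total variance) the simpler linear model is kept, so exact
lines are never classified quadratic by floating-point noise.

Vertices aggregated to a pathway use only members whose chosen model is
quadratic *and* whose vertex lies inside the observed age range plus a
1-year margin: an extrapolated vertex is not a tipping point within the
lifespan. The pathway tipping point is reported as mean ± sample (n − 1)
standard deviation. No multiple-testing correction is applied across
transcripts for model choice, mirroring the screening convention upstream; a
few linear-module members are therefore expected (≈5%) to be classified
quadratic with essentially random vertices — visible in timelines as
low-membership, high-SD events.

### Staining onset by the tangent method

Staining fractions are averaged over replicate images per animal (avoiding
pseudo-replication) and fitted with the 4-parameter logistic
`b + L/(1 + exp(−k(x − x0)))` by bounded Levenberg–Marquardt least squares
from a deterministic multi-start grid (`x0` at the age quartiles,
`k ∈ {0.2, 0.5, 1, 2}` per year, `b = min(y)`, `L = range(y)`). The
"inoculum level" of growth-curve lag estimation maps to the fitted lower
asymptote `b`. The tangent at the inflection point has slope `L·k/4`;
intersecting it with the two asymptotes gives closed forms
`a_on = x0 − 2/k` and `a_end = x0 + 2/k` (verified against the numeric
root-solving construction to 1e−6). The *fast* phase is where that tangent
still overlaps the sigmoid: the scan (0.01-year grid) finds the outermost
ages at which `|tangent − f| ≤ ε·L`, with ε = 0.02 by default — a tolerance
the source construction leaves unspecified; 2% of amplitude puts the
departure near `x0 ∓ 1/k` for a pure logistic and is configurable. Because
the fitted logistic is symmetric, the fast window is symmetric about `x0`;
an empirically asymmetric fast phase would require an asymmetric sigmoid
(e.g. Richards), which the package deliberately does not fit.

### Timeline

Events (pathway tipping points, staining windows, optional morphometric
vertices) are sorted by age — windows by their start — with alphabetical
tie-break, and annotated with human-equivalent ages. The conversion is
`round(4.0 × age)` (half away from zero): factor 4 is the ratio implied by
every published baboon/human pair this package targets (7.5→30, 13.0→52,
22.1→88), and it is configurable since the underlying equivalence is an
external convention.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline's recovery properties are asserted.

* **Ages**: 35 animals, uniform on 7.5–22.1 years, sorted. Uniform sampling
  reflects a design in which age is a continuous covariate without
  prescribed spacing.
* **Modules**: each planted module has a latent log-scale trajectory —
  flat, linear (`slope·(age − mid)`), or quadratic
  (`curvature·(age − vertex)²`, centred) — plus a shared Gaussian
  "wiggle" (sd 0.6 log-units) representing coherent non-age biological
  variation. Members scale the shared signal by loadings in [0.6, 1] and
  add member noise calibrated so members correlate at 0.95 before count
  noise. Counts are negative binomial with mean `exp(latent)` times a
  log-normal library-size factor (sd 0.15), dispersion 0.02.
* **Defaults** (one planted scenario): a metabolic module tipping downward
  at 12.5 years (curvature −0.05 /yr²), a GAG-precursor module tipping
  upward at 13.65 years, a linearly increasing module (slope 0.08 /yr), a
  hypertrophy module tipping upward at 14.8 years, and 80 unassigned
  background transcripts; pathway sets of 20 coherent members per module
  plus a null background set; staining logistic b = 0.02, L = 0.10,
  x0 = 16.3 years, k = 0.4 /yr (accumulation window 11.3–21.3 years by the
  tangent closed forms) with per-image Gaussian noise sd 0.005.
* **Reproducibility**: all draws flow from one master seed through named
  sub-streams, so adding a stage never changes another stage's data and
  equal seeds give byte-identical cohorts.

Two geometric facts shaped these defaults, and they are worth knowing when
interpreting real data:

1. **A centred parabola is invisible to a linear screen.** The Pearson
   correlation between age and `(age − v)²` is proportional to the distance
   of the vertex `v` from the mean age. A symmetric quadratic trajectory
   whose vertex sits at the centre of the age range has almost no linear
   age correlation, so it cannot pass the `|r| ≥ 0.30` eigengene screen no
   matter how strong it is. Real "flat-then-rise" expression curves are
   asymmetric and escape this; exact parabolas with late vertices do not.
   The planted vertices therefore sit left of the range centre, and
   `run_pipeline(fit_scope = "assigned")` exists for recovery analyses that
   should not be gated by the stochastic screen.
2. **Separability and screen stability pull against each other.** Two
   modules whose trajectories are strongly (anti-)correlated are only
   topologically separable in an unsigned network through their independent
   non-age variation — the shared wiggle. But that same wiggle adds a
   random component to each eigengene's sample correlation with age
   (sd ≈ 0.17 at n = 35), so some truly age-driven modules will fail the
   screen in any given replicate. The default wiggle sd (0.6) balances the
   two; the test suite asserts planted-partition recovery with mean
   adjusted Rand index ≥ 0.8 and vertex bias within ±0.5 years over 20
   replicates at these settings.

What the generator does **not** emulate: transcript-length and GC biases,
outlier samples, batch structure, correlated background transcripts,
asymmetric (hinge-like) trajectories, dropout, or tens of thousands of
transcripts (the default cohort is 240 transcripts × 35 samples so the full
suite runs in seconds; the network stage is dense and is not intended for
>50k-transcript blockwise analysis). Passing tests therefore demonstrate
correctness of the statistical machinery and recoverability under the
planted model, not robustness to every artifact of real RNA-seq.

## Problem sizes and budgets

Defaults were chosen so that a complete pipeline run takes well under a
second and the full test suite — including 20-replicate recovery, a
1000-replicate F-test type-I simulation at n = 35, a 200-replicate
false-discovery simulation, and exhaustive small-table enumeration oracles
for the Fisher test and topological overlap — completes in about half a
minute on one CPU.

## Known limitations

* The static tree cut is a simplification; on real dendrograms the dynamic
  hybrid algorithm is more adaptive. The parameters (deep split 2, merge
  height 0.25, minimum size 30, power 12) follow the conventional defaults.
* The activation z-score here is the unweighted form; bias-corrected
  variants and knowledge-base edge weights are out of scope.
* The symmetric logistic forces a symmetric fast-accumulation window;
  empirical asymmetry is flattened into it.
* With n = 35, per-transcript vertex estimates carry ~0.3–0.5-year errors;
  pathway aggregation reduces member noise but not module-level shared
  variation, so adjacent events closer than ~0.5 years cannot be reliably
  ordered.
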