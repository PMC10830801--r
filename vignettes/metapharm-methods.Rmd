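---
title: "Methods: integrated metabolomics and network-pharmacology screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated metabolomics and network-pharmacology screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metapharm` implements a two-stream screening workflow for complex
interventions against metabolic disease: serum LC-MS global metabolomics
(which metabolites shift in disease and move back under treatment) joined
with network pharmacology (which proteins the intervention's components and
the disease share, and which of those the shifted metabolites also point
at). This vignette is the package's account of the underlying models, the
choices we made where the methodology is genuinely open, and what the
synthetic-data generator does and does not emulate.

## Study design encoded in the data model

The feature table is a features × samples intensity matrix with per-feature
m/z and retention time and a per-sample group label: N (normal), D (disease
model), P (reference drug), H (treatment), L (low-dose treatment), QC
(pooled quality-control injections). Downstream modeling uses N, D and H —
the treatment arm of interest — while P exists so that choosing H as the
better responder is an exercised decision, and QC only enters PCA as an
instrument-stability check.

## Preprocessing

Four steps, each appending to an auditable processing log:

* **RT window** (default 2–20 min, endpoints inclusive): early/late eluters
  are gradient artifacts. The filter is a per-feature predicate, so it
  commutes with the detection filter (asserted in the tests).
* **Detection-rate filter** (default 50 %): the phrase "detection rate
  below the threshold in the single group" admits two readings. We default
  to the permissive one — keep a feature if *any* biological group detects
  it at ≥ 50 % — because a metabolite absent in one condition but reliably
  measured in another is biologically informative (presence/absence is
  itself a disease signal). The strict all-groups reading is available via
  `per_group = TRUE`.
* **Half-minimum imputation**, per feature, across all samples: the
  standard stand-in under left-censoring at a shared detection limit. We
  impute before the log transform and use the feature's own minimum (not a
  global one): a whole-table minimum would assign absurdly low values to
  high-abundance features (documented by a dedicated test comparing the two
  choices).
* **log10 transform** then **scaling**. Scaling defaults to **Pareto**
  (centre, divide by √sd). Unit-variance scaling equalizes every feature
  and therefore hands a large share of the PLS weight norm to pure-noise
  features when informative features are few; on planted-truth simulations
  (10 true features of 500, n = 8/group) UV roughly triples the number of
  noise features crossing VIP > 1.5 and halves Q² relative to Pareto, which
  preserves effect-size information. We verified this is not an artifact of
  our fitter by reproducing the same UV selection behavior with an
  independent PLS-DA implementation (mixOmics) on identical data. Pareto is
  also the common convention for MS intensity data. UV and plain centering
  remain available everywhere via `scaling=`.

## Discriminant model

Multiclass OPLS-DA in the orthogonal-filtering-then-PLS2 formulation (the
proprietary reference implementation's exact multiclass internals are
unpublished; ours is the standard open formulation). With centered
class-indicator matrix $Y$ (one column per group) and scaled $X$:

1. For each orthogonal component: take the PLS weight from the first left
   singular vector of $X'Y$, form the X-loading of its score, and keep the
   part of that loading orthogonal to the column space of $X'Y$ (the
   centered indicator makes $X'Y$ rank-deficient, so the projection uses an
   orthonormal QR basis rather than a Gram-matrix inverse). Deflate $X$.
2. Fit $K-1$ predictive PLS2 components by NIPALS on the filtered matrix.

$R^2Y = 1 - \lVert Y-\hat Y\rVert^2/\lVert Y\rVert^2$; per-component
explained Y-variance $SS_a = (t_a't_a)\,(q_a'q_a)$ feeds the VIP:

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a SS_a\,(w_{aj}/\lVert w_a\rVert)^2}{\sum_a SS_a}},$$

over predictive components only (the standard OPLS VIP; a combined variant
that also weighs orthogonal components by their X-variance is available via
`vip(model, "combined")`). $\sum_j \mathrm{VIP}_j^2 = p$ exactly — asserted
on every fitted model.

**Cross-validation.** Q² uses seven segments (the convention of the
chemometrics software this emulates) with venetian-blind, class-stratified
assignment by sample order — deterministic, no RNG. Each fold refits the
scaling on its training samples. When a class has fewer samples than
segments, trailing empty segments are skipped; a fold that would empty a
class entirely is an error.

**Orthogonal-component count.** Chosen by cross-validation: add a component
only while Q² improves by more than 0.01, capped at 5. The cap and
threshold are our own stopping rule; both are exposed.

**Permutation test.** Class labels are shuffled `n_perm = 999` times, the
model refit at fixed component counts, and $(R^2Y, Q^2)$ recorded against
the mean absolute column-wise Pearson correlation between permuted and
original indicators. Straight lines through the $n_{perm}+1$ points (the
real model sits at correlation 1) give intercepts at zero correlation; the
model is declared valid when both intercepts lie below the real values and
the Q² intercept is below 0.05. The correlation statistic is our choice of
abscissa — the reference software plots a comparable quantity but does not
publish its definition.

## Screening cascade

Stages, all strict inequalities, all thresholds configurable:
VIP > 1.5 → Mann–Whitney raw p < 0.05 (N vs D) → recovery → BH-FDR < 0.05.
Three deliberate conventions:

* **Raw-scale statistics.** Fold change (mean D / mean N) and the recovery
  sign check use raw (pre-log) intensities — large printed fold changes
  (30-fold and more) are only meaningful on the raw scale. The U-test is
  rank-based, so the log transform cannot change its p-value (asserted).
* **Recovery is a pure sign criterion**: the treated mean lies on the
  normal side of the diseased mean. An optional minimum-restoration
  fraction exists but defaults off.
* **FDR family = stage-3 survivors.** The correction is applied after the
  biological filters, over exactly the features that reached stage 4, so
  the family size equals the survivor count (recorded in the screen log).
  Whole-table adjustment is available via `fdr_scope = "all"`.

The U-test uses the exact null distribution when $n_x+n_y \le 16$ with no
ties (the study's 8 + 8 design) and the tie-corrected,
continuity-corrected normal approximation otherwise; when every
observation is tied the test is uninformative and returns p = 1.

## Mass annotation

Monoisotopic masses from most-abundant-isotope atomic masses (C 12 exactly,
H 1.0078250319, N 14.0030740052, O 15.9949146221, P 30.97376151,
S 31.97207069). Two adduct conventions coexist deliberately:

* `h_atom` (default): [M+H]⁺ = M + mass of a neutral hydrogen atom. This
  reproduces the "exact mass" columns of printed metabolite tables, which
  ignore the electron.
* `proton_electron`: [M+H]⁺ = M + proton; fragment cations = atomic sum −
  electron mass (0.0005486 Da). Head-group fragments like phosphocholine
  C₅H₁₅NO₄P⁺ (184.0733) are computed this way.

The two differ by exactly one electron mass — an asserted invariant.
Display rounding is half-up at 4 decimals, as mass tables print. One
diagnostic fragment (124.9999, the cyclic ethylene-phosphate ion) is stored
as a fixed value rather than a formula: the best candidate composition
computes 0.1 mDa lower and the discrepancy is unexplained. Retention time
is carried as metadata only — matching it would require a
reference-standard RT library the workflow does not have.

## Network pharmacology

Symbols are canonicalized by trimming and uppercasing; no alias database is
consulted. Disease targets are kept at relevance score strictly > 20. The
PPI graph keeps edges with confidence ≥ 0.4 (the "medium confidence"
convention; the cutoff is configurable because the source workflow does not
state one), collapses duplicates to the maximum score, and retains isolated
whitelist nodes at degree 0.

Centralities follow the NetworkAnalyzer conventions, because the published
screening thresholds (0.00533, 0.5236) are only meaningful on normalized
scales: betweenness is Brandes on unweighted shortest paths scaled by
$2/((N-1)(N-2))$ and closeness is $(N-1)/\sum d$, both with $N$ the size of
the node's own connected component (plain per-component values; no
cross-component penalty factor). Both are verified against a brute-force
BFS path-enumeration oracle on random graphs. The critical-target screen is
the strict conjunction degree > 11 ∧ betweenness > 0.00533 ∧ closeness >
0.5236; final candidates are the intersection of the critical set with the
union of the screened metabolites' targets, with per-target provenance.

Enrichment is plain one-sided hypergeometric ORA with BH adjustment over
the tested terms, against a local GMT — a documented stand-in for
web-service enrichment (whose hybrid multi-ontology scoring and term
clustering we do not reproduce). The default background is the union of
all collection members.

## qPCR

2^-ΔΔCt with amplification efficiency fixed at 2. The calibrator is the
arithmetic mean ΔCt of group N — a deterministic choice (a
per-sample-of-N calibrator would make results depend on sample pairing).
Consequently the calibrator group's geometric-mean RQ is exactly 1 for
every gene, an asserted invariant. Technical replicates are averaged per
(gene, sample) before ΔCt. Group comparison uses the same Mann–Whitney
operation as the metabolite screen (the source methodology lists two
statistics packages without naming the test; we use the U-test for
consistency), and "significant retracement" requires both the correct sign
(H between D and N) and D-vs-H p < 0.05.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with planted
ground truth, and its defaults *are* the emulated study conditions:
8 samples per biological group, 500 features, 10 planted differential
features at 3-fold disease effect, 80 % recovery in H (half that in P, so
H is the better responder), 15 % lognormal replicate noise, pooled QC at
5 % CV, left-censoring of the lowest 5 % of intensities at a shared
detection limit, and a 0–25 min gradient. Feature baselines are lognormal
with medians log-uniform over three decades. Retention times are uniform
over the gradient for decoys while planted metabolites elute inside the
2–20 min analysis window (the RT filter should model interference removal,
not destroy planted truth); the first seven planted features take the m/z
of a built-in seven-compound serum-lipid library within ±5 ppm, and decoy
m/z are redrawn to stay ≥ 30 ppm from any library adduct so annotation is
unambiguous.

Target databases mirror a realistic funnel: 243 component targets, 990
disease targets, 88 metabolite targets, 6 planted criticals present in all
three lists with relevance scores comfortably above 20, plus 56 decoys
common to the component and disease lists only (so the common set has 62
members). The planted criticals form a PPI clique with spokes from the
decoy periphery (two hubs per decoy), which guarantees hub degree far
above 11, high betweenness, and closeness above 0.5236, while decoys stay
at degree ≈ 2; each library compound targets three criticals round-robin,
so the final intersection is robust to a single metabolite dropping out of
the screen. The Ct generator shifts responsive genes by a configurable
cycle effect in D (default −1 cycle ⇒ ≈ 2-fold expression) with 0.1-cycle
Gaussian replicate noise and 80 % retracement in H.

What the generator does **not** emulate: raw spectra, chromatographic peak
shape, isotope patterns, instrument drift beyond the QC CV, correlated
metabolite modules, batch effects, or gene-symbol aliasing. Passing tests
therefore demonstrate that the *screening logic* recovers planted truth
under realistic noise — not that the workflow is robust to every failure
mode of real acquisitions.

## Operating characteristics and limits

With only 10 informative features among ~350 retained and n = 8 per group,
cross-validated Q² of the three-class model sits well below the values
seen on real serum profiles (where discriminant signal spans hundreds of
correlated features): treatment recovery makes N and H nearly coincide, so
the second predictive component has little true signal to find. The
permutation test still separates cleanly — the real Q² exceeds all 999
permuted values and both regression intercepts fall below the real
diagnostics — and the cascade recovers the planted features (median recall
1.0, median false positives ≤ 2 over 20 seeds under the default
conditions, as the acceptance tests compute). VIP selection at 1.5 admits
a tail of chance-correlated noise features by construction at this sample
size; the cascade's U-test and recovery stages are what remove them.

## Problem sizes in the test suite

The suite fits models at the default study scale (500 × 40), runs the full
999-permutation validation once, repeats the end-to-end pipeline over 20
seeds at reduced permutation counts (permutations do not affect target
recovery), and checks oracle equivalence on 50 random graphs of up to 30
nodes and exhaustive U-test enumeration at 3 + 3 and 8 + 8 — sizes chosen
so the whole suite completes in a few minutes on one CPU while still
exercising the study-scale model once.
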