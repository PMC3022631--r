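---
title: "Searching expression compendia by differential-expression signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching expression compendia by differential-expression signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigsearch)
```

## The problem

A two-group expression comparison — disease vs. normal, knockdown vs.
control — can be condensed into a *differential expression (DE)
profile*: one score per gene, optionally with a significance estimate.
Given a library of such profiles, the retrieval question is: which
experiments regulate the same transcriptional programs as mine? This
vignette describes the model behind each stage of the package, the
parameters that matter, and the choices made where the design was
genuinely open.

## Profile construction

**Scale.** All computation happens on log2 intensities. Files of unknown
provenance pass through `ensure_log_scale()`, which has to guess the
scale without metadata. The rule: any negative value, or a maximum at or
below 50, means the data are already logged; otherwise non-positive
entries are floored at 1.0 and log2 applied. Log2 intensities rarely
exceed ~20 while linear intensities exceed 50, so the rule only
misclassifies pathological inputs; the threshold and floor are arguments
for such cases. The operation is idempotent, and flooring (rather than
dropping) non-positive values preserves matrix shape.

**Probe aggregation.** Platforms measure a gene with several probes of
unequal reliability. `aggregate_probes_fixed_effects()` applies the
fixed-effect meta-estimate: probe weight `1/v_p` with `v_p` the probe's
variance across *all* samples of the experiment, giving the gene value
`Σ(x_p/v_p)/Σ(1/v_p)` per sample and the meta-variance `1/Σ(1/v_p)`.
Estimating `v_p` across all samples rather than within groups is
deliberate: it matches the meta-analysis convention in which each probe
is a "study" with its own sampling variance, and it keeps the weights
identical for both groups so group means stay comparable. Zero-variance
probes are floored at `1e-8` so a constant probe dominates its gene
gracefully instead of dividing by zero. Exactly the same estimator
implements gene-set meta-scores in `module_meta_scores()` — one shared
routine, and a test asserts the two paths agree when each "set" is a
gene's probe set.

**Scores and p-values.** The profile score is the log fold-change
(difference of group means; antisymmetric in the group order, which is
recorded on the profile so sign conventions stay auditable). Gene-level
significance uses the empirical-Bayes moderated *t*: the pooled
within-group variance `s_g²` on `d_g` residual df is shrunk toward a
prior, `s̃_g² = (d₀·s₀² + d_g·s_g²)/(d₀ + d_g)`, and
`t = Δ/(s̃·√(1/n_a + 1/n_b))` is referred to `d₀ + d_g` df. The prior
`(d₀, s₀²)` comes from moment matching on `log s_g²` (digamma/trigamma
inversion by Newton iteration); genes without residual df are excluded
from the fit and assigned p = 1. With `prior_df = 0` the machinery
collapses to the ordinary pooled t-test — a property the tests exploit —
and a separate test cross-checks the full fit against the limma
implementation. Adjusted p-values (Benjamini–Hochberg) of exactly zero
are floored at `1e-300` because the similarity weights take their log.

**Rank profiles.** The rank representation first ranks all probes within
each sample (average ties), averages ranks within each group, and scores
a gene as the median over all ordered probe pairs `(p, q)` of the gene's
probe set of `rank_a(p) − rank_b(q)`. "All pairwise combinations" is
ambiguous between ordered cross pairs, unordered pairs, and
within-condition differences; ordered cross pairs (including `p = q`)
were chosen because they reduce to the natural single-probe answer and
keep the score antisymmetric in the groups. Ranking happens *before*
restriction to mapped probes, so the profile is invariant to any
strictly increasing per-sample transform of the raw values.

**Cross-species mapping.** `map_to_human()` keeps only genes with a
one-to-one homolog (within species, source and human ids each unique)
and renames them; profiles with no surviving gene raise a "failed to
map" error, which indexing converts into an exclusion-report entry
rather than an abort.

## Dimension reduction

A component basis *S* (components × genes, unit-L2 rows) defines a
reduced space; a gene profile *X* projects as `A[c] = Σ_g S[c,g]·X[g]`
over the genes shared by profile and basis (genes absent from the
profile contribute zero). The projection is linear and, for an
orthonormal square basis, norm-preserving — both property-tested. For
component-level *p*-values the projection is applied to each sample's
expression first and the moderated t is run on the projected values
(`component_profile()`); projecting p-values directly would be
meaningless.

`derive_components()` builds a basis from any samples × genes
compendium: (1) balance over-represented conditions by average-linkage
clustering of samples on correlation distance, cutting at
`balance_height` (default 0.05) and keeping one medoid per cluster —
duplicated or near-duplicate samples collapse to one representative,
which also makes the output invariant to duplicating the whole
compendium; (2) run fixed-point ICA (logcosh contrast, PCA whitening,
symmetric decorrelation) `n_runs` times from different random starts;
(3) pool all components, unit-normalized and oriented so the heavier
loading tail is positive (ICA signs are arbitrary, and the module rule
below is one-directional); (4) cluster the pool with partitioning around
medoids on `1 − |r|` distance — so sign-flipped duplicates cluster
together — and return the medoids. No installed package provides
fixed-point ICA, so the ~40-line fixed-point iteration is part of the
package. The default `n_runs = 20` follows standard practice for
stabilizing ICA; the package's own evaluation uses 5 runs, which on the
simulated compendia already yields >0.99 recovery of planted sources.

Modules are extracted per component as genes loading more than 3 SD
above the component mean (positive direction only, per the orientation
convention); degenerate constant components yield empty modules and are
dropped with a warning.

`stack_experiments()` prepares a derivation compendium from
heterogeneous platforms: samples are stacked over the union of genes and
a gene missing from a platform is imputed at its mean across the samples
that measure it, i.e. it carries no differential signal for those
samples — a neutral choice that avoids discarding the (small)
cross-platform gene intersection.

## Similarity

Profiles are compared on their shared features with a weighted
correlation
`r = Σw(x−x̄_w)(y−ȳ_w) / √(Σw(x−x̄_w)²·Σw(y−ȳ_w)²)`,
where means are weighted (`x̄_w = Σwx/Σw`). Whether the centering should
be weighted is not obvious; weighted centering is the standard weighted-
correlation definition and was adopted. Three weight schemes:

- *unweighted* — all ones;
- *inverse variance* — `1/var(feature across the compendium)`; when no
  external variance table exists, the indexed library itself supplies it
  (`library_feature_variances()`);
- *p-value* — `w_i = [−log(p_i1·p_i2)]^(1/C)`, the two profiles'
  FDR-adjusted p-values. The log base is unspecified in the usual
  formulation; the natural log is used here, and because the correlation
  is invariant to uniform weight rescaling (property-tested) the choice
  is immaterial. `C` (default 2) flattens the weight profile as it
  grows; it is exposed on `weight_scheme()`.

The Spearman variants rank first (unweighted, average ties) and weight
second. Per-feature contributions
`w_i(x_i−x̄_w)(y_i−ȳ_w)/√(·)` sum exactly to the signed correlation and
stay signed even in absolute mode, so a contribution plot still shows
direction. A minimum-overlap guard (default 100 shared genes, 10 shared
components/modules) refuses comparisons on too little common ground.

## Search, null and network

`build_index()` collects profiles into one space (projecting gene-space
profiles when a basis is supplied) and records failures in an exclusion
report instead of aborting. `sample_null()` scores random distinct
profile pairs (default 10,000, seeded): self-pairs are excluded, but
pairs from the same source experiment are allowed — the background can
therefore contain genuinely related pairs, which biases q-values
upward, i.e. conservatively. If fewer distinct pairs exist than
requested, all of them are used and the shortfall reported. The
empirical q-value is add-one smoothed,
`q = (#{null ≥ s}+1)/(n+1)`: pure exceedance counting would report q = 0
above the background maximum, and the smoothed version is never
anti-conservative. Query results sort by score with lexicographic
tie-break on target id, so output is deterministic. Networks keep edges
at `q < q_threshold` (default 0.001); absolute-value scoring is the
default for search and networks because the direction of an arbitrary
library comparison is meaningless, while the evaluation harness uses
signed correlation since its compendia share a fixed case-vs-control
direction.

## Evaluation harness

Leave-one-out retrieval ranks, for each profile, all remaining profiles;
relevance means sharing the query's condition label. AUC uses the
rank/Mann–Whitney form with half credit for ties, the mean and standard
error are taken over queries, and the average ROC curve is formed by
vertical averaging on a 101-point false-positive-rate grid (the
averaging convention is not canonical; vertical averaging is the common
default). Precision-at-k (default k = 4) is compared against a
label-permutation null in which all labels are permuted and relevance
recomputed; for balanced designs the per-query null mean is the
hypergeometric expectation `(m−1)/(n−1)`, which the tests verify at
10,000 permutations. `evaluate_grid()` runs the full measure × reduction
design (Pearson/Spearman × three weightings × any supplied spaces) and
tabulates mean AUC ± SE per cell.

## The synthetic compendium

`simulate_compendium()` generates the study conditions end to end: each
*condition* owns a fixed signed program of `program_size` genes; each
*experiment* of that condition gets its own platform (a fraction
`platform_dropout` of genes absent; per-gene probe multiplicities drawn
from `probes_per_gene`), a per-gene batch offset `N(0, batch_sd)`,
case/control groups of `samples_per_group`, i.i.d. Gaussian noise
`N(0, noise_sd)` on the log2 scale, and probe-level values = gene value
+ fixed probe offset + probe noise, so probe aggregation has real work
to do. A `species_mix` fraction of experiments is labeled non-human with
species-prefixed identifiers and a generated one-to-one homolog map.

Reference defaults — 3 conditions × 8 experiments, 5,000 genes, 200-gene
programs, effect 1.0 log2 units, noise SD 1.0, batch SD 0.25, dropout
0.2, 5 samples per group — describe a modest, realistic setting:
GEO-scale group sizes, an effect equal to the noise SD, and programs
covering 4% of the transcriptome. The generator reproduces the
*structure* that matters to the pipeline (shared programs across
platforms, probe redundancy, batch shifts, cross-platform gene
intersections, cross-species mapping) but not array chemistry,
normalization artifacts, correlated gene modules outside the planted
programs, or heavy-tailed noise. Passing tests therefore show the
machinery is correct and calibrated under clean Gaussian conditions —
not that retrieval performance on real heterogeneous compendia will
match; on real data the profile p-values absorb some, but not all, of
that extra structure.

## Problem sizes and numerical choices

The package's evaluation uses: 20 generator seeds for gene-space
retrieval (and 20 for the zero-effect control); 20 seeds for the
component-space comparison, each deriving a 50-component basis with 5
ICA runs from 24 held-out experiments of the same conditions; a fully
null 50-profile library (all 1,225 distinct pairs as background) for
q-value calibration; a 150-profile, 10-condition library for the
q < 0.001 network (large enough that q < 0.001 is attainable under
add-one smoothing, which needs more than ~1,000 background pairs); and 5
seeds at SNR 10 for ICA source recovery. The acceptance script repeats
the same computations at 10/5 seeds to stay lightweight.

Other numerical details, collected: probe and gene variances floored at
`1e-8`; p-values floored at `1e-300` before logs; trigamma inversion by
Newton with closed-form guards at both extremes; ICA convergence at
`max|diag(W W_old') − 1| < 1e-6`, 200 iterations max; PAM uses the
`pamonce = 5` shortcut, which changes runtime, not medoids' quality
class; all RNG flows through seed arguments and restores the caller's
RNG state.

## Limitations

Only two-group comparisons of a single factor are modeled — no paired or
multi-factor designs. The homolog map is input data; no annotation
service is consulted. The compendium variance for inverse-variance
weighting defaults to the library itself, which is circular for very
small libraries. Empirical q-values inherit the granularity of the
background (`q ≥ 1/(n+1)`), so small libraries cannot reach stringent
thresholds — by design, not accident. The balancing step in component
derivation implements the *intent* (collapse near-duplicate samples),
not any particular published recipe.
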