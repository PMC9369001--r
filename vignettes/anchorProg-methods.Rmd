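---
title: "anchorProg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{anchorProg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind each pipeline stage, the
tunable parameters and their defaults, the numerical conventions, and the
design decisions that were genuinely open — the choices a maintainer would
otherwise have to reverse-engineer from the code.

## The question the pipeline answers

An *anchor gene* (the package default symbol is `POLI`, a translesion
synthesis polymerase) can be a positive prognostic factor in one tumor
context and a negative one in another. The pipeline treats the direction of
the anchor–survival association as a property of the tumor transcriptome:
two *reference cohorts* with opposite, established anchor prognosis define
the contexts, a classifier learns to recognize them from anchor-associated
genes, and every other patient is assigned to the context their
transcriptome resembles. Survival analysis is then run inside the predicted
groups rather than inside nominal cancer types.

## Stage models

**Transform.** Raw FPKM-like values are mapped with `log2(x + 1)` and
z-scored per gene *within each cancer type* (sample standard deviation;
zero-variance genes dropped and logged). The log base is a convention —
any monotone log leaves Spearman statistics untouched and Pearson
statistics unchanged up to scale; base 2 with a pseudocount of 1 is the
RNA-seq default. The `CohortExpression` container tracks the transform
state so standardization cannot be applied twice.

**Candidate pooling.** Within a standardized reference cohort, every
non-anchor gene receives a Pearson (default) or Spearman correlation with
the anchor; the top `nPos = 500` positive and top `nNeg = 500` negative
coefficients form the pool. Boundary ties break lexicographically by gene
symbol so reruns are bit-identical. Genes with undefined correlations are
excluded and logged.

**Graphical-lasso selection.** The pool's correlation matrix `S` (computed
on standardized values, so correlation equals covariance) feeds an
L1-penalized Gaussian likelihood maximization for the precision matrix,
solved by block coordinate descent in C++. Conventions:

* the penalty applies to off-diagonal entries only (`W_ii = S_ii`), so
  `lambda = 0` reduces to the direct inverse — this is also the convention
  of the main Python implementation, which the test suite uses as a frozen
  cross-check;
* convergence: mean absolute change of the working covariance off-diagonal
  below `1e-4` of the mean off-diagonal magnitude; non-convergence is an
  error carrying the offending `lambda`;
* an edge exists when `|Theta_ij| > 1e-6` (numerical zero).

The solution is exactly block diagonal over the connected components of the
thresholded graph `{|S_ij| > lambda}` (the screening results of Witten et
al. 2011 and Mazumder & Hastie 2012). `estimatePrecision()` exploits this to
solve per component, and `tuneLambdaToTarget()` uses the same fact to read
the selection size at any `lambda` without refitting — a gene has at least
one edge iff some `|S_ij|` exceeds `lambda`.

*Selection criterion.* "Retained in the sparse network" is read as *incident
to at least one edge anywhere*, not only edges touching the anchor:
selection happens on a gene–gene precision matrix, and anchor-adjacency
alone typically cannot produce 200 genes. Because the selection size is a
step function of `lambda`, bisection (40 iterations over `[1e-3, 1]`)
converges to the smallest penalty whose selection is at least the target;
any excess is dropped by smallest maximum off-diagonal precision magnitude,
ties again by symbol. This exact-cardinality rule is reused verbatim for
the 100 → 50 network refinement so the two stages stay consistent.

**Classifier.** The two reference cohorts are balanced by uniform
under-sampling of the majority cohort, split 70/30 stratified by cohort, and
fed to a 500-tree random forest (`floor(sqrt(p))` candidate features per
split, Gini impurity, unlimited depth — the ecosystem defaults, since no
hyperparameters are prescribed). Importances are normalized mean decreases
in Gini impurity. Transfer patients get the forest's vote fraction for
group 1; the predicted group is group 1 when the fraction is at least 0.5,
with exact ties going to group 1 and logged.

*Feature scaling — a deliberate deviation.* Classifier features are
`log2(x + 1)` values standardized per gene with parameters **fitted on the
pooled reference cohorts and applied frozen to transfer cohorts**, not
re-standardized per cohort. The reason is structural: a per-cohort z-score
removes every cohort-constant signal, so two pure-context reference cohorts
become *distributionally identical* after per-cohort standardization and no
classifier can beat chance — the training signal is exactly the
between-cohort component that per-cohort centering deletes. Freezing the
train-time scaler is the standard supervised-learning remedy and keeps
transfer assignments invariant to the composition of the cohort a patient
arrives in. The correlation and graphical-lasso stages, which are genuinely
within-cohort analyses, keep per-cancer-type standardization. The tradeoff:
real cohort-level batch effects (sequencing depth, platform) would leak into
reference-scaled features; with real data the scaler should be combined
with an upstream batch correction.

**Survival.** Follow-up times are divided by the maximum within their
cancer type and multiplied by 1000, making cohorts poolable on a common
[0, 1000] axis. Patients are stratified at the *pooled* anchor median
(per-cohort standardized anchor expression; at-the-median samples go to
"low", logged) — the paper-style analysis pools first and stratifies second,
and the median is the least-parameterized cutoff. K–M curves and the
two-sample log-rank test (hypergeometric variance at each distinct event
time, chi-square with 1 df) are computed via the `survival` package; the
test suite verifies both against hand-rolled product-limit and
moment-summation oracles to 1e-10.

*Backward selection.* Starting from all cancer types with group-classified
patients, the pooled log-rank p is computed; while `p >= alpha` and more
than one type remains, the single type whose removal minimizes the pooled p
is removed (re-stratifying within the reduced pool). Every step is recorded
(`BackwardSelectionTrace`) together with the effect direction — which arm's
K–M curve lies lower at the pooled median follow-up. Greedy p-minimization
*inflates* significance; the final p is a selection-optimized quantity and
is reported as such, not as a calibrated test. The trace exists precisely so
alternative stopping rules can be audited.

**Networks.** The forest's top-100 importance genes are refined to a
50-gene core per reference cohort with the same tuning rule; clusters are
connected components (matching the "isolated cluster" language of
association-network practice); node order is reverse Cuthill–McKee (BFS from
a George–Liu pseudo-peripheral minimum-degree start, neighbors by increasing
degree, order reversed; an edgeless graph keeps its input order). Chord-plot
edge widths use the off-diagonal precision magnitude (a partial-correlation
proxy); heatmap axis labels are drawn only for genes flagged in the
classifier's top-importance list.

## The synthetic generator

`generateCohort()` draws a per-sample latent factor `f ~ N(0, 1)` and builds
the per-gene Gaussian field

* anchor: `sqrt(rhoAnchor)·f + sqrt(1 − rhoAnchor)·ε` (default reliability
  `rhoAnchor = 0.9`);
* positive / negative modules (60 + 60 genes by default):
  `±sqrt(rhoMod)·f + …` with `rhoMod = 0.7`, so the model-implied
  anchor–module correlation is `sqrt(rhoMod · rhoAnchor)`;
* context signature (60 genes): loading `±sqrt(rhoSig)·f` with
  `rhoSig = 0.3` *plus* a context mean shift of `±delta/2` (`delta = 2` SD),
  so the two pure contexts differ by `delta` per signature gene. The shift
  direction is balanced against the loading sign (++, +−, −+, −− cycle) so
  the context discriminant is orthogonal to the latent factor; the loading
  itself encodes the working hypothesis that the context signature lives
  *among* the anchor-correlated genes and therefore flows through the
  pipeline's own feature selection;
* remaining genes: independent noise.

The field is exponentiated (`2^(2·z + b_g)`, per-gene baselines
`b_g ~ U(2, 10)` drawn once and shared by all cohorts) so the pipeline's log
transform recovers it; the `+1` pseudocount mildly attenuates shifts for
low-baseline genes, which the tests quantify. Survival is exponential with
hazard `h0 · exp(s·beta·z_anchor)` (`h0 = 0.001`/day, `beta = 1`, `s = +1`
in context A — high anchor hastens death — and `−1` in context B);
censoring is administrative at the empirical time quantile matching the
configured rate (default 20%), which hits the target exactly and suffices
for K–M testing. All draws derive from the master seed via per-stage seed
hashing, so cohorts are individually reproducible.

What the generator does **not** emulate: real marginal count distributions,
batch effects, gene-length/GC biases, real gene symbols, competing risks, or
covariate-dependent censoring. Passing tests demonstrate that the pipeline
recovers structure it is pointed at, not that real tumor cohorts contain
such structure.

## Problem sizes and numerical choices in the tests

The suite exercises the full default conditions (1200 genes, 1000-gene
pool, 200-gene selections, 100 samples per reference cohort) in the
acceptance tests and scales other simulations down (250–400 genes, 60–200
samples) so the whole suite runs in a few minutes on one CPU. Monte-Carlo
properties use 15–100 fixed-seed replicates: log-rank power (β = 1,
n = 300, 20% censoring, ≥ 90% detection), transfer group recovery (δ = 2,
ρ_mod = 0.7, n = 200 per cohort, ≥ 90% per-patient accuracy),
permuted-label forests (held-out accuracy ≈ 50%), and the backward-selection
stress test. The latter plants 4 × 40-sample effect cohorts (β = 0.3) in
2 × 1500-sample null cohorts with `alpha = 0.001`: the pooled log-rank
dilution from added null cohorts is empirically much weaker than an
events-fraction heuristic suggests (administrative censoring concentrates
arm imbalance late in follow-up), so a strict threshold is what separates
"shed the null cohorts" from "stop one step early". The null-everywhere
variant documents, without asserting control, that greedy selection yields
anti-conservative final p-values.

## Known limitations

* The graphical-lasso selection criterion, the backward-selection stopping
  rule, and the high/low cutoff are all under-determined by the motivating
  analysis; each implemented choice is logged or traced so alternatives can
  be compared, but results can depend on them.
* Exact-cardinality selection makes the gene count, not a sparsity level,
  the invariant; two cohorts' selections can overlap heavily or barely,
  and the merged feature count varies accordingly.
* The final log-rank p-values inherit greedy-selection optimism and should
  be treated as descriptive.
* Transfer classification assumes the reference-fitted scaler is valid for
  other cohorts; strong batch effects violate this (see above).
* Figures are static exports; no interactive network visualization.
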