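# anchorProg

Context-dependent prognostic stratification for an anchor gene across cancer
cohorts.

## The problem

Expression of a single gene can predict survival in opposite directions
depending on the tumor context. The motivating case is a translesion
synthesis (TLS) DNA polymerase gene (*POLI*): TLS polymerases let replication
forks bypass the DNA lesions caused by genotoxic chemotherapy, so high TLS
polymerase expression often marks therapy-resistant, poor-prognosis tumors —
yet in some cancer types the association flips, and high expression
accompanies *better* survival. If the surrounding transcriptome dictates
which way the association points, then the transcriptome should also be able
to *predict* it: patients whose tumors look like a "high anchor expression →
worse survival" reference cohort should show that pattern regardless of
their nominal cancer type.

`anchorProg` implements that idea as a tested, fully seeded pipeline, generic
in the anchor gene:

1. **Transform** — per cancer type, expression is `log2(x + 1)` transformed
   and z-scored per gene.
2. **Candidate pooling** — within each of two reference cohorts with
   opposite anchor prognosis, all genes are ranked by Pearson (or Spearman)
   correlation with the anchor; the top 500 positively and top 500
   negatively correlated genes form a 1000-gene pool.
3. **Graphical-lasso selection** — a sparse inverse covariance (precision)
   matrix Θ is estimated over the pool by maximizing the L1-penalized
   Gaussian log-likelihood

   `log det Θ − tr(SΘ) − λ ‖Θ‖₁,off`

   and the penalty λ is tuned by bisection until exactly 200 genes remain
   connected in the precision graph (the selection size is a step function
   of λ; exact cardinality is guaranteed by dropping weakest-edge genes at
   the boundary). The two 200-gene sets are merged into the classifier
   feature set.
4. **Random-forest transfer classification** — after under-sampling the
   larger reference cohort and a stratified 70/30 split, a 500-tree random
   forest learns to separate the two reference cohorts; patients from every
   other cohort are assigned to Group 1 ("reference-A-like": high anchor →
   worse survival) or Group 2 ("reference-B-like") by forest vote.
5. **Survival analysis** — follow-up times are normalized per cancer type
   (each type's maximum maps to 1000), patients are stratified at the pooled
   anchor-expression median, and Kaplan–Meier / log-rank analysis is run per
   predicted group. Greedy backward selection removes, one at a time, the
   cancer type whose removal most decreases the pooled log-rank p, stopping
   when p < α — isolating the cohort pools where the anchor's prognostic
   value stands out.
6. **Network refinement** — the forest's top-100 importance genes are
   reduced to a 50-gene core association network per reference cohort
   (graphical lasso again), clustered into connected components, ordered by
   reverse Cuthill–McKee for band-structured display, and exported as
   chord-plot and heatmap figures.

Because the real inputs are controlled-access-scale TCGA cohorts, the
package ships a first-class synthetic generator: multi-cohort expression
with planted anchor-correlated modules (`ρ_mod`), two latent transcriptome
contexts with a `δ`-SD signature separation, and exponential survival whose
hazard is `h0·exp(s·β·z_anchor)` with the sign `s` flipped by context. Every
stage of the pipeline is tested against that ground truth.

## Worked example

```r
library(anchorProg)

synth <- syntheticConfig(nGenes = 400, nPosMod = 30, nNegMod = 30,
                         nSignature = 40, samplesPerCohort = 200, seed = 42)
scenario <- syntheticScenario(synth, nTransfer = 3)   # REFA, REFB + 3 cohorts
config <- runConfig(nPos = 120, nNeg = 120, targetSelect = 120,
                    networkTopK = 40, networkCore = 20, seed = 42)
res <- runPipeline(scenario$cohorts, scenario$clinical, config,
                   outdir = "prognosis_run")
```

The run log prints each stage; on this scenario the model card reports

```
[anchorProg] merged 120 + 120 genes -> 140 unique (overlap 100)
[anchorProg] held-out accuracy: 1
```

i.e. the two reference selections share 100 genes, and the forest separates
the held-out reference patients perfectly. Per-patient assignments carry the
group-1 vote fraction:

```r
head(res$assignments, 3)
#>             sample_id cancer_type  group vote_group1
#>  SYN3-S0001 SYN3-S0001        SYN3 group1       0.958
#>  SYN3-S0002 SYN3-S0002        SYN3 group1       0.932
#>  SYN3-S0003 SYN3-S0003        SYN3 group1       0.952
```

and the per-group survival analysis confirms the planted directions — in
Group 1 the anchor-high arm has worse survival, in Group 2 better:

```r
res$survival$group1$trace
#>   step removed n_types            p  direction
#> 1    0    <NA>       2 1.489086e-27 high_worse
res$survival$group2$trace
#>   step removed n_types            p   direction
#> 1    0    <NA>       2 1.027185e-30 high_better
res$networks$REFA
#> GeneNetwork [REFA]: 20 genes, 17 edges, 3 clusters (sizes 15, 3, 2)
```

`prognosis_run/` then contains every stage output as TSV (rankings, pools,
selections, merged features, model card, assignments, group counts, K–M
curves, log-rank reports, backward-selection traces, network edge lists)
plus chord/heatmap figures and a JSON run manifest with per-file hashes —
re-running with the same config and seed reproduces the hashes.

A file-level CLI with per-stage subcommands (`simulate`, `rank`, `select`,
`train`, `classify`, `survive`, `network`, `all`) is available via
`anchorProgCLI()` or the `inst/cli/anchorprog` Rscript.

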