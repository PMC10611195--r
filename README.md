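# tpodr

Transcriptomic points of departure (TPODs) from short-term dose-response
gene-expression studies.

Regulatory toxicology traditionally derives a point of departure (POD) from
long apical studies — NOAELs/LOAELs from multi-month rodent bioassays, or
NOECs/LOECs from chronic fish exposures. A short transcriptomic study (days)
can stand in for them: expose to a dose or concentration series, sequence,
fit continuous dose-response models to each responsive gene, and read a POD
off the most sensitive biologically coherent gene set. `tpodr` implements
that workflow end to end for bulk RNA-seq count matrices from either a
dietary rodent design (doses in mg/Kg-bw/day) or an aquatic larva design
(concentrations in mg/L), and includes a synthetic-data generator with known
per-gene ground truth so every stage is testable without any external data.

## The method

For a gene with normalized expression $y$ (log2 CPM + 1) and dose $d$:

1. **Filtering and normalization.** Genes with median count ≤ 8 across all
   samples are removed; counts are normalized to counts per million and
   log2-transformed with a pseudocount of 1; dietary (mouse-like) designs are
   additionally adjusted for blocking batches with a per-gene linear model.
2. **Prefilter.** One-way ANOVA across dose groups plus a maximum absolute
   fold-change gate (maxFC ≥ 2). Significance uses Benjamini–Hochberg
   FDR-adjusted p < 0.05 in mouse-like mode and raw p < 0.05 in minnow-like
   mode.
3. **Benchmark-dose modeling.** Each candidate gene is fitted with nine
   continuous models (Exp2–Exp5, Linear, Poly2, Poly3, Hill, Power) by
   constant-variance maximum likelihood. The polynomial order is promoted
   only when a nested likelihood-ratio chi-square rejects (p < 0.05); the
   family champion competes with the other models on lowest AIC; a winning
   Hill fit with $k$ below one third of the lowest positive dose is set aside
   for the next-best model with goodness-of-fit p > 0.05. The benchmark dose
   solves $|\mu(\mathrm{BMD}) - \mu(0)| = 1.349\,\hat\sigma$ (a ~10% tail
   shift), with one-sided 95% profile-likelihood bounds BMDL/BMDU. Genes with
   BMD above the highest tested dose or BMDU:BMDL > 40 are excluded.
4. **Gene sets and TPOD.** Surviving genes are tested for gene-set
   over-representation with a two-tailed Fisher exact test (enriched: p <
   0.05 and ≥ 3 overlapping genes). The enriched set with the lowest median
   BMD is the most sensitive; its median BMD is the transcriptomic BMD and
   its median BMDL is the **TPOD**.
5. **Concordance.** TPODs are compared against apical PODs by absolute fold
   difference ($\max/\min$, always ≥ 1), the 10-fold agreement band,
   per-chemical mean ± SD summaries, and potency rankings.

## Worked example

```r
library(tpodr)

cfg <- simulation_config("mouse_like", n_genes = 500, n_gene_sets = 40, seed = 1)
sim <- generate_experiment(cfg)
sim$experiment
#> <dr_experiment> 500 genes x 35 samples
#>   dose levels (mg/Kg-bw/day): 0, 1.5, 3.75, 7.5, 15
#>   batches: batch1, batch2

res <- run_tpod_pipeline(sim$experiment, sim$gene_sets,
                         tpod_config("mouse_like"),
                         chemical = "chemA", assay = "mouse-like")
res
#> <tpod_result> status: ok
#>   genes: input=500, filtered=500, candidates=49, modeled=49, retained=49
#>   most sensitive enriched set: SET0003
#>   gene-set BMD = 2.127, TPOD (median BMDL) = 1.606, BMDU = 2.776
```

Of 500 simulated genes, 49 pass the ANOVA/fold-change prefilter, all survive
the BMD filters, and 5 of 40 annotated sets are enriched; the most sensitive
enriched set (SET0003) puts the gene-set BMD at 2.13 mg/Kg-bw/day and the
TPOD — the median lower confidence bound across its genes — at 1.61
mg/Kg-bw/day. `tidy(res)` returns the per-gene model/BMD table and
`glance(res)` the one-row summary; `plot_accumulation(res$enrichment)` draws
the gene-set accumulation curve.

Comparison against an apical POD:

```r
fold_difference(0.093, 0.01, chemical = "methidathion")
#> # A tibble: 1 × 7
#>   chemical      tpod  apod  fold fold_display direction           within_10fold
#>   <chr>        <dbl> <dbl> <dbl>        <dbl> <chr>               <lgl>
#> 1 methidathion 0.093  0.01   9.3          9.3 apod_more_sensitive TRUE

potency_ranking(c(FT = 0.009, MT = 0.093, PT = 0.046))
#> # A tibble: 3 × 4
#>   chemical  tpod  rank tied
#>   <chr>    <dbl> <int> <lgl>
#> 1 FT       0.009     1 FALSE
#> 2 PT       0.046     2 FALSE
#> 3 MT       0.093     3 FALSE
```

Real data enter through `read_experiment()` (counts TSV + sample CSV),
`read_gmt()` (gene sets) and `read_apod()` (apical POD table); see the
methods vignette (`vignettes/tpod-methods.Rmd`) for the modeling details,
parameter defaults and limitations.

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch on a
simulated mouse-like experiment (simulation, filtering, normalization, batch
adjustment, prefilter, nine-model BMD fitting with profile bounds, gene-set
enrichment, TPOD derivation) and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
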