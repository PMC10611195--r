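---
title: "Transcriptomic benchmark-dose modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic benchmark-dose modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpodr)
```

`tpodr` turns a dose-series gene-expression count matrix into gene-level
benchmark doses (BMDs), a gene-set-level transcriptomic point of departure
(TPOD), and concordance summaries against apical points of departure. This
vignette documents the statistical model at each stage, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices a maintainer should
know about.

## The response model

All modeling happens on the normalized scale $y = \log_2(\mathrm{CPM} + 1)$.
The central assumption is **constant variance**: residuals of $y$ around the
dose-response mean are Gaussian with a standard deviation $\sigma$ that does
not depend on dose. For RNA-seq counts this is the log-scale analogue of a
constant coefficient of variation, and it makes the benchmark response
(defined in units of $\sigma$) a single number per gene.

Nine mean functions are supported, in the EPA BMDS continuous tradition:

| model | mean function | mean parameters |
|---|---|---|
| linear | $\beta_0 + \beta_1 d$ | 2 |
| poly2 / poly3 | adds $\beta_2 d^2$ (and $\beta_3 d^3$) | 3 / 4 |
| power | $\gamma + \beta d^\delta$, $\delta \in [1, 18]$ | 3 |
| hill | $\gamma + v\,d^n / (k^n + d^n)$, $n \in (0, 18]$, $k > 0$ | 4 |
| exp2 | $a e^{u d}$, $a > 0$ | 2 |
| exp3 | $a e^{u d^c}$, $c \in [1, 18]$ | 3 |
| exp4 | $a (c - (c - 1) e^{-b d})$, $b > 0$ | 3 |
| exp5 | $a (c - (c - 1) e^{-(b d)^g})$, $g \in [1, 18]$ | 4 |

Two parameterization choices depart from the most literal reading of the
BMDS manuals and are deliberate. First, exp2/exp3 fold the adverse-direction
sign $s$ and the positive rate $b$ into one signed rate $u = s\,b^c$; the
families are identical, but the parameter space is smooth, which matters for
the deterministic multistart optimizer. Second, exp5 carries a separate
power parameter $g$ (four mean parameters), the standard BMDS form; a
three-parameter variant that reuses the asymptote parameter as the power is
sometimes written down, but it is not the BMDS family and cannot represent
the same sigmoid shapes.

Fitting maximizes the Gaussian likelihood, equivalently minimizes the SSE,
with the variance MLE $\hat\sigma^2 = \mathrm{SSE}/n$. Because the
likelihood depends on the data only through group means, group sizes and the
pooled within-group sum of squares, all fitting and profiling runs on those
sufficient statistics — a large constant-factor speedup at identical
results. Linear/polynomial models are solved in closed form (weighted least
squares on group means); the nonlinear models use eight deterministic starts
derived from data quantiles, so there is **no RNG anywhere in fitting** and
refits are bit-reproducible. AIC counts the variance parameter:
$\mathrm{AIC} = 2(p_{\text{mean}} + 1) - 2\ell$.

## Model selection

Within the polynomial family, a higher order is accepted only when the
nested likelihood-ratio chi-square (df = parameter-count difference) rejects
at p < 0.05. The family champion then competes with the exponential, Hill
and power fits on lowest AIC. A winning Hill fit whose half-maximal dose
$k$ falls below one third of the lowest positive dose is flagged — such a
fit asserts a plateau below the observable dose range — and the next-best
model by AIC with goodness-of-fit p > 0.05 is taken instead; if none
qualifies the gene has no selection and is excluded. Goodness of fit is the
likelihood ratio against the saturated group-means model (df = number of
dose groups minus mean parameters; undefined when df ≤ 0, which is treated
as acceptable since the model is then as flexible as the saturated one).
The "p-value > 0.05" in the flagged-Hill fallback is read as this
goodness-of-fit p; the output records which path selected each model.

## BMD, BMDL, BMDU

The benchmark response is $\mathrm{BMR} = 1.349\,\hat\sigma$ (default
`bmr_factor = 1.349`, a ~10% tail shift under normality). The BMD is the
smallest dose with $|\mu(d) - \mu(0)| = \mathrm{BMR}$, located by bracketing
on a log grid over $(0, 10 \cdot d_{\max}]$ and root refinement to 1e-8
relative tolerance. Searching beyond the tested range is intentional: a
crossing at, say, $1.2\,d_{\max}$ is found and then excluded by the
"BMD above highest dose" rule with its reason recorded, rather than being
silently absent.

Confidence bounds are one-sided 95% profile-likelihood limits (the BMDS
convention; Wald intervals are unstable for BMD functionals). The BMR
constraint ties $\sigma$ to the mean parameters —
$\sigma = |\mu(b) - \mu(0)| / 1.349$ for a pinned BMD value $b$ — so the
profile is maximized over mean parameters only, and each bound is found by
monotone bisection on $b$ against the cutoff
$\ell_{\max} - \chi^2_1(0.90)/2 \approx \ell_{\max} - 1.3528$. An upper
bound that cannot be located below $100 \cdot d_{\max}$ is reported `NA`
and excludes the gene (reason `no_bmd_in_range`).

Gene-level exclusions (strict inequalities, boundary retained): BMD above
the highest tested dose; BMDU:BMDL ratio above 40; no convergent/selected
model; any of BMD/BMDL/BMDU undefined.

## Gene sets and the TPOD

Enrichment uses the two-tailed Fisher exact test: the p-value sums all
hypergeometric table probabilities not exceeding the observed one (relative
tolerance 1e-7 against floating-point ties). A set is enriched when p <
0.05 **and** at least three responsive genes overlap it. The universe is
the tested transcriptome — all genes surviving the low-count filter — not
all annotated genes (`universe_mode = "filtered"`; `"annotated"` is
available). Gene sets come from GMT files as-is; no ontology-ancestry
rollup is performed.

The most sensitive enriched set is the one with the lowest **median BMD**
(ties: lower median BMDL, then smaller p, then set id). Its median BMD is
the transcriptomic BMD; its median BMDL is the TPOD. Set-level medians of
BMD, BMDL and BMDU are each the median of their own column over the
overlapping non-excluded genes (an even-sized list uses the midpoint mean),
so the set-level BMDL is a median of lower bounds, not the bound of a
median gene — the output labels it accordingly. When no set is enriched the
result is explicitly empty (`n_enriched_sets = 0`); nothing is fabricated.

Note one subtlety: because the winner is chosen by median BMD but the TPOD
is that winner's median BMDL, removing the winning set can in principle
*lower* the TPOD (the next winner may carry wider per-gene uncertainty).
The monotone quantity is the winning median BMD, and that is what the
property tests assert.

## Defaults and where they come from

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | prefilter and enrichment significance |
| `min_fc` | 2 | maximum absolute fold-change gate (inclusive) |
| `bmr_factor` | 1.349 | benchmark response in residual SDs |
| `confidence` | 0.95 | one-sided level of BMDL/BMDU |
| `ratio_cutoff` | 40 | BMDU:BMDL exclusion threshold |
| `hill_k_fraction` | 1/3 | Hill flag threshold vs. lowest positive dose |
| `min_overlap` | 3 | enrichment overlap requirement |

Mode controls two behaviors: `mouse_like` uses FDR-adjusted prefilter
p-values and applies batch adjustment when labels exist; `minnow_like` uses
raw p-values and never batch-adjusts.

The prefilter fold change is computed from group means of
$\log_2(\mathrm{CPM}+1)$, back-transformed ($2^{|\bar y_g - \bar y_0|}$) —
the same matrix the ANOVA uses — rather than from raw count ratios. This is
the single fold-change definition used everywhere.

## The synthetic-data generator

`simulation_config()` encodes two stated designs: **mouse-like** (control +
4 dose levels at 0/1.5/3.75/7.5/15 mg/Kg-bw/day, n = 7 per group, two
balanced blocking batches) and **minnow-like** (control + 10 half-log-spaced
concentrations, n = 8 per group, no batches). A fraction of genes (default
10%) follows a known curve shape (linear, Hill, exp5 or power) with an
absolute log2 effect at the top dose drawn from [1, 3]; directions are
random ±1. Noise is Gaussian on the log2 scale with SD $\log_2(1 + cv)$
(default cv = 0.25 — the real studies' dispersions are unknown, so this is
a free knob chosen once as typical for bulk RNA-seq), constant across dose,
matching the modeling assumption. Counts arise by scaling $2^x$ to a
lognormal per-sample library size (mean 3e6) and rounding. Baselines are
shifted so the *expected realized* total CPM is 1e6, which requires
budgeting for the lognormal noise's Jensen factor
$E[2^\varepsilon] = e^{(\sigma \ln 2)^2/2}$; without it every realized
log2 CPM mean sits ~0.04 below the recorded truth curve and the generator's
own fidelity contract fails. Batch effects are additive per-gene log2
shifts (SD 0.3) shared within balanced blocks, matching the linear-model
adjustment downstream.

Every responsive gene's true BMD is computed analytically from its
noiseless curve at the configured BMR with $\sigma$ set to the configured
noise SD — not an estimate — so recovery error is attributable to the
analysis, and each closed form is cross-checked against numeric
root-finding in the tests.

What the generator does **not** emulate: read-level sequencing error,
probe-level structure, count overdispersion beyond the lognormal
(no gene-specific dispersion), dropout/mortality, and correlated
co-expression. A green test therefore establishes correctness of the
statistical machinery under the stated model, not robustness to real-data
pathologies.

Two generator facts worth knowing. First, CPM normalization is
compositional: if *every* gene responds, the per-sample totals move with
dose and all slopes are biased (measured at ~2-fold median BMD error for
up-regulated genes in a responsive-only matrix). Recovery experiments
therefore embed responsive genes in a majority-flat transcriptome, as real
data do. Second, parameter-recovery calibration (median relative BMD error
~12%, one-sided BMDL coverage ~95% at n = 7/group) holds for the
*generating* model class; running the full nine-model AIC cascade on
linear-truth genes adds model-selection noise (occasional exp/polynomial
winners with large BMD error) and the usual post-selection degradation of
interval coverage. That is a property of AIC-cascade workflows generally,
not of this implementation, and is why the recovery tests fit the known
model class while the cascade's own logic is tested separately.

## Numerical conventions and degenerate inputs

* Genes with zero within-group variance everywhere: ANOVA p = 0 if group
  means differ, else 1.
* SSE is floored at 1e-300 before taking logs, so noiseless fixtures give
  large finite log-likelihoods instead of infinities.
* The Hill fraction is evaluated as $1/(1 + (k/d)^n)$, avoiding overflow of
  $d^n$ at large $n$; exponentials are clamped at $e^{700}$.
* Multistart non-convergence is reported honestly (`converged = FALSE`,
  never fabricated parameters); an all-unconverged gene is excluded with
  reason `no_converged_model`.
* Median-count filtering uses a strict "> 8" retention rule; a gene at
  exactly the median-8 boundary is removed.
* "Less-than" apical PODs (values printed as "< x") enter fold arithmetic
  at their printed bound, with the qualifier propagated.
* Display rounding of fold differences is one decimal, half-up; the
  unrounded fold is always reported alongside.
* No conversion between mg/L and mg/Kg-bw/day is ever attempted; unit
  mismatches are errors.

## Interfaces

Counts TSV (genes × samples), sample CSV (`sample_id`, `dose`, optional
`batch`), GMT gene sets, and an apical-POD CSV (`chemical`, `species`,
`endpoint_type` NOAEL/LOAEL/NOEC/LOEC, `value`, `units`, optional
`qualifier` exact/less_than) are read by `read_experiment()`, `read_gmt()`
and `read_apod()`. `run_tpod_pipeline()` composes all stages, writes every
intermediate table as CSV stamped with a config hash plus a JSON manifest,
and is fully deterministic for fixed inputs. An ortholog mapping (for
cross-species gene-set use) is a user-supplied two-column table applied to
gene ids before enrichment; no sequence-similarity mapping is performed
here.

## Known limitations

* Only constant-variance Gaussian likelihoods: no power-of-mean variance
  models, model averaging, Bayesian BMD, or dichotomous endpoints.
* Profile bounds assume the usual chi-square calibration; at very small
  group counts the one-sided coverage can drift a few points from nominal.
* The exponential families are multiplicative, so their fits (unlike
  linear/polynomial/Hill/power) are not invariant to adding a constant to
  the response — relevant only if the input is something other than a
  non-negative log2 expression scale.
* The exact parameter bounds BMDS uses internally are not public in every
  version; the bounds above are documented and configurable in code, and
  results should be compared across tools with that caveat.
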