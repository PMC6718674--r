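---
title: "Within-pair methylome and transcriptome analysis in discordant monozygotic twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-pair methylome and transcriptome analysis in discordant monozygotic twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinewas)
```

## The design and the model

Monozygotic (MZ) twin pairs discordant for a phenotype are a matched design:
the two members share genotype, age, sex and early family environment, so a
within-pair contrast cancels those factors. For each CpG probe (or gene) the
response is the within-pair log2 ratio

$$
y_j \;=\; \log_2\!\frac{\text{value in affected twin}_j}
                        {\text{value in unaffected co-twin}_j}
\;=\; \alpha + \sum_i \beta_i x_{ij} + u_{b(j)} + \varepsilon_j ,
$$

one observation per pair $j$. The intercept $\alpha$ is the mean within-pair
log2 fold change; $\mathrm{FC} = 2^\alpha$, with $\alpha>0$ read as
hypermethylation (or upregulation) in the affected twin. The $x_{ij}$ are
pair-level covariates; $u_b$ is a random intercept for the array batch
(twins of a pair are always hybridized on the same chip, so batch is a
pair-level grouping factor). `fit_pair_model()` estimates this by REML
(through lme4) and tests $\alpha = 0$ with a Wald $t$ on
$n_\text{pairs} - n_\text{fixed}$ degrees of freedom; when the batch-variance
estimate is zero, or fewer than three batches exist, it falls back to
ordinary least squares. With balanced batches the two intercept estimates
coincide, which the tests assert.

The genome-wide scan (`run_feature_scan()`) additionally pools the batch
variance across features, as limma's `duplicateCorrelation` does for array
duplicates: per-feature REML ratios hit the boundary at zero for a
sizeable share of features even when the batch effect is real, and a Wald
test at a boundary estimate ignores the true within-batch correlation —
in calibration runs those features rejected at ~14% instead of 5%. The
scan therefore reports the per-feature REML batch variance but computes
test statistics by GLS at the *consensus* ratio (median over features),
which is estimated from thousands of features and makes the per-feature
$t$ essentially exact. A consensus ratio of zero reduces to OLS.

Covariate coding: twin-varying covariates (BMI, smoking, alcohol use, income,
education, adverse-childhood-experience, PTSD and antidepressant indicators)
enter as within-pair differences, affected minus unaffected; pair-shared
covariates (age, sex) enter as the pair value. A ratio response pairs
naturally with difference-coded regressors; pair-shared covariates can still
matter because effect sizes may vary with, say, age. Pair-shared covariates
are mean-centered before fitting, so $\alpha$ is the mean log2 FC at the
cohort-average age and sex — uncentered they would make the intercept an
extrapolation (e.g. to age 0) with a badly inflated standard error.
Difference-coded covariates are deliberately *not* centered: when a
covariate differs systematically between affected and unaffected twins,
that shared component belongs to the covariate, not the intercept, which is
what makes sensitivity re-runs able to strip confounded associations. Methylation ratios use
a $10^{-6}$ floor on beta values (beta $=0$ is representable on the array);
expression ratios use $\log_2(\mathrm{TPM}+1)$, i.e. an offset of 1,
matching the scale of the gene filter. The degrees of freedom ignore the
uncertainty of the batch-variance estimate (no Satterthwaite correction); at
the batch counts used here the calibration tests show the nominal 5% level
is held within binomial tolerance.

## Region calling

Adjacent probes are spatially correlated, so inference is aggregated to
regions. Candidates are maximal same-chromosome runs of retained probes with
inter-probe gaps of at most 1,000 bp (the bandwidth scale of kernel-based
region callers); singletons are dropped. Each candidate gets:

* a **peak p** (minimum probe p; ties broken by larger $|\alpha|$, then
  position),
* a **region p** from an equal-weight signed Stouffer combination,
  $Z = \sum_i s_i z_i / \sqrt{k}$ with $z_i$ the two-sided probe z-score and
  $s_i$ the sign of the probe's $\alpha$ — this respects both effect
  direction and probe count,
* the mean pairwise Pearson correlation of beta values over all samples
  ("correlation among probes"; a minimum-pairwise variant is available via
  `corr_method = "min"`),
* mean FC $2^{\bar\alpha}$ and the mean / peak within-pair percent
  methylation differences.

A DMR requires at least 5 probes, peak p strictly below 0.01 and mean probe
correlation at least 0.30; significance is Benjamini–Hochberg q < 0.05 with
the full scored candidate count as the correction family (the family size is
data-dependent and logged per run). An exact mean-FC tie at 1 is broken to
"hyper" and flagged.

## Cis methylation–expression integration

For every probe within ±5 kb of a gene's TSS (strand-aware offsets, negative
= upstream), `cis_correlations()` computes the partial Pearson correlation
of beta with $\log_2(\mathrm{TPM}+1)$ after residualizing both on the
sample-level covariates. The significance threshold is empirical:
`permutation_threshold()` permutes the expression sample labels (not the
methylation ones — equivalent under exchangeability, and it keeps covariates
attached to the methylation samples), recomputes all cis-pair partial
correlations per permutation, pools them, and takes the
$(\alpha/2,\,1-\alpha/2)$ percentiles. The default is this symmetric
two-tail rule; `tail = "one"` selects the literal one-tail fifth-percentile
reading instead. For i.i.d. Gaussian data the upper threshold converges to
the analytic critical value $r^\* = t_{0.975}/\sqrt{t_{0.975}^2 + \nu}$,
$\nu = n-2-k$, which the acceptance suite verifies to ±0.02 at $B=500$.
Classified pairs are summarized by count, negative fraction and a TSS-offset
profile in 500 bp bins; `robustness_with_mdd()` re-runs the correlations
with the phenotype indicator appended and reports the fraction of
significant pairs that survive.

## Networks and differential connectivity

Nodes are features at nominal raw p < 0.001 (regions are represented by the
per-sample mean beta of their probes). Per twin group, the network is the
unsigned weighted adjacency $|r|^\beta$ with the soft power chosen as the
smallest integer in 1–12 reaching a scale-free fit $R^2 \ge 0.8$ (fallback
6), plus the topological overlap matrix (TOM) and binary degrees at an
adjacency cutoff of 0.1. Modules come from average-linkage clustering of
$1-\mathrm{TOM}$ with a **static cut at height 0.95**: TOM dissimilarities
compress toward 1 once the soft power exceeds ~2 (a fully connected 60-node
block at within-correlation 0.7 and power 6 sits near dissimilarity 0.88),
so a lower cut such as 0.75 dissolves genuine modules; 0.95 recovers planted
partitions while between-block dissimilarities stay at ≈ 1. Modules smaller
than 50 nodes are dissolved; each module's hub maximizes module membership
(mean within-module adjacency), ties broken by node order.

Differential connectivity between affected and unaffected groups uses the
mean binary degree difference of a node set. The null respects the twin
design: within each pair, the group labels of the two members are flipped
independently, both networks rebuilt, and the two-sided p is
$(1 + \#\{|T^\*| \ge |T|\})/(B+1)$. When networks are so sparse that
degrees are all zero the statistic is an atom at zero and p-values pile at 1
— valid but conservative; the calibration tests therefore run in a regime
where degrees vary (correlated nodes, power 1, cutoff 0.3).

## Enrichment, replication

`fisher_overlap()` tests whether differentially methylated genes are also
differentially expressed, on the background of genes present in both the
probe annotation and the retained expression set, reporting both the odds
ratio and the observed/expected fold (the two readings of "x times more
likely"). `casecontrol_scan()` replicates probes/genes in an unpaired
dataset by logistic regression with covariates; region-level calls use each
region's minimum probe p with BH over the number of regions (the discovery
family), and require a direction concordant with the discovery sign.

## The synthetic cohort generator

`sim_twin_study()` emulates the data structure the analysis assumes, with
ground-truth labels for every planted signal:

* **Cohort**: `n_pairs` pairs (default 79, the design scale), age
  U(18, 70) and sex (68.4% female) shared within pair, twin-varying
  covariates drawn per twin; pairs assigned to `n_batches` chips in
  contiguous blocks, both twins on one chip. Covariate distributions are
  conventions chosen for plausibility, not reconstructions of any cohort.
* **Methylation**: logit-scale generation guarantees valid betas. Per probe:
  a baseline from a low/mid/high mixture, a pair-shared biological effect
  (SD 0.5 logit), individual noise scaled so the within-pair log2-ratio
  residual SD equals `noise_sd` (default 0.2), and a within-pair treatment
  contrast $\pm\alpha/2$ combining the planted log2 FC, a per-probe batch
  intercept (`batch_sd`, default 0.1, on the ratio scale) and covariate
  effects. Ratio-scale quantities map to the logit scale by local
  linearization at the probe baseline, with the slope floored at baseline
  beta 0.8: beyond that the conversion diverges and symmetric logit noise
  would produce unbounded log2 ratios (the co-twin beta runs down the
  logit scale). Consequently, effects planted on high-methylation probes are
  realized compressed; planted probes are therefore given mid-range
  baselines, and the generator records each planted probe's realized mean
  ratio in the truth table. Planted blocks are adjacent manifest rows at the
  configured gap, sharing a per-sample block factor that yields the target
  within-block correlation; background probes are spaced ≥ 1.5 kb so they
  never co-cluster at the default region gap.
* **Expression**: log-normal TPM with planted within-pair fold changes, and
  cis couplings that add a scaled standardized copy of the coupled probe's
  beta to the gene's log-expression, reaching the target partial correlation;
  coupled genes get a TSS at the configured strand-aware offset from the
  probe. Uncoupled genes land near random probes so null cis pairs arise.
* One integer seed drives all stages through deterministic per-stage
  sub-streams; identical configurations are bit-identical.

What the generator does **not** emulate: raw array intensities, bisulfite
conversion, probe-type chemistry bias, cell-type mixtures, genotype effects
on methylation, count-level sequencing noise, or heavy-tailed/outlier
samples. Passing tests therefore demonstrate correctness of the estimators
and calling rules under the assumed generative structure, not robustness to
every artifact of real array/RNA-seq data.

## Numerical choices and problem sizes

p-values of zero are floored at 1e-300 before z-conversion; Stouffer uses
equal weights; zero-variance probes contribute correlation 0 with a warning;
partial correlations with (numerically) zero residual variance are reported
missing; permutation p-values are never below $1/(B+1)$. The validation
suite runs at the study's design scale where the quantity under test needs
it — 79 pairs with 2,000 probes for null calibration, 500 planted probes for
effect recovery, $n=158$ samples with 7 covariates and $B=500$ for the
permutation threshold, 50 node sets at $B_\text{perm}=200$ for connectivity
calibration — and at reduced scale elsewhere; each test states its own
sizes.

## Known limitations

Degrees of freedom for the intercept test are approximate under few batches;
the region-p combination assumes probe z-scores are well-calibrated (their
correlation is not modeled, so region p is anti-conservative for strongly
correlated probes — the q-value is used for ranking and the three explicit
criteria gate the calls); module detection is deterministic but the static
cut is cruder than dynamic hybrid cutting; and the replication scan assumes
an unpaired design with a correctly specified logistic model.
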