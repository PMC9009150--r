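---
title: "Methods: pan-cancer NET scoring and the NRG discovery cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer NET scoring and the NRG discovery cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neutrophil extracellular traps (NETs) — webs of decondensed chromatin and
granule proteins released by neutrophils — are implicated in tumor
progression, metastasis and immune evasion, but their prognostic meaning
differs between cancer types. `netscreen` implements a transcriptomic
work-flow that (i) quantifies NET activity per tumor sample from a 23-gene
signature, (ii) classifies cancer types by whether high NET activity
predicts longer or shorter survival, (iii) screens for NET-associated
regulatory genes (NRGs) whose expression tracks the NET score recurrently
and class-exclusively, (iv) nominates the key over-expressed NRG (the
SPP1-type candidate), and (v) quantifies the joint NET-by-gene effect on
survival and on an in-silico epithelial–mesenchymal-transition (EMT) score.

Because the real substrate of such a screen is a multi-cohort pan-cancer
download, the package ships a synthetic-data generator with planted ground
truth so that every stage is testable, end to end, on a desk machine.

## The NET score

The per-sample NET score is a single-sample enrichment statistic in the
gene set variation analysis style. For gene $i$ with expression $x_{ij}$
across $n$ samples, a Gaussian-kernel CDF estimate

$$\hat F_i(x_{ij}) = \frac{1}{n}\sum_{k=1}^{n}
  \Phi\!\left(\frac{x_{ij} - x_{ik}}{h_i}\right), \qquad h_i = s_i/4,$$

converts expression to a sample-relative quantile ($s_i$ is the gene's
sample standard deviation; constant genes are dropped with a warning since
the kernel is undefined at zero bandwidth). Within each sample, genes are
ranked by $\hat F$ (descending; ties broken by input row order for
determinism) and the symmetric rank statistic $z_{ij} = |p/2 - r_{ij}|$ is
formed, $p$ being the gene count. A random walk down the ranked list adds
$z^{\tau}$ (normalized by the set's total weight, $\tau = 1$) at signature
genes and subtracts $1/(p-m)$ elsewhere ($m$ = set size); the score is the
sum of the walk's largest positive and largest negative deviations (the
"max-diff" form), which is bounded in $[-1, 1]$ and invariant to per-gene
positive-affine transforms of the input. The kernel CDF is implemented in
C++ (it is the one $O(pn^2)$ step); the walk is plain R. Tests verify
bit-level agreement with a literal loop-by-loop R oracle on hundreds of
random instances.

Hallmark-style associations use the companion ssGSEA statistic
(rank-weight exponent $\alpha = 0.25$; optional division of the score
matrix by its range — both behaviors are exposed because published usage
varies), immune/stromal abundances use the marker-mean statistic (the
arithmetic mean of a population's marker genes), and NRG-set comparisons
use pre-ranked GSEA with a seeded gene-set permutation null
($\mathrm{NES} = \mathrm{ES}/\overline{|\mathrm{ES}_{null}|}$ over nulls
of matching sign). Phenotype-label permutation is not available to a
pre-ranked analysis, hence the gene-set scheme. When the walk's largest
positive and negative excursions tie exactly in magnitude, the first
extreme along the list is reported; the tie has probability zero for
continuous metrics.

Scoring is run separately within each cancer cohort (`net_scores_by_type`),
mirroring the per-cohort convention that avoids cross-cohort batch
structure; the pooled quantile Kaplan–Meier analysis is run on those
per-cohort scores.

## Survival-direction classification

Within each cancer type (at least 20 subjects with follow-up), samples are
split at the maximally selected log-rank cutpoint: every distinct score
value whose split leaves both groups within the 10–90% admissibility
window is evaluated and the maximizing threshold kept. The log-rank p at
the selected threshold is reported as-is but flagged `selection_biased`
(no minP adjustment — the work-flow this mirrors uses the unadjusted
value, and the planted-recovery tests account for the inflation). A type
is *favorable* when p < 0.05 and the high-score group has the larger
Kaplan–Meier median survival, *poor* when smaller, else *neutral*. An
undefined median (curve never reaching 0.5) counts as $+\infty$; if both
medians are undefined the Cox coefficient's sign decides. Direction is
taken from the KM curves rather than from the hazard ratio because the
two can be stated inconsistently when quoted together; the reported HR is
high-vs-low from a univariate Cox fit (Efron ties, Newton–Raphson via the
`survival` package, monotone likelihoods flagged `converged = FALSE`).

## The NRG cascade

1. **Pairs.** Per cancer type (≥ 10 tumors), each candidate gene
   (signature genes excluded — self-correlation) is Pearson-correlated
   with the NET score; pairs with $|R| > 0.35$ and $p < 0.05$ qualify.
   The hallmark screen uses a separate $|R| > 0.30$ threshold; the two
   cuts are distinct config fields on purpose.
2. **Recurrence.** Genes appearing in fewer than 5 cancer types of a
   survival class are dropped from that class ("5 or more" retained —
   the boundary reading). Neutral types count toward neither class.
   Class-only core sets (core minus the shared overlap) are reported and
   are, structurally, exact set differences.
3. **Exclusivity.** A gene is class-exclusive when its *positive*
   correlation recurs in more than 5 types of one class (≥ 6) and fewer
   than 2 of the other (≤ 1); negative pairs remain in the pair table but
   do not confer exclusivity (the criterion is stated for positive
   correlation, and a worked example with counts 7 and 1 fixes the strict
   reading).
4. **Nomination.** Poor-exclusive genes are ranked primarily by their
   over-expression in poor-class versus favorable-class tumors (Welch DE
   log2 fold change, pooled across types without batch adjustment — a
   documented limitation), with recurrence count and mean correlation as
   tie-breaks. Over-expression leads the ranking because it is the
   discriminating feature of the screen's end point: all class-exclusive
   NRGs share the same correlation structure by construction, so counts
   and mean r cannot separate the key gene from its co-planted
   neighbours, whereas the planted expression shift can. Welch's t
   replaces moderated-t DE deliberately: the consumers of this step use
   only sign and threshold, and Welch is assumption-light.
5. **Joint stratification.** NET score and the nominee are median-split
   (mean and optimal-cutpoint variants exposed), the four joint groups
   formed, and high/high is contrasted with low/low by univariate Cox.
   By default this runs within poor-classified types, where the nominee's
   coupling is defined; pooling all types would mix opposite-signed NET
   hazard effects and dilute an effect that is class-specific by design.

The EMT statistic is $\sum_{mes} z - \sum_{epi} z$ per sample (each gene
z-scored across samples; higher = more mesenchymal). The sum rather than
the mean is used — the two differ only by a scale that cancels in every
comparison the pipeline makes.

## The synthetic study and what it does (not) show

A single latent NET activity $a_s \sim N(0,1)$ per tumor drives
everything; this is the minimal structure the screen can see, because the
screen only uses pairwise correlations with the NET score. Defaults: 22
cancer types (6 favorable / 7 poor / 9 neutral, the counts of the named
types in the motivating analysis), 150 tumors and 20 para-tumor normals
per type, 2000 genes. Signature genes load on $a_s$ with $\lambda = 0.8$;
30 planted NRGs per class have population correlation 0.5 with $a_s$ in
their class's types only; the key gene adds a 1.2 log2-unit shift in
poor-type tumors; mesenchymal/epithelial programs (20 genes each — a
typical published program size) load $\pm 0.5$ on the standardized
product of $a_s$ and the z-scored key gene; normals sit 1.0 log2 units
below tumors on the signature. Survival is exponential with hazard
$h_0 e^{\gamma_c a_s}$, $h_0 = 10^{-3}$/day, $\gamma = +0.6$ (poor),
$-0.6$ (favorable), $0$ (neutral), censored uniformly on 200–2000 days
(roughly 60% events). Per-gene baselines are uniform on [4, 8] log2
units, i.e. moderately expressed genes.

What this does **not** emulate: count-level (negative-binomial) noise,
batch effects, correlated gene modules beyond the single factor,
non-proportional hazards, and informative censoring. Passing the planted
recovery tests therefore shows the cascade's logic and statistics are
implemented correctly at realistic effect sizes and sample counts — not
that the thresholds are optimal for any particular real cohort.

Test problem sizes were chosen so the whole suite runs comfortably on one
core: oracle comparisons use matrices up to 20 × 10; calibration loops
use 200–1000 replicates; end-to-end recovery uses 20 seeded runs of the
full default study.

## Numerical and degenerate-input choices

* All rankings break ties by input position (stable `order`), making every
  stage bit-reproducible under a fixed seed.
* Constant genes: dropped with a warning in GSVA; `p = 1, t = 0` in DE
  (logged, not an error); an error where a correlation is simply undefined.
* Quantile stratification uses type-7 quantiles; boundary ties fall to the
  lower group; all-equal scores collapse to group 1 with a warning.
* `read_expression` collapses duplicate gene rows by keeping the
  highest-mean row (the common probe-collapse convention); symbols are
  case-sensitive and never aliased.
* Expression is assumed log2-scale; `log2(x+1)` is applied on request for
  raw FPKM-like input. The linear "fold change > 2" cut is read as
  $|\mathrm{log2FC}| \ge 1$.
* The bundled 23-gene signature is a partial reconstruction assembled from
  NET-component genes named in the NET literature and is meant as a
  default, not a curated truth; real analyses should pass their own GMT.
* The treatment-response comparison defaults to a Mann–Whitney test
  (exact for small untied samples) — robust, and assumption-free about
  score distributions; a Welch alternative is a one-line swap. Whether
  stable disease belongs to the responder or non-responder group differs
  between published conventions, so the grouping is left to the caller's
  labels.

## Known limitations

* The selection-biased cutpoint p inflates the neutral-to-directional
  misclassification rate on null data; with the defaults the neutral
  recovery rate stays above 80% empirically, and the planted-direction
  criteria are evaluated only on directional types.
* The pooled quantile Kaplan–Meier analysis is close to null on the
  default synthetic study *by design*: the favorable ($-0.6$) and poor
  ($+0.6$) hazard signs nearly cancel when all types are pooled. The
  pooled view is informative only when one direction dominates the
  cohort mix.
* Pooled class DE carries cancer-type composition as a confounder; in the
  synthetic design that confounding is absent by construction, in real
  data it is not.
* Pair counting can be done per gene or per (gene, cancer type); both
  tallies are emitted (`summary` counts types per gene; `core_pairs` holds
  the pair-level table) since published figures mix the two conventions.
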