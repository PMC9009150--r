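# netscreen

Pan-cancer analysis of neutrophil extracellular trap (NET) activity from
bulk transcriptomes. NETs — chromatin webs expelled by neutrophils — can
promote or restrain tumor progression depending on context, and their
prognostic direction differs between cancer types. `netscreen` implements
the full screening work-flow as a tested R package plus numbered analysis
drivers:

1. **NET score** — a GSVA-style single-sample enrichment score of a
   23-gene NET signature: per-gene Gaussian-kernel CDF
   $\hat F_i(x) = n^{-1}\sum_k \Phi((x - x_{ik})/h_i)$ with $h_i = s_i/4$,
   per-sample ranking, and a weighted Kolmogorov–Smirnov random walk whose
   signed max-diff statistic is the score (bounded in $[-1,1]$).
2. **Survival-direction classification** — per cancer type, a maximally
   selected log-rank cutpoint splits high vs low NET score; log-rank
   p < 0.05 plus the Kaplan–Meier median direction assigns
   *favorable* / *poor* / *neutral*, with a univariate Cox hazard ratio
   (Efron ties) reported per type.
3. **NRG screen** — per cancer type, genes with Pearson $|R| > 0.35$ and
   p < 0.05 against the NET score are NET-associated regulatory genes;
   recurrence filtering (≥ 5 types per survival class) defines core genes,
   and class exclusivity (positive correlation in ≥ 6 types of one class,
   ≤ 1 of the other) shortlists candidates.
4. **Key-gene nomination** — poor-exclusive genes ranked by their
   over-expression in poor-class vs favorable-class tumors (Welch DE);
   the top gene is the SPP1-type nominee.
5. **Joint stratification & EMT** — median splits of NET score × nominee
   give four groups; high/high vs low/low is contrasted by Cox HR, and an
   in-silico EMT score ($\sum z_{mes} - \sum z_{epi}$) is compared between
   the extremes.

Everything runs on a bundled synthetic pan-cancer generator (22 cancer
types, 150 tumors + 20 normals each, 2000 genes) with planted ground
truth: a latent per-sample NET activity, class-specific planted NRGs, an
over-expressed key gene, coupled EMT programs, and cancer-type-specific
survival hazards. Real data can be supplied as tab-separated
expression/clinical tables and GMT gene sets via `read_expression()`,
`read_clinical()`, `read_gmt()`.

## Worked example

```r
library(netscreen)

d <- synth_generate(synth_config(seed = 1))        # 2000 x 3740 study
b <- run_pipeline(d$expr, d$clinical, d$sets, analysis_config(seed = 1))

table(b$classes$class)
#> favorable   neutral      poor
#>         9         6         7
b$nominee
#> [1] "SPP1"
b$combined$cox$hr; b$combined$cox$p
#> [1] 3.013058     # high/high vs low/low hazard ratio in poor-class types
#> [1] 4.082218e-27
cor(b$net_scores[names(d$truth$activity)], d$truth$activity)
#> [1] 0.9563023    # NET score tracks the planted latent activity
```

All 6 planted favorable and all 7 planted poor types are classified
correctly at this seed (three neutral types drift to "favorable" — the
expected cost of the selection-biased cutpoint p, discussed in the
vignette); the screen shortlists the planted poor-class NRGs, nominates
the planted key gene, and the joint high/high group carries a ~3× hazard.
Numbers are from seed 1; other seeds vary within the tested bands.

The same steps, narrated and writing result tables, live in `analysis/`:

```sh
Rscript analysis/01_simulate.R        # synthetic study -> scratch/, results/
Rscript analysis/02_net_scores.R
Rscript analysis/03_survival_classes.R
Rscript analysis/04_nrg_screen.R
Rscript analysis/05_combined_stratification.R
```

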