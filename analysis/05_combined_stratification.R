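#!/usr/bin/env Rscript
# Step 5: joint effect of NET score and the nominated key gene. Median
# dichotomies of both features in poor-class cancer types give four joint
# groups; high/high is contrasted against low/low with a univariate Cox
# model, and the in-silico EMT score is compared between those extremes.

suppressPackageStartupMessages(library(netscreen))

d <- readRDS("scratch/synthetic_study.rds")
scores <- readRDS("scratch/net_scores.rds")
classes <- readRDS("scratch/survival_classes.rds")
nrg <- readRDS("scratch/nrg_screen.rds")
key <- nrg$nominees$gene[1]

poor_types <- classes$cancer_type[classes$class == "poor"]
cl_poor <- d$clinical[d$clinical$cancer_type %in% poor_types, ]
res <- combined_stratification(scores, d$expr[key, ], cl_poor,
                               cutoff = "median")
message(sprintf(
  "NETs/%s high-high vs low-low in poor-class types: HR = %.2f, p = %.2e (4-group log-rank p = %.2e)",
  key, res$cox$hr, res$cox$p, res$logrank$p))
write.table(
  data.frame(sample = names(res$groups), joint_group = unname(res$groups)),
  "results/05_joint_groups.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

# EMT contrast between the joint extremes
tum <- intersect(cl_poor$sample[cl_poor$tissue == "tumor"], names(scores))
emt <- emt_score(d$expr[, tum], d$truth$epithelial, d$truth$mesenchymal)
grp <- res$groups[tum]
sel <- grp %in% c("high/high", "low/low")
cmp <- group_compare(emt[sel], grp[sel])
message(sprintf(
  "EMT score, high/high vs low/low: median diff = %.2f, Mann-Whitney p = %.2e",
  cmp$median_a - cmp$median_b, cmp$p))
emt_tab <- data.frame(sample = tum, emt = unname(emt),
                      joint_group = unname(grp))
write.table(emt_tab, "results/05_emt_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
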