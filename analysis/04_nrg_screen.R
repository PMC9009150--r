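#!/usr/bin/env Rscript
# Step 4: the NRG discovery cascade. Per-cancer correlation pairs against
# the NET score, recurrence (core) filtering, class-exclusivity shortlist,
# differential expression between the survival classes, key-gene nomination,
# pre-ranked enrichment of the class-only core sets, and the pan-cancer
# mean-cutoff HR sweep over the shortlisted genes.

suppressPackageStartupMessages(library(netscreen))

d <- readRDS("scratch/synthetic_study.rds")
scores <- readRDS("scratch/net_scores.rds")
classes <- readRDS("scratch/survival_classes.rds")
cfg <- analysis_config(seed = 1L)

pairs <- suppressWarnings(
  nrg_pairs(scores, d$expr, d$clinical, cfg,
            exclude_genes = d$sets$NET_SIGNATURE))
screen <- recurrence_filter(pairs, classes, cfg)
shortlist <- exclusivity_filter(screen$summary, cfg)
write.table(pairs, "results/04_nrg_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(screen$summary, "results/04_screen_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cg <- screen$core_genes
message(sprintf(
  "%d qualifying NET-NRG pairs; core genes: %d favorable / %d poor (%d shared, %d fav-only, %d poor-only)",
  nrow(pairs), length(cg$favorable), length(cg$poor), length(cg$shared),
  length(cg$fav_only), length(cg$poor_only)))
message(sprintf("class-exclusive shortlists: %d poor, %d favorable",
                length(shortlist$poor), length(shortlist$favorable)))

de <- class_de(d$expr, d$clinical, classes,
               union(shortlist$poor, shortlist$favorable))
nominees <- nominate_key_gene(shortlist$poor, de, pairs, classes)
write.table(nominees, "results/04_nominees.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf(
  "nominated key gene: %s (planted: %s) with class log2FC = %.2f",
  nominees$gene[1], d$truth$key_gene, nominees$logfc[1]))

# enrichment of the class-only core sets in the all-gene class DE ranking
de_all <- class_de(d$expr, d$clinical, classes, unique(pairs$gene))
metric <- setNames(de_all$logfc, de_all$gene)
for (side in c("poor_only", "fav_only")) {
  gs <- intersect(cg[[side]], names(metric))
  if (length(gs) >= 2 && length(gs) < length(metric)) {
    g <- preranked_gsea(metric, gs, n_perm = cfg$perm_count, seed = cfg$seed)
    message(sprintf("%s core set: NES = %.2f, permutation p = %.3f",
                    side, g$nes, g$p))
  }
}

# pan-cancer mean-cutoff hazard sweep over the shortlisted genes
sweep <- suppressWarnings(pan_cancer_hr_sweep(
  d$expr, d$clinical, union(shortlist$poor, shortlist$favorable), cfg$p_sig))
write.table(sweep$fits, "results/04_hr_sweep.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("HR sweep: %d fits, %d significant (%d risk / %d protective)",
                sweep$summary$n_fit, sweep$summary$n_sig,
                sweep$summary$n_sig_risk, sweep$summary$n_sig_protective))
saveRDS(list(pairs = pairs, screen = screen, shortlist = shortlist,
             nominees = nominees), "scratch/nrg_screen.rds")
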