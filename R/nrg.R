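#' Per-cancer NET-score / gene correlation pairs
#'
#' The screen's first stage: within each cancer type (tumor samples only,
#' >= 10 required, smaller types skipped with a warning), every candidate
#' gene is correlated with the per-sample NET score; pairs with
#' `|r| > r_nrg` and `p < p_sig` are retained as NET-associated regulatory
#' gene (NRG) pairs. Signature genes must be excluded from the candidates
#' (self-correlation artifact).
#'
#' @param net_scores named per-sample NET scores.
#' @param expr expression matrix.
#' @param clinical clinical data.frame (`sample`, `cancer_type`, `tissue`).
#' @param cfg configuration from [analysis_config()].
#' @param exclude_genes genes removed from the candidate list (typically the
#'   NET signature).
#' @return data.frame with `cancer_type`, `gene`, `r`, `p`, `sign`
#'   (`"+"`/`"-"`), one row per retained pair.
#' @export
nrg_pairs <- function(net_scores, expr, clinical, cfg = analysis_config(),
                      exclude_genes = character()) {
  check_expression_matrix(expr)
  clinical <- check_clinical(clinical)
  cand <- setdiff(rownames(expr), exclude_genes)
  rows <- list()
  for (ct in unique(clinical$cancer_type)) {
    ids <- clinical$sample[clinical$cancer_type == ct &
                             clinical$tissue == "tumor"]
    ids <- intersect(ids, intersect(colnames(expr), names(net_scores)))
    if (length(ids) < 10L) {
      warning("cancer type '", ct, "' skipped in NRG screen: <10 samples")
      next
    }
    sc <- net_scores[ids]
    if (sd(sc) == 0) {
      warning("cancer type '", ct, "' skipped: constant NET score")
      next
    }
    sub <- expr[cand, ids, drop = FALSE]
    sds <- apply(sub, 1L, sd)
    n <- length(ids)
    r <- rep(NA_real_, length(cand))
    ok <- sds > 0
    r[ok] <- as.numeric(cor(t(sub[ok, , drop = FALSE]), sc))
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p[abs(r) >= 1] <- 0
    keep <- which(ok & abs(r) > cfg$r_nrg & p < cfg$p_sig)
    if (length(keep))
      rows[[ct]] <- data.frame(cancer_type = ct, gene = cand[keep],
                               r = r[keep], p = p[keep],
                               sign = ifelse(r[keep] > 0, "+", "-"),
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cancer_type = character(), gene = character(),
                      r = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Recurrence filter and per-gene screen summary
#'
#' Counts, per gene and survival class, the cancer types contributing a
#' qualifying NRG pair (neutral types contribute to neither class). A gene
#' is "core" for a class when its count there reaches `recurrence_min`
#' (default 5, i.e. genes appearing in fewer than 5 types are dropped).
#' Positive-sign-only counts are tracked separately for the exclusivity
#' stage. Core pairs are the retained (cancer type, gene) rows whose type's
#' class has the gene core.
#'
#' @param pairs data.frame from [nrg_pairs()].
#' @param classes data.frame with `cancer_type` and `class`
#'   (favorable/poor/neutral), e.g. from [classify_net_survival()].
#' @param cfg configuration.
#' @return list with `summary` (per-gene counts, core flags, class-only
#'   core-set membership), `core_pairs` (filtered pair table),
#'   `core_genes` (list: `favorable`, `poor`, `shared`, `fav_only`,
#'   `poor_only`).
#' @export
recurrence_filter <- function(pairs, classes, cfg = analysis_config()) {
  miss <- setdiff(unique(pairs$cancer_type), classes$cancer_type)
  if (length(miss)) stop("no survival class for cancer type(s): ",
                         paste(miss, collapse = ", "))
  cls <- setNames(classes$class, classes$cancer_type)
  pairs$class <- unname(cls[pairs$cancer_type])
  genes <- unique(pairs$gene)
  cnt <- function(sub) {
    tab <- table(sub$gene[!duplicated(paste(sub$gene, sub$cancer_type))])
    out <- setNames(integer(length(genes)), genes)
    out[names(tab)] <- as.integer(tab)
    out
  }
  count_fav <- cnt(pairs[pairs$class == "favorable", , drop = FALSE])
  count_poor <- cnt(pairs[pairs$class == "poor", , drop = FALSE])
  pos <- pairs[pairs$sign == "+", , drop = FALSE]
  pos_fav <- cnt(pos[pos$class == "favorable", , drop = FALSE])
  pos_poor <- cnt(pos[pos$class == "poor", , drop = FALSE])
  summary <- data.frame(
    gene = genes,
    count_fav = unname(count_fav), count_poor = unname(count_poor),
    pos_fav = unname(pos_fav), pos_poor = unname(pos_poor),
    core_fav = unname(count_fav >= cfg$recurrence_min),
    core_poor = unname(count_poor >= cfg$recurrence_min),
    stringsAsFactors = FALSE)
  core_fav_genes <- summary$gene[summary$core_fav]
  core_poor_genes <- summary$gene[summary$core_poor]
  core_pairs <- pairs[
    (pairs$class == "favorable" & pairs$gene %in% core_fav_genes) |
      (pairs$class == "poor" & pairs$gene %in% core_poor_genes), ,
    drop = FALSE]
  rownames(core_pairs) <- NULL
  list(
    summary = summary,
    core_pairs = core_pairs,
    core_genes = list(
      favorable = core_fav_genes,
      poor = core_poor_genes,
      shared = intersect(core_fav_genes, core_poor_genes),
      fav_only = setdiff(core_fav_genes, core_poor_genes),
      poor_only = setdiff(core_poor_genes, core_fav_genes)
    )
  )
}

#' Class-exclusivity filter
#'
#' Shortlists genes whose positive NET correlation recurs in more than 5
#' cancer types of one survival class (`pos >= exclusive_in_min`, default 6)
#' while appearing in fewer than 2 types of the other class
#' (`pos <= exclusive_out_max`, default 1). Only positive-sign pairs count
#' here; negative pairs stay in the pair table but do not confer
#' exclusivity.
#'
#' @param summary per-gene summary from [recurrence_filter()].
#' @param cfg configuration.
#' @return list with character vectors `poor` and `favorable` (the
#'   class-exclusive shortlists).
#' @export
exclusivity_filter <- function(summary, cfg = analysis_config()) {
  poor <- summary$gene[summary$pos_poor >= cfg$exclusive_in_min &
                         summary$pos_fav <= cfg$exclusive_out_max]
  fav <- summary$gene[summary$pos_fav >= cfg$exclusive_in_min &
                        summary$pos_poor <= cfg$exclusive_out_max]
  list(poor = poor, favorable = fav)
}

#' Differential expression between survival classes
#'
#' Welch differential expression of pooled poor-class tumor samples versus
#' pooled favorable-class tumor samples, restricted to a gene shortlist
#' (no batch adjustment across cancer types; a documented limitation).
#'
#' @param expr expression matrix.
#' @param clinical clinical data.frame.
#' @param classes per-cancer-type survival classes.
#' @param genes gene shortlist; empty gives an empty result with a warning.
#' @return data.frame as from [de_test()] (poor minus favorable logfc).
#' @export
class_de <- function(expr, clinical, classes, genes) {
  if (length(genes) == 0L) {
    warning("empty shortlist; no class differential expression computed")
    return(data.frame(gene = character(), logfc = numeric(), t = numeric(),
                      p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  }
  clinical <- check_clinical(clinical)
  cls <- setNames(classes$class, classes$cancer_type)
  tum <- clinical[clinical$tissue == "tumor" &
                    clinical$sample %in% colnames(expr), , drop = FALSE]
  poor_ids <- tum$sample[cls[tum$cancer_type] %in% "poor"]
  fav_ids <- tum$sample[cls[tum$cancer_type] %in% "favorable"]
  if (length(poor_ids) < 2L || length(fav_ids) < 2L) {
    warning("a survival class has fewer than 2 tumor samples; ",
            "no class differential expression computed")
    return(data.frame(gene = character(), logfc = numeric(), t = numeric(),
                      p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  }
  genes <- intersect(genes, rownames(expr))
  de_test(expr[genes, , drop = FALSE], poor_ids, fav_ids)
}

#' Nominate the key NET-associated gene
#'
#' Ranks the poor-exclusive shortlist the way the screen's end point is
#' defined: primarily by over-expression in poor-class versus
#' favorable-class tumors (class DE log2 fold change, descending), breaking
#' ties by the number of poor-class cancer types with a positive qualifying
#' pair and then by the mean correlation across those types. The top-ranked
#' gene is the nominee (the SPP1-type candidate).
#'
#' @param shortlist character vector of poor-exclusive genes.
#' @param de class DE table from [class_de()].
#' @param pairs pair table from [nrg_pairs()] (used for mean r).
#' @param classes per-cancer-type survival classes.
#' @return data.frame ranked best-first: `gene`, `logfc`, `p_adj`,
#'   `count_poor`, `mean_r_poor`. Errors on an empty shortlist.
#' @export
nominate_key_gene <- function(shortlist, de, pairs, classes) {
  if (length(shortlist) == 0L)
    stop("empty poor-exclusive shortlist: no gene recurs in >= ",
         "the required number of poor-class cancer types (",
         nrow(de), " genes had class DE results; ",
         length(unique(pairs$gene)), " genes had any qualifying pair)")
  cls <- setNames(classes$class, classes$cancer_type)
  pp <- pairs[pairs$gene %in% shortlist & pairs$sign == "+" &
                cls[pairs$cancer_type] %in% "poor", , drop = FALSE]
  agg_n <- tapply(pp$cancer_type, pp$gene, function(x) length(unique(x)))
  agg_r <- tapply(pp$r, pp$gene, mean)
  dei <- de[match(shortlist, de$gene), , drop = FALSE]
  tab <- data.frame(
    gene = shortlist,
    logfc = dei$logfc,
    p_adj = dei$p_adj,
    count_poor = as.integer(agg_n[shortlist]),
    mean_r_poor = as.numeric(agg_r[shortlist]),
    stringsAsFactors = FALSE)
  tab$count_poor[is.na(tab$count_poor)] <- 0L
  tab$logfc[is.na(tab$logfc)] <- -Inf
  o <- order(-tab$logfc, -tab$count_poor, -tab$mean_r_poor, tab$gene)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Pan-cancer hazard-ratio sweep over a gene list
#'
#' For each gene, pooled samples are dichotomized at the gene's mean
#' expression and a univariate Cox model is fitted on the high-expression
#' indicator. Degenerate dichotomies (one side empty) are skipped with a
#' warning.
#'
#' @param expr expression matrix.
#' @param clinical clinical data.frame with survival.
#' @param genes genes to sweep.
#' @param p_sig significance level for the summary counts.
#' @return list with `fits` (data.frame: `gene`, `hr`, `p`, `converged`)
#'   and `summary` (`n_fit`, `n_sig`, `n_sig_risk` HR > 1, `n_sig_protective`).
#' @export
pan_cancer_hr_sweep <- function(expr, clinical, genes, p_sig = 0.05) {
  clinical <- check_clinical(clinical)
  surv <- clinical[clinical$tissue == "tumor" & !is.na(clinical$time) &
                     !is.na(clinical$event) & clinical$time > 0 &
                     clinical$sample %in% colnames(expr), , drop = FALSE]
  if (nrow(surv) < 2L || sum(surv$event) < 1L)
    stop("no pooled survival data available")
  rows <- list()
  for (g in intersect(genes, rownames(expr))) {
    x <- expr[g, surv$sample]
    ind <- as.numeric(x > mean(x))
    if (length(unique(ind)) < 2L) {
      warning("gene '", g, "' skipped: degenerate mean dichotomy")
      next
    }
    cx <- cox_univariate(surv$time, surv$event, ind)
    rows[[g]] <- data.frame(gene = g, hr = cx$hr, p = cx$p,
                            converged = cx$converged,
                            stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, rows)
  if (is.null(fits))
    fits <- data.frame(gene = character(), hr = numeric(), p = numeric(),
                       converged = logical(), stringsAsFactors = FALSE)
  rownames(fits) <- NULL
  okf <- fits[fits$converged, , drop = FALSE]
  sig <- okf[okf$p < p_sig, , drop = FALSE]
  list(fits = fits,
       summary = list(n_fit = nrow(fits), n_sig = nrow(sig),
                      n_sig_risk = sum(sig$hr > 1),
                      n_sig_protective = sum(sig$hr < 1)))
}

#' Combined NET-score-by-gene survival stratification
#'
#' Dichotomizes the NET score and a gene's expression (median, mean, or
#' maximally selected cutoff), forms the four joint groups, and contrasts
#' high/high against low/low with a univariate Cox model (the mixed groups
#' are excluded from that contrast); also reports the 4-group log-rank test.
#' Any empty joint group is an error naming the group.
#'
#' @param net_scores named per-sample NET scores.
#' @param gene_expr named per-sample expression of the gene.
#' @param clinical clinical data.frame with survival for these samples.
#' @param cutoff `"median"` (default), `"mean"`, or `"optimal"`.
#' @param quantile_range admissibility window when `cutoff = "optimal"`.
#' @return list with `groups` (per-sample joint label), `cox`
#'   (high/high vs low/low [cox_univariate()] fit), `logrank`
#'   (4-group chi-square and p), `cutoffs`.
#' @export
combined_stratification <- function(net_scores, gene_expr, clinical,
                                    cutoff = c("median", "mean", "optimal"),
                                    quantile_range = c(0.10, 0.90)) {
  cutoff <- match.arg(cutoff)
  clinical <- check_clinical(clinical)
  surv <- clinical[clinical$tissue == "tumor" & !is.na(clinical$time) &
                     !is.na(clinical$event) & clinical$time > 0, , drop = FALSE]
  ids <- intersect(surv$sample, intersect(names(net_scores), names(gene_expr)))
  if (length(ids) < 4L) stop("too few samples with survival for stratification")
  surv <- surv[match(ids, surv$sample), , drop = FALSE]
  ns <- net_scores[ids]; gx <- gene_expr[ids]
  if (sd(ns) == 0 || sd(gx) == 0) stop("both features must be non-constant")
  cut_of <- function(v) switch(cutoff,
    median = median(v),
    mean = mean(v),
    optimal = optimal_cutpoint(v, surv$time, surv$event,
                               quantile_range = quantile_range)$threshold)
  c_net <- cut_of(ns); c_gene <- cut_of(gx)
  lab <- paste0(ifelse(ns > c_net, "high", "low"), "/",
                ifelse(gx > c_gene, "high", "low"))
  want <- c("high/high", "high/low", "low/high", "low/low")
  missing_groups <- setdiff(want, unique(lab))
  if (length(missing_groups))
    stop("empty joint group(s): ", paste(missing_groups, collapse = ", "))
  contrast <- lab %in% c("high/high", "low/low")
  cx <- cox_univariate(surv$time[contrast], surv$event[contrast],
                       as.numeric(lab[contrast] == "high/high"))
  sd4 <- survdiff(Surv(surv$time, surv$event) ~ lab)
  chisq <- unname(sd4$chisq)
  list(groups = setNames(lab, ids), cox = cx,
       logrank = list(chisq = chisq,
                      p = pchisq(chisq, df = 3, lower.tail = FALSE)),
       cutoffs = c(net = c_net, gene = c_gene))
}

#' Per-cancer NET scores from a signature
#'
#' GSVA scoring of one signature set run separately within each cancer type
#' (tumor and normal samples of the type together), mirroring the
#' per-cohort analysis convention that avoids cross-cohort batch structure.
#'
#' @param expr expression matrix. @param clinical clinical data.frame.
#' @param signature character vector of signature genes.
#' @return named numeric vector of per-sample NET scores.
#' @export
net_scores_by_type <- function(expr, clinical, signature) {
  clinical <- check_clinical(clinical)
  out <- numeric(0)
  for (ct in unique(clinical$cancer_type)) {
    ids <- intersect(clinical$sample[clinical$cancer_type == ct],
                     colnames(expr))
    if (length(ids) < 3L) {
      warning("cancer type '", ct, "' skipped in scoring: <3 samples")
      next
    }
    sc <- gsva_scores(expr[, ids, drop = FALSE],
                      list(NET = signature))
    out <- c(out, setNames(as.numeric(sc[1L, ]), colnames(sc)))
  }
  if (length(out) == 0L) stop("no cancer type could be scored")
  out
}

#' Run the full NET screen pipeline
#'
#' Orchestrates the whole cascade on aligned inputs: per-cancer NET scoring
#' of the signature, pan-cancer quantile stratification, survival-direction
#' classification of cancer types, the per-cancer NRG pair screen,
#' recurrence and exclusivity filtering, class differential expression,
#' key-gene nomination, an enrichment comparison of the class-only core
#' gene sets against the class DE ranking, and combined NET-by-nominee
#' stratification (by default within poor-class cancer types, where the
#' nominee's effect is defined).
#'
#' @param expr expression matrix.
#' @param clinical clinical data.frame.
#' @param sets gene-set collection; must contain `signature_name`.
#' @param cfg configuration from [analysis_config()].
#' @param signature_name name of the NET signature set (default
#'   `"NET_SIGNATURE"`).
#' @param strat_scope samples used for the combined stratification:
#'   `"poor"` (default) or `"all"`.
#' @param out_dir optional directory; when given, every intermediate table
#'   is written there as tab-separated text.
#' @return list bundle: `net_scores`, `quantile_groups`, `pan_logrank`,
#'   `classes`, `pairs`, `screen` (summary/core), `shortlist`, `class_de`,
#'   `nominees` (ranked table), `nominee`, `gsea`, `combined`, `config`.
#' @export
run_pipeline <- function(expr, clinical, sets, cfg = analysis_config(),
                         signature_name = "NET_SIGNATURE",
                         strat_scope = c("poor", "all"),
                         out_dir = NULL) {
  strat_scope <- match.arg(strat_scope)
  check_gene_sets(sets)
  if (!signature_name %in% names(sets))
    stop("signature set '", signature_name, "' not in the collection")
  al <- align_samples(expr, clinical)
  expr <- al$expr; clinical <- al$clinical
  signature <- sets[[signature_name]]

  scores <- net_scores_by_type(expr, clinical, signature)

  # pan-cancer quantile stratification of tumor scores
  tum_ids <- intersect(names(scores),
                       clinical$sample[clinical$tissue == "tumor" &
                                         !is.na(clinical$time) &
                                         !is.na(clinical$event) &
                                         clinical$time > 0])
  qg <- quantile_stratify(scores[tum_ids], k = cfg$n_quantile_groups)
  cl_t <- clinical[match(tum_ids, clinical$sample), , drop = FALSE]
  sdq <- survdiff(Surv(cl_t$time, cl_t$event) ~ qg)
  pan_logrank <- list(chisq = unname(sdq$chisq),
                      p = pchisq(unname(sdq$chisq),
                                 df = cfg$n_quantile_groups - 1,
                                 lower.tail = FALSE))

  classes <- classify_net_survival(scores, clinical, cfg)
  pairs <- nrg_pairs(scores, expr, clinical, cfg, exclude_genes = signature)
  screen <- recurrence_filter(pairs, classes, cfg)
  shortlist <- exclusivity_filter(screen$summary, cfg)

  de <- class_de(expr, clinical, classes,
                 union(shortlist$poor, shortlist$favorable))
  nominees <- if (length(shortlist$poor)) {
    nominate_key_gene(shortlist$poor, de, pairs, classes)
  } else {
    warning("empty poor-exclusive shortlist; no key gene nominated")
    NULL
  }
  nominee <- if (!is.null(nominees)) nominees$gene[1L] else NA_character_

  # enrichment of the class-only core sets in the class DE ranking
  gsea <- NULL
  de_all <- class_de(expr, clinical, classes,
                     unique(pairs$gene))
  if (nrow(de_all) > 1L) {
    metric <- setNames(de_all$logfc, de_all$gene)
    gsea <- list()
    for (side in c("poor_only", "fav_only")) {
      gs <- intersect(screen$core_genes[[side]], names(metric))
      if (length(gs) >= 2L && length(gs) < length(metric))
        gsea[[side]] <- preranked_gsea(metric, gs,
                                       n_perm = cfg$perm_count,
                                       seed = cfg$seed)
    }
  }

  combined <- NULL
  if (!is.na(nominee)) {
    scope_cl <- clinical
    if (strat_scope == "poor") {
      poor_types <- classes$cancer_type[classes$class == "poor"]
      scope_cl <- clinical[clinical$cancer_type %in% poor_types, , drop = FALSE]
    }
    if (nrow(scope_cl) >= 4L)
      combined <- tryCatch(
        combined_stratification(scores, expr[nominee, ], scope_cl,
                                cutoff = "median"),
        error = function(e) {
          warning("combined stratification failed: ", conditionMessage(e))
          NULL
        })
  }

  bundle <- list(net_scores = scores, quantile_groups = qg,
                 pan_logrank = pan_logrank, classes = classes, pairs = pairs,
                 screen = screen, shortlist = shortlist, class_de = de,
                 nominees = nominees, nominee = nominee, gsea = gsea,
                 combined = combined, config = cfg)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a pipeline result bundle as tab-separated tables
#' @param bundle result of [run_pipeline()].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(df, file) {
    write.table(df, file.path(out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(data.frame(sample = names(bundle$net_scores),
                net_score = as.numeric(bundle$net_scores),
                stringsAsFactors = FALSE), "net_scores.tsv")
  wt(bundle$classes, "survival_class.tsv")
  wt(bundle$pairs, "nrg_pairs.tsv")
  wt(bundle$screen$summary, "screen_summary.tsv")
  wt(data.frame(class = c(rep("poor", length(bundle$shortlist$poor)),
                          rep("favorable", length(bundle$shortlist$favorable))),
                gene = c(bundle$shortlist$poor, bundle$shortlist$favorable),
                stringsAsFactors = FALSE), "shortlist.tsv")
  if (!is.null(bundle$nominees)) wt(bundle$nominees, "nominee.tsv")
  if (!is.null(bundle$class_de) && nrow(bundle$class_de))
    wt(bundle$class_de, "class_de.tsv")
  invisible(out_dir)
}
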