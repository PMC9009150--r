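#' Pearson correlation with a two-sided t-test p-value
#'
#' Product-moment correlation; p two-sided from
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2} df. `|r| = 1` returns
#' `p = 0`. Constant input is an error (r undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = sign(r), p = 0, n = n))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Per-gene two-group differential expression (Welch t)
#'
#' Welch two-sample t-test per gene between two sample groups on log2-scale
#' expression, with Welch--Satterthwaite degrees of freedom and
#' Benjamini--Hochberg adjustment across all tested genes. The log fold
#' change is `mean(group_a) - mean(group_b)` in the log2 domain, so the
#' conventional "fold change > 2" significance cut corresponds to
#' `|logfc| >= 1`. Genes constant in both groups get `t = 0, p = 1`
#' (reported, not an error).
#'
#' @param expr expression matrix.
#' @param group_a,group_b character vectors of sample ids (>= 2 each,
#'   disjoint).
#' @return data.frame with columns `gene`, `logfc`, `t`, `p`, `p_adj`.
#' @export
de_test <- function(expr, group_a, group_b) {
  if (!is.matrix(expr) || !is.numeric(expr) || is.null(rownames(expr)) ||
      is.null(colnames(expr)) || anyDuplicated(rownames(expr)) ||
      anyDuplicated(colnames(expr)) || !all(is.finite(expr)))
    stop("expr must be a finite numeric matrix with unique dimnames")
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss)) stop("unknown sample id(s): ", paste(head(miss, 3), collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need at least 2 samples per group")
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, var); vb <- apply(b, 1L, var)
  logfc <- ma - mb
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, logfc / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               1)
  p <- ifelse(se2 > 0, 2 * pt(-abs(tstat), df = df), 1)
  # degenerate genes (constant in both groups): flat, uninformative
  data.frame(gene = rownames(expr), logfc = logfc, t = tstat, p = p,
             p_adj = bh_adjust(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini--Hochberg false-discovery-rate adjustment
#'
#' Step-up BH via [stats::p.adjust()], with input validation.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Quantile stratification of per-sample scores
#'
#' Splits samples into `k` groups at the `j/k` empirical quantiles (type-7
#' interpolation). Group 1 holds the lowest scores; a score tied with a cut
#' boundary goes to the lower group. All-equal input collapses to group 1
#' with a warning.
#'
#' @param scores named numeric vector of per-sample scores.
#' @param k number of groups (default 4).
#' @return integer vector of group labels `1..k`, named like `scores`.
#' @export
quantile_stratify <- function(scores, k = 4L) {
  if (k < 2L) stop("k must be at least 2")
  if (length(scores) < k) stop("need at least k samples")
  cuts <- quantile(scores, probs = seq_len(k - 1) / k, type = 7, names = FALSE)
  if (length(unique(scores)) == 1L) {
    warning("all scores equal; every sample assigned to group 1")
    return(setNames(rep(1L, length(scores)), names(scores)))
  }
  # ties at a boundary fall into the lower group
  g <- 1L + vapply(scores, function(s) sum(s > cuts), integer(1))
  setNames(as.integer(g), names(scores))
}

#' In-silico EMT score
#'
#' Per-sample epithelial--mesenchymal-transition statistic: each matched gene
#' is z-scored across samples, and the score is the summed mesenchymal
#' z-scores minus the summed epithelial z-scores, so higher means more
#' mesenchymal. Invariant to per-gene positive-affine transforms of the
#' expression matrix.
#'
#' @param expr expression matrix.
#' @param epithelial,mesenchymal character vectors of gene symbols (each
#'   matching >= 2 non-constant genes).
#' @return named numeric vector of per-sample EMT scores.
#' @export
emt_score <- function(expr, epithelial, mesenchymal) {
  check_expression_matrix(expr)
  zsum <- function(genes, label) {
    idx <- which(rownames(expr) %in% genes)
    if (length(idx) < 2L) stop(label, " set matches fewer than 2 genes")
    sub <- expr[idx, , drop = FALSE]
    sds <- apply(sub, 1L, sd)
    if (any(sds == 0)) stop(label, " set contains constant gene(s)")
    colSums((sub - rowMeans(sub)) / sds)
  }
  zsum(mesenchymal, "mesenchymal") - zsum(epithelial, "epithelial")
}

#' Two-group score comparison (Mann--Whitney)
#'
#' Wilcoxon rank-sum comparison of a per-sample score between two groups
#' (exact for small untied samples, tie-corrected normal approximation
#' otherwise), reporting the U statistic for the first group, the two-sided
#' p, and group medians.
#'
#' @param scores numeric vector.
#' @param labels vector with exactly two distinct values; the first level in
#'   sort order is the reference group.
#' @return list with `u`, `p`, `median_a`, `median_b`, `direction` (sign of
#'   `median_a - median_b`), and the group labels.
#' @export
group_compare <- function(scores, labels) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("labels must define exactly two groups")
  xa <- scores[labels == lv[1L]]
  xb <- scores[labels == lv[2L]]
  if (length(xa) < 3L || length(xb) < 3L) stop("need >= 3 samples per group")
  wt <- suppressWarnings(wilcox.test(xa, xb, alternative = "two.sided"))
  list(u = unname(wt$statistic), p = wt$p.value,
       median_a = median(xa), median_b = median(xb),
       direction = sign(median(xa) - median(xb)),
       group_a = lv[1L], group_b = lv[2L])
}

#' Over-representation analysis (hypergeometric upper tail)
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected under hypergeometric sampling from the universe:
#' \eqn{P(X \ge k)} with overlap `k`, in-universe set size `K`, query size
#' `n`, universe size `N`; BH adjustment across sets. Sets disjoint from the
#' universe are skipped with a warning.
#'
#' @param query character vector of genes (subset of `universe`).
#' @param sets named list of gene sets.
#' @param universe character vector of background genes.
#' @return data.frame with `set_name`, `k`, `K`, `n`, `N`, `p`, `p_adj`.
#' @export
ora_test <- function(query, sets, universe) {
  check_gene_sets(sets)
  universe <- unique(universe)
  query <- unique(query)
  if (length(query) == 0L) stop("query gene list is empty")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    inuniv <- intersect(sets[[nm]], universe)
    if (length(inuniv) == 0L) {
      warning("set '", nm, "' is disjoint from the universe; skipped")
      return(NULL)
    }
    K <- length(inuniv)
    k <- length(intersect(query, inuniv))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(set_name = character(), k = integer(),
                                      K = integer(), n = integer(),
                                      N = integer(), p = numeric(),
                                      p_adj = numeric()))
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
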