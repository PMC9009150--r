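#' GSVA-style single-sample enrichment scores
#'
#' Non-parametric single-sample enrichment after the gene set variation
#' analysis construction. For every gene \eqn{i} a Gaussian-kernel CDF
#' estimate \eqn{\hat F_i(x_{ij}) = n^{-1}\sum_k \Phi((x_{ij}-x_{ik})/h_i)}
#' with bandwidth \eqn{h_i = s_i/4} converts expression to a sample-relative
#' quantile. Within each sample, genes are ranked by \eqn{\hat F} (descending,
#' ties broken by input row order) and the rank statistic
#' \eqn{z_{ij} = |p/2 - r_{ij}|} is formed. A Kolmogorov–Smirnov-like random
#' walk down the ranked list adds \eqn{z^\tau} (normalized by the set's total
#' weight) at in-set genes and subtracts \eqn{1/(p-m)} at out-of-set genes;
#' the score is the signed sum of the walk's largest positive and largest
#' negative deviations ("max-diff" form), bounded in \eqn{[-1, 1]}.
#'
#' Constant genes (zero sample standard deviation) are dropped with a warning
#' before scoring. Scores are invariant to per-gene positive-affine transforms
#' of the input and to gene-row order.
#'
#' @param expr expression matrix (genes x samples, >= 3 samples).
#' @param sets named list of gene sets; each must match >= 2 retained genes.
#' @param tau rank-weight exponent (default 1).
#' @return score matrix, sets in rows, samples in columns (same sample order
#'   as `expr`).
#' @export
gsva_scores <- function(expr, sets, tau = 1) {
  check_expression_matrix(expr)
  check_gene_sets(sets)
  if (ncol(expr) < 3L) stop("gsva_scores needs at least 3 samples")
  sds <- apply(expr, 1L, sd)
  if (all(sds == 0)) stop("all genes are constant")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before GSVA scoring")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  p <- nrow(expr); n <- ncol(expr)
  Fhat <- .kcdf_gauss(expr)
  # per-sample ranks by Fhat descending; order() is stable, so ties keep
  # input row order
  z <- matrix(0, p, n)
  ord <- matrix(0L, p, n)
  for (j in seq_len(n)) {
    o <- order(Fhat[, j], decreasing = TRUE)
    r <- integer(p); r[o] <- seq_len(p)
    z[, j] <- abs(p / 2 - r)
    ord[, j] <- o
  }
  scores <- matrix(NA_real_, length(sets), n,
                   dimnames = list(names(sets), colnames(expr)))
  for (s in seq_along(sets)) {
    idx <- which(rownames(expr) %in% sets[[s]])
    if (length(idx) < 2L)
      stop("gene set '", names(sets)[s],
           "' matches fewer than 2 non-constant genes")
    inset <- logical(p); inset[idx] <- TRUE
    m <- length(idx)
    dec <- 1 / (p - m)
    for (j in seq_len(n)) {
      o <- ord[, j]
      w <- z[, j]^tau
      ins <- inset[o]
      steps <- ifelse(ins, w[o] / sum(w[idx]), -dec)
      walk <- cumsum(steps)
      scores[s, j] <- max(c(0, walk)) + min(c(0, walk))
    }
  }
  scores
}

#' ssGSEA single-sample enrichment scores
#'
#' Rank-weighted single-sample enrichment: per sample, genes are ranked by
#' expression (descending, stable ties), in-set genes carry weight
#' `rank^alpha` (rank = p for the highest gene), and the score is the sum
#' over list positions of the difference between the weighted in-set
#' cumulative fraction and the unweighted out-of-set cumulative fraction.
#'
#' @param expr expression matrix.
#' @param sets named list of gene sets (each matching >= 2 genes).
#' @param alpha rank weight exponent (default 0.25).
#' @param normalize divide the whole score matrix by its range (default TRUE).
#' @return score matrix, sets x samples.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  check_expression_matrix(expr)
  check_gene_sets(sets)
  p <- nrow(expr); n <- ncol(expr)
  scores <- matrix(NA_real_, length(sets), n,
                   dimnames = list(names(sets), colnames(expr)))
  memb <- lapply(names(sets), function(nm) {
    idx <- which(rownames(expr) %in% sets[[nm]])
    if (length(idx) < 1L || length(idx) >= p)
      stop("gene set '", nm, "' must match a nonempty proper subset of genes")
    idx
  })
  for (j in seq_len(n)) {
    o <- order(expr[, j], decreasing = TRUE)
    rankval <- (p:1)  # rank value at list position k is p - k + 1
    for (s in seq_along(sets)) {
      ins <- o %in% memb[[s]]
      m <- sum(ins)
      w <- ifelse(ins, rankval^alpha, 0)
      pin <- cumsum(w) / sum(w)
      pout <- cumsum(!ins) / (p - m)
      scores[s, j] <- sum(pin - pout)
    }
  }
  if (normalize) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Marker-gene mean abundance scores
#'
#' Transcriptomic abundance estimate for immune/stromal cell populations in
#' the marker-mean style: the score for a population in a sample is the
#' arithmetic mean of its marker genes' expression values there.
#'
#' @param expr expression matrix.
#' @param marker_sets named list of marker gene sets (each matching >= 1 gene).
#' @return score matrix, cell populations x samples.
#' @export
marker_mean_score <- function(expr, marker_sets) {
  check_expression_matrix(expr)
  check_gene_sets(marker_sets)
  out <- matrix(NA_real_, length(marker_sets), ncol(expr),
                dimnames = list(names(marker_sets), colnames(expr)))
  for (s in seq_along(marker_sets)) {
    idx <- which(rownames(expr) %in% marker_sets[[s]])
    if (length(idx) == 0L)
      stop("marker set '", names(marker_sets)[s], "' matches no genes")
    out[s, ] <- colMeans(expr[idx, , drop = FALSE])
  }
  out
}

#' Pre-ranked gene-set enrichment (GSEA) with a gene-set permutation null
#'
#' Classic weighted Kolmogorov–Smirnov enrichment of a gene set in a ranked
#' list: walking down the list (metric descending, stable ties), in-set genes
#' add \eqn{|metric|/\sum_{set}|metric|} and out-of-set genes subtract
#' \eqn{1/(N-m)}; ES is the walk value of largest magnitude (signed). The
#' null is built from `n_perm` random gene sets of the same size drawn with
#' the given seed; NES = ES / mean(|null ES| of matching sign) and the
#' permutation p-value is \eqn{(1 + \#\{same-sign\ null\ at\ least\ as\
#' extreme\}) / (1 + \#\{same-sign\ null\})}.
#'
#' @param metric named numeric vector (unique gene names); ranking metric,
#'   e.g. a log fold change.
#' @param set character vector, a nonempty proper subset of `names(metric)`.
#' @param n_perm number of permutation sets (default 1000).
#' @param seed integer seed for the permutation draw.
#' @return list with `es`, `nes`, `p`, `n_perm`, `set_size`.
#' @export
preranked_gsea <- function(metric, set, n_perm = 1000L, seed = 1L) {
  if (is.null(names(metric)) || anyDuplicated(names(metric)))
    stop("metric must be uniquely named")
  set <- unique(set)
  set <- set[set %in% names(metric)]
  N <- length(metric)
  m <- length(set)
  if (m == 0L || m >= N) stop("set must be a nonempty proper subset of the ranked genes")
  o <- order(metric, decreasing = TRUE)
  ranked_genes <- names(metric)[o]
  absval <- abs(metric)[o]
  es_of <- function(idx_in) {
    w <- sum(absval[idx_in])
    steps <- rep(-1 / (N - length(idx_in)), N)
    steps[idx_in] <- if (w > 0) absval[idx_in] / w else 1 / length(idx_in)
    walk <- cumsum(steps)
    walk[which.max(abs(walk))]
  }
  es <- es_of(which(ranked_genes %in% set))
  null_es <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      es_of(sort(sample.int(N, m)))
    }, numeric(1))
  })
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same) && mean(abs(same)) > 0) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(es = es, nes = nes, p = p, n_perm = n_perm, set_size = m)
}

# evaluate `code` under a local RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
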