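# Independent brute-force oracles, written as literal step-by-step
# enumerations (plain loops, stats:: primitives) so they share no code with
# the package implementations they check.

oracle_kcdf <- function(x) {
  p <- nrow(x); n <- ncol(x)
  out <- matrix(NA_real_, p, n)
  for (i in seq_len(p)) {
    h <- stats::sd(x[i, ]) / 4
    for (j in seq_len(n)) {
      out[i, j] <- mean(stats::pnorm((x[i, j] - x[i, ]) / h))
    }
  }
  out
}

oracle_gsva <- function(x, set_genes, tau = 1) {
  Fh <- oracle_kcdf(x)
  p <- nrow(x); n <- ncol(x)
  m <- sum(rownames(x) %in% set_genes)
  scores <- numeric(n)
  for (j in seq_len(n)) {
    o <- order(Fh[, j], decreasing = TRUE)
    r <- integer(p); r[o] <- seq_len(p)
    z <- abs(p / 2 - r)
    wsum <- sum(z[rownames(x) %in% set_genes]^tau)
    v <- 0; vmax <- 0; vmin <- 0
    for (k in seq_len(p)) {
      g <- o[k]
      if (rownames(x)[g] %in% set_genes) {
        v <- v + z[g]^tau / wsum
      } else {
        v <- v - 1 / (p - m)
      }
      if (v > vmax) vmax <- v
      if (v < vmin) vmin <- v
    }
    scores[j] <- vmax + vmin
  }
  scores
}

oracle_ssgsea <- function(x, set_genes, alpha = 0.25) {
  p <- nrow(x); n <- ncol(x)
  scores <- numeric(n)
  for (j in seq_len(n)) {
    o <- order(x[, j], decreasing = TRUE)
    inset <- rownames(x)[o] %in% set_genes
    m <- sum(inset)
    v <- 0; cin <- 0; cout <- 0
    win <- sum(((p:1)[inset])^alpha)
    for (k in seq_len(p)) {
      if (inset[k]) cin <- cin + (p - k + 1)^alpha / win else
        cout <- cout + 1 / (p - m)
      v <- v + cin - cout
    }
    scores[j] <- v
  }
  scores
}

oracle_es <- function(metric, set_genes) {
  o <- order(metric, decreasing = TRUE)
  g <- names(metric)[o]
  a <- abs(metric)[o]
  inset <- g %in% set_genes
  m <- sum(inset)
  N <- length(metric)
  win <- sum(a[inset])
  v <- 0; best <- 0
  for (k in seq_len(N)) {
    v <- if (inset[k]) v + a[k] / win else v - 1 / (N - m)
    if (abs(v) > abs(best)) best <- v
  }
  unname(best)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (stats::sd(x) * stats::sd(y))
}

# Efron/Breslow partial log-likelihood for untied single-covariate data,
# evaluated literally; used for grid-search verification of Cox fits
oracle_cox_loglik <- function(time, event, x, beta) {
  o <- order(time)
  time <- time[o]; event <- event[o]; x <- x[o]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

rand_expr <- function(p, n, seed) {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%02d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  m
}
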