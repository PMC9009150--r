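#' Validate a gene-by-sample expression matrix
#'
#' The expression container used throughout the package is a plain numeric
#' matrix with unique gene symbols as rownames and unique sample identifiers
#' as colnames, holding log2-scale expression values. This validator enforces
#' those invariants and is called at every public entry point.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @param arg name used in error messages.
#' @return `x`, invisibly, if valid.
#' @export
check_expression_matrix <- function(x, arg = "expr") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(arg, " must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(arg, " must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(arg, ": duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(arg, ": duplicate sample identifiers", call. = FALSE)
  if (!all(is.finite(x)))
    stop(arg, ": all values must be finite", call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop(arg, ": need at least 2 genes and 2 samples", call. = FALSE)
  invisible(x)
}

#' Read a tab-separated gene-by-sample expression matrix
#'
#' First column holds gene symbols, the header row sample identifiers,
#' remaining cells numeric log2-scale expression. Duplicate gene rows are
#' collapsed by keeping the row with the highest mean expression (the usual
#' probe-collapse convention); the number collapsed is reported via `message()`.
#'
#' @param path file path.
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` on load (for raw
#'   FPKM-like input). Default `FALSE`: values are assumed log2 already.
#' @return validated expression matrix.
#' @export
read_expression <- function(path, log2_transform = FALSE) {
  # read.table mangles duplicate header names silently; check the raw header
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(hdr))
    stop("duplicate sample id in header: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression file needs a gene column and >=2 samples")
  genes <- as.character(df[[1L]])
  vals <- df[-1L]
  samples <- colnames(vals)
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1L]
      if (is.na(bad)) bad <- which(is.na(col))[1L]
      stop("non-numeric value in column '", samples[j], "', row ",
           if (is.na(bad)) "?" else bad, " (gene ",
           if (is.na(bad)) "?" else genes[bad], ")")
    }
    if (anyNA(col))
      stop("missing value in column '", samples[j], "', row ",
           which(is.na(col))[1L], " (gene ", genes[which(is.na(col))[1L]], ")")
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    mu <- rowMeans(m)
    keep <- unlist(lapply(split(seq_along(genes), genes), function(ix) {
      ix[which.max(mu[ix])]
    }), use.names = FALSE)
    keep <- sort(keep)
    message(sum(duplicated(genes)), " duplicate gene row(s) collapsed; ",
            "kept the highest-mean row per gene")
    m <- m[keep, , drop = FALSE]
  }
  check_expression_matrix(m)
  if (log2_transform) {
    if (any(m < 0)) stop("log2_transform requested but matrix has negatives")
    m <- log2(m + 1)
  }
  m
}

#' Write an expression matrix as tab-separated text
#' @param x expression matrix. @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  check_expression_matrix(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard MSigDB dialect: one set per line, `name<TAB>description<TAB>gene...`.
#' Within-set duplicate symbols are dropped with a warning; duplicate set
#' names or lines with fewer than three fields are errors.
#'
#' @param path GMT file path.
#' @return named list of character vectors (a gene-set collection).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, ": fewer than 3 tab-separated fields")
    nms[i] <- f[1L]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", f[1L], "': duplicate gene symbol(s) dropped")
      genes <- genes[!duplicated(genes)]
    }
    if (length(genes) == 0L) stop("GMT line ", i, ": empty gene set")
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set name: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  check_gene_sets(sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a gene-set collection
#' @param sets named list of character vectors.
#' @return `sets`, invisibly.
#' @export
check_gene_sets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must be a uniquely named list", call. = FALSE)
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (!is.character(g) || length(g) == 0L)
      stop("gene set '", nm, "' is empty or not character", call. = FALSE)
    if (anyDuplicated(g))
      stop("gene set '", nm, "' has duplicate symbols", call. = FALSE)
  }
  invisible(sets)
}

#' Read a per-sample clinical annotation table
#'
#' Tab-separated with named columns `sample`, `cancer_type`, `tissue`
#' (tumor/normal), and optional `time` (days), `event` (0/1), `response`.
#' Survival fields are validated: negative times and events outside {0, 1}
#' are errors, as is an event recorded without a time.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  check_clinical(df)
}

#' Validate a clinical annotation table
#' @param df data.frame with columns `sample`, `cancer_type`, `tissue` and
#'   optionally `time`, `event`, `response`.
#' @return the validated (typed) data.frame.
#' @export
check_clinical <- function(df) {
  need <- c("sample", "cancer_type", "tissue")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample))
    stop("duplicate sample id in clinical table: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "),
         call. = FALSE)
  if (!all(df$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'", call. = FALSE)
  if (!"time" %in% colnames(df)) df$time <- NA_real_
  if (!"event" %in% colnames(df)) df$event <- NA_integer_
  if (!"response" %in% colnames(df)) df$response <- NA_character_
  df$time <- suppressWarnings(as.numeric(df$time))
  ev_raw <- df$event
  df$event <- suppressWarnings(as.integer(df$event))
  bad_ev <- !is.na(ev_raw) & ev_raw != "" & !(df$event %in% c(0L, 1L))
  if (any(bad_ev, na.rm = TRUE))
    stop("event must be 0 or 1 (sample ",
         df$sample[which(bad_ev)[1L]], ")", call. = FALSE)
  if (any(df$time < 0, na.rm = TRUE))
    stop("negative survival time (sample ",
         df$sample[which(df$time < 0)[1L]], ")", call. = FALSE)
  orphan <- !is.na(df$event) & is.na(df$time)
  if (any(orphan))
    stop("event recorded without a survival time (sample ",
         df$sample[which(orphan)[1L]], ")", call. = FALSE)
  df
}

#' Align an expression matrix and a clinical table on shared samples
#'
#' Restricts both to the intersection of sample identifiers, in the same
#' order. Idempotent. Errors if the intersection is empty.
#'
#' @param expr expression matrix. @param clinical clinical data.frame.
#' @return list with elements `expr` and `clinical`.
#' @export
align_samples <- function(expr, clinical) {
  check_expression_matrix(expr)
  clinical <- check_clinical(clinical)
  shared <- intersect(colnames(expr), clinical$sample)
  if (length(shared) == 0L)
    stop("no samples shared between expression matrix and clinical table")
  message(length(shared), " sample(s) shared after alignment")
  expr <- expr[, shared, drop = FALSE]
  clinical <- clinical[match(shared, clinical$sample), , drop = FALSE]
  rownames(clinical) <- NULL
  list(expr = expr, clinical = clinical)
}

#' Analysis configuration
#'
#' Bundles every threshold the screen uses, with the study defaults:
#' NRG correlation cut `r_nrg = 0.35`, hallmark cut `r_hallmark = 0.30`,
#' significance `p_sig = 0.05`, linear fold-change cut `fc_min = 2` (i.e.
#' |log2 FC| >= 1 on the log2 scale), recurrence in at least
#' `recurrence_min = 5` cancer types per survival class, class exclusivity
#' as more than 5 (`exclusive_in_min = 6`) positive-correlation types inside
#' the class and fewer than 2 (`exclusive_out_max = 1`) outside,
#' `n_quantile_groups = 4` NET-score strata, `perm_count = 1000` gene-set
#' permutations, and a 10--90% admissibility window for the maximally
#' selected survival cutpoint.
#'
#' @param ... named overrides of any default.
#' @return a classed list of configuration values.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    r_nrg = 0.35,
    r_hallmark = 0.30,
    p_sig = 0.05,
    fc_min = 2.0,
    recurrence_min = 5L,
    exclusive_in_min = 6L,
    exclusive_out_max = 1L,
    n_quantile_groups = 4L,
    perm_count = 1000L,
    seed = 1L,
    cutpoint_quantile_range = c(0.10, 0.90)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(
    cfg$r_nrg > 0, cfg$r_hallmark > 0, cfg$p_sig > 0, cfg$fc_min > 0,
    cfg$recurrence_min >= 1, cfg$exclusive_in_min >= 1,
    cfg$exclusive_out_max >= 0, cfg$n_quantile_groups >= 2,
    cfg$perm_count >= 1,
    length(cfg$cutpoint_quantile_range) == 2,
    all(cfg$cutpoint_quantile_range > 0),
    all(cfg$cutpoint_quantile_range < 1),
    diff(cfg$cutpoint_quantile_range) > 0
  )
  class(cfg) <- "netscreen_config"
  cfg
}

#' Read / write an analysis configuration as YAML
#' @param path YAML file path.
#' @return for `read_config`, the configuration; for `write_config`, `path`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  do.call(analysis_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg configuration from [analysis_config()].
#' @export
write_config <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write YAML configs")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Bundled default NET signature
#'
#' Returns the default 23-gene neutrophil-extracellular-trap signature
#' shipped with the package (`inst/extdata/net_signature.gmt`). The membership
#' is a partial reconstruction built from NET component and NET-driving genes
#' reported in the NET literature (granule proteases, antimicrobial peptides,
#' calprotectin subunits, chromatin-decondensation enzymes); real analyses
#' should supply their own curated signature where available.
#'
#' @return character vector of 23 gene symbols.
#' @export
net_signature <- function() {
  path <- system.file("extdata", "net_signature.gmt", package = "netscreen")
  read_gmt(path)[["NET_SIGNATURE"]]
}
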