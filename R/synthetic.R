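#' Synthetic pan-cancer study configuration
#'
#' Defaults mirror the study design the pipeline targets: 22 cancer types
#' (6 with favorable, 7 with poor, 9 with neutral NET-related survival),
#' 150 tumors and 20 para-tumor normals per type, 2000 genes including a
#' 23-gene NET signature driven by a per-sample latent NET activity
#' (loading 0.8), 30 planted NET-associated regulatory genes per survival
#' class with population correlation 0.5 to the activity in their class's
#' cancer types only, a key gene (the SPP1 analog) that is a poor-class
#' NRG plus a 1.2 log2-unit mean shift in poor-type tumors, epithelial and
#' mesenchymal programs coupled to the NET-by-key-gene interaction, and
#' exponential survival whose log-hazard is +0.6 (poor) / -0.6 (favorable)
#' / 0 (neutral) per unit of latent activity, censored uniformly on
#' 200--2000 days.
#'
#' @param ... named overrides of any default.
#' @return classed list of generator settings.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_fav = 6L, n_poor = 7L, n_neutral = 9L,
    samples_per_type = 150L, normals_per_type = 20L,
    n_genes = 2000L, n_signature = 23L,
    signature_loading = 0.8,
    n_planted_nrg_per_class = 30L,
    planted_r = 0.5,
    key_gene_logfc = 1.2,
    gamma_poor = 0.6, gamma_fav = -0.6, gamma_neutral = 0,
    baseline_hazard = 1 / 1000,
    censor_min = 200, censor_max = 2000,
    emt_coupling = 0.5,
    n_emt_genes = 20L,
    normal_signature_shift = 1.0,
    noise_sd = 1.0,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown synth config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(
    cfg$n_fav >= 0, cfg$n_poor >= 0, cfg$n_neutral >= 0,
    cfg$n_fav + cfg$n_poor + cfg$n_neutral >= 1,
    cfg$samples_per_type >= 2, cfg$normals_per_type >= 0,
    cfg$n_genes >= cfg$n_signature + 2 * cfg$n_planted_nrg_per_class +
      2 * cfg$n_emt_genes,
    cfg$n_signature >= 2, cfg$noise_sd > 0,
    cfg$baseline_hazard > 0, cfg$censor_min > 0,
    cfg$censor_max > cfg$censor_min
  )
  if (abs(cfg$signature_loading) >= 1 || abs(cfg$planted_r) >= 1)
    stop("loadings/correlations must lie strictly inside (-1, 1)")
  class(cfg) <- "netscreen_synth_config"
  cfg
}

# loading L such that cor(L * a + noise_sd * sqrt(1 - L^2) * e, a) = r
# (a, e standard normal); reduces to L = r when noise_sd = 1
.loading_for_r <- function(r, noise_sd) {
  if (r == 0) return(0)
  c2 <- noise_sd^2
  L2 <- r^2 * c2 / (1 - r^2 + r^2 * c2)
  if (L2 >= 1) stop("requested correlation is infeasible at this noise level")
  sign(r) * sqrt(L2)
}

#' Generate a synthetic pan-cancer dataset with planted ground truth
#'
#' Single-latent-factor model: each tumor sample carries a latent NET
#' activity `a ~ N(0, 1)`. Signature genes load on `a` in every tumor;
#' planted NRGs load on `a` only in their class's cancer types (pure noise
#' elsewhere); the key gene is a poor-class NRG with an additional mean
#' shift in poor-type tumors; mesenchymal (epithelial) genes load
#' positively (negatively) on the standardized product of `a` and the
#' z-scored key-gene expression; para-tumor normal samples are noise with
#' signature genes shifted down. Survival times are exponential with
#' log-hazard `gamma_c * a` (cancer-type-specific sign), censored at an
#' independent uniform time.
#'
#' @param cfg settings from [synth_config()].
#' @return list with `expr` (genes x samples), `clinical` (per-sample
#'   annotation with survival for tumors), `sets` (signature, EMT programs,
#'   decoys), and `truth` (latent activity, planted gene lists, key gene,
#'   per-type hazard signs and survival classes).
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "netscreen_synth_config"))
  withr_seed(cfg$seed, .synth_generate_impl(cfg))
}

.synth_generate_impl <- function(cfg) {
  types <- c(
    if (cfg$n_fav) paste0("FAV", seq_len(cfg$n_fav)),
    if (cfg$n_poor) paste0("POOR", seq_len(cfg$n_poor)),
    if (cfg$n_neutral) paste0("NEU", seq_len(cfg$n_neutral))
  )
  type_class <- c(rep("favorable", cfg$n_fav), rep("poor", cfg$n_poor),
                  rep("neutral", cfg$n_neutral))
  names(type_class) <- types
  gamma <- c(favorable = cfg$gamma_fav, poor = cfg$gamma_poor,
             neutral = cfg$gamma_neutral)[type_class]
  names(gamma) <- types

  sig_genes <- sprintf("NETSIG%02d", seq_len(cfg$n_signature))
  npc <- cfg$n_planted_nrg_per_class
  poor_nrgs <- if (npc >= 1) c("SPP1", sprintf("NRGP%02d", seq_len(npc))[-1]) else character()
  fav_nrgs <- if (npc >= 1) sprintf("NRGF%02d", seq_len(npc)) else character()
  key_gene <- if (npc >= 1) "SPP1" else NA_character_
  mes_genes <- sprintf("MES%02d", seq_len(cfg$n_emt_genes))
  epi_genes <- sprintf("EPI%02d", seq_len(cfg$n_emt_genes))
  n_bg <- cfg$n_genes - length(sig_genes) - length(poor_nrgs) -
    length(fav_nrgs) - length(mes_genes) - length(epi_genes)
  bg_genes <- sprintf("G%04d", seq_len(n_bg))
  genes <- c(sig_genes, poor_nrgs, fav_nrgs, mes_genes, epi_genes, bg_genes)

  tum_ids <- unlist(lapply(types, function(ct)
    sprintf("%s_T%03d", ct, seq_len(cfg$samples_per_type))))
  nor_ids <- if (cfg$normals_per_type >= 1)
    unlist(lapply(types, function(ct)
      sprintf("%s_N%03d", ct, seq_len(cfg$normals_per_type)))) else character()
  tum_type <- rep(types, each = cfg$samples_per_type)
  nor_type <- rep(types, each = cfg$normals_per_type)
  n_tum <- length(tum_ids); n_nor <- length(nor_ids)

  a <- rnorm(n_tum)
  names(a) <- tum_ids
  mu <- runif(length(genes), 4, 8)
  names(mu) <- genes
  sdn <- cfg$noise_sd

  # tumors: baseline noise, then planted structure on top
  X <- matrix(rnorm(length(genes) * n_tum, sd = sdn), length(genes), n_tum,
              dimnames = list(genes, tum_ids))
  lam <- cfg$signature_loading
  if (length(sig_genes)) {
    noise_scale <- sdn * sqrt(1 - lam^2)
    X[sig_genes, ] <- matrix(rnorm(length(sig_genes) * n_tum,
                                   sd = noise_scale),
                             length(sig_genes), n_tum) +
      rep(lam * a, each = length(sig_genes))
  }
  plant <- function(gset, target_types) {
    if (!length(gset)) return()
    L <- .loading_for_r(cfg$planted_r, sdn)
    sel <- tum_type %in% target_types
    if (!any(sel)) return()
    noise_scale <- sdn * sqrt(1 - L^2)
    X[gset, sel] <<- matrix(rnorm(length(gset) * sum(sel), sd = noise_scale),
                            length(gset), sum(sel)) +
      rep(L * a[sel], each = length(gset))
  }
  plant(poor_nrgs, types[type_class == "poor"])
  plant(fav_nrgs, types[type_class == "favorable"])
  if (!is.na(key_gene)) {
    in_poor <- tum_type %in% types[type_class == "poor"]
    X[key_gene, in_poor] <- X[key_gene, in_poor] + cfg$key_gene_logfc
  }
  # EMT programs: load on the standardized NET-activity x key-gene product
  if (cfg$n_emt_genes >= 1 && !is.na(key_gene)) {
    keyz <- as.numeric(scale(X[key_gene, ]))
    w <- a * keyz
    wz <- if (sd(w) > 0) as.numeric(scale(w)) else w
    X[mes_genes, ] <- X[mes_genes, ] + rep(cfg$emt_coupling * wz,
                                           each = length(mes_genes))
    X[epi_genes, ] <- X[epi_genes, ] - rep(cfg$emt_coupling * wz,
                                           each = length(epi_genes))
  }
  X <- X + mu  # per-gene baselines

  # para-tumor normals: noise around baselines, signature shifted down
  if (n_nor > 0) {
    Xn <- matrix(rnorm(length(genes) * n_nor, sd = sdn), length(genes), n_nor,
                 dimnames = list(genes, nor_ids)) + mu
    if (length(sig_genes))
      Xn[sig_genes, ] <- Xn[sig_genes, ] - cfg$normal_signature_shift
    X <- cbind(X, Xn)
  }

  # exponential survival, log-linear hazard in the latent activity
  rate <- cfg$baseline_hazard * exp(gamma[tum_type] * a)
  t_death <- rexp(n_tum, rate = rate)
  t_cens <- runif(n_tum, cfg$censor_min, cfg$censor_max)
  time <- pmin(t_death, t_cens)
  event <- as.integer(t_death <= t_cens)

  clinical <- rbind(
    data.frame(sample = tum_ids, cancer_type = tum_type, tissue = "tumor",
               time = time, event = event, response = NA_character_,
               stringsAsFactors = FALSE),
    if (n_nor > 0)
      data.frame(sample = nor_ids, cancer_type = nor_type, tissue = "normal",
                 time = NA_real_, event = NA_integer_,
                 response = NA_character_, stringsAsFactors = FALSE)
  )

  bg_pool <- bg_genes
  decoys <- list(
    DECOY1 = bg_pool[seq_len(min(30, n_bg))],
    DECOY2 = bg_pool[seq_len(min(30, max(0, n_bg - 30))) + 30],
    DECOY3 = bg_pool[seq_len(min(30, max(0, n_bg - 60))) + 60]
  )
  decoys <- decoys[vapply(decoys, length, integer(1)) > 0]
  sets <- c(list(NET_SIGNATURE = sig_genes,
                 EPITHELIAL = epi_genes,
                 MESENCHYMAL = mes_genes), decoys)

  truth <- list(
    activity = a,
    poor_nrgs = poor_nrgs,
    fav_nrgs = fav_nrgs,
    key_gene = key_gene,
    gamma = gamma,
    class = type_class,
    epithelial = epi_genes,
    mesenchymal = mes_genes
  )
  list(expr = X, clinical = clinical, sets = sets, truth = truth)
}

#' Null synthetic dataset (no planted structure)
#'
#' Same generator with every loading, mean shift, EMT coupling and hazard
#' coefficient set to zero: expression is exchangeable noise and survival is
#' independent of everything. Used for type-I-error and screen-calibration
#' checks.
#'
#' @param cfg settings from [synth_config()]; loadings/effects are overridden.
#' @return same structure as [synth_generate()].
#' @export
synth_null <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "netscreen_synth_config"))
  cfg$signature_loading <- 0
  cfg$planted_r <- 0
  cfg$key_gene_logfc <- 0
  cfg$emt_coupling <- 0
  cfg$gamma_poor <- 0
  cfg$gamma_fav <- 0
  cfg$gamma_neutral <- 0
  synth_generate(cfg)
}
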