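mk_clin <- function(samples, ct, tissue = "tumor") {
  data.frame(sample = samples, cancer_type = ct, tissue = tissue,
             time = NA_real_, event = NA_integer_,
             response = NA_character_, stringsAsFactors = FALSE)
}

test_that("NRG pair screen applies exactly its correlation thresholds", {
  set.seed(11)
  n <- 40
  score <- rnorm(n)
  ids <- sprintf("s%02d", 1:n)
  m <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(sprintf("g%02d", 1:30), ids))
  # plant a clear positive and a clear negative correlate
  m["g01", ] <- score + rnorm(n, sd = 0.5)
  m["g02", ] <- -score + rnorm(n, sd = 0.5)
  clin <- mk_clin(ids, "CT1")
  pairs <- suppressWarnings(
    nrg_pairs(setNames(score, ids), m, clin, analysis_config()))
  # independent recomputation of the retained set
  expected <- character()
  for (g in rownames(m)) {
    ct <- cor.test(m[g, ], score)
    if (abs(ct$estimate) > 0.35 && ct$p.value < 0.05)
      expected <- c(expected, g)
  }
  expect_setequal(pairs$gene, expected)
  expect_true(all(c("g01", "g02") %in% pairs$gene))
  expect_equal(pairs$sign[pairs$gene == "g01"], "+")
  expect_equal(pairs$sign[pairs$gene == "g02"], "-")
  # relaxing both thresholds keeps every candidate pair
  all_pairs <- nrg_pairs(setNames(score, ids), m, clin,
                         analysis_config(r_nrg = 1e-9, p_sig = 1 + 1e-9))
  expect_equal(nrow(all_pairs), 30L)
  # signature exclusion removes candidates
  pairs2 <- nrg_pairs(setNames(score, ids), m, clin, analysis_config(),
                      exclude_genes = "g01")
  expect_false("g01" %in% pairs2$gene)
})

test_that("small cancer types are skipped in the pair screen", {
  m <- rand_expr(5, 8, seed = 2)
  clin <- mk_clin(colnames(m), "TINY")
  sc <- setNames(rnorm(8), colnames(m))
  expect_warning(p <- nrg_pairs(sc, m, clin), "<10 samples")
  expect_equal(nrow(p), 0L)
})

fake_pairs <- function(gene, types, sign = "+") {
  data.frame(cancer_type = types, gene = gene, r = ifelse(sign == "+", .5, -.5),
             p = 0.01, sign = sign, stringsAsFactors = FALSE)
}

fake_classes <- function() {
  data.frame(cancer_type = c(paste0("F", 1:6), paste0("P", 1:7), "N1"),
             class = c(rep("favorable", 6), rep("poor", 7), "neutral"),
             stringsAsFactors = FALSE)
}

test_that("recurrence filter counts types per class with the >=5 boundary", {
  pairs <- rbind(
    fake_pairs("gA", paste0("F", 1:4)),          # 4 favorable: dropped
    fake_pairs("gB", paste0("F", 1:5)),          # exactly 5: retained
    fake_pairs("gC", c(paste0("P", 1:6), "N1")), # neutral doesn't count
    fake_pairs("gD", c(paste0("F", 1:5), paste0("P", 1:5))))
  res <- recurrence_filter(pairs, fake_classes())
  s <- res$summary
  expect_false(s$core_fav[s$gene == "gA"])
  expect_true(s$core_fav[s$gene == "gB"])
  expect_equal(s$count_poor[s$gene == "gC"], 6L)
  expect_true(s$core_poor[s$gene == "gC"])
  expect_setequal(res$core_genes$shared, "gD")
  expect_setequal(res$core_genes$fav_only, "gB")
  expect_setequal(res$core_genes$poor_only, "gC")
  # dropped genes leave the core pair table
  expect_false("gA" %in% res$core_pairs$gene)
  # class-only sets are exactly core minus overlap
  expect_setequal(res$core_genes$fav_only,
                  setdiff(res$core_genes$favorable, res$core_genes$poor))
  expect_error(recurrence_filter(fake_pairs("g", "UNKNOWN"), fake_classes()),
               "no survival class")
})

test_that("exclusivity uses positive-sign counts with >5 / <2 bounds", {
  mk_sum <- function(pos_poor, pos_fav) {
    data.frame(gene = "g", count_fav = pos_fav, count_poor = pos_poor,
               pos_fav = pos_fav, pos_poor = pos_poor,
               core_fav = FALSE, core_poor = FALSE, stringsAsFactors = FALSE)
  }
  expect_equal(exclusivity_filter(mk_sum(7, 1))$poor, "g")
  expect_length(exclusivity_filter(mk_sum(6, 2))$poor, 0)
  expect_length(exclusivity_filter(mk_sum(3, 0))$poor, 0)
  expect_equal(exclusivity_filter(mk_sum(1, 7))$favorable, "g")
  # negative-sign pairs do not confer exclusivity
  pairs <- fake_pairs("gN", paste0("P", 1:7), sign = "-")
  res <- recurrence_filter(pairs, fake_classes())
  expect_length(exclusivity_filter(res$summary)$poor, 0)
})

test_that("key-gene nomination ranks by over-expression with documented ties", {
  de <- data.frame(gene = c("g1", "g2", "g3"), logfc = c(0.2, 1.5, 1.5),
                   t = 1, p = 0.01, p_adj = c(0.2, 0.01, 0.01),
                   stringsAsFactors = FALSE)
  pairs <- rbind(fake_pairs("g1", paste0("P", 1:7)),
                 fake_pairs("g2", paste0("P", 1:6)),
                 fake_pairs("g3", paste0("P", 1:7)))
  tab <- nominate_key_gene(c("g1", "g2", "g3"), de, pairs, fake_classes())
  # highest logfc first; the g2/g3 logfc tie resolves by poor-type count
  expect_equal(tab$gene, c("g3", "g2", "g1"))
  expect_error(nominate_key_gene(character(), de, pairs, fake_classes()),
               "empty poor-exclusive shortlist")
})

test_that("pan-cancer HR sweep flags planted risk genes and skips constants", {
  set.seed(12)
  n <- 200
  ids <- sprintf("s%03d", 1:n)
  risk <- rnorm(n)
  m <- rbind(RISKG = risk, FLATG = rep(3, n), NOISEG = rnorm(n))
  colnames(m) <- ids
  clin <- mk_clin(ids, "CT")
  clin$time <- rexp(n, rate = 0.002 * exp(0.9 * risk)) + 0.01
  clin$event <- 1L
  res <- suppressWarnings(
    pan_cancer_hr_sweep(m, clin, c("RISKG", "FLATG", "NOISEG")))
  expect_false("FLATG" %in% res$fits$gene)
  expect_gt(res$fits$hr[res$fits$gene == "RISKG"], 1)
  expect_lt(res$fits$p[res$fits$gene == "RISKG"], 0.05)
  expect_equal(res$summary$n_fit, 2L)
})

test_that("combined stratification contrasts the joint extremes", {
  set.seed(13)
  n <- 120
  ids <- sprintf("s%03d", 1:n)
  a <- rnorm(n)
  net <- a + rnorm(n, sd = 0.4)
  gene <- a + rnorm(n, sd = 0.4)
  clin <- mk_clin(ids, "CT")
  clin$time <- rexp(n, rate = 0.002 * exp(0.8 * a)) + 0.01
  clin$event <- 1L
  res <- combined_stratification(setNames(net, ids), setNames(gene, ids), clin)
  expect_setequal(names(res$groups), ids)
  expect_gt(res$cox$hr, 1)
  expect_lt(res$cox$p, 0.05)
  expect_lt(res$logrank$p, 0.05)
  # identical features empty the mixed groups
  expect_error(
    combined_stratification(setNames(net, ids), setNames(net, ids), clin),
    "empty joint group")
})

test_that("the pipeline is deterministic and degrades sanely on null data", {
  cfg <- synth_config(n_fav = 2, n_poor = 2, n_neutral = 1,
                      samples_per_type = 60, normals_per_type = 4,
                      n_genes = 150, n_emt_genes = 5,
                      n_planted_nrg_per_class = 5, seed = 21)
  d <- synth_generate(cfg)
  run <- function() suppressWarnings(suppressMessages(
    run_pipeline(d$expr, d$clinical, d$sets, analysis_config(seed = 21))))
  b1 <- run(); b2 <- run()
  expect_identical(b1$net_scores, b2$net_scores)
  expect_identical(b1$classes, b2$classes)
  expect_identical(b1$pairs, b2$pairs)
  expect_identical(b1$nominees, b2$nominees)

  dn <- synth_null(cfg)
  w <- capture_warnings(
    bn <- suppressMessages(
      run_pipeline(dn$expr, dn$clinical, dn$sets, analysis_config(seed = 21))))
  expect_match(w, "shortlist|neutral|skipped|survival class", all = FALSE)
  expect_true(is.na(bn$nominee) || length(bn$shortlist$poor) == 0)
})

test_that("pipeline bundles write as readable tab-separated tables", {
  cfg <- synth_config(n_fav = 2, n_poor = 2, n_neutral = 0,
                      samples_per_type = 60, normals_per_type = 0,
                      n_genes = 150, n_emt_genes = 5,
                      n_planted_nrg_per_class = 5, seed = 22)
  d <- synth_generate(cfg)
  out <- tempfile()
  b <- suppressWarnings(suppressMessages(
    run_pipeline(d$expr, d$clinical, d$sets, analysis_config(seed = 22),
                 out_dir = out)))
  expect_true(file.exists(file.path(out, "net_scores.tsv")))
  cls <- read.delim(file.path(out, "survival_class.tsv"))
  expect_equal(nrow(cls), nrow(b$classes))
  unlink(out, recursive = TRUE)
})
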