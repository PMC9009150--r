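test_that("pearson_with_p matches closed forms and the covariance oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_with_p(x, x), list(r = 1, p = 0, n = 4))
  expect_equal(pearson_with_p(x, -x)$r, -1)
  res <- pearson_with_p(x, c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$p, 0.2)
  expect_error(pearson_with_p(x, rep(2, 4)), "constant")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")

  for (seed in 1:20) {
    set.seed(seed)
    a <- rnorm(15); b <- rnorm(15)
    res <- pearson_with_p(a, b)
    expect_equal(res$r, oracle_pearson(a, b), tolerance = 1e-12)
    # p is invariant under affine transforms of either argument
    res2 <- pearson_with_p(3 * a - 1, 0.5 * b + 7)
    expect_equal(res2$p, res$p, tolerance = 1e-12)
  }
})

test_that("Welch DE recovers exact mean differences and degenerate cases", {
  m <- rbind(g1 = c(1, 2, 3, 2, 3, 4), g2 = c(5, 5, 5, 5, 5, 5),
             g3 = c(1, 2, 3, 1, 2, 3))
  colnames(m) <- paste0("s", 1:6)
  # group b = group a shifted +1 on g1's pattern
  m["g1", 4:6] <- m["g1", 1:3] + 1
  de <- de_test(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(de$logfc[de$gene == "g1"], -1)
  expect_equal(de$p[de$gene == "g2"], 1)
  expect_equal(de$t[de$gene == "g2"], 0)
  expect_equal(de$logfc[de$gene == "g3"], 0)
  expect_equal(de$p[de$gene == "g3"], 1)
  expect_true(all(de$p_adj >= de$p - 1e-15))

  # identical groups (same multisets): everything flat
  de2 <- de_test(m, paste0("s", 1:3), paste0("s", 1:3))
  expect_true(all(de2$logfc == 0))
  expect_true(all(de2$p == 1))
})

test_that("Welch DE agrees with t.test gene by gene", {
  m <- rand_expr(10, 12, seed = 31)
  ga <- colnames(m)[1:5]; gb <- colnames(m)[6:12]
  de <- de_test(m, ga, gb)
  for (g in rownames(m)[1:4]) {
    tt <- t.test(m[g, ga], m[g, gb])
    expect_equal(de$p[de$gene == g], tt$p.value, tolerance = 1e-12)
    expect_equal(de$t[de$gene == g], unname(tt$statistic), tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up rule and stays monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(5)
  p <- runif(50)
  adj <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("quantile stratification splits at empirical quartiles", {
  s <- setNames(1:8, paste0("s", 1:8))
  g <- quantile_stratify(s, k = 4)
  expect_equal(as.integer(table(g)), rep(2L, 4))
  expect_equal(unname(g[c("s1", "s8")]), c(1L, 4L))
  # a value tied with a cut boundary goes to the lower group
  s2 <- setNames(c(1, 2, 2, 3), paste0("t", 1:4))
  g2 <- quantile_stratify(s2, k = 2)
  expect_equal(unname(g2), c(1L, 1L, 1L, 2L))
  expect_warning(gq <- quantile_stratify(setNames(rep(1, 6), 1:6), k = 3),
                 "all scores equal")
  expect_true(all(gq == 1L))
  expect_error(quantile_stratify(s, k = 1), "at least 2")
})

test_that("EMT score follows hand z-score arithmetic and affine invariance", {
  m <- rbind(EPI1 = c(1, 2, 3), EPI2 = c(2, 4, 6),
             MES1 = c(3, 2, 1), MES2 = c(5, 5.5, 6))
  colnames(m) <- paste0("s", 1:3)
  sc <- emt_score(m, c("EPI1", "EPI2"), c("MES1", "MES2"))
  hand <- colSums(rbind(scale(m["MES1", ])[, 1], scale(m["MES2", ])[, 1])) -
    colSums(rbind(scale(m["EPI1", ])[, 1], scale(m["EPI2", ])[, 1]))
  expect_equal(unname(sc), unname(hand), tolerance = 1e-12)

  set.seed(2)
  m2 <- m * runif(4, 0.5, 2) + rnorm(4)
  expect_equal(emt_score(m2, c("EPI1", "EPI2"), c("MES1", "MES2")), sc,
               tolerance = 1e-12)
  # equal programs cancel
  sc0 <- emt_score(m, c("EPI1", "EPI2"), c("EPI1", "EPI2"))
  expect_equal(unname(sc0), rep(0, 3))
  expect_error(emt_score(m, "EPI1", c("MES1", "MES2")), "fewer than 2")
})

test_that("group comparison gives exact small-sample rank-sum results", {
  sc <- c(1, 2, 3, 4, 5, 6)
  lab <- c("a", "a", "a", "b", "b", "b")
  res <- group_compare(sc, lab)
  expect_equal(res$u, 0)
  expect_equal(res$p, 0.1)  # exact enumeration over C(6,3) = 20 orderings
  expect_equal(res$direction, -1)
  res2 <- group_compare(rev(sc), rev(lab))
  expect_equal(res2$u, 0)  # maximal separation the other way has U = 0 too
  expect_error(group_compare(sc, rep("a", 6)), "two groups")

  # every x > every y: U maximal
  res3 <- group_compare(c(10, 11, 12, 1, 2, 3), lab)
  expect_equal(res3$u, 9)
})

test_that("null label shuffles give roughly uniform comparison p-values", {
  set.seed(8)
  ps <- replicate(200, {
    sc <- rnorm(24)
    group_compare(sc, rep(c("a", "b"), each = 12))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("over-representation test reproduces hypergeometric tails", {
  universe <- paste0("u", 1:10)
  sets <- list(S = universe[1:5], OFF = c("x1", "x2"))
  query <- c(universe[1:4], "u9")
  expect_warning(res <- ora_test(query, sets, universe), "disjoint")
  expect_equal(res$p[res$set_name == "S"], 26 / 252, tolerance = 1e-12)
  expect_equal(res$k[res$set_name == "S"], 4L)

  # zero overlap: upper tail from zero is 1
  res0 <- ora_test(universe[6:10], list(S = universe[1:5],
                                        T = universe[5:6]), universe)
  expect_equal(res0$p[res0$set_name == "S"], 1)
  expect_error(ora_test(character(), sets, universe), "empty")
  expect_error(ora_test("zz", sets, universe), "subset")
})
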