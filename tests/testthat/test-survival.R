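test_that("Kaplan-Meier estimates follow the product-limit closed form", {
  # all censored: flat at 1 (no event rows)
  km0 <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_equal(nrow(km0), 0L)

  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km1$n_risk, c(3, 2, 1))

  # censoring shrinks the risk set: S(1) = 2/3, S(3) = 0
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv, c(2 / 3, 0))
  expect_equal(km2$time, c(1, 3))

  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")

  set.seed(3)
  km3 <- km_estimate(rexp(50) + 0.01, rbinom(50, 1, 0.7))
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_true(all(km3$surv >= 0 & km3$surv <= 1))
})

test_that("log-rank statistic vanishes for identical groups and is symmetric", {
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  event <- c(1, 0, 1, 1, 1, 0, 1, 1)
  grp <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  set.seed(4)
  t2 <- rexp(30) + 0.01; e2 <- rbinom(30, 1, 0.8)
  g2 <- rep(c("x", "y"), 15)
  a <- logrank_test(t2, e2, g2)
  b <- logrank_test(t2, e2, ifelse(g2 == "x", "y", "x"))
  expect_equal(a$chisq, b$chisq, tolerance = 1e-12)
  expect_gte(a$chisq, 0)
  expect_error(logrank_test(t2, e2, rep("x", 30)), "two groups")
})

test_that("log-rank p agrees with an exact label-permutation oracle", {
  time <- c(1, 3, 5, 7, 9, 11)
  event <- rep(1, 6)
  grp <- c("a", "a", "a", "b", "b", "b")
  obs <- logrank_test(time, event, grp)$chisq
  combs <- combn(6, 3)
  perm_stats <- apply(combs, 2, function(ix) {
    g <- rep("b", 6); g[ix] <- "a"
    logrank_test(time, event, g)$chisq
  })
  perm_p <- mean(perm_stats >= obs - 1e-12)
  expect_lt(abs(perm_p - logrank_test(time, event, grp)$p), 0.25)
})

test_that("univariate Cox solves the worked 4-subject fixture", {
  time <- 1:4; event <- rep(1, 4); x <- c(1, 0, 1, 0)
  fit <- cox_univariate(time, event, x)
  expect_equal(fit$hr, (1 + sqrt(17)) / 2, tolerance = 1e-4)
  expect_true(fit$converged)
  # grid-search oracle on the literal partial likelihood
  grid <- seq(0, 2, by = 1e-4)
  ll <- vapply(grid, function(b) oracle_cox_loglik(time, event, x, b),
               numeric(1))
  expect_equal(grid[which.max(ll)], fit$beta, tolerance = 2e-4)
})

test_that("Cox fits are equivariant under affine covariate maps", {
  set.seed(6)
  time <- rexp(40) + 0.01; event <- rbinom(40, 1, 0.8)
  x <- rnorm(40)
  f1 <- cox_univariate(time, event, x)
  f2 <- cox_univariate(time, event, 2.5 * x - 3)
  expect_equal(f2$beta, f1$beta / 2.5, tolerance = 1e-6)
  expect_equal(f2$p, f1$p, tolerance = 1e-6)
  expect_error(cox_univariate(time, event, rep(1, 40)), "constant")
})

test_that("Cox flags monotone likelihoods instead of reporting them", {
  # perfect separation: the covariate orders exactly with survival
  time <- c(1, 2, 3, 10, 11, 12)
  event <- rep(1, 6)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_univariate(time, event, x)
  expect_false(fit$converged)
})

test_that("optimal cutpoint respects its admissibility window", {
  set.seed(7)
  sc <- rnorm(60)
  time <- rexp(60, rate = exp(0.8 * (sc > 0))) + 0.01
  event <- rep(1, 60)
  cut <- optimal_cutpoint(sc, time, event)
  q <- quantile(sc, c(0.10, 0.90))
  expect_gte(mean(sc <= cut$threshold), 0.10)
  expect_lte(mean(sc <= cut$threshold), 0.90)
  expect_true(cut$selection_biased)
  expect_error(optimal_cutpoint(rep(1, 30), time[1:30], event[1:30]),
               "constant")
  expect_error(optimal_cutpoint(sc[1:10], time[1:10], event[1:10]),
               "at least 20")
})

test_that("optimal cutpoint recovers a planted hazard boundary", {
  hit <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 80
    sc <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))  # well-separated populations
    time <- rexp(n, rate = ifelse(sc > 0, 4, 0.5)) + 0.001
    cut <- optimal_cutpoint(sc, time, rep(1, n))
    if (cut$threshold > -1.2 && cut$threshold < 1.2) hit <- hit + 1
  }
  expect_gte(hit, 18)
})

test_that("survival-direction classification follows the threshold rule", {
  # strong effect in one type, pure noise in another
  set.seed(8)
  mk <- function(ct, gamma, n = 60) {
    sc <- rnorm(n)
    data.frame(sample = sprintf("%s%02d", ct, 1:n), cancer_type = ct,
               tissue = "tumor",
               time = rexp(n, rate = 0.002 * exp(gamma * sc)) + 0.01,
               event = 1L, response = NA_character_, score = sc,
               stringsAsFactors = FALSE)
  }
  cl <- rbind(mk("RISK", 1.2), mk("PROT", -1.2), mk("NULLT", 0))
  scores <- setNames(cl$score, cl$sample)
  suppressWarnings(res <- classify_net_survival(scores, cl[, 1:6]))
  expect_equal(res$class[res$cancer_type == "RISK"], "poor")
  expect_equal(res$class[res$cancer_type == "PROT"], "favorable")
  expect_gt(res$hr[res$cancer_type == "RISK"], 1)
  expect_lt(res$hr[res$cancer_type == "PROT"], 1)
  # non-significant p forces neutral regardless of HR: identical groups
  clf <- mk("FLAT", 0, n = 40)
  scores_f <- setNames(clf$score, clf$sample)
  suppressWarnings(resf <- classify_net_survival(scores_f, clf[, 1:6]))
  if (resf$p >= 0.05) expect_equal(resf$class, "neutral")
})
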