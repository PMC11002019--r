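test_that("fisher 2x2 matches hand enumerations and the symmetric case", {
  expect_equal(as.numeric(fisher_exact(matrix(c(1, 1, 1, 1), 2))), 1.0)
  # [[2,0],[0,2]]: observed prob 1/6, tail = 2/6
  expect_equal(as.numeric(fisher_exact(matrix(c(2, 0, 0, 2), 2))), 1 / 3)
  # [[5,0],[0,5]]: 2 * C(5,5)C(5,0)/C(10,5) = 2/252
  expect_equal(as.numeric(fisher_exact(matrix(c(5, 0, 0, 5), 2))), 2 / 252)
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero")
  expect_equal(as.numeric(p0), 1)
})

test_that("fisher 2x2 equals brute-force enumeration and is transpose-invariant", {
  set.seed(61)
  for (i in 1:60) {
    tab <- random_2x2(30)
    p <- as.numeric(fisher_exact(tab))
    expect_equal(p, oracle_fisher_2x2(tab), tolerance = 1e-10)
    expect_equal(as.numeric(fisher_exact(t(tab))), p, tolerance = 1e-12)
    # independent reference implementation
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("Freeman-Halton reduces to the 2x2 result and matches the reference on r x c", {
  set.seed(62)
  for (i in 1:20) {
    tab <- random_2x2(20)
    expect_equal(as.numeric(freeman_halton(tab)),
                 as.numeric(fisher_exact(tab)), tolerance = 1e-10)
  }
  tab3 <- matrix(c(7, 34, 5, 0, 9, 37), 3, byrow = TRUE)
  expect_equal(as.numeric(freeman_halton(tab3)),
               stats::fisher.test(tab3)$p.value, tolerance = 1e-6)
  tab4 <- matrix(c(2, 18, 6, 23, 0, 10, 13, 20), 4, byrow = TRUE)
  expect_equal(as.numeric(freeman_halton(tab4)),
               stats::fisher.test(tab4)$p.value, tolerance = 1e-6)
  expect_identical(attr(freeman_halton(tab3), "method"), "enumeration")
})

test_that("Freeman-Halton Monte-Carlo fallback is seeded and close to enumeration", {
  tab <- matrix(c(7, 34, 5, 0, 9, 37), 3, byrow = TRUE)
  p_mc <- freeman_halton(tab, max_tables = 10, mc_reps = 2e4, mc_seed = 5)
  expect_identical(attr(p_mc, "method"), "monte-carlo")
  expect_identical(as.numeric(p_mc),
                   as.numeric(freeman_halton(tab, max_tables = 10,
                                             mc_reps = 2e4, mc_seed = 5)))
  expect_lt(abs(as.numeric(p_mc) - as.numeric(freeman_halton(tab))), 0.005)
})

test_that("Mann-Whitney matches exact enumeration and rank invariance", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 / 6)
  expect_identical(r$method, "exact")
  # same multiset -> P = 1
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  # scale invariance of (U, P)
  x <- c(1.2, 3.4, 0.5, 8); y <- c(2.2, 9.1, 4.4)
  expect_equal(mann_whitney_u(x * 10, y * 10)[c("U", "p_value")],
               mann_whitney_u(x, y)[c("U", "p_value")])
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
  # large-sample branch agrees with the reference normal approximation
  set.seed(63)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(12, 0.5)
    got <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_identical(got$method, "normal")
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis matches the hand example and the two-group MW approximation", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2L)
  # all-constant convention
  flat <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(flat$H, 0)
  expect_equal(flat$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  set.seed(64)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20, 0.3)
    p_kw <- kruskal_wallis(list(x, y))$p_value
    p_mw <- mann_whitney_u(x, y)$p_value
    expect_lt(abs(p_kw - p_mw), 0.02)
  }
})

test_that("Spearman correlation matches hand ranks and flags zero variance", {
  expect_equal(spearman_correlation(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_correlation(1:5, -(1:5))$rho, -1)
  r <- spearman_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)
  ref <- suppressWarnings(
    stats::cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "spearman"))
  expect_equal(r$rho, unname(ref$estimate))
  flat <- spearman_correlation(c(1, 1, 1), 1:3)
  expect_true(flat$undefined)
  expect_error(spearman_correlation(1:3, 1:4), "equal length")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("Kaplan-Meier and log-rank match hand computations", {
  # uncensored single group: S drops by 1/n at each event
  fit <- survival::survfit(survival::Surv(c(1, 2, 3, 4), rep(1, 4)) ~ 1)
  expect_equal(fit$surv, c(0.75, 0.5, 0.25, 0))
  # identical groups: chi-square 0, P 1
  d <- data.frame(time = rep(c(1, 2, 3), 2), event = 1,
                  group = rep(c("a", "b"), each = 3))
  same <- survival_compare(d, "a", "b")
  expect_lt(same$chisq, 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-6)
  # A events at (1,2), B events at (3,4): O_A = 2, E_A = 1/2 + 1/3 = 5/6,
  # V = 1/4 + 2/9 = 17/36, chi2 = (7/6)^2 / (17/36)
  d2 <- data.frame(time = c(1, 2, 3, 4), event = 1,
                   group = c("A", "A", "B", "B"))
  cmp <- survival_compare(d2, "A", "B")
  expect_equal(cmp$chisq, (7 / 6)^2 / (17 / 36), tolerance = 1e-10)
  # medians use the first time S(t) <= 0.5
  expect_equal(unname(cmp$medians[["A"]]), 1)
  expect_error(survival_compare(data.frame(time = c(-1, 1), event = 1,
                                           group = c("a", "b"))),
               "positive")
})

test_that("ROC AUC matches the pair-counting definition and the U identity", {
  expect_equal(roc_auc(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(10, 9, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(65)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.4)
  expect_equal(roc_auc(sc, lb),
               as.numeric(suppressMessages(pROC::auc(lb, sc))))
})

test_that("AUC equals U/(n1 n2) on random data", {
  set.seed(66)
  for (i in 1:100) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    pos <- rnorm(n1, 0.3); neg <- rnorm(n2)
    auc <- roc_auc(c(pos, neg), rep(c(1, 0), c(n1, n2)))
    U <- mann_whitney_u(pos, neg)$U
    expect_equal(auc, U / (n1 * n2), tolerance = 1e-12)
  }
})

test_that("test P-values are approximately uniform under the null", {
  set.seed(67)
  p_mw <- replicate(500, mann_whitney_u(rnorm(12), rnorm(12))$p_value)
  expect_gt(suppressWarnings(ks.test(p_mw, "punif"))$p.value, 0.01)
  p_sp <- replicate(500, spearman_correlation(rnorm(15), rnorm(15))$p_value)
  expect_gt(suppressWarnings(ks.test(p_sp, "punif"))$p.value, 0.01)
})
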