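test_that("Welch t handles identical, separated and degenerate samples", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(sep$df, 4)

  const <- welch_t(c(5, 5), c(5, 5))
  expect_equal(const$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("Welch p-values match the reference t distribution", {
  set.seed(51)
  for (rep in 1:20) {
    a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1), sd = 2)
    ours <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("Mann-Whitney exact path matches hand enumeration and wilcox.test", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)

  tie <- mann_whitney(5, 5)
  expect_equal(tie$statistic, 0.5)
  expect_equal(tie$p_value, 1)

  set.seed(52)
  for (rep in 1:20) {
    a <- sample(1:1000, sample(2:6, 1))
    b <- sample(2000:3000, sample(2:6, 1))
    b <- b + runif(length(b))  # ensure no ties with a
    ours <- mann_whitney(a, b)
    expect_equal(ours$p_value, oracle_mw_perm_p(a, b), tolerance = 1e-12)
    expect_equal(ours$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney approximation agrees with wilcox.test on large samples", {
  set.seed(53)
  for (rep in 1:10) {
    a <- rnorm(25); b <- rnorm(30, 0.5)
    ours <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  # tied data exercise the tie correction
  a <- rep(1:5, 4); b <- rep(2:6, 4)
  expect_equal(mann_whitney(a, b)$p_value,
               suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE)$p.value),
               tolerance = 1e-9)
})

test_that("two-sided p-values are symmetric under sample swap", {
  set.seed(54)
  for (rep in 1:10) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1), 1)
    expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)
    a2 <- rnorm(5); b2 <- rnorm(7)
    expect_equal(welch_t(a2, b2)$p_value, welch_t(b2, a2)$p_value)
  }
})

test_that("Kruskal-Wallis + Dunn matches rank arithmetic and kruskal.test", {
  null3 <- dunn_posthoc(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(null3$H, 0)
  expect_true(all(null3$comparisons$p_adjusted == 1))

  sep <- dunn_posthoc(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  expect_equal(sep$H, 32 / 7, tolerance = 1e-12)
  expect_equal(sep$df, 2)

  set.seed(55)
  for (rep in 1:10) {
    gs <- list(rnorm(6), rnorm(7, 1), rnorm(5, 2))
    ours <- dunn_posthoc(gs)
    ref <- kruskal.test(gs)
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }

  expect_error(dunn_posthoc(list(1:3, 4:6)), "k >= 3")
  expect_error(dunn_posthoc(list(1:3, 4:6, 7)), "n >= 2")
})

test_that("Dunn z statistics match a direct mean-rank computation", {
  gs <- list(a = c(3, 1, 4, 1, 5), b = c(9, 2, 6, 5), c = c(3, 5, 8, 9, 7, 9))
  res <- dunn_posthoc(gs)
  x <- unlist(gs); g <- rep(1:3, lengths(gs)); N <- length(x)
  r <- rank(x)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rb <- tapply(r, g, mean)
  z12 <- (rb[1] - rb[2]) /
    sqrt((N * (N + 1) / 12 - tie_term) * (1 / 5 + 1 / 4))
  expect_equal(res$comparisons$z[1], unname(z12), tolerance = 1e-12)
  expect_equal(res$comparisons$p_adjusted,
               pmin(1, res$comparisons$p_value * 3))
})

test_that("all reported p-values lie in [0, 1]", {
  set.seed(56)
  for (rep in 1:20) {
    a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1))
    expect_gte(welch_t(a, b)$p_value, 0)
    expect_lte(welch_t(a, b)$p_value, 1)
    p <- mann_whitney(a, b)$p_value
    expect_gte(p, 0); expect_lte(p, 1)
  }
})
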