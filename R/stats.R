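# Group comparisons reported alongside abscission phenotypes. All tests
# are two-sided. The Mann-Whitney test uses exact enumeration for small
# untied problems and a tie- and continuity-corrected Normal approximation
# otherwise; Dunn's post hoc comparisons follow a tie-corrected
# Kruskal-Wallis test (Dunn's procedure is defined on ranks, so the
# "one-way ANOVA with Dunn's post hoc" phrasing common in figure legends
# is implemented on the rank scale).

new_test_result <- function(statistic, p_value, method, n, notes = NULL,
                            ...) {
  structure(c(list(statistic = statistic, p_value = p_value, method = method,
                   n = n, notes = notes), list(...)),
            class = "petal_test")
}

#' @export
print.petal_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  if (!is.null(x$notes)) cat("  note: ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom; two-sided p from the t distribution. If both samples are
#' constant with equal means the test is degenerate and returns p = 1.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return A `petal_test` with fields `statistic` (t), `df`, `p_value`.
#' @export
welch_t <- function(sample_a, sample_b) {
  a <- sample_a[!is.na(sample_a)]; b <- sample_b[!is.na(sample_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs n >= 2", call. = FALSE)
  va <- var(a); vb <- var(b)
  na <- length(a); nb <- length(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(new_test_result(0, 1, "Welch two-sample t test", c(na, nb),
                             notes = "both samples constant and equal",
                             df = NA_real_))
    stop("both samples have zero variance with different means; ",
         "the Welch statistic is undefined", call. = FALSE)
  }
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  new_test_result(t, min(1, 2 * pt(-abs(t), df)), "Welch two-sample t test",
                  c(na, nb), df = df)
}

# Mann-Whitney U of sample a (midranks): U_a = R_a - n_a (n_a + 1) / 2
mw_u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact two-sided p by full enumeration of rank assignments (no ties)
mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  u_obs <- mw_u_stat(a, b)
  ranks <- seq_len(N)
  sets <- combn(N, na)
  us <- colSums(matrix(ranks[sets], nrow = na)) - na * (na + 1) / 2
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U statistic computed with midranks. For `n_a + n_b <= 12` with no ties
#' the two-sided p-value is exact, by full enumeration of all rank
#' assignments; otherwise a Normal approximation with tie correction and
#' continuity correction is used. Complete degeneracy (all values tied
#' across both samples) returns p = 1.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 1.
#' @return A `petal_test` with fields `statistic` (U of `sample_a`),
#'   `p_value`, `notes` naming the p-value method.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  a <- sample_a[!is.na(sample_a)]; b <- sample_b[!is.na(sample_b)]
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  u <- mw_u_stat(a, b)
  ties <- anyDuplicated(c(a, b)) > 0L
  if (N <= 12L && !ties) {
    p <- mw_exact_p(a, b)
    return(new_test_result(u, p, "Mann-Whitney test", c(na, nb),
                           notes = "exact enumeration"))
  }
  mu <- na * nb / 2
  tie_tab <- table(c(a, b))
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0)
    return(new_test_result(u, 1, "Mann-Whitney test", c(na, nb),
                           notes = "degenerate: all values tied"))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-max(z, 0)))
  new_test_result(u, p, "Mann-Whitney test", c(na, nb),
                  notes = "Normal approximation with tie and continuity correction")
}

# tie-corrected Kruskal-Wallis H on a list of samples
kw_h_stat <- function(samples) {
  x <- unlist(samples)
  g <- rep(seq_along(samples), lengths(samples))
  N <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / lengths(samples)) - 3 * (N + 1)
  tie_tab <- table(x)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (corr == 0) stop("all observations tied", call. = FALSE)
  h / corr
}

#' Kruskal-Wallis test followed by Dunn's pairwise comparisons
#'
#' Computes the tie-corrected Kruskal-Wallis H over `k >= 3` groups, then
#' Dunn's z statistics on mean ranks for every pair, with multiplicity
#' adjustment (Bonferroni by default) of the two-sided p-values.
#'
#' @param samples list of `k >= 3` numeric vectors, each of length >= 2.
#' @param p_adjust adjustment method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return List with `H`, `df`, `p_value` (Kruskal-Wallis) and
#'   `comparisons`, a data.frame of pairwise `petal_test`-style rows
#'   (`group_a`, `group_b`, `z`, `p_value`, `p_adjusted`).
#' @export
dunn_posthoc <- function(samples, p_adjust = "bonferroni") {
  if (!is.list(samples) || length(samples) < 3L)
    stop("need k >= 3 groups; use welch_t()/mann_whitney() for two groups",
         call. = FALSE)
  samples <- lapply(samples, function(s) s[!is.na(s)])
  if (any(lengths(samples) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  k <- length(samples)
  nm <- names(samples) %||% paste0("group", seq_len(k))
  x <- unlist(samples)
  g <- rep(seq_len(k), lengths(samples))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_g <- lengths(samples)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  H <- kw_h_stat(samples)
  kw_p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  pairs <- combn(k, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[i1] + 1 / n_g[i2]))
    z[j] <- (rbar[i1] - rbar[i2]) / se
    p[j] <- min(1, 2 * pnorm(-abs(z[j])))
  }
  comparisons <- data.frame(group_a = nm[pairs[1, ]], group_b = nm[pairs[2, ]],
                            z = z, p_value = p,
                            p_adjusted = p.adjust(p, method = p_adjust))
  list(H = H, df = k - 1, p_value = kw_p, method = "Kruskal-Wallis + Dunn",
       comparisons = comparisons)
}
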