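# Group statistics: rank-sum tests, permutation confirmation, binomial
# multiple-comparison probability, effect sizes.

# Internal: two-sided rank-sum p for group-1 rank sum W given pooled
# midranks. Normal approximation with tie correction and continuity
# correction; identical formula is used for observed and permuted data.
ranksum_p_normal <- function(W, n1, n2, ranks) {
  n <- n1 + n2
  tie_tab <- table(ranks)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  mu <- n1 * (n + 1) / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) return(rep(1, length(W)))
  z <- (W - mu)
  z <- (abs(z) - 0.5) / sqrt(sig2)
  z[z < 0] <- 0
  pmin(1, 2 * stats::pnorm(-z))
}

# Internal: exact two-sided rank-sum p by enumeration of all C(n, n1)
# assignments of the pooled midranks (used when n <= 12; at most 924
# combinations). Exact conditional on the observed tie pattern.
ranksum_p_exact <- function(W, n1, ranks) {
  idx <- utils::combn(length(ranks), n1)
  Ws <- colSums(matrix(ranks[idx], nrow = n1))
  mu <- n1 * (length(ranks) + 1) / 2
  eps <- 1e-9
  mean(abs(Ws - mu) >= abs(W - mu) - eps)
}

#' Wilcoxon rank-sum test between two samples
#'
#' Non-parametric two-sided comparison of two independent samples.
#' For pooled sizes up to 12 the p-value is computed by exact
#' enumeration of all group assignments of the pooled (mid)ranks;
#' otherwise the normal approximation with tie and continuity
#' correction is used. The direction reports which sample has the
#' larger median (falling back to means on median ties).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return A one-row tibble with columns `p_value`, `direction`
#'   (`"a_higher"` / `"b_higher"` / `"tied"`), `statistic` (rank sum of
#'   `a`), `n_a`, `n_b`.
#' @examples
#' wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_ranksum <- function(a, b) {
  assert_numeric_series(a, "a", 2L)
  assert_numeric_series(b, "b", 2L)
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  W <- sum(ranks[seq_len(n1)])
  p <- if (n1 + n2 <= 12L) {
    ranksum_p_exact(W, n1, ranks)
  } else {
    ranksum_p_normal(W, n1, n2, ranks)
  }
  dm <- median(a) - median(b)
  if (dm == 0) dm <- mean(a) - mean(b)
  tibble(
    p_value = p,
    direction = if (dm > 0) "a_higher" else if (dm < 0) "b_higher" else "tied",
    statistic = W, n_a = n1, n_b = n2
  )
}

#' Monte Carlo permutation confirmation of a rank-sum result
#'
#' Re-randomizes the pooled observations into groups of the original
#' sizes, recomputes the rank-sum p-value for each permutation, and
#' confirms the original result if its p-value is smaller than 95% of
#' the permuted ones (i.e. below their 5th percentile).
#'
#' @param a,b Numeric samples.
#' @param n_permutations Number of random label permutations
#'   (default 16000).
#' @param seed Integer seed for the permutation stream.
#' @return A one-row tibble with `p_value` (observed), `confirmed`
#'   (logical), `quantile` (fraction of permuted p-values strictly below
#'   the observed one) and `n_permutations`.
#' @export
permutation_confirmation <- function(a, b, n_permutations = 16000,
                                     seed = 1L) {
  assert_numeric_series(a, "a", 2L)
  assert_numeric_series(b, "b", 2L)
  if (n_permutations < 100) {
    stop_nvcoh("`n_permutations` must be at least 100.",
               "nvcoh_validation_error")
  }
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  obs <- wilcoxon_ranksum(a, b)$p_value
  ranks <- rank(c(a, b))
  perm_p <- with_seed_nv(seed, {
    Ws <- vapply(seq_len(n_permutations), function(i) {
      sum(ranks[sample.int(n, n1)])
    }, numeric(1))
    if (n <= 12L) {
      vapply(Ws, ranksum_p_exact, numeric(1), n1 = n1, ranks = ranks)
    } else {
      ranksum_p_normal(Ws, n1, n2, ranks)
    }
  })
  q5 <- as.numeric(quantile(perm_p, 0.05, type = 1))
  tibble(
    p_value = obs,
    confirmed = obs < q5,
    quantile = mean(perm_p < obs),
    n_permutations = n_permutations
  )
}

#' Exact binomial tail probability for multiple comparisons
#'
#' Probability of observing `k` or more positive outcomes among `n`
#' independent tests when each is positive with probability `p` (0.05
#' for tests run at the 5% level). Used to judge whether a count of
#' significant channel pairs could plausibly arise if all null
#' hypotheses were true.
#'
#' @param k Observed number of positive outcomes (0 <= k <= n).
#' @param n Total number of comparisons.
#' @param p Per-test positive probability, in (0, 1). Default 0.05.
#' @return The exact tail probability (a number in `[0, 1]`, accurate
#'   down to the smallest representable magnitudes).
#' @examples
#' binomial_tail(36, 55)   # ~1.6e-33
#' binomial_tail(2, 16)    # ~0.19
#' @export
binomial_tail <- function(k, n, p = 0.05) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p) == 1L)
  if (k < 0 || n < 0 || k != round(k) || n != round(n)) {
    stop_nvcoh("`k` and `n` must be nonnegative integers.",
               "nvcoh_validation_error")
  }
  if (k > n) {
    stop_nvcoh("`k` must not exceed `n`.", "nvcoh_validation_error")
  }
  if (p <= 0 || p >= 1) {
    stop_nvcoh("`p` must lie strictly between 0 and 1.",
               "nvcoh_validation_error")
  }
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(a) - mean(b))` divided by the
#' pooled (n-1) standard deviation.
#'
#' @param a,b Numeric samples of length >= 2.
#' @return A scalar; `NA` with a warning if the pooled variance is zero.
#' @export
cohens_d <- function(a, b) {
  assert_numeric_series(a, "a", 2L)
  assert_numeric_series(b, "b", 2L)
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) {
    warn("Zero pooled variance; Cohen's d undefined.")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Compare two cohorts of band-averaged summaries
#'
#' Runs the per-pair group comparison used throughout the analysis: a
#' two-sided Wilcoxon rank-sum test on each channel pair's band-averaged
#' values, Cohen's d, optional Monte Carlo permutation confirmation, and
#' a multiplicity summary giving the exact binomial probability of the
#' observed count of significant pairs under the global null.
#'
#' @param table1,table2 `nv_band_table` objects (see
#'   [build_summary_table()]) over the same pair universe; `table1` is
#'   sample `a` in each test.
#' @param alpha Significance level (default 0.05).
#' @param n_permutations Permutations for confirmation; 0 skips the
#'   permutation step.
#' @param seed Integer seed for the permutation streams.
#' @return A `nv_group_comparison` list with elements `comparisons`
#'   (tibble: pair, p_value, direction, cohens_d, confirmed,
#'   permutation_quantile) and `summary` (tibble: n_tests,
#'   n_significant, alpha, binomial_tail_probability).
#' @export
compare_groups <- function(table1, table2, alpha = 0.05,
                           n_permutations = 16000, seed = 1L) {
  stopifnot(is.data.frame(table1), is.data.frame(table2))
  pairs1 <- sort(unique(table1$pair))
  pairs2 <- sort(unique(table2$pair))
  if (!identical(pairs1, pairs2)) {
    stop_nvcoh("The two tables cover different pair universes.",
               "nvcoh_usage_error")
  }
  rows <- purrr::map(pairs1, function(pr) {
    a <- table1$value[table1$pair == pr]
    b <- table2$value[table2$pair == pr]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(pair = pr, p_value = NA_real_, direction = NA_character_,
                    cohens_d = NA_real_, confirmed = NA,
                    permutation_quantile = NA_real_))
    }
    w <- wilcoxon_ranksum(a, b)
    d <- suppressWarnings(cohens_d(a, b))
    conf <- NA
    pq <- NA_real_
    if (n_permutations > 0) {
      pc <- permutation_confirmation(a, b, n_permutations,
                                     seed = derive_seed(seed, pr))
      conf <- pc$confirmed
      pq <- pc$quantile
    }
    tibble(pair = pr, p_value = w$p_value, direction = w$direction,
           cohens_d = d, confirmed = conf, permutation_quantile = pq)
  })
  comparisons <- dplyr::bind_rows(rows)
  tested <- comparisons[!is.na(comparisons$p_value), ]
  n_sig <- sum(tested$p_value < alpha)
  summary <- tibble(
    n_tests = nrow(tested),
    n_significant = n_sig,
    alpha = alpha,
    binomial_tail_probability =
      if (nrow(tested) > 0) binomial_tail(n_sig, nrow(tested), alpha) else NA_real_
  )
  structure(list(comparisons = comparisons, summary = summary),
            class = "nv_group_comparison")
}

#' @export
print.nv_group_comparison <- function(x, ...) {
  cat("Group comparison:", x$summary$n_significant, "of",
      x$summary$n_tests, "pairs significant at alpha =",
      x$summary$alpha, "\n")
  cat("Binomial tail probability:",
      format(x$summary$binomial_tail_probability, digits = 3), "\n")
  print(x$comparisons, ...)
  invisible(x)
}
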