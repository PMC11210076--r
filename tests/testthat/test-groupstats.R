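test_that("small-sample rank-sum p-values are exact", {
  w <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_equal(w$direction, "b_higher")
  # identical samples
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # agreement with the exact reference implementation on tie-free draws
  set.seed(14)
  for (sizes in list(c(3, 3), c(4, 5), c(6, 6), c(2, 8))) {
    a <- sample(1:100, sizes[1])
    b <- sample(101:200, sizes[2]) / 7
    expect_equal(wilcoxon_ranksum(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large-sample rank-sum matches the corrected normal approximation", {
  set.seed(15)
  for (r in 1:5) {
    a <- rnorm(13)
    b <- rnorm(29, mean = 0.5)
    ours <- wilcoxon_ranksum(a, b)$p_value
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
  # ties are handled via the tie-corrected variance
  a <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7)
  b <- c(rep(2, 10), rep(5, 10), rep(7, 9))
  expect_equal(wilcoxon_ranksum(a, b)$p_value,
               suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE)$p.value),
               tolerance = 1e-9)
  # strongly separated groups
  set.seed(16)
  a <- rnorm(15); b <- rnorm(33) + 10
  expect_lt(wilcoxon_ranksum(a, b)$p_value, 1e-3)
})

test_that("rank-sum p is invariant under monotone transforms", {
  set.seed(17)
  a <- abs(rnorm(10)) + 0.1
  b <- abs(rnorm(12)) + 0.2
  p1 <- wilcoxon_ranksum(a, b)$p_value
  expect_equal(wilcoxon_ranksum(log(a), log(b))$p_value, p1)
  expect_equal(wilcoxon_ranksum(a^3, b^3)$p_value, p1)
})

test_that("rank-sum type-I error is calibrated at the study group sizes", {
  set.seed(18)
  p <- replicate(2500, wilcoxon_ranksum(rnorm(13), rnorm(29))$p_value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})

test_that("binomial tail probabilities are exact and monotone", {
  expect_equal(binomial_tail(0, 10, 0.05), 1)
  expect_equal(binomial_tail(36, 55, 0.05), 1.58e-33, tolerance = 1e-2)
  # complement identity to machine precision
  k <- 7; n <- 20; p <- 0.3
  expect_lt(abs(binomial_tail(k, n, p) +
                  sum(dbinom(0:(k - 1), n, p)) - 1), 1e-12)
  # decreasing in k, increasing in p
  tails_k <- vapply(0:20, binomial_tail, numeric(1), n = 20, p = 0.05)
  expect_true(all(diff(tails_k) <= 0))
  expect_lt(binomial_tail(5, 20, 0.05), binomial_tail(5, 20, 0.2))
  expect_error(binomial_tail(6, 5, 0.05), class = "nvcoh_validation_error")
  expect_error(binomial_tail(1, 5, 0), class = "nvcoh_validation_error")
})

test_that("Cohen's d recovers unit shifts and flags degenerate input", {
  set.seed(19)
  b <- rnorm(200)
  b <- (b - mean(b)) / sd(b)
  expect_equal(cohens_d(b + 1, b), 1, tolerance = 1e-9)
  expect_equal(cohens_d(b, b), 0)
  expect_warning(d0 <- cohens_d(rep(1, 5), rep(1, 7)))
  expect_true(is.na(d0))
  # estimator recovery at the study sizes
  dd <- replicate(400, cohens_d(rnorm(13, mean = 1.03), rnorm(29)))
  expect_lt(abs(mean(dd) - 1.03), 0.08)
})

test_that("permutation confirmation separates real effects from null ones", {
  expect_equal(eval(formals(permutation_confirmation)$n_permutations), 16000)
  set.seed(20)
  a <- rnorm(13, mean = 2)  # d = 2 vs the pooled sd
  b <- rnorm(29)
  pc <- permutation_confirmation(a, b, n_permutations = 2000, seed = 3)
  expect_true(pc$confirmed)
  expect_lt(pc$quantile, 0.05)
  expect_identical(pc,
                   permutation_confirmation(a, b, n_permutations = 2000,
                                            seed = 3))
  expect_error(permutation_confirmation(a, b, n_permutations = 10),
               class = "nvcoh_validation_error")
})

test_that("group comparison counts significant pairs and their binomial tail", {
  g <- make_log_grid(0.02, 0.5, 30)
  mk <- function(vals) {
    res <- tidyr::expand_grid(subject = paste0("S", seq_along(vals)),
                              pair = c("P1", "P2"))
    res$spectrum <- lapply(rep(vals, each = 2), function(v) {
      tibble::tibble(frequency = g$values, effective = v)
    })
    build_summary_table(res, c(0.05, 0.2), metric = "coherence")
  }
  set.seed(21)
  t1 <- mk(rnorm(8))
  cmp0 <- compare_groups(t1, t1, n_permutations = 0)
  expect_equal(cmp0$summary$n_significant, 0)
  expect_equal(cmp0$summary$binomial_tail_probability, 1)
  t2 <- mk(rnorm(8) + 5)
  cmp1 <- compare_groups(t2, t1, n_permutations = 200, seed = 4)
  expect_equal(cmp1$summary$n_significant, 2)
  expect_true(all(cmp1$comparisons$direction == "a_higher"))
  expect_true(all(cmp1$comparisons$cohens_d > 1))
  expect_equal(cmp1$summary$binomial_tail_probability,
               binomial_tail(2, 2, 0.05))
  bad <- t1
  bad$pair <- sub("P2", "P9", bad$pair)
  expect_error(compare_groups(t1, bad), class = "nvcoh_usage_error")
  expect_s3_class(generics::tidy(cmp1), "tbl_df")
  expect_equal(generics::glance(cmp1), cmp1$summary)
})
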