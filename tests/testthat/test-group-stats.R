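test_that("Wilcoxon rank-sum matches hand-derived small cases", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$U, 0)
  expect_equal(w$p, 0.1)
  expect_equal(wilcoxon_rank_sum(5, 5)$p, 1)
  expect_equal(wilcoxon_rank_sum(c(0.9, 0.4), c(0.5, 0.1))$U, 3)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("U and its role-swapped complement sum to nA*nB; p symmetric", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1))
    a <- wilcoxon_rank_sum(x, y); b <- wilcoxon_rank_sum(y, x)
    expect_equal(a$U + b$U, length(x) * length(y))
    expect_equal(a$p, b$p)
  }
})

test_that("exact p equals full enumeration for tie-free n <= 5", {
  set.seed(3)
  for (i in 1:25) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- sample(seq(0.1, 10, by = 0.1), nx)
    y <- setdiff(seq(0.1, 10, by = 0.1), x)[seq_len(ny)]
    expect_equal(wilcoxon_rank_sum(x, y)$p, wilcox_p_enum(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation p-values agree on the 0.05 side
           for most tie-free small samples", {
  set.seed(7)
  n <- 200; same_side <- 0
  for (i in seq_len(n)) {
    x <- rnorm(sample(3:6, 1), mean = sample(c(0, 1.5), 1))
    y <- rnorm(sample(3:6, 1))
    p_exact <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    p_approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    same_side <- same_side + ((p_exact < 0.05) == (p_approx < 0.05))
  }
  expect_gte(same_side / n, 0.95)
})

test_that("median log10 fold-change handles zeros by flagging", {
  expect_equal(median_log10_fold_change(c(10, 10), c(1, 1)), 1)
  expect_equal(median_log10_fold_change(1:5, 1:5), 0)
  expect_equal(median_log10_fold_change(240, 3.78), 1.8027194419,
               tolerance = 1e-9)
  expect_identical(median_log10_fold_change(c(1, 2), c(0, 0)), Inf)
  expect_identical(median_log10_fold_change(c(0, 0), c(1, 2)), -Inf)
  expect_true(is.na(median_log10_fold_change(0, 0)))
})

test_that("Spearman age trend recovers monotone relations and flags
           degenerate input", {
  expect_equal(age_trend(1:5, 2 * (1:5))$rho, 1)
  expect_equal(age_trend(1:5, -(1:5)^3)$rho, -1)
  at <- age_trend(c(2, 8, 14, 18), c(80, 60, 30, 10))
  expect_equal(at$rho, -1)
  # invariance under strictly monotone transforms
  ages <- c(3, 7, 11, 15, 19); fr <- c(70, 55, 40, 20, 10)
  expect_equal(age_trend(exp(ages / 5), fr)$rho, age_trend(ages, fr)$rho)
  deg <- age_trend(c(1, 1, 1), c(2, 3, 4))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$rho))
  expect_error(age_trend(1:2, 1:2), "3")
})

test_that("compare_groups reports medians, fold change, stars and symmetry", {
  df <- tibble::tibble(group = rep(c("A", "B"), each = 4),
                       value = c(1, 2, 3, 4, 1, 2, 3, 4))
  res <- compare_groups(df, "feat", list(c("A", "B")))
  expect_equal(res$p, 1)
  expect_equal(res$log10_fc, 0)
  expect_equal(res$stars, "ns")
  df2 <- tibble::tibble(group = rep(c("A", "B"), each = 5),
                        value = c(10, 11, 12, 13, 14, 1, 2, 3, 4, 5))
  fwd <- compare_groups(df2, "feat", list(c("A", "B")))
  rev <- compare_groups(df2, "feat", list(c("B", "A")))
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$log10_fc, -rev$log10_fc)
  expect_equal(fwd$stars, "**")  # exact two-sided p = 2/choose(10,5)
  bh <- compare_groups(df2, "feat", list(c("A", "B"), c("B", "A")),
                       bh = TRUE)
  expect_true("p_adj" %in% names(bh))
  expect_error(compare_groups(df2, "feat", list(c("A", "Z"))), "Z")
})

test_that("significance stars follow the published convention", {
  expect_equal(stars_for_p(c(0.2, 0.04, 0.009, 9e-4, 9e-5)),
               c("ns", "*", "**", "***", "****"))
})
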