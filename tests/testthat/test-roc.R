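test_that("ROC curves and AUC match hand-counted pair fractions", {
  r <- roc_curve(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_equal(auc_mann_whitney(c(0.9, 0.4, 0.5, 0.1),
                                c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  # perfectly separated
  expect_equal(roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # anti-separated
  expect_equal(auc_mann_whitney(c(1, 2, 5, 6),
                                c(TRUE, TRUE, FALSE, FALSE)), 0)
  # fully tied scores collapse to the chance diagonal
  tied <- roc_curve(rep(3, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(tied$auc, 0.5)
  expect_equal(min(tied$points$fpr), 0)
  expect_equal(max(tied$points$tpr), 1)
  # one cross-class tie among 2 vs 2 donors: (3 + 0.5) / 4
  expect_equal(auc_mann_whitney(c(5, 3, 3, 1),
                                c(TRUE, TRUE, FALSE, FALSE)), 0.875)
})

test_that("curves run from (0,0) to (1,1) with monotone FPR/TPR", {
  set.seed(5)
  s <- rnorm(30); l <- rep(c(TRUE, FALSE), 15)
  r <- roc_curve(s, l)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("trapezoidal AUC equals the Mann-Whitney fraction on random
           tied instances", {
  set.seed(31)
  for (i in 1:300) {
    n1 <- sample(2:8, 1); n0 <- sample(2:8, 1)
    s <- sample(1:5, n1 + n0, replace = TRUE)  # heavy ties
    l <- c(rep(TRUE, n1), rep(FALSE, n0))
    expect_equal(roc_curve(s, l)$auc, auc_mann_whitney(s, l),
                 tolerance = 1e-9)
    expect_equal(auc_mann_whitney(s, l), auc_pairs_brute(s, l),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms and
           complements for tie-free scores", {
  set.seed(77)
  s <- runif(20); l <- rep(c(TRUE, FALSE), 10)
  expect_equal(auc_mann_whitney(exp(3 * s), l), auc_mann_whitney(s, l))
  expect_equal(roc_curve(exp(3 * s), l)$auc, roc_curve(s, l)$auc)
  expect_equal(auc_mann_whitney(s, l) + auc_mann_whitney(-s, l), 1)
})

test_that("infinite sentinel scores rank above all finite scores", {
  expect_equal(roc_curve(c(Inf, 5, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(auc_mann_whitney(c(Inf, Inf, 0.1, 3),
                                c(TRUE, TRUE, FALSE, FALSE)), 1)
  # sentinels tie among themselves at the top rank
  expect_equal(auc_mann_whitney(c(Inf, Inf, 1), c(TRUE, FALSE, FALSE)), 0.75)
})

test_that("single-class input is rejected", {
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  expect_error(auc_mann_whitney(1:3, c(FALSE, FALSE, FALSE)), "both classes")
})

test_that("roc_summary evaluates AMR and coNCS over the present contrasts", {
  set.seed(2)
  sc <- tibble::tibble(
    donor_id = sprintf("d%02d", 1:20),
    group = rep(c("MS", "MOGAD", "otherADS", "NIND"), each = 5),
    amr = c(runif(5, 1, 2), runif(5, 0, 0.3), runif(5, 0, 0.3),
            runif(5, 0, 0.1)),
    concs = c(runif(5, 100, 300), runif(5, 0, 60), runif(5, 0, 60),
              runif(5, 0, 10)))
  rs <- roc_summary(sc)
  expect_equal(nrow(rs$summary), 6)
  expect_setequal(unique(rs$summary$contrast),
                  c("MS-vs-MOGAD", "MS-vs-otherADS", "MS-vs-MOGAD/otherADS"))
  expect_true(all(rs$summary$auc == 1))
  expect_equal(rs$summary$n_pos, rep(5L, 6))
})
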