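test_that("frequencies on the worked example match hand arithmetic", {
  cnt <- apply_gate_tree(toy_events(), default_gate_tree(),
                         default_thresholds())
  fr <- suppressMessages(population_frequencies(cnt))
  get <- function(p, col) fr[[col]][fr$population == p]
  expect_equal(get("T", "pct_leukocytes"), 2 / 7 * 100)
  expect_equal(get("T", "pct_lymphocytes"), 2 / 4 * 100)
  expect_equal(get("CD4", "pct_T"), 50)
  expect_equal(get("leukocytes", "pct_parent"), 7 / 8 * 100)
  expect_true(is.na(get("CD14_myeloid", "pct_lymphocytes")))
  expect_true(is.na(get("B", "pct_T")))
})

test_that("zero denominators yield frequency 0 with a flag, not NA", {
  ev <- toy_events()[c(1, 5, 7), ]  # no T cells at all
  cnt <- apply_gate_tree(ev, default_gate_tree(), default_thresholds())
  expect_message(fr <- population_frequencies(cnt), "zero denominator")
  expect_equal(fr$pct_T[fr$population == "CD4"], 0)
  expect_true("CD4" %in% attr(fr, "zero_denominator"))
})

test_that("cells_per_ml converts frequency and concentration", {
  expect_equal(cells_per_ml(10, 0.63), 63)
  expect_equal(cells_per_ml(0, 5), 0)
  expect_equal(cells_per_ml(100, 1), 1000)
  expect_error(cells_per_ml(120, 1), "100")
  expect_error(cells_per_ml(10, -1), "non-negative")
})

test_that("doubling concentration doubles counts and fixes frequencies", {
  cfg <- tiny_config("MS", clamp = c(1000L, 1000L))
  d <- simulate_donor(cfg, "MS", 4, donor_id = "MS_01")
  cnt <- list(MS_01 = apply_gate_tree(d$events, donor_id = "MS_01"))
  meta <- d$record
  tab1 <- population_table(cnt, meta)
  meta2 <- meta
  meta2$concentration_cells_per_uL <- 2 * meta$concentration_cells_per_uL
  tab2 <- population_table(cnt, meta2)
  expect_equal(tab2$cells_per_ml, 2 * tab1$cells_per_ml)
  expect_equal(tab2$pct_leukocytes, tab1$pct_leukocytes)
})

test_that("percent-of-parent sums to 100 over exhaustive partitions", {
  cfg <- tiny_config("MOGAD", clamp = c(2000L, 2000L))
  d <- simulate_donor(cfg, "MOGAD", 6)
  fr <- suppressMessages(population_frequencies(apply_gate_tree(d$events)))
  subsets <- c("CD4", "CD8", "DN", "DP")
  expect_equal(sum(fr$pct_parent[fr$population %in% subsets]), 100,
               tolerance = 1e-9)
  quadrants <- c("CD4_naive", "CD4_CM", "CD4_EM", "CD4_TEMRA")
  expect_equal(sum(fr$pct_parent[fr$population %in% quadrants]), 100,
               tolerance = 1e-9)
})

test_that("cohort_summary uses the mean-of-middle median convention", {
  tab <- tibble::tibble(
    donor_id = letters[1:4], group = "NIND", population = "B",
    cells_per_ml = c(1, 2, 3, 4))
  s <- cohort_summary(tab, "cells_per_ml", "B", "NIND")
  expect_equal(s$median, 2.5)
  expect_equal(c(s$min, s$max), c(1, 4))
  s3 <- cohort_summary(tab[1:3, ], "cells_per_ml", "B", "NIND")
  expect_equal(s3$median, 2)
  s1 <- cohort_summary(tab[1, ], "cells_per_ml", "B", "NIND")
  expect_equal(s1$median, 1)
  expect_error(cohort_summary(tab, "cells_per_ml", "B", "MS"), "no donors")
})
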