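test_that("naive CD8 fraction follows the clamped linear age model", {
  params <- c(intercept = 0.74, slope = 0.0467, lo = 0.02, hi = 0.95)
  expect_equal(naive_cd8_fraction(11, params), 0.2263)
  expect_equal(naive_cd8_fraction(0, params), 0.74)
  expect_equal(naive_cd8_fraction(100, params), 0.02)
  ages <- seq(0, 40, by = 0.5)
  expect_true(all(diff(naive_cd8_fraction(ages, params)) <= 0))
  expect_true(all(naive_cd8_fraction(ages, params) >= 0 &
                    naive_cd8_fraction(ages, params) <= 1))
})

test_that("simulate_donor is bit-identical under a fixed seed and leaves the
           caller's RNG state alone", {
  cfg <- tiny_config("NIND")
  set.seed(123); before <- runif(1)
  set.seed(123)
  a <- simulate_donor(cfg, "NIND", 7)
  expect_identical(runif(1), before)
  b <- simulate_donor(cfg, "NIND", 7)
  expect_identical(a, b)
  c <- simulate_donor(cfg, "NIND", 8)
  expect_false(identical(a$record$concentration_cells_per_uL,
                         c$record$concentration_cells_per_uL))
})

test_that("a degenerate all-T composition yields only T-lineage labels", {
  cfg <- tiny_config("NIND", clamp = c(5000L, 5000L))
  cfg$groups$NIND$composition[] <- 0
  cfg$groups$NIND$composition[["T"]] <- 1
  cfg$dirichlet_conc <- Inf
  d <- simulate_donor(cfg, "NIND", 3)
  expect_true(all(startsWith(d$events$latent_label, "T|")))
})

test_that("latent lineage proportions recover the configured composition
           within four binomial standard errors", {
  cfg <- tiny_config("NIND", clamp = c(10000L, 10000L))
  cfg$dirichlet_conc <- Inf  # isolate the multinomial layer
  d <- simulate_donor(cfg, "NIND", 11)
  p <- cfg$groups$NIND$composition
  counts <- latent_population_counts(
    d$events$latent_label,
    c("T", "CD14_myeloid", "NK", "DC", "B", "PMN", "unassigned"))
  phat <- counts$count / 10000
  names(phat) <- c("T", "myeloid", "NK", "DC", "B", "PMN", "unassigned")
  for (k in names(p))
    expect_lt(abs(phat[[k]] - p[[k]]), 4 * sqrt(p[[k]] * (1 - p[[k]]) / 1e4))
})

test_that("event counts derive from concentration, volume and the clamp", {
  cfg <- tiny_config("NIND", clamp = c(200L, 50000L))
  for (seed in 1:5) {
    d <- simulate_donor(cfg, "NIND", seed)
    expected <- round(d$record$concentration_cells_per_uL * 3 * 1000)
    expect_equal(nrow(d$events), min(max(expected, 200), 50000))
  }
})

test_that("ASC zero-inflation hits the configured donor fraction", {
  cfg <- build_default_config("MOGAD", event_clamp = c(300L, 300L))
  cfg$groups$MOGAD$conc_median <- 0.1
  cfg$groups$MOGAD$composition[] <- 0
  cfg$groups$MOGAD$composition[["B"]] <- 0.2
  cfg$groups$MOGAD$composition[["T"]] <- 0.8
  n_donors <- 150
  zero_asc <- vapply(seq_len(n_donors), function(s) {
    d <- simulate_donor(cfg, "MOGAD", 1000 + s)
    !any(d$events$latent_label == "B|ASC")
  }, TRUE)
  se <- sqrt(0.25 / n_donors)
  expect_lt(abs(mean(zero_asc) - 0.5), 4 * se)
})

test_that("simulate_cohort honors group sizes, labels and the seed ladder", {
  cfg <- tiny_config(c("NIND", "MS"), n_donors = 4L)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$metadata), 8L)
  expect_equal(sum(cohort$metadata$group == "NIND"), 4L)
  expect_named(cohort$events, cohort$metadata$donor_id)
  # deterministic rerun
  again <- simulate_cohort(cfg)
  expect_identical(cohort, again)
  # different master seed changes the draws
  cfg2 <- cfg; cfg2$master_seed <- 999L
  other <- simulate_cohort(cfg2)
  expect_false(identical(cohort$metadata$concentration_cells_per_uL,
                         other$metadata$concentration_cells_per_uL))
  # ages fall in the configured ranges
  expect_true(all(cohort$metadata$age >= 2.6 & cohort$metadata$age <= 19.4))
})
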