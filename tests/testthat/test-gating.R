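test_that("the default tree is structurally valid and places ASC under B", {
  tree <- default_gate_tree()
  expect_silent(validate_gate_tree(tree))
  names <- vapply(tree, `[[`, "", "name")
  asc <- tree[[which(names == "ASC")]]
  expect_equal(asc$parent, "B")
  non_asc <- tree[[which(names == "non_ASC")]]
  expect_equal(non_asc$complement_of, "ASC")
  expect_equal(tree[[which(names == "lymphocytes")]]$union_of,
               c("T", "B", "NK"))
})

test_that("hand-gated eight-event worked example reproduces frozen counts", {
  cnt <- apply_gate_tree(toy_events(), default_gate_tree(),
                         default_thresholds())
  get <- function(p) cnt$count[cnt$population == p]
  expect_equal(get("leukocytes"), 7L)
  expect_equal(get("T"), 2L)
  expect_equal(get("B"), 1L)
  expect_equal(get("ASC"), 1L)
  expect_equal(get("NK"), 1L)
  expect_equal(get("DC"), 1L)
  expect_equal(get("CD14_myeloid"), 1L)
  expect_equal(get("PMN"), 1L)
  expect_equal(get("CD4"), 1L)
  expect_equal(get("CD8"), 1L)
  expect_equal(get("CD4_CM"), 1L)
  expect_equal(get("CD8_naive"), 1L)
})

test_that("empty input gives all-zero counts", {
  cnt <- apply_gate_tree(blank_events(0), default_gate_tree(),
                         default_thresholds())
  expect_true(all(cnt$count == 0L))
  expect_equal(attr(cnt, "n_events"), 0L)
})

test_that("gating is invariant under row permutation and nested in counts", {
  cfg <- tiny_config("MS", clamp = c(2000L, 2000L))
  d <- simulate_donor(cfg, "MS", 5)
  tree <- default_gate_tree()
  cnt <- apply_gate_tree(d$events, tree, default_thresholds())
  perm <- d$events[sample(nrow(d$events)), ]
  cnt2 <- apply_gate_tree(perm, tree, default_thresholds())
  expect_equal(cnt$count, cnt2$count)
  # monotone nesting: descendant counts never exceed any ancestor's
  byname <- stats::setNames(cnt$count, cnt$population)
  for (node in tree) {
    if (is.na(node$parent)) next
    expect_lte(byname[[node$name]], byname[[node$parent]])
  }
})

test_that("exhaustive sibling partitions conserve the parent count exactly", {
  cfg <- tiny_config("MOGAD", clamp = c(3000L, 3000L))
  d <- simulate_donor(cfg, "MOGAD", 21)
  cnt <- apply_gate_tree(d$events, default_gate_tree(),
                         default_thresholds())
  byname <- stats::setNames(cnt$count, cnt$population)
  expect_identical(byname[["CD4"]] + byname[["CD8"]] + byname[["DN"]] +
                     byname[["DP"]], byname[["T"]])
  expect_identical(byname[["CD4_naive"]] + byname[["CD4_CM"]] +
                     byname[["CD4_EM"]] + byname[["CD4_TEMRA"]],
                   byname[["CD4"]])
  expect_identical(byname[["CD4_memory"]],
                   byname[["CD4_CM"]] + byname[["CD4_EM"]] +
                     byname[["CD4_TEMRA"]])
  expect_identical(byname[["Th1_like"]] + byname[["Th17_like"]] +
                     byname[["Th_DP"]] + byname[["Th_DN"]],
                   byname[["CD4_memory"]])
  expect_identical(byname[["ASC"]] + byname[["non_ASC"]], byname[["B"]])
})

test_that("gated counts agree with latent labels to within 0.1% of events", {
  cfg <- tiny_config("MS", clamp = c(10000L, 10000L))
  d <- simulate_donor(cfg, "MS", 31)
  cnt <- apply_gate_tree(d$events, default_gate_tree(),
                         default_thresholds())
  lat <- latent_population_counts(d$events$latent_label, cnt$population)
  expect_true(all(abs(cnt$count - lat$count) < 0.001 * nrow(d$events)))
})

test_that("a referenced channel missing from the events is named", {
  ev <- toy_events()
  ev$CD3 <- NULL
  expect_error(apply_gate_tree(ev, default_gate_tree(),
                               default_thresholds()), "CD3")
})

test_that("gate trees round-trip through YAML", {
  tree <- default_gate_tree()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gate_tree_yaml(tree, path)
  back <- read_gate_tree_yaml(path)
  expect_equal(vapply(back, `[[`, "", "name"),
               vapply(tree, `[[`, "", "name"))
  cnt1 <- apply_gate_tree(toy_events(), tree, default_thresholds())
  cnt2 <- apply_gate_tree(toy_events(), back, default_thresholds())
  expect_equal(cnt1$count, cnt2$count)
})
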