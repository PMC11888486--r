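#' Run the full simulate-gate-summarize-score-compare-ROC pipeline
#'
#' Simulates the configured cohort, estimates per-donor thresholds, applies
#' the gate tree, builds the population table and score records, runs the
#' standard cross-group comparisons (pooled-ADS absolute counts against each
#' control group; MS/MOGAD/otherADS frequency contrasts), evaluates the AMR
#' and coNCS ROC classifiers, and writes every artifact plus a run manifest
#' to `out_dir`. Re-running with the same configuration and seed reproduces
#' identical CSV contents (the manifest timestamp aside).
#'
#' @param config A `csf_cohort_config`.
#' @param out_dir Output directory (created if needed).
#' @param threshold_method `"midpoint-mixture"` (default) or `"fixed"`.
#' @param tree Gate tree.
#' @param bh Append Benjamini-Hochberg adjusted p-values to comparisons.
#' @param write_events Also write one events CSV per donor (the slowest
#'   artifact; disable for large cohorts).
#' @return Invisibly, a list with `metadata`, `counts`, `table`, `scores`,
#'   `comparisons`, `roc`, and `manifest`.
#' @export
csf_run_all <- function(config = build_default_config(),
                        out_dir,
                        threshold_method = c("midpoint-mixture", "fixed"),
                        tree = default_gate_tree(),
                        bh = FALSE,
                        write_events = TRUE) {
  threshold_method <- match.arg(threshold_method)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, stage) {
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  }

  t0 <- tic()
  cohort <- simulate_cohort(config)
  toc(t0, "simulate")

  t0 <- tic()
  counts <- lapply(names(cohort$events), function(id) {
    ev <- cohort$events[[id]]
    th <- suppressWarnings(
      estimate_thresholds(ev, threshold_method))
    apply_gate_tree(ev, tree, th, donor_id = id)
  })
  names(counts) <- names(cohort$events)
  toc(t0, "gate")

  t0 <- tic()
  tab <- population_table(counts, cohort$metadata, tree)
  toc(t0, "summarize")

  t0 <- tic()
  scores <- if ("NIND" %in% cohort$metadata$group)
    compute_score_table(tab, cohort$metadata) else NULL
  toc(t0, "score")

  t0 <- tic()
  comparisons <- standard_comparisons(tab, bh = bh)
  toc(t0, "compare")

  t0 <- tic()
  roc <- if (!is.null(scores) &&
             "MS" %in% scores$group &&
             any(scores$group %in% c("MOGAD", "otherADS")))
    roc_summary(scores) else NULL
  toc(t0, "roc")

  paths <- list(metadata = file.path(out_dir, "metadata.csv"),
                counts = file.path(out_dir, "counts.csv"),
                table = file.path(out_dir, "population_table.csv"),
                config = file.path(out_dir, "config.yaml"))
  write_metadata_csv(cohort$metadata, paths$metadata)
  write_counts_csv(counts, paths$counts)
  utils::write.csv(as.data.frame(tab), paths$table, row.names = FALSE)
  write_config_yaml(config, paths$config)
  if (!is.null(scores)) {
    paths$scores <- file.path(out_dir, "scores.csv")
    utils::write.csv(as.data.frame(scores), paths$scores, row.names = FALSE)
  }
  if (!is.null(comparisons)) {
    paths$comparisons <- file.path(out_dir, "comparisons.csv")
    utils::write.csv(as.data.frame(comparisons), paths$comparisons,
                     row.names = FALSE)
  }
  if (!is.null(roc)) {
    paths$roc_summary <- file.path(out_dir, "roc_summary.csv")
    utils::write.csv(as.data.frame(roc$summary), paths$roc_summary,
                     row.names = FALSE)
    pts <- do.call(rbind, lapply(roc$curves, function(r)
      cbind(contrast = r$contrast, score = r$score_name,
            as.data.frame(r$points))))
    paths$roc_points <- file.path(out_dir, "roc_points.csv")
    utils::write.csv(pts, paths$roc_points, row.names = FALSE)
  }
  if (write_events) {
    ev_dir <- file.path(out_dir, "events")
    dir.create(ev_dir, showWarnings = FALSE)
    for (id in names(cohort$events))
      write_events_csv(cohort$events[[id]],
                       file.path(ev_dir, paste0(id, ".csv")))
    paths$events_dir <- ev_dir
  }

  manifest <- list(
    package = "cytocsf",
    version = as.character(utils::packageVersion("cytocsf")),
    master_seed = config$master_seed,
    threshold_method = threshold_method,
    groups = names(config$groups),
    outputs = lapply(paths, normalizePath),
    stage_seconds = as.list(timings),
    created = format(Sys.time(), tz = "UTC"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(metadata = cohort$metadata, counts = counts, table = tab,
                 scores = scores, comparisons = comparisons, roc = roc,
                 manifest = manifest))
}

# The comparisons the analysis routinely reports: pooled-ADS vs each control
# group on absolute lineage counts, and the three ADS-subtype contrasts on
# B/ASC/CD14 frequencies. Pairs whose groups are absent are skipped.
standard_comparisons <- function(tab, bh = FALSE) {
  groups <- unique(tab$group)
  ads <- intersect(c("MS", "MOGAD", "otherADS"), groups)
  out <- list()
  if (length(ads)) {
    pooled <- tab
    pooled$group[pooled$group %in% ads] <- "ADS"
    controls <- intersect(c("NIND", "PIND", "AIE", "IDWM"), groups)
    for (popn in c("T", "CD14_myeloid", "NK", "DC", "PMN", "B")) {
      df <- extract_feature(pooled, popn, "cells_per_ml")
      cmps <- lapply(controls, function(g) c("ADS", g))
      if (length(cmps))
        out[[paste0(popn, "_counts")]] <-
          compare_groups(df, paste0(popn, ":cells_per_ml"), cmps, bh = bh)
    }
  }
  subtype_pairs <- list(c("MS", "MOGAD"), c("MS", "otherADS"),
                        c("MOGAD", "otherADS"))
  subtype_pairs <- Filter(function(p) all(p %in% groups), subtype_pairs)
  if (length(subtype_pairs)) {
    for (popn in c("B", "ASC", "CD14_myeloid")) {
      df <- extract_feature(tab, popn, "pct_leukocytes")
      out[[paste0(popn, "_freq")]] <-
        compare_groups(df, paste0(popn, ":pct_leukocytes"), subtype_pairs,
                       bh = bh)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
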