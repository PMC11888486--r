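# Frequency and absolute-count measures derived from population counts.

# ancestry helpers on a gate tree
tree_parents <- function(tree) {
  stats::setNames(vapply(tree, `[[`, "", "parent"),
                  vapply(tree, `[[`, "", "name"))
}

# nodes whose frequency is interpretable as % of lymphocytes / % of T cells
lymphoid_nodes <- function(tree) {
  parents <- tree_parents(tree)
  seeds <- c("lymphocytes", "T", "B", "NK")
  out <- intersect(seeds, names(parents))
  repeat {
    add <- names(parents)[parents %in% out & !(names(parents) %in% out)]
    if (!length(add)) break
    out <- c(out, add)
  }
  out
}

descendants_of <- function(tree, root) {
  parents <- tree_parents(tree)
  out <- root
  repeat {
    add <- names(parents)[parents %in% out & !(names(parents) %in% out)]
    if (!length(add)) break
    out <- c(out, add)
  }
  out
}

#' Population frequencies under the standard denominators
#'
#' Converts gate-tree counts into percentages: of the immediate parent
#' population (for the root, of all acquired events), of CD45+ leukocytes,
#' of lymphocytes (T+B+NK and their subsets only), and of CD3+ T cells (T
#' lineage only). A zero denominator yields frequency 0 and the affected
#' populations are reported in the `zero_denominator` attribute (and as a
#' message), rather than as missing values, so downstream score zero-rules
#' apply without special cases.
#'
#' @param counts A `csf_population_counts` from [apply_gate_tree()].
#' @param tree The gate tree the counts were produced with.
#' @return Tibble with columns `population`, `count`, `pct_parent`,
#'   `pct_leukocytes`, `pct_lymphocytes`, `pct_T` (NA where a denominator
#'   does not apply).
#' @export
population_frequencies <- function(counts, tree = default_gate_tree()) {
  if (!all(vapply(tree, `[[`, "", "name") == counts$population))
    stop_cytocsf("counts do not match the gate tree's populations")
  cnt <- stats::setNames(counts$count, counts$population)
  parents <- tree_parents(tree)
  n_total <- attr(counts, "n_events") %||% cnt[["leukocytes"]]

  zero_flag <- character()
  pct <- function(num, den, pop) {
    if (is.na(den)) return(NA_real_)
    if (den == 0) {
      zero_flag <<- c(zero_flag, pop)
      return(0)
    }
    100 * num / den
  }

  lymph <- lymphoid_nodes(tree)
  t_nodes <- descendants_of(tree, "T")
  out <- counts
  out$pct_parent <- out$pct_leukocytes <- out$pct_lymphocytes <-
    out$pct_T <- NA_real_
  for (i in seq_len(nrow(out))) {
    p <- out$population[i]
    den_parent <- if (is.na(parents[[p]])) n_total else cnt[[parents[[p]]]]
    out$pct_parent[i] <- pct(cnt[[p]], den_parent, p)
    out$pct_leukocytes[i] <- pct(cnt[[p]], cnt[["leukocytes"]], p)
    if (p %in% lymph)
      out$pct_lymphocytes[i] <- pct(cnt[[p]], cnt[["lymphocytes"]], p)
    if (p %in% t_nodes)
      out$pct_T[i] <- pct(cnt[[p]], cnt[["T"]], p)
  }
  zero_flag <- unique(zero_flag)
  if (length(zero_flag))
    message("zero denominator; frequency set to 0 for: ",
            paste(zero_flag, collapse = ", "))
  attr(out, "zero_denominator") <- zero_flag
  out
}

#' Absolute counts from frequency and concentration
#'
#' `cells/mL = (frequency / 100) * concentration_cells_per_uL * 1000`.
#'
#' @param frequency_of_leukocytes Frequency in percent of CD45+ leukocytes
#'   (in `[0, 100]`).
#' @param concentration CSF cell concentration in cells/uL (>= 0), as counted
#'   on a hemocytometer.
#' @return Absolute count in cells/mL.
#' @export
#' @examples
#' cells_per_ml(10, 0.63)  # 63
cells_per_ml <- function(frequency_of_leukocytes, concentration) {
  assert_pct(frequency_of_leukocytes, "frequency")
  assert_nonneg(concentration, "concentration")
  (frequency_of_leukocytes / 100) * concentration * 1000
}

#' Per-donor population table for a gated cohort
#'
#' Gates every donor, derives all denominator frequencies and absolute
#' counts, and stacks the result in long format.
#'
#' @param counts_by_donor Named list of `csf_population_counts`, keyed by
#'   donor id (e.g. one [apply_gate_tree()] result per donor).
#' @param metadata Donor metadata tibble (needs `donor_id`, `group`,
#'   `concentration_cells_per_uL`).
#' @param tree The gate tree used to produce the counts.
#' @return Tidy tibble: donor_id, group, population, count, pct_parent,
#'   pct_leukocytes, pct_lymphocytes, pct_T, cells_per_ml.
#' @export
population_table <- function(counts_by_donor, metadata,
                             tree = default_gate_tree()) {
  rows <- lapply(names(counts_by_donor), function(id) {
    meta <- metadata[metadata$donor_id == id, ]
    if (nrow(meta) != 1)
      stop_cytocsf("donor '", id, "' not found (once) in metadata")
    fr <- suppressMessages(
      population_frequencies(counts_by_donor[[id]], tree))
    fr$donor_id <- id
    fr$group <- meta$group
    fr$cells_per_ml <- cells_per_ml(fr$pct_leukocytes,
                                    meta$concentration_cells_per_uL)
    fr[, c("donor_id", "group", "population", "count", "pct_parent",
           "pct_leukocytes", "pct_lymphocytes", "pct_T", "cells_per_ml")]
  })
  do.call(rbind, rows)
}

#' Cohort summary of one measure
#'
#' Median (mean-of-middle-two convention for even n), minimum and maximum of
#' a population-table measure over the donors of one group.
#'
#' @param table Population table from [population_table()] (or any tibble
#'   with `group`, `population` and the measure column).
#' @param measure Column name, e.g. `"cells_per_ml"` or `"pct_leukocytes"`.
#' @param population Population name.
#' @param group Group label.
#' @return One-row tibble: group, population, measure, n, median, min, max.
#' @export
cohort_summary <- function(table, measure, population, group) {
  if (!measure %in% names(table))
    stop_cytocsf("unknown measure '", measure, "'")
  v <- table[[measure]][table$group == group &
                          table$population == population]
  if (!length(v))
    stop_cytocsf("no donors for group '", group, "' and population '",
                 population, "'")
  tibble::tibble(group = group, population = population, measure = measure,
                 n = length(v), median = stats::median(v),
                 min = min(v), max = max(v))
}

#' Extract one feature per donor
#'
#' Convenience accessor pulling a single (population, measure) pair out of a
#' population table, one row per donor.
#'
#' @inheritParams cohort_summary
#' @return Tibble: donor_id, group, value.
#' @export
extract_feature <- function(table, population, measure) {
  sub <- table[table$population == population, ]
  if (!nrow(sub)) stop_cytocsf("unknown population '", population, "'")
  if (!measure %in% names(sub)) stop_cytocsf("unknown measure '", measure, "'")
  tibble::tibble(donor_id = sub$donor_id, group = sub$group,
                 value = sub[[measure]])
}
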