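# Declarative hierarchical gating: a gate tree is an ordered list of
# population definitions. A node is either
#   * a conjunction of marker-state predicates applied within its parent,
#   * a union of previously defined sibling nodes (e.g. memory = CM+EM+TEMRA),
#   * or the complement of a sibling within the parent (e.g. non-ASC B cells).
# Marker states: pos (>= primary threshold), neg/lo (< primary),
# hi (>= high threshold).

gate_node <- function(name, parent, predicates = list(), union_of = NULL,
                      complement_of = NULL) {
  list(name = name, parent = parent, predicates = predicates,
       union_of = union_of, complement_of = complement_of)
}

pred <- function(channel, state) list(channel = channel, state = state)

#' The default CSF gating hierarchy
#'
#' Encodes the population definitions used throughout the package:
#' CD45+ leukocytes split into PMN (SSC-high), CD14+ myeloid (CD14+), and
#' CD14-/SSC-low non-myeloid cells; non-myeloid cells into T (CD3+CD19-),
#' B (CD19+CD3-), NK (CD3-CD19-CD56+), DC (CD3-CD19-CD56-HLA-DR+CD11c+) and
#' lineage-negative `unassigned` cells, with `lymphocytes` the union of T, B
#' and NK. T cells partition into CD4/CD8/DN/DP (with an overlapping NKT =
#' CD3+CD56+ overlay); CD4 and CD8 each split on the CD27 x CD45RA plane into
#' naive/CM/EM/TEMRA with `memory` the union of the three non-naive
#' quadrants; memory CD4 carries the four CXCR3 x CCR6 quadrants and a
#' CD38+HLA-DR+ activated gate, memory CD8 an activated gate; Treg =
#' CD4+CD25+CD127-low; ASC = CD19+CD27-high CD38-high with `non_ASC` its
#' complement within B.
#'
#' @return A `csf_gate_tree` object (ordered list of population definitions).
#' @export
#' @examples
#' tree <- default_gate_tree()
#' vapply(tree, `[[`, "", "name")
default_gate_tree <- function() {
  nodes <- list(
    gate_node("leukocytes", NA_character_, list(pred("CD45", "pos"))),
    gate_node("PMN", "leukocytes", list(pred("SSC", "hi"))),
    gate_node("CD14_myeloid", "leukocytes", list(pred("CD14", "pos"))),
    gate_node("non_myeloid", "leukocytes",
              list(pred("CD14", "neg"), pred("SSC", "lo"))),
    gate_node("T", "non_myeloid",
              list(pred("CD3", "pos"), pred("CD19", "neg"))),
    gate_node("B", "non_myeloid",
              list(pred("CD19", "pos"), pred("CD3", "neg"))),
    gate_node("NK", "non_myeloid",
              list(pred("CD3", "neg"), pred("CD19", "neg"),
                   pred("CD56", "pos"))),
    gate_node("DC", "non_myeloid",
              list(pred("CD3", "neg"), pred("CD19", "neg"),
                   pred("CD56", "neg"), pred("HLA-DR", "pos"),
                   pred("CD11c", "pos"))),
    gate_node("unassigned", "non_myeloid",
              list(pred("CD3", "neg"), pred("CD19", "neg"),
                   pred("CD56", "neg"), pred("HLA-DR", "neg"),
                   pred("CD11c", "neg"))),
    gate_node("lymphocytes", "non_myeloid", union_of = c("T", "B", "NK")),
    gate_node("CD4", "T", list(pred("CD4", "pos"), pred("CD8", "neg"))),
    gate_node("CD8", "T", list(pred("CD8", "pos"), pred("CD4", "neg"))),
    gate_node("DN", "T", list(pred("CD4", "neg"), pred("CD8", "neg"))),
    gate_node("DP", "T", list(pred("CD4", "pos"), pred("CD8", "pos"))),
    gate_node("NKT", "T", list(pred("CD56", "pos"))),
    gate_node("CD4_naive", "CD4",
              list(pred("CD27", "pos"), pred("CD45RA", "pos"))),
    gate_node("CD4_CM", "CD4",
              list(pred("CD27", "pos"), pred("CD45RA", "neg"))),
    gate_node("CD4_EM", "CD4",
              list(pred("CD27", "neg"), pred("CD45RA", "neg"))),
    gate_node("CD4_TEMRA", "CD4",
              list(pred("CD27", "neg"), pred("CD45RA", "pos"))),
    gate_node("CD4_memory", "CD4",
              union_of = c("CD4_CM", "CD4_EM", "CD4_TEMRA")),
    gate_node("Th1_like", "CD4_memory",
              list(pred("CXCR3", "pos"), pred("CCR6", "neg"))),
    gate_node("Th17_like", "CD4_memory",
              list(pred("CCR6", "pos"), pred("CXCR3", "neg"))),
    gate_node("Th_DP", "CD4_memory",
              list(pred("CXCR3", "pos"), pred("CCR6", "pos"))),
    gate_node("Th_DN", "CD4_memory",
              list(pred("CXCR3", "neg"), pred("CCR6", "neg"))),
    gate_node("CD4_activated", "CD4_memory",
              list(pred("CD38", "pos"), pred("HLA-DR", "pos"))),
    gate_node("Treg", "CD4", list(pred("CD25", "pos"), pred("CD127", "lo"))),
    gate_node("CD8_naive", "CD8",
              list(pred("CD27", "pos"), pred("CD45RA", "pos"))),
    gate_node("CD8_CM", "CD8",
              list(pred("CD27", "pos"), pred("CD45RA", "neg"))),
    gate_node("CD8_EM", "CD8",
              list(pred("CD27", "neg"), pred("CD45RA", "neg"))),
    gate_node("CD8_TEMRA", "CD8",
              list(pred("CD27", "neg"), pred("CD45RA", "pos"))),
    gate_node("CD8_memory", "CD8",
              union_of = c("CD8_CM", "CD8_EM", "CD8_TEMRA")),
    gate_node("CD8_activated", "CD8_memory",
              list(pred("CD38", "pos"), pred("HLA-DR", "pos"))),
    gate_node("ASC", "B", list(pred("CD27", "hi"), pred("CD38", "hi"))),
    gate_node("non_ASC", "B", complement_of = "ASC")
  )
  structure(nodes, class = "csf_gate_tree")
}

#' Validate a gate tree
#'
#' Checks the structural invariants: a single root named `leukocytes`, unique
#' node names, parents defined before children (so every node is reachable
#' from the root and ancestry is acyclic), and union/complement members
#' defined before use.
#'
#' @param tree A `csf_gate_tree`.
#' @param panel Channel names predicates may reference.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_gate_tree <- function(tree, panel = csf_marker_panel()) {
  names <- vapply(tree, `[[`, "", "name")
  if (anyDuplicated(names)) stop_cytocsf("gate tree names must be unique")
  roots <- which(vapply(tree, function(n) is.na(n$parent), TRUE))
  if (length(roots) != 1 || names[roots] != "leukocytes" || roots != 1)
    stop_cytocsf("gate tree must have the single root 'leukocytes' first")
  seen <- character()
  for (node in tree) {
    if (!is.na(node$parent) && !(node$parent %in% seen))
      stop_cytocsf("parent of '", node$name, "' must be defined before it")
    for (m in c(node$union_of, node$complement_of))
      if (!(m %in% seen))
        stop_cytocsf("member '", m, "' of '", node$name, "' is undefined")
    for (p in node$predicates) {
      if (!(p$channel %in% panel))
        stop_cytocsf("channel '", p$channel, "' is not in the panel")
      if (!(p$state %in% c("pos", "neg", "hi", "lo")))
        stop_cytocsf("unknown marker state '", p$state, "'")
    }
    seen <- c(seen, node$name)
  }
  invisible(tree)
}

#' Default fixed gating thresholds
#'
#' Primary (positive/negative) threshold 2.0 for every fluorescence channel,
#' matched to the default expression model (state means 0 and 4, sd 0.5, a
#' 4-sigma margin each side); high thresholds 5.0 for CD27 and CD38 (the
#' ASC-defining channels); side scatter splits low/high at 3.0.
#'
#' @return A tibble with columns `channel`, `primary`, `high` (NA where no
#'   high threshold is defined; for SSC the high threshold equals the
#'   low/high boundary).
#' @export
default_thresholds <- function() {
  panel <- csf_marker_panel()
  th <- tibble::tibble(channel = panel, primary = 2, high = NA_real_)
  th$high[th$channel %in% c("CD27", "CD38")] <- 5
  th$primary[th$channel == "SSC"] <- 3
  th$high[th$channel == "SSC"] <- 3
  th
}

validate_thresholds <- function(thresholds) {
  stopifnot(all(c("channel", "primary", "high") %in% names(thresholds)))
  bad <- !is.na(thresholds$high) & thresholds$high < thresholds$primary
  if (any(bad))
    stop_cytocsf("high threshold below primary for: ",
                 paste(thresholds$channel[bad], collapse = ", "))
  invisible(thresholds)
}

# events -> numeric matrix restricted to panel channels, erroring with the
# name of any referenced channel that is absent.
event_matrix <- function(events, channels) {
  missing <- setdiff(channels, colnames(events))
  if (length(missing))
    stop_cytocsf("events are missing channel(s): ",
                 paste(missing, collapse = ", "))
  as.matrix(as.data.frame(events, check.names = FALSE)[, channels,
                                                       drop = FALSE])
}

#' Apply a gate tree to an event matrix
#'
#' Hard (binary) hierarchical gating: an event belongs to a population iff it
#' satisfies the node's marker-state predicates and all of its ancestors';
#' values exactly at a threshold count as positive. Union and complement
#' nodes are resolved from their members' memberships, so exhaustive sibling
#' partitions (CD4/CD8/DN/DP; the CD27 x CD45RA and CXCR3 x CCR6 quadrants)
#' conserve their parent's count exactly.
#'
#' @param events Event tibble/data.frame (or matrix) whose columns cover the
#'   channels referenced by the tree; extra columns (e.g. `latent_label`) are
#'   ignored.
#' @param tree A `csf_gate_tree`.
#' @param thresholds Threshold tibble as from [default_thresholds()] or
#'   [estimate_thresholds()].
#' @param donor_id Optional donor identifier attached to the result.
#' @return A tibble of class `csf_population_counts` with columns
#'   `population` and `count`, attributes `n_events` and `donor_id`.
#' @export
#' @examples
#' cfg <- build_default_config("NIND")
#' d <- simulate_donor(cfg, "NIND", 7)
#' apply_gate_tree(d$events, default_gate_tree(), default_thresholds())
apply_gate_tree <- function(events, tree = default_gate_tree(),
                            thresholds = default_thresholds(),
                            donor_id = NA_character_) {
  validate_thresholds(thresholds)
  channels <- unique(unlist(lapply(tree, function(n)
    vapply(n$predicates, `[[`, "", "channel"))))
  n <- nrow(events)
  X <- if (n > 0) event_matrix(events, channels) else NULL

  eval_pred <- function(p) {
    row <- match(p$channel, thresholds$channel)
    if (is.na(row))
      stop_cytocsf("no threshold defined for channel '", p$channel, "'")
    primary <- thresholds$primary[row]
    high <- thresholds$high[row]
    v <- X[, p$channel]
    switch(p$state,
           pos = v >= primary,
           neg = v < primary,
           lo  = v < primary,
           hi  = {
             if (is.na(high))
               stop_cytocsf("state 'hi' needs a high threshold for '",
                            p$channel, "'")
             v >= high
           })
  }

  memb <- list()
  for (node in tree) {
    base <- if (is.na(node$parent)) rep(TRUE, n) else memb[[node$parent]]
    m <- if (!is.null(node$union_of)) {
      Reduce(`|`, memb[node$union_of])
    } else if (!is.null(node$complement_of)) {
      base & !memb[[node$complement_of]]
    } else if (n == 0) {
      logical(0)
    } else {
      Reduce(`&`, lapply(node$predicates, eval_pred), base)
    }
    memb[[node$name]] <- m
  }
  node_names <- vapply(tree, `[[`, "", "name")
  counts <- tibble::tibble(
    population = node_names,
    count = unname(vapply(memb, sum, 0L)[node_names]))
  attr(counts, "n_events") <- n
  attr(counts, "donor_id") <- donor_id
  class(counts) <- c("csf_population_counts", class(counts))
  counts
}

# Count events per gate-tree population from the generator's latent labels
# (synthetic data only); the independent oracle for gating accuracy.
#' Population counts implied by latent labels
#'
#' For synthetic event data carrying a `latent_label` column, counts the
#' events whose latent population corresponds to each gate-tree node. Used as
#' an oracle to measure gating accuracy.
#'
#' @param labels Character vector of latent labels.
#' @param populations Gate-tree node names to count.
#' @return Tibble with `population` and `count`.
#' @export
latent_population_counts <- function(labels,
                                     populations = vapply(default_gate_tree(),
                                                          `[[`, "", "name")) {
  is_t <- startsWith(labels, "T|")
  match_pop <- function(pop) {
    switch(pop,
      leukocytes = rep(TRUE, length(labels)),
      PMN = labels == "PMN",
      CD14_myeloid = labels == "myeloid",
      non_myeloid = !(labels %in% c("myeloid", "PMN")),
      T = is_t,
      B = startsWith(labels, "B|"),
      NK = labels == "NK",
      DC = labels == "DC",
      unassigned = labels == "unassigned",
      lymphocytes = is_t | startsWith(labels, "B|") | labels == "NK",
      CD4 = startsWith(labels, "T|CD4|"),
      CD8 = startsWith(labels, "T|CD8|"),
      DN = startsWith(labels, "T|DN|"),
      DP = startsWith(labels, "T|DP|"),
      NKT = is_t & grepl("|nkt", labels, fixed = TRUE),
      CD4_naive = startsWith(labels, "T|CD4|naive"),
      CD4_CM = startsWith(labels, "T|CD4|CM"),
      CD4_EM = startsWith(labels, "T|CD4|EM"),
      CD4_TEMRA = startsWith(labels, "T|CD4|TEMRA"),
      CD4_memory = startsWith(labels, "T|CD4|") &
        !startsWith(labels, "T|CD4|naive"),
      Th1_like = grepl("\\|Th1\\b", labels),
      Th17_like = grepl("\\|Th17\\b", labels),
      Th_DP = grepl("\\|ThDP\\b", labels),
      Th_DN = grepl("\\|ThDN\\b", labels),
      CD4_activated = startsWith(labels, "T|CD4|") &
        !startsWith(labels, "T|CD4|naive") &
        grepl("|act", labels, fixed = TRUE),
      Treg = grepl("|treg", labels, fixed = TRUE),
      CD8_naive = startsWith(labels, "T|CD8|naive"),
      CD8_CM = startsWith(labels, "T|CD8|CM"),
      CD8_EM = startsWith(labels, "T|CD8|EM"),
      CD8_TEMRA = startsWith(labels, "T|CD8|TEMRA"),
      CD8_memory = startsWith(labels, "T|CD8|") &
        !startsWith(labels, "T|CD8|naive"),
      CD8_activated = startsWith(labels, "T|CD8|") &
        !startsWith(labels, "T|CD8|naive") &
        grepl("|act", labels, fixed = TRUE),
      ASC = labels == "B|ASC",
      non_ASC = labels == "B|nonASC",
      stop_cytocsf("no latent mapping for population '", pop, "'"))
  }
  tibble::tibble(population = populations,
                 count = unname(vapply(populations,
                                       function(p) sum(match_pop(p)), 0L)))
}
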