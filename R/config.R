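#' @keywords internal
csf_group_labels <- function() {
  c("NIND", "PIND", "AIE", "IDWM", "otherADS", "MOGAD", "MS")
}

# Built-in per-group generative parameters.
#
# NIND leukocyte composition and T-subset fractions are anchored on the
# published cohort medians; the inflammatory groups are direction-constrained
# (higher cellularity than NIND; strong B-cell enrichment in all demyelinating
# groups; MS with elevated ASC, depressed CD14+ myeloid and near-absent PMN
# relative to MOGAD/other ADS). See the methods vignette for rationale.
group_defaults_table <- function() {
  comp <- function(T, myeloid, NK, DC, B, PMN) {
    x <- c(T = T, myeloid = myeloid, NK = NK, DC = DC, B = B, PMN = PMN)
    c(x, unassigned = 1 - sum(x))
  }
  list(
    NIND = list(
      n_donors = 33L, age_range = c(2.6, 19.4),
      conc_median = 0.63, conc_log_sd = 0.9,
      composition = comp(0.673, 0.129, 0.043, 0.016, 0.006, 0.003),
      asc_of_b = 0.02, asc_zero_p = 0, treated_prob = 0),
    PIND = list(
      n_donors = 7L, age_range = c(3.5, 19.4),
      conc_median = 0.8, conc_log_sd = 0.6,
      composition = comp(0.65, 0.15, 0.04, 0.015, 0.010, 0.005),
      asc_of_b = 0.02, asc_zero_p = 0, treated_prob = 0),
    AIE = list(
      n_donors = 6L, age_range = c(8.7, 19),
      conc_median = 1.2, conc_log_sd = 0.6,
      composition = comp(0.68, 0.12, 0.04, 0.015, 0.015, 0.005),
      asc_of_b = 0.03, asc_zero_p = 0, treated_prob = 0),
    IDWM = list(
      n_donors = 4L, age_range = c(1.3, 17.2),
      conc_median = 0.7, conc_log_sd = 0.6,
      composition = comp(0.60, 0.18, 0.04, 0.015, 0.008, 0.005),
      asc_of_b = 0.02, asc_zero_p = 0, treated_prob = 0),
    otherADS = list(
      n_donors = 10L, age_range = c(0.7, 17.9),
      conc_median = 4.0, conc_log_sd = 0.6,
      composition = comp(0.55, 0.22, 0.04, 0.015, 0.040, 0.030),
      asc_of_b = 0.10, asc_zero_p = 0.5, treated_prob = 0.25),
    MOGAD = list(
      n_donors = 10L, age_range = c(1.8, 16.2),
      conc_median = 5.0, conc_log_sd = 0.6,
      composition = comp(0.52, 0.24, 0.04, 0.015, 0.040, 0.035),
      asc_of_b = 0.10, asc_zero_p = 0.5, treated_prob = 0.25),
    MS = list(
      n_donors = 15L, age_range = c(11.6, 19.1),
      conc_median = 3.0, conc_log_sd = 0.6,
      composition = comp(0.66, 0.05, 0.04, 0.015, 0.120, 0.002),
      asc_of_b = 0.12, asc_zero_p = 0, treated_prob = 0.25)
  )
}

# T-cell sub-structure shared by all groups (cohort medians where published,
# conventional CSF phenotype otherwise).
subset_defaults <- function() {
  list(
    # CD4/CD8/DN/DP of T; published medians 67.2 / 23.6 / 8.4 / 0.7 (%)
    subset_t = c(CD4 = 0.672, CD8 = 0.236, DN = 0.084, DP = 0.007) /
      sum(c(0.672, 0.236, 0.084, 0.007)),
    memory_of_cd4 = 0.978,                       # age-independent
    cm_em_temra_cd4 = c(CM = 0.80, EM = 0.18, TEMRA = 0.02),
    cm_em_temra_cd8 = c(CM = 0.55, EM = 0.35, TEMRA = 0.10),
    # CXCR3 x CCR6 states of memory CD4 (Th1-dominant)
    th_states = c(Th1 = 0.60, Th17 = 0.15, ThDP = 0.10, ThDN = 0.15),
    act_of_mem_cd4 = 0.02, act_of_mem_cd8 = 0.05,
    treg_of_cd4 = 0.05,
    nkt_of_t = 0.05,
    # naive CD8 declines linearly with age, clamped
    naive_cd8 = c(intercept = 0.74, slope = 0.0467, lo = 0.02, hi = 0.95)
  )
}

#' Build the default synthetic-cohort configuration
#'
#' Returns the built-in generative parameters for the requested diagnosis
#' groups. The NIND leukocyte composition equals the published cohort medians
#' (T 67.3%, CD14+ myeloid 12.9%, NK 4.3%, DC 1.6%, B 0.6%, PMN 0.3%) with
#' the remainder assigned to an `unassigned` lineage-negative population;
#' inflammatory groups are parameterized to reproduce the qualitative
#' orderings of the source cohort (higher cellularity, B-cell enrichment in
#' demyelinating disease, elevated ASC and depressed CD14+ myeloid in MS).
#'
#' @param groups_requested Character vector of group labels, drawn from
#'   `r paste(csf_group_labels(), collapse = ", ")`. May be empty.
#' @param master_seed Integer master seed; donor seeds are
#'   `master_seed + donor_index`.
#' @param volume_ml Simulated CSF volume in mL used to convert concentration
#'   (cells/uL) into an acquired event count.
#' @param event_clamp Length-2 integer bounds on per-donor event counts.
#' @param dirichlet_conc Total concentration of the Dirichlet distribution
#'   used for donor-level composition jitter; `Inf` disables jitter.
#' @param expression A `csf_expression_model`.
#' @return A list of class `csf_cohort_config` with elements `panel`,
#'   `expression`, `groups` (named list of group specs), `volume_ml`,
#'   `event_clamp`, `dirichlet_conc`, `master_seed`.
#' @export
#' @examples
#' cfg <- build_default_config("NIND")
#' cfg$groups$NIND$composition
build_default_config <- function(groups_requested = csf_group_labels(),
                                 master_seed = 1L,
                                 volume_ml = 3,
                                 event_clamp = c(200L, 50000L),
                                 dirichlet_conc = 200,
                                 expression = default_expression_model()) {
  known <- csf_group_labels()
  bad <- setdiff(groups_requested, known)
  if (length(bad))
    stop_cytocsf("unknown group label(s): ", paste(bad, collapse = ", "))
  defs <- group_defaults_table()
  sub <- subset_defaults()
  groups <- lapply(groups_requested, function(g) {
    spec <- c(list(label = g), defs[[g]], sub)
    validate_group_spec(spec)
    spec
  })
  names(groups) <- groups_requested
  cfg <- structure(
    list(panel = csf_marker_panel(), expression = expression,
         groups = groups, volume_ml = volume_ml,
         event_clamp = as.integer(event_clamp),
         dirichlet_conc = dirichlet_conc,
         master_seed = as.integer(master_seed)),
    class = "csf_cohort_config")
  validate_config(cfg)
}

validate_group_spec <- function(spec) {
  check_partition <- function(p, what) {
    if (any(p < 0) || any(p > 1))
      stop_cytocsf(what, " proportions must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9)
      stop_cytocsf(what, " must sum to 1 (off by ", sum(p) - 1, ")")
  }
  check_partition(spec$composition, paste0(spec$label, " composition"))
  check_partition(spec$subset_t, "T subsets")
  check_partition(spec$cm_em_temra_cd4, "CD4 memory states")
  check_partition(spec$cm_em_temra_cd8, "CD8 memory states")
  check_partition(spec$th_states, "Th states")
  frac <- c(spec$memory_of_cd4, spec$act_of_mem_cd4, spec$act_of_mem_cd8,
            spec$treg_of_cd4, spec$nkt_of_t, spec$asc_of_b, spec$asc_zero_p,
            spec$treated_prob)
  if (any(frac < 0 | frac > 1))
    stop_cytocsf(spec$label, ": subset fractions must lie in [0, 1]")
  if (spec$n_donors < 1) stop_cytocsf(spec$label, ": n_donors must be >= 1")
  if (spec$conc_median <= 0)
    stop_cytocsf(spec$label, ": concentration median must be positive")
  if (spec$naive_cd8[["lo"]] > spec$naive_cd8[["hi"]])
    stop_cytocsf(spec$label, ": naive CD8 clamp bounds inverted")
  invisible(spec)
}

validate_config <- function(cfg) {
  if (cfg$volume_ml <= 0) stop_cytocsf("volume_ml must be positive")
  if (length(cfg$event_clamp) != 2 || cfg$event_clamp[1] < 1 ||
      cfg$event_clamp[1] > cfg$event_clamp[2])
    stop_cytocsf("event_clamp must be [min, max] with min >= 1")
  if (anyDuplicated(names(cfg$groups)))
    stop_cytocsf("group labels must be unique")
  validate_expression_model(cfg$expression)
  cfg
}

#' @export
print.csf_cohort_config <- function(x, ...) {
  cat("<csf_cohort_config>\n")
  cat("  groups:", if (length(x$groups))
    paste(sprintf("%s (n=%d)", names(x$groups),
                  vapply(x$groups, `[[`, 1L, "n_donors")), collapse = ", ")
    else "(none)", "\n")
  cat("  volume:", x$volume_ml, "mL; event clamp",
      paste(x$event_clamp, collapse = "-"),
      "; master seed", x$master_seed, "\n")
  invisible(x)
}
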