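# Per-donor discriminative scores: AMR, coNCS, full NCS, PMN flag.

#' ASC to CD14+ myeloid cell ratio (AMR)
#'
#' Ratio of the antibody-secreting-cell frequency to the CD14+ myeloid-cell
#' frequency, both expressed as percent of CD45+ leukocytes (the ratio is
#' invariant to the common denominator). Edge rules: a zero ASC frequency
#' gives 0 regardless of the denominator; positive ASC with zero CD14+
#' frequency gives `Inf`, a flagged sentinel that ranks above every finite
#' ratio in ROC construction.
#'
#' @param asc_pct,cd14_pct Frequencies in percent (`[0, 100]`), vectorized.
#' @return Numeric ratio(s); `Inf` marks the sentinel.
#' @export
#' @examples
#' compute_amr(2, 10)  # 0.2
compute_amr <- function(asc_pct, cd14_pct) {
  assert_pct(asc_pct, "asc_pct"); assert_pct(cd14_pct, "cd14_pct")
  ifelse(asc_pct == 0, 0,
         ifelse(cd14_pct == 0, Inf, asc_pct / cd14_pct))
}

#' CSF-only neuroinflammatory composite score (coNCS)
#'
#' `(cells/uL + 1) * B% * 100 / (CD14% * NKT%)`, where B% is the B-cell
#' frequency as percent of CSF lymphocytes, CD14% the CD14+ myeloid frequency
#' as percent of CSF cells, and NKT% the CD3+CD56+ T-cell frequency as
#' percent of CSF lymphocytes. If the numerator or the denominator is 0 the
#' score is 0.
#'
#' @param concentration CSF cell concentration, cells/uL (>= 0).
#' @param b_pct,cd14_pct,nkt_pct Frequencies in percent. All vectorized.
#' @return Non-negative score.
#' @export
#' @examples
#' compute_concs(2, 5, 10, 2)  # 75
compute_concs <- function(concentration, b_pct, cd14_pct, nkt_pct) {
  assert_nonneg(concentration, "concentration")
  assert_pct(b_pct, "b_pct"); assert_pct(cd14_pct, "cd14_pct")
  assert_pct(nkt_pct, "nkt_pct")
  ifelse(b_pct == 0 | cd14_pct == 0 | nkt_pct == 0, 0,
         (concentration + 1) * b_pct * 100 / (cd14_pct * nkt_pct))
}

#' Full neuroinflammatory composite score (NCS)
#'
#' The coNCS with the blood CD56dim NK-cell frequency (% of blood
#' lymphocytes) added to the denominator:
#' `(cells/uL + 1) * B% * 100 / (bloodCD56dim% * CD14% * NKT%)`, with the
#' same zero rules. A missing blood value yields `NA` (score absent), not 0.
#'
#' @inheritParams compute_concs
#' @param blood_cd56dim_pct Blood CD56dim NK frequency, percent of blood
#'   lymphocytes; `NA` if unavailable.
#' @return Non-negative score, or `NA` where the blood value is missing.
#' @export
#' @examples
#' compute_ncs(2, 5, 10, 2, 10)  # 7.5
compute_ncs <- function(concentration, b_pct, cd14_pct, nkt_pct,
                        blood_cd56dim_pct) {
  assert_nonneg(concentration, "concentration")
  assert_pct(b_pct, "b_pct"); assert_pct(cd14_pct, "cd14_pct")
  assert_pct(nkt_pct, "nkt_pct")
  assert_pct(blood_cd56dim_pct[!is.na(blood_cd56dim_pct)], "blood_cd56dim_pct")
  ifelse(is.na(blood_cd56dim_pct), NA_real_,
         ifelse(b_pct == 0 | cd14_pct == 0 | nkt_pct == 0 |
                  blood_cd56dim_pct == 0, 0,
                (concentration + 1) * b_pct * 100 /
                  (blood_cd56dim_pct * cd14_pct * nkt_pct)))
}

#' PMN threshold flag
#'
#' TRUE iff the donor's PMN frequency strictly exceeds twice the mean PMN
#' frequency of the NIND group (both as percent of leukocytes). PMN presence
#' above this threshold is associated with MOGAD/other ADS and essentially
#' excludes MS.
#'
#' @param pmn_pct Donor PMN frequency, percent of leukocytes (vectorized).
#' @param nind_mean_pmn_pct Mean NIND PMN frequency (>= 0).
#' @return Logical flag(s).
#' @export
#' @examples
#' pmn_flag(0.61, 0.30)  # TRUE
#' pmn_flag(0.60, 0.30)  # FALSE (strict inequality)
pmn_flag <- function(pmn_pct, nind_mean_pmn_pct) {
  assert_nonneg(nind_mean_pmn_pct, "nind_mean_pmn_pct")
  pmn_pct > 2 * nind_mean_pmn_pct
}

#' Per-donor score records
#'
#' Assembles the AMR, coNCS, full NCS (where a blood CD56dim NK value is
#' available) and the PMN flag for every donor of a gated cohort. The NIND
#' PMN mean for the flag is computed from the NIND donors of the same run,
#' or may be supplied when the cohort contains none.
#'
#' @param table Population table from [population_table()].
#' @param metadata Donor metadata (needs `donor_id`, `group`,
#'   `concentration_cells_per_uL`; an optional `blood_cd56dim_nk_pct` column
#'   feeds the full NCS).
#' @param nind_mean_pmn_pct NIND mean PMN frequency (% of leukocytes);
#'   computed from the run's NIND donors when `NULL`.
#' @return Tibble: donor_id, group, amr, amr_is_sentinel, concs, ncs,
#'   pmn_flag.
#' @export
compute_score_table <- function(table, metadata, nind_mean_pmn_pct = NULL) {
  get <- function(population, measure)
    extract_feature(table, population, measure)$value
  ids <- unique(table$donor_id)
  ord <- match(metadata$donor_id, ids)
  if (anyNA(ord) || length(ids) != nrow(metadata))
    stop_cytocsf("metadata donors do not match the population table")
  feat <- tibble::tibble(
    donor_id = ids,
    asc_leuk = get("ASC", "pct_leukocytes"),
    cd14_leuk = get("CD14_myeloid", "pct_leukocytes"),
    b_lymph = get("B", "pct_lymphocytes"),
    nkt_lymph = get("NKT", "pct_lymphocytes"),
    pmn_leuk = get("PMN", "pct_leukocytes"))
  feat <- feat[match(metadata$donor_id, feat$donor_id), ]
  if (is.null(nind_mean_pmn_pct)) {
    nind <- feat$pmn_leuk[metadata$group == "NIND"]
    if (!length(nind))
      stop_cytocsf("no NIND donors in run; supply nind_mean_pmn_pct")
    nind_mean_pmn_pct <- mean(nind)
  }
  conc <- metadata$concentration_cells_per_uL
  blood <- if ("blood_cd56dim_nk_pct" %in% names(metadata))
    metadata$blood_cd56dim_nk_pct else rep(NA_real_, nrow(metadata))
  amr <- compute_amr(feat$asc_leuk, feat$cd14_leuk)
  tibble::tibble(
    donor_id = metadata$donor_id,
    group = metadata$group,
    amr = amr,
    amr_is_sentinel = is.infinite(amr),
    concs = compute_concs(conc, feat$b_lymph, feat$cd14_leuk,
                          feat$nkt_lymph),
    ncs = compute_ncs(conc, feat$b_lymph, feat$cd14_leuk, feat$nkt_lymph,
                      blood),
    pmn_flag = pmn_flag(feat$pmn_leuk, nind_mean_pmn_pct))
}
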