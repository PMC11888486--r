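#' Age-dependent naive CD8+ T-cell fraction
#'
#' Linear decline of the naive fraction of CD8+ T cells with age, clamped to
#' `[lo, hi]`: `clamp(intercept - slope * age, lo, hi)`. The default
#' parameters (intercept 0.74, slope 0.0467/yr) put the expected memory-CD8
#' fraction near 77% at the cohort's median age of about 11 years.
#'
#' @param age Age in years (non-negative, vectorized).
#' @param params Named numeric vector `(intercept, slope, lo, hi)`.
#' @return Naive CD8 fraction(s) in `[0, 1]`, non-increasing in age.
#' @export
#' @examples
#' naive_cd8_fraction(11)  # 0.2263
naive_cd8_fraction <- function(age,
                               params = subset_defaults()$naive_cd8) {
  assert_nonneg(age, "age")
  lo <- params[["lo"]]; hi <- params[["hi"]]
  if (lo > hi) stop_cytocsf("naive CD8 clamp bounds inverted")
  pmin(pmax(params[["intercept"]] - params[["slope"]] * age, lo), hi)
}

# Draw a donor leukocyte composition around the group composition.
# Group compositions are interpreted as cohort *medians* (their anchoring
# values are published medians, and concentration is likewise
# median-parameterized), so the Dirichlet is median-centered: each gamma
# shape gets a +1/3 offset, putting the marginal median of component k at
# ~p_k via the Gamma(a) median ~ a - 1/3 approximation. Mean-centering
# instead would bias recovered medians of rare populations (PMN, DC, B)
# well below their configured values.
draw_composition <- function(p, dirichlet_conc) {
  if (is.null(dirichlet_conc) || !is.finite(dirichlet_conc)) return(p)
  g <- stats::rgamma(length(p), shape = dirichlet_conc * p + (p > 0) / 3)
  g[p == 0] <- 0
  out <- g / sum(g)
  names(out) <- names(p)
  out
}

# Vectorized hierarchical draw of per-event latent populations. Returns a
# data.frame of attributes plus the compact latent-label string.
sample_latent <- function(n, spec, composition, naive8, asc_frac) {
  lin <- sample(names(composition), n, replace = TRUE, prob = composition)
  subset <- mem <- th <- rep(NA_character_, n)
  act <- treg <- nkt <- asc <- rep(FALSE, n)

  is_t <- lin == "T"
  nt <- sum(is_t)
  if (nt) {
    subset[is_t] <- sample(names(spec$subset_t), nt, replace = TRUE,
                           prob = spec$subset_t)
    nkt[is_t] <- stats::runif(nt) < spec$nkt_of_t
    # naive/memory: CD8 follows the donor's age model, everything else the
    # (age-independent) CD4 memory fraction
    p_naive <- ifelse(subset[is_t] == "CD8", naive8, 1 - spec$memory_of_cd4)
    naive <- stats::runif(nt) < p_naive
    memstate <- character(nt)
    memstate[naive] <- "naive"
    mem8 <- !naive & subset[is_t] == "CD8"
    mem4 <- !naive & subset[is_t] != "CD8"
    if (any(mem8))
      memstate[mem8] <- sample(names(spec$cm_em_temra_cd8), sum(mem8),
                               replace = TRUE, prob = spec$cm_em_temra_cd8)
    if (any(mem4))
      memstate[mem4] <- sample(names(spec$cm_em_temra_cd4), sum(mem4),
                               replace = TRUE, prob = spec$cm_em_temra_cd4)
    mem[is_t] <- memstate
    # chemokine-receptor states only modelled on memory CD4
    th_idx <- is_t & subset == "CD4" & mem != "naive"
    if (any(th_idx))
      th[th_idx] <- sample(names(spec$th_states), sum(th_idx), replace = TRUE,
                           prob = spec$th_states)
    act_idx4 <- is_t & subset == "CD4" & mem != "naive"
    act_idx8 <- is_t & subset == "CD8" & mem != "naive"
    act[act_idx4] <- stats::runif(sum(act_idx4)) < spec$act_of_mem_cd4
    act[act_idx8] <- stats::runif(sum(act_idx8)) < spec$act_of_mem_cd8
    cd4_idx <- is_t & subset == "CD4"
    treg[cd4_idx] <- stats::runif(sum(cd4_idx)) < spec$treg_of_cd4
  }
  is_b <- lin == "B"
  if (any(is_b)) asc[is_b] <- stats::runif(sum(is_b)) < asc_frac

  label <- lin
  if (nt) {
    lt <- paste(lin[is_t], subset[is_t], mem[is_t], sep = "|")
    lt <- paste0(lt, ifelse(is.na(th[is_t]), "", paste0("|", th[is_t])))
    lt <- paste0(lt, ifelse(act[is_t], "|act", ""),
                 ifelse(treg[is_t], "|treg", ""),
                 ifelse(nkt[is_t], "|nkt", ""))
    label[is_t] <- lt
  }
  label[is_b] <- paste0("B|", ifelse(asc[is_b], "ASC", "nonASC"))

  data.frame(lineage = lin, subset = subset, mem = mem, th = th,
             act = act, treg = treg, nkt = nkt, asc = asc,
             latent_label = label, stringsAsFactors = FALSE)
}

# Map latent attributes to a per-channel state matrix, then to intensities.
draw_intensities <- function(att, expression, panel) {
  n <- nrow(att)
  is_t <- att$lineage == "T"
  memory_t <- is_t & att$mem != "naive"
  pos <- list(
    "CD45"   = rep(TRUE, n),
    "CD14"   = att$lineage == "myeloid",
    "CD3"    = is_t,
    "CD19"   = att$lineage == "B",
    "CD56"   = att$lineage == "NK" | (is_t & att$nkt),
    "HLA-DR" = att$lineage %in% c("myeloid", "DC", "B") | (is_t & att$act),
    "CD4"    = is_t & att$subset %in% c("CD4", "DP"),
    "CD8"    = is_t & att$subset %in% c("CD8", "DP"),
    "CD38"   = is_t & att$act,
    "CD27"   = is_t & att$mem %in% c("naive", "CM"),
    "CD45RA" = is_t & att$mem %in% c("naive", "TEMRA"),
    "CD11c"  = att$lineage %in% c("myeloid", "DC"),
    "CD127"  = is_t & !att$treg,
    "CD25"   = is_t & att$treg,
    "CXCR3"  = memory_t & att$th %in% c("Th1", "ThDP"),
    "CCR6"   = memory_t & att$th %in% c("Th17", "ThDP")
  )
  hi <- list("CD27" = att$asc, "CD38" = att$asc)

  fluor <- setdiff(panel, "SSC")
  X <- matrix(0, nrow = n, ncol = length(panel),
              dimnames = list(NULL, panel))
  for (ch in fluor) {
    mu <- ifelse(pos[[ch]], expression$mu_pos, expression$mu_neg)
    h <- hi[[ch]]
    if (!is.null(h)) mu[h] <- expression$mu_hi
    X[, ch] <- stats::rnorm(n, mu, expression$sigma)
  }
  mu_ssc <- ifelse(att$lineage == "PMN", expression$ssc_mu_hi,
                   expression$ssc_mu_lo)
  X[, "SSC"] <- stats::rnorm(n, mu_ssc, expression$ssc_sigma)
  X
}

#' Simulate one CSF donor
#'
#' Draws donor metadata (age uniform on the group's age range, lognormal cell
#' concentration, sex, treatment flag), an acquired event count
#' `round(concentration * volume_mL * 1000)` clamped to the configured bounds,
#' per-event latent populations from the hierarchical composition (with
#' donor-level Dirichlet jitter, the donor's age-dependent naive CD8 fraction,
#' and zero-inflated ASC presence), and per-channel intensities from the
#' expression model. Identical `(config, group, donor_seed)` give
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param config A `csf_cohort_config` (see [build_default_config()]).
#' @param group Group label present in `config$groups`.
#' @param donor_seed Integer seed for this donor.
#' @param donor_id Donor identifier stored in the outputs.
#' @return A list with `record` (one-row tibble: donor_id, group, age, sex,
#'   concentration_cells_per_uL, treated, volume_mL) and `events` (tibble of
#'   events x 17 panel channels plus a `latent_label` column). The donor's
#'   realized leukocyte composition is attached to `events` as attribute
#'   `composition`.
#' @export
simulate_donor <- function(config, group, donor_seed,
                           donor_id = paste0(group, "_", donor_seed)) {
  spec <- config$groups[[group]]
  if (is.null(spec))
    stop_cytocsf("group '", group, "' is not present in the config")
  with_seed(donor_seed, {
    age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
    sex <- sample(c("F", "M"), 1)
    treated <- stats::runif(1) < spec$treated_prob
    conc <- stats::rlnorm(1, meanlog = log(spec$conc_median),
                          sdlog = spec$conc_log_sd)
    comp <- draw_composition(spec$composition, config$dirichlet_conc)
    asc_frac <- if (stats::runif(1) < spec$asc_zero_p) 0 else spec$asc_of_b
    n <- round(conc * config$volume_ml * 1000)
    n <- min(max(n, config$event_clamp[1]), config$event_clamp[2])
    naive8 <- naive_cd8_fraction(age, spec$naive_cd8)
    att <- sample_latent(n, spec, comp, naive8, asc_frac)
    X <- draw_intensities(att, config$expression, config$panel)
    events <- tibble::as_tibble(as.data.frame(X, check.names = FALSE))
    events$latent_label <- att$latent_label
    attr(events, "composition") <- comp
    record <- tibble::tibble(
      donor_id = donor_id, group = group, age = age, sex = sex,
      concentration_cells_per_uL = conc, treated = treated,
      volume_mL = config$volume_ml)
    list(record = record, events = events)
  })
}

#' Simulate a multi-group CSF cohort
#'
#' One donor per `n_donors` per configured group, with donor seeds derived
#' deterministically from the master seed (`master_seed + donor_index`,
#' indexing donors consecutively across groups in configuration order).
#'
#' @param config A `csf_cohort_config`.
#' @return A list with `metadata` (tibble of donor records) and `events`
#'   (named list of per-donor event tibbles, keyed by donor_id).
#' @export
#' @examples
#' cfg <- build_default_config("NIND")
#' cfg$groups$NIND$n_donors <- 2L
#' cohort <- simulate_cohort(cfg)
#' cohort$metadata
simulate_cohort <- function(config) {
  validate_config(config)
  records <- list(); events <- list()
  idx <- 0L
  for (g in names(config$groups)) {
    for (j in seq_len(config$groups[[g]]$n_donors)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", g, j)
      d <- simulate_donor(config, g, config$master_seed + idx, donor_id = id)
      records[[idx]] <- d$record
      events[[id]] <- d$events
    }
  }
  list(metadata = do.call(rbind, records), events = events)
}
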