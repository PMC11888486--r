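# Cross-group nonparametric statistics.

#' Wilcoxon rank-sum comparison
#'
#' Mann-Whitney U = number of pairs `(x_i, y_j)` with `x_i > y_j`, ties
#' counted one half. The two-sided p-value uses the exact rank-sum
#' distribution when `length(x) * length(y) <= 400` and the pooled sample is
#' tie-free, and the tie-corrected normal approximation (with continuity
#' correction) otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` and `p`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y))
    stop_cytocsf("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = (nx * ny <= 400) && !ties,
                       correct = TRUE)$p.value)
  # a fully tied pooled sample has zero rank variance; no evidence against
  # the null
  if (is.na(p)) p <- 1
  list(U = U, p = min(p, 1))
}

#' log10 fold-change of medians
#'
#' `log10(median(x) / median(y))`. A zero `median(y)` with positive
#' `median(x)` gives `Inf` (flagged infinite); both medians zero give `NA`
#' (undefined); zero `median(x)` with positive `median(y)` gives `-Inf`.
#'
#' @param x,y Non-empty numeric samples.
#' @return A single numeric value (possibly infinite or `NA`).
#' @export
#' @examples
#' median_log10_fold_change(c(10, 10), c(1, 1))  # 1
median_log10_fold_change <- function(x, y) {
  if (!length(x) || !length(y))
    stop_cytocsf("both samples must be non-empty")
  mx <- stats::median(x); my <- stats::median(y)
  if (mx == 0 && my == 0) return(NA_real_)
  if (my == 0) return(Inf)
  if (mx == 0) return(-Inf)
  log10(mx / my)
}

#' Age trend of a frequency
#'
#' Spearman rank correlation (average ranks on ties) between age and a
#' population frequency, with an exact permutation p-value for n <= 9
#' (tie-free) and the t-approximation otherwise. A constant input vector
#' yields `rho = NA` with a flag rather than an error.
#'
#' @param ages,freqs Paired numeric vectors, at least 3 pairs.
#' @return List with `rho`, `p`, and logical `degenerate`.
#' @export
#' @examples
#' age_trend(c(2, 8, 14, 18), c(80, 60, 30, 10))  # rho = -1
age_trend <- function(ages, freqs) {
  if (length(ages) != length(freqs) || length(ages) < 3)
    stop_cytocsf("need >= 3 paired observations")
  if (stats::sd(ages) == 0 || stats::sd(freqs) == 0)
    return(list(rho = NA_real_, p = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(ages, freqs, method = "spearman",
                    exact = length(ages) <= 9))
  list(rho = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

stars_for_p <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Pairwise group comparisons of one feature
#'
#' One Wilcoxon rank-sum comparison per requested group pair: group medians,
#' log10 fold-change of medians (A vs B), U, raw two-sided p, and the
#' significance stars convention `* p<0.05, ** p<0.01, *** p<0.001,
#' **** p<0.0001`. Benjamini-Hochberg adjusted p-values are appended (over
#' the comparisons in this call) when `bh = TRUE`; no multiplicity
#' correction is applied by default.
#'
#' @param df Tibble with columns `group` and `value`, one row per donor
#'   (see [extract_feature()]).
#' @param feature Feature name recorded in the output.
#' @param comparisons List of length-2 character vectors `c(groupA, groupB)`.
#' @param bh Append a Benjamini-Hochberg `p_adj` column?
#' @return Tibble with one row per comparison.
#' @export
compare_groups <- function(df, feature, comparisons, bh = FALSE) {
  if (!all(c("group", "value") %in% names(df)))
    stop_cytocsf("df must have columns 'group' and 'value'")
  rows <- lapply(comparisons, function(cmp) {
    a <- df$value[df$group == cmp[1]]
    b <- df$value[df$group == cmp[2]]
    if (!length(a)) stop_cytocsf("unknown or empty group '", cmp[1], "'")
    if (!length(b)) stop_cytocsf("unknown or empty group '", cmp[2], "'")
    w <- wilcoxon_rank_sum(a, b)
    tibble::tibble(
      feature = feature, group_a = cmp[1], group_b = cmp[2],
      n_a = length(a), n_b = length(b),
      median_a = stats::median(a), median_b = stats::median(b),
      log10_fc = median_log10_fold_change(a, b),
      U = w$U, p = w$p, stars = stars_for_p(w$p))
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
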