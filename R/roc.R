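# ROC/AUC evaluation of score-based classifiers. Orientation is fixed a
# priori: a higher score predicts the positive (MS) class.

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  stop_cytocsf("labels must be logical (TRUE = positive class) or 0/1")
}

# Sentinel (infinite) scores are mapped, rank-preservingly, just above the
# largest finite score; ties among sentinels collapse.
definite_scores <- function(scores) {
  inf <- is.infinite(scores) & scores > 0
  if (any(inf)) {
    top <- if (all(inf)) 1 else max(scores[!inf])
    scores[inf] <- top + 1
  }
  scores
}

#' ROC curve for a score
#'
#' Empirical ROC curve with thresholds at every distinct score value (ties
#' collapse to a single operating point), built with \pkg{pROC}. The curve
#' runs from (0, 0) to (1, 1) with non-decreasing FPR/TPR; the trapezoidal
#' AUC equals the Mann-Whitney pair fraction (see [auc_mann_whitney()]).
#' Infinite sentinel scores are permitted and rank above all finite scores.
#'
#' @param scores Per-donor score values.
#' @param labels Logical (TRUE = positive class, i.e. MS) or 0/1 vector.
#' @param score_name,contrast Labels stored in the result.
#' @return List of class `csf_roc`: `contrast`, `score_name`, `points`
#'   (tibble threshold/fpr/tpr ordered by decreasing threshold), `auc`,
#'   `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_curve(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
roc_curve <- function(scores, labels, score_name = "score",
                      contrast = NA_character_) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop_cytocsf("both classes must be present")
  s <- definite_scores(scores)
  r <- pROC::roc(response = labels, predictor = s, direction = "<",
                 levels = c(FALSE, TRUE), quiet = TRUE)
  ord <- order(r$thresholds, decreasing = TRUE)
  points <- tibble::tibble(threshold = r$thresholds[ord],
                           fpr = 1 - r$specificities[ord],
                           tpr = r$sensitivities[ord])
  structure(list(contrast = contrast, score_name = score_name,
                 points = points, auc = as.numeric(r$auc),
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "csf_roc")
}

#' @export
print.csf_roc <- function(x, ...) {
  cat(sprintf("<csf_roc> %s / %s: AUC %.3f (%d pos, %d neg, %d points)\n",
              x$contrast %||% "?", x$score_name, x$auc, x$n_pos, x$n_neg,
              nrow(x$points)))
  invisible(x)
}

#' Mann-Whitney AUC
#'
#' Fraction of (positive, negative) pairs in which the positive donor's
#' score exceeds the negative donor's, ties counted one half -- the rank
#' statistic that the trapezoidal area under the empirical ROC curve equals
#' exactly. Kept as an independent computation (average ranks, no curve
#' construction) so it can serve as an oracle for [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop_cytocsf("both classes must be present")
  s <- definite_scores(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  r <- rank(s)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC summary over the standard diagnostic contrasts
#'
#' Builds ROC curves for the AMR and coNCS classifiers over the contrasts
#' MS-vs-MOGAD, MS-vs-otherADS and MS-vs-MOGAD/otherADS (those whose groups
#' are present in the score table).
#'
#' @param score_table Tibble from [compute_score_table()].
#' @return List with `curves` (list of `csf_roc`) and `summary` (tibble:
#'   contrast, score, auc, n_pos, n_neg).
#' @export
roc_summary <- function(score_table) {
  contrasts <- list(
    "MS-vs-MOGAD" = "MOGAD",
    "MS-vs-otherADS" = "otherADS",
    "MS-vs-MOGAD/otherADS" = c("MOGAD", "otherADS"))
  curves <- list()
  for (cname in names(contrasts)) {
    neg_groups <- contrasts[[cname]]
    keep <- score_table$group %in% c("MS", neg_groups)
    sub <- score_table[keep, ]
    if (!any(sub$group == "MS") || !any(sub$group %in% neg_groups)) next
    for (score in c("amr", "concs")) {
      curves[[paste(cname, score, sep = ":")]] <-
        roc_curve(sub[[score]], sub$group == "MS",
                  score_name = score, contrast = cname)
    }
  }
  summary <- do.call(rbind, lapply(curves, function(r)
    tibble::tibble(contrast = r$contrast, score = r$score_name,
                   auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg)))
  list(curves = curves, summary = summary)
}
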