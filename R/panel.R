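#' The 17-channel CSF immunophenotyping panel
#'
#' Ordered channel names for the staining panel used throughout the package:
#' 16 antibody markers (CD45, CD14, CD3, CD19, CD56, HLA-DR, CD4, CD8, CD38,
#' CD27, CD45RA, CD11c, CD127, CD25, CXCR3, CCR6) plus a side-scatter channel
#' (`SSC`), which is always last.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' csf_marker_panel()
csf_marker_panel <- function() {
  c("CD45", "CD14", "CD3", "CD19", "CD56", "HLA-DR", "CD4", "CD8",
    "CD38", "CD27", "CD45RA", "CD11c", "CD127", "CD25", "CXCR3", "CCR6",
    "SSC")
}

#' Default marker-expression model
#'
#' Three-state Gaussian intensity model in transformed (arcsinh-like) units:
#' each fluorescence channel draws from a negative, positive or high state
#' with a shared standard deviation; side scatter has low/high states. The
#' defaults guarantee at least a 6-sigma gap between the negative and positive
#' state means, so hard gating at the midpoint is essentially error-free.
#'
#' @param mu_neg,mu_pos,mu_hi State means for fluorescence channels.
#' @param sigma Shared fluorescence standard deviation (> 0).
#' @param ssc_mu_lo,ssc_mu_hi,ssc_sigma Side-scatter state means and sd.
#' @return A list of class `csf_expression_model`.
#' @export
default_expression_model <- function(mu_neg = 0, mu_pos = 4, mu_hi = 6,
                                     sigma = 0.5,
                                     ssc_mu_lo = 0, ssc_mu_hi = 6,
                                     ssc_sigma = 0.5) {
  m <- list(mu_neg = mu_neg, mu_pos = mu_pos, mu_hi = mu_hi, sigma = sigma,
            ssc_mu_lo = ssc_mu_lo, ssc_mu_hi = ssc_mu_hi,
            ssc_sigma = ssc_sigma)
  validate_expression_model(m)
  structure(m, class = "csf_expression_model")
}

validate_expression_model <- function(m) {
  if (m$sigma <= 0 || m$ssc_sigma <= 0)
    stop_cytocsf("expression model sigma must be positive")
  if (!(m$mu_neg < m$mu_pos && m$mu_pos < m$mu_hi))
    stop_cytocsf("expression model requires mu_neg < mu_pos < mu_hi")
  if ((m$mu_pos - m$mu_neg) < 6 * m$sigma)
    stop_cytocsf("expression model requires (mu_pos - mu_neg) >= 6*sigma")
  if (m$ssc_mu_lo >= m$ssc_mu_hi)
    stop_cytocsf("SSC model requires ssc_mu_lo < ssc_mu_hi")
  invisible(m)
}
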