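#' Estimate gating thresholds from event data
#'
#' `method = "fixed"` returns `fixed_values` unchanged. For
#' `method = "midpoint-mixture"`, each channel's primary threshold is the
#' midpoint of the two component means of a two-component equal-variance
#' Gaussian mixture fitted to that channel's values
#' (`mclust::Mclust(G = 2, modelNames = "E")`); high thresholds, where the
#' fixed set defines one, are re-derived as primary + 3. A channel whose fit
#' is degenerate -- the fit fails, or the component means are separated by
#' less than three common standard deviations, as happens when fewer than a
#' couple of percent of events are positive and the mixture splits the
#' majority mode instead -- falls back to the fixed default for that channel,
#' with a warning naming the channels concerned.
#'
#' @param events Event tibble/data.frame covering the panel channels
#'   (non-empty for the mixture method).
#' @param method `"fixed"` or `"midpoint-mixture"`.
#' @param fixed_values Threshold tibble used for `"fixed"` and as the
#'   per-channel fallback.
#' @param max_events Mixture fits use at most this many events per channel
#'   (deterministic, evenly spaced subsample); mclust's hierarchical
#'   initialisation is quadratic in the number of points.
#' @return A threshold tibble (`channel`, `primary`, `high`).
#' @export
#' @examples
#' cfg <- build_default_config("NIND")
#' d <- simulate_donor(cfg, "NIND", 1)
#' estimate_thresholds(d$events, "midpoint-mixture")
estimate_thresholds <- function(events,
                                method = c("fixed", "midpoint-mixture"),
                                fixed_values = default_thresholds(),
                                max_events = 2000L) {
  method <- match.arg(method)
  validate_thresholds(fixed_values)
  if (method == "fixed") return(fixed_values)
  if (is.null(events) || nrow(events) == 0)
    stop_cytocsf("midpoint-mixture threshold estimation needs events")
  X <- event_matrix(events, fixed_values$channel)
  out <- fixed_values
  fell_back <- character()
  for (i in seq_len(nrow(out))) {
    v <- X[, out$channel[i]]
    if (length(v) > max_events)
      v <- v[round(seq(1, length(v), length.out = max_events))]
    mid <- mixture_midpoint(v)
    if (is.na(mid)) {
      fell_back <- c(fell_back, out$channel[i])
    } else {
      out$primary[i] <- mid
      if (!is.na(out$high[i]))
        out$high[i] <- if (out$channel[i] == "SSC") mid else mid + 3
    }
  }
  if (length(fell_back))
    warning("degenerate mixture fit; default threshold kept for: ",
            paste(fell_back, collapse = ", "), call. = FALSE)
  validate_thresholds(out)
  out
}

# Midpoint of a two-component equal-variance univariate Gaussian mixture;
# NA when the fit fails or the modes are not separated by >= 3 sd.
mixture_midpoint <- function(v, min_sep_sd = 3) {
  if (length(unique(v)) < 3) return(NA_real_)
  fit <- tryCatch(
    mclust::Mclust(v, G = 2, modelNames = "E", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  mu <- fit$parameters$mean
  sd <- sqrt(fit$parameters$variance$sigmasq[1])
  if (abs(diff(mu)) < min_sep_sd * sd) return(NA_real_)
  mean(mu)
}
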