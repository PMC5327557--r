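# Lag profiling: how quickly the surrogate source picks cases up after the
# registry diagnosis month.

#' Cumulative sensitivity/PPV by identification lag
#'
#' For each offset `m = 0..W` the profile gives the cumulative sensitivity
#' and cumulative PPV counting only true positives first identified between
#' the registry diagnosis month and `m` months after it.  Cases first
#' identified before the diagnosis month (negative lag) are excluded from
#' the series and reported separately as `negative_lag_fraction`, so the
#' series value at `m = W` plus that fraction equals the overall
#' sensitivity.
#'
#' @param mc A `"match_classification"` from [classify_cases()].
#' @return A `"lag_profile"` object: data.frame with columns `offset`,
#'   `cum_tp`, `cum_sensitivity`, `cum_ppv`, plus attributes
#'   `negative_lag_fraction`, `overall_sensitivity`, `n_registry_cases`,
#'   `n_identified`.
#' @export
lag_profile <- function(mc) {
  W <- attr(mc, "window_months")
  lab <- mc$label
  n_registry <- sum(lab %in% c("TP", "FN", "FN_and_FP"))
  n_identified <- sum(lab %in% c("TP", "FN_and_FP", "FP"))
  lags <- mc$lag_months[lab == "TP"]
  offs <- 0:W
  cum_tp <- vapply(offs, function(m) sum(lags >= 0 & lags <= m), integer(1))
  neg <- sum(lags < 0)
  df <- data.frame(
    offset = offs,
    cum_tp = cum_tp,
    cum_sensitivity = if (n_registry > 0) cum_tp / n_registry else NA_real_,
    cum_ppv = if (n_identified > 0) cum_tp / n_identified else NA_real_)
  structure(df, class = c("lag_profile", "data.frame"),
            negative_lag_fraction =
              if (n_registry > 0) neg / n_registry else NA_real_,
            overall_sensitivity =
              if (n_registry > 0) length(lags) / n_registry else NA_real_,
            n_registry_cases = n_registry,
            n_identified = n_identified,
            cancer_type = attr(mc, "cancer_type"),
            indicator = attr(mc, "indicator"))
}

#' @export
print.lag_profile <- function(x, ...) {
  cat(sprintf("Lag profile [%s, %s]: %d registry case(s)\n",
              attr(x, "indicator"), attr(x, "cancer_type"),
              attr(x, "n_registry_cases")))
  print.data.frame(as.data.frame(x))
  cat(sprintf("  identified before diagnosis month: %.1f%% of cases\n",
              100 * attr(x, "negative_lag_fraction")))
  invisible(x)
}
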