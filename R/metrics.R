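# Diagnostic-accuracy metrics with Wilson score confidence intervals.

#' Wilson score confidence interval for a proportion
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (n >= 1; `n = 0` returns `NA` bounds).
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`, both in `[0, 1]` and
#'   bracketing `k/n`.
#' @examples
#' wilson_ci(2140, 2253)
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  stopifnot(k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

normal_ci <- function(k, n, level = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  half <- z * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - half), upper = min(1, p + half))
}

prop_with_ci <- function(k, n, level, method) {
  ci <- if (method == "wilson") wilson_ci(k, n, level) else normal_ci(k, n, level)
  list(estimate = if (n > 0) k / n else NA_real_,
       lower = unname(ci[1]), upper = unname(ci[2]), k = k, n = n)
}

#' Validity metrics from a classification's marginal counts
#'
#' Builds sensitivity, specificity and PPV directly from the two-by-two
#' marginals, the form in which validation studies print their results:
#' sensitivity = TP / registry cases; PPV = TP / cases identified;
#' specificity = TN / non-cases, where TN = non-cases never flagged
#' (`n_evaluated - n_registry - (n_identified - tp)` when every non-TP
#' identification is a non-case; supply `fn_and_fp` when some identified
#' persons are out-of-window registry cases, which are not specificity-side
#' false positives).
#'
#' @param tp True positives.
#' @param n_identified Persons flagged by the indicator.
#' @param n_registry Registry cases in the evaluation window.
#' @param n_evaluated Evaluated persons (cohort denominator).
#' @param fn_and_fp Registry cases flagged outside the window (default 0).
#' @param level Confidence level (default 0.95).
#' @param ci_method `"wilson"` (default) or `"normal"`.
#' @return A `"validity_metrics"` object.
#' @export
metrics_from_counts <- function(tp, n_identified, n_registry, n_evaluated,
                                fn_and_fp = 0, level = 0.95,
                                ci_method = c("wilson", "normal")) {
  ci_method <- match.arg(ci_method)
  fp_spec <- n_identified - tp - fn_and_fp   # flagged true non-cases
  n_non <- n_evaluated - n_registry
  tn <- n_non - fp_spec
  stopifnot(tp >= 0, fp_spec >= 0, tn >= 0, n_registry >= tp)
  structure(list(
    n_evaluated = n_evaluated,
    n_registry_cases = n_registry,
    n_identified = n_identified,
    tp = tp, fn = n_registry - tp, fn_and_fp = fn_and_fp,
    fp = n_identified - tp, tn = tn,
    sensitivity = prop_with_ci(tp, n_registry, level, ci_method),
    specificity = prop_with_ci(tn, n_non, level, ci_method),
    ppv = if (n_identified > 0)
      prop_with_ci(tp, n_identified, level, ci_method)
    else list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
              k = 0, n = 0),
    ppv_undefined = n_identified == 0,
    ci_method = ci_method, level = level),
    class = "validity_metrics")
}

#' Compute validity metrics from a match classification
#'
#' @param mc A `"match_classification"` from [classify_cases()].
#' @param level Confidence level (default 0.95).
#' @param ci_method `"wilson"` (default) or `"normal"`.
#' @return A `"validity_metrics"` object with counts, point estimates and
#'   confidence intervals for sensitivity, specificity and PPV.  When no
#'   person is identified the PPV is undefined and reported as `NA` with
#'   `ppv_undefined = TRUE`.
#' @export
compute_metrics <- function(mc, level = 0.95,
                            ci_method = c("wilson", "normal")) {
  ci_method <- match.arg(ci_method)
  lab <- mc$label
  tp <- sum(lab == "TP")
  fnfp <- sum(lab == "FN_and_FP")
  n_registry <- tp + fnfp + sum(lab == "FN")
  n_identified <- tp + fnfp + sum(lab == "FP")
  m <- metrics_from_counts(tp, n_identified, n_registry, nrow(mc),
                           fn_and_fp = fnfp, level = level,
                           ci_method = ci_method)
  m$cancer_type <- attr(mc, "cancer_type")
  m$indicator <- attr(mc, "indicator")
  m$window_months <- attr(mc, "window_months")
  m
}

#' @export
print.validity_metrics <- function(x, ...) {
  fmt <- function(p) {
    if (is.na(p$estimate)) return("   NA (undefined)")
    sprintf("%5.1f%% (%4.1f-%5.1f%%)", 100 * p$estimate, 100 * p$lower,
            100 * p$upper)
  }
  hdr <- if (!is.null(x$indicator))
    sprintf(" [%s, %s, W = %s]", x$indicator, x$cancer_type,
            x$window_months) else ""
  cat(sprintf("Validity metrics%s\n", hdr))
  cat(sprintf("  registry cases %d | identified %d | TP %d | evaluated %d\n",
              x$n_registry_cases, x$n_identified, x$tp, x$n_evaluated))
  cat(sprintf("  sensitivity %s\n  specificity %s\n  PPV         %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv)))
  cat(sprintf("  (%s score %g%% CI)\n", x$ci_method, 100 * x$level))
  invisible(x)
}

#' One-row data.frame view of validity metrics
#'
#' @param x A `"validity_metrics"` object.
#' @return data.frame with counts, estimates and CI bounds; convenient for
#'   binding into a report table.
#' @export
metrics_row <- function(x) {
  data.frame(cancer_type = x$cancer_type %||% NA_character_,
             indicator = x$indicator %||% NA_character_,
             window_months = x$window_months %||% NA_integer_,
             n_evaluated = x$n_evaluated,
             n_registry_cases = x$n_registry_cases,
             n_identified = x$n_identified,
             tp = x$tp,
             sensitivity = x$sensitivity$estimate,
             sensitivity_low = x$sensitivity$lower,
             sensitivity_high = x$sensitivity$upper,
             specificity = x$specificity$estimate,
             specificity_low = x$specificity$lower,
             specificity_high = x$specificity$upper,
             ppv = x$ppv$estimate,
             ppv_low = x$ppv$lower,
             ppv_high = x$ppv$upper,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
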