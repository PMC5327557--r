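# Temporal matching of ascertained cases against the gold-standard registry.

#' Classify persons as TP / FN / FP / TN against the registry
#'
#' Every evaluated person receives exactly one label for one cancer type,
#' one indicator and one matching half-width `W` (months):
#'
#' * `TP` — registry case (earliest registry record of the cancer type
#'   inside the evaluation window) whose indicator first date lies within
#'   `W` months either side of the registry diagnosis month;
#' * `FN` — registry case never flagged by the indicator in the window;
#' * `FN_and_FP` — registry case flagged, but outside the matching window;
#'   counted as a miss for sensitivity and as a false alarm for PPV;
#' * `FP` — flagged person with no in-window registry record;
#' * `TN` — neither flagged nor a registry case.
#'
#' Lags are month-index differences (`first date` minus `diagnosis month`);
#' the registry supplies no day of diagnosis, so sub-month timing never
#' enters the match.
#'
#' @param asc An `"ascertainment"` set (see [extract_indicator()]).
#' @param registry Registry table (see [cohort()]).
#' @param cancer_type Registry cancer type to evaluate.
#' @param eval_window Character `c(start, end)`, `"YYYY-MM"`: the period
#'   over which registry and surrogate data are compared.
#' @param window_months Matching half-width `W` in months (default 12).
#' @param persons Character vector of evaluated person ids (or a persons
#'   data.frame with a `person_id` column): the denominator population.
#' @return A `"match_classification"` data.frame with columns `person_id`,
#'   `label`, `lag_months` (TP and FN_and_FP only), `diagnosis_month`,
#'   `first_date`.
#' @export
classify_cases <- function(asc, registry, cancer_type, eval_window,
                           window_months = 12, persons) {
  stopifnot(window_months >= 0)
  if (is.data.frame(persons)) persons <- persons$person_id
  persons <- as.character(persons)
  ws <- month_index(eval_window[1]); we <- month_index(eval_window[2])

  r <- registry[registry$cancer_type == cancer_type, , drop = FALSE]
  if (nrow(r)) {
    rmi <- month_index(r$diagnosis_month)
    r <- r[rmi >= ws & rmi <= we, , drop = FALSE]
  }
  diag_mi <- rep(NA_integer_, length(persons))
  if (nrow(r)) {
    rmi <- month_index(r$diagnosis_month)
    ord <- order(r$person_id, rmi)
    r <- r[ord, , drop = FALSE]
    first <- r[!duplicated(r$person_id), , drop = FALSE]
    diag_mi[match(first$person_id, persons)] <-
      month_index(first$diagnosis_month)
  }

  first_mi <- rep(NA_integer_, length(persons))
  first_date <- rep(NA_character_, length(persons))
  if (nrow(asc)) {
    i <- match(asc$person_id, persons)
    ok <- !is.na(i)
    first_mi[i[ok]] <- month_index(asc$first_date[ok])
    first_date[i[ok]] <- asc$first_date[ok]
  }

  is_case <- !is.na(diag_mi)
  flagged <- !is.na(first_mi)
  lag <- first_mi - diag_mi
  label <- ifelse(is_case & flagged & abs(lag) <= window_months, "TP",
           ifelse(is_case & flagged, "FN_and_FP",
           ifelse(is_case, "FN",
           ifelse(flagged, "FP", "TN"))))

  out <- data.frame(person_id = persons, label = label,
                    lag_months = ifelse(is_case & flagged, lag, NA_integer_),
                    diagnosis_month = ifelse(is_case, format_month(diag_mi),
                                             NA_character_),
                    first_date = first_date,
                    stringsAsFactors = FALSE)
  structure(out, class = c("match_classification", "data.frame"),
            cancer_type = cancer_type,
            indicator = attr(asc, "indicator"),
            window_months = window_months,
            eval_window = eval_window)
}

#' @export
print.match_classification <- function(x, ...) {
  tab <- table(factor(x$label, c("TP", "FN", "FN_and_FP", "FP", "TN")))
  cat(sprintf("Match classification: %s, indicator '%s', W = %d months\n",
              attr(x, "cancer_type"), attr(x, "indicator"),
              attr(x, "window_months")))
  print(tab)
  invisible(x)
}
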