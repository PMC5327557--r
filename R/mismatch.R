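# Characterisation of matched vs unmatched registry cases: are the cases the
# surrogate misses systematically different?

share_table <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NULL)
  tab <- table(x)
  as.data.frame(prop.table(tab), stringsAsFactors = FALSE,
                responseName = "share")
}

group_summary <- function(ids, persons, registry_first, death_within) {
  pi <- match(ids, persons$person_id)
  ri <- match(ids, registry_first$person_id)
  age <- registry_first$age_at_diagnosis[ri]
  dmi <- persons$death_date[pi]
  diag_mi <- month_index(registry_first$diagnosis_month[ri])
  death_mi <- rep(NA_integer_, length(ids))
  hd <- !is.na(dmi)
  if (any(hd)) death_mi[hd] <- month_index(dmi[hd])
  list(
    n = length(ids),
    spread = share_table(registry_first$spread_of_disease[ri]),
    remoteness = share_table(persons$remoteness[pi]),
    low_ses_share = mean(persons$ses_quintile[pi] >= 4, na.rm = TRUE),
    border_share = mean(persons$border_resident[pi], na.rm = TRUE),
    age_median = stats::median(age, na.rm = TRUE),
    age_iqr = unname(stats::quantile(age, c(0.25, 0.75), na.rm = TRUE,
                                     type = 7)),
    death_within = vapply(death_within, function(k) {
      sum(!is.na(death_mi) & death_mi - diag_mi <= k, na.rm = TRUE)
    }, numeric(1))
  )
}

#' Compare matched and unmatched registry cases
#'
#' Splits the registry cases of a classification into "matches" (label
#' `TP`) and "non-matches" (`FN` or `FN_and_FP`) and summarises each group:
#' distribution of spread of disease at diagnosis and of remoteness, share
#' living in the two most disadvantaged SES quintiles, share resident near
#' a state border, median and IQR of age at diagnosis, and counts dying
#' within `death_within` months of the diagnosis month.  Category shares
#' sum to one within each group.
#'
#' @param mc A `"match_classification"`.
#' @param persons Persons table of the evaluated cohort.
#' @param registry Registry table (used for spread of disease and age at
#'   diagnosis of the earliest in-window record per person).
#' @param death_within Integer vector of month horizons for death counts
#'   (default `c(1, 12)`).
#' @return A `"mismatch_report"`: list with `matches` and `non_matches`
#'   group summaries and a `degenerate` flag when either group is empty.
#' @export
stratify_mismatches <- function(mc, persons, registry,
                                death_within = c(1, 12)) {
  ct <- attr(mc, "cancer_type")
  ew <- attr(mc, "eval_window")
  ws <- month_index(ew[1]); we <- month_index(ew[2])
  r <- registry[registry$cancer_type == ct, , drop = FALSE]
  rmi <- month_index(r$diagnosis_month)
  r <- r[rmi >= ws & rmi <= we, , drop = FALSE]
  r <- r[order(r$person_id, month_index(r$diagnosis_month)), , drop = FALSE]
  registry_first <- r[!duplicated(r$person_id), , drop = FALSE]

  match_ids <- mc$person_id[mc$label == "TP"]
  nonmatch_ids <- mc$person_id[mc$label %in% c("FN", "FN_and_FP")]

  for (col in c("remoteness", "ses_quintile", "border_resident")) {
    if (all(is.na(persons[[col]])))
      warning("attribute '", col, "' wholly missing; stratum omitted",
              call. = FALSE)
  }
  names(death_within) <- paste0("within_", death_within, "m")
  out <- list(
    matches = group_summary(match_ids, persons, registry_first,
                            death_within),
    non_matches = group_summary(nonmatch_ids, persons, registry_first,
                                death_within),
    degenerate = length(match_ids) == 0L || length(nonmatch_ids) == 0L,
    cancer_type = ct)
  class(out) <- "mismatch_report"
  out
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(sprintf("Mismatch report (%s): %d matches vs %d non-matches%s\n",
              x$cancer_type, x$matches$n, x$non_matches$n,
              if (x$degenerate) " [degenerate group]" else ""))
  for (g in c("matches", "non_matches")) {
    s <- x[[g]]
    if (s$n == 0) next
    cat(sprintf("  %s: low-SES %.0f%%, border %.0f%%, median age %.0f (IQR %.0f-%.0f)\n",
                g, 100 * s$low_ses_share, 100 * s$border_share,
                s$age_median, s$age_iqr[1], s$age_iqr[2]))
    if (!is.null(s$spread)) {
      cat("    spread of disease: ",
          paste(sprintf("%s %.0f%%", s$spread[[1]], 100 * s$spread$share),
                collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}
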