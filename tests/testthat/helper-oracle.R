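# Brute-force reference implementations: per-person scans over all events
# and slots, written as directly as possible so they stay independent of
# the package's vectorised code paths.

oracle_code_match <- function(code, code_set, prefix) {
  norm <- function(x) gsub(".", "", toupper(trimws(x)), fixed = TRUE)
  for (i in seq_along(code_set)) {
    if (prefix[i]) {
      if (startsWith(norm(code), norm(code_set[i]))) return(TRUE)
    } else {
      if (norm(code) == norm(code_set[i])) return(TRUE)
    }
  }
  FALSE
}

oracle_extract <- function(events, ind, eval_window) {
  ws <- month_index(eval_window[1]); we <- month_index(eval_window[2])
  out_id <- character(0); out_date <- character(0)
  for (p in unique(events$person_id)) {
    best <- NULL   # list(mi, has_day, day, slot, date)
    rows <- which(events$person_id == p)
    for (r in rows) {
      if (events$source[r] != ind$source) next
      if (events$slot_role[r] != ind$slot_role) next
      if (events$code_system[r] != ind$code_system) next
      if (ind$source == "death" && ind$cause_position == "underlying_only" &&
          events$slot[r] != 1L) next
      mi <- month_index(events$event_date[r])
      if (mi < ws || mi > we) next
      if (!oracle_code_match(events$code[r], ind$code_set, ind$prefix)) next
      d <- parse_study_date(events$event_date[r])
      cand <- list(mi = mi, has_day = !is.na(d$day),
                   day = if (is.na(d$day)) 99L else d$day,
                   slot = events$slot[r], date = events$event_date[r])
      if (is.null(best) ||
          cand$mi < best$mi ||
          (cand$mi == best$mi && cand$has_day && !best$has_day) ||
          (cand$mi == best$mi && cand$has_day == best$has_day &&
             cand$day < best$day) ||
          (cand$mi == best$mi && cand$has_day == best$has_day &&
             cand$day == best$day && cand$slot < best$slot)) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      out_id <- c(out_id, p)
      out_date <- c(out_date, best$date)
    }
  }
  data.frame(person_id = out_id, first_date = out_date,
             stringsAsFactors = FALSE)
}

# per-person truth-table evaluation of a composite expression tree
oracle_composite_members <- function(tree, member_sets) {
  if (!is.null(tree$leaf)) return(member_sets[[tree$leaf]])
  parts <- lapply(tree$args, oracle_composite_members, member_sets)
  if (tree$op == "OR") Reduce(union, parts) else Reduce(intersect, parts)
}

oracle_classify <- function(asc, registry, cancer_type, eval_window, W,
                            persons) {
  ws <- month_index(eval_window[1]); we <- month_index(eval_window[2])
  labels <- character(length(persons))
  for (j in seq_along(persons)) {
    p <- persons[j]
    diag <- NA_integer_
    for (r in which(registry$person_id == p &
                    registry$cancer_type == cancer_type)) {
      mi <- month_index(registry$diagnosis_month[r])
      if (mi >= ws && mi <= we && (is.na(diag) || mi < diag)) diag <- mi
    }
    first <- NA_integer_
    hit <- which(asc$person_id == p)
    if (length(hit)) first <- month_index(asc$first_date[hit[1]])
    labels[j] <-
      if (!is.na(diag) && !is.na(first) && abs(first - diag) <= W) "TP"
      else if (!is.na(diag) && !is.na(first)) "FN_and_FP"
      else if (!is.na(diag)) "FN"
      else if (!is.na(first)) "FP"
      else "TN"
  }
  labels
}

# Random small linked fixture with near-miss codes and mixed precision
# dates, for oracle-equivalence and property testing.
random_fixture <- function(seed, n_persons = 60, n_events = 150) {
  set.seed(seed)
  pid <- sprintf("q%03d", seq_len(n_persons))
  persons <- data.frame(
    person_id = pid,
    baseline_date = "2006-01-15",
    age_at_baseline = sample(45:90, n_persons, replace = TRUE),
    sex = sample(c("female", "male"), n_persons, replace = TRUE),
    ses_quintile = sample(1:5, n_persons, replace = TRUE),
    remoteness = sample(c("metropolitan", "non_metropolitan"), n_persons,
                        replace = TRUE),
    border_resident = sample(c(TRUE, FALSE), n_persons, replace = TRUE),
    death_date = NA_character_,
    stringsAsFactors = FALSE)
  code_pool <- c("C18.1", "C18.9", "C19", "C20.0", "C20", "C34.1", "C341",
                 "C34.9", "C78.5", "C79.9", "Z85.0", "Z85.1", "K52.9",
                 "J44.9", "32024", "38438", "13950")
  months <- month_index("2006-02"):month_index("2010-12")
  mi <- sample(months, n_events, replace = TRUE)
  has_day <- sample(c(TRUE, FALSE), n_events, replace = TRUE, prob = c(.7, .3))
  dates <- ifelse(has_day,
                  sprintf("%s-%02d", format_month(mi),
                          sample(1:28, n_events, replace = TRUE)),
                  format_month(mi))
  events <- data.frame(
    event_id = sprintf("ev%04d", seq_len(n_events)),
    person_id = sample(pid, n_events, replace = TRUE),
    source = sample(c("inpatient", "emergency", "claims_medical",
                      "claims_pharma", "death"), n_events, replace = TRUE,
                    prob = c(.5, .1, .15, .1, .15)),
    event_date = dates,
    slot_role = sample(c("diagnosis", "procedure", "item",
                         "cause_of_death"), n_events, replace = TRUE),
    code_system = sample(c("ICD10", "ICD9", "ACHI", "MBS_ITEM"), n_events,
                         replace = TRUE, prob = c(.7, .1, .1, .1)),
    code = sample(code_pool, n_events, replace = TRUE),
    slot = sample(1:5, n_events, replace = TRUE),
    stringsAsFactors = FALSE)
  n_reg <- max(3L, rpois(1, n_persons / 6))
  registry <- data.frame(
    person_id = sample(pid, n_reg, replace = TRUE),
    cancer_type = sample(c("colorectal", "lung"), n_reg, replace = TRUE),
    diagnosis_month = format_month(sample(months, n_reg, replace = TRUE)),
    spread_of_disease = sample(c("localised", "regional", "distant",
                                 "unknown"), n_reg, replace = TRUE),
    age_at_diagnosis = sample(45:95, n_reg, replace = TRUE),
    stringsAsFactors = FALSE)
  coverage <- data.frame(
    source = c("inpatient", "emergency", "claims_medical", "claims_pharma",
               "death"),
    start = "2001-01", end = "2014-12", stringsAsFactors = FALSE)
  list(persons = persons, events = events, registry = registry,
       coverage = coverage,
       eval_window = c("2006-02", "2010-12"))
}

# minimal valid cohort tables for constructor-level tests
tiny_cohort_tables <- function() {
  persons <- data.frame(
    person_id = c("a", "b", "c"),
    baseline_date = c("2006-03-10", "2007-01-02", "2008-11-20"),
    age_at_baseline = c(52, 61, 70),
    sex = c("female", "male", "female"),
    ses_quintile = c(2L, 5L, 3L),
    remoteness = c("metropolitan", "non_metropolitan", "metropolitan"),
    border_resident = c(FALSE, TRUE, FALSE),
    death_date = c(NA, "2010-06-15", NA),
    stringsAsFactors = FALSE)
  events <- data.frame(
    event_id = c("e1", "e1", "e2", "e3"),
    person_id = c("a", "a", "b", "c"),
    source = c("inpatient", "inpatient", "inpatient", "death"),
    event_date = c("2007-05-14", "2007-05-14", "2009-02-01", "2010-01"),
    slot_role = c("diagnosis", "procedure", "diagnosis", "cause_of_death"),
    code_system = c("ICD10", "ACHI", "ICD10", "ICD10"),
    code = c("C18.2", "32024", "K52.9", "C34.1"),
    slot = c(1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
  registry <- data.frame(
    person_id = c("a", "c"),
    cancer_type = c("colorectal", "lung"),
    diagnosis_month = c("2007-05", "2009-12"),
    spread_of_disease = c("localised", "distant"),
    age_at_diagnosis = c(53.2, 71.1),
    stringsAsFactors = FALSE)
  coverage <- data.frame(
    source = c("inpatient", "death", "registry"),
    start = c("2001-07", "2006-01", "1994-01"),
    end = c("2014-06", "2012-12", "2010-12"),
    stringsAsFactors = FALSE)
  list(persons = persons, events = events, registry = registry,
       coverage = coverage)
}

# strip class/attributes for content comparison of ascertainment sets
norm_asc <- function(x) {
  d <- data.frame(person_id = as.character(x$person_id),
                  first_date = as.character(x$first_date),
                  stringsAsFactors = FALSE)
  d <- d[order(d$person_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}
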