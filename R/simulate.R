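# Synthetic linked-cohort generator with known ground truth.
#
# The generator emulates the statistical structure of a mid-to-older-age
# cohort linked to inpatient, emergency, medical-claims, pharmaceutical and
# death data plus a gold-standard cancer registry: per-cancer incidence over
# the evaluation window, month-lagged probabilistic coding of true cases,
# prevalent-case re-coding, pure miscoding, interstate-leakage capture loss
# for border residents, case fatality with imperfect death-certificate
# coding (including secondary-site and other-disease miscertification), and
# treatment records.  Every emitted event is traceable to one generating
# mechanism, and the detection model admits exact closed-form expected
# metrics (see expected_metrics), so the whole validation pipeline is
# testable by parameter recovery.
#
# Deliberate simplifications, chosen to keep the closed forms exact: cancer
# statuses are mutually exclusive across types within a person; miscoded
# events arise only in persons with no true cancer history; no event is
# ever dated after its person's death; repeat admissions are emitted only
# after an in-window first coded admission.

#' Per-cancer simulation parameters
#'
#' All probabilities are per the unit stated; the defaults describe a
#' colorectal-like cancer in a 45+ cohort.
#'
#' @param incidence_month Per-person per-month probability of incident
#'   diagnosis within the evaluation (and extension) window.
#' @param p_code Probability a true case ever receives a matching inpatient
#'   diagnosis code (before the border capture penalty).
#' @param lag_pmf Named numeric vector: probability mass over the lag in
#'   months between registry diagnosis month and first coded admission
#'   (names are integer offsets; must sum to 1).  Mass beyond the matching
#'   half-width creates out-of-window identifications.
#' @param prevalent_fraction Probability a person with no incident cancer
#'   is a prevalent case (diagnosed before the window).
#' @param p_recode Probability a prevalent case is re-coded with a primary
#'   diagnosis code during the window.
#' @param miscode_month Per-person per-month probability of a spurious
#'   matching diagnosis code in a person with no cancer history.
#' @param case_fatality_month Monthly case fatality after diagnosis.
#' @param p_prevalent_death Probability a prevalent case dies during the
#'   evaluation window.
#' @param p_death_cause Probability the death certificate of a dying case
#'   (incident or prevalent) carries the cancer as a cause.
#' @param p_secondary_miscode Probability that the death certificate of a
#'   dying case of *another* cancer type miscertifies this type as the
#'   underlying cause; such certificates also carry a secondary-site code.
#' @param p_death_miscert Probability a person with no cancer history dies
#'   during the window with this cancer certified as the underlying cause
#'   (other disease of the site).
#' @param p_surgery,p_mbs_surgery,p_mbs_chemo,p_pbs_chemo,p_ed,p_history
#'   Probabilities that an incident case accrues, respectively, an
#'   inpatient surgical resection, a claims surgical item, claims
#'   chemotherapy items, pharmaceutical chemotherapy supplies, an
#'   emergency-department diagnosis, and later history-of-cancer coded
#'   admissions.
#' @param p_history_prevalent Probability a prevalent case accrues
#'   history-of-cancer coded admissions in the window.
#' @param bg_surgery,bg_mbs_chemo,bg_pbs_chemo,bg_ed Per-person (whole
#'   window) probabilities of the corresponding records in persons with no
#'   cancer history (treatments indicated for, but not exclusive to, the
#'   cancer).
#' @param repeat_mean Mean number of repeat coded admissions after the
#'   first.
#' @return List of class `"cancer_sim_params"`.
#' @export
cancer_sim_params <- function(incidence_month = 1.45e-4,
                              p_code = 0.97,
                              lag_pmf = c("-1" = 0.03, "0" = 0.85,
                                          "1" = 0.05, "2" = 0.02,
                                          "3" = 0.015, "6" = 0.01,
                                          "12" = 0.005, "13" = 0.01,
                                          "18" = 0.01),
                              prevalent_fraction = 0.003,
                              p_recode = 0.25,
                              miscode_month = 6e-6,
                              case_fatality_month = 0.012,
                              p_prevalent_death = 0.10,
                              p_death_cause = 0.80,
                              p_secondary_miscode = 0.03,
                              p_death_miscert = 2e-5,
                              p_surgery = 0.85, p_mbs_surgery = 0.45,
                              p_mbs_chemo = 0.30, p_pbs_chemo = 0.35,
                              p_ed = 0.01, p_history = 0.25,
                              p_history_prevalent = 0.30,
                              bg_surgery = 0.004, bg_mbs_chemo = 0.015,
                              bg_pbs_chemo = 0.004, bg_ed = 1e-4,
                              repeat_mean = 1.0) {
  p <- as.list(environment())
  pv <- unlist(p[setdiff(names(p), c("lag_pmf", "repeat_mean"))])
  if (any(pv < 0 | pv > 1))
    stop("configuration error: probabilities must lie in [0, 1]",
         call. = FALSE)
  offs <- suppressWarnings(as.integer(names(lag_pmf)))
  if (anyNA(offs)) stop("lag_pmf names must be integer offsets",
                        call. = FALSE)
  if (any(lag_pmf < 0) || abs(sum(lag_pmf) - 1) > 1e-8)
    stop("configuration error: lag_pmf must be a probability mass function",
         call. = FALSE)
  if (repeat_mean < 0) stop("repeat_mean must be >= 0", call. = FALSE)
  class(p) <- "cancer_sim_params"
  p
}

#' Synthetic cohort configuration
#'
#' @param n_persons Cohort size (>= 1).
#' @param eval_window `c(start, end)` `"YYYY-MM"`: the period over which
#'   registry and surrogate data overlap and validation is performed.
#' @param registry_start First month of registry history (prevalent cases
#'   are diagnosed between here and the window start).
#' @param extension_end Last month of inpatient follow-through beyond the
#'   registry, for incremental-case counting.
#' @param recruit_window `c(start, end)` of baseline recruitment.
#' @param cancers Named list of [cancer_sim_params()], one per cancer type
#'   key of the diagnosis code-set dictionary.
#' @param border_fraction Fraction of the cohort resident near a state
#'   border.
#' @param border_penalty Multiplier (< 1 loses capture) on `p_code` for
#'   border residents, emulating interstate hospitalisation loss.
#' @param coverage Optional coverage data.frame overriding the defaults
#'   (inpatient from 2001-07 to `extension_end`; emergency 2005-01 to
#'   2014-12; claims 2004-06 to 2014-12; death 2006-01 to 2012-12).
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical tables.
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(n_persons = 50000,
                          eval_window = c("2006-02", "2010-12"),
                          registry_start = "1994-01",
                          extension_end = "2014-06",
                          recruit_window = c("2006-01", "2009-12"),
                          cancers = list(
                            colorectal = cancer_sim_params(),
                            lung = cancer_sim_params(
                              incidence_month = 6.6e-5,
                              p_code = 0.87,
                              lag_pmf = c("-1" = 0.025, "0" = 0.55,
                                          "1" = 0.10, "2" = 0.07,
                                          "3" = 0.06, "4" = 0.05,
                                          "5" = 0.01, "6" = 0.04,
                                          "9" = 0.03, "12" = 0.025,
                                          "14" = 0.02, "20" = 0.02),
                              prevalent_fraction = 8e-4,
                              p_recode = 0.2,
                              miscode_month = 1.5e-6,
                              case_fatality_month = 0.045,
                              p_prevalent_death = 0.25,
                              p_death_cause = 0.90,
                              p_secondary_miscode = 0.04,
                              p_death_miscert = 4e-5,
                              p_surgery = 0.25, p_mbs_surgery = 0.15,
                              p_mbs_chemo = 0.40, p_pbs_chemo = 0.35,
                              p_ed = 0.03, p_history = 0.10,
                              p_history_prevalent = 0.15,
                              bg_surgery = 0.002, bg_mbs_chemo = 0.02,
                              bg_pbs_chemo = 0.01, bg_ed = 2e-4)),
                          border_fraction = 0.08,
                          border_penalty = 0.5,
                          coverage = NULL,
                          seed = 1L) {
  if (n_persons < 1) stop("n_persons must be >= 1", call. = FALSE)
  if (border_fraction < 0 || border_fraction > 1 ||
      border_penalty < 0 || border_penalty > 1)
    stop("configuration error: border parameters must lie in [0, 1]",
         call. = FALSE)
  if (!length(cancers) || is.null(names(cancers)))
    stop("cancers must be a named list of cancer_sim_params", call. = FALSE)
  for (ct in names(cancers)) {
    if (!inherits(cancers[[ct]], "cancer_sim_params"))
      stop("cancers$", ct, " is not a cancer_sim_params object",
           call. = FALSE)
  }
  ws <- month_index(eval_window[1]); we <- month_index(eval_window[2])
  if (ws > we) stop("eval_window start after end", call. = FALSE)
  q1 <- vapply(cancers, function(p)
    1 - (1 - p$incidence_month)^(we - ws + 1), numeric(1))
  if (sum(q1) >= 1)
    stop("configuration error: combined incidence too high", call. = FALSE)
  if (is.null(coverage)) {
    coverage <- data.frame(
      source = c("inpatient", "emergency", "claims_medical",
                 "claims_pharma", "death"),
      start = c("2001-07", "2005-01", "2004-06", "2004-06", "2006-01"),
      end = c(extension_end, "2014-12", "2014-12", "2014-12", "2012-12"),
      stringsAsFactors = FALSE)
  }
  structure(list(n_persons = as.integer(n_persons),
                 eval_window = eval_window,
                 registry_start = registry_start,
                 registry_end = eval_window[2],
                 extension_end = extension_end,
                 recruit_window = recruit_window,
                 cancers = cancers,
                 border_fraction = border_fraction,
                 border_penalty = border_penalty,
                 coverage = coverage,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

terminal_dx_codes <- function(ct) {
  switch(ct,
         colorectal = c("C18.0", "C18.2", "C18.7", "C18.9", "C19", "C20"),
         lung = c("C34.0", "C34.1", "C34.3", "C34.8", "C34.9"),
         paste0(toupper(substr(ct, 1, 1)), "99.9"))
}
SECONDARY_DX_CODES <- c("C78.0", "C78.5", "C78.7", "C79.9")
OTHER_CAUSE_CODES <- c("I21.9", "I50.0", "J44.9", "I64")

rand_day <- function(n) sample.int(28L, n, replace = TRUE)
date_str <- function(mi, day) sprintf("%s-%02d", format_month(mi), day)

#' Generate a synthetic linked cohort with ground truth
#'
#' See [cohort_config()] for the generative model.  Reproducible: the
#' configured seed spawns one sub-seed per mechanism and source, so adding
#' a mechanism draws from a fresh stream.
#'
#' @param cfg A [cohort_config()].
#' @return List with elements `cohort` (a validated [cohort()]; the
#'   registry table holds exactly the true incident in-window cases plus
#'   prevalent cases within registry coverage), `truth` (list of `persons`
#'   — per-person true status, diagnosis month, coding outcome and death —
#'   and `events` — per-event generating mechanism), and `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  N <- cfg$n_persons
  ws <- month_index(cfg$eval_window[1]); we <- month_index(cfg$eval_window[2])
  M <- we - ws + 1L
  re <- month_index(cfg$registry_end)
  xe <- month_index(cfg$extension_end)
  rs <- month_index(cfg$registry_start)
  cts <- names(cfg$cancers)
  NODEATH <- .Machine$integer.max %/% 4L

  set.seed(cfg$seed)
  sub_seed <- sample.int(.Machine$integer.max - 1L, 400L)
  k <- 0L
  stage <- function() { k <<- k + 1L; set.seed(sub_seed[k]) }

  ## demographics ----------------------------------------------------------
  stage()
  pid <- sprintf("p%06d", seq_len(N))
  rws <- month_index(cfg$recruit_window[1])
  rwe <- month_index(cfg$recruit_window[2])
  base_mi <- sample(rws:rwe, N, replace = TRUE)
  persons <- data.frame(
    person_id = pid,
    baseline_date = date_str(base_mi, rand_day(N)),
    age_at_baseline = pmin(99, pmax(45, round(stats::rnorm(N, 62, 10)))),
    sex = sample(c("female", "male"), N, replace = TRUE,
                 prob = c(0.54, 0.46)),
    ses_quintile = sample(1:5, N, replace = TRUE),
    remoteness = sample(c("metropolitan", "non_metropolitan"), N,
                        replace = TRUE, prob = c(0.55, 0.45)),
    border_resident = stats::runif(N) < cfg$border_fraction,
    death_date = NA_character_,
    stringsAsFactors = FALSE)

  ## mutually exclusive cancer status across types -------------------------
  stage()
  Mx <- max(0L, xe - re)                     # extension months
  q1 <- vapply(cts, function(ct)
    1 - (1 - cfg$cancers[[ct]]$incidence_month)^M, numeric(1))
  q2 <- vapply(cts, function(ct)
    1 - (1 - cfg$cancers[[ct]]$incidence_month)^Mx, numeric(1))
  fr <- vapply(cts, function(ct) cfg$cancers[[ct]]$prevalent_fraction,
               numeric(1))
  r1 <- 1 - sum(q1)
  r2 <- r1 * (1 - sum(q2))
  widths <- c(q1, r1 * q2, r2 * fr)
  status_names <- c(paste0("inc_", cts), paste0("ext_", cts),
                    paste0("prev_", cts))
  u <- stats::runif(N)
  status_idx <- findInterval(u, cumsum(c(0, widths)),
                             rightmost.closed = FALSE)
  status <- rep("never", N)
  inside <- status_idx >= 1L & status_idx <= length(widths)
  status[inside] <- status_names[status_idx[inside]]

  truth_p <- data.frame(person_id = pid, status = "never",
                        cancer_type = NA_character_,
                        diagnosis_month = NA_character_,
                        coded = NA, lag = NA_integer_,
                        death_month = NA_character_,
                        death_mechanism = NA_character_,
                        stringsAsFactors = FALSE)
  registry_rows <- list()
  event_rows <- list()
  death_mi_all <- rep(NA_integer_, N)   # realised death month (<= xe kept)
  death_ct <- rep(NA_character_, N)     # true cancer behind a case death

  add_events <- function(person, mi, day, source, slot_role, code_system,
                         code, slot, mechanism, record) {
    event_rows[[length(event_rows) + 1L]] <<- data.frame(
      person_id = person, event_mi = mi, day = day, source = source,
      slot_role = slot_role, code_system = code_system, code = code,
      slot = slot, mechanism = mechanism, record = record,
      stringsAsFactors = FALSE)
  }

  cov_of <- function(src) {
    i <- match(src, cfg$coverage$source)
    c(month_index(cfg$coverage$start[i]), month_index(cfg$coverage$end[i]))
  }
  cov_inp <- cov_of("inpatient"); cov_ed <- cov_of("emergency")
  cov_mbs <- cov_of("claims_medical"); cov_pbs <- cov_of("claims_pharma")
  cov_cod <- cov_of("death")

  for (ct in cts) {
    pm <- cfg$cancers[[ct]]
    dxc <- terminal_dx_codes(ct)
    items <- synthetic_item_codes(ct)
    hist_code <- default_code_sets()$history[[ct]]
    if (is.null(hist_code)) hist_code <- "Z85.9"

    inc_i <- which(status == paste0("inc_", ct))
    ext_i <- which(status == paste0("ext_", ct))
    prev_i <- which(status == paste0("prev_", ct))
    case_i <- c(inc_i, ext_i)

    ## diagnosis months and survival ---------------------------------------
    stage()
    D <- integer(N)
    D[inc_i] <- ws + (sample.int(M, length(inc_i), replace = TRUE) - 1L)
    if (length(ext_i)) {
      D[ext_i] <- re + sample.int(Mx, length(ext_i), replace = TRUE)
    }
    S <- rep(NODEATH, N)
    if (pm$case_fatality_month > 0 && length(case_i)) {
      S[case_i] <- stats::rgeom(length(case_i), pm$case_fatality_month)
    }
    dmi <- rep(NA_integer_, N)
    dmi[case_i] <- pmin(D[case_i] + S[case_i], NODEATH)

    ## detection in the inpatient source -----------------------------------
    stage()
    p_eff <- pm$p_code *
      ifelse(persons$border_resident, cfg$border_penalty, 1)
    coded <- logical(N)
    if (length(case_i))
      coded[case_i] <- stats::runif(length(case_i)) < p_eff[case_i]
    offs <- as.integer(names(pm$lag_pmf))
    lag <- rep(NA_integer_, N)
    cc <- case_i[coded[case_i]]
    if (length(cc))
      lag[cc] <- sample(offs, length(cc), replace = TRUE, prob = pm$lag_pmf)
    E <- D + lag
    emit <- rep(FALSE, N)
    emit[cc] <- S[cc] >= pmax(lag[cc], 0L) &
      E[cc] >= cov_inp[1] & E[cc] <= cov_inp[2]
    ee <- intersect(cc, ext_i)
    emit[ee] <- emit[ee] & E[ee] > re
    em_i <- which(emit)
    if (length(em_i)) {
      add_events(pid[em_i], E[em_i], rand_day(length(em_i)), "inpatient",
                 "diagnosis", "ICD10",
                 sample(dxc, length(em_i), replace = TRUE),
                 sample(1:3, length(em_i), replace = TRUE),
                 "true_case_coding", paste0("dx_", ct, "_", em_i))
    }

    ## repeat coded admissions after an in-window first admission ----------
    stage()
    first_in_eval <- em_i[E[em_i] >= ws & E[em_i] <= we & em_i %in% inc_i]
    if (length(first_in_eval) && pm$repeat_mean > 0) {
      nrep <- stats::rpois(length(first_in_eval), pm$repeat_mean)
      idx <- rep(first_in_eval, nrep)
      if (length(idx)) {
        gap <- cumsum_gaps(idx, 1L + stats::rgeom(length(idx), 0.25))
        rm_ <- E[idx] + gap
        cap <- pmin(we, dmi[idx])
        keep <- rm_ <= cap
        if (any(keep)) {
          add_events(pid[idx[keep]], rm_[keep], rand_day(sum(keep)),
                     "inpatient", "diagnosis", "ICD10",
                     sample(dxc, sum(keep), replace = TRUE),
                     sample(1:3, sum(keep), replace = TRUE),
                     "repeat_coding",
                     paste0("rep_", ct, "_", seq_len(length(idx))[keep]))
        }
      }
    }

    ## prevalent cases: history in registry, deaths, re-coding, Z85 --------
    stage()
    Dp <- integer(N)
    prev_death <- integer(0)
    if (length(prev_i)) {
      Dp[prev_i] <- rs + (sample.int(ws - rs, length(prev_i),
                                     replace = TRUE) - 1L)
      prev_death <- prev_i[stats::runif(length(prev_i)) <
                             pm$p_prevalent_death]
      if (length(prev_death)) {
        dmi[prev_death] <- ws + (sample.int(M, length(prev_death),
                                            replace = TRUE) - 1L)
        death_ct[prev_death] <- ct
      }
      recode <- prev_i[stats::runif(length(prev_i)) < pm$p_recode]
      if (length(recode)) {
        # re-code month uniform over the window, truncated at death
        hi <- pmin(we, ifelse(is.na(dmi[recode]), we, dmi[recode]))
        rec_mi <- ws + floor(stats::runif(length(recode)) * (hi - ws + 1L))
        add_events(pid[recode], as.integer(rec_mi), rand_day(length(recode)),
                   "inpatient", "diagnosis", "ICD10",
                   sample(dxc, length(recode), replace = TRUE),
                   sample(1:3, length(recode), replace = TRUE),
                   "prevalent_recode", paste0("prc_", ct, "_", recode))
      }
      hist_p <- prev_i[stats::runif(length(prev_i)) <
                         pm$p_history_prevalent]
      if (length(hist_p)) {
        hi <- pmin(we, ifelse(is.na(dmi[hist_p]), we, dmi[hist_p]))
        hm <- ws + floor(stats::runif(length(hist_p)) * (hi - ws + 1L))
        add_events(pid[hist_p], as.integer(hm), rand_day(length(hist_p)),
                   "inpatient", "diagnosis", "ICD10", hist_code,
                   sample(4:10, length(hist_p), replace = TRUE),
                   "prevalent_history", paste0("phx_", ct, "_", hist_p))
      }
    }

    ## treatments and other sources for incident/extension cases ----------
    stage()
    treat <- function(prob, src, role, sys, codes, lag_max, covr, mech,
                      n_items_max = 1L) {
      if (!length(case_i)) return(invisible())
      sel <- case_i[stats::runif(length(case_i)) < prob]
      if (!length(sel)) return(invisible())
      n_it <- if (n_items_max > 1L)
        sample.int(n_items_max, length(sel), replace = TRUE)
      else rep(1L, length(sel))
      idx <- rep(sel, n_it)
      mo <- D[idx] + sample(0:lag_max, length(idx), replace = TRUE)
      cap <- pmin(dmi[idx], ifelse(idx %in% inc_i, we, xe))
      keep <- mo >= covr[1] & mo <= pmin(covr[2], cap)
      keep <- keep & !(idx %in% ext_i & mo <= re)
      if (!any(keep)) return(invisible())
      add_events(pid[idx[keep]], mo[keep], rand_day(sum(keep)), src, role,
                 sys, sample(codes, sum(keep), replace = TRUE),
                 sample(1:4, sum(keep), replace = TRUE), mech,
                 paste0(mech, "_", ct, "_", seq_along(idx)[keep]))
    }
    treat(pm$p_surgery, "inpatient", "procedure", "ACHI",
          items$surgery_achi, 2L, cov_inp, "treatment_surgery")
    treat(pm$p_mbs_surgery, "claims_medical", "item", "MBS_ITEM",
          items$surgery_mbs, 2L, cov_mbs, "treatment_mbs_surgery")
    treat(pm$p_mbs_chemo, "claims_medical", "item", "MBS_ITEM",
          items$chemo_mbs, 6L, cov_mbs, "treatment_mbs_chemo",
          n_items_max = 6L)
    treat(pm$p_pbs_chemo, "claims_pharma", "item", "PBS_ITEM",
          items$chemo_pbs, 6L, cov_pbs, "treatment_pbs_chemo",
          n_items_max = 6L)
    treat(pm$p_ed, "emergency", "diagnosis", "ICD10", dxc, 1L, cov_ed,
          "case_ed_dx")

    stage()
    hist_c <- inc_i[stats::runif(length(inc_i)) < pm$p_history]
    if (length(hist_c)) {
      hm <- D[hist_c] + 3L + sample(0:21, length(hist_c), replace = TRUE)
      keep <- hm <= pmin(we, dmi[hist_c])
      if (any(keep)) {
        add_events(pid[hist_c[keep]], hm[keep], rand_day(sum(keep)),
                   "inpatient", "diagnosis", "ICD10", hist_code,
                   sample(4:10, sum(keep), replace = TRUE),
                   "case_history", paste0("chx_", ct, "_", hist_c[keep]))
      }
    }

    ## registry rows --------------------------------------------------------
    stage()
    reg_i <- c(inc_i, prev_i)
    if (length(reg_i)) {
      dm <- ifelse(reg_i %in% inc_i, D[reg_i], Dp[reg_i])
      in_cov <- dm >= rs & dm <= re
      reg_i2 <- reg_i[in_cov]; dm <- dm[in_cov]
      spread_pool <- c("localised", "regional", "distant", "unknown")
      pr_coded <- c(0.42, 0.35, 0.11, 0.12)
      pr_uncoded <- c(0.24, 0.20, 0.11, 0.45)
      is_coded <- coded[reg_i2]
      spread <- character(length(reg_i2))
      if (any(is_coded))
        spread[is_coded] <- sample(spread_pool, sum(is_coded),
                                   replace = TRUE, prob = pr_coded)
      if (any(!is_coded))
        spread[!is_coded] <- sample(spread_pool, sum(!is_coded),
                                    replace = TRUE, prob = pr_uncoded)
      registry_rows[[length(registry_rows) + 1L]] <- data.frame(
        person_id = pid[reg_i2],
        cancer_type = ct,
        diagnosis_month = format_month(dm),
        spread_of_disease = spread,
        age_at_diagnosis = pmax(40, round(
          persons$age_at_baseline[reg_i2] + (dm - base_mi[reg_i2]) / 12,
          1)),
        stringsAsFactors = FALSE)
    }

    ## ground truth bookkeeping --------------------------------------------
    truth_p$status[inc_i] <- "incident"
    truth_p$status[ext_i] <- "incident_extension"
    truth_p$status[prev_i] <- "prevalent"
    truth_p$cancer_type[c(case_i, prev_i)] <- ct
    truth_p$diagnosis_month[case_i] <- format_month(D[case_i])
    truth_p$diagnosis_month[prev_i] <- format_month(Dp[prev_i])
    truth_p$coded[case_i] <- coded[case_i]
    truth_p$lag[cc] <- lag[cc]
    has_d <- c(case_i, prev_death)
    has_d <- has_d[!is.na(dmi[has_d]) & dmi[has_d] <= xe]
    death_mi_all[has_d] <- dmi[has_d]
    death_ct[intersect(has_d, case_i)] <- ct
    truth_p$death_month[has_d] <- format_month(dmi[has_d])
    truth_p$death_mechanism[intersect(has_d, case_i)] <- "case_fatality"
    truth_p$death_mechanism[intersect(has_d, prev_death)] <-
      "prevalent_death"
  }

  ## never-cancer persons: miscertified deaths -----------------------------
  stage()
  never_i <- which(status == "never")
  p_mcd <- vapply(cts, function(ct) cfg$cancers[[ct]]$p_death_miscert,
                  numeric(1))
  u <- stats::runif(length(never_i))
  mis_idx <- findInterval(u, cumsum(c(0, p_mcd)))
  mis_idx[u >= sum(p_mcd)] <- 0L
  miscert_any <- never_i[mis_idx >= 1L & mis_idx <= length(cts)]
  miscert_ct <- rep(NA_character_, N)
  if (length(miscert_any)) {
    miscert_ct[miscert_any] <- cts[mis_idx[mis_idx >= 1L &
                                             mis_idx <= length(cts)]]
    dm <- ws + (sample.int(M, length(miscert_any), replace = TRUE) - 1L)
    death_mi_all[miscert_any] <- dm
    truth_p$death_month[miscert_any] <- format_month(dm)
    truth_p$death_mechanism[miscert_any] <- "miscertified"
  }
  clean_i <- setdiff(never_i, miscert_any)

  ## miscoded inpatient diagnoses in clean never-cancer persons ------------
  for (ct in cts) {
    stage()
    pm <- cfg$cancers[[ct]]
    if (pm$miscode_month > 0 && length(clean_i)) {
      n_mis <- stats::rbinom(length(clean_i), M, pm$miscode_month)
      sel <- clean_i[n_mis > 0]
      nm <- n_mis[n_mis > 0]
      if (length(sel)) {
        idx <- rep(sel, nm)
        mm <- ws + (sample.int(M, length(idx), replace = TRUE) - 1L)
        add_events(pid[idx], mm, rand_day(length(idx)), "inpatient",
                   "diagnosis", "ICD10",
                   sample(terminal_dx_codes(ct), length(idx),
                          replace = TRUE),
                   sample(1:5, length(idx), replace = TRUE), "miscode",
                   paste0("mis_", ct, "_", seq_along(idx)))
      }
    }
  }

  ## one death record per dying person -------------------------------------
  stage()
  dying <- which(!is.na(death_mi_all) & death_mi_all >= cov_cod[1] &
                   death_mi_all <= cov_cod[2])
  if (length(dying)) {
    day <- rand_day(length(dying))
    # secondary-site miscertification: a dying case of type A may be
    # certified as another type B (first other type, by configured order)
    cert_as <- death_ct[dying]                       # true cancer or NA
    mech <- ifelse(is.na(cert_as), "death_other", "death_true_cause")
    sec_flag <- rep(FALSE, length(dying))
    if (length(cts) > 1L) {
      u2 <- stats::runif(length(dying))
      for (j in seq_along(dying)) {
        a <- death_ct[dying[j]]
        if (is.na(a)) next
        others <- setdiff(cts, a)
        if (!length(others)) next
        b <- others[1L]
        if (u2[j] < cfg$cancers[[b]]$p_secondary_miscode) {
          cert_as[j] <- b
          sec_flag[j] <- TRUE
          mech[j] <- "death_secondary_miscert"
        }
      }
    }
    # miscertified never-cancer deaths always carry the cancer code
    is_mc <- !is.na(miscert_ct[dying])
    cert_as[is_mc] <- miscert_ct[dying[is_mc]]
    mech[is_mc] <- "death_miscertified"

    u3 <- stats::runif(length(dying))
    for (j in seq_along(dying)) {
      i <- dying[j]
      dm <- death_mi_all[i]
      rec <- paste0("death_", i)
      ct_code <- if (!is.na(cert_as[j]))
        sample(terminal_dx_codes(cert_as[j]), 1L) else NA_character_
      p_cause <- if (!is.na(death_ct[i]))
        cfg$cancers[[death_ct[i]]]$p_death_cause else 1
      carries_ct <- !is.na(ct_code) && (is_mc[j] || sec_flag[j] ||
                                          u3[j] < p_cause)
      if (carries_ct) {
        underlying <- u3[j] < 0.8 * p_cause || is_mc[j] || sec_flag[j]
        if (underlying) {
          add_events(pid[i], dm, day[j], "death", "cause_of_death",
                     "ICD10", ct_code, 1L, mech[j], rec)
          add_events(pid[i], dm, day[j], "death", "cause_of_death",
                     "ICD10", sample(OTHER_CAUSE_CODES, 1L), 2L, mech[j],
                     rec)
        } else {
          add_events(pid[i], dm, day[j], "death", "cause_of_death",
                     "ICD10", sample(OTHER_CAUSE_CODES, 1L), 1L, mech[j],
                     rec)
          add_events(pid[i], dm, day[j], "death", "cause_of_death",
                     "ICD10", ct_code, 2L, mech[j], rec)
        }
        if (sec_flag[j]) {
          add_events(pid[i], dm, day[j], "death", "cause_of_death",
                     "ICD10", sample(SECONDARY_DX_CODES, 1L), 3L, mech[j],
                     rec)
        }
      } else {
        add_events(pid[i], dm, day[j], "death", "cause_of_death", "ICD10",
                   sample(OTHER_CAUSE_CODES, 1L), 1L, mech[j], rec)
      }
    }
  }

  ## background treatments in persons with no cancer history ---------------
  for (ct in cts) {
    stage()
    pm <- cfg$cancers[[ct]]
    items <- synthetic_item_codes(ct)
    bg <- function(prob, src, role, sys, codes, covr, mech) {
      if (!length(clean_i)) return(invisible())
      sel <- clean_i[stats::runif(length(clean_i)) < prob]
      if (!length(sel)) return(invisible())
      mo <- ws + (sample.int(M, length(sel), replace = TRUE) - 1L)
      keep <- mo >= covr[1] & mo <= covr[2]
      if (!any(keep)) return(invisible())
      add_events(pid[sel[keep]], mo[keep], rand_day(sum(keep)), src, role,
                 sys, sample(codes, sum(keep), replace = TRUE),
                 sample(1:4, sum(keep), replace = TRUE), mech,
                 paste0(mech, "_", ct, "_", sel[keep]))
    }
    bg(pm$bg_surgery, "inpatient", "procedure", "ACHI", items$surgery_achi,
       cov_inp, "background_surgery")
    bg(pm$bg_mbs_chemo, "claims_medical", "item", "MBS_ITEM",
       items$chemo_mbs, cov_mbs, "background_mbs_chemo")
    bg(pm$bg_pbs_chemo, "claims_pharma", "item", "PBS_ITEM",
       items$chemo_pbs, cov_pbs, "background_pbs_chemo")
    bg(pm$bg_ed, "emergency", "diagnosis", "ICD10", terminal_dx_codes(ct),
       cov_ed, "background_ed_dx")
  }

  ## assemble ---------------------------------------------------------------
  ev <- if (length(event_rows)) do.call(rbind, event_rows) else
    data.frame(person_id = character(0), event_mi = integer(0),
               day = integer(0), source = character(0),
               slot_role = character(0), code_system = character(0),
               code = character(0), slot = integer(0),
               mechanism = character(0), record = character(0))
  ev <- ev[order(ev$person_id, ev$event_mi, ev$source, ev$record,
                 ev$slot), , drop = FALSE]
  ev$event_id <- sprintf("e%07d", match(ev$record, unique(ev$record)))
  events <- data.frame(event_id = ev$event_id, person_id = ev$person_id,
                       source = ev$source,
                       event_date = date_str(ev$event_mi, ev$day),
                       slot_role = ev$slot_role,
                       code_system = ev$code_system, code = ev$code,
                       slot = ev$slot, stringsAsFactors = FALSE)
  rownames(events) <- NULL
  truth_events <- unique(data.frame(event_id = ev$event_id,
                                    mechanism = ev$mechanism,
                                    stringsAsFactors = FALSE))
  rownames(truth_events) <- NULL

  stage()
  hd <- which(!is.na(death_mi_all))
  persons$death_date[hd] <- date_str(death_mi_all[hd], rand_day(length(hd)))

  registry <- if (length(registry_rows)) do.call(rbind, registry_rows) else
    data.frame(person_id = character(0), cancer_type = character(0),
               diagnosis_month = character(0),
               spread_of_disease = character(0),
               age_at_diagnosis = numeric(0))
  registry <- registry[order(registry$person_id, registry$cancer_type), ,
                       drop = FALSE]
  rownames(registry) <- NULL

  coverage <- rbind(cfg$coverage,
                    data.frame(source = "registry",
                               start = cfg$registry_start,
                               end = cfg$registry_end,
                               stringsAsFactors = FALSE))

  ch <- cohort(persons, events, registry, coverage)
  list(cohort = ch,
       truth = list(persons = truth_p, events = truth_events),
       config = cfg)
}

# per-group cumulative gaps so repeat admissions are increasing in time
cumsum_gaps <- function(group, gaps) {
  o <- order(group)
  g <- gaps[o]
  grp <- group[o]
  cs <- stats::ave(g, grp, FUN = cumsum)
  out <- integer(length(gaps))
  out[o] <- cs
  out
}

#' Closed-form expected validity metrics for the synthetic model
#'
#' Analytic expectations for the inpatient primary-diagnosis indicator
#' under a [cohort_config()], against which simulated cohorts can be
#' checked (parameter recovery).  Writing `M` for the number of window
#' months, `q1` for the per-person probability of an incident in-window
#' case, `phi` for monthly case fatality and `P(l)` for the lag mass:
#'
#' * sensitivity `= p_eff * sum_{|l| <= W} P(l) * t(l) * (1-phi)^max(l,0)`,
#'   where `p_eff = p_code * (1 - border_fraction * (1 - border_penalty))`
#'   marginalises the border capture penalty and `t(l) = max(M-|l|, 0)/M`
#'   is the pre-/post-window truncation factor for a diagnosis month
#'   uniform over the window (the survival factor reflects that a person
#'   cannot be admitted after death);
#' * specificity `= 1 - [P(prev) * p_recode + P(never) * (1 - sum
#'   p_death_miscert) * (1 - (1-miscode_month)^M)] / (1 - q1)`;
#' * PPV `= E[TP] / E[identified]`, with `E[TP] = N q1 p_eff T(W)` and
#'   `E[identified]` adding in-window detections at any lag, prevalent
#'   re-codes and miscodes.
#'
#' @param cfg A [cohort_config()].
#' @param W Matching half-width in months.
#' @param cancer_type Cancer type (default: first configured).
#' @return List with `sensitivity`, `specificity`, `ppv`, and the expected
#'   counts `e_registry_cases`, `e_identified`, `e_tp` (per cohort of
#'   `cfg$n_persons`).
#' @export
expected_metrics <- function(cfg, W, cancer_type = names(cfg$cancers)[1]) {
  stopifnot(inherits(cfg, "cohort_config"))
  pm <- cfg$cancers[[cancer_type]]
  if (is.null(pm)) stop("unknown cancer_type: ", cancer_type, call. = FALSE)
  ws <- month_index(cfg$eval_window[1]); we <- month_index(cfg$eval_window[2])
  M <- we - ws + 1L
  xe <- month_index(cfg$extension_end); re <- month_index(cfg$registry_end)
  Mx <- max(0L, xe - re)
  cts <- names(cfg$cancers)

  q1 <- vapply(cts, function(ct)
    1 - (1 - cfg$cancers[[ct]]$incidence_month)^M, numeric(1))
  q2 <- vapply(cts, function(ct)
    1 - (1 - cfg$cancers[[ct]]$incidence_month)^Mx, numeric(1))
  fr <- vapply(cts, function(ct) cfg$cancers[[ct]]$prevalent_fraction,
               numeric(1))
  r1 <- 1 - sum(q1)
  r2 <- r1 * (1 - sum(q2))
  p_never <- r2 * (1 - sum(fr))
  p_prev <- r2 * fr[[cancer_type]]
  q1_ct <- q1[[cancer_type]]

  offs <- as.integer(names(pm$lag_pmf))
  phi <- pm$case_fatality_month
  trunc_f <- pmax(M - abs(offs), 0) / M
  surv_f <- (1 - phi)^pmax(offs, 0)
  term <- pm$lag_pmf * trunc_f * surv_f
  p_eff <- pm$p_code *
    (1 - cfg$border_fraction * (1 - cfg$border_penalty))
  TW <- sum(term[abs(offs) <= W])
  Tany <- sum(term)

  sens <- p_eff * TW
  p_mis_window <- 1 - (1 - pm$miscode_month)^M
  p_mcd_sum <- sum(vapply(cts, function(ct)
    cfg$cancers[[ct]]$p_death_miscert, numeric(1)))
  flag_noncase <- p_prev * pm$p_recode +
    p_never * (1 - p_mcd_sum) * p_mis_window
  spec <- 1 - flag_noncase / (1 - q1_ct)

  N <- cfg$n_persons
  e_tp <- N * q1_ct * p_eff * TW
  e_id <- N * (q1_ct * p_eff * Tany + flag_noncase)
  list(sensitivity = sens,
       specificity = spec,
       ppv = if (e_id > 0) e_tp / e_id else NA_real_,
       e_registry_cases = N * q1_ct,
       e_identified = e_id,
       e_tp = e_tp)
}
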