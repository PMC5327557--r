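mk_registry <- function(person_id, month, type = "colorectal") {
  data.frame(person_id = person_id, cancer_type = type,
             diagnosis_month = month, spread_of_disease = "localised",
             age_at_diagnosis = 70, stringsAsFactors = FALSE)
}

W_DEFAULT <- c("2006-02", "2010-12")

test_that("an out-of-window ascertainment is both a miss and a false alarm", {
  reg <- mk_registry("p1", "2007-01")
  asc <- caseval:::new_ascertainment("p1", "2008-02-10", "x", W_DEFAULT)
  mc <- classify_cases(asc, reg, "colorectal", W_DEFAULT, 12,
                       c("p1", "p2"))
  expect_identical(mc$label[mc$person_id == "p1"], "FN_and_FP")
  expect_identical(mc$lag_months[mc$person_id == "p1"], 13L)
  expect_identical(mc$label[mc$person_id == "p2"], "TN")
  m <- compute_metrics(mc)
  expect_identical(m$n_registry_cases, 1L)   # still a sensitivity miss
  expect_identical(m$n_identified, 1L)       # still a PPV false alarm
  expect_identical(m$tp, 0L)
  # the same ascertainment at W = 13 becomes a true positive
  mc13 <- classify_cases(asc, reg, "colorectal", W_DEFAULT, 13,
                         c("p1", "p2"))
  expect_identical(mc13$label[mc13$person_id == "p1"], "TP")
})

test_that("empty ascertainment labels registry cases FN and the rest TN", {
  reg <- mk_registry(c("p1", "p3"), c("2007-01", "2009-06"))
  asc <- caseval:::new_ascertainment(character(0), character(0), "x",
                                     W_DEFAULT)
  mc <- classify_cases(asc, reg, "colorectal", W_DEFAULT, 12,
                       paste0("p", 1:4))
  expect_identical(sort(mc$label[mc$person_id %in% c("p1", "p3")]),
                   c("FN", "FN"))
  expect_identical(sort(mc$label[mc$person_id %in% c("p2", "p4")]),
                   c("TN", "TN"))
})

test_that("the earliest in-window registry record defines the diagnosis month", {
  reg <- mk_registry(c("p1", "p1", "p1"),
                     c("2004-05", "2008-03", "2009-10"))
  asc <- caseval:::new_ascertainment("p1", "2008-04-02", "x", W_DEFAULT)
  mc <- classify_cases(asc, reg, "colorectal", W_DEFAULT, 12, "p1")
  expect_identical(mc$diagnosis_month, "2008-03")   # 2004 record pre-window
  expect_identical(mc$lag_months, 1L)
})

test_that("classification equals per-person brute force on random fixtures", {
  for (sd in 11:25) {
    fx <- random_fixture(sd)
    ind <- indicator("crc", "inpatient", "diagnosis", "ICD10",
                     c("C18", "C19", "C20"))
    asc <- extract_indicator(fx$events, ind, fx$eval_window)
    for (W in c(3, 12)) {
      mc <- classify_cases(asc, fx$registry, "colorectal", fx$eval_window,
                           W, fx$persons)
      ora <- oracle_classify(asc, fx$registry, "colorectal",
                             fx$eval_window, W, fx$persons$person_id)
      expect_identical(mc$label, ora)
    }
  }
})

test_that("conservation identities hold on random fixtures", {
  for (sd in 26:35) {
    fx <- random_fixture(sd)
    ind <- indicator("lung", "inpatient", "diagnosis", "ICD10", "C34")
    asc <- extract_indicator(fx$events, ind, fx$eval_window)
    mc <- classify_cases(asc, fx$registry, "lung", fx$eval_window, 12,
                         fx$persons)
    m <- compute_metrics(mc)
    lab <- table(factor(mc$label, c("TP", "FN", "FN_and_FP", "FP", "TN")))
    expect_identical(m$n_registry_cases,
                     unname(lab[["TP"]] + lab[["FN"]] + lab[["FN_and_FP"]]))
    expect_identical(m$n_identified,
                     unname(lab[["TP"]] + lab[["FN_and_FP"]] + lab[["FP"]]))
    expect_identical(m$tn + lab[["FP"]],
                     nrow(mc) - m$n_registry_cases)
    expect_identical(nrow(mc), nrow(fx$persons))
  }
})

test_that("sensitivity grows with the window while specificity ignores it", {
  for (sd in 36:40) {
    fx <- random_fixture(sd)
    ind <- indicator("crc", "inpatient", "diagnosis", "ICD10",
                     c("C18", "C19", "C20"))
    asc <- extract_indicator(fx$events, ind, fx$eval_window)
    prev_sens <- -1; spec0 <- NULL
    for (W in c(0, 3, 12, 60)) {
      m <- compute_metrics(classify_cases(asc, fx$registry, "colorectal",
                                          fx$eval_window, W, fx$persons))
      expect_gte(m$sensitivity$estimate, prev_sens)
      prev_sens <- m$sensitivity$estimate
      if (is.null(spec0)) spec0 <- m$specificity$estimate
      expect_equal(m$specificity$estimate, spec0)
      expect_identical(m$n_identified, nrow(asc))
    }
  }
})

test_that("OR dominates components on sensitivity, AND on specificity", {
  for (sd in 41:48) {
    fx <- random_fixture(sd)
    a <- indicator("a", "inpatient", "diagnosis", "ICD10",
                   c("C18", "C19", "C20"))
    b <- indicator("b", "death", "cause_of_death", "ICD10",
                   c("C18", "C19", "C20"))
    sa <- extract_indicator(fx$events, a, fx$eval_window)
    sb <- extract_indicator(fx$events, b, fx$eval_window)
    met <- function(s) compute_metrics(
      classify_cases(s, fx$registry, "colorectal", fx$eval_window, 12,
                     fx$persons))
    s_or <- combine_or(sa, sb)
    s_and <- combine_and(sa, sb, anchor = "a")
    # membership dominance: OR cases contain, AND cases are contained in,
    # every component's cases
    expect_true(all(sa$person_id %in% s_or$person_id))
    expect_true(all(sb$person_id %in% s_or$person_id))
    expect_true(all(s_and$person_id %in% sa$person_id))
    expect_true(all(s_and$person_id %in% sb$person_id))
    # flagging more persons can only lower specificity, fewer only raise it
    m_or <- met(s_or); m_and <- met(s_and); ma <- met(sa); mb <- met(sb)
    expect_lte(m_or$specificity$estimate,
               min(ma$specificity$estimate, mb$specificity$estimate))
    expect_gte(m_and$specificity$estimate,
               max(ma$specificity$estimate, mb$specificity$estimate))
    # the anchor-dated AND composite can never beat its anchor on
    # sensitivity
    expect_lte(m_and$sensitivity$estimate, ma$sensitivity$estimate)
  }
})
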