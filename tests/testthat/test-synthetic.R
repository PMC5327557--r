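test_that("identical configuration and seed reproduce identical tables", {
  cfg <- cohort_config(n_persons = 3000, seed = 77)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$persons, g2$cohort$persons)
  expect_identical(g1$cohort$events, g2$cohort$events)
  expect_identical(g1$cohort$registry, g2$cohort$registry)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_cohort(cohort_config(n_persons = 3000, seed = 78))
  expect_false(identical(g1$cohort$events, g3$cohort$events))
})

test_that("the noiseless limit yields perfect validity on all metrics", {
  gen <- generate_cohort(noiseless_config())
  cfg <- gen$config
  for (ct in c("colorectal", "lung")) {
    ind <- default_indicators(ct)$indicators$hospital_dx
    asc <- extract_indicator(gen$cohort$events, ind, cfg$eval_window,
                             gen$cohort$coverage)
    m <- compute_metrics(classify_cases(asc, gen$cohort$registry, ct,
                                        cfg$eval_window, 12,
                                        gen$cohort$persons))
    expect_gt(m$n_registry_cases, 0)
    expect_equal(m$sensitivity$estimate, 1)
    expect_equal(m$specificity$estimate, 1)
    expect_equal(m$ppv$estimate, 1)
  }
  em <- expected_metrics(cfg, 12, "colorectal")
  expect_equal(em$sensitivity, 1)
  expect_equal(em$specificity, 1)
  expect_equal(em$ppv, 1)
})

test_that("a never-coding source yields zero sensitivity, full specificity", {
  cfg <- noiseless_config(n = 3000, seed = 11)
  cfg$cancers$colorectal$p_code <- 0
  gen <- generate_cohort(cfg)
  ind <- default_indicators("colorectal")$indicators$hospital_dx
  asc <- extract_indicator(gen$cohort$events, ind, cfg$eval_window,
                           gen$cohort$coverage)
  m <- compute_metrics(classify_cases(asc, gen$cohort$registry,
                                      "colorectal", cfg$eval_window, 12,
                                      gen$cohort$persons))
  expect_equal(m$sensitivity$estimate, 0)
  expect_equal(m$specificity$estimate, 1)
  expect_equal(expected_metrics(cfg, 12, "colorectal")$sensitivity, 0)
})

test_that("expected sensitivity is the direct product in the untruncated case", {
  cfg <- noiseless_config()
  cfg$cancers$colorectal$p_code <- 0.8
  em <- expected_metrics(cfg, 12, "colorectal")
  # lag identically 0, no fatality, no border stratum, no truncation loss
  expect_equal(em$sensitivity, 0.8)
})

test_that("closed-form metrics match exhaustive outcome enumeration", {
  # tiny state space: 2-month window, lag support {-1, 0, 1}
  pm <- cancer_sim_params(
    incidence_month = 0.2, p_code = 0.7,
    lag_pmf = c("-1" = 0.2, "0" = 0.5, "1" = 0.3),
    prevalent_fraction = 0.15, p_recode = 0.4, miscode_month = 0.1,
    case_fatality_month = 0.25, p_prevalent_death = 0.3,
    p_death_cause = 0.6, p_secondary_miscode = 0, p_death_miscert = 0.05)
  cfg <- cohort_config(
    n_persons = 3, eval_window = c("2006-02", "2006-03"),
    extension_end = "2006-03", cancers = list(colorectal = pm),
    border_fraction = 0.3, border_penalty = 0.5, seed = 1)

  M <- 2; phi <- pm$case_fatality_month
  q1 <- 1 - (1 - pm$incidence_month)^M
  p_prev <- (1 - q1) * pm$prevalent_fraction
  p_never <- (1 - q1) * (1 - pm$prevalent_fraction)
  p_eff <- c(border = pm$p_code * cfg$border_penalty,
             inland = pm$p_code)
  w_border <- c(border = cfg$border_fraction,
                inland = 1 - cfg$border_fraction)

  for (W in c(0, 1)) {
    # enumerate (border, diagnosis month, coded, lag, survives-to-event)
    e_tp <- 0; e_flag_case <- 0
    for (b in names(w_border)) {
      for (D in 1:2) {                       # month within the window
        for (l in c(-1L, 0L, 1L)) {
          p_lag <- unname(pm$lag_pmf[as.character(l)])
          p_surv <- if (l > 0) (1 - phi)^l else 1
          E <- D + l
          in_window <- E >= 1 && E <= 2
          p_path <- w_border[[b]] * (1 / 2) * p_eff[[b]] * p_lag * p_surv
          if (in_window) {
            e_flag_case <- e_flag_case + p_path
            if (abs(l) <= W) e_tp <- e_tp + p_path
          }
        }
      }
    }
    p_mis_any <- 1 - (1 - pm$miscode_month)^M
    e_flag_prev <- pm$p_recode
    e_flag_never <- (1 - pm$p_death_miscert) * p_mis_any
    enum_sens <- e_tp
    enum_spec <- 1 - (p_prev * e_flag_prev + p_never * e_flag_never) /
      (1 - q1)
    enum_ppv <- (q1 * e_tp) /
      (q1 * e_flag_case + p_prev * e_flag_prev + p_never * e_flag_never)

    em <- expected_metrics(cfg, W, "colorectal")
    expect_equal(em$sensitivity, enum_sens, tolerance = 1e-9)
    expect_equal(em$specificity, enum_spec, tolerance = 1e-9)
    expect_equal(em$ppv, enum_ppv, tolerance = 1e-9)
  }
})

test_that("raising the miscode rate strictly degrades specificity and PPV", {
  cfgs <- lapply(c(1e-5, 1e-4, 1e-3), function(p) {
    cfg <- cohort_config(n_persons = 10000, seed = 33)
    cfg$cancers$colorectal$miscode_month <- p
    cfg
  })
  em <- lapply(cfgs, expected_metrics, W = 12, cancer_type = "colorectal")
  expect_true(all(diff(vapply(em, `[[`, 1, "specificity")) < 0))
  expect_true(all(diff(vapply(em, `[[`, 1, "ppv")) < 0))
  obs <- vapply(cfgs, function(cfg) {
    gen <- generate_cohort(cfg)
    ind <- default_indicators("colorectal")$indicators$hospital_dx
    asc <- extract_indicator(gen$cohort$events, ind, cfg$eval_window,
                             gen$cohort$coverage)
    m <- compute_metrics(classify_cases(asc, gen$cohort$registry,
                                        "colorectal", cfg$eval_window, 12,
                                        gen$cohort$persons))
    m$specificity$estimate
  }, numeric(1))
  expect_true(all(diff(obs) < 0))
})

test_that("a border capture penalty concentrates border residents among
           missed cases", {
  cfg <- cohort_config(n_persons = 30000, seed = 55,
                       border_fraction = 0.15, border_penalty = 0.3)
  gen <- generate_cohort(cfg)
  ind <- default_indicators("colorectal")$indicators$hospital_dx
  asc <- extract_indicator(gen$cohort$events, ind, cfg$eval_window,
                           gen$cohort$coverage)
  mc <- classify_cases(asc, gen$cohort$registry, "colorectal",
                       cfg$eval_window, 12, gen$cohort$persons)
  rep <- stratify_mismatches(mc, gen$cohort$persons, gen$cohort$registry)
  expect_gt(rep$non_matches$border_share, rep$matches$border_share)
})

test_that("every event traces to exactly one generating mechanism", {
  gen <- shared_synth()
  ev_ids <- unique(gen$cohort$events$event_id)
  expect_setequal(gen$truth$events$event_id, ev_ids)
  expect_identical(anyDuplicated(gen$truth$events$event_id), 0L)
})

test_that("the registry holds exactly the true incident and prevalent cases", {
  gen <- shared_synth()
  cfg <- gen$config
  truth <- gen$truth$persons
  reg <- gen$cohort$registry
  for (ct in names(cfg$cancers)) {
    expected_ids <- truth$person_id[
      truth$cancer_type %in% ct & truth$status %in% c("incident",
                                                      "prevalent")]
    expect_setequal(reg$person_id[reg$cancer_type == ct], expected_ids)
    # extension-period cases never appear
    ext_ids <- truth$person_id[truth$cancer_type %in% ct &
                                 truth$status == "incident_extension"]
    expect_false(any(ext_ids %in% reg$person_id[reg$cancer_type == ct]))
    # diagnosis months agree with the ground truth
    i <- match(reg$person_id[reg$cancer_type == ct], truth$person_id)
    expect_identical(reg$diagnosis_month[reg$cancer_type == ct],
                     truth$diagnosis_month[i])
  }
  # no event is dated after its person's death, so exclusions are a no-op
  res <- apply_exclusions(gen$cohort)
  expect_identical(nrow(res$report), 0L)
})
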