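test_that("cohort constructor validates structure and referential integrity", {
  tb <- tiny_cohort_tables()
  ch <- cohort(tb$persons, tb$events, tb$registry, tb$coverage)
  expect_s3_class(ch, "cohort")
  expect_identical(nrow(ch$persons), 3L)

  bad <- tb
  bad$events$person_id[3] <- "zz"
  expect_error(cohort(bad$persons, bad$events, bad$registry, bad$coverage),
               "absent from persons table at row\\(s\\): 3")

  bad <- tb
  bad$registry$diagnosis_month[1] <- "2007-05-14"
  expect_error(cohort(bad$persons, bad$events, bad$registry, bad$coverage),
               "month precision")

  bad <- tb
  bad$events$event_date[3] <- "1999-01-01"   # before inpatient coverage
  expect_error(cohort(bad$persons, bad$events, bad$registry, bad$coverage),
               "outside source coverage")

  bad <- tb
  bad$persons <- bad$persons[, setdiff(names(bad$persons), "sex")]
  expect_error(cohort(bad$persons, bad$events, bad$registry, bad$coverage),
               "missing column")
})

test_that("write_cohort / read_cohort round-trips field for field", {
  tb <- tiny_cohort_tables()
  ch <- cohort(tb$persons, tb$events, tb$registry, tb$coverage)
  dir <- withr::local_tempdir()
  paths <- write_cohort(ch, dir)
  back <- read_cohort(paths)
  expect_identical(back$persons, ch$persons)
  expect_identical(back$registry, ch$registry)
  expect_identical(back$coverage, ch$coverage)
  # events: same content (row order within person/event preserved)
  expect_identical(back$events, ch$events)
})

test_that("wide inpatient layouts gather populated slots only", {
  dir <- withr::local_tempdir()
  tb <- tiny_cohort_tables()
  wide <- data.frame(pid = "a", adm_id = "w1", admdate = "2007-06-03",
                     stringsAsFactors = FALSE)
  for (i in 1:55) wide[[paste0("diag", i)]] <- NA_character_
  for (i in 1:50) wide[[paste0("proc", i)]] <- NA_character_
  wide$diag1 <- "C18.9"; wide$diag7 <- "Z85.0"
  ev_path <- file.path(dir, "apdc.csv")
  write.csv(wide, ev_path, row.names = FALSE, na = "")
  write.csv(tb$persons, file.path(dir, "persons.csv"), row.names = FALSE,
            na = "")
  write.csv(tb$registry, file.path(dir, "registry.csv"), row.names = FALSE,
            na = "")
  write.csv(tb$coverage, file.path(dir, "coverage.csv"), row.names = FALSE,
            na = "")
  sch <- default_schema()
  sch$events <- list(layout = "wide", source = "inpatient", person = "pid",
                     event_id = "adm_id", date = "admdate",
                     slots = list(diagnosis = list(prefix = "diag", n = 55,
                                                   code_system = "ICD10")))
  ch <- read_cohort(list(persons = file.path(dir, "persons.csv"),
                         events = ev_path,
                         registry = file.path(dir, "registry.csv"),
                         coverage = file.path(dir, "coverage.csv")),
                    schema = sch)
  expect_identical(nrow(ch$events), 2L)
  expect_setequal(ch$events$code, c("C18.9", "Z85.0"))
  expect_identical(ch$events$slot[ch$events$code == "Z85.0"], 7L)
  expect_true(all(ch$events$slot_role == "diagnosis"))
})

test_that("reader reports schema and type failures with row diagnostics", {
  dir <- withr::local_tempdir()
  tb <- tiny_cohort_tables()
  tb$persons$baseline_date[2] <- "junk"
  ch <- cohort(tiny_cohort_tables()$persons, tb$events, tb$registry,
               tb$coverage)
  paths <- write_cohort(ch, dir)
  bad_persons <- tb$persons
  write.csv(bad_persons, paths$persons, row.names = FALSE, na = "")
  expect_error(read_cohort(paths), "invalid baseline_date at row\\(s\\) 2")

  mangled <- read.csv(paths$registry)
  names(mangled)[1] <- "id"
  write.csv(mangled, paths$registry, row.names = FALSE, na = "")
  tb2 <- tiny_cohort_tables()
  write.csv(tb2$persons, paths$persons, row.names = FALSE, na = "")
  expect_error(read_cohort(paths), "schema error")
})

test_that("exclusions remove under-age and after-death persons, idempotently", {
  tb <- tiny_cohort_tables()
  tb$persons$age_at_baseline[1] <- 44        # person a under age
  tb$persons$death_date[2] <- "2008-06-15"   # person b event 2009-02 after
  ch <- cohort(tb$persons, tb$events, tb$registry, tb$coverage)
  res <- apply_exclusions(ch, min_age = 45)
  expect_setequal(res$report$person_id, c("a", "b"))
  expect_identical(res$report$reason[res$report$person_id == "a"],
                   "under_min_age")
  expect_identical(res$report$reason[res$report$person_id == "b"],
                   "event_after_death")
  expect_identical(res$cohort$persons$person_id, "c")
  expect_false(any(res$cohort$events$person_id %in% c("a", "b")))
  expect_false(any(res$cohort$registry$person_id %in% c("a", "b")))

  twice <- apply_exclusions(res$cohort, min_age = 45)
  expect_identical(nrow(twice$report), 0L)
  expect_identical(twice$cohort$persons, res$cohort$persons)
  expect_identical(twice$cohort$events, res$cohort$events)
})

test_that("same-month death and admission is not irreconcilable", {
  tb <- tiny_cohort_tables()
  tb$persons$death_date[1] <- "2007-05-02"   # event a: 2007-05-14, same month
  ch <- cohort(tb$persons, tb$events, tb$registry, tb$coverage)
  res <- apply_exclusions(ch)
  expect_false("a" %in% res$report$person_id)
})
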