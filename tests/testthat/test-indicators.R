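colorectal_set <- c("C18", "C19", "C20")

test_that("code matching uses prefix category semantics", {
  expect_true(code_matches("C18.2", colorectal_set))
  expect_true(code_matches("C20", colorectal_set))
  expect_true(code_matches("c19.0", colorectal_set))
  expect_false(code_matches("C78.5", colorectal_set))  # secondary site
  expect_false(code_matches("C17.9", colorectal_set))
  expect_true(code_matches("Z85.0", "Z85.0"))
  expect_false(code_matches("Z85.1", "Z85.0"))
  # exact entries do not match extensions
  expect_false(code_matches("C18.2", "C18", prefix = FALSE))
  expect_true(code_matches("C18", "C18", prefix = FALSE))
  expect_error(code_matches("C18", character(0)), "empty code set")
})

test_that("expression parser honours precedence and parentheses", {
  t1 <- caseval:::parse_indicator_expression("a OR b AND c")
  expect_identical(t1$op, "OR")
  expect_identical(t1$args[[2]]$op, "AND")
  t2 <- caseval:::parse_indicator_expression("(a OR b) AND c")
  expect_identical(t2$op, "AND")
  expect_identical(t2$args[[1]]$op, "OR")
  expect_identical(caseval:::expression_leaves(t2), c("a", "b", "c"))
  expect_error(caseval:::parse_indicator_expression("a OR (b AND"),
               "unbalanced|unexpected")
  expect_error(caseval:::parse_indicator_expression("a b"), "trailing")
  expect_error(caseval:::parse_indicator_expression("OR a"), "unexpected")
  expect_error(composite("x", "a OR b", anchor = "c"), "not a leaf")
})

test_that("extraction respects source, slot role, window and code system", {
  fx <- random_fixture(1)
  ind <- indicator("crc_dx", "inpatient", "diagnosis", "ICD10",
                   colorectal_set)
  s <- extract_indicator(fx$events, ind, fx$eval_window, fx$coverage)
  ora <- oracle_extract(fx$events, ind, fx$eval_window)
  expect_identical(norm_asc(s), norm_asc(ora))
  # window outside coverage is a configuration error
  expect_error(extract_indicator(fx$events, ind, c("1998-01", "2010-12"),
                                 fx$coverage),
               "configuration error")
})

test_that("first occurrence takes the earliest admission", {
  ev <- data.frame(
    event_id = c("x1", "x2", "x3"),
    person_id = c("p1", "p1", "p2"),
    source = "inpatient",
    event_date = c("2008-05-20", "2008-02-03", "2008-02"),
    slot_role = "diagnosis", code_system = "ICD10",
    code = c("C18.1", "C18.9", "C18.1"), slot = 1L,
    stringsAsFactors = FALSE)
  ind <- indicator("crc_dx", "inpatient", "diagnosis", "ICD10",
                   colorectal_set)
  s <- extract_indicator(ev, ind, c("2006-02", "2010-12"))
  expect_identical(s$first_date[s$person_id == "p1"], "2008-02-03")
  expect_identical(s$first_date[s$person_id == "p2"], "2008-02")
})

test_that("death-source indicators can restrict to the underlying cause", {
  ev <- data.frame(
    event_id = c("d1", "d1"), person_id = c("p1", "p1"), source = "death",
    event_date = "2009-03-14", slot_role = "cause_of_death",
    code_system = "ICD10", code = c("I21.9", "C34.1"), slot = c(1L, 2L),
    stringsAsFactors = FALSE)
  any_cause <- indicator("lc_any", "death", "cause_of_death", "ICD10",
                         "C34")
  und_only <- indicator("lc_und", "death", "cause_of_death", "ICD10",
                        "C34", cause_position = "underlying_only")
  w <- c("2006-02", "2010-12")
  expect_identical(extract_indicator(ev, any_cause, w)$person_id, "p1")
  expect_identical(nrow(extract_indicator(ev, und_only, w)), 0L)
})

test_that("combine_or unions persons with elementwise-earliest dates", {
  w <- c("2006-01", "2010-12")
  A <- caseval:::new_ascertainment("p1", "2006-01-10", "A", w)
  B <- caseval:::new_ascertainment(c("p1", "p2"), c("2006-03-01", "2006-02"),
                                   "B", w)
  u <- combine_or(A, B)
  expect_identical(u$first_date[u$person_id == "p1"], "2006-01-10")
  expect_identical(u$first_date[u$person_id == "p2"], "2006-02")
  expect_identical(norm_asc(combine_or(A, A)), norm_asc(A))
  # intra-month ties go to the earlier-listed set
  C <- caseval:::new_ascertainment("p1", "2006-01-25", "C", w)
  expect_identical(combine_or(C, A)$first_date, "2006-01-25")
  set.seed(9)
  for (i in 1:20) {
    ids1 <- sample(letters, sample(1:10, 1))
    ids2 <- sample(letters, sample(1:10, 1))
    s1 <- caseval:::new_ascertainment(ids1, rep("2007-05", length(ids1)),
                                      "s1", w)
    s2 <- caseval:::new_ascertainment(ids2, rep("2007-06", length(ids2)),
                                      "s2", w)
    expect_gte(nrow(combine_or(s1, s2)), max(nrow(s1), nrow(s2)))
    expect_setequal(combine_or(s1, s2)$person_id, union(ids1, ids2))
  }
})

test_that("combine_and intersects persons and dates by the anchor", {
  w <- c("2006-01", "2010-12")
  A <- caseval:::new_ascertainment(c("p1", "p2"),
                                   c("2006-01-10", "2006-02-01"), "A", w)
  B <- caseval:::new_ascertainment("p1", "2006-06-15", "B", w)
  res <- combine_and(A, B, anchor = "A")
  expect_identical(res$person_id, "p1")
  expect_identical(res$first_date, "2006-01-10")
  D <- caseval:::new_ascertainment("p9", "2006-06", "D", w)
  expect_identical(nrow(combine_and(A, D, anchor = "A")), 0L)
  same <- combine_and(A, A, anchor = "A")
  expect_identical(norm_asc(same), norm_asc(A))
  expect_error(combine_and(A, B, anchor = "Z"), "configuration error")
})

test_that("composite evaluation equals structural combination and oracle", {
  fx <- random_fixture(2)
  inds <- list(
    a = indicator("a", "inpatient", "diagnosis", "ICD10", colorectal_set),
    b = indicator("b", "death", "cause_of_death", "ICD10", "C34"),
    c = indicator("c", "inpatient", "procedure", "ACHI", "32024"))
  w <- fx$eval_window
  # degenerate single-leaf tree
  single <- evaluate_composite(fx$events, composite("only_a", "a"), w, inds)
  direct <- extract_indicator(fx$events, inds$a, w)
  expect_identical(norm_asc(single), norm_asc(direct))
  # (a OR b) == combine_or of the parts
  ab <- evaluate_composite(fx$events, composite("ab", "a OR b"), w, inds)
  parts <- lapply(inds[c("a", "b")], extract_indicator,
                  events = fx$events, eval_window = w)
  expect_identical(norm_asc(ab), norm_asc(combine_or(parts))) 
  # (a AND (b OR c)) against per-person truth-table evaluation
  comp <- composite("mix", "a AND (b OR c)")
  res <- evaluate_composite(fx$events, comp, w, inds)
  members <- lapply(inds, function(i) oracle_extract(fx$events, i, w)$person_id)
  expected_ids <- oracle_composite_members(comp$tree, members)
  expect_setequal(res$person_id, expected_ids)
  # AND composite carries the anchor leaf's dates
  a_dates <- oracle_extract(fx$events, inds$a, w)
  expect_identical(res$first_date,
                   a_dates$first_date[match(res$person_id,
                                            a_dates$person_id)])
})

test_that("enlarging a code set never loses persons nor delays dates", {
  for (sd in 1:5) {
    fx <- random_fixture(sd)
    narrow <- indicator("n", "inpatient", "diagnosis", "ICD10", "C18")
    wide <- indicator("w", "inpatient", "diagnosis", "ICD10",
                      c("C18", "C19", "C20", "C34"))
    s_n <- extract_indicator(fx$events, narrow, fx$eval_window)
    s_w <- extract_indicator(fx$events, wide, fx$eval_window)
    expect_true(all(s_n$person_id %in% s_w$person_id))
    shared <- intersect(s_n$person_id, s_w$person_id)
    expect_true(all(
      month_index(s_w$first_date[match(shared, s_w$person_id)]) <=
        month_index(s_n$first_date[match(shared, s_n$person_id)])))
  }
})

test_that("widening the window never loses persons and dates move earlier", {
  for (sd in 6:10) {
    fx <- random_fixture(sd)
    ind <- indicator("x", "inpatient", "diagnosis", "ICD10",
                     c("C18", "C34"))
    s1 <- extract_indicator(fx$events, ind, c("2007-01", "2009-12"))
    s2 <- extract_indicator(fx$events, ind, c("2006-02", "2010-12"))
    expect_true(all(s1$person_id %in% s2$person_id))
    shared <- s1$person_id
    expect_true(all(
      month_index(s2$first_date[match(shared, s2$person_id)]) <=
        month_index(s1$first_date[match(shared, s1$person_id)])))
  }
})
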