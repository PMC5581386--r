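demo_rec <- function(...) {
  c(meta_cols(1), list(consent = "yes"), list(...))
}

demo_rule <- function(form, id) {
  form$rules[[match(id, vapply(form$rules, `[[`, "", "rule_id"))]]
}

test_that("each error class reproduces its canonical scenario", {
  form <- demo_form_template()
  ev <- function(id, rec) eval_rule(demo_rule(form, id), rec, form)

  ## impossible multi-question combination: male respondent, ever given birth
  r <- ev("d2", demo_rec(gender = "male", ever_birth = "yes"))
  expect_true(r$reached)
  expect_true(r$error)
  expect_false(ev("d2", demo_rec(gender = "female", ever_birth = "yes"))$error)

  ## exclusive option co-selected with a substantive one
  r <- ev("d3", demo_rec(advice_src = "clinic unknown"))
  expect_true(r$error)
  expect_false(ev("d3", demo_rec(advice_src = "clinic drugstore"))$error)
  expect_false(ev("d3", demo_rec(advice_src = "unknown"))$error)

  ## intentional redundancy: 6 births then 5 births
  r <- ev("d4", demo_rec(ever_birth = "yes", num_births_1 = "6",
                         num_births_2 = "5"))
  expect_true(r$reached)
  expect_true(r$error)
  expect_false(ev("d4", demo_rec(ever_birth = "yes", num_births_1 = "6",
                                 num_births_2 = "6"))$error)

  ## manual skip logic: never visited a clinic, chose the clinical branch
  r <- ev("d5", demo_rec(clinic_visit = "no", branch_choice = "clinical"))
  expect_true(r$error)
  expect_false(ev("d5", demo_rec(clinic_visit = "no",
                                 branch_choice = "skip_clinical"))$error)
  expect_false(ev("d5", demo_rec(clinic_visit = "yes",
                                 branch_choice = "clinical"))$error)

  ## removed range constraint: implausible value slips through
  r <- ev("d6", demo_rec(household_size = "657"))
  expect_true(r$error)
  expect_match(r$detail, "657")
  expect_false(ev("d6", demo_rec(household_size = "12"))$error)

  ## manual calculation: stated age disagrees with birthdate arithmetic
  rec <- demo_rec(resp_dob = "1996-06-04", resp_age = "24")
  rec$survey_date <- "2016-06-03"
  r <- ev("d7", rec)
  expect_true(r$error)
  expect_match(r$detail, "derived 19")
  rec$resp_age <- "19"
  expect_false(ev("d7", rec)$error)

  ## invalid data type on a count question
  r <- ev("d8", demo_rec(doctor_visits = "sometimes"))
  expect_true(r$error)
  expect_false(ev("d8", demo_rec(doctor_visits = "3"))$error)

  ## required question skipped vs never reached
  r <- ev("d1", demo_rec(ever_birth = "yes", num_births_1 = "2"))
  expect_true(r$reached)
  expect_true(r$error)   # postnatal_care reached but blank
  r <- ev("d1", demo_rec(ever_birth = "no"))
  expect_false(r$reached)  # gate closed: no opportunity, no error
  expect_false(r$error)
})

test_that("untypeable values are diagnosed and excluded, not counted as errors", {
  form <- demo_form_template()
  recs <- demo_records(6, seed = 2)
  recs$household_size[1] <- "many"   # minmax rule cannot type this
  det <- run_detection(form, recs)
  d6 <- det$outcomes[det$outcomes$rule_id == "d6", ]
  expect_equal(nrow(d6), 5)          # record 1 excluded from opportunities
  expect_equal(sum(d6$error), 0)
  expect_true(any(det$diagnostics$issue == "unparseable numeric" &
                    det$diagnostics$record_id == recs$record_id[1]))
})

test_that("tick distance is a component-sum metric", {
  expect_equal(tick_distance(as.Date("2016-06-03"), as.Date("2016-06-03")), 0L)
  expect_equal(tick_distance(as.Date("2014-05-10"), as.Date("2014-05-11")), 1L)
  expect_equal(tick_distance(as.Date("2014-05-10"), as.Date("2015-06-10")), 2L)
  grid <- as.Date(c("2012-01-05", "2012-02-05", "2012-02-07", "2013-11-30",
                    "2014-01-01", "2016-12-31"))
  for (a in seq_along(grid)) for (b in seq_along(grid)) {
    expect_gte(tick_distance(grid[a], grid[b]), 0L)
    expect_identical(tick_distance(grid[a], grid[b]),
                     tick_distance(grid[b], grid[a]))
    expect_identical(tick_distance(grid[a], grid[b]) == 0L, a == b)
    for (cc in seq_along(grid))
      expect_lte(tick_distance(grid[a], grid[b]),
                 tick_distance(grid[a], grid[cc]) +
                   tick_distance(grid[cc], grid[b]))
  }
})

test_that("completed-years age matches an anniversary-counting oracle", {
  expect_equal(derive_completed_years(as.Date("1996-06-04"),
                                      as.Date("2016-06-03")), 19L)
  expect_equal(derive_completed_years(as.Date("1996-06-04"),
                                      as.Date("2016-06-04")), 20L)
  expect_error(derive_completed_years(as.Date("2020-01-01"),
                                      as.Date("2019-01-01")),
               "after")
  ## oracle: count anniversaries that have occurred by the reference date
  oracle <- function(b, a) {
    bl <- as.POSIXlt(b)
    y <- 0
    repeat {
      anniv <- as.Date(sprintf("%04d-%02d-%02d", bl$year + 1900 + y + 1,
                               bl$mon + 1, bl$mday))
      if (anniv > a) break
      y <- y + 1
    }
    y
  }
  set.seed(5)
  for (k in 1:60) {
    repeat {   # skip Feb 29 so the oracle's date strings stay valid
      b <- as.Date("1950-01-01") + sample(0:25000, 1)
      bl <- as.POSIXlt(b)
      if (!(bl$mon == 1 && bl$mday == 29)) break
    }
    a <- b + sample(0:20000, 1)
    expect_equal(derive_completed_years(b, a), oracle(b, a),
                 info = paste(b, a))
  }
})

test_that("an error always implies an opportunity, on arbitrary records", {
  for (form in list(demo_form_template(), reference_form_template())) {
    recs <- random_records(form, 60, seed = 9)
    det <- run_detection(form, recs)
    expect_true(all(det$outcomes$reached))
    expect_true(all(!det$outcomes$error | det$outcomes$reached))
    ## scalar path agrees on a subsample
    for (i in c(1, 17, 42)) for (rule in form$rules) {
      r <- eval_rule(rule, as.list(recs[i, ]), form)
      expect_false(r$error && !r$reached)
    }
  }
})

test_that("exact-comparator redundancy is symmetric in its question pair", {
  form <- demo_form_template()
  rule <- demo_rule(form, "d4")
  flipped <- relaxed_rule("d4f", "redundancy",
                          list(qa = rule$params$qb, qb = rule$params$qa,
                               comparator = "exact"))
  recs <- random_records(form, 40, seed = 13)
  for (i in seq_len(nrow(recs))) {
    a <- eval_rule(rule, as.list(recs[i, ]), form)
    b <- eval_rule(flipped, as.list(recs[i, ]), form)
    expect_identical(a$reached, b$reached)
    expect_identical(a$error, b$error)
  }
})
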