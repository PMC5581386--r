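test_that("parse_form handles minimal, packaged, and invalid specs", {
  f <- parse_form('{"questions":[{"id":"note","rtype":"text"}]}')
  expect_s3_class(f, "vr_form")
  expect_length(f$questions, 1)
  expect_length(f$rules, 0)

  pkg_form <- parse_form(system.file("extdata", "fixture_form.json",
                                     package = "validrelax"))
  expect_length(pkg_form$rules, 11)
  expect_setequal(vapply(pkg_form$rules, `[[`, "", "rule_class"),
                  c("redundancy", "illogical_single", "required_skip",
                    "illogical_multi"))

  expect_error(
    parse_form(paste0('{"questions":[',
      '{"id":"a","rtype":"text","relevance":',
      '{"op":"selected","question":"b","option":"x"}},',
      '{"id":"b","rtype":"select_one","choices":["x"]}]}')),
    "not an earlier question")
  expect_error(parse_form('{"questions":[{"id":"q"}]}'), "rtype")
})

test_that("form invariants are enforced at construction", {
  expect_error(form_spec(list(question("a", "text"), question("a", "text"))),
               "duplicate")
  expect_error(question("q", "select_one"), "non-empty choice list")
  expect_error(question("q", "integer", choices = c("x")), "only allowed")
  expect_error(form_spec(list(question("a", "text")),
                         list(relaxed_rule("r", "required_skip",
                                           list(question = "zzz")))),
               "unknown question")
})

test_that("relevance evaluation: base cases and missing-answer semantics", {
  expect_true(eval_relevance(NULL, list()))
  expect_true(eval_relevance(list(op = "true"), list()))
  expect_true(eval_relevance(rel_selected("ever_birth", "yes"),
                             list(ever_birth = "yes")))
  expect_false(eval_relevance(rel_selected("ever_birth", "yes"),
                              list(ever_birth = NA)))
  expect_false(eval_relevance(rel_selected("ever_birth", "yes"),
                              list(ever_birth = "no")))
  ## select_multiple token membership
  expect_true(eval_relevance(rel_selected("src", "chw"),
                             list(src = "clinic chw")))
  ## numeric vs string comparison
  expect_true(eval_relevance(rel_cmp("=", "n", 7), list(n = "07")))
  expect_false(eval_relevance(rel_cmp(">=", "n", 5), list(n = "abc")))
  expect_error(eval_relevance(rel_selected("nope", "x"), list(a = "1")),
               "undeclared")
})

test_that("compound relevance agrees with truth-table enumeration", {
  form <- tiny_form()
  expr <- form$questions[[4]]$relevance
  vals_a <- c("yes", "no", NA)
  vals_c <- c("2", "9", NA)
  for (a in vals_a) for (b in vals_a) for (cc in vals_c) {
    ans <- list(a = a, b = b, c = cc)
    expect_identical(eval_relevance(expr, ans),
                     isTRUE(naive_relevance(expr, ans)),
                     info = paste(a, b, cc))
  }
})

test_that("question_reached honours gates and always-true relevance", {
  form <- reference_form_template()
  rec <- c(meta_cols(1), list(consent = "yes", ever_birth_1 = "no",
                              has_time = "yes"))
  expect_true(question_reached(form, rec, "consent"))
  expect_true(question_reached(form, rec, "ever_birth_1"))
  ## birth-section question gated on ever-birth = "yes"
  expect_false(question_reached(form, rec, "child_dob_1"))
  expect_true(question_reached(form, rec, "advice_src"))
  rec$consent <- "no"
  expect_false(question_reached(form, rec, "ever_birth_1"))
})

test_that("reached-set equals the sequential replay oracle on random records", {
  for (form in list(reference_form_template(), demo_form_template(), tiny_form())) {
    recs <- random_records(form, 100, seed = 42)
    for (i in seq_len(nrow(recs))) {
      rec <- as.list(recs[i, ])
      expect_identical(reached_questions(form, rec), replay_oracle(form, rec),
                       info = paste(form$title, i))
    }
  }
})

test_that("reached-set is deterministic and monotone under answer removal", {
  form <- reference_form_template()
  recs <- random_records(form, 40, seed = 7)
  set.seed(11)
  for (i in seq_len(nrow(recs))) {
    rec <- as.list(recs[i, ])
    base <- reached_questions(form, rec)
    expect_identical(reached_questions(form, rec), base)
    answered <- setdiff(names(rec)[!is.na(unlist(rec))],
                        c("record_id", "enumerator_id", "survey_date"))
    for (drop in sample(answered, min(4, length(answered)))) {
      rec2 <- rec
      rec2[[drop]] <- NA_character_
      expect_true(all(reached_questions(form, rec2) %in% c(base, drop)),
                  info = paste(i, drop))
      ## removing an answer never adds *other* questions to the reached-set
      expect_true(all(setdiff(reached_questions(form, rec2), base) %in% drop))
    }
  }
})

test_that("submission validation flags unknown columns and bad dates", {
  form <- tiny_form()
  recs <- random_records(form, 5, seed = 1)
  expect_silent(validate_records(recs, form))
  bad <- recs
  bad$zzz <- "1"
  expect_error(validate_records(bad, form), "unknown submission column")
  bad2 <- recs
  bad2$survey_date[2] <- "12/04/2016"
  expect_error(validate_records(bad2, form), "survey_date")
})

test_that("submissions round-trip through CSV and JSON-lines", {
  form <- tiny_form()
  recs <- random_records(form, 8, seed = 3)
  csv <- tempfile(fileext = ".csv")
  write_submissions(recs, csv)
  back <- read_submissions(csv, form)
  expect_equal(back, recs, ignore_attr = TRUE)
  jl <- tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(nrow(recs)), function(i)
    jsonlite::toJSON(as.list(recs[i, ]), auto_unbox = TRUE, na = "null"), ""),
    jl)
  back2 <- read_submissions(jl, form)
  expect_equal(back2[, names(recs)], recs, ignore_attr = TRUE)
})
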