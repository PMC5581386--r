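## Synthetic survey generation: (a) a deterministic fixture that reproduces
## the reference cluster-survey's per-rule opportunity and error counts
## exactly, and (b) a stochastic simulator with a configurable logistic
## error process for property testing.

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

YN <- c("yes", "no")
TREAT_SRC <- c("clinic", "drugstore", "chw", "traditional", "family", "other")
ADVICE <- c("clinic", "drugstore", "chw", "traditional", "other",
            "refused", "unknown")
EBOLA_SIGNS <- c("fever", "muscle_pain", "vomiting", "sore_throat", "diarrhea",
                 "bleeding", "other", "refused", "unknown")

#' Packaged cluster-survey form template
#'
#' A compact maternal/child-health survey instrument whose skip-logic routing
#' produces five distinct opportunity pools — a consent gate, an
#' ever-given-birth gate into the birth section, a time-availability gate into
#' the health-knowledge section, and two child-treatment branches — and which
#' carries the eleven relaxed validation rules monitored in the reference
#' survey: four intentional-redundancy pairs, two single-question illogical
#' combinations, three required-question removals and two multi-question
#' illogical combinations.
#'
#' @return a [form_spec()] with 22 questions and 11 relaxed rules
#'   (`r1`..`r11`).
#' @export
reference_form_template <- function() {
  Rc <- rel_selected("consent", "yes")
  Rb <- rel_and(Rc, rel_selected("ever_birth_1", "yes"))
  Rf <- rel_and(Rb, rel_selected("child_fever", "yes"))
  Rd <- rel_and(Rb, rel_selected("child_diarrhea", "yes"))
  Rh <- rel_and(Rc, rel_selected("has_time", "yes"))
  qs <- list(
    question("consent", "select_one", "Do you consent to be interviewed?",
             YN, section = "intro"),
    question("ever_birth_1", "select_one", "Have you ever given birth?",
             YN, Rc, section = "demographics"),
    question("facility_birth_1", "select_one",
             "Was your most recent birth in a health facility?", YN, Rb,
             section = "birth"),
    question("child_dob_1", "date",
             "What was the date of birth of your most recently birthed child?",
             relevance = Rb, section = "birth"),
    question("child_alive_1", "select_one",
             "Is your most recently birthed child still alive?", YN, Rb,
             section = "birth"),
    question("child_fever", "select_one",
             "Did the child have fever or cough in the last two weeks?", YN,
             Rb, section = "birth"),
    question("fever_treat_src", "select_multiple",
             "From whom did the child get treatment (fever or cough)?",
             TREAT_SRC, Rf, section = "birth"),
    question("fever_treat_first", "select_one",
             "From whom did the child get treatment FIRST?", TREAT_SRC, Rf,
             section = "birth"),
    question("child_diarrhea", "select_one",
             "Did the child have diarrhea in the last two weeks?", YN, Rb,
             section = "birth"),
    question("diar_treat_src", "select_multiple",
             "From whom did the child get treatment (diarrhea)?", TREAT_SRC,
             Rd, section = "birth"),
    question("diar_treat_first", "select_one",
             "From whom did the child get treatment FIRST?", TREAT_SRC, Rd,
             section = "birth"),
    question("has_time", "select_one",
             "Do you have time to answer the health knowledge questions?", YN,
             Rc, section = "health"),
    question("advice_src", "select_multiple",
             "Where do you go to get medical advice or treatment?", ADVICE,
             Rh, section = "health"),
    question("ebola_signs", "select_multiple",
             "What are the signs of someone who can have ebola?", EBOLA_SIGNS,
             Rh, section = "health"),
    question("ebola_touch", "select_one",
             "Can people get Ebola from touching an Ebola patient?", YN, Rh,
             required = TRUE, section = "health"),
    question("ebola_air", "select_one", "Can people get Ebola from the air?",
             YN, Rh, required = TRUE, section = "health"),
    question("ebola_body", "select_one",
             "Can people get Ebola by touching or washing a dead body?", YN,
             Rh, required = TRUE, section = "health"),
    question("ever_birth_2", "select_one",
             "Have you ever given birth? (verification)", YN, Rc,
             section = "verification"),
    question("facility_birth_2", "select_one",
             "Was your most recent birth in a health facility? (verification)",
             YN, Rb, section = "verification"),
    question("child_dob_2", "date",
             "Date of birth of your most recently birthed child? (verification)",
             relevance = Rb, section = "verification"),
    question("child_alive_2", "select_one",
             "Is your most recently birthed child still alive? (verification)",
             YN, Rb, section = "verification"),
    question("interview_end", "text", "Interviewer comments", relevance = Rc,
             section = "verification"))
  substantive_advice <- setdiff(ADVICE, c("refused", "unknown"))
  substantive_signs <- setdiff(EBOLA_SIGNS, c("refused", "unknown"))
  rules <- list(
    relaxed_rule("r1", "redundancy",
                 list(qa = "facility_birth_1", qb = "facility_birth_2",
                      comparator = "exact")),
    relaxed_rule("r2", "redundancy",
                 list(qa = "ever_birth_1", qb = "ever_birth_2",
                      comparator = "exact")),
    relaxed_rule("r3", "redundancy",
                 list(qa = "child_dob_1", qb = "child_dob_2",
                      comparator = "date")),
    relaxed_rule("r4", "redundancy",
                 list(qa = "child_alive_1", qb = "child_alive_2",
                      comparator = "exact")),
    relaxed_rule("r5", "illogical_single",
                 list(question = "advice_src",
                      exclusive = c("refused", "unknown"),
                      substantive = substantive_advice)),
    relaxed_rule("r6", "illogical_single",
                 list(question = "ebola_signs",
                      exclusive = c("refused", "unknown"),
                      substantive = substantive_signs)),
    relaxed_rule("r7", "required_skip", list(question = "ebola_touch")),
    relaxed_rule("r8", "required_skip", list(question = "ebola_air")),
    relaxed_rule("r9", "required_skip", list(question = "ebola_body")),
    relaxed_rule("r10", "illogical_multi",
                 list(conditions = list(list(question = "fever_treat_first",
                                             not_in = "fever_treat_src")))),
    relaxed_rule("r11", "illogical_multi",
                 list(conditions = list(list(question = "diar_treat_first",
                                             not_in = "diar_treat_src")))))
  form_spec(qs, rules, title = "cluster survey template")
}

#' Demonstration template covering all eight error classes
#'
#' A small instrument carrying one relaxed rule of every class — including
#' the four classes (manual skip logic, removed min/max constraint, manual
#' calculation, invalid data type) that the packaged cluster-survey template
#' does not use. Intended for plant-and-recover testing and demos.
#'
#' @return a [form_spec()] with 13 questions and 8 rules (`d1`..`d8`).
#' @export
demo_form_template <- function() {
  Rc <- rel_selected("consent", "yes")
  Rb <- rel_and(Rc, rel_selected("ever_birth", "yes"))
  qs <- list(
    question("consent", "select_one", choices = YN),
    question("gender", "select_one", "What is your gender?",
             c("male", "female"), Rc),
    question("resp_dob", "date", "What is your birthday?", relevance = Rc),
    question("resp_age", "integer", "What is your age, in years?",
             relevance = Rc),
    question("household_size", "integer", relevance = Rc),
    question("doctor_visits", "integer",
             "How many times have you seen a doctor in the past month?",
             relevance = Rc),
    question("advice_src", "select_multiple", choices = ADVICE, relevance = Rc),
    question("clinic_visit", "select_one",
             "Have you ever been to a health clinic?", YN, Rc),
    question("branch_choice", "select_one", "Choose the next section",
             c("clinical", "skip_clinical"), Rc),
    question("ever_birth", "select_one", "Have you ever given birth?", YN, Rc),
    question("num_births_1", "integer", "How many times have you given birth?",
             relevance = Rb),
    question("postnatal_care", "select_one",
             "Did you receive postnatal care?", YN, Rb, required = TRUE),
    question("num_births_2", "integer",
             "How many times have you given birth? (verification)",
             relevance = Rb))
  rules <- list(
    relaxed_rule("d1", "required_skip", list(question = "postnatal_care")),
    relaxed_rule("d2", "illogical_multi",
                 list(conditions = list(
                   list(question = "gender", equals = "male"),
                   list(question = "ever_birth", equals = "yes")))),
    relaxed_rule("d3", "illogical_single",
                 list(question = "advice_src",
                      exclusive = c("refused", "unknown"),
                      substantive = setdiff(ADVICE, c("refused", "unknown")))),
    relaxed_rule("d4", "redundancy",
                 list(qa = "num_births_1", qb = "num_births_2",
                      comparator = "exact")),
    relaxed_rule("d5", "manual_skip",
                 list(branch_question = "branch_choice",
                      cases = list(
                        list(when = list(question = "clinic_visit",
                                         equals = "yes"),
                             correct = "clinical"),
                        list(when = list(question = "clinic_visit",
                                         equals = "no"),
                             correct = "skip_clinical")))),
    relaxed_rule("d6", "minmax_removed",
                 list(question = "household_size", min = 1, max = 30)),
    relaxed_rule("d7", "manual_calc",
                 list(target = "resp_age",
                      derive = list(type = "age_years", birthdate = "resp_dob"),
                      tolerance = 0)),
    relaxed_rule("d8", "invalid_type",
                 list(question = "doctor_visits", expected = "integer")))
  form_spec(qs, rules, title = "all-classes demo template")
}

## ---- fixture specification --------------------------------------------------

#' Fixture specification
#'
#' Describes the dataset [build_fixture()] must produce on the
#' [reference_form_template()] routing: the size of each opportunity pool, the
#' number of planted errors per rule, the tick-distance composition of the
#' date-redundancy errors, and (optionally) an enumerator-by-period
#' allocation of opportunities and errors.
#'
#' @param respondents total records (consent refusals are
#'   `respondents - consented`).
#' @param consented records passing the consent gate (pool of rule `r2`).
#' @param birth records entering the birth section (rules `r1`, `r3`, `r4`).
#' @param health records entering the health-knowledge section (rules
#'   `r5`-`r9`).
#' @param fever,diarrhea records entering each child-treatment branch (rules
#'   `r10`, `r11`).
#' @param errors named integer vector of planted error counts, names
#'   `r1`..`r11` (missing names default to 0).
#' @param ticks integer vector `c(t1, t2, t3plus)`: how many `r3` errors are
#'   1 tick off, 2 ticks off, and more; must sum to `errors["r3"]`.
#' @param enumerators enumerator id tokens.
#' @param days number of survey days (day 0 .. days-1).
#' @param start_date `Date`; survey day 0.
#' @param allocation optional list with matrices `N` and `E`
#'   (enumerators x periods) of opportunity and error totals per
#'   enumerator-period cell, and `periods` (list of day windows).
#' @return a validated `vr_fixture_spec` list.
#' @export
fixture_spec <- function(respondents, consented, birth, health, fever,
                         diarrhea, errors = c(), ticks = c(0L, 0L, 0L),
                         enumerators = as.character(2:7), days = 46L,
                         start_date = as.Date("2016-04-12"),
                         allocation = NULL) {
  e <- stats::setNames(integer(11), paste0("r", 1:11))
  if (length(errors)) {
    bad <- setdiff(names(errors), names(e))
    if (length(bad)) stop("unknown rule(s) in errors: ", paste(bad, collapse = ", "))
    e[names(errors)] <- as.integer(errors)
  }
  pools <- c(r1 = birth, r2 = consented, r3 = birth, r4 = birth, r5 = health,
             r6 = health, r7 = health, r8 = health, r9 = health, r10 = fever,
             r11 = diarrhea)
  if (consented > respondents) stop("consented exceeds respondents")
  if (birth > consented || health > consented)
    stop("birth/health pools exceed consented pool")
  if (fever > birth || diarrhea > birth)
    stop("treatment branch pools exceed birth pool")
  if (any(e > pools))
    stop("planted errors exceed pool for rule(s): ",
         paste(names(e)[e > pools], collapse = ", "))
  if (sum(ticks) != e[["r3"]])
    stop("tick counts must sum to the r3 error count")
  if (!is.null(allocation)) {
    total_opp <- consented + 5L * health + 3L * birth + fever + diarrhea
    if (sum(allocation$N) != total_opp)
      stop("allocation opportunity totals (", sum(allocation$N),
           ") disagree with pool sizes (", total_opp, ")")
    if (sum(allocation$E) != sum(e))
      stop("allocation error totals disagree with per-rule error counts")
    allocation$periods <- allocation$periods %||% DEFAULT_PERIODS
  }
  spec <- list(respondents = as.integer(respondents),
               consented = as.integer(consented), birth = as.integer(birth),
               health = as.integer(health), fever = as.integer(fever),
               diarrhea = as.integer(diarrhea), errors = e,
               ticks = as.integer(ticks), enumerators = enumerators,
               days = as.integer(days), start_date = as.Date(start_date),
               allocation = allocation)
  class(spec) <- "vr_fixture_spec"
  spec
}

#' The packaged reference fixture specification
#'
#' Encodes the reference survey's study conditions: 972 respondents over a
#' 46-day window starting 2016-04-12, opportunity pools 961 (consent), 618
#' (birth section), 895 (health section), 325 and 202 (treatment branches),
#' planted error counts per rule (125 total over 7817 opportunities), the
#' tick-distance composition of the date-redundancy errors (25 at 1 tick, 14
#' at 2, 45 further off), and the enumerator-by-period allocation of
#' opportunities and errors across six enumerators and three 15/15/16-day
#' periods.
#'
#' @return a `vr_fixture_spec`.
#' @export
reference_fixture_spec <- function() {
  Nm <- matrix(c(458, 465, 415,
                 452, 382, 334,
                 605, 506, 393,
                 386, 364, 286,
                 552, 528, 436,
                 512, 380, 363), nrow = 6, byrow = TRUE,
               dimnames = list(as.character(2:7), NULL))
  Em <- matrix(c(14, 2, 5,
                 13, 3, 6,
                 17, 9, 5,
                 7, 6, 3,
                 14, 5, 1,
                 7, 6, 2), nrow = 6, byrow = TRUE,
               dimnames = list(as.character(2:7), NULL))
  fixture_spec(
    respondents = 972, consented = 961, birth = 618, health = 895,
    fever = 325, diarrhea = 202,
    errors = c(r1 = 19, r2 = 10, r3 = 84, r4 = 10, r5 = 2),
    ticks = c(25L, 14L, 45L),
    allocation = list(N = Nm, E = Em, periods = DEFAULT_PERIODS))
}

## ---- base records and error planting ---------------------------------------

## Deterministic, internally consistent answer set for one respondent of the
## cluster-survey template; i drives benign variety (child birth dates are
## kept with day <= 24 and month <= 10 so tick offsets never cross a
## component boundary).
base_reference_answers <- function(i, consent, health, birth, fever, diar) {
  dob <- sprintf("%04d-%02d-%02d", 2010 + i %% 6, 1 + i %% 10, 5 + i %% 20)
  a <- list(consent = if (consent) "yes" else "no")
  if (!consent) return(a)
  a$ever_birth_1 <- if (birth) "yes" else "no"
  a$ever_birth_2 <- a$ever_birth_1
  a$has_time <- if (health) "yes" else "no"
  if (birth) {
    a$facility_birth_1 <- a$facility_birth_2 <- YN[1 + i %% 2]
    a$child_dob_1 <- a$child_dob_2 <- dob
    a$child_alive_1 <- a$child_alive_2 <- "yes"
    a$child_fever <- if (fever) "yes" else "no"
    if (fever) {
      a$fever_treat_src <- "clinic chw"
      a$fever_treat_first <- c("clinic", "chw")[1 + i %% 2]
    }
    a$child_diarrhea <- if (diar) "yes" else "no"
    if (diar) {
      a$diar_treat_src <- "clinic drugstore"
      a$diar_treat_first <- "clinic"
    }
  }
  if (health) {
    a$advice_src <- ADVICE[1 + i %% 5]
    a$ebola_signs <- paste("fever", EBOLA_SIGNS[2 + i %% 6])
    a$ebola_touch <- "yes"
    a$ebola_air <- "no"
    a$ebola_body <- "yes"
  }
  a$interview_end <- "ok"
  a
}

#' Plant a rule's error into a record
#'
#' Mutates one record's answers so that the given relaxed rule flags an
#' error, without altering the record's routing (the reached-set). The record
#' must already present an opportunity for the rule.
#'
#' @param answers named list of the record's raw answers.
#' @param rule a [relaxed_rule()] of the form.
#' @param form the [form_spec()].
#' @param tau for date-comparator redundancy rules: the tick distance the
#'   planted mismatch should have (component offsets are chosen to sum to
#'   `tau` without crossing month/year boundaries).
#' @return the mutated answers list.
#' @export
plant_error <- function(answers, rule, form, tau = 1L) {
  p <- rule$params
  other_choice <- function(qid, current) {
    ch <- form_question(form, qid)$choices
    setdiff(ch, current)[1]
  }
  switch(rule$rule_class,
    required_skip = {
      answers[[p$question]] <- NA_character_
    },
    illogical_multi = {
      for (cn in p$conditions) {
        if (!is.null(cn$equals)) answers[[cn$question]] <- cn$equals
        else if (!is.null(cn$selected)) {
          cur <- answers[[cn$question]]
          if (is.na(cur) || !cn$selected %in% strsplit(cur, "\\s+")[[1]])
            answers[[cn$question]] <- trimws(paste(cur %||% "", cn$selected))
        } else {
          sel <- strsplit(answers[[cn$not_in]], "\\s+")[[1]]
          answers[[cn$question]] <- other_choice(cn$question, sel)
        }
      }
    },
    illogical_single = {
      answers[[p$question]] <- paste(p$substantive[1], p$exclusive[1])
    },
    redundancy = {
      if (identical(p$comparator, "date")) {
        d <- as.POSIXlt(parse_iso_date(answers[[p$qa]]))
        off <- switch(min(tau, 3L), c(1, 0, 0), c(2, 0, 0),
                      c(tau - 2, 1, 1))
        answers[[p$qb]] <- sprintf("%04d-%02d-%02d",
                                   d$year + 1900 + off[3], d$mon + 1 + off[2],
                                   d$mday + off[1])
      } else {
        cur <- answers[[p$qa]]
        q <- form_question(form, p$qa)
        answers[[p$qb]] <- if (length(q$choices)) other_choice(p$qa, cur)
                           else as.character(parse_numeric(cur) + 1)
      }
    },
    manual_skip = {
      correct <- NA_character_
      for (cs in p$cases) {
        cn <- cs$when
        a <- answers[[cn$question]]
        hit <- if (!is.null(cn$equals)) identical(trimws(a), cn$equals)
               else cn$selected %in% strsplit(a %||% "", "\\s+")[[1]]
        if (isTRUE(hit)) { correct <- cs$correct; break }
      }
      if (is.na(correct)) stop("no manual_skip case matches this record")
      answers[[p$branch_question]] <- other_choice(p$branch_question, correct)
    },
    minmax_removed = {
      answers[[p$question]] <- as.character((p$max %||% 0) + 537)
    },
    manual_calc = {
      answers[[p$target]] <- as.character(parse_numeric(answers[[p$target]]) + 5)
    },
    invalid_type = {
      answers[[p$question]] <- "sometimes"
    })
  answers
}

## ---- allocation solver -------------------------------------------------------

## Distribute record profiles across enumerator-period cells so that each
## cell's opportunity total matches the allocation exactly. Profiles on the
## cluster-survey routing: birth+health record = 9 opportunities, health-only
## = 6, consent-only = 1; fever/diarrhea branch flags add 1 each (placed on
## birth records). Largest-remainder apportionment plus a bounded repair.
solve_cell_profiles <- function(spec) {
  al <- spec$allocation
  Tv <- as.vector(t(al$N))
  n_cells <- length(Tv)
  A <- spec$birth                      # birth+health records
  H <- spec$health - spec$birth        # health-only
  O <- spec$consented - spec$health    # consent-only
  if (H < 0 || O < 0)
    stop("allocation mode requires birth <= health <= consented")
  a <- apportion_integer(A, Tv)
  h <- apportion_integer(H, Tv)
  o <- apportion_integer(O, Tv)
  x <- Tv - 9L * a - 6L * h - o        # branch-flag units per cell
  ## repair: move a unit of flags between cells via 6->9 swaps if out of range
  for (pass in 1:50) {
    lo <- which(x < 0); hi <- which(x > 2L * a)
    if (!length(lo) && !length(hi)) break
    if (length(lo)) {
      i <- lo[1]
      ## cell demands fewer flag units than its profile mix implies: trade a
      ## birth record here for a health-only record from the cell with the
      ## largest flag demand
      j <- which.max(x)
      if (j == i || h[j] < 1 || a[i] < 1)
        stop("infeasible allocation (repair failed)")
      a[i] <- a[i] - 1L; h[i] <- h[i] + 1L
      a[j] <- a[j] + 1L; h[j] <- h[j] - 1L
      x[i] <- x[i] + 3L; x[j] <- x[j] - 3L
    } else {
      i <- hi[1]
      j <- which.min(x)
      if (j == i || h[i] < 1 || a[j] < 1)
        stop("infeasible allocation (repair failed)")
      a[i] <- a[i] + 1L; h[i] <- h[i] - 1L
      a[j] <- a[j] - 1L; h[j] <- h[j] + 1L
      x[i] <- x[i] - 3L; x[j] <- x[j] + 3L
    }
  }
  if (any(x < 0 | x > 2L * a)) stop("infeasible enumerator allocation")
  ## split flag units into fever (f <= a) and diarrhea (d <= a)
  f_lo <- pmax(0L, x - a); f_hi <- pmin(a, x)
  Fv <- spec$fever
  if (sum(f_lo) > Fv || Fv > sum(f_hi))
    stop("infeasible fever/diarrhea branch split")
  f <- f_lo + apportion_integer(Fv - sum(f_lo), pmax(f_hi - f_lo, 1e-9))
  for (pass in 1:50) {
    over <- f > f_hi
    if (!any(over)) break
    excess <- sum(f[over] - f_hi[over]); f[over] <- f_hi[over]
    slack <- f_hi - f
    for (i in order(slack, decreasing = TRUE)) {
      add <- min(excess, slack[i]); f[i] <- f[i] + add; excess <- excess - add
      if (excess == 0) break
    }
  }
  d <- x - f
  stopifnot(sum(f) == spec$fever, sum(d) == spec$diarrhea,
            all(f >= 0), all(d >= 0), all(f <= a), all(d <= a),
            all(9L * a + 6L * h + o + f + d == Tv))
  list(a = a, h = h, o = o, f = f, d = d)
}

## Distribute each rule's planted errors across cells so row sums match the
## allocation's per-cell error totals and no cell exceeds its hosting
## capacity for that rule. Greedy on remaining need; exact by construction
## when feasible (asserted).
solve_cell_errors <- function(spec, prof) {
  Ev <- as.vector(t(spec$allocation$E))
  need <- spec$errors
  with_err <- names(need)[need > 0]
  if (sum(Ev) != sum(need))
    stop("allocation error totals disagree with per-rule error counts")
  cap <- sapply(with_err, function(r) switch(r,
    r2 = prof$a + prof$h + prof$o,
    r5 = , r6 = , r7 = , r8 = , r9 = prof$a + prof$h,
    r10 = prof$f, r11 = prof$d,
    prof$a))                      # r1, r3, r4: birth records
  cap <- matrix(cap, ncol = length(with_err),
                dimnames = list(NULL, with_err))
  alloc <- matrix(0L, length(Ev), length(with_err),
                  dimnames = list(NULL, with_err))
  rem <- need[with_err]
  for (cell in order(Ev, decreasing = TRUE)) {
    for (k in seq_len(Ev[cell])) {
      cand <- with_err[rem[with_err] > 0 & alloc[cell, ] < cap[cell, ]]
      if (!length(cand)) stop("infeasible error allocation at a cell")
      pick <- cand[which.max(rem[cand])]
      alloc[cell, pick] <- alloc[cell, pick] + 1L
      rem[pick] <- rem[pick] - 1L
    }
  }
  stopifnot(all(colSums(alloc) == need[with_err]), all(rowSums(alloc) == Ev))
  alloc
}

## ---- fixture builder ---------------------------------------------------------

#' Build a deterministic fixture dataset
#'
#' Generates submission records on the [reference_form_template()] routing such
#' that detection recovers the spec's planted counts exactly: each rule is
#' reached exactly its pool-size many times and flags exactly the specified
#' number of errors, date-redundancy errors carry the specified tick-distance
#' composition, and — when the spec carries an enumerator allocation — each
#' enumerator-period cell matches its opportunity and error totals.
#'
#' @param spec a [fixture_spec()] (default [reference_fixture_spec()]).
#' @param seed integer; drives the seeded shuffle used for error placement.
#' @return a submissions data.frame (character columns) ready for
#'   [run_detection()] against [reference_form_template()].
#' @export
build_fixture <- function(spec = reference_fixture_spec(), seed = 1L) {
  stopifnot(inherits(spec, "vr_fixture_spec"))
  form <- reference_form_template()
  rules <- stats::setNames(form$rules, vapply(form$rules, `[[`, "", "rule_id"))
  with_seed(seed, {
    if (is.null(spec$allocation))
      recs <- build_fixture_simple(spec, form, rules)
    else
      recs <- build_fixture_allocated(spec, form, rules)
  })
  recs
}

## tick distances for the r3 errors, in planting order
tau_sequence <- function(spec) {
  rep(c(1L, 2L, 3L), times = spec$ticks)
}

assemble_records <- function(rows, form, enumerators, days_vec, start_date) {
  df <- data.frame(record_id = sprintf("r%04d", seq_along(rows)),
                   enumerator_id = enumerators,
                   survey_date = as.character(start_date + days_vec),
                   stringsAsFactors = FALSE)
  for (id in form$ids)
    df[[id]] <- vapply(rows, function(a) {
      v <- a[[id]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, "")
  df
}

## Simple path (no enumerator allocation): pools nested by a seeded shuffle,
## errors planted on a seeded sample of each rule's eligible records,
## enumerators and days assigned round-robin.
build_fixture_simple <- function(spec, form, rules) {
  n <- spec$consented
  consented <- rep(TRUE, n)
  health <- seq_len(n) %in% sample(n, spec$health)
  birth <- seq_len(n) %in% sample(n, spec$birth)
  bidx <- which(birth)
  fever <- seq_len(n) %in% bidx[sample(length(bidx), spec$fever)]
  diar <- seq_len(n) %in% bidx[sample(length(bidx), spec$diarrhea)]
  rows <- lapply(seq_len(n), function(i)
    base_reference_answers(i, TRUE, health[i], birth[i], fever[i], diar[i]))
  eligible <- list(r1 = which(birth), r2 = seq_len(n), r3 = which(birth),
                   r4 = which(birth), r5 = which(health), r6 = which(health),
                   r7 = which(health), r8 = which(health), r9 = which(health),
                   r10 = which(fever), r11 = which(diar))
  taus <- tau_sequence(spec)
  for (r in names(spec$errors)) {
    e <- spec$errors[[r]]
    if (e == 0) next
    hosts <- eligible[[r]][sample(length(eligible[[r]]), e)]
    for (k in seq_along(hosts)) {
      i <- hosts[k]
      rows[[i]] <- plant_error(rows[[i]], rules[[r]], form,
                               tau = if (r == "r3") taus[k] else 1L)
    }
  }
  refusals <- spec$respondents - spec$consented
  rows <- c(rows, lapply(seq_len(refusals), function(i)
    base_reference_answers(i, FALSE, FALSE, FALSE, FALSE, FALSE)))
  m <- length(rows)
  enums <- rep(spec$enumerators, length.out = m)
  days <- rep(seq_len(spec$days) - 1L, length.out = m)
  assemble_records(rows, form, enums, days, spec$start_date)
}

## Allocated path: solve per-cell profile and error counts, then emit
## records cell by cell with dates cycling through the period's window.
build_fixture_allocated <- function(spec, form, rules) {
  al <- spec$allocation
  prof <- solve_cell_profiles(spec)
  errs <- solve_cell_errors(spec, prof)
  periods <- al$periods
  n_enum <- nrow(al$N); n_per <- ncol(al$N)
  taus <- tau_sequence(spec)
  tau_used <- 0L
  rows <- list(); enums <- character(); days <- integer()
  counter <- 0L
  for (ei in seq_len(n_enum)) for (pi in seq_len(n_per)) {
    cell <- (ei - 1L) * n_per + pi
    na <- prof$a[cell]; nh <- prof$h[cell]; no <- prof$o[cell]
    nf <- prof$f[cell]; nd <- prof$d[cell]
    ## birth+health records first (fever flags from the front, diarrhea from
    ## the back so they overlap only when necessary), then health-only, then
    ## consent-only
    cell_rows <- c(
      lapply(seq_len(na), function(k) {
        counter <<- counter + k   # benign variety; not order-sensitive
        base_reference_answers(counter, TRUE, TRUE, TRUE,
                           fever = k <= nf, diar = k > na - nd)
      }),
      lapply(seq_len(nh), function(k) {
        base_reference_answers(counter + k, TRUE, TRUE, FALSE, FALSE, FALSE)
      }),
      lapply(seq_len(no), function(k) {
        base_reference_answers(counter + k, TRUE, FALSE, FALSE, FALSE, FALSE)
      }))
    ## eligible host indices within the cell, per rule
    eligible <- list(r1 = seq_len(na), r2 = seq_along(cell_rows),
                     r3 = seq_len(na), r4 = seq_len(na),
                     r5 = seq_len(na + nh), r6 = seq_len(na + nh),
                     r7 = seq_len(na + nh), r8 = seq_len(na + nh),
                     r9 = seq_len(na + nh),
                     r10 = seq_len(nf), r11 = na - nd + seq_len(nd))
    for (r in colnames(errs)) {
      e <- errs[cell, r]
      if (e == 0) next
      pool <- eligible[[r]]
      hosts <- pool[sample(length(pool), e)]
      for (i in hosts) {
        tau <- 1L
        if (r == "r3") { tau_used <- tau_used + 1L; tau <- taus[tau_used] }
        cell_rows[[i]] <- plant_error(cell_rows[[i]], rules[[r]], form, tau)
      }
    }
    w <- periods[[pi]]
    wdays <- w[1]:w[2]
    rows <- c(rows, cell_rows)
    enums <- c(enums, rep(rownames(al$N)[ei], length(cell_rows)))
    days <- c(days, rep(wdays, length.out = length(cell_rows)))
  }
  refusals <- spec$respondents - spec$consented
  if (refusals > 0) {
    rows <- c(rows, lapply(seq_len(refusals), function(i)
      base_reference_answers(i, FALSE, FALSE, FALSE, FALSE, FALSE)))
    enums <- c(enums, rep(rownames(al$N), length.out = refusals))
    days <- c(days, rep(0L, refusals))
  }
  assemble_records(rows, form, enums, days, spec$start_date)
}

#' Write submissions to CSV
#'
#' @param records submissions data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_submissions <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

## ---- stochastic simulator ----------------------------------------------------

#' Simulator configuration
#'
#' Parameters of the stochastic survey generator: the window, the workforce,
#' the routing probabilities (defaults are the reference survey's pool
#' proportions), and the logistic error process
#' `P(error at day t) = invlogit(beta0 + beta1 t + u_e)`.
#'
#' @param days number of survey days.
#' @param enumerators enumerator id tokens.
#' @param records_per_enum_day respondents interviewed per enumerator per day.
#' @param p_consent,p_birth,p_health,p_fever,p_diar routing probabilities.
#' @param beta0 intercept on the logit scale (default `logit(0.023)`).
#' @param beta1 slope per day on the logit scale (default `log(0.969)`).
#' @param enum_effects optional named numeric vector of per-enumerator
#'   intercept shifts on the logit scale.
#' @param start_date survey day 0.
#' @return a `vr_sim_config` list.
#' @export
sim_config <- function(days = 46L, enumerators = as.character(2:7),
                       records_per_enum_day = 4L,
                       p_consent = 961 / 972, p_birth = 618 / 961,
                       p_health = 895 / 961, p_fever = 325 / 618,
                       p_diar = 202 / 618,
                       beta0 = logit(0.023), beta1 = log(0.969),
                       enum_effects = NULL,
                       start_date = as.Date("2016-04-12")) {
  stopifnot(days >= 1,
            all(c(p_consent, p_birth, p_health, p_fever, p_diar) >= 0),
            all(c(p_consent, p_birth, p_health, p_fever, p_diar) <= 1))
  structure(list(days = as.integer(days), enumerators = enumerators,
                 records_per_enum_day = as.integer(records_per_enum_day),
                 p_consent = p_consent, p_birth = p_birth,
                 p_health = p_health, p_fever = p_fever, p_diar = p_diar,
                 beta0 = beta0, beta1 = beta1, enum_effects = enum_effects,
                 start_date = as.Date(start_date)),
            class = "vr_sim_config")
}

#' Simulate a survey dataset from the logistic error process
#'
#' Generates records on the [reference_form_template()] routing: each record's
#' section gates are Bernoulli draws with the configured probabilities, and
#' each reached rule-opportunity at day `t` independently commits its error
#' with probability `invlogit(beta0 + beta1 t + u_e)`. Date-redundancy errors
#' draw their tick distance from the empirical mix (30% one tick, 17% two).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical (config, seed) give identical data.
#' @return a submissions data.frame.
#' @export
simulate_survey <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "vr_sim_config"))
  form <- reference_form_template()
  rules <- stats::setNames(form$rules, vapply(form$rules, `[[`, "", "rule_id"))
  with_seed(seed, {
    rows <- list(); enums <- character(); days <- integer()
    i <- 0L
    for (d in seq_len(config$days) - 1L) for (e in config$enumerators) {
      u <- if (is.null(config$enum_effects)) 0 else config$enum_effects[[e]] %||% 0
      p_err <- invlogit(config$beta0 + config$beta1 * d + u)
      for (k in seq_len(config$records_per_enum_day)) {
        i <- i + 1L
        consent <- stats::runif(1) < config$p_consent
        birth <- consent && stats::runif(1) < config$p_birth
        health <- consent && stats::runif(1) < config$p_health
        fever <- birth && stats::runif(1) < config$p_fever
        diar <- birth && stats::runif(1) < config$p_diar
        a <- base_reference_answers(i, consent, health, birth, fever, diar)
        if (consent) {
          open <- c(r1 = birth, r2 = TRUE, r3 = birth, r4 = birth,
                    r5 = health, r6 = health, r7 = health, r8 = health,
                    r9 = health, r10 = fever, r11 = diar)
          for (r in names(open)[open]) {
            if (stats::runif(1) < p_err) {
              tau <- sample(1:4, 1, prob = c(0.30, 0.17, 0.33, 0.20))
              a <- plant_error(a, rules[[r]], form, tau = tau)
            }
          }
        }
        rows[[i]] <- a; enums[i] <- e; days[i] <- d
      }
    }
    assemble_records(rows, form, enums, days, config$start_date)
  })
}

#' Simulate bare trend observations
#'
#' Draws `n` binary error opportunities with survey days uniform on
#' `days` and `P(error) = invlogit(beta0 + beta1 day)`, each tagged with a
#' cluster id cycled over `clusters` — the generative mirror of the logistic
#' trend model, without the survey plumbing. The default cluster set mirrors
#' the two-stage design's 86 sampled communities, which is the survey unit
#' the variance correction targets (and enough clusters for the normal
#' sandwich quantile to be adequate).
#'
#' @param n number of opportunities.
#' @param beta0,beta1 logistic process parameters.
#' @param days integer vector of candidate days.
#' @param clusters cluster id tokens.
#' @param seed integer seed.
#' @return data.frame with `error`, `day`, `cluster` (input for
#'   [fit_logistic_trend()]).
#' @export
simulate_trend_obs <- function(n, beta0 = logit(0.023), beta1 = log(0.969),
                               days = 0:45, clusters = sprintf("c%02d", 1:86),
                               seed = 1L) {
  with_seed(seed, {
    day <- sample(days, n, replace = TRUE)
    p <- invlogit(beta0 + beta1 * day)
    data.frame(error = as.integer(stats::runif(n) < p), day = day,
               cluster = rep(clusters, length.out = n),
               stringsAsFactors = FALSE)
  })
}
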