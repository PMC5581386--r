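## Shared fixtures: tiny forms built in code, random record generators, and
## independent oracles (naive relevance evaluator, sequential replay).

yn <- c("yes", "no")

## three-question form with compound relevance, for truth-table checks
tiny_form <- function() {
  form_spec(list(
    question("a", "select_one", choices = yn),
    question("b", "select_one", choices = yn),
    question("c", "integer"),
    question("d", "text",
             relevance = rel_or(rel_and(rel_selected("a", "yes"),
                                        rel_not(rel_selected("b", "no"))),
                                rel_cmp(">=", "c", 5)))))
}

meta_cols <- function(n) {
  data.frame(record_id = sprintf("x%03d", seq_len(n)),
             enumerator_id = rep(c("e1", "e2"), length.out = n),
             survey_date = as.character(as.Date("2016-04-12") +
                                          (seq_len(n) %% 10)),
             stringsAsFactors = FALSE)
}

## incoherent random records (answers may be stray w.r.t. routing)
random_records <- function(form, n, seed, p_answer = 0.8) {
  set.seed(seed)
  df <- meta_cols(n)
  for (q in form$questions) {
    v <- vapply(seq_len(n), function(i) {
      if (runif(1) > p_answer) return(NA_character_)
      switch(q$rtype,
        select_one = sample(q$choices, 1),
        select_multiple = paste(sample(q$choices, sample(seq_along(q$choices), 1)),
                                collapse = " "),
        integer = as.character(sample(0:20, 1)),
        date = as.character(as.Date("2010-01-01") + sample(0:2000, 1)),
        text = "x")
    }, "")
    df[[q$id]] <- v
  }
  df
}

## independent scalar Kleene evaluator, structured differently from the
## package's vectorized one: explicit three-valued truth tables
naive_relevance <- function(expr, answers) {
  ev <- function(e) {
    if (is.null(e) || e$op == "true") return(TRUE)
    if (e$op == "and") {
      vals <- vapply(e$args, ev, NA)
      if (any(!vals, na.rm = TRUE)) return(FALSE)
      if (anyNA(vals)) return(NA)
      return(TRUE)
    }
    if (e$op == "or") {
      vals <- vapply(e$args, ev, NA)
      if (any(vals, na.rm = TRUE)) return(TRUE)
      if (anyNA(vals)) return(NA)
      return(FALSE)
    }
    if (e$op == "not") {
      v <- ev(e$arg)
      return(if (is.na(v)) NA else !v)
    }
    a <- answers[[e$question]]
    if (is.null(a) || length(a) == 0 || is.na(a) || !nzchar(trimws(a)))
      return(NA)
    a <- trimws(a)
    if (e$op == "selected")
      return(e$option %in% strsplit(a, "\\s+")[[1]])
    num_a <- suppressWarnings(as.numeric(a))
    num_v <- suppressWarnings(as.numeric(as.character(e$value)))
    switch(e$op,
      "="  = if (!is.na(num_v)) isTRUE(num_a == num_v) else a == as.character(e$value),
      "!=" = if (!is.na(num_v)) !isTRUE(num_a == num_v) else a != as.character(e$value),
      "<"  = isTRUE(num_a < num_v),
      "<=" = isTRUE(num_a <= num_v),
      ">"  = isTRUE(num_a > num_v),
      ">=" = isTRUE(num_a >= num_v))
  }
  ev(expr)
}

## independent sequential-replay oracle for the reached-set
replay_oracle <- function(form, record) {
  eff <- list()
  reached <- character()
  for (q in form$questions) {
    r <- naive_relevance(q$relevance, eff)
    if (isTRUE(r)) {
      reached <- c(reached, q$id)
      a <- record[[q$id]]
      if (!is.null(a) && length(a) && !is.na(a) && nzchar(trimws(as.character(a))))
        eff[[q$id]] <- as.character(a)
    }
  }
  reached
}

## coherent error-free records for the demo (all-classes) template; every
## record consents, a seeded mix routes through the birth section
demo_records <- function(n, seed) {
  set.seed(seed)
  df <- meta_cols(n)
  birth <- runif(n) < 0.6
  male <- runif(n) < 0.3 & !birth
  dob <- as.Date("1980-06-15") + sample(0:6000, n, replace = TRUE)
  age <- derive_completed_years(dob, as.Date(df$survey_date))
  clinic <- sample(yn, n, replace = TRUE)
  df$consent <- "yes"
  df$gender <- ifelse(male, "male", "female")
  df$resp_dob <- as.character(dob)
  df$resp_age <- as.character(age)
  df$household_size <- as.character(sample(1:15, n, replace = TRUE))
  df$doctor_visits <- as.character(sample(0:9, n, replace = TRUE))
  df$advice_src <- sample(c("clinic", "drugstore", "unknown"), n, replace = TRUE)
  df$clinic_visit <- clinic
  df$branch_choice <- ifelse(clinic == "yes", "clinical", "skip_clinical")
  df$ever_birth <- ifelse(birth, "yes", "no")
  df$num_births_1 <- ifelse(birth, as.character(sample(1:8, n, replace = TRUE)), NA)
  df$postnatal_care <- ifelse(birth, sample(yn, n, replace = TRUE), NA)
  df$num_births_2 <- df$num_births_1
  df
}

## independent brute-force maximiser of the Bernoulli log-likelihood:
## Newton-Raphson on the analytic gradient/hessian, to machine precision
newton_logistic <- function(day, error, tol = 1e-12) {
  b <- c(0, 0)
  X <- cbind(1, day)
  for (it in 1:100) {
    p <- 1 / (1 + exp(-(X %*% b)))
    grad <- crossprod(X, error - p)
    hess <- -crossprod(X, X * as.numeric(p * (1 - p)))
    step <- solve(hess, grad)
    b <- b - as.numeric(step)
    if (max(abs(grad)) < tol) break
  }
  b
}

## small, fast fixture spec variants for property tests
random_fixture_spec <- function(seed) {
  set.seed(seed)
  consented <- sample(60:120, 1)
  birth <- sample(20:(consented - 10), 1)
  health <- sample(birth:(consented - 5), 1)
  fever <- sample(5:birth, 1)
  diar <- sample(2:fever, 1)
  e3 <- sample(0:8, 1)
  t1 <- if (e3 > 0) sample(0:e3, 1) else 0
  t2 <- if (e3 - t1 > 0) sample(0:(e3 - t1), 1) else 0
  fixture_spec(
    respondents = consented + sample(0:5, 1), consented = consented,
    birth = birth, health = health, fever = fever, diarrhea = diar,
    errors = c(r1 = sample(0:5, 1), r2 = sample(0:5, 1), r3 = e3,
               r4 = sample(0:5, 1), r5 = sample(0:3, 1), r6 = sample(0:3, 1),
               r7 = sample(0:3, 1), r8 = sample(0:2, 1), r9 = sample(0:2, 1),
               r10 = sample(0:2, 1), r11 = sample(0:2, 1)),
    ticks = c(t1, t2, e3 - t1 - t2))
}
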