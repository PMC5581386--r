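## The eight-class taxonomy of detectable errors. Each relaxed rule turns a
## deliberately removed validation constraint into an evaluable check that
## yields, per record, an opportunity flag (were the requisite questions
## reached?) and an error flag.

#' Declare a relaxed validation rule
#'
#' A relaxed rule names one monitored, deliberately-permitted error. The
#' class-specific `params` are:
#'
#' * `required_skip`: `question` — a normally-required question; the error is
#'   reaching it and leaving it blank.
#' * `illogical_multi`: `conditions` — a list of predicates over distinct
#'   questions whose conjunction is logically impossible. Each predicate is a
#'   list with `question` and one of `equals` (value), `selected` (option
#'   token), or `not_in` (id of a `select_multiple` question the answer must
#'   appear in; the error condition is that it does not).
#' * `illogical_single`: `question`, `exclusive`, `substantive` — a
#'   `select_multiple` where co-selecting any exclusive option (e.g.
#'   "unknown") with any substantive option is impossible.
#' * `redundancy`: `qa`, `qb`, `comparator` (`"exact"` or `"date"`) — the same
#'   question asked in two sections; differing answers are an error. For the
#'   date comparator the tick distance between the two dates is retained as a
#'   diagnostic.
#' * `manual_skip`: `branch_question`, `cases` — the enumerator chooses the
#'   next branch manually; each case is a list with `when` (a predicate as in
#'   `illogical_multi`) and `correct` (the branch option that should be
#'   chosen). Choosing any other branch is an error.
#' * `minmax_removed`: `question` plus logical `min` and/or `max` — the range
#'   constraint was removed; a typed value outside the range is an error.
#' * `manual_calc`: `target`, `derive`, `tolerance` (default 0) — the value
#'   could be computed from earlier answers. `derive` is either
#'   `list(type = "age_years", birthdate = <question id>)` (completed years at
#'   the survey date) or `list(type = "arith", op = "+"|"-"|"*", args =
#'   list(...))` with each arg `list(question = id)` or `list(const = n)`.
#'   An absolute discrepancy beyond `tolerance` is an error.
#' * `invalid_type`: `question`, `expected` (`"integer"` or `"date"`) — the
#'   type constraint was removed; an unparseable value is an error.
#'
#' @param rule_id unique token identifying the rule.
#' @param rule_class one of the eight class tokens above.
#' @param params named list of class-specific parameters.
#' @return a `vr_rule` object.
#' @export
relaxed_rule <- function(rule_id, rule_class, params) {
  rule_class <- match.arg(rule_class, RULE_CLASSES)
  structure(list(rule_id = as.character(rule_id), rule_class = rule_class,
                 params = params),
            class = "vr_rule")
}

rule_questions <- function(rule) {
  p <- rule$params
  switch(rule$rule_class,
    required_skip   = p$question,
    illogical_multi = unique(unlist(lapply(p$conditions, function(cn)
                        c(cn$question, cn$not_in)))),
    illogical_single = p$question,
    redundancy      = c(p$qa, p$qb),
    manual_skip     = unique(c(p$branch_question,
                        vapply(p$cases, function(cs) cs$when$question, ""))),
    minmax_removed  = p$question,
    manual_calc     = unique(c(p$target,
                        if (identical(p$derive$type, "age_years")) p$derive$birthdate
                        else unlist(lapply(p$derive$args, `[[`, "question")))),
    invalid_type    = p$question)
}

validate_rule <- function(rule, form) {
  if (!inherits(rule, "vr_rule")) stop("rules must be vr_rule objects")
  p <- rule$params
  need <- function(...) {
    miss <- setdiff(c(...), names(p))
    if (length(miss))
      stop("rule '", rule$rule_id, "' (", rule$rule_class,
           "): missing param(s) ", paste(miss, collapse = ", "))
  }
  switch(rule$rule_class,
    required_skip = need("question"),
    illogical_multi = {
      need("conditions")
      if (length(p$conditions) < 1)
        stop("rule '", rule$rule_id, "': empty condition list")
      for (cn in p$conditions)
        if (is.null(cn$question) ||
            is.null(cn$equals) + is.null(cn$selected) + is.null(cn$not_in) != 2)
          stop("rule '", rule$rule_id,
               "': each condition needs question + exactly one of equals/selected/not_in")
    },
    illogical_single = {
      need("question", "exclusive", "substantive")
      q <- form_question(form, p$question)
      bad <- setdiff(c(p$exclusive, p$substantive), q$choices)
      if (length(bad))
        stop("rule '", rule$rule_id, "': option(s) not in choice list: ",
             paste(bad, collapse = ", "))
    },
    redundancy = {
      need("qa", "qb")
      cmp <- p$comparator %||% "exact"
      if (!cmp %in% c("exact", "date"))
        stop("rule '", rule$rule_id, "': comparator must be exact or date")
    },
    manual_skip = {
      need("branch_question", "cases")
      for (cs in p$cases)
        if (is.null(cs$when$question) || is.null(cs$correct))
          stop("rule '", rule$rule_id, "': each case needs when$question and correct")
    },
    minmax_removed = {
      need("question")
      if (is.null(p$min) && is.null(p$max))
        stop("rule '", rule$rule_id, "': needs min and/or max")
    },
    manual_calc = {
      need("target", "derive")
      if (!identical(p$derive$type, "age_years") &&
          !identical(p$derive$type, "arith"))
        stop("rule '", rule$rule_id, "': derive$type must be age_years or arith")
    },
    invalid_type = {
      need("question", "expected")
      if (!p$expected %in% c("integer", "date"))
        stop("rule '", rule$rule_id, "': expected must be integer or date")
    })
  bad <- setdiff(rule_questions(rule), form$ids)
  if (length(bad))
    stop("rule '", rule$rule_id, "' references unknown question(s): ",
         paste(bad, collapse = ", "))
  invisible(rule)
}

## ---- date helpers -----------------------------------------------------------

#' Tick distance between two calendar dates
#'
#' Models scroll-widget overshoot on date pickers: the distance is the sum of
#' absolute day, month and year component offsets between the raw calendar
#' components (no carrying/normalisation). `2016-05-10` vs `2016-06-11` is 2
#' ticks (one month, one day).
#'
#' @param a,b `Date` vectors (recycled).
#' @return non-negative integer vector.
#' @export
tick_distance <- function(a, b) {
  a <- as.POSIXlt(as.Date(a)); b <- as.POSIXlt(as.Date(b))
  as.integer(abs(a$mday - b$mday) + abs(a$mon - b$mon) + abs(a$year - b$year))
}

#' Completed years between a birthdate and a reference date
#'
#' Age in completed years: the year difference, minus one when the birthday
#' has not yet been reached in the reference year.
#'
#' @param birthdate,asof `Date` vectors (recycled); `birthdate` must not be
#'   after `asof`.
#' @return non-negative integer vector.
#' @export
derive_completed_years <- function(birthdate, asof) {
  b <- as.POSIXlt(as.Date(birthdate)); a <- as.POSIXlt(as.Date(asof))
  if (any(as.Date(asof) < as.Date(birthdate), na.rm = TRUE))
    stop("birthdate after reference date")
  yrs <- a$year - b$year
  before <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(yrs - before)
}

## ---- rule evaluation --------------------------------------------------------

## ctx: output of replay_form() plus record metadata; everything vectorized
## over records. Returns reached/error/detail/tau vectors and a diagnostics
## data.frame of values that could not be typed (excluded from opportunities).
eval_rule_vec <- function(rule, ctx, form) {
  p <- rule$params
  n <- nrow(ctx$reached)
  ans <- ctx$answers
  reached_q <- function(q) ctx$reached[, q]
  answered <- function(q) !is.na(ans[[q]])
  diag_rows <- NULL
  note <- function(q, bad, issue) {
    if (any(bad))
      diag_rows <<- rbind(diag_rows, data.frame(
        record_id = ctx$record_id[bad], rule_id = rule$rule_id,
        question = q, value = as.character(ctx$raw[[q]][bad]),
        issue = issue, stringsAsFactors = FALSE))
  }
  err <- rep(FALSE, n); detail <- rep(NA_character_, n); tau <- rep(NA_integer_, n)

  hold <- function(cn) {
    ## predicate over effective answers; NA-safe (FALSE when unanswered)
    a <- ans[[cn$question]]
    if (!is.null(cn$equals)) !is.na(a) & trimws(a) == cn$equals
    else if (!is.null(cn$selected))
      vapply(strsplit(ifelse(is.na(a), "", a), "\\s+"),
             function(t) cn$selected %in% t, NA)
    else {
      other <- ans[[cn$not_in]]
      !is.na(a) & !is.na(other) &
        !mapply(function(x, t) x %in% t, trimws(a),
                strsplit(ifelse(is.na(other), "", other), "\\s+"))
    }
  }

  switch(rule$rule_class,
    required_skip = {
      opp <- reached_q(p$question)
      err <- opp & !answered(p$question)
    },
    illogical_multi = {
      qs <- rule_questions(rule)
      opp <- Reduce(`&`, lapply(qs, function(q) reached_q(q) & answered(q)))
      if (opp_any <- any(opp)) {
        allhold <- Reduce(`&`, lapply(p$conditions, hold))
        err <- opp & allhold
        detail[err] <- "impossible combination"
      }
    },
    illogical_single = {
      opp <- reached_q(p$question) & answered(p$question)
      toks <- strsplit(ifelse(is.na(ans[[p$question]]), "", ans[[p$question]]), "\\s+")
      ex <- vapply(toks, function(t) any(t %in% p$exclusive), NA)
      su <- vapply(toks, function(t) any(t %in% p$substantive), NA)
      err <- opp & ex & su
      detail[err] <- vapply(toks[err], function(t)
        paste0(intersect(t, p$exclusive)[1], "+", intersect(t, p$substantive)[1]), "")
    },
    redundancy = {
      cmp <- p$comparator %||% "exact"
      opp <- reached_q(p$qa) & answered(p$qa) & reached_q(p$qb) & answered(p$qb)
      if (cmp == "date") {
        da <- parse_iso_date(ans[[p$qa]]); db <- parse_iso_date(ans[[p$qb]])
        bad <- opp & (is.na(da) | is.na(db))
        note(p$qa, opp & answered(p$qa) & is.na(da), "unparseable date")
        note(p$qb, opp & answered(p$qb) & is.na(db), "unparseable date")
        opp <- opp & !bad
        err <- opp & da != db
        err[is.na(err)] <- FALSE
        tau[err] <- tick_distance(da[err], db[err])
        detail[err] <- paste0("tau=", tau[err])
      } else {
        err <- opp & trimws(ans[[p$qa]]) != trimws(ans[[p$qb]])
        err[is.na(err)] <- FALSE
        detail[err] <- paste0(ans[[p$qa]][err], "|", ans[[p$qb]][err])
      }
    },
    manual_skip = {
      qs <- rule_questions(rule)
      opp <- Reduce(`&`, lapply(qs, function(q) reached_q(q))) &
             answered(p$branch_question)
      correct <- rep(NA_character_, n)
      for (cs in rev(p$cases)) {   # first matching case wins
        h <- hold(cs$when)
        correct[h] <- cs$correct
      }
      opp <- opp & !is.na(correct)
      chosen <- trimws(ans[[p$branch_question]])
      err <- opp & chosen != correct
      err[is.na(err)] <- FALSE
      detail[err] <- paste0("chose ", chosen[err], ", expected ", correct[err])
    },
    minmax_removed = {
      opp <- reached_q(p$question) & answered(p$question)
      v <- parse_numeric(ans[[p$question]])
      bad <- opp & is.na(v)
      note(p$question, bad, "unparseable numeric")
      opp <- opp & !bad
      out <- rep(FALSE, n)
      if (!is.null(p$min)) out <- out | (v < p$min)
      if (!is.null(p$max)) out <- out | (v > p$max)
      err <- opp & !is.na(out) & out
      detail[err] <- paste0("value ", v[err], " outside [",
                            p$min %||% "-Inf", ", ", p$max %||% "Inf", "]")
    },
    manual_calc = {
      qs <- rule_questions(rule)
      opp <- Reduce(`&`, lapply(qs, function(q) reached_q(q) & answered(q)))
      entered <- parse_numeric(ans[[p$target]])
      bad <- opp & is.na(entered)
      note(p$target, bad, "unparseable numeric")
      if (identical(p$derive$type, "age_years")) {
        bd <- parse_iso_date(ans[[p$derive$birthdate]])
        badd <- opp & is.na(bd)
        note(p$derive$birthdate, badd, "unparseable date")
        bad <- bad | badd
        derived <- rep(NA_real_, n)
        ok <- !is.na(bd) & bd <= ctx$survey_date
        badb <- opp & !is.na(bd) & !ok
        note(p$derive$birthdate, badb, "birthdate after survey date")
        bad <- bad | badb
        derived[ok] <- derive_completed_years(bd[ok], ctx$survey_date[ok])
      } else {
        vals <- lapply(p$derive$args, function(a)
          if (!is.null(a$const)) rep(as.numeric(a$const), n)
          else parse_numeric(ans[[a$question]]))
        for (i in seq_along(p$derive$args)) {
          a <- p$derive$args[[i]]
          if (!is.null(a$question)) {
            badq <- opp & is.na(vals[[i]])
            note(a$question, badq, "unparseable numeric")
            bad <- bad | badq
          }
        }
        derived <- Reduce(switch(p$derive$op, "+" = `+`, "-" = `-`, "*" = `*`),
                          vals)
      }
      opp <- opp & !bad
      tol <- p$tolerance %||% 0
      err <- opp & !is.na(derived) & abs(entered - derived) > tol
      err[is.na(err)] <- FALSE
      detail[err] <- paste0("entered ", entered[err], ", derived ", derived[err])
    },
    invalid_type = {
      opp <- reached_q(p$question) & answered(p$question)
      v <- ans[[p$question]]
      okv <- if (p$expected == "integer") !is.na(parse_integer_strict(v))
             else !is.na(parse_iso_date(v))
      err <- opp & !okv
      detail[err] <- paste0("'", v[err], "' not a valid ", p$expected)
    })

  list(reached = opp, error = err, detail = detail, tau = tau,
       diagnostics = diag_rows)
}

#' Evaluate one relaxed rule on one record
#'
#' Determines whether the record presented an *opportunity* for this rule
#' (all requisite questions reached — and answered, for classes that compare
#' values) and whether the permitted error was committed.
#'
#' @param rule a [relaxed_rule()] declared on the form.
#' @param record a single submission record (one-row data.frame or named list)
#'   including the form's metadata fields.
#' @param form the [form_spec()].
#' @return a list with `record_id`, `rule_id`, `rule_class`, `reached`,
#'   `error`, `detail` (diagnostic string when an error), and `tau` (tick
#'   distance, date-redundancy errors only).
#' @export
eval_rule <- function(rule, record, form) {
  rec <- as.data.frame(as.list(record), stringsAsFactors = FALSE)
  ctx <- detection_context(form, validate_records(rec, form))
  v <- eval_rule_vec(rule, ctx, form)
  list(record_id = ctx$record_id[1], rule_id = rule$rule_id,
       rule_class = rule$rule_class,
       reached = unname(v$reached[1]), error = unname(v$error[1]),
       detail = unname(v$detail[1]), tau = unname(v$tau[1]))
}
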