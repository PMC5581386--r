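## Survey instrument model: ordered questions, relevance (skip-logic)
## expressions, relaxed-rule declarations, and "reached" semantics.

RTYPES <- c("select_one", "select_multiple", "integer", "date", "text")
RULE_CLASSES <- c("required_skip", "illogical_multi", "illogical_single",
                  "redundancy", "manual_skip", "minmax_removed",
                  "manual_calc", "invalid_type")

#' Construct a survey question
#'
#' @param id unique question identifier (token).
#' @param rtype response type: one of `select_one`, `select_multiple`,
#'   `integer`, `date`, `text`.
#' @param prompt question text shown to the enumerator.
#' @param choices ordered option tokens; required for the select types and
#'   disallowed otherwise.
#' @param relevance a relevance expression (see [eval_relevance()]) or `NULL`
#'   for always-shown.
#' @param required logical; whether the platform would normally require an
#'   answer.
#' @param section section token, used only for labelling.
#' @param constraints optional retained range constraint, a list with `min`
#'   and/or `max`, for questions whose validation is *not* relaxed.
#' @return a `vr_question` list.
#' @export
question <- function(id, rtype, prompt = id, choices = NULL, relevance = NULL,
                     required = FALSE, section = "main", constraints = NULL) {
  rtype <- match.arg(rtype, RTYPES)
  if (rtype %in% c("select_one", "select_multiple")) {
    if (is.null(choices) || length(choices) == 0)
      stop("question '", id, "': select types need a non-empty choice list")
  } else if (!is.null(choices)) {
    stop("question '", id, "': choices only allowed for select types")
  }
  structure(list(id = as.character(id), prompt = prompt, rtype = rtype,
                 choices = as.character(choices %||% character()),
                 relevance = relevance, required = isTRUE(required),
                 section = section, constraints = constraints),
            class = "vr_question")
}

#' Construct a form specification
#'
#' A form is an ordered list of questions plus submission metadata field names
#' and the declarations of relaxed validation rules to monitor.
#'
#' @param questions list of [question()] objects, in form order.
#' @param rules list of [relaxed_rule()] objects.
#' @param meta named list with entries `record_id`, `enumerator_id`,
#'   `survey_date`: the submission column names holding metadata.
#' @param title optional form title.
#' @return a validated `vr_form` object.
#' @export
form_spec <- function(questions, rules = list(),
                      meta = list(record_id = "record_id",
                                  enumerator_id = "enumerator_id",
                                  survey_date = "survey_date"),
                      title = "form") {
  ids <- vapply(questions, function(q) q$id, "")
  if (anyDuplicated(ids))
    stop("duplicate question ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (m in c("record_id", "enumerator_id", "survey_date"))
    if (is.null(meta[[m]])) stop("meta field '", m, "' missing")
  form <- structure(list(title = title, questions = questions, rules = rules,
                         meta = meta, ids = ids),
                    class = "vr_form")
  ## relevance may only reference strictly earlier questions
  for (i in seq_along(questions)) {
    refs <- relevance_refs(questions[[i]]$relevance)
    bad <- setdiff(refs, ids[seq_len(i - 1L)])
    if (length(bad))
      stop("question '", ids[i], "': relevance references '",
           paste(bad, collapse = "', '"),
           "' which is not an earlier question")
  }
  for (r in rules) validate_rule(r, form)
  form
}

#' @export
print.vr_form <- function(x, ...) {
  cat("<vr_form> '", x$title, "': ", length(x$questions), " questions, ",
      length(x$rules), " relaxed rules\n", sep = "")
  invisible(x)
}

form_question <- function(form, id) {
  i <- match(id, form$ids)
  if (is.na(i)) stop("unknown question id '", id, "'")
  form$questions[[i]]
}

## ---- relevance expressions --------------------------------------------------

## Expressions are nested lists: list(op = "and", args = list(...)),
## list(op = "not", arg = ...), list(op = "selected", question =, option =),
## list(op = "=", question =, value =) and likewise for !=, <, <=, >, >=,
## or list(op = "true"). NULL means always relevant.

REL_CMP <- c("=", "!=", "<", "<=", ">", ">=")

relevance_refs <- function(expr) {
  if (is.null(expr)) return(character())
  op <- expr$op
  if (op == "true") return(character())
  if (op %in% c("and", "or"))
    return(unique(unlist(lapply(expr$args, relevance_refs))))
  if (op == "not") return(relevance_refs(expr$arg))
  if (op == "selected" || op %in% REL_CMP) return(expr$question)
  stop("unknown relevance operator '", op, "'")
}

#' Evaluate a relevance (skip-logic) expression
#'
#' Relevance expressions decide whether a question is displayed given answers
#' to earlier questions. Evaluation uses three-valued (Kleene) logic: a leaf
#' over a missing answer is unknown (`NA`), `and`/`or`/`not` combine as in R,
#' and an unknown result at the top level means *not relevant*. This keeps the
#' reached-set monotone: removing an answer can never reveal a question.
#'
#' Comparison leaves (`<`, `<=`, `>`, `>=`) coerce the answer numerically and
#' evaluate to `FALSE` on a non-numeric answer; `=`/`!=` compare numerically
#' when both sides parse as numbers and as strings otherwise. `selected`
#' matches one token of a space-separated `select_multiple` answer.
#'
#' @param expr a relevance expression (nested list, see Details) or `NULL`
#'   (always `TRUE`).
#' @param answers a named list or single-row data.frame of raw answers; a
#'   missing/empty value is treated as unanswered. Vector values evaluate the
#'   expression element-wise.
#' @return logical (vector), never `NA`: unknown collapses to `FALSE`.
#' @examples
#' eval_relevance(rel_selected("ever_birth", "yes"), list(ever_birth = "yes"))
#' eval_relevance(rel_selected("ever_birth", "yes"), list(ever_birth = NA))
#' @export
eval_relevance <- function(expr, answers) {
  v <- eval_relevance_na(expr, answers)
  !is.na(v) & v
}

## Kleene-valued core: returns logical with NA = unknown.
eval_relevance_na <- function(expr, answers) {
  n <- if (length(answers)) max(lengths(answers)) else 1L
  if (is.null(expr)) return(rep(TRUE, n))
  op <- expr$op
  if (op == "true") return(rep(TRUE, n))
  if (op == "and") {
    out <- rep(TRUE, n)
    for (a in expr$args) out <- out & eval_relevance_na(a, answers)
    return(out)
  }
  if (op == "or") {
    out <- rep(FALSE, n)
    for (a in expr$args) out <- out | eval_relevance_na(a, answers)
    return(out)
  }
  if (op == "not") return(!eval_relevance_na(expr$arg, answers))
  ## leaf: fetch referenced answer
  if (!expr$question %in% names(answers))
    stop("relevance references undeclared question '", expr$question, "'")
  raw <- as.character(answers[[expr$question]])
  if (length(raw) == 1L && n > 1L) raw <- rep(raw, n)
  ans <- ifelse(is_answered(raw), trimws(raw), NA_character_)
  if (op == "selected") {
    hit <- vapply(strsplit(ifelse(is.na(ans), "", ans), "\\s+"),
                  function(t) expr$option %in% t, NA)
    return(ifelse(is.na(ans), NA, hit))
  }
  if (op %in% REL_CMP) {
    val <- as.character(expr$value)
    num_v <- parse_numeric(val)
    num_a <- parse_numeric(ans)
    if (op %in% c("=", "!=")) {
      eq <- if (!is.na(num_v)) !is.na(num_a) & num_a == num_v else ans == val
      out <- if (op == "=") eq else !eq
      return(ifelse(is.na(ans), NA, out))
    }
    if (is.na(num_v)) stop("relevance comparison '", op, "' needs a numeric literal")
    cmp <- switch(op, "<" = num_a < num_v, "<=" = num_a <= num_v,
                  ">" = num_a > num_v, ">=" = num_a >= num_v)
    out <- !is.na(num_a) & cmp
    return(ifelse(is.na(ans), NA, out))
  }
  stop("unknown relevance operator '", op, "'")
}

#' Relevance expression constructors
#'
#' Convenience builders for the nested-list relevance dialect used in form
#' specifications: `rel_selected()` tests membership of an option in an
#' answer, `rel_cmp()` compares an answer against a literal, and
#' `rel_and()`/`rel_or()`/`rel_not()` combine sub-expressions.
#'
#' @param question question id referenced by the leaf.
#' @param option choice token to test.
#' @param op comparison operator, one of `=`, `!=`, `<`, `<=`, `>`, `>=`.
#' @param value literal to compare against.
#' @param ... sub-expressions.
#' @param expr sub-expression to negate.
#' @return a relevance expression (nested list).
#' @export
rel_selected <- function(question, option)
  list(op = "selected", question = question, option = option)

#' @rdname rel_selected
#' @export
rel_cmp <- function(op, question, value) {
  stopifnot(op %in% REL_CMP)
  list(op = op, question = question, value = value)
}

#' @rdname rel_selected
#' @export
rel_and <- function(...) list(op = "and", args = list(...))

#' @rdname rel_selected
#' @export
rel_or <- function(...) list(op = "or", args = list(...))

#' @rdname rel_selected
#' @export
rel_not <- function(expr) list(op = "not", arg = expr)

## ---- reached semantics ------------------------------------------------------

## Sequential replay of the form over a set of records. A question is reached
## when its relevance holds over the *effective* answers accumulated so far;
## answers attached to unreached questions are stray and ignored downstream.
## Returns reached (n x Q logical matrix) and the effective answer columns.
replay_form <- function(form, records) {
  n <- nrow(records)
  ids <- form$ids
  reached <- matrix(FALSE, n, length(ids), dimnames = list(NULL, ids))
  eff <- list()
  for (j in seq_along(ids)) {
    id <- ids[j]
    r <- eval_relevance_na(form$questions[[j]]$relevance, eff)
    if (length(r) == 1L) r <- rep(r, n)
    rj <- !is.na(r) & r
    reached[, j] <- rj
    raw <- if (id %in% names(records)) as.character(records[[id]])
           else rep(NA_character_, n)
    raw[!rj | !is_answered(raw)] <- NA_character_
    eff[[id]] <- raw
  }
  list(reached = reached, answers = eff)
}

#' Which questions does a record reach?
#'
#' Replays the form in order, evaluating each question's relevance over the
#' effective answers accumulated so far. Answers recorded against unreached
#' questions (stray data) are ignored by later relevance evaluations.
#'
#' @param form a [form_spec()].
#' @param record a single submission record (one-row data.frame or named
#'   list of raw answers).
#' @return character vector of reached question ids, in form order.
#' @export
reached_questions <- function(form, record) {
  rec <- as.data.frame(as.list(record), stringsAsFactors = FALSE)
  rp <- replay_form(form, rec)
  form$ids[rp$reached[1L, ]]
}

#' Is a specific question reached by a record?
#'
#' @inheritParams reached_questions
#' @param id question id.
#' @return logical scalar.
#' @export
question_reached <- function(form, record, id) {
  if (!id %in% form$ids) stop("unknown question id '", id, "'")
  id %in% reached_questions(form, record)
}

## ---- submissions ------------------------------------------------------------

#' Read and validate survey submissions
#'
#' Submissions are flat records, one row per respondent: the metadata columns
#' named by the form's `meta` block plus one column per question (raw string
#' values; `select_multiple` answers are space-separated option tokens).
#' Accepted on disk as CSV (UTF-8, header row) or JSON-lines.
#'
#' @param path file path (`.csv` or `.jsonl`/`.ndjson`).
#' @param form the [form_spec()] to validate against.
#' @return a validated data.frame of character columns.
#' @export
read_submissions <- function(path, form) {
  if (!file.exists(path)) stop("submissions file not found: ", path)
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    rows <- lapply(lines[nzchar(lines)], jsonlite::fromJSON)
    all_names <- unique(unlist(lapply(rows, names)))
    df <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
      vapply(all_names, function(nm) {
        v <- r[[nm]]
        if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
      }, "")
    })), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, na.strings = c("NA", ""))
  }
  validate_records(df, form)
}

#' @rdname read_submissions
#' @param records data.frame of raw submissions.
#' @export
validate_records <- function(records, form) {
  meta_cols <- unlist(form$meta)
  miss <- setdiff(meta_cols, names(records))
  if (length(miss))
    stop("submissions missing metadata column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(records), c(meta_cols, form$ids))
  if (length(unknown))
    stop("unknown submission column(s): ", paste(unknown, collapse = ", "))
  records[] <- lapply(records, as.character)
  d <- parse_iso_date(records[[form$meta$survey_date]])
  if (anyNA(d))
    stop("unparseable survey_date (ISO 8601 YYYY-MM-DD required) in record(s): ",
         paste(utils::head(records[[form$meta$record_id]][is.na(d)], 5), collapse = ", "))
  if (anyDuplicated(records[[form$meta$record_id]]))
    stop("duplicate record ids")
  records
}
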