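## JSON form-spec dialect: a compact, JSON-compatible subset of XLSForm
## semantics — enough to express ordered questions, types, choice lists,
## relevance expressions and relaxed-rule declarations.

#' Parse a form specification from JSON
#'
#' The documented schema has top-level keys `title`, `meta`
#' (`record_id`/`enumerator_id`/`survey_date` column names), `questions[]`
#' (`id`, `rtype`, `prompt`, `choices`, `relevance`, `required`, `section`,
#' `constraints`) and `rules[]` (`rule_id`, `rule_class`, `params`; see
#' [relaxed_rule()]). Relevance expressions are JSON objects mirroring the
#' nested-list dialect of [eval_relevance()], e.g.
#' `{"op":"selected","question":"ever_birth","option":"yes"}`.
#'
#' @param text JSON string, or a path to a JSON file.
#' @return a validated [form_spec()].
#' @export
parse_form <- function(text) {
  src <- if (length(text) == 1 && file.exists(text)) text
         else paste(text, collapse = "\n")
  js <- jsonlite::fromJSON(src, simplifyVector = FALSE)
  if (is.null(js$questions)) stop("form spec: missing 'questions'")
  qs <- lapply(js$questions, function(q) {
    if (is.null(q$id) || is.null(q$rtype))
      stop("form spec: every question needs 'id' and 'rtype'")
    question(id = q$id, rtype = q$rtype, prompt = q$prompt %||% q$id,
             choices = if (!is.null(q$choices)) unlist(q$choices),
             relevance = q$relevance,
             required = isTRUE(q$required),
             section = q$section %||% "main",
             constraints = q$constraints)
  })
  rules <- lapply(js$rules %||% list(), function(r) {
    if (is.null(r$rule_id) || is.null(r$rule_class))
      stop("form spec: every rule needs 'rule_id' and 'rule_class'")
    relaxed_rule(r$rule_id, r$rule_class, normalize_params(r$params %||% list()))
  })
  meta <- js$meta %||% list()
  form_spec(qs, rules,
            meta = list(record_id = meta$record_id %||% "record_id",
                        enumerator_id = meta$enumerator_id %||% "enumerator_id",
                        survey_date = meta$survey_date %||% "survey_date"),
            title = js$title %||% "form")
}

## jsonlite (simplifyVector = FALSE) leaves scalars as length-1 lists inside
## params; flatten the fields that the rule engine expects as vectors.
normalize_params <- function(p) {
  for (f in c("exclusive", "substantive")) {
    if (!is.null(p[[f]])) p[[f]] <- unlist(p[[f]])
  }
  p
}

#' Serialise a form specification to JSON
#'
#' @param form a [form_spec()].
#' @param path optional file path; when given, writes the JSON there.
#' @return the JSON string, invisibly when `path` is given.
#' @export
write_form <- function(form, path = NULL) {
  qs <- lapply(form$questions, function(q) {
    out <- list(id = q$id, rtype = q$rtype, prompt = q$prompt)
    if (length(q$choices)) out$choices <- as.list(q$choices)
    if (!is.null(q$relevance)) out$relevance <- q$relevance
    if (q$required) out$required <- TRUE
    out$section <- q$section
    if (!is.null(q$constraints)) out$constraints <- q$constraints
    out
  })
  rules <- lapply(form$rules, function(r)
    list(rule_id = r$rule_id, rule_class = r$rule_class, params = r$params))
  js <- jsonlite::toJSON(list(title = form$title, meta = form$meta,
                              questions = qs, rules = rules),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
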