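## Run every relaxed rule over every submission record, producing the
## opportunity/error outcome matrix and aggregate counts.

## Shared per-dataset evaluation context: reached matrix, effective answers,
## metadata vectors. Built once, reused by every rule.
detection_context <- function(form, records) {
  rp <- replay_form(form, records)
  list(reached = rp$reached, answers = rp$answers, raw = records,
       record_id = records[[form$meta$record_id]],
       enumerator_id = records[[form$meta$enumerator_id]],
       survey_date = parse_iso_date(records[[form$meta$survey_date]]))
}

#' Run error detection over a submission dataset
#'
#' Evaluates every relaxed rule declared on the form against every record.
#' The result holds one outcome row per (record, rule) pair where the rule's
#' requisite questions were reached (an *opportunity*), with the error flag,
#' a diagnostic detail string, and — for date-redundancy errors — the tick
#' distance between the two entered dates.
#'
#' @param form a [form_spec()] carrying relaxed rules.
#' @param records validated submissions data.frame (see [read_submissions()]).
#' @return a `vr_detection` object: list with `outcomes` (data.frame:
#'   `record_id`, `enumerator_id`, `survey_date`, `day`, `rule_id`,
#'   `rule_class`, `reached`, `error`, `detail`, `tau`), `totals` (`errors`,
#'   `opportunities`), `by_rule` summary, `diagnostics` (untypeable values
#'   excluded from opportunities), and `day_origin`.
#' @param day_origin optional `Date`; day 0 of the survey window. Defaults to
#'   the earliest survey date present.
#' @export
run_detection <- function(form, records, day_origin = NULL) {
  stopifnot(inherits(form, "vr_form"))
  if (nrow(records) == 0 || length(form$rules) == 0) {
    out <- empty_outcomes()
    return(new_detection(out, NULL, form, day_origin %||% as.Date(NA)))
  }
  records <- validate_records(records, form)
  ctx <- detection_context(form, records)
  origin <- day_origin %||% min(ctx$survey_date)
  day <- as.integer(ctx$survey_date - origin)
  pieces <- lapply(form$rules, function(rule) {
    v <- eval_rule_vec(rule, ctx, form)
    keep <- v$reached
    list(out = data.frame(
           record_id = ctx$record_id[keep],
           enumerator_id = ctx$enumerator_id[keep],
           survey_date = as.character(ctx$survey_date[keep]),
           day = day[keep],
           rule_id = rule$rule_id, rule_class = rule$rule_class,
           reached = TRUE, error = v$error[keep], detail = v$detail[keep],
           tau = v$tau[keep], stringsAsFactors = FALSE),
         diag = v$diagnostics)
  })
  outcomes <- do.call(rbind, lapply(pieces, `[[`, "out"))
  diagnostics <- do.call(rbind, lapply(pieces, `[[`, "diag"))
  new_detection(outcomes, diagnostics, form, origin)
}

empty_outcomes <- function() {
  data.frame(record_id = character(), enumerator_id = character(),
             survey_date = character(), day = integer(), rule_id = character(),
             rule_class = character(), reached = logical(), error = logical(),
             detail = character(), tau = integer(), stringsAsFactors = FALSE)
}

new_detection <- function(outcomes, diagnostics, form, day_origin) {
  rule_ids <- vapply(form$rules, `[[`, "", "rule_id")
  by_rule <- data.frame(
    rule_id = rule_ids,
    rule_class = vapply(form$rules, `[[`, "", "rule_class"),
    errors = vapply(rule_ids, function(r)
      sum(outcomes$error[outcomes$rule_id == r]), 0L, USE.NAMES = FALSE),
    opportunities = vapply(rule_ids, function(r)
      sum(outcomes$rule_id == r), 0L, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  by_rule$rate <- ifelse(by_rule$opportunities > 0,
                         by_rule$errors / by_rule$opportunities, NA_real_)
  structure(list(outcomes = outcomes,
                 totals = list(errors = sum(outcomes$error),
                               opportunities = nrow(outcomes)),
                 by_rule = by_rule,
                 diagnostics = diagnostics,
                 day_origin = day_origin),
            class = "vr_detection")
}

#' @export
print.vr_detection <- function(x, ...) {
  E <- x$totals$errors; N <- x$totals$opportunities
  cat("<vr_detection> ", E, " errors / ", N, " opportunities",
      if (N > 0) sprintf(" (%.2f%%)", 100 * E / N), "\n", sep = "")
  if (!is.null(x$diagnostics) && nrow(x$diagnostics) > 0)
    cat("  ", nrow(x$diagnostics), " value(s) excluded as untypeable\n", sep = "")
  invisible(x)
}

#' Opportunity-denominated error rate
#'
#' The error rate is the number of committed errors divided by the number of
#' opportunities (times the requisite questions were reached). With zero
#' opportunities the rate is undefined and returned as `NA`, never 0.
#'
#' @param E error count.
#' @param N opportunity count.
#' @return proportion in `[0, 1]`, or `NA` when `N` is 0.
#' @export
error_rate <- function(E, N) {
  stopifnot(all(N >= 0), all(E >= 0))
  if (any(E > N)) stop("errors exceed opportunities")
  ifelse(N > 0, E / N, NA_real_)
}

#' Export / re-import detection outcomes
#'
#' Writes the per-(record, rule) outcome table to CSV in a stable column
#' order; `read_outcomes()` restores it with correct column types.
#'
#' @param det a `vr_detection` result (or an outcomes data.frame).
#' @param path CSV file path.
#' @return `write_outcomes()` the path, invisibly; `read_outcomes()` the
#'   outcomes data.frame.
#' @export
write_outcomes <- function(det, path) {
  out <- if (inherits(det, "vr_detection")) det$outcomes else det
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  df$day <- as.integer(df$day)
  df$reached <- df$reached == "TRUE"
  df$error <- df$error == "TRUE"
  df$tau <- suppressWarnings(as.integer(df$tau))
  df
}

#' Tick-distance distribution of date-redundancy errors
#'
#' Summarises how far apart the two entered dates were for every error
#' committed on date-comparator redundancy rules: the share of errors exactly
#' 1 tick off, exactly 2 ticks off, and further.
#'
#' @param det a `vr_detection` result.
#' @param rule_id optionally restrict to one rule.
#' @return data.frame with `tau_class` (`"1"`, `"2"`, `">2"`), `count` and
#'   `share` (proportion of date-redundancy errors).
#' @export
tick_summary <- function(det, rule_id = NULL) {
  out <- det$outcomes
  sel <- out$error & !is.na(out$tau)
  if (!is.null(rule_id)) sel <- sel & out$rule_id == rule_id
  tau <- out$tau[sel]
  cls <- factor(ifelse(tau == 1, "1", ifelse(tau == 2, "2", ">2")),
                levels = c("1", "2", ">2"))
  tab <- table(cls)
  data.frame(tau_class = names(tab), count = as.integer(tab),
             share = if (length(tau)) as.integer(tab) / length(tau) else NA_real_,
             stringsAsFactors = FALSE)
}
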