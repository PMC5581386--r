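## Monitoring report: error rates by rule, enumerator, day and period
## windows, Wilson confidence intervals, and the between-group ANOVA used to
## compare enumerators.

DEFAULT_PERIODS <- list(c(0L, 14L), c(15L, 29L), c(30L, 45L))

period_label <- function(p) paste0("day ", p[1], "-", p[2])

#' Wilson score confidence interval for a proportion
#'
#' Preferred over the Wald interval for the small error counts typical of
#' monitoring cells (a Wald interval at 1/436 is degenerate).
#'
#' @param E number of successes (errors).
#' @param N number of trials (opportunities); `N = 0` yields `NA` bounds.
#' @param level confidence level in (0, 1).
#' @return named numeric vector `c(lower, upper)`, clipped to `[0, 1]`.
#' @export
proportion_ci <- function(E, N, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (N == 0) return(c(lower = NA_real_, upper = NA_real_))
  if (E > N || E < 0) stop("need 0 <= E <= N")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- E / N
  den <- 1 + z^2 / N
  ctr <- (p + z^2 / (2 * N)) / den
  hw <- z * sqrt(p * (1 - p) / N + z^2 / (4 * N^2)) / den
  ## exact at the boundaries (the algebra gives 0/1 there up to rounding)
  c(lower = if (E == 0) 0 else max(0, ctr - hw),
    upper = if (E == N) 1 else min(1, ctr + hw))
}

#' Rate table keyed by rule, enumerator, day or period
#'
#' Aggregates detection outcomes into monitoring cells: error count,
#' opportunity count, rate and Wilson interval per group. Grouping
#' `"enumerator_period"` crosses enumerators with day windows (the layout of
#' the enumerator-monitoring table); `"period"` and `"enumerator"` include an
#' overall row/window.
#'
#' @param det a `vr_detection` result from [run_detection()].
#' @param group_by one of `"rule"`, `"enumerator"`, `"day"`, `"period"`,
#'   `"enumerator_period"`.
#' @param periods list of 2-element day windows; default
#'   `[0,14], [15,29], [30,45]`.
#' @param level confidence level for the Wilson intervals.
#' @return data.frame of cells with key column(s), `errors`, `opportunities`,
#'   `rate`, `lower`, `upper`. Zero-opportunity cells carry `NA` rates.
#' @export
rate_table <- function(det, group_by = c("rule", "enumerator", "day", "period",
                                         "enumerator_period"),
                       periods = DEFAULT_PERIODS, level = 0.95) {
  group_by <- match.arg(group_by)
  out <- det$outcomes
  cell <- function(key, sel) {
    E <- sum(out$error[sel]); N <- sum(sel)
    ci <- proportion_ci(E, N, level)
    cbind(key, data.frame(errors = E, opportunities = N,
                          rate = error_rate(E, N),
                          lower = ci[["lower"]], upper = ci[["upper"]],
                          stringsAsFactors = FALSE))
  }
  if (group_by == "rule") {
    keys <- unique(out$rule_id)
    res <- do.call(rbind, lapply(keys, function(k)
      cell(data.frame(rule_id = k, stringsAsFactors = FALSE), out$rule_id == k)))
  } else if (group_by == "enumerator") {
    keys <- sort(unique(out$enumerator_id))
    res <- do.call(rbind, lapply(keys, function(k)
      cell(data.frame(enumerator_id = k, stringsAsFactors = FALSE),
           out$enumerator_id == k)))
  } else if (group_by == "day") {
    keys <- sort(unique(out$day))
    res <- do.call(rbind, lapply(keys, function(k)
      cell(data.frame(day = k), out$day == k)))
  } else if (group_by == "period") {
    res <- do.call(rbind, lapply(periods, function(p)
      cell(data.frame(period = period_label(p), stringsAsFactors = FALSE),
           out$day >= p[1] & out$day <= p[2])))
    res <- rbind(res, cell(data.frame(period = "overall",
                                      stringsAsFactors = FALSE),
                           rep(TRUE, nrow(out))))
  } else {
    keys <- sort(unique(out$enumerator_id))
    res <- do.call(rbind, lapply(keys, function(k) {
      rows <- lapply(periods, function(p)
        cell(data.frame(enumerator_id = k, period = period_label(p),
                        stringsAsFactors = FALSE),
             out$enumerator_id == k & out$day >= p[1] & out$day <= p[2]))
      rows <- c(rows, list(cell(data.frame(enumerator_id = k,
                                           period = "overall",
                                           stringsAsFactors = FALSE),
                                out$enumerator_id == k)))
      do.call(rbind, rows)
    }))
  }
  rownames(res) <- NULL
  res
}

#' One-way ANOVA on binary error indicators, from group counts
#'
#' Computes the one-way analysis of variance that would be obtained by
#' expanding each group's counts into `N_i` binary observations (`E_i` ones),
#' directly from the counts: with `p_i = E_i/N_i` and pooled `p`,
#' `SSB = sum N_i (p_i - p)^2`, `SSW = sum N_i p_i (1 - p_i)`,
#' `F = (SSB/(k-1)) / (SSW/(N - k))`.
#'
#' @param E integer vector of per-group error counts.
#' @param N integer vector of per-group opportunity counts (all positive).
#' @return object of class `vr_anova`: list with `SSB`, `SSW`, `df_between`,
#'   `df_within`, `F`, `p_value`, `groups`.
#' @export
anova_between_groups <- function(E, N) {
  stopifnot(length(E) == length(N), length(E) >= 2)
  if (any(N <= 0)) stop("all group opportunity counts must be positive")
  if (any(E < 0 | E > N)) stop("need 0 <= E_i <= N_i")
  k <- length(E); n <- sum(N)
  p_i <- E / N; p_bar <- sum(E) / n
  SSB <- sum(N * (p_i - p_bar)^2)
  SSW <- sum(N * p_i * (1 - p_i))
  df_b <- k - 1; df_w <- n - k
  Fst <- if (SSW == 0) {
    if (SSB == 0) 0 else Inf
  } else (SSB / df_b) / (SSW / df_w)
  p <- if (is.infinite(Fst)) 0 else stats::pf(Fst, df_b, df_w, lower.tail = FALSE)
  structure(list(SSB = SSB, SSW = SSW, df_between = df_b, df_within = df_w,
                 F = Fst, p_value = p, groups = k),
            class = "vr_anova")
}

#' @export
print.vr_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on binary outcomes: F(%d, %d) = %.4f, P = %.3g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

## ---- rendering --------------------------------------------------------------

## Rate formatting follows the monitoring-report convention: one decimal for
## per-rule / per-enumerator cells, two decimals for the overall rate, and an
## em dash for cells with no opportunities (0/0 is not a zero rate).
format_rate <- function(E, N, digits = 1) {
  ifelse(N == 0, "—", sprintf(paste0("%.", digits, "f"), 100 * E / N))
}

#' Render the monitoring report as markdown
#'
#' Human-readable summary: per-rule error rates, the enumerator-by-period
#' table with the between-enumerator ANOVA P value per period column, and the
#' tick-distance breakdown for date-redundancy rules.
#'
#' @param det a `vr_detection` result.
#' @param periods day windows, as in [rate_table()].
#' @return character vector of markdown lines.
#' @export
render_report <- function(det, periods = DEFAULT_PERIODS) {
  E <- det$totals$errors; N <- det$totals$opportunities
  lines <- c("# Error monitoring report", "",
             sprintf("Overall error rate: **%s%%** (%d/%d)",
                     format_rate(E, N, 2), E, N), "")
  br <- det$by_rule
  lines <- c(lines, "## Error rate by rule", "",
             "| Rule | Class | Errors | Rate, % |",
             "| --- | --- | --- | --- |",
             sprintf("| %s | %s | %d/%d | %s |", br$rule_id, br$rule_class,
                     br$errors, br$opportunities,
                     format_rate(br$errors, br$opportunities)), "")
  ep <- rate_table(det, "enumerator_period", periods)
  if (nrow(ep)) {
    plabs <- c(vapply(periods, period_label, ""), "overall")
    enums <- unique(ep$enumerator_id)
    hdr <- paste0("| Enumerator | ",
                  paste(sub("^day", "Rate, % (day", paste0(plabs, ")")),
                        collapse = " | "), " |")
    rows <- vapply(enums, function(e) {
      sub <- ep[ep$enumerator_id == e, ]
      cells <- vapply(plabs, function(pl) {
        r <- sub[sub$period == pl, ]
        sprintf("%s (%d/%d)",
                format_rate(r$errors, r$opportunities,
                            if (pl == "overall") 2 else 1),
                r$errors, r$opportunities)
      }, "")
      paste0("| ", e, " | ", paste(cells, collapse = " | "), " |")
    }, "")
    pvals <- vapply(plabs, function(pl) {
      sub <- ep[ep$period == pl & ep$opportunities > 0, ]
      if (nrow(sub) < 2) return("—")
      sprintf("%.2f", anova_between_groups(sub$errors, sub$opportunities)$p_value)
    }, "")
    lines <- c(lines, "## Error rate by enumerator and period", "", hdr,
               paste0("| --- |", paste(rep(" --- |", length(plabs)), collapse = "")),
               rows,
               paste0("| ANOVA P | ", paste(pvals, collapse = " | "), " |"), "")
  }
  ts <- tick_summary(det)
  if (sum(ts$count) > 0)
    lines <- c(lines, "## Date-redundancy tick distances", "",
               sprintf("- %s tick(s) off: %d (%.0f%%)", ts$tau_class, ts$count,
                       100 * ts$share), "")
  lines
}
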