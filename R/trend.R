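## Error-rate trends over the survey window: logistic regression of the
## binary error indicator on survey day with a cluster-robust sandwich
## variance, predicted/extrapolated rates, aggregated linear sensitivity
## fits, and the between-enumerator dispersion trend.

#' Build trend-regression observations from a detection result
#'
#' The default observation unit is one binary observation per (record x
#' reached rule) — i.e. per opportunity, matching the error-rate denominator.
#' The alternative `"record"` unit collapses to one observation per record
#' (error = any rule error). The cluster variable defaults to the enumerator.
#'
#' @param det a `vr_detection` result.
#' @param unit `"opportunity"` or `"record"`.
#' @param cluster `"enumerator"` or `"record"`.
#' @return data.frame with columns `error` (0/1), `day`, `cluster`.
#' @export
trend_observations <- function(det, unit = c("opportunity", "record"),
                               cluster = c("enumerator", "record")) {
  unit <- match.arg(unit); cluster <- match.arg(cluster)
  out <- det$outcomes
  if (unit == "record") {
    agg <- stats::aggregate(error ~ record_id + enumerator_id + day,
                            data = out, FUN = any)
    out <- agg
  }
  data.frame(error = as.integer(out$error), day = out$day,
             cluster = if (cluster == "enumerator") out$enumerator_id
                       else out$record_id,
             stringsAsFactors = FALSE)
}

#' Logistic trend of the error odds over survey time
#'
#' Fits `error ~ day` by maximum likelihood (no covariates) and estimates the
#' variance with the clustered sandwich `A^-1 B A^-1`, where `A` is the
#' observed information and `B` sums outer products of within-cluster score
#' sums, scaled by the small-sample factor `G/(G-1)`. With a single cluster
#' the fit falls back to the independence (heteroskedasticity-robust)
#' sandwich with a warning.
#'
#' @param obs data.frame with columns `error` (0/1), `day`, `cluster` (see
#'   [trend_observations()]).
#' @return a `vr_trend` object: coefficients `beta0`, `beta1`, odds ratio per
#'   day `or` with confidence interval, cluster-robust `vcov`, `n`, `G`.
#' @param level confidence level for the OR interval.
#' @export
fit_logistic_trend <- function(obs, level = 0.95) {
  stopifnot(all(c("error", "day", "cluster") %in% names(obs)))
  if (length(unique(obs$day)) < 2) stop("need at least 2 distinct days")
  if (length(unique(obs$error)) < 2) stop("need both error outcomes present")
  fit <- stats::glm(error ~ day, family = stats::binomial(), data = obs,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  beta <- stats::coef(fit)
  if (!fit$converged || any(abs(beta) > 30))
    stop("logistic trend did not converge (possible complete separation)")
  X <- stats::model.matrix(fit)
  p <- stats::fitted(fit)
  ## inverse observed information (= expected, for the canonical logit link)
  bread <- stats::vcov(fit)
  cl <- as.character(obs$cluster)
  G <- length(unique(cl))
  scores <- X * (obs$error - p)
  if (G < 2) {
    warning("single cluster: falling back to the independence sandwich")
    cl <- as.character(seq_len(nrow(X)))
    G <- nrow(X)
  }
  Sg <- rowsum(scores, cl)
  B <- crossprod(Sg) * G / (G - 1)
  V <- bread %*% B %*% bread
  dimnames(V) <- list(names(beta), names(beta))
  z <- stats::qnorm(1 - (1 - level) / 2)
  se1 <- sqrt(max(V[2, 2], 0))   # degenerate fits can leave -1e-18 dust
  structure(list(beta0 = unname(beta[1]), beta1 = unname(beta[2]),
                 or = exp(unname(beta[2])),
                 or_ci = exp(unname(beta[2]) + c(-1, 1) * z * se1),
                 vcov = V, n = nrow(obs), G = G, level = level,
                 p_value = if (se1 > 0) 2 * stats::pnorm(-abs(beta[2] / se1))
                           else NA_real_,
                 converged = TRUE),
            class = "vr_trend")
}

#' @export
print.vr_trend <- function(x, ...) {
  cat(sprintf(
    "<vr_trend> OR per day = %.4f (%d%% CI %.4f-%.4f), n = %d, clusters = %d\n",
    x$or, round(100 * x$level), x$or_ci[1], x$or_ci[2], x$n, x$G))
  invisible(x)
}

#' Predicted error rate at a given survey day
#'
#' `p(t) = invlogit(beta0 + beta1 t)`, with a confidence interval from the
#' delta method on the logit scale (then transformed), using the fit's
#' cluster-robust covariance.
#'
#' @param fit a `vr_trend` from [fit_logistic_trend()].
#' @param t survey day (vectorized).
#' @param level confidence level.
#' @return data.frame with `day`, `rate`, `lower`, `upper`.
#' @export
predict_rate <- function(fit, t, level = 0.95) {
  eta <- fit$beta0 + fit$beta1 * t
  ## quadratic form in a PSD matrix; clamp rounding dust at 0
  v <- pmax(0, fit$vcov[1, 1] + 2 * t * fit$vcov[1, 2] + t^2 * fit$vcov[2, 2])
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(day = t, rate = invlogit(eta),
             lower = invlogit(eta - z * se), upper = invlogit(eta + z * se))
}

#' Extrapolate an error rate along a per-day odds ratio
#'
#' Closed-form trend extrapolation on the log-odds scale:
#' `invlogit(logit(p0) + t * log(or_per_day))`. Equivalent to
#' [predict_rate()] at the fitted coefficients.
#'
#' @param p0 rate at day 0, strictly inside (0, 1).
#' @param or_per_day multiplicative change in odds per day (> 0).
#' @param t days elapsed (vectorized).
#' @return extrapolated rate(s).
#' @examples
#' extrapolate_rate(0.023, 0.969, 45)  # ~0.0057
#' @export
extrapolate_rate <- function(p0, or_per_day, t) {
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must be strictly inside (0, 1)")
  if (any(or_per_day <= 0)) stop("or_per_day must be positive")
  invlogit(logit(p0) + t * log(or_per_day))
}

#' Aggregate outcomes to enumerator-day (or day) rate observations
#'
#' @param det a `vr_detection` result.
#' @param by `"enumerator_day"` (one observation per enumerator per day) or
#'   `"day"` (one per day).
#' @return data.frame with `day`, optional `enumerator_id`, `errors`,
#'   `opportunities`, `rate`.
#' @export
aggregate_daily <- function(det, by = c("enumerator_day", "day")) {
  by <- match.arg(by)
  out <- det$outcomes
  f <- if (by == "enumerator_day") list(enumerator_id = out$enumerator_id,
                                        day = out$day)
       else list(day = out$day)
  E <- stats::aggregate(as.integer(out$error), f, sum)
  N <- stats::aggregate(rep(1L, nrow(out)), f, sum)
  res <- E
  names(res)[ncol(res)] <- "errors"
  res$opportunities <- N$x
  res$rate <- res$errors / res$opportunities
  res[order(res$day), , drop = FALSE]
}

#' Linear trend of aggregated daily error rates
#'
#' Sensitivity analysis on collapsed data: ordinary least squares of the
#' aggregated rate on survey day, with a t-based confidence interval for the
#' slope.
#'
#' @param cells data.frame with columns `day` and `rate` (e.g. from
#'   [aggregate_daily()]).
#' @param level confidence level.
#' @return a `vr_lintrend` list: `slope`, `intercept`, `slope_ci`, `n`,
#'   `p_value`, and `predict(t)` helper values via [stats::lm()].
#' @export
fit_linear_aggregated <- function(cells, level = 0.95) {
  stopifnot(all(c("day", "rate") %in% names(cells)))
  if (nrow(cells) < 3) stop("need at least 3 aggregated observations")
  if (length(unique(cells$day)) < 2) stop("day is constant")
  fit <- stats::lm(rate ~ day, data = cells)
  ci <- stats::confint(fit, "day", level = level)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_ci = c(ci[1], ci[2]), n = nrow(cells),
                 p_value = sm$coefficients["day", "Pr(>|t|)"],
                 lm = fit),
            class = "vr_lintrend")
}

#' @export
print.vr_lintrend <- function(x, ...) {
  cat(sprintf("<vr_lintrend> slope = %.6f per day (CI %.6f to %.6f), n = %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$n))
  invisible(x)
}

#' Trend in the between-enumerator dispersion of daily error rates
#'
#' For each survey day, the sample standard deviation of enumerator-specific
#' error rates; then an OLS slope of that dispersion on day. Days with fewer
#' than two enumerators are excluded with a warning.
#'
#' @param cells enumerator-day rate observations (from
#'   [aggregate_daily()] with `by = "enumerator_day"`).
#' @return list with `series` (data.frame `day`, `sd`, `n_enumerators`),
#'   `slope`, `intercept`.
#' @export
daily_sd_trend <- function(cells) {
  stopifnot(all(c("day", "enumerator_id", "rate") %in% names(cells)))
  sds <- stats::aggregate(rate ~ day, data = cells,
                          FUN = function(r) c(sd = stats::sd(r), n = length(r)))
  series <- data.frame(day = sds$day, sd = sds$rate[, "sd"],
                       n_enumerators = sds$rate[, "n"])
  drop <- series$n_enumerators < 2
  if (any(drop)) {
    warning(sum(drop), " day(s) with < 2 enumerators excluded")
    series <- series[!drop, , drop = FALSE]
  }
  if (nrow(series) < 2) stop("fewer than 2 usable days")
  fit <- stats::lm(sd ~ day, data = series)
  list(series = series, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
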