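saturated_obs <- function(n0, e0, n1, e1) {
  data.frame(error = c(rep(1, e0), rep(0, n0 - e0), rep(1, e1), rep(0, n1 - e1)),
             day = rep(c(0, 1), c(n0, n1)),
             cluster = rep(c("a", "b", "c", "d"), length.out = n0 + n1))
}

test_that("two-day saturated data recovers the closed-form odds ratio", {
  obs <- saturated_obs(100, 10, 100, 5)
  fit <- fit_logistic_trend(obs)
  expect_equal(fit$beta0, logit(0.10), tolerance = 1e-6)
  expect_equal(fit$beta1, logit(0.05) - logit(0.10), tolerance = 1e-6)
  expect_equal(fit$or, (5 / 95) / (10 / 90), tolerance = 1e-6)
})

test_that("flat rates give OR = 1", {
  obs <- saturated_obs(60, 6, 60, 6)
  obs$day <- rep(c(0, 7), c(60, 60))
  fit <- fit_logistic_trend(obs)
  expect_equal(fit$or, 1, tolerance = 1e-8)
})

test_that("coefficients match a brute-force likelihood maximiser on small data", {
  set.seed(3)
  obs <- data.frame(day = sample(0:9, 40, replace = TRUE),
                    cluster = sample(letters[1:5], 40, replace = TRUE))
  obs$error <- rbinom(40, 1, invlogit(-1 + 0.15 * obs$day))
  fit <- fit_logistic_trend(obs)
  b <- newton_logistic(obs$day, obs$error)
  expect_equal(fit$beta0, b[1], tolerance = 1e-6)
  expect_equal(fit$beta1, b[2], tolerance = 1e-6)
})

test_that("complete separation is reported, not silently fitted", {
  obs <- data.frame(error = rep(c(0, 1), each = 20),
                    day = rep(c(0, 1), each = 20),
                    cluster = rep(c("a", "b"), 20))
  suppressWarnings(   # glm itself warns about fitted 0/1 probabilities
    expect_error(fit_logistic_trend(obs), "converge|separation"))
})

test_that("cluster sandwich matches the sandwich-package oracle", {
  skip_if_not_installed("sandwich")
  set.seed(8)
  obs <- data.frame(day = sample(0:20, 400, replace = TRUE),
                    cluster = sample(sprintf("c%02d", 1:12), 400, replace = TRUE))
  obs$error <- rbinom(400, 1, invlogit(-2 + 0.05 * obs$day))
  fit <- fit_logistic_trend(obs)
  g <- stats::glm(error ~ day, binomial(), data = obs,
                  control = stats::glm.control(epsilon = 1e-10))
  V <- sandwich::vcovCL(g, cluster = obs$cluster, type = "HC0",
                        cadjust = TRUE, fix = FALSE)
  ## same sandwich up to the finite-sample convention: vcovCL's HC0 cadjust
  ## multiplies by G/(G-1) as well
  expect_equal(unname(fit$vcov), unname(as.matrix(V)), tolerance = 1e-6)
})

test_that("singleton clusters collapse to the HC sandwich", {
  skip_if_not_installed("sandwich")
  set.seed(9)
  obs <- data.frame(day = sample(0:15, 150, replace = TRUE))
  obs$error <- rbinom(150, 1, invlogit(-1.5 + 0.05 * obs$day))
  obs$cluster <- sprintf("s%03d", seq_len(nrow(obs)))
  fit <- fit_logistic_trend(obs)
  g <- stats::glm(error ~ day, binomial(), data = obs,
                  control = stats::glm.control(epsilon = 1e-10))
  ## 1e-4: estfun evaluates IRLS working weights one step stale,
  ## so the two scores agree only to the glm stopping precision
  hc0 <- sandwich::vcovHC(g, type = "HC0")
  n <- nrow(obs)
  expect_equal(unname(fit$vcov), unname(as.matrix(hc0)) * n / (n - 1),
               tolerance = 1e-4)
})

test_that("predicted rates equal closed-form extrapolation and are monotone", {
  obs <- saturated_obs(120, 12, 120, 7)
  fit <- fit_logistic_trend(obs)
  t <- c(0, 5.5, 45)
  pr <- predict_rate(fit, t)
  expect_equal(pr$rate, extrapolate_rate(invlogit(fit$beta0), fit$or, t),
               tolerance = 1e-12)
  ## OR < 1 means strictly decreasing predicted rates
  expect_true(fit$or < 1)
  grid <- predict_rate(fit, 0:45)$rate
  expect_true(all(diff(grid) < 0))
  expect_error(extrapolate_rate(0, 0.97, 3), "inside")
  expect_equal(extrapolate_rate(0.37, 1, 999), 0.37)
})

test_that("delta-method CI matches Monte-Carlo propagation of the fit", {
  obs <- simulate_trend_obs(4000, seed = 77)
  fit <- fit_logistic_trend(obs)
  pr <- predict_rate(fit, c(0, 45))
  set.seed(101)
  L <- chol(fit$vcov)
  draws <- matrix(rnorm(2 * 1e5), ncol = 2) %*% L
  for (i in 1:2) {
    t <- pr$day[i]
    eta <- (fit$beta0 + draws[, 1]) + (fit$beta1 + draws[, 2]) * t
    q <- invlogit(stats::quantile(eta, c(0.025, 0.975), names = FALSE))
    expect_lt(abs(pr$lower[i] - q[1]), 1e-3)
    expect_lt(abs(pr$upper[i] - q[2]), 1e-3)
  }
})

test_that("aggregated linear fit matches the normal equations and symmetry", {
  ## perfectly linear rates are recovered exactly
  cells <- data.frame(day = 0:10, rate = 0.05 - 0.002 * (0:10))
  fit <- suppressWarnings(fit_linear_aggregated(cells))  # exact fit warning
  expect_equal(fit$slope, -0.002, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.05, tolerance = 1e-12)
  ## noisy rates: direct algebra oracle
  set.seed(15)
  cells <- data.frame(day = rep(0:20, each = 3),
                      rate = pmax(0, 0.04 - 0.001 * rep(0:20, each = 3) +
                                    rnorm(63, 0, 0.01)))
  fit <- fit_linear_aggregated(cells)
  X <- cbind(1, cells$day)
  beta <- solve(t(X) %*% X, t(X) %*% cells$rate)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  ## reversing the day axis negates the slope
  rev_cells <- cells
  rev_cells$day <- max(cells$day) - cells$day
  expect_equal(fit_linear_aggregated(rev_cells)$slope, -fit$slope,
               tolerance = 1e-10)
  expect_true(fit$slope_ci[1] <= fit$slope & fit$slope <= fit$slope_ci[2])
  expect_error(fit_linear_aggregated(data.frame(day = c(1, 1, 1),
                                                rate = c(0.1, 0.2, 0.3))),
               "constant")
})

test_that("daily dispersion series and its trend match direct computation", {
  ## identical enumerator rates: zero dispersion everywhere, zero slope
  flat <- expand.grid(enumerator_id = c("a", "b", "c"), day = 0:5)
  flat$rate <- 0.02
  ds <- daily_sd_trend(flat)
  expect_true(all(ds$series$sd == 0))
  expect_equal(ds$slope, 0)
  ## two enumerators: sd = |p - q| / sqrt(2)
  two <- data.frame(enumerator_id = c("a", "b", "a", "b"),
                    day = c(0, 0, 1, 1), rate = c(0.10, 0.04, 0.20, 0.30))
  ds <- daily_sd_trend(two)
  expect_equal(ds$series$sd, c(abs(0.10 - 0.04), abs(0.20 - 0.30)) / sqrt(2))
  ## random panel vs oracle OLS on independently computed SDs
  set.seed(16)
  panel <- expand.grid(enumerator_id = letters[1:5], day = 0:12)
  panel$rate <- runif(nrow(panel), 0, 0.1)
  ds <- daily_sd_trend(panel)
  sds <- tapply(panel$rate, panel$day, sd)
  oracle <- stats::lm(as.numeric(sds) ~ as.numeric(names(sds)))
  expect_equal(ds$slope, unname(coef(oracle)[2]), tolerance = 1e-12)
  ## days with a single enumerator are dropped with a warning
  panel2 <- rbind(panel, data.frame(enumerator_id = "z", day = 99, rate = 0.5))
  expect_warning(ds2 <- daily_sd_trend(panel2), "excluded")
  expect_false(99 %in% ds2$series$day)
})

test_that("trend observations can collapse to one row per record", {
  det <- run_detection(demo_form_template(), {
    r <- demo_records(25, seed = 30)
    r$num_births_2[r$ever_birth == "yes"][1] <- "42"
    r
  })
  opp <- trend_observations(det, "opportunity")
  rec <- trend_observations(det, "record")
  expect_equal(nrow(opp), det$totals$opportunities)
  expect_equal(nrow(rec), 25)
  expect_equal(sum(rec$error), 1)
})
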