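# Kaplan-Meier estimation and censored Weibull AFT regression: exact small
# cases, oracle equivalence, parameter recovery and the hazard-ratio map.

make_sample <- function(times, events) {
  structure(list(times = times, events = as.integer(events),
                 design_matrix = matrix(numeric(0), length(times), 0),
                 referent = c(chemical = "acetone", photoperiod = "short_day")),
            class = "survival_sample")
}

test_that("KM equals the empirical survivor function on complete data", {
  km <- km_fit(make_sample(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(attr(km, "median"), 2)

  set.seed(91)
  tt <- rexp(60, 1 / 10)
  km2 <- km_fit(make_sample(tt, rep(1, 60)))
  emp <- vapply(km2$time, function(t) mean(tt > t), 0)
  expect_equal(km2$survival, emp)
})

test_that("an all-censored group yields survival 1 and an undefined median", {
  km <- km_fit(make_sample(5, 0))
  expect_equal(nrow(km), 0)
  expect_true(is.na(attr(km, "median")))
})

test_that("KM median recovers the generating Weibull median", {
  set.seed(92)
  mu <- log(39); sigma <- 0.45
  tt <- rweibull(200, shape = 1 / sigma, scale = exp(mu))
  km <- km_fit(make_sample(tt, rep(1, 200)))
  med_true <- exp(mu) * log(2)^sigma
  se_med <- 0.5 / (dweibull(med_true, 1 / sigma, exp(mu)) * sqrt(200))
  expect_equal(attr(km, "median"), med_true, tolerance = 3 * se_med / med_true)
  ci <- attr(km, "median_ci")
  expect_true(ci[1] <= attr(km, "median") && attr(km, "median") <= ci[2])
})

test_that("the AFT MLE matches brute-force likelihood maximization", {
  for (seed in c(101, 102, 103)) {
    set.seed(seed)
    n <- 25 + (seed %% 3) * 2
    x1 <- rbinom(n, 1, 0.5)
    x2 <- rbinom(n, 1, 0.4)
    lp <- 3 + 0.6 * x1 - 0.8 * x2
    tt <- rweibull(n, shape = 1 / 0.6, scale = exp(lp))
    horizon <- quantile(tt, 0.8)
    ev <- as.integer(tt <= horizon)
    tt <- pmin(tt, horizon)
    sm <- structure(list(times = tt, events = ev,
                         design_matrix = cbind(a = x1, b = x2),
                         referent = c(g = "ref")),
                    class = "survival_sample")
    fit <- fit_weibull_aft(sm)
    X <- cbind(1, x1, x2)
    par <- oracle_aft_fit(tt, ev, X)
    expect_equal(unname(fit$coefficients), par[1:3], tolerance = 1e-4)
    expect_equal(fit$log_scale, par[4], tolerance = 1e-4)
    expect_equal(fit$loglik,
                 -oracle_aft_nll(c(fit$coefficients, fit$log_scale), tt, ev, X),
                 tolerance = 1e-8)
    expect_gte(fit$loglik, fit$null_loglik)
    # vcov is symmetric positive semi-definite
    expect_equal(fit$vcov, t(fit$vcov))
    expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > -1e-10))
  }
})

test_that("refitting preset data recovers the generating AFT parameters", {
  d <- study_design(containers_per_cell = 17L)  # ~2040 females
  pre <- rearing_preset("september")
  s <- generate_survival(d, pre, seed = 111)
  fit <- fit_weibull_aft(survival_sample(s))
  truth <- c("(Intercept)" = pre$aft_intercept, pre$aft_coeffs)
  for (nm in names(truth)) {
    expect_lt(abs(fit$coefficients[[nm]] - truth[[nm]]), 3 * fit$se[[nm]])
  }
  expect_lt(abs(fit$log_scale - pre$aft_log_scale), 3 * fit$se[["log_scale"]])
})

test_that("a covariate-free fit equals its null and the LRT is zero", {
  set.seed(121)
  tt <- rweibull(40, 2, 10)
  fit <- fit_weibull_aft(make_sample(tt, rep(1, 40)))
  lrt <- aft_lrt(fit)
  expect_equal(lrt$chi2, 0, tolerance = 1e-6)
  expect_equal(lrt$df, 0)
  expect_equal(lrt$p, 1)
})

test_that("the LRT matches the chi-square tail", {
  # the reported model-fit statistic is far in the tail
  expect_lt(pchisq(162.6, df = 3, lower.tail = FALSE), 1e-4)
  expect_lt(pchisq(29.98, df = 3, lower.tail = FALSE), 1e-4)
})

test_that("hazard ratios invert the AFT coefficients", {
  expect_equal(hazard_ratio(0, -0.5), 1)
  # hr(beta) * hr(-beta) = 1 at fixed sigma
  for (b in c(-1, -0.3, 0.2, 0.9)) {
    expect_equal(hazard_ratio(b, -0.815) * hazard_ratio(-b, -0.815), 1)
  }
  # a fitted table brackets each ratio with a finite interval
  d <- study_design(containers_per_cell = 8L)
  s <- generate_survival(d, rearing_preset("september"), seed = 131)
  fit <- fit_weibull_aft(survival_sample(s))
  hr <- hazard_ratios(fit)
  expect_true(all(hr$lo <= hr$hr & hr$hr <= hr$hi))
  expect_true(all(hr$hr > 0 & is.finite(hr$hi)))
  expect_identical(attr(hr, "referent"),
                   c(chemical = "acetone", photoperiod = "short_day"))
})

test_that("degenerate designs are refused with informative errors", {
  set.seed(141)
  tt <- rweibull(20, 2, 10)
  x <- rbinom(20, 1, 0.5)
  sm <- structure(list(times = tt, events = rep(1L, 20),
                       design_matrix = cbind(a = x, b = x),
                       referent = c(g = "ref")),
                  class = "survival_sample")
  expect_error(fit_weibull_aft(sm), "aliased")
  sm2 <- structure(list(times = tt, events = as.integer(x == 0),
                        design_matrix = cbind(a = x),
                        referent = c(g = "ref")),
                   class = "survival_sample")
  expect_error(fit_weibull_aft(sm2), "no events")
})
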