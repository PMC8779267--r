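# Negative-binomial egg-production models: exact cases, brute-force oracle
# equivalence, the hurdle decomposition, F-test calibration and power.

two_group_sample <- function(y, x, cells = NULL) {
  structure(list(counts = y, design_matrix = cbind(g = x),
                 referent = c(g = "ref"),
                 cells = cells %||% paste0("c", x, ":p", x)),
            class = "count_sample")
}

intercept_sample <- function(y) {
  structure(list(counts = y, design_matrix = matrix(numeric(0), length(y), 0),
                 referent = c(g = "ref"), cells = rep("a:b", length(y))),
            class = "count_sample")
}

test_that("the intercept-only NB MLE is the log sample mean", {
  fit <- fit_nb_glm(intercept_sample(c(10L, 20L, 30L, 40L)))
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), log(25),
               tolerance = 1e-6)
})

test_that("the NB MLE matches brute-force likelihood maximization", {
  set.seed(201)
  y <- rnbinom(12, size = 4, mu = exp(3 + 0.8 * rep(c(0, 1), each = 6)))
  x <- rep(c(0, 1), each = 6)
  fit <- fit_nb_glm(two_group_sample(y, x))
  par <- oracle_nb_fit(y, cbind(1, x))
  expect_equal(unname(fit$coefficients), par[1:2], tolerance = 1e-4)
  expect_equal(log(fit$theta), par[3], tolerance = 1e-4)
  # response-scale ratio between cells is exp of the coefficient
  expect_equal(exp(sum(fit$coefficients)) / exp(fit$coefficients[[1]]),
               exp(fit$coefficients[["g"]]))
})

test_that("NB log-likelihood dominates the Poisson fit (theta boundary)", {
  set.seed(202)
  for (i in 1:5) {
    y <- rnbinom(16, size = 2, mu = 50)
    fit <- suppressWarnings(fit_nb_glm(intercept_sample(y)))
    ll_pois <- sum(dpois(y, mean(y), log = TRUE))
    expect_gte(fit$loglik + 1e-8, ll_pois)
  }
})

test_that("an all-zero cell raises the documented under-dispersion error", {
  d <- study_design(containers_per_cell = 4L)
  con <- generate_fecundity(d, rearing_preset("september"), seed = 211)
  cs <- count_sample(con)
  expect_error(fit_nb_glm(cs), class = "parayield_underdispersion_error")
  expect_error(fit_nb_glm(cs), "hurdle")
  # the hurdle model handles the same data
  h <- fit_hurdle_nb(cs)
  expect_s3_class(h, "hurdle_fit")
  expect_true(h$zero$penalized)  # all-zero vs all-positive cells separate
})

test_that("the hurdle model decomposes into its two likelihood factors", {
  set.seed(221)
  y <- ifelse(runif(40) < 0.45, 0L, as.integer(rnbinom(40, size = 5, mu = 60) + 1L))
  cs <- intercept_sample(y)
  h <- fit_hurdle_nb(cs)
  expect_equal(h$loglik, h$zero$loglik + h$count$loglik)
  expect_false(h$zero$penalized)
  expect_equal(unname(h$zero$coefficients[["(Intercept)"]]),
               qlogis(mean(y > 0)), tolerance = 1e-6)
})

test_that("the zero-truncated NB count part matches its oracle", {
  set.seed(222)
  # small-sample fit equivalence
  p0 <- pnbinom(0, size = 3, mu = 20)
  y <- as.integer(qnbinom(runif(25, p0, 1), size = 3, mu = 20))
  tf <- parayield:::fit_truncated_nb(y, matrix(numeric(0), 25, 0))
  par <- oracle_tnb_fit(y, matrix(1, 25, 1))
  expect_equal(unname(tf$coefficients[[1]]), par[1], tolerance = 1e-4)
  expect_equal(unname(tf$log_theta), par[2], tolerance = 1e-3)

  # large-sample mean recovery against the truncated-mean formula
  mu <- 176; theta <- 25; n <- 10000
  p0 <- pnbinom(0, size = theta, mu = mu)
  y2 <- as.integer(qnbinom(runif(n, p0, 1), size = theta, mu = mu))
  tf2 <- parayield:::fit_truncated_nb(y2, matrix(numeric(0), n, 0))
  m_hat <- parayield:::truncated_nb_mean(exp(tf2$coefficients[[1]]), tf2$theta)
  m_true <- oracle_tnb_mean(mu, theta)
  se <- sd(y2) / sqrt(n)
  expect_equal(unname(m_hat), m_true, tolerance = 3 * se / m_true)
})

test_that("term F tests are calibrated under the null", {
  set.seed(231)
  n_sim <- 1000
  rej <- 0; done <- 0
  for (i in seq_len(n_sim)) {
    y <- rnbinom(20, size = 25, mu = 100)
    f <- tryCatch(suppressWarnings(fit_nb_glm(
      two_group_sample(y, rep(c(0, 1), each = 10)))),
      error = function(e) NULL)
    if (is.null(f)) next
    done <- done + 1
    if (term_f_tests(f, terms = list(g = "g"))$p[1] <= 0.05) rej <- rej + 1
  }
  expect_gt(done, 0.99 * n_sim)
  expect_gt(rej / done, 0.03)
  expect_lt(rej / done, 0.07)
})

test_that("a term with no columns gives F = 0", {
  fit <- suppressWarnings(fit_nb_glm(two_group_sample(
    rnbinom(12, size = 25, mu = 80), rep(c(0, 1), each = 6))))
  ft <- term_f_tests(fit, terms = list(nothing = character()))
  expect_equal(ft$F, 0)
  expect_equal(ft$p, 1)
})

test_that("photoperiod and chemical are detected at the preset effect sizes", {
  d <- study_design(containers_per_cell = 4L)
  pre <- rearing_preset("september")
  hits <- 0
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    con <- generate_fecundity(d, pre, seed = 4000 + i)
    cs <- count_sample(con, drop_cells = "acetone:short_day")
    fit <- tryCatch(suppressWarnings(fit_nb_glm(cs)), error = function(e) NULL)
    if (is.null(fit)) next
    ft <- term_f_tests(fit)
    if (all(ft$p <= 0.01)) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_rep)
})

test_that("refitting preset data recovers the egg-model intercept", {
  # mean of intercept estimates over many replicate experiments
  d <- study_design(containers_per_cell = 4L)
  pre <- rearing_preset("september")
  ints <- vapply(seq_len(500), function(i) {
    con <- generate_fecundity(d, pre, seed = 6000 + i)
    cs <- count_sample(con, drop_cells = "acetone:short_day")
    fit <- tryCatch(suppressWarnings(fit_nb_glm(cs)), error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$coefficients[["(Intercept)"]]
  }, 0)
  expect_lt(abs(mean(ints, na.rm = TRUE) - pre$egg_log_mean_intercept), 0.05)
})
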