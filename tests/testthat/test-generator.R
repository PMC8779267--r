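# Synthetic-data generator: determinism, closed-form agreement with the
# generating distributions, structural invariants and CSV round-trips.

test_that("identical (design, params, seed) triples give identical tables", {
  d <- study_design(containers_per_cell = 2L, followup_days = 30L)
  p <- rearing_preset("september")
  expect_identical(generate_survival(d, p, seed = 7),
                   generate_survival(d, p, seed = 7))
  expect_identical(generate_fecundity(d, p, seed = 7),
                   generate_fecundity(d, p, seed = 7))
  expect_identical(generate_clutch_outcomes(d, p, seed = 7),
                   generate_clutch_outcomes(d, p, seed = 7))
  a <- generate_survival(d, p, seed = 7)
  b <- generate_survival(d, p, seed = 8)
  expect_false(identical(a$time_days, b$time_days))
})

test_that("death times follow the Weibull AFT surface", {
  # sigma = 1 reduces to an exponential: median = scale * ln 2
  n <- 10000L
  d <- single_cell_design(n)
  p <- flat_params(aft_intercept = log(20), aft_log_scale = 0)
  s <- generate_survival(d, p, seed = 31)
  se_med <- 0.5 / (dexp(20 * log(2), 1 / 20) * sqrt(n))
  expect_equal(median(s$time_days), 20 * log(2), tolerance = 3 * se_med / (20 * log(2)))
  expect_true(all(s$event == 1))  # horizon far beyond the distribution

  # September referent cell (short-day + acetone): median exp(mu) ln2^sigma
  d2 <- study_design(containers_per_cell = 125L, followup_days = 120L)
  pre <- rearing_preset("september")
  s2 <- generate_survival(d2, pre, seed = 32)
  ref <- s2[s2$chemical == "acetone" & s2$photoperiod == "short_day" &
              s2$sex == "f", ]
  sigma <- exp(pre$aft_log_scale)
  med_true <- exp(pre$aft_intercept) * log(2)^sigma
  f_med <- dweibull(med_true, shape = 1 / sigma, scale = exp(pre$aft_intercept))
  se_med <- 0.5 / (f_med * sqrt(nrow(ref)))
  expect_equal(median(ref$time_days), med_true, tolerance = 3 * se_med / med_true)

  # censoring is applied at the follow-up horizon
  d3 <- study_design(containers_per_cell = 10L, followup_days = 40L)
  s3 <- generate_survival(d3, pre, seed = 33)
  expect_true(all(s3$time_days > 0 & s3$time_days <= 40))
  expect_true(all(s3$time_days[s3$event == 0] == 40))
})

test_that("unknown treatment labels in coefficient maps are refused", {
  d <- study_design(containers_per_cell = 1L)
  p <- rearing_preset("september")
  p$aft_coeffs <- c(p$aft_coeffs, bogus_level = 1)
  expect_error(generate_survival(d, p, seed = 1),
               class = "parayield_config_error")
})

test_that("egg totals follow the negative-binomial surface", {
  n <- 10000L
  mu <- exp(5.172)
  theta <- 25
  d <- single_cell_design(n)
  p <- flat_params(egg_log_mean_intercept = 5.172, nb_dispersion = theta)
  con <- generate_fecundity(d, p, seed = 41)
  se <- sqrt((mu + mu^2 / theta) / n)
  expect_equal(mean(con$total_eggs), mu, tolerance = 3 * se / mu)

  # Poisson limit: variance/mean -> 1 as theta grows
  p2 <- flat_params(egg_log_mean_intercept = log(50), nb_dispersion = 1e8)
  con2 <- generate_fecundity(d, p2, seed = 42)
  expect_equal(var(con2$total_eggs) / mean(con2$total_eggs), 1, tolerance = 0.1)
})

test_that("the hurdle zero process and clutch partition are consistent", {
  d <- study_design(containers_per_cell = 6L, followup_days = 30L)
  p <- rearing_preset("september")  # zero_prob = 1 for short-day acetone
  con <- generate_fecundity(d, p, seed = 51)
  zero_cell <- con$chemical == "acetone" & con$photoperiod == "short_day"
  expect_true(all(con$total_eggs[zero_cell] == 0))
  expect_true(all(con$total_eggs[!zero_cell] > 0))  # truncated draws
  expect_identical(con$total_eggs == 0, con$n_clutches == 0)
  expect_true(all(con$n_clutches <= con$total_eggs))
  expect_true(all(con$female_days <=
                    d$females_per_container * d$followup_days + 1e-9))
})

test_that("clutch outcomes are binomial with the preset probabilities", {
  d <- study_design()
  p <- rearing_preset("september")
  big <- stats::setNames(rep(500L, length(p$emergence_prob)),
                         names(p$emergence_prob))
  cl <- generate_clutch_outcomes(d, p, seed = 61,
                                 outcome_type = "parasitoid_emergence",
                                 clutches_per_cell = big)
  expect_true(all(cl$n_eggs >= 15))
  expect_true(all(cl$n_success <= cl$n_eggs))
  for (cell in names(p$emergence_prob)) {
    cc <- cl[paste(cl$chemical, cl$photoperiod, sep = ":") == cell, ]
    prop <- sum(cc$n_success) / sum(cc$n_eggs)
    p_true <- p$emergence_prob[[cell]]
    se <- sqrt(p_true * (1 - p_true) / sum(cc$n_eggs))
    expect_equal(prop, p_true, tolerance = (3 * se + 1e-12) / max(p_true, 1e-12))
  }

  # degenerate probabilities are honored exactly
  p0 <- rearing_preset("september")
  p0$host_eclosion_prob[] <- 0
  cl0 <- generate_clutch_outcomes(d, p0, seed = 62, outcome_type = "host_eclosion")
  expect_true(all(cl0$n_success == 0))
  p1 <- rearing_preset("september")
  p1$host_eclosion_prob[] <- 1
  cl1 <- generate_clutch_outcomes(d, p1, seed = 62, outcome_type = "host_eclosion")
  expect_identical(cl1$n_success, cl1$n_eggs)

  # requesting a cell with no probability is a configuration error
  expect_error(generate_clutch_outcomes(d, p, seed = 63,
                                        outcome_type = "host_eclosion",
                                        clutches_per_cell = c("acetone:short_day" = 5L)),
               class = "parayield_config_error")
})

test_that("event tables survive a CSV round-trip", {
  d <- study_design(containers_per_cell = 2L, followup_days = 30L)
  tabs <- generate_experiment(d, seed = 71)
  dir <- withr::local_tempdir()
  write_event_tables(tabs, dir)
  back <- read_event_tables(dir)
  for (nm in names(tabs)) expect_equal(back[[nm]], tabs[[nm]])
})

test_that("the preset encodes the reported September estimates", {
  p <- rearing_preset("september")
  expect_equal(p$aft_coeffs[["pyr_1.0"]], -0.621)
  expect_equal(p$aft_intercept, 4.307)
  expect_equal(p$aft_log_scale, -0.815)
  expect_equal(p$egg_log_mean_intercept, 5.172)
  expect_equal(p$egg_coeffs[["short_day"]], -0.666)
  expect_equal(p$emergence_prob[["acetone:long_day"]], 0.3469)
  expect_equal(p$host_eclosion_prob[["pyr_1.0:short_day"]], 0)
  expect_equal(unname(p$zero_prob["acetone:short_day"]), 1)
  # ~69 parasitoid-exposed clutches, as in the original assay
  expect_equal(sum(p$parasitism_clutches), 69, tolerance = 0.05)
})
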