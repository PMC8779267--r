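# Estimated marginal means, Tukey-adjusted contrasts and the compact letter
# display: exact reductions, quadrature oracle, independent cross-check
# against emmeans, and the letter/contrast consistency property.

fit_preset_nb <- function(seed = 301) {
  d <- study_design(containers_per_cell = 4L)
  con <- generate_fecundity(d, rearing_preset("september"), seed = seed)
  fit_nb_glm(count_sample(con, drop_cells = "acetone:short_day"))
}

test_that("EMMs back-transform the linear predictor at each cell", {
  fit <- fit_preset_nb()
  cells <- c("acetone:long_day", "pyr_0.1:long_day", "pyr_1.0:short_day")
  e <- emm_counts(fit, cells)
  expect_equal(e$estimate[1], exp(fit$coefficients[["(Intercept)"]]))
  expect_equal(e$estimate[2], exp(fit$coefficients[["(Intercept)"]] +
                                    fit$coefficients[["pyr_0.1"]]))
  # cell ratio equals exp of the coefficient
  expect_equal(e$estimate[2] / e$estimate[1], exp(fit$coefficients[["pyr_0.1"]]))
  # intervals respect exp monotonicity
  expect_true(all(e$lo < e$estimate & e$estimate < e$hi))
  expect_true(all(e$estimate > 0))
  expect_error(emm_counts(fit, "benzene:long_day"), "span")
})

test_that("EMM link-scale estimates and errors agree with emmeans", {
  skip_if_not_installed("emmeans")
  fit <- fit_preset_nb()
  cells <- c("acetone:long_day", "pyr_0.1:long_day", "pyr_1.0:long_day",
             "pyr_0.1:short_day", "pyr_1.0:short_day")
  e <- emm_counts(fit, cells)
  rg <- emmeans::ref_grid(fit$glm,
                          at = list(`pyr_1.0` = c(0, 1), `pyr_0.1` = c(0, 1),
                                    short_day = c(0, 1)),
                          data = fit$model_frame)
  em <- summary(rg, type = "link")
  key <- function(p1, p01, sd) which(em$pyr_1.0 == p1 & em$pyr_0.1 == p01 &
                                       em$short_day == sd)
  rows <- c(key(0, 0, 0), key(0, 1, 0), key(1, 0, 0), key(0, 1, 1), key(1, 0, 1))
  expect_equal(unname(attr(e, "lp")), em$prediction[rows], tolerance = 1e-6)
  expect_equal(e$se_link, em$SE[rows], tolerance = 1e-6)
})

test_that("Tukey adjustment with two cells reduces to the two-sided t test", {
  fit <- fit_preset_nb()
  e <- emm_counts(fit, c("acetone:long_day", "pyr_1.0:long_day"))
  tk <- tukey_pairs(e)
  expect_equal(tk$contrasts$p_adjusted, tk$contrasts$p_unadjusted,
               tolerance = 1e-9)
})

test_that("identical cells get adjusted p = 1 and share a letter", {
  fit <- fit_preset_nb()
  e <- emm_counts(fit, c("acetone:long_day", "acetone:long_day"))
  tk <- tukey_pairs(e)
  expect_equal(tk$contrasts$p_adjusted, 1)
  expect_equal(unname(tk$letters[1]), unname(tk$letters[2]))
})

test_that("adjusted p-values match studentized-range quadrature", {
  # equal-SE three-cell case evaluated against direct numerical integration
  lp <- c(a = 0, b = 0.35, c = 1.1)
  V <- diag(0.04, 3); dimnames(V) <- list(names(lp), names(lp))
  e <- parayield:::emm_result(names(lp), lp, V, df = 16, exp)
  tk <- tukey_pairs(e)
  for (r in seq_len(nrow(tk$contrasts))) {
    q <- sqrt(2) * abs(tk$contrasts$t[r])
    expect_equal(tk$contrasts$p_adjusted[r], 1 - oracle_ptukey(q, 3, 16),
                 tolerance = 1e-4)
  }
})

test_that("letters are consistent with the adjusted contrasts", {
  set.seed(311)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    lp <- rnorm(k, sd = 0.8)
    names(lp) <- paste0("cell", seq_len(k), ":x")
    V <- diag(runif(k, 0.01, 0.2)); dimnames(V) <- list(names(lp), names(lp))
    e <- parayield:::emm_result(names(lp), lp, V, df = 12, exp)
    tk <- tukey_pairs(e, alpha = 0.05)
    shares <- function(a, b) {
      any(strsplit(tk$letters[[a]], "")[[1]] %in%
            strsplit(tk$letters[[b]], "")[[1]])
    }
    for (r in seq_len(nrow(tk$contrasts))) {
      sig <- tk$contrasts$p_adjusted[r] <= 0.05
      expect_identical(shares(tk$contrasts$cell1[r], tk$contrasts$cell2[r]),
                       !sig)
    }
    expect_true(all(nzchar(tk$letters)))
  }
})

test_that("adjusted p-values never fall below the unadjusted ones", {
  fit <- fit_preset_nb()
  cells <- c("acetone:long_day", "pyr_0.1:long_day", "pyr_1.0:long_day",
             "pyr_0.1:short_day")
  tk <- tukey_pairs(emm_counts(fit, cells))
  expect_true(all(tk$contrasts$p_adjusted >= tk$contrasts$p_unadjusted - 1e-12))
})

test_that("hurdle EMMs combine the two parts correctly", {
  d <- study_design(containers_per_cell = 4L)
  con <- generate_fecundity(d, rearing_preset("september"), seed = 321)
  h <- fit_hurdle_nb(count_sample(con))
  cells <- c("acetone:long_day", "pyr_1.0:long_day")
  cond <- emm_counts(h, cells, type = "conditional")
  unc <- emm_counts(h, cells, type = "unconditional")
  # the unconditional mean is the positive probability times the conditional
  bz <- h$zero$coefficients
  ppos <- plogis(c(bz[["(Intercept)"]],
                   bz[["(Intercept)"]] + bz[["pyr_1.0"]]))
  expect_equal(unc$estimate, cond$estimate * ppos, tolerance = 1e-8)
  expect_true(all(unc$estimate <= cond$estimate))
})
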