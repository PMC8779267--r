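# Monte-Carlo parasitoid yield: propagate the sampling uncertainty of the
# fitted egg mean and emergence probability into parasitoids produced per
# replicate of 20 host females, per treatment.
#
# The sampling distributions are normal on each model's link scale -- i.e. a
# log-normal egg mean and a logit-normal emergence probability -- consistent
# with drawing "from the probability distribution produced by the modeled
# treatment response".  The two draws are independent: they come from
# disjoint experiments (container fecundity vs clutch exposure assays).

#' Assemble yield-simulation inputs per treatment cell
#'
#' Matches link-scale (mean, SE) pairs for the egg model and the emergence
#' model cell by cell.  Cells present in only one source -- such as the
#' short-day acetone cell, which produced no eggs and was never exposed to
#' parasitoids -- are excluded with an explicit reason rather than silently
#' dropped.
#'
#' @param count_emm An `emm_result` from [emm_counts()] (link = log eggs).
#' @param prop_emm An `emm_result` from [emm_props()] for parasitoid
#'   emergence (link = logit).
#' @return An object of class `yield_inputs`: data frame of `cell`,
#'   `egg_mean_link`, `egg_se_link`, `emerg_mean_link`, `emerg_se_link`, with
#'   an `excluded` attribute listing dropped cells and reasons.
#' @export
treatment_distributions <- function(count_emm, prop_emm) {
  egg_lp <- attr(count_emm, "lp")
  prop_lp <- attr(prop_emm, "lp")
  shared <- intersect(names(egg_lp), names(prop_lp))
  if (!length(shared)) stop("no cells shared between the two models")
  excl <- rbind(
    if (length(only <- setdiff(names(egg_lp), shared)))
      data.frame(cell = only, reason = "no emergence estimate",
                 stringsAsFactors = FALSE),
    if (length(only <- setdiff(names(prop_lp), shared)))
      data.frame(cell = only, reason = "no egg estimate",
                 stringsAsFactors = FALSE))
  inputs <- data.frame(
    cell = shared,
    egg_mean_link = unname(egg_lp[shared]),
    egg_se_link = count_emm$se_link[match(shared, count_emm$cell)],
    emerg_mean_link = unname(prop_lp[shared]),
    emerg_se_link = prop_emm$se_link[match(shared, prop_emm$cell)],
    stringsAsFactors = FALSE)
  if (any(inputs$egg_se_link < 0 | inputs$emerg_se_link < 0))
    stop("standard errors must be non-negative")
  structure(inputs, class = c("yield_inputs", "data.frame"),
            excluded = excl %||% data.frame(cell = character(),
                                            reason = character()))
}

#' Yield inputs from the reported model estimates
#'
#' Preset mode: builds [treatment_distributions()] inputs directly from the
#' built-in September calibration ([preset_tables()]).  Egg link means are the
#' intercept plus the applicable coefficients; each cell's egg link SE is
#' taken as the intercept's SE (every cell has the same number of replicate
#' containers and the response is roughly homoscedastic on the log scale;
#' the coefficient covariances needed for an exact cell SE are not part of
#' the reported tables).  Emergence percentages and their per-cell SEs are
#' delta-transformed to the logit scale.  The short-day acetone cell is
#' excluded: it produced no eggs and no parasitoid exposures were conducted.
#'
#' @param tables A [preset_tables()] list.
#' @return A `yield_inputs` object.
#' @export
yield_preset <- function(tables = preset_tables()) {
  eg <- tables$eggs[tables$eggs$collection == "september", ]
  co <- stats::setNames(eg$estimate, eg$term)
  se_int <- eg$se[eg$term == "(Intercept)"]
  via <- tables$viability[tables$viability$outcome == "parasitoid_emergence", ]
  via$cell <- cell_label(via$chemical, via$photoperiod)
  cp <- split_cell(via$cell)
  egg_lp <- co[["(Intercept)"]] +
    ifelse(cp$chemical == "pyr_1.0", co[["pyr_1.0"]], 0) +
    ifelse(cp$chemical == "pyr_0.1", co[["pyr_0.1"]], 0) +
    ifelse(cp$photoperiod == "short_day", co[["short_day"]], 0)
  p <- via$percent / 100
  se_p <- via$se / 100
  inputs <- data.frame(
    cell = via$cell,
    egg_mean_link = egg_lp,
    egg_se_link = se_int,
    emerg_mean_link = stats::qlogis(p),
    emerg_se_link = se_p / (p * (1 - p)),
    stringsAsFactors = FALSE)
  structure(inputs, class = c("yield_inputs", "data.frame"),
            excluded = data.frame(
              cell = "acetone:short_day",
              reason = "no eggs produced; no parasitoid exposures conducted",
              stringsAsFactors = FALSE))
}

#' Monte-Carlo draws of parasitoid yield
#'
#' Per draw and cell: an egg total from the log-normal sampling distribution
#' of the fitted egg mean, an emergence probability from the logit-normal
#' sampling distribution of the fitted emergence rate, and their product --
#' the parasitoids produced by one replicate of 20 host females.
#'
#' @param inputs A `yield_inputs` object.
#' @param n_draws Number of simulation repetitions per treatment.
#' @param seed Integer seed; fixed seed gives identical draws.
#' @return An object of class `yield_draws`: an `n_draws` x cells matrix with
#'   the inputs attached.
#' @export
simulate_yield <- function(inputs, n_draws = 2000L, seed = 1L) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  set.seed(seed)
  draws <- vapply(seq_len(nrow(inputs)), function(i) {
    eggs <- stats::rlnorm(n_draws, inputs$egg_mean_link[i],
                          inputs$egg_se_link[i])
    pr <- stats::plogis(stats::rnorm(n_draws, inputs$emerg_mean_link[i],
                                     inputs$emerg_se_link[i]))
    eggs * pr
  }, numeric(n_draws))
  if (!is.matrix(draws)) draws <- matrix(draws, nrow = n_draws)
  colnames(draws) <- inputs$cell
  structure(draws, class = c("yield_draws", "matrix"),
            inputs = inputs, seed = seed)
}

#' Summarize simulated parasitoid yields
#'
#' Per-cell means and empirical 95% quantile intervals, percent increase of
#' every cell over the referent (`100 (mean/mean_ref - 1)`), and a compact
#' letter display from a gamma GLM with log link fitted to the draws (yields
#' are positive and right-skewed), with Tukey-adjusted pairwise contrasts.
#'
#' @param draws A [simulate_yield()] result.
#' @param referent Referent cell for percent increases.
#' @param alpha Significance level for the letter display.
#' @param conf_level Level for the quantile intervals.
#' @param letters Compute the comparison GLM and letters (default `TRUE`).
#' @return An object of class `yield_summary`: data frame of `cell`, `mean`,
#'   `lo`, `hi`, `pct_increase`, `letter`; contrasts attached as an attribute.
#' @export
summarize_yield <- function(draws, referent = "acetone:long_day",
                            alpha = 0.05, conf_level = 0.95, letters = TRUE) {
  cells <- colnames(draws)
  if (!referent %in% cells) stop("referent cell '", referent, "' not present")
  m <- colMeans(draws)
  qs <- apply(draws, 2, stats::quantile,
              probs = c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2))
  if (m[referent] == 0) {
    warning("referent mean is zero; percent increases undefined")
    pct <- rep(NA_real_, length(cells))
  } else {
    pct <- 100 * (m / m[referent] - 1)
  }
  out <- data.frame(cell = cells, mean = unname(m),
                    lo = unname(qs[1, ]), hi = unname(qs[2, ]),
                    pct_increase = unname(pct),
                    stringsAsFactors = FALSE)
  contrasts <- NULL
  if (letters && length(cells) >= 2) {
    long <- data.frame(y = as.vector(draws),
                       cell = factor(rep(cells, each = nrow(draws)),
                                     levels = cells))
    gfit <- stats::glm(y ~ cell, family = stats::Gamma(link = "log"),
                       data = long)
    # cell-means linear predictors and covariance on the log scale
    L <- matrix(0, length(cells), length(cells),
                dimnames = list(cells, names(stats::coef(gfit))))
    L[, 1] <- 1
    for (i in seq_along(cells)[-1]) L[i, i] <- 1
    lp <- drop(L %*% stats::coef(gfit))
    V <- L %*% stats::vcov(gfit) %*% t(L)
    emm <- emm_result(cells, lp, V, gfit$df.residual, exp, conf_level)
    tk <- tukey_pairs(emm, alpha = alpha)
    out$letter <- unname(tk$letters[cells])
    contrasts <- tk$contrasts
  }
  structure(out, class = c("yield_summary", "data.frame"),
            contrasts = contrasts, referent = referent, alpha = alpha)
}

#' @export
print.yield_summary <- function(x, ...) {
  cat("Simulated parasitoid yield per 20 host females (referent: ",
      attr(x, "referent"), ")\n", sep = "")
  print.data.frame(sig4(as.data.frame(x)), row.names = FALSE, ...)
  invisible(x)
}

#' Boxplot of simulated yields per treatment
#'
#' @param x A `yield_draws` object.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.yield_draws <- function(x, ...) {
  graphics::boxplot(unclass(x), ylab = "parasitoids per 20 host females",
                    las = 2, ...)
}
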