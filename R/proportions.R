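# Clutch-level viability stage: binomial logistic regression in which every
# egg carries a binary outcome and clutches enter with their size as weight,
# then estimated marginal means on the proportion scale.

#' Build a binomial sample from the clutch table
#'
#' One row per clutch: successes, trials (the clutch size, which acts as the
#' weight) and the treatment cell.  The model is a cell-means logit: the
#' intercept is the referent cell and every other cell gets an indicator
#' column named by its `"chemical:photoperiod"` label.
#'
#' @param clutches Clutch-record data frame (see [generate_clutch_outcomes()]).
#' @param outcome_type `"host_eclosion"` or `"parasitoid_emergence"`.
#' @param referent_cell Referent cell label (intercept).
#' @param collection Optional collection label to subset to.
#' @return An object of class `binomial_sample`.
#' @export
binomial_sample <- function(clutches, outcome_type,
                            referent_cell = "acetone:long_day",
                            collection = NULL) {
  d <- clutches[clutches$outcome_type == outcome_type, ]
  if (!is.null(collection)) d <- d[d$collection %in% collection, ]
  if (!nrow(d)) stop("no clutches for outcome '", outcome_type, "'")
  if (any(d$n_success > d$n_eggs)) stop("successes exceed clutch size")
  cells <- cell_label(d$chemical, d$photoperiod)
  if (!referent_cell %in% cells)
    stop_config("referent cell '", referent_cell, "' has no clutches")
  lev <- c(referent_cell, sort(setdiff(unique(cells), referent_cell)))
  X <- matrix(0, nrow(d), length(lev) - 1L,
              dimnames = list(NULL, lev[-1]))
  for (j in lev[-1]) X[, j] <- as.numeric(cells == j)
  structure(list(successes = d$n_success,
                 trials = d$n_eggs,
                 cells = cells,
                 cell_levels = lev,
                 design_matrix = X,
                 referent_cell = referent_cell,
                 outcome_type = outcome_type,
                 data = d),
            class = "binomial_sample")
}

#' Clutch-size-weighted binomial logistic regression
#'
#' IRLS maximum likelihood for the binomial logit in which each clutch
#' contributes `n_success` successes out of `n_eggs` trials; this is exactly
#' the egg-level Bernoulli likelihood aggregated by clutch.  Cells whose
#' pooled outcome sits on the boundary (no successes, or all successes) have
#' no finite MLE; with `penalize = "auto"` (default) such boundary cells or
#' detected separation trigger a Firth-penalized refit, flagged in the result.
#'
#' @param sample A [binomial_sample()].
#' @param penalize `"auto"`, `"never"` or `"always"`.
#' @return An object of class `logit_fit` with coefficients on the logit
#'   scale, their covariance, the log-likelihood, clutch and egg counts,
#'   boundary-cell flags and the penalization flag.
#' @export
fit_weighted_logit <- function(sample, penalize = c("auto", "never", "always")) {
  penalize <- match.arg(penalize)
  s <- sample$successes
  m <- sample$trials
  pooled_s <- tapply(s, sample$cells, sum)
  pooled_m <- tapply(m, sample$cells, sum)
  if (all(pooled_s == 0) || all(pooled_s == pooled_m))
    stop("both outcome classes must be present somewhere")
  boundary <- names(pooled_s)[pooled_s == 0 | pooled_s == pooled_m]
  X <- cbind("(Intercept)" = 1, sample$design_matrix)
  warned <- FALSE
  gfit <- withCallingHandlers(
    stats::glm.fit(X, s / m, weights = m, family = stats::binomial()),
    warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
  use_firth <- switch(penalize,
                      never = FALSE,
                      always = TRUE,
                      auto = length(boundary) > 0 || logit_separated(gfit, warned))
  if (use_firth) {
    ff <- firth_logit(X, s, m)
    coefs <- ff$coefficients
    V <- ff$vcov
    ll <- ff$loglik
  } else {
    coefs <- stats::setNames(gfit$coefficients, colnames(X))
    mu <- gfit$fitted.values
    V <- chol2inv(chol(crossprod(X, X * m * mu * (1 - mu))))
    dimnames(V) <- list(colnames(X), colnames(X))
    ll <- sum(stats::dbinom(s, m, mu, log = TRUE))
  }
  p <- length(coefs)
  structure(list(coefficients = coefs,
                 se = sqrt(diag(V)),
                 vcov = V,
                 loglik = ll,
                 n_clutches = length(s),
                 n_eggs = sum(m),
                 df_residual = length(s) - p,
                 cell_levels = sample$cell_levels,
                 referent_cell = sample$referent_cell,
                 boundary_cells = boundary,
                 penalized = use_firth,
                 pooled = data.frame(cell = names(pooled_s),
                                     successes = as.integer(pooled_s),
                                     trials = as.integer(pooled_m)),
                 outcome_type = sample$outcome_type),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Weighted binomial logit (", x$outcome_type, "): ",
      x$n_clutches, " clutches, ", x$n_eggs, " eggs",
      if (x$penalized) ", Firth-penalized" else "", "\n", sep = "")
  print(signif(cbind(estimate = x$coefficients, se = x$se), 4))
  if (length(x$boundary_cells))
    cat("boundary cell(s):", paste(x$boundary_cells, collapse = ", "), "\n")
  invisible(x)
}

#' Estimated marginal means on the proportion scale
#'
#' Inverse-logit cell estimates with back-transformed link-scale t intervals
#' (`df = clutches - parameters`).  A boundary cell (pooled 0% or 100%) keeps
#' its raw estimate and is given a one-sided rule-of-three interval
#' (`1 - alpha^(1/n)` on the open side) and a `degenerate` flag; its letter
#' comes from the penalized fit.
#'
#' @param fit A [fit_weighted_logit()] result.
#' @param cells Cells to estimate; default all cells in the fit.
#' @param conf_level Confidence level.
#' @return An `emm_result` data frame with a `degenerate` column.
#' @export
emm_props <- function(fit, cells = NULL, conf_level = 0.95) {
  if (is.null(cells)) cells <- fit$cell_levels
  bad <- setdiff(cells, fit$cell_levels)
  if (length(bad))
    stop("cell(s) outside the design span: ", paste(bad, collapse = ", "))
  cols <- names(fit$coefficients)
  L <- matrix(0, length(cells), length(cols), dimnames = list(cells, cols))
  L[, "(Intercept)"] <- 1
  for (j in intersect(cells, cols)) L[j, j] <- 1
  lp <- drop(L %*% fit$coefficients)
  V <- L %*% fit$vcov %*% t(L)
  out <- emm_result(cells, lp, V, fit$df_residual, stats::plogis, conf_level)
  out$degenerate <- FALSE
  alpha <- 1 - conf_level
  for (bc in intersect(fit$boundary_cells, cells)) {
    n <- fit$pooled$trials[fit$pooled$cell == bc]
    sc <- fit$pooled$successes[fit$pooled$cell == bc]
    out$degenerate[out$cell == bc] <- TRUE
    if (sc == 0) {
      out$estimate[out$cell == bc] <- 0
      out$lo[out$cell == bc] <- 0
      out$hi[out$cell == bc] <- 1 - alpha^(1 / n)
    } else {
      out$estimate[out$cell == bc] <- 1
      out$lo[out$cell == bc] <- alpha^(1 / n)
      out$hi[out$cell == bc] <- 1
    }
  }
  out
}
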