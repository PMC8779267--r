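# Egg-production stage: negative-binomial GLM (log link), hurdle variant with
# a hand-written zero-truncated NB count part, and term-level F tests.

#' Build a count sample from the container table
#'
#' @param containers Container-record data frame (see [generate_fecundity()]).
#' @param collection Optional collection label to subset to.
#' @param referent Named character referent levels; the default intercept cell
#'   is long-day + acetone, matching the egg-production model's convention.
#' @param drop_cells Optional character vector of `"chemical:photoperiod"`
#'   cells to exclude (e.g. an all-zero cell when fitting the plain NB model).
#' @return An object of class `count_sample` with `counts`, `design_matrix`,
#'   `referent` and the per-row cell labels.
#' @export
count_sample <- function(containers, collection = NULL,
                         referent = c(chemical = "acetone",
                                      photoperiod = "long_day"),
                         drop_cells = NULL) {
  d <- containers
  if (!is.null(collection)) d <- d[d$collection %in% collection, ]
  cells <- cell_label(d$chemical, d$photoperiod)
  if (!is.null(drop_cells)) {
    keep <- !cells %in% drop_cells
    d <- d[keep, ]
    cells <- cells[keep]
  }
  if (!nrow(d)) stop("no containers left after filtering")
  X <- indicator_matrix(d, c("chemical", "photoperiod"), referent)
  structure(list(counts = as.integer(d$total_eggs),
                 design_matrix = X,
                 referent = referent,
                 cells = cells,
                 data = d),
            class = "count_sample")
}

all_zero_cells <- function(sample) {
  mx <- tapply(sample$counts, sample$cells, max)
  names(mx)[mx == 0]
}

#' Negative-binomial GLM for container egg totals
#'
#' Log-link negative-binomial regression fitted by `MASS::glm.nb`
#' (alternating IRLS for the coefficients and profile ML for theta).  A
#' treatment cell whose counts are all zero makes the NB likelihood degenerate
#' (under-dispersion at the boundary); that situation is detected up front and
#' raised as an error recommending the hurdle model, mirroring how the
#' original analysis had to switch models.
#'
#' @param sample A [count_sample()].
#' @return An object of class `nb_fit` with coefficients, their covariance,
#'   `theta`, log-likelihoods and the Pearson dispersion.
#' @export
fit_nb_glm <- function(sample) {
  if (all(sample$counts == 0) || length(az <- all_zero_cells(sample))) {
    what <- if (all(sample$counts == 0)) "all counts are zero"
            else paste0("cell(s) with repeating zero counts: ",
                        paste(az, collapse = ", "))
    stop(errorCondition(
      paste0("negative binomial fit failed due to under-dispersion (", what,
             "); use fit_hurdle_nb() or drop the cell(s)"),
      class = c("parayield_underdispersion_error", "error")))
  }
  X <- sample$design_matrix
  if (ncol(X) && qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("design matrix is singular")
  df <- data.frame(.count = sample$counts)
  df <- cbind(df, as.data.frame(X))
  fml <- if (ncol(X))
    stats::reformulate(sprintf("`%s`", colnames(X)), response = ".count")
  else .count ~ 1
  fit <- MASS::glm.nb(fml, data = df,
                      control = stats::glm.control(epsilon = 1e-12, maxit = 200))
  if (fit$theta > 1e5)
    warning("theta estimate at the Poisson limit (theta > 1e5)")
  if (fit$theta < 1e-3)
    warning("theta estimate at the lower bound (theta < 1e-3)")
  V <- stats::vcov(fit)
  strip <- function(s) sub("^`|`$", "", s)
  rownames(V) <- colnames(V) <- strip(rownames(V))
  cf <- stats::coef(fit)
  names(cf) <- strip(names(cf))
  p <- length(cf)
  n <- nrow(df)
  null <- MASS::glm.nb(.count ~ 1, data = df,
                       control = stats::glm.control(epsilon = 1e-12, maxit = 200))
  structure(list(coefficients = cf,
                 se = sqrt(diag(V)),
                 vcov = V,
                 theta = fit$theta,
                 theta_se = fit$SE.theta,
                 loglik = as.numeric(stats::logLik(fit)),
                 null_loglik = as.numeric(stats::logLik(null)),
                 n = n,
                 df_residual = n - p,
                 dispersion = sum(stats::residuals(fit, "pearson")^2) / (n - p),
                 deviance = fit$deviance,
                 referent = sample$referent,
                 cells = sample$cells,
                 glm = fit,
                 model_frame = df),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative-binomial GLM (log link), n =", x$n,
      " theta =", signif(x$theta, 4), "\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    z = x$coefficients / x$se)
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  print(signif(tab, 4))
  invisible(x)
}

#' Term-level F tests for a negative-binomial fit
#'
#' For each term (a named set of design columns) the model is refitted without
#' those columns holding theta at the full-model estimate, and
#' `F = (deviance drop / df1) / dispersion` is referred to an F distribution
#' with `df2 = n - p` denominator degrees of freedom, where the dispersion is
#' the full model's Pearson statistic over `df2`.
#'
#' @param fit An [fit_nb_glm()] result.
#' @param terms Named list mapping term name to design-column names; default
#'   groups the chemical indicators and the photoperiod indicator.
#' @return A data frame with `term`, `F`, `df1`, `df2`, `p`.
#' @export
term_f_tests <- function(fit, terms = NULL) {
  cols <- setdiff(names(fit$coefficients), "(Intercept)")
  if (is.null(terms)) {
    chem <- grep("^pyr", cols, value = TRUE)
    photo <- setdiff(cols, chem)
    terms <- list()
    if (length(chem)) terms$chemical <- chem
    if (length(photo)) terms$photoperiod <- photo
  }
  fam <- MASS::negative.binomial(theta = fit$theta)
  df <- fit$model_frame
  full <- stats::glm(stats::reformulate(sprintf("`%s`", cols), response = ".count"),
                     family = fam, data = df,
                     control = stats::glm.control(epsilon = 1e-12, maxit = 200))
  out <- lapply(names(terms), function(tm) {
    keep <- setdiff(cols, terms[[tm]])
    # columns absent from the model contribute nothing
    tcols <- intersect(terms[[tm]], cols)
    df1 <- length(tcols)
    if (df1 == 0)
      return(data.frame(term = tm, F = 0, df1 = 0, df2 = fit$df_residual, p = 1))
    fml <- if (length(keep))
      stats::reformulate(sprintf("`%s`", keep), response = ".count")
    else .count ~ 1
    red <- stats::glm(fml, family = fam, data = df,
                      control = stats::glm.control(epsilon = 1e-12, maxit = 200))
    drop <- max(red$deviance - full$deviance, 0)
    Fv <- (drop / df1) / fit$dispersion
    data.frame(term = tm, F = Fv, df1 = df1, df2 = fit$df_residual,
               p = stats::pf(Fv, df1, fit$df_residual, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# --- zero-truncated negative binomial machinery (count part of the hurdle) ---

# log P(Y = 0) for NB(mu, theta)
nb_log_p0 <- function(mu, theta) theta * (log(theta) - log(theta + mu))

# mean of the zero-truncated NB
truncated_nb_mean <- function(mu, theta) {
  mu / (1 - exp(nb_log_p0(mu, theta)))
}

truncated_nb_loglik <- function(y, mu, theta) {
  lp0 <- nb_log_p0(mu, theta)
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE) -
        log1p(-exp(lp0)))
}

fit_truncated_nb <- function(y, X) {
  X1 <- cbind("(Intercept)" = 1, X)
  nll <- function(par) {
    beta <- par[seq_len(ncol(X1))]
    theta <- exp(par[length(par)])
    mu <- exp(drop(X1 %*% beta))
    if (any(!is.finite(mu)) || theta > 1e7) return(1e10)
    -truncated_nb_loglik(y, mu, theta)
  }
  # initialize from a log-linear least squares fit; truncation is a small
  # correction whenever the mean is well above zero
  b0 <- tryCatch(stats::coef(stats::lm(log(y + 0.5) ~ X1 - 1)),
                 error = function(e) c(log(mean(y)), rep(0, ncol(X1) - 1)))
  b0[!is.finite(b0)] <- 0
  th0 <- max(min(mean(y)^2 / max(stats::var(y) - mean(y), 1e-3), 1e4), 0.1)
  opt <- stats::optim(c(b0, log(th0)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12),
                      hessian = TRUE)
  if (opt$convergence != 0)
    stop("truncated NB fit did not converge (optim code ", opt$convergence, ")")
  par <- opt$par
  nm <- c(colnames(X1), "log_theta")
  V <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, length(par), length(par))
  })
  dimnames(V) <- list(nm, nm)
  list(coefficients = stats::setNames(par[seq_len(ncol(X1))], colnames(X1)),
       theta = exp(par[length(par)]),
       log_theta = par[length(par)],
       vcov = V,
       se = sqrt(pmax(diag(V), 0)),
       loglik = -opt$value)
}

#' Hurdle negative-binomial model for egg totals
#'
#' Two-part model: a binomial logit for zero vs positive containers and a
#' zero-truncated negative binomial for the positive totals.  The two parts
#' are disjoint likelihood factors, so the joint log-likelihood is their sum.
#' Cells whose containers are all zero are carried by the zero part alone;
#' columns without support among the positives are dropped from the count part
#' and reported in `count$aliased`.  Complete separation in the zero part
#' (e.g. one cell all-zero, the rest all-positive) triggers a Firth-penalized
#' logit, flagged in `zero$penalized`.
#'
#' @param sample A [count_sample()].
#' @return An object of class `hurdle_fit` with `zero`, `count` and `loglik`.
#' @export
fit_hurdle_nb <- function(sample) {
  y <- sample$counts
  if (!any(y == 0) || !any(y > 0))
    stop("hurdle model needs at least one zero and one positive count")
  X <- sample$design_matrix
  z <- as.integer(y > 0)
  warned <- FALSE
  zfit <- withCallingHandlers(
    stats::glm.fit(cbind("(Intercept)" = 1, X), z,
                   family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  penalized <- logit_separated(zfit, warned)
  if (penalized) {
    zf <- firth_logit(cbind("(Intercept)" = 1, X), z, rep(1L, length(z)))
    zero <- list(coefficients = zf$coefficients, vcov = zf$vcov, se = zf$se,
                 loglik = zf$loglik, penalized = TRUE)
  } else {
    Xz <- cbind("(Intercept)" = 1, X)
    V <- chol2inv(chol(crossprod(Xz, Xz * zfit$weights)))
    dimnames(V) <- list(colnames(Xz), colnames(Xz))
    mu <- zfit$fitted.values
    zero <- list(coefficients = stats::setNames(zfit$coefficients, colnames(Xz)),
                 vcov = V, se = sqrt(diag(V)),
                 loglik = sum(stats::dbinom(z, 1, mu, log = TRUE)),
                 penalized = FALSE)
  }
  pos <- y > 0
  Xp <- X[pos, , drop = FALSE]
  aliased <- character()
  if (ncol(Xp)) {
    qd <- qr(cbind(1, Xp))
    if (qd$rank < ncol(Xp) + 1) {
      aliased <- colnames(Xp)[qd$pivot[-seq_len(qd$rank)] - 1L]
      Xp <- Xp[, setdiff(colnames(Xp), aliased), drop = FALSE]
    }
  }
  cfit <- fit_truncated_nb(y[pos], Xp)
  cfit$aliased <- aliased
  structure(list(zero = zero, count = cfit,
                 loglik = zero$loglik + cfit$loglik,
                 n = length(y), n_positive = sum(pos),
                 referent = sample$referent, cells = sample$cells,
                 design_colnames = colnames(X)),
            class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat("Hurdle NB model: n =", x$n, "(", x$n_positive, "positive )\n")
  cat("zero part (logit",
      if (x$zero$penalized) ", Firth-penalized" else "", "):\n", sep = "")
  print(signif(cbind(estimate = x$zero$coefficients, se = x$zero$se), 4))
  cat("count part (zero-truncated NB, theta =", signif(x$count$theta, 4), "):\n")
  print(signif(cbind(estimate = x$count$coefficients,
                     se = x$count$se[names(x$count$coefficients)]), 4))
  if (length(x$count$aliased))
    cat("count-part columns dropped (no positive support):",
        paste(x$count$aliased, collapse = ", "), "\n")
  invisible(x)
}
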