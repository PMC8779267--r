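# Survival stage: Kaplan-Meier curves and censored Weibull accelerated
# failure-time regression with likelihood-ratio tests and hazard-ratio
# conversion.  Only females enter the analysis; males are removed at ingest.

#' Build a survival sample from the subject table
#'
#' Filters to the requested sex and collection and builds a 0/1 treatment
#' design matrix with an explicit referent cell.  Non-referent factor levels
#' become indicator columns named by their level, so with the default referent
#' (short-day + acetone) the columns are `pyr_0.1`, `pyr_1.0` and `long_day`.
#'
#' @param subjects Subject-record data frame (see [generate_survival()]).
#' @param collection Optional collection label to subset to.
#' @param covariates Character vector of covariate column names to encode.
#' @param referent Named character: the referent level per covariate.
#' @param sex Sex to keep (default `"f"`; the models describe female survival).
#' @return An object of class `survival_sample` with `times`, `events`,
#'   `design_matrix` and `referent`.
#' @export
survival_sample <- function(subjects, collection = NULL,
                            covariates = c("chemical", "photoperiod"),
                            referent = c(chemical = "acetone",
                                         photoperiod = "short_day"),
                            sex = "f") {
  d <- subjects
  if (!is.null(collection)) d <- d[d$collection %in% collection, ]
  if (!is.null(sex) && "sex" %in% names(d)) d <- d[d$sex %in% sex, ]
  if (!nrow(d)) stop("no subjects left after filtering")
  X <- indicator_matrix(d, covariates, referent)
  structure(list(times = d$time_days,
                 events = as.integer(d$event),
                 design_matrix = X,
                 referent = referent,
                 data = d),
            class = "survival_sample")
}

# indicator columns for all non-referent levels of each covariate
indicator_matrix <- function(d, covariates, referent) {
  cols <- list()
  for (cv in covariates) {
    levs <- unique(d[[cv]])
    ref <- referent[[cv]]
    if (is.null(ref) || !ref %in% levs)
      stop_config("referent level for '", cv, "' not present in data")
    for (lv in setdiff(levs, ref)) cols[[lv]] <- as.numeric(d[[cv]] == lv)
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(numeric(0), nrow(d), 0)
  X
}

#' Kaplan-Meier survival curve with Greenwood errors
#'
#' Product-limit estimate with Greenwood standard errors and a median (the
#' earliest time at which survival drops to 0.5 or below) whose confidence
#' interval comes from inverting the log(-log) transformed pointwise band,
#' the convention of standard survival software.  Deaths precede censorings
#' at tied times.  With no events the curve stays at 1 and the median is
#' `NA` (flagged, not an error).
#'
#' @param sample A [survival_sample()].
#' @param group Optional factor (length of the sample) giving one curve per
#'   level.
#' @param conf_level Confidence level for bands and the median interval.
#' @return A `km_curve` (data frame of `time`, `n_risk`, `n_event`,
#'   `survival`, `se`, `lo`, `hi` with attributes `median`, `median_ci`), or a
#'   named list of curves when `group` is given.
#' @export
km_fit <- function(sample, group = NULL, conf_level = 0.95) {
  if (!is.null(group)) {
    g <- as.factor(group)
    out <- lapply(levels(g), function(lv) {
      sub <- structure(list(times = sample$times[g == lv],
                            events = sample$events[g == lv]),
                       class = "survival_sample")
      km_fit(sub, conf_level = conf_level)
    })
    names(out) <- levels(g)
    return(out)
  }
  fit <- survival::survfit(survival::Surv(sample$times, sample$events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  sm <- summary(fit, censored = FALSE)
  curve <- data.frame(time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
                      survival = sm$surv, se = sm$std.err,
                      lo = sm$lower, hi = sm$upper)
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  ci <- c(lo = unname(tab["0.95LCL"]), hi = unname(tab["0.95UCL"]))
  structure(curve, class = c("km_curve", "data.frame"),
            median = med, median_ci = ci, n = fit$n)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, median = %s days (95%% CI %s-%s)\n",
              attr(x, "n"),
              format(attr(x, "median")),
              format(attr(x, "median_ci")[1]),
              format(attr(x, "median_ci")[2])))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Censored Weibull accelerated failure-time fit
#'
#' Maximum likelihood for the model `log T = mu + x beta + sigma W`, `W`
#' standard minimum Gumbel, with right censoring at the follow-up horizon.
#' Fitting is done by `survival::survreg` (tight tolerance); the returned
#' object carries the coefficient vector, `log(sigma)`, the observed
#' information covariance over (coefficients, log scale), the maximized
#' log-likelihood and the intercept-only null log-likelihood.
#'
#' @param sample A [survival_sample()].
#' @return An object of class `aft_fit`.
#' @export
fit_weibull_aft <- function(sample) {
  X <- sample$design_matrix
  if (ncol(X)) {
    r <- qr(cbind(1, X))$rank
    if (r < ncol(X) + 1) {
      alias <- colnames(X)[qr(cbind(1, X))$pivot[-seq_len(r)] - 1L]
      stop("design matrix is singular; aliased column(s): ",
           paste(alias, collapse = ", "))
    }
    for (j in seq_len(ncol(X))) {
      if (any(X[, j] == 1) && sum(sample$events[X[, j] == 1]) < 1)
        stop("no events in the support of column '", colnames(X)[j], "'")
    }
  }
  if (sum(sample$events) < 1) stop("no events in sample")
  df <- data.frame(.time = sample$times, .event = sample$events)
  df <- cbind(df, as.data.frame(X))
  fml <- if (ncol(X)) {
    stats::reformulate(sprintf("`%s`", colnames(X)),
                       response = quote(survival::Surv(.time, .event)))
  } else {
    survival::Surv(.time, .event) ~ 1
  }
  withCallingHandlers(
    fit <- survival::survreg(fml, data = df, dist = "weibull",
                             control = survival::survreg.control(
                               maxiter = 200, rel.tolerance = 1e-11)),
    warning = function(w) {
      if (grepl("iterations", conditionMessage(w)))
        stop("AFT fit did not converge: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  V <- stats::vcov(fit)  # includes the Log(scale) row/column
  cf <- stats::coef(fit)
  names(cf) <- sub("^`|`$", "", names(cf))
  rn <- sub("^`|`$", "", rownames(V))
  rownames(V) <- colnames(V) <- sub("Log\\(scale\\)", "log_scale", rn)
  se <- sqrt(diag(V))
  structure(list(coefficients = cf,
                 log_scale = log(fit$scale),
                 se = se,
                 vcov = V,
                 loglik = fit$loglik[2],
                 null_loglik = fit$loglik[1],
                 n = nrow(df),
                 referent = sample$referent,
                 survreg = fit),
            class = "aft_fit")
}

#' @export
print.aft_fit <- function(x, ...) {
  cat("Weibull AFT fit (n =", x$n, ")\n")
  cat("referent:", paste(names(x$referent), x$referent,
                         sep = "=", collapse = ", "), "\n")
  est <- c(x$coefficients, log_scale = x$log_scale)
  tab <- data.frame(estimate = est, se = x$se[names(est)],
                    z = est / x$se[names(est)])
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  print(signif(tab, 4))
  lrt <- aft_lrt(x)
  cat(sprintf("LRT vs null: chi2 = %.2f, df = %d, p = %.3g\n",
              lrt$chi2, lrt$df, lrt$p))
  invisible(x)
}

#' Likelihood-ratio test of an AFT fit against its intercept-only null
#'
#' @param fit An [fit_weibull_aft()] result.
#' @return A list with `chi2 = 2 (loglik - null_loglik)`, `df` (number of
#'   non-intercept coefficients) and the upper-tail chi-square `p`.
#' @export
aft_lrt <- function(fit) {
  chi2 <- 2 * (fit$loglik - fit$null_loglik)
  df <- sum(names(fit$coefficients) != "(Intercept)")
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Hazard ratio implied by a Weibull AFT coefficient
#'
#' Under the Weibull AFT model a log-time shift `beta` at scale
#' `sigma = exp(log_scale)` corresponds to a proportional-hazards ratio
#' `exp(-beta / sigma)` relative to the referent cell.
#'
#' @param coef Log-time coefficient(s).
#' @param log_scale Log of the Weibull scale parameter.
#' @return Hazard ratio(s), vectorized over `coef`.
#' @export
hazard_ratio <- function(coef, log_scale) {
  exp(-coef / exp(log_scale))
}

#' Hazard ratios with delta-method confidence intervals
#'
#' Transforms every non-intercept coefficient of an AFT fit to a hazard ratio
#' with a confidence interval from the delta method applied to
#' `g(beta, log sigma) = -beta exp(-log sigma)` using the fit's joint
#' covariance, then exponentiated.
#'
#' @param fit An [fit_weibull_aft()] result.
#' @param conf_level Confidence level.
#' @return A data frame with `term`, `hr`, `lo`, `hi` and a `referent`
#'   attribute.
#' @export
hazard_ratios <- function(fit, conf_level = 0.95) {
  if (exp(fit$log_scale) <= 0) stop("scale must be positive")
  terms <- setdiff(names(fit$coefficients), "(Intercept)")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  inv_sigma <- exp(-fit$log_scale)
  out <- lapply(terms, function(tm) {
    b <- fit$coefficients[[tm]]
    g <- -b * inv_sigma
    vb <- fit$vcov[tm, tm]
    vl <- fit$vcov["log_scale", "log_scale"]
    cbl <- fit$vcov[tm, "log_scale"]
    # grad: d/db = -1/sigma, d/dlogsigma = b/sigma
    vg <- inv_sigma^2 * (vb - 2 * b * cbl + b^2 * vl)
    se <- sqrt(pmax(vg, 0))
    data.frame(term = tm, hr = exp(g), lo = exp(g - z * se),
               hi = exp(g + z * se), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "referent") <- fit$referent
  out
}
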