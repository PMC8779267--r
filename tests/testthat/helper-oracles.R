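# Independent brute-force oracles.  These deliberately re-derive each
# likelihood from first principles and maximize it numerically, so they share
# no code path with the package's fitting routines.

# --- censored Weibull AFT -------------------------------------------------
# log T = X beta + sigma W, W standard minimum Gumbel; z = (log t - xb)/sigma
oracle_aft_nll <- function(par, time, event, X) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sigma <- exp(par[p + 1])
  z <- (log(time) - drop(X %*% beta)) / sigma
  ll <- sum(ifelse(event == 1,
                   -log(sigma) - log(time) + z - exp(z),
                   -exp(z)))
  -ll
}

oracle_aft_fit <- function(time, event, X) {
  init <- c(stats::coef(stats::lm(log(time) ~ X - 1)), 0)
  o <- stats::optim(init, oracle_aft_nll, time = time, event = event, X = X,
                    method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  o <- stats::optim(o$par, oracle_aft_nll, time = time, event = event, X = X,
                    method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  unname(o$par)  # (beta, log sigma)
}

# --- negative binomial GLM ------------------------------------------------
oracle_nb_nll <- function(par, y, X) {
  p <- ncol(X)
  mu <- exp(drop(X %*% par[seq_len(p)]))
  theta <- exp(par[p + 1])
  -sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
}

oracle_nb_fit <- function(y, X) {
  init <- c(stats::coef(stats::lm(log(y + 0.5) ~ X - 1)), log(5))
  o <- stats::optim(init, oracle_nb_nll, y = y, X = X, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  o <- stats::optim(o$par, oracle_nb_nll, y = y, X = X, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  unname(o$par)  # (beta, log theta)
}

# --- zero-truncated negative binomial -------------------------------------
oracle_tnb_mean <- function(mu, theta) {
  # E[Y | Y > 0] for NB(mu, theta), from the definition
  mu / (1 - (theta / (theta + mu))^theta)
}

oracle_tnb_nll <- function(par, y, X) {
  p <- ncol(X)
  mu <- exp(drop(X %*% par[seq_len(p)]))
  theta <- exp(par[p + 1])
  p0 <- (theta / (theta + mu))^theta
  -sum(dnbinom(y, size = theta, mu = mu, log = TRUE) - log(1 - p0))
}

oracle_tnb_fit <- function(y, X) {
  init <- c(stats::coef(stats::lm(log(y + 0.5) ~ X - 1)), log(5))
  o <- stats::optim(init, oracle_tnb_nll, y = y, X = X, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  o <- stats::optim(o$par, oracle_tnb_nll, y = y, X = X, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  unname(o$par)
}

# --- weighted binomial logit ----------------------------------------------
oracle_logit_nll <- function(beta, s, m, X) {
  p <- plogis(drop(X %*% beta))
  -sum(dbinom(s, m, p, log = TRUE))
}

oracle_logit_fit <- function(s, m, X) {
  o <- stats::optim(rep(0, ncol(X)), oracle_logit_nll, s = s, m = m, X = X,
                    method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-15))
  o <- stats::optim(o$par, oracle_logit_nll, s = s, m = m, X = X,
                    method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  unname(o$par)
}

# --- studentized range CDF by direct quadrature ---------------------------
oracle_ptukey <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      g <- function(z) dnorm(z) * (pnorm(z) - pnorm(z - q * si))^(k - 1)
      k * stats::integrate(g, -9, 9, rel.tol = 1e-11,
                           subdivisions = 400L)$value
    }, 0)
  }
  # density of s = sqrt(chi2_df / df)
  fs <- function(s) exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
                          (df - 1) * log(s) - df * s^2 / 2)
  stats::integrate(function(s) fs(s) * inner(s), 0, Inf,
                   rel.tol = 1e-9, subdivisions = 400L)$value
}

# --- numeric means of link-scale sampling distributions -------------------
oracle_logitnormal_mean <- function(mu, sigma) {
  if (sigma == 0) return(plogis(mu))
  stats::integrate(function(z) plogis(z) * dnorm(z, mu, sigma),
                   mu - 10 * sigma, mu + 10 * sigma, rel.tol = 1e-10)$value
}

oracle_lognormal_mean <- function(mu, sigma) exp(mu + sigma^2 / 2)

# --- shared small fixtures ------------------------------------------------
tiny_design <- function(...) {
  study_design(collections = "september", ...)
}

single_cell_design <- function(containers, followup = 100000L) {
  study_design(collections = "september", photoperiods = "long_day",
               chemicals = "acetone", containers_per_cell = containers,
               females_per_container = 1L, males_per_container = 0L,
               followup_days = followup)
}

no_coeffs <- function() stats::setNames(numeric(0), character(0))

flat_params <- function(aft_intercept = log(20), aft_log_scale = 0,
                        egg_log_mean_intercept = log(50), nb_dispersion = 25,
                        ...) {
  generator_params(aft_intercept = aft_intercept, aft_coeffs = no_coeffs(),
                   aft_log_scale = aft_log_scale,
                   egg_log_mean_intercept = egg_log_mean_intercept,
                   egg_coeffs = no_coeffs(), nb_dispersion = nb_dispersion,
                   ...)
}
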