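# Firth-penalized binomial logistic regression (Jeffreys-prior score
# correction), used as the documented fallback when a logit fit separates or
# an outcome cell sits on the boundary.  Hand-rolled IRLS with the hat-value
# half-correction on the working response.

firth_logit <- function(X, successes, trials, maxit = 200, tol = 1e-10) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- trials * mu * (1 - mu)
    w <- pmax(w, 1e-12)
    XW <- X * w
    XtWX <- crossprod(X, XW)
    R <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(R)) stop("information matrix is singular in penalized logit")
    # hat values of the weighted design
    Xs <- X * sqrt(w)
    H <- Xs %*% chol2inv(R) %*% t(Xs)
    h <- diag(H)
    U <- crossprod(X, successes - trials * mu + h * (0.5 - mu))
    delta <- drop(chol2inv(R) %*% U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(trials * mu * (1 - mu), 1e-12)
  vcov <- chol2inv(chol(crossprod(X, X * w)))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  ll <- sum(stats::dbinom(successes, trials, mu, log = TRUE))
  list(coefficients = stats::setNames(beta, colnames(X)),
       vcov = vcov, se = sqrt(diag(vcov)),
       fitted = mu, loglik = ll, iterations = it,
       converged = max(abs(delta)) < tol)
}

# crude separation heuristic for an unpenalized logit fit
logit_separated <- function(glm_fit, warned) {
  warned || any(abs(stats::coef(glm_fit)) > 12, na.rm = TRUE)
}
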