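# Estimated marginal means, Tukey-adjusted pairwise contrasts, and the
# compact letter display.  The machinery works from link-scale linear
# predictors and their covariance, so count, proportion and yield models all
# share it.

#' Construct an EMM result from link-scale estimates
#'
#' Internal workhorse: given cell linear predictors, their covariance, a
#' degrees-of-freedom value and an inverse link, produces response-scale
#' estimates with back-transformed t intervals.  The link-scale covariance is
#' retained for [tukey_pairs()].
#'
#' @keywords internal
emm_result <- function(cells, lp, vcov_link, df, linkinv, conf_level = 0.95,
                       link = "log") {
  se <- sqrt(pmax(diag(vcov_link), 0))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  out <- data.frame(cell = cells,
                    estimate = linkinv(lp),
                    lo = linkinv(lp - tq * se),
                    hi = linkinv(lp + tq * se),
                    se_link = se,
                    df = df,
                    stringsAsFactors = FALSE)
  structure(out, class = c("emm_result", "data.frame"),
            lp = stats::setNames(lp, cells), vcov_link = vcov_link,
            link = link, linkinv = linkinv)
}

# rows of the contrast matrix for treatment cells, given indicator columns
# named by factor levels (plus an intercept)
cell_contrast_matrix <- function(cells, colnames_) {
  cp <- split_cell(cells)
  L <- matrix(0, length(cells), length(colnames_),
              dimnames = list(cells, colnames_))
  if ("(Intercept)" %in% colnames_) L[, "(Intercept)"] <- 1
  for (j in setdiff(colnames_, "(Intercept)")) {
    hit <- cp$chemical == j | cp$photoperiod == j | cells == j
    L[hit, j] <- 1
  }
  L
}

#' Estimated marginal means for egg-production fits
#'
#' Cell means on the response (egg) scale with back-transformed link-scale t
#' intervals, using `df = n - p` to respect the small replicate counts.  For
#' a hurdle fit, `type = "unconditional"` multiplies the zero part's positive
#' probability into the zero-truncated count mean (the overall expected egg
#' total), while `type = "conditional"` reports the count part alone (the
#' expected total of an egg-producing container).
#'
#' @param fit An [fit_nb_glm()] or [fit_hurdle_nb()] result.
#' @param cells Character vector of `"chemical:photoperiod"` cells.
#' @param type For hurdle fits, `"unconditional"` (default) or `"conditional"`.
#' @param conf_level Confidence level for the intervals.
#' @return An `emm_result` data frame.
#' @export
emm_counts <- function(fit, cells, type = c("unconditional", "conditional"),
                       conf_level = 0.95) {
  type <- match.arg(type)
  if (inherits(fit, "nb_fit")) {
    check_span(cells, names(fit$coefficients), fit$referent)
    L <- cell_contrast_matrix(cells, names(fit$coefficients))
    lp <- drop(L %*% fit$coefficients)
    V <- L %*% fit$vcov %*% t(L)
    return(emm_result(cells, lp, V, fit$df_residual, exp, conf_level))
  }
  if (!inherits(fit, "hurdle_fit")) stop("unsupported fit class")
  emm_hurdle(fit, cells, type, conf_level)
}

# every non-referent level a cell names must have a design column
check_span <- function(cells, cols, referent) {
  cp <- split_cell(cells)
  for (i in seq_along(cells)) {
    lv <- c(cp$chemical[i], cp$photoperiod[i])
    unknown <- setdiff(lv, c(cols, unname(unlist(referent))))
    if (length(unknown))
      stop("cell '", cells[i], "' is outside the design span (unknown: ",
           paste(unknown, collapse = ", "), ")")
  }
  invisible(TRUE)
}

# delta-method EMM for the hurdle model on the log scale
emm_hurdle <- function(fit, cells, type, conf_level) {
  cz <- names(fit$zero$coefficients)
  cc <- names(fit$count$coefficients)
  check_span(cells, unique(c(cz, cc, fit$design_colnames)), fit$referent)
  Lz <- cell_contrast_matrix(cells, cz)
  Lc <- cell_contrast_matrix(cells, cc)
  theta <- fit$count$theta
  par <- c(fit$zero$coefficients,
           fit$count$coefficients, log_theta = fit$count$log_theta)
  nz <- length(fit$zero$coefficients)
  Vc <- fit$count$vcov  # over (beta, log_theta)
  V <- matrix(0, length(par), length(par))
  V[seq_len(nz), seq_len(nz)] <- fit$zero$vcov
  V[(nz + 1):length(par), (nz + 1):length(par)] <- Vc
  log_emm <- function(p) {
    bz <- p[seq_len(nz)]
    bc <- p[(nz + 1):(length(p) - 1)]
    th <- exp(p[length(p)])
    mu <- exp(drop(Lc %*% bc))
    m <- truncated_nb_mean(mu, th)
    if (type == "unconditional") {
      ppos <- stats::plogis(drop(Lz %*% bz))
      log(ppos * m)
    } else {
      log(m)
    }
  }
  lp <- log_emm(par)
  G <- numeric_jacobian(log_emm, par)
  Vlp <- G %*% V %*% t(G)
  df <- fit$n - length(fit$zero$coefficients)
  emm_result(cells, lp, Vlp, df, exp, conf_level)
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Tukey-adjusted pairwise contrasts with a compact letter display
#'
#' All pairwise link-scale differences between EMM cells, with adjusted
#' p-values from the studentized-range distribution (k cells, the fit's
#' denominator df) and letters assigned by the insert-and-absorb procedure:
#' cells sharing a letter are not significantly different at `alpha`.
#'
#' @param emm An `emm_result` (from [emm_counts()], [emm_props()] or the
#'   yield summary).
#' @param alpha Significance level for the letter display.
#' @return A list with `contrasts` (cell pair, link-scale difference, se, t,
#'   unadjusted and adjusted p) and `letters` (named character per cell).
#' @export
tukey_pairs <- function(emm, alpha = 0.05) {
  lp <- attr(emm, "lp")
  V <- attr(emm, "vcov_link")
  df <- emm$df[1]
  k <- length(lp)
  if (k < 2) stop("need at least two cells")
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- lp[i] - lp[j]
    se <- sqrt(max(V[i, i] + V[j, j] - 2 * V[i, j], 0))
    tval <- if (se > 0) d / se else ifelse(d == 0, 0, sign(d) * Inf)
    p_un <- 2 * stats::pt(-abs(tval), df)
    p_adj <- stats::ptukey(sqrt(2) * abs(tval), nmeans = k, df = df,
                           lower.tail = FALSE)
    data.frame(cell1 = names(lp)[i], cell2 = names(lp)[j],
               diff = d, se = se, t = tval,
               p_unadjusted = p_un, p_adjusted = max(p_adj, p_un),
               stringsAsFactors = FALSE)
  })
  contrasts <- do.call(rbind, rows)
  rownames(contrasts) <- NULL
  letters_map <- cld_letters(names(lp), emm$estimate,
                             contrasts[contrasts$p_adjusted <= alpha,
                                       c("cell1", "cell2")])
  list(contrasts = contrasts, letters = letters_map, alpha = alpha)
}

# insert-and-absorb compact letter display; sig_pairs is a two-column frame
# of cell pairs that must not share a letter
cld_letters <- function(cells, estimates, sig_pairs) {
  ord <- order(-estimates)
  groups <- list(seq_along(cells))
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      i <- match(sig_pairs$cell1[r], cells)
      j <- match(sig_pairs$cell2[r], cells)
      new <- list()
      for (g in groups) {
        if (i %in% g && j %in% g) {
          new <- c(new, list(setdiff(g, i)), list(setdiff(g, j)))
        } else {
          new <- c(new, list(g))
        }
      }
      # absorb: drop duplicates and subsets
      new <- new[lengths(new) > 0]
      new <- unique(lapply(new, sort))
      keep <- vapply(seq_along(new), function(a) {
        !any(vapply(seq_along(new), function(b) {
          a != b && all(new[[a]] %in% new[[b]]) &&
            (length(new[[a]]) < length(new[[b]]) || a > b)
        }, TRUE))
      }, TRUE)
      groups <- new[keep]
    }
  }
  # letter groups ordered by the highest-estimate member
  first <- vapply(groups, function(g) min(match(g, ord)), 1L)
  groups <- groups[order(first)]
  out <- stats::setNames(rep("", length(cells)), cells)
  for (gi in seq_along(groups)) {
    for (m in groups[[gi]]) {
      out[m] <- paste0(out[m], letters[gi])
    }
  }
  out
}
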