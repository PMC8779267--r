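# internal helpers shared across modules

cell_label <- function(chemical, photoperiod) {
  paste(chemical, photoperiod, sep = ":")
}

split_cell <- function(cell) {
  parts <- strsplit(cell, ":", fixed = TRUE)
  data.frame(
    chemical    = vapply(parts, `[`, "", 1L),
    photoperiod = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

#' Derive a reproducible child seed for a pipeline stage
#'
#' A single user-facing seed fans out to per-stage seeds through a fixed
#' linear-congruential step, so any stage can be re-run in isolation and
#' reproduce the run-everything result.  All values stay below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stage Stage name (one of `"survival"`, `"fecundity"`, `"clutches"`,
#'   `"yield"`, `"pipeline"`) or a small integer index.
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  stages <- c(survival = 1L, fecundity = 2L, clutches = 3L,
              yield = 4L, pipeline = 5L)
  k <- if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stages[[stage]]
  } else {
    as.integer(stage)
  }
  # 69069 is a classic LCG multiplier; seed < 2^31 keeps the product exact
  as.integer((((as.double(seed) %% 2147483647) * 69069) %% 2147483642) + k)
}

# FNV-1a over a deparsed object; stable across runs, used for run manifests
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (as.double(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# round floats for CSV output (full precision is kept in JSON artifacts)
sig4 <- function(df, digits = 4) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

# zero-truncated Poisson draws via inverse CDF
rtpois <- function(n, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  lo <- stats::dpois(0, lambda)
  stats::qpois(stats::runif(n, lo, 1), lambda)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("parayield_config_error", "error")))
}
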