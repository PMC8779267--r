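# Synthetic event-table generator.
#
# The generator inverts the analysis models: death times come from the Weibull
# AFT surface, container egg totals from a (hurdle) negative binomial with a
# log link, and clutch outcomes from per-treatment binomials.  With the preset
# parameters the tables carry the same statistical structure the downstream
# fits assume, so every stage is testable without the original raw data.

# linear predictor from a coefficient map keyed by treatment labels
lp_from_coeffs <- function(intercept, coeffs, chemical, photoperiod, design) {
  valid <- c(design$chemicals, design$photoperiods)
  bad <- setdiff(names(coeffs), valid)
  if (length(bad))
    stop_config("unknown treatment label(s) in coefficient map: ",
                paste(bad, collapse = ", "))
  lp <- rep(intercept, length(chemical))
  for (lab in names(coeffs)) {
    lp <- lp + coeffs[[lab]] * (chemical == lab | photoperiod == lab)
  }
  lp
}

container_grid <- function(design, collection) {
  g <- expand.grid(replicate = seq_len(design$containers_per_cell),
                   chemical = design$chemicals,
                   photoperiod = design$photoperiods,
                   stringsAsFactors = FALSE)
  g$collection <- collection
  g$container_id <- sprintf("%s:%s:%s:r%d", collection, g$chemical,
                            g$photoperiod, g$replicate)
  g
}

#' Generate per-insect survival records
#'
#' Each insect's death time is Weibull with log-location
#' `aft_intercept + sum(applicable aft_coeffs)` and shape
#' `1/exp(aft_log_scale)`.  Times beyond the follow-up horizon are recorded as
#' right-censored at the horizon.  Males receive the same AFT surface as
#' females (the analysis stages model females only and drop males at ingest).
#'
#' @param design A [study_design()].
#' @param params A [generator_params()].
#' @param seed Integer seed; identical inputs give identical tables.
#' @param collection Collection label for the generated table.
#' @return A data frame of subject records (`subject_id`, `container_id`,
#'   `sex`, `collection`, `photoperiod`, `chemical`, `time_days`, `event`).
#' @export
generate_survival <- function(design, params, seed = params$seed,
                              collection = attr(params, "collection") %||%
                                design$collections[1]) {
  grid <- container_grid(design, collection)
  n_per <- design$females_per_container + design$males_per_container
  idx <- rep(seq_len(nrow(grid)), each = n_per)
  sex <- rep(c(rep("f", design$females_per_container),
               rep("m", design$males_per_container)), nrow(grid))
  chem <- grid$chemical[idx]
  photo <- grid$photoperiod[idx]
  lp <- lp_from_coeffs(params$aft_intercept, params$aft_coeffs,
                       chem, photo, design)
  sigma <- exp(params$aft_log_scale)
  set.seed(seed)
  t_raw <- stats::rweibull(length(lp), shape = 1 / sigma, scale = exp(lp))
  event <- as.integer(t_raw <= design$followup_days)
  data.frame(
    subject_id = sprintf("%s:%s%03d", grid$container_id[idx], sex,
                         stats::ave(idx, idx, FUN = seq_along)),
    container_id = grid$container_id[idx],
    sex = sex,
    collection = collection,
    photoperiod = photo,
    chemical = chem,
    time_days = pmin(t_raw, design$followup_days),
    event = event,
    stringsAsFactors = FALSE)
}

# split a container total into clutches with iid zero-truncated Poisson sizes;
# the last clutch takes the remainder (always >= 1)
partition_clutches <- function(total, clutch_size_mean) {
  if (total == 0) return(integer())
  sizes <- integer()
  left <- total
  while (left > 0) {
    s <- min(rtpois(1L, clutch_size_mean), left)
    sizes <- c(sizes, s)
    left <- left - s
  }
  sizes
}

#' Generate per-container egg-production records
#'
#' With probability `zero_prob[cell]` a container lays nothing; otherwise its
#' egg total is negative binomial (zero-truncated when any hurdle cell is
#' active) with mean `exp(egg_log_mean_intercept + sum(applicable egg_coeffs))`
#' and dispersion `nb_dispersion`.  Totals are partitioned into clutches of
#' mean size `clutch_size_mean`.  Cumulative female-days come from the
#' supplied survival table when given, otherwise from a fresh draw of the same
#' AFT surface.
#'
#' @inheritParams generate_survival
#' @param subjects Optional survival table (from [generate_survival()]) used
#'   to compute per-container female-days.
#' @param hurdle Logical; `NULL` (default) activates zero truncation whenever
#'   any cell has `zero_prob > 0`.
#' @return A data frame of container records (`container_id`, `collection`,
#'   `photoperiod`, `chemical`, `total_eggs`, `n_clutches`, `female_days`).
#' @export
generate_fecundity <- function(design, params, seed = params$seed,
                               collection = attr(params, "collection") %||%
                                 design$collections[1],
                               subjects = NULL, hurdle = NULL) {
  grid <- container_grid(design, collection)
  cells <- cell_label(grid$chemical, grid$photoperiod)
  bad <- setdiff(names(params$zero_prob),
                 cell_label(rep(design$chemicals, each = length(design$photoperiods)),
                            rep(design$photoperiods, length(design$chemicals))))
  if (length(bad))
    stop_config("zero_prob names are not design cells: ", paste(bad, collapse = ", "))
  zp <- ifelse(cells %in% names(params$zero_prob),
               params$zero_prob[cells], 0)
  if (is.null(hurdle)) hurdle <- any(zp > 0)
  mu <- exp(lp_from_coeffs(params$egg_log_mean_intercept, params$egg_coeffs,
                           grid$chemical, grid$photoperiod, design))
  theta <- params$nb_dispersion
  set.seed(seed)
  zero <- stats::runif(nrow(grid)) < zp
  total <- integer(nrow(grid))
  pos <- which(!zero)
  if (length(pos)) {
    if (hurdle) {
      p0 <- stats::pnbinom(0, size = theta, mu = mu[pos])
      total[pos] <- stats::qnbinom(stats::runif(length(pos), p0, 1),
                                   size = theta, mu = mu[pos])
      total[pos] <- pmax(total[pos], 1L)
    } else {
      total[pos] <- stats::rnbinom(length(pos), size = theta, mu = mu[pos])
    }
  }
  total <- as.integer(total)
  n_clutches <- vapply(total, function(tt)
    length(partition_clutches(tt, params$clutch_size_mean)), 1L)
  if (!is.null(subjects)) {
    f <- subjects[subjects$sex == "f", ]
    fd <- tapply(f$time_days, f$container_id, sum)
    female_days <- as.numeric(fd[grid$container_id])
    female_days[is.na(female_days)] <- 0
  } else {
    lp_s <- lp_from_coeffs(params$aft_intercept, params$aft_coeffs,
                           grid$chemical, grid$photoperiod, design)
    nf <- design$females_per_container
    female_days <- vapply(lp_s, function(l) {
      tt <- stats::rweibull(nf, shape = 1 / exp(params$aft_log_scale),
                            scale = exp(l))
      sum(pmin(tt, design$followup_days))
    }, 0)
  }
  data.frame(container_id = grid$container_id,
             collection = collection,
             photoperiod = grid$photoperiod,
             chemical = grid$chemical,
             total_eggs = total,
             n_clutches = n_clutches,
             female_days = female_days,
             stringsAsFactors = FALSE)
}

#' Generate per-clutch eclosion or emergence outcomes
#'
#' For each assayed clutch, the number of successes is binomial in the clutch
#' size with the cell's outcome probability.  Parasitism clutches are at least
#' 15 eggs (the exposure assay's minimum clutch size); eclosion clutch sizes
#' are zero-truncated Poisson.  Cells absent from the probability map (no eggs
#' produced, hence no assay) yield no clutches.
#'
#' @inheritParams generate_survival
#' @param outcome_type `"host_eclosion"` or `"parasitoid_emergence"`.
#' @param clutches_per_cell Optional named integer overriding the preset
#'   number of clutches per cell.
#' @return A data frame of clutch records (`clutch_id`, `collection`,
#'   `photoperiod`, `chemical`, `n_eggs`, `outcome_type`, `n_success`).
#' @export
generate_clutch_outcomes <- function(design, params, seed = params$seed,
                                     collection = attr(params, "collection") %||%
                                       design$collections[1],
                                     outcome_type = c("host_eclosion",
                                                      "parasitoid_emergence"),
                                     clutches_per_cell = NULL) {
  outcome_type <- match.arg(outcome_type)
  probs <- if (outcome_type == "host_eclosion") params$host_eclosion_prob
           else params$emergence_prob
  all_cells <- cell_label(rep(design$chemicals, each = length(design$photoperiods)),
                          rep(design$photoperiods, length(design$chemicals)))
  bad <- setdiff(names(probs), all_cells)
  if (length(bad))
    stop_config("probability map names are not design cells: ",
                paste(bad, collapse = ", "))
  if (!length(probs)) {
    return(data.frame(clutch_id = character(), collection = character(),
                      photoperiod = character(), chemical = character(),
                      n_eggs = integer(), outcome_type = character(),
                      n_success = integer(), stringsAsFactors = FALSE))
  }
  n_default <- if (outcome_type == "host_eclosion") params$eclosion_clutches
               else params$parasitism_clutches
  if (is.null(clutches_per_cell)) clutches_per_cell <- n_default
  miss <- setdiff(names(probs), names(clutches_per_cell))
  if (length(miss))
    clutches_per_cell[miss] <- if (outcome_type == "host_eclosion") 10L else 14L
  extra <- setdiff(names(clutches_per_cell), names(probs))
  if (length(extra))
    stop_config("no outcome probability for cell(s): ",
                paste(extra, collapse = ", "))
  set.seed(seed)
  min_eggs <- if (outcome_type == "parasitoid_emergence") 15L else 1L
  rows <- lapply(names(probs), function(cell) {
    k <- clutches_per_cell[[cell]]
    if (k < 1L) return(NULL)
    lam <- params$clutch_size_mean
    if (min_eggs > 1L) {
      # truncated Poisson conditioned on >= 15 eggs, via inverse CDF
      lo <- stats::ppois(min_eggs - 1L, lam)
      n_eggs <- as.integer(stats::qpois(stats::runif(k, lo, 1), lam))
    } else {
      n_eggs <- as.integer(rtpois(k, lam))
    }
    cp <- split_cell(cell)
    data.frame(clutch_id = sprintf("%s:%s:%s:k%02d", collection, cell,
                                   substr(outcome_type, 1, 4), seq_len(k)),
               collection = collection,
               photoperiod = cp$photoperiod,
               chemical = cp$chemical,
               n_eggs = n_eggs,
               outcome_type = outcome_type,
               n_success = stats::rbinom(k, n_eggs, probs[[cell]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the full synthetic experiment
#'
#' Runs the three generators for each requested collection with seeds derived
#' from one master seed, coupling female-days in the container table to the
#' survival table.
#'
#' @param design A [study_design()].
#' @param presets Named list of [generator_params()] per collection; defaults
#'   to the built-in calibration for both collections.
#' @param seed Master integer seed.
#' @return A list with data frames `subjects`, `containers`, `clutches`.
#' @export
generate_experiment <- function(design = study_design(),
                                presets = list(august = rearing_preset("august"),
                                               september = rearing_preset("september")),
                                seed = 1L) {
  subjects <- containers <- clutches <- list()
  for (i in seq_along(presets)) {
    coll <- names(presets)[i]
    p <- presets[[i]]
    s_seed <- child_seed(seed + i, "survival")
    subjects[[coll]] <- generate_survival(design, p, seed = s_seed,
                                          collection = coll)
    containers[[coll]] <- generate_fecundity(design, p,
                                             seed = child_seed(seed + i, "fecundity"),
                                             collection = coll,
                                             subjects = subjects[[coll]])
    cl <- list()
    if (length(p$host_eclosion_prob))
      cl$ecl <- generate_clutch_outcomes(design, p,
                                         seed = child_seed(seed + i, "clutches"),
                                         collection = coll,
                                         outcome_type = "host_eclosion")
    if (length(p$emergence_prob))
      cl$par <- generate_clutch_outcomes(design, p,
                                         seed = child_seed(seed + i, "clutches") + 1L,
                                         collection = coll,
                                         outcome_type = "parasitoid_emergence")
    clutches[[coll]] <- if (length(cl)) do.call(rbind, cl) else NULL
  }
  out <- list(subjects = do.call(rbind, subjects),
              containers = do.call(rbind, containers),
              clutches = do.call(rbind, Filter(Negate(is.null), clutches)))
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  out
}

#' Write / read the three event tables as CSV
#'
#' Plain UTF-8 CSV with "." decimals and headers exactly matching the record
#' field names; day indices only, no dates.
#'
#' @param tables List with `subjects`, `containers`, `clutches` data frames.
#' @param dir Directory to write into (created if missing).
#' @return `write_event_tables` returns the file paths invisibly;
#'   `read_event_tables` returns the list of tables.
#' @export
write_event_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             containers = file.path(dir, "containers.csv"),
             clutches = file.path(dir, "clutches.csv"))
  for (nm in names(paths)) {
    if (!is.null(tables[[nm]]))
      utils::write.csv(tables[[nm]], paths[[nm]], row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(paths)
}

#' @rdname write_event_tables
#' @export
read_event_tables <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  list(subjects = rd("subjects.csv"),
       containers = rd("containers.csv"),
       clutches = rd("clutches.csv"))
}
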