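# Pipeline orchestration: ingest or simulate -> survival fits -> count fits
# -> proportion fits -> yield simulation -> report bundle on disk.  One
# master seed fans out to per-stage child seeds (see child_seed()) so any
# stage can be reproduced in isolation.

#' Assemble and validate a pipeline configuration
#'
#' @param input_dir Directory holding `subjects.csv`, `containers.csv`,
#'   `clutches.csv`; mutually exclusive with `synthetic = TRUE`.
#' @param synthetic Generate the event tables from the built-in calibration.
#' @param seed Master seed for generation and simulation.
#' @param hurdle Use the hurdle model when a treatment cell has only zero
#'   counts (default `TRUE`; with `FALSE` the plain NB fit is attempted and
#'   its under-dispersion failure propagates).
#' @param alpha Significance level for letter displays.
#' @param n_draws Monte-Carlo repetitions per treatment for the yield stage.
#' @param referent_cell Referent for yield percent increases.
#' @param design A [study_design()] used when `synthetic = TRUE`.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, synthetic = is.null(input_dir),
                            seed = 1L, hurdle = TRUE, alpha = 0.05,
                            n_draws = 2000L,
                            referent_cell = "acetone:long_day",
                            design = study_design()) {
  if (is.null(input_dir) && !synthetic)
    stop_config("either input_dir or synthetic = TRUE is required")
  if (!is.null(input_dir) && synthetic)
    stop_config("input_dir and synthetic = TRUE are mutually exclusive")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  if (n_draws < 1) stop_config("n_draws must be >= 1")
  structure(list(input_dir = input_dir, synthetic = synthetic,
                 seed = as.integer(seed), hurdle = isTRUE(hurdle),
                 alpha = alpha, n_draws = as.integer(n_draws),
                 referent_cell = referent_cell, design = design),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Expects top-level blocks `design:`, `params:` (analysis options) and
#' `seed:`; all entries optional, falling back to [pipeline_config()]
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  dz <- y$design %||% list()
  design <- do.call(study_design, dz)
  pz <- y$params %||% list()
  pipeline_config(input_dir = pz$input_dir,
                  synthetic = pz$synthetic %||% is.null(pz$input_dir),
                  seed = y$seed %||% 1L,
                  hurdle = pz$hurdle %||% TRUE,
                  alpha = pz$alpha %||% 0.05,
                  n_draws = pz$n_draws %||% 2000L,
                  referent_cell = pz$referent_cell %||% "acetone:long_day",
                  design = design)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
      class = c("parayield_stage_error", class(e)[1], "error")))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic generation (or ingest + validation), the
#' Weibull AFT survival fits with hazard ratios and KM curves per collection,
#' the egg-production fits (hurdle when an all-zero cell is present and
#' `hurdle` is enabled) with EMMs and Tukey letters, the clutch-level
#' eclosion/emergence fits, and the Monte-Carlo yield simulation.  Writes a
#' report bundle of CSV tables plus a JSON yield summary and run manifest.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param out_dir Output directory for the report bundle (created if needed).
#' @return The report bundle, invisibly: a list of fitted objects, summary
#'   tables and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  seed <- config$seed
  design <- config$design

  tables <- stage("data", {
    if (config$synthetic) {
      generate_experiment(design, seed = seed)
    } else {
      read_event_tables(config$input_dir)
    }
  })
  val <- stage("validate", validate_tables(tables$subjects, tables$containers,
                                           tables$clutches, design = design))
  if (any(val$status == "fail"))
    stop(errorCondition(
      paste0("pipeline stage 'validate' failed: ",
             paste(val$detail[val$status == "fail"], collapse = "; ")),
      class = c("parayield_stage_error", "error")))

  collections <- intersect(design$collections, unique(tables$subjects$collection))

  survival_out <- stage("survival", lapply(stats::setNames(collections, collections),
    function(coll) {
      sm <- survival_sample(tables$subjects, collection = coll)
      fit <- fit_weibull_aft(sm)
      grp <- cell_label(sm$data$chemical, sm$data$photoperiod)
      list(fit = fit, lrt = aft_lrt(fit), hr = hazard_ratios(fit),
           km = km_fit(sm, group = grp))
    }))

  counts_out <- stage("counts", lapply(stats::setNames(collections, collections),
    function(coll) {
      cs <- count_sample(tables$containers, collection = coll)
      az <- all_zero_cells(cs)
      if (length(az) && config$hurdle) {
        fit <- fit_hurdle_nb(cs)
        cells <- setdiff(unique(cs$cells), az)
        emm <- emm_counts(fit, cells, type = "conditional")
      } else {
        fit <- fit_nb_glm(cs)  # under-dispersion error surfaces here
        cells <- unique(cs$cells)
        emm <- emm_counts(fit, cells)
      }
      tk <- tukey_pairs(emm, alpha = config$alpha)
      ft <- if (inherits(fit, "nb_fit")) term_f_tests(fit) else NULL
      list(fit = fit, emm = emm, tukey = tk, f_tests = ft,
           dropped = az)
    }))

  props_out <- stage("proportions", {
    out <- list()
    if (!is.null(tables$clutches) && nrow(tables$clutches)) {
      for (ot in unique(tables$clutches$outcome_type)) {
        bs <- binomial_sample(tables$clutches, outcome_type = ot)
        fit <- fit_weighted_logit(bs)
        emm <- emm_props(fit)
        tk <- tukey_pairs(emm, alpha = config$alpha)
        out[[ot]] <- list(fit = fit, emm = emm, tukey = tk)
      }
    }
    out
  })

  yield_out <- stage("yield", {
    if (!is.null(props_out$parasitoid_emergence)) {
      yc <- if ("september" %in% names(counts_out)) "september"
            else collections[length(collections)]
      inputs <- treatment_distributions(counts_out[[yc]]$emm,
                                        props_out$parasitoid_emergence$emm)
      draws <- simulate_yield(inputs, n_draws = config$n_draws,
                              seed = child_seed(seed, "yield"))
      summ <- summarize_yield(draws, referent = config$referent_cell,
                              alpha = config$alpha)
      list(inputs = inputs, draws = draws, summary = summ)
    } else NULL
  })

  manifest <- list(package = "parayield",
                   version = as.character(utils::packageVersion("parayield")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = seed,
                   config_hash = config_hash(unclass(config)[setdiff(names(config), "design")]),
                   stages = c("data", "validate", "survival", "counts",
                              "proportions", "yield"))

  bundle <- list(tables = tables, validation = val, survival = survival_out,
                 counts = counts_out, proportions = props_out,
                 yield = yield_out, manifest = manifest, config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

# serialize the bundle's headline tables; floats at 4 significant digits in
# CSVs, full precision in JSON
write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name) utils::write.csv(sig4(df), file.path(out_dir, name),
                                              row.names = FALSE)
  write_event_tables(bundle$tables, file.path(out_dir, "data"))

  surv_tab <- do.call(rbind, lapply(names(bundle$survival), function(coll) {
    f <- bundle$survival[[coll]]$fit
    est <- c(f$coefficients, log_scale = f$log_scale)
    data.frame(collection = coll, factor = names(est), coefficient = unname(est),
               se = unname(f$se[names(est)]),
               z = unname(est / f$se[names(est)]),
               p = unname(2 * stats::pnorm(-abs(est / f$se[names(est)]))))
  }))
  wcsv(surv_tab, "survival_coefficients.csv")
  hr_tab <- do.call(rbind, lapply(names(bundle$survival), function(coll)
    cbind(collection = coll, bundle$survival[[coll]]$hr)))
  wcsv(hr_tab, "hazard_ratios.csv")
  km_tab <- do.call(rbind, lapply(names(bundle$survival), function(coll) {
    do.call(rbind, lapply(names(bundle$survival[[coll]]$km), function(g) {
      k <- bundle$survival[[coll]]$km[[g]]
      cbind(collection = coll, group = g,
            as.data.frame(k)[, c("time", "survival", "lo", "hi")])
    }))
  }))
  wcsv(km_tab, "km_curves.csv")

  egg_tab <- do.call(rbind, lapply(names(bundle$counts), function(coll) {
    f <- bundle$counts[[coll]]$fit
    if (inherits(f, "nb_fit")) {
      est <- f$coefficients; se <- f$se[names(est)]
    } else {
      est <- f$count$coefficients
      se <- f$count$se[names(est)]
    }
    data.frame(collection = coll, factor = names(est), coefficient = unname(est),
               se = unname(se), z = unname(est / se),
               p = unname(2 * stats::pnorm(-abs(est / se))))
  }))
  wcsv(egg_tab, "egg_coefficients.csv")
  emm_tab <- do.call(rbind, lapply(names(bundle$counts), function(coll) {
    e <- bundle$counts[[coll]]$emm
    lt <- bundle$counts[[coll]]$tukey$letters
    cbind(collection = coll, as.data.frame(e), letter = lt[e$cell])
  }))
  wcsv(emm_tab, "egg_emm.csv")

  if (length(bundle$proportions)) {
    prop_tab <- do.call(rbind, lapply(names(bundle$proportions), function(ot) {
      e <- bundle$proportions[[ot]]$emm
      lt <- bundle$proportions[[ot]]$tukey$letters
      cp <- split_cell(e$cell)
      data.frame(outcome = ot, chemical = cp$chemical,
                 photoperiod = cp$photoperiod,
                 percent = 100 * e$estimate, lo = 100 * e$lo, hi = 100 * e$hi,
                 letter = unname(lt[e$cell]))
    }))
    wcsv(prop_tab, "viability_emm.csv")
  }

  if (!is.null(bundle$yield)) {
    dr <- bundle$yield$draws
    ytab <- data.frame(cell = rep(colnames(dr), each = nrow(dr)),
                       draw = rep(seq_len(nrow(dr)), ncol(dr)),
                       yield = as.vector(dr))
    wcsv(ytab, "yields.csv")
    summ <- bundle$yield$summary
    jsonlite::write_json(
      list(summary = as.data.frame(summ),
           excluded = attr(bundle$yield$inputs, "excluded"),
           referent = attr(summ, "referent")),
      file.path(out_dir, "yield_summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Validate event tables against the data contract
#'
#' Checks every structural invariant of the three tables: positive death
#' times within follow-up, binary event flags, egg totals consistent with
#' clutch counts, female-days within the possible range, clutch successes
#' bounded by clutch size, and the 15-egg minimum for parasitism clutches
#' (a warning, since small clutches are only unusable for exposure, not
#' malformed).
#'
#' @param subjects,containers,clutches Event tables (any may be `NULL`).
#' @param design Optional [study_design()] supplying the follow-up horizon
#'   and container capacity.
#' @return A data frame with `table`, `rule`, `status` (`pass`/`warn`/`fail`)
#'   and `detail`.
#' @export
validate_tables <- function(subjects = NULL, containers = NULL,
                            clutches = NULL, design = NULL) {
  res <- list()
  add <- function(tab, rule, ok, bad_rows = integer(), warn = FALSE) {
    status <- if (ok) "pass" else if (warn) "warn" else "fail"
    detail <- if (ok) "" else paste0(rule,
      if (length(bad_rows)) paste0(" (rows ", paste(utils::head(bad_rows, 5),
                                                    collapse = ", "),
                                   if (length(bad_rows) > 5) ", ..." else "",
                                   ")") else "")
    res[[length(res) + 1]] <<- data.frame(table = tab, rule = rule,
                                          status = status, detail = detail,
                                          stringsAsFactors = FALSE)
  }
  fu <- if (!is.null(design)) design$followup_days else Inf
  if (!is.null(subjects)) {
    bad <- which(!(subjects$time_days > 0))
    add("subjects", "time_days > 0", !length(bad), bad)
    bad <- which(subjects$time_days > fu)
    add("subjects", "time_days <= followup_days", !length(bad), bad)
    bad <- which(!subjects$event %in% c(0L, 1L))
    add("subjects", "event in {0, 1}", !length(bad), bad)
  }
  if (!is.null(containers)) {
    bad <- which((containers$total_eggs == 0) != (containers$n_clutches == 0))
    add("containers", "total_eggs = 0 iff n_clutches = 0", !length(bad), bad)
    bad <- which(containers$total_eggs < 0 | containers$n_clutches < 0)
    add("containers", "non-negative totals", !length(bad), bad)
    if (!is.null(design)) {
      cap <- design$females_per_container * design$followup_days
      bad <- which(containers$female_days > cap + 1e-8)
      add("containers", "female_days within container capacity", !length(bad), bad)
    }
  }
  if (!is.null(clutches) && nrow(clutches)) {
    bad <- which(clutches$n_success > clutches$n_eggs)
    add("clutches", "n_success <= n_eggs", !length(bad), bad)
    bad <- which(clutches$n_eggs < 1 | clutches$n_success < 0)
    add("clutches", "positive clutch size, non-negative successes",
        !length(bad), bad)
    par <- clutches$outcome_type == "parasitoid_emergence"
    bad <- which(par & clutches$n_eggs < 15)
    add("clutches", "parasitism clutches have >= 15 eggs", !length(bad), bad,
        warn = TRUE)
  }
  do.call(rbind, res)
}
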