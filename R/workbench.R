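#' Per-participant common-metric d' table
#'
#' Objective and subjective sensitivity per participant for the
#' multiple-task and visibility blocks, in long format, ready for the 2x2
#' Bayesian repeated-measures ANOVA ([rm_anova_bf()], factors block and
#' d'-type) and the between-measure correlations ([jeffreys_corr_bf()]).
#'
#' @param cohort trial-level data.frame containing both blocks.
#' @return data.frame: `participant`, `block`, `type`
#'   (`objective`/`subjective`), `d_prime`.
#' @export
common_dprime_table <- function(cohort) {
  blocks <- c("multiple", "visibility")
  if (!all(blocks %in% cohort$block))
    stop("cohort must contain the multiple-task and visibility blocks")
  rows <- list()
  for (b in blocks) for (m in c("objective", "subjective")) {
    tab <- sdt_by_participant(cohort, b, m)
    rows[[paste(b, m)]] <- data.frame(participant = tab$participant,
                                      block = b, type = m,
                                      d_prime = tab$d_prime)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes, for a simulated or supplied cohort, the block-wise analysis
#' battery: congruency Bayes-factor tests (all trials and, in the
#' multiple-task block, PAS-1 trials only), one-sample Bayes tests of mean
#' objective d' against chance, the measurement-error regression predicting
#' priming at zero awareness, the GRT model family with SvA curves for the
#' multiple-task and visibility blocks, and the common-d' comparison (2x2
#' ANOVA + correlations). Stages whose blocks are absent are skipped; a
#' stage failure is recorded in the report and dependent stages are
#' skipped.
#'
#' @param config list with either `trials` (a trial-level data.frame) or
#'   `spec` + `params` (passed to [simulate_experiment()]); optional
#'   elements `seed` (default 1), `grt` (list: `fit_all` logical, default
#'   FALSE fits only the most constrained and full templates; `restarts`;
#'   `n_boot`, default 0 = no bootstrap bands), `regression` (sampler
#'   overrides for [fit_me_regression()]).
#' @return an `analysis_report` list; see [write_report_json()].
#' @export
run_pipeline <- function(config) {
  seed <- if (is.null(config$seed)) 1L else config$seed
  trials <- config$trials
  if (is.null(trials)) {
    if (is.null(config$spec) || is.null(config$params))
      stop("config must name either trials or spec + params")
    trials <- simulate_experiment(config$spec, config$params)
  }
  report <- list(provenance = list(seed = seed, n_participants =
                                     length(unique(trials$participant)),
                                   blocks = unique(trials$block),
                                   package_version =
                                     as.character(utils::packageVersion("awarekit"))),
                 stages = list())
  excl <- tryCatch(exclusion_flags(trials), error = function(e) NULL)
  report$exclusions <- excl
  keep <- if (!is.null(excl)) excl$participant[!excl$excluded] else
    unique(trials$participant)
  trials <- trials[trials$participant %in% keep, , drop = FALSE]

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      list(.failed = TRUE, error = conditionMessage(e))
    })
    report$stages[[name]] <<- res
    res
  }
  effects_by_block <- function(block, pas1_only = FALSE) {
    ids <- sort(unique(trials$participant))
    rows <- lapply(ids, function(id) {
      tr <- trials[trials$participant == id & trials$block == block, , drop = FALSE]
      if (pas1_only) tr <- select_pas1(tr)
      tr <- trim_rts(tr, for_rt_analysis = TRUE)$trials
      cbind(participant = id, congruency_effect(tr))
    })
    do.call(rbind, rows)
  }

  blocks <- unique(trials$block)
  for (b in intersect(c("single", "multiple"), blocks)) {
    stage(paste0("priming_", b), {
      eff <- effects_by_block(b)
      bf <- jzs_ttest_bf(eff$effect_ms)
      list(mean_effect_ms = mean(eff$effect_ms), bf10 = bf$bf10,
           error_pct = bf$error_pct, n = nrow(eff))
    })
  }
  if ("multiple" %in% blocks) {
    stage("priming_multiple_pas1", {
      eff <- effects_by_block("multiple", pas1_only = TRUE)
      bf <- jzs_ttest_bf(eff$effect_ms)
      list(mean_effect_ms = mean(eff$effect_ms), bf10 = bf$bf10, n = nrow(eff))
    })
  }
  for (b in intersect(c("multiple", "visibility"), blocks)) {
    stage(paste0("dprime_obj_", b), {
      d <- sdt_by_participant(trials, b, "objective")
      bf <- jzs_ttest_bf(d$d_prime)
      list(mean_dprime = mean(d$d_prime), bf10 = bf$bf10, n = nrow(d))
    })
  }
  # regression: single-task effects vs offline awareness; multiple-task
  # effects vs the online forced-choice when available
  reg_cfg <- if (is.null(config$regression)) list() else config$regression
  if (all(c("single", "visibility") %in% blocks)) {
    stage("regression_single", {
      inp <- me_regression_input(trials, "single", "visibility")
      fit <- fit_me_regression(inp, sampler = utils::modifyList(
        list(seed = seed), reg_cfg))
      fit[c("intercept_mean_ms", "intercept_ci95", "slope_mean",
            "bf10_intercept", "rhat_max")]
    })
  }
  if ("multiple" %in% blocks) {
    stage("regression_multiple", {
      inp <- me_regression_input(trials, "multiple", "multiple")
      fit <- fit_me_regression(inp, sampler = utils::modifyList(
        list(seed = seed + 1L), reg_cfg))
      fit[c("intercept_mean_ms", "intercept_ci95", "slope_mean",
            "bf10_intercept", "rhat_max")]
    })
  }
  grt_cfg <- utils::modifyList(list(fit_all = FALSE, restarts = 2L, n_boot = 0L),
                               if (is.null(config$grt)) list() else config$grt)
  for (b in intersect(c("multiple", "visibility"), blocks)) {
    stage(paste0("grt_", b), {
      cnt <- grt_counts_from_trials(trials, b)
      fits <- if (grt_cfg$fit_all) {
        fit_all_grt_models(cnt, restarts = grt_cfg$restarts, rng = seed)
      } else {
        lapply(list(grt_model_spec(TRUE, TRUE, TRUE, TRUE), grt_model_spec()),
               function(t) fit_grt_wind(cnt, t, restarts = grt_cfg$restarts,
                                        rng = seed))
      }
      best <- select_model(fits)
      curve <- if (grt_cfg$n_boot >= 2)
        bootstrap_sva(best, cnt, n_boot = grt_cfg$n_boot, rng = seed)
      else sva_curve(best)
      d_at_crit <- if (is.finite(curve$ideal_criterion))
        conditional_dprime(best$spec, curve$ideal_criterion) else NA_real_
      list(selected_constraints = names(best$flags)[best$flags],
           aic = best$aic, pct_accounted = best$pct_accounted,
           ideal_criterion = curve$ideal_criterion,
           d_cond_at_criterion = d_at_crit,
           curve = curve)
    })
  }
  if (all(c("multiple", "visibility") %in% blocks)) {
    stage("common_dprime", {
      tab <- common_dprime_table(trials)
      an <- rm_anova_bf(tab, value = "d_prime", participant = "participant",
                        factor_a = "block", factor_b = "type")
      pick <- function(b, m) tab$d_prime[tab$block == b & tab$type == m]
      corrs <- list(
        within_multiple = jeffreys_corr_bf(pick("multiple", "objective"),
                                           pick("multiple", "subjective")),
        within_visibility = jeffreys_corr_bf(pick("visibility", "objective"),
                                             pick("visibility", "subjective")),
        objective_across = jeffreys_corr_bf(pick("multiple", "objective"),
                                            pick("visibility", "objective")),
        subjective_across = jeffreys_corr_bf(pick("multiple", "subjective"),
                                             pick("visibility", "subjective")))
      list(anova_bf_incl = an$bf_incl, anova_model_bf10 = an$model_bf10,
           correlations = lapply(corrs, function(cc)
             list(bf10 = cc$bf10, r = cc$r)),
           table = tab)
    })
  }
  class(report) <- "analysis_report"
  report
}

#' Write an analysis report as JSON
#'
#' Serializes the report (dropping non-scalar curve objects) and checks it
#' against the structural schema shipped in
#' `inst/extdata/report-schema.json`.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  slim <- report
  for (nm in names(slim$stages)) {
    slim$stages[[nm]]$curve <- NULL
    slim$stages[[nm]]$table <- NULL
  }
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}

#' Validate a report's structure
#'
#' Checks the presence and types of required top-level fields against the
#' shipped schema.
#'
#' @param report an `analysis_report` (or a list parsed from its JSON).
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "awarekit"))
  for (fld in names(schema$required)) {
    if (is.null(report[[fld]]))
      stop("report is missing required field '", fld, "'")
  }
  if (!is.list(report$stages)) stop("'stages' must be a mapping")
  invisible(TRUE)
}
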