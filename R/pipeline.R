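# Full-pipeline runner: design -> cohort -> fits -> selection -> group stats.

design_keys <- c("n_trials", "tau_table", "payoff_min", "payoff_max",
                 "payoff_step", "max_abs_corr", "max_tries")
estimation_keys <- c("model", "method", "n_folds", "n_repeats", "selection",
                     "resample")
group_keys <- c("regression", "mediation", "n_boot", "standardize",
                "include_main_sex", "questionnaire_method")

merge_section <- function(defaults, user, section) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop_fmt("unknown %s key(s): %s", section,
             paste(unknown, collapse = ", "))
  }
  defaults[names(user)] <- user
  defaults
}

#' Assemble a full-pipeline configuration
#'
#' Bundles the per-stage settings (design generation, cohort simulation,
#' estimation/model selection, group inference) with one master seed that
#' is fanned out deterministically to the stages, so a configuration plus
#' seed fully determines every pipeline output. Unknown keys in any
#' section are rejected.
#'
#' @param seed Master seed (integer).
#' @param design Named list of [generate_design()] settings.
#' @param cohort A [cohort_config()].
#' @param estimation Named list: \code{model} (fit model name),
#'   \code{method}, \code{n_folds}, \code{n_repeats}, \code{selection}
#'   (run cohort model selection), \code{resample}.
#' @param group Named list: \code{regression} (run the covariate-by-sex
#'   regression), \code{mediation}, \code{n_boot}, \code{standardize},
#'   \code{include_main_sex}, \code{questionnaire_method}.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1L,
                            design = list(),
                            cohort = cohort_config(),
                            estimation = list(),
                            group = list()) {
  stopifnot(is_count(seed), inherits(cohort, "cohort_config"))
  design_defaults <- list(n_trials = 45L, tau_table = canonical_tau_table(),
                          payoff_min = 100L, payoff_max = 1000L,
                          payoff_step = 10L, max_abs_corr = 0.30,
                          max_tries = 1000L)
  est_defaults <- list(model = "RwGuIq", method = "firth", n_folds = 3L,
                       n_repeats = 500L, selection = TRUE,
                       resample = "partition")
  group_defaults <- list(regression = TRUE, mediation = TRUE,
                         n_boot = 10000L, standardize = TRUE,
                         include_main_sex = FALSE,
                         questionnaire_method = "pearson")
  structure(list(
    seed = as.integer(seed),
    design = merge_section(design_defaults, design, "design"),
    cohort = cohort,
    estimation = merge_section(est_defaults, estimation, "estimation"),
    group = merge_section(group_defaults, group, "group")
  ), class = "pipeline_config")
}

#' Small demonstration configuration
#'
#' Twelve participants, the canonical 45-trial design, 50 cross-validation
#' repeats, a reduced bootstrap, and no covariate regression (12
#' participants cannot identify the 22-coefficient model); completes in
#' well under two minutes and exercises every stage.
#'
#' @param seed Master seed.
#' @return A \code{pipeline_config}.
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(seed = seed,
                  cohort = cohort_config(n_per_sex = 6L),
                  estimation = list(n_repeats = 50L),
                  group = list(regression = FALSE, n_boot = 1000L))
}

#' Read and write pipeline configurations as YAML
#'
#' @param config A \code{pipeline_config}.
#' @param path File path.
#' @return \code{read_pipeline_config} returns a \code{pipeline_config};
#'   \code{write_pipeline_config} returns \code{path} invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(seed = config$seed,
              design = as.list(config$design),
              cohort = unclass(config$cohort),
              estimation = config$estimation,
              group = config$group)
  out$design$tau_table <- as.list(config$design$tau_table)
  out$cohort$covariates <- as.list(config$cohort$covariates)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw),
                     c("seed", "design", "cohort", "estimation", "group"))
  if (length(unknown) > 0) {
    stop_fmt("unknown top-level config key(s): %s",
             paste(unknown, collapse = ", "))
  }
  design <- raw$design %||% list()
  if (!is.null(design$tau_table)) {
    design$tau_table <- unlist(design$tau_table)
  }
  cohort_args <- raw$cohort %||% list()
  if (!is.null(cohort_args$covariates)) {
    cohort_args$covariates <- as.data.frame(cohort_args$covariates)
  }
  cohort_args$n_per_sex <- cohort_args$n_per_sex %||% 26L
  pipeline_config(seed = raw$seed %||% 1L,
                  design = design,
                  cohort = do.call(cohort_config, cohort_args),
                  estimation = raw$estimation %||% list(),
                  group = raw$group %||% list())
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains design generation, cohort simulation, per-participant fitting,
#' model selection, and group inference, writing every stage artifact into
#' \code{out_dir}: \code{design.csv}, \code{cohort_choices.csv} and
#' \code{cohort_covariates.csv}, \code{fits.csv}, \code{selection.json},
#' \code{group.json}, a run log (\code{log.txt}) recording the derived
#' per-stage seeds, and an MD5 \code{MANIFEST.txt}. Reruns with the same
#' configuration produce byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage progress.
#' @return Invisibly, a \code{pipeline_run} list with the stage objects
#'   and artifact paths.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- vapply(1:4, function(k) derive_seed(config$seed, k), numeric(1))
  names(seeds) <- c("design", "cohort", "estimation", "group")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  say("stage design (seed %d)", seeds[["design"]])
  design <- stage("design", do.call(generate_design,
                                    c(config$design, list(seed = seeds[["design"]]))))
  write_design(design, file.path(out_dir, "design.csv"))

  say("stage cohort (seed %d)", seeds[["cohort"]])
  cohort <- stage("cohort",
                  simulate_cohort(design, config$cohort,
                                  seed = seeds[["cohort"]]))
  write_cohort(cohort, file.path(out_dir, "cohort"))

  say("stage estimation (seed %d)", seeds[["estimation"]])
  est <- config$estimation
  fits <- stage("estimation",
                fit_cohort(cohort$choices, design, est$model,
                           method = est$method, pooled = TRUE))
  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE,
                   quote = FALSE)
  selection <- NULL
  if (isTRUE(est$selection)) {
    selection <- stage("estimation",
                       cohort_model_select(cohort$choices, design,
                                           n_folds = est$n_folds,
                                           n_repeats = est$n_repeats,
                                           method = est$method,
                                           resample = est$resample,
                                           seed = seeds[["estimation"]]))
    write_json_file(list(
      table = selection$table,
      best_by_mean_pred_nll = selection$best_cv,
      best_by_mean_bic = selection$best_bic,
      cv_winners = as.list(selection$cv_winners),
      bic_winners = as.list(selection$bic_winners),
      n_folds = selection$n_folds, n_repeats = selection$n_repeats
    ), file.path(out_dir, "selection.json"))
  }

  say("stage group (seed %d)", seeds[["group"]])
  part <- cohort$participants
  ind <- fits[fits$pid != "pooled", ]
  ind <- ind[match(part$pid, ind$pid), ]
  group <- stage("group", {
    res <- list()
    male <- part$sex == "male"
    res$welch_guilt <- welch_test(ind$beta_guilt[male],
                                  ind$beta_guilt[!male])
    res$welch_inequity <- welch_test(ind$beta_inequity[!male],
                                     ind$beta_inequity[male])
    res$questionnaire <- questionnaire_correlation(
      ind$beta_guilt, part[c("q_a", "q_b", "q_c")],
      method = config$group$questionnaire_method)
    if (isTRUE(config$group$regression)) {
      reg <- interaction_regression(
        part, ind$beta_guilt,
        include_main_sex = config$group$include_main_sex,
        standardize = config$group$standardize)
      res$regression <- list(coefficients = reg$coefficients,
                             adj_r2 = reg$adj_r2, n_obs = reg$n_obs,
                             n_dropped = reg$n_dropped)
    }
    if (isTRUE(config$group$mediation)) {
      med <- mediate(as.numeric(male), part$mediator, ind$beta_guilt,
                     n_boot = config$group$n_boot,
                     seed = seeds[["group"]])
      res$mediation <- list(
        a = med$path_a, b = med$path_b, c = med$path_c,
        c_prime = med$path_c_prime,
        indirect = list(estimate = med$indirect$estimate,
                        ci_lower = med$indirect$ci[1],
                        ci_upper = med$indirect$ci[2],
                        p = med$indirect$p),
        three_test_significant = med$three_test_significant,
        complete_mediation = med$complete_mediation)
    }
    res
  })
  write_json_file(group, file.path(out_dir, "group.json"))

  log_lines <- c(
    "trustgame pipeline run",
    sprintf("package version: %s",
            as.character(utils::packageVersion("trustgame"))),
    sprintf("master seed: %d", config$seed),
    sprintf("stage seeds: %s",
            paste(sprintf("%s=%d", names(seeds), seeds), collapse = " ")),
    sprintf("design: %d trials, max |r| threshold %.2f",
            config$design$n_trials, config$design$max_abs_corr),
    sprintf("cohort: %d participants per sex", config$cohort$n_per_sex),
    sprintf("estimation: model %s, %s, %d x %d-fold CV, selection = %s",
            est$model, est$method, est$n_repeats, est$n_folds,
            est$selection),
    sprintf("group: regression = %s, mediation = %s (%d bootstrap)",
            config$group$regression, config$group$mediation,
            config$group$n_boot)
  )
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  artifacts <- c("design.csv", "cohort_choices.csv", "cohort_covariates.csv",
                 "fits.csv", "group.json", "log.txt")
  if (!is.null(selection)) artifacts <- append(artifacts, "selection.json",
                                               after = 4L)
  sums <- tools::md5sum(file.path(out_dir, artifacts))
  writeLines(sprintf("%s  %s", unname(sums), artifacts),
             file.path(out_dir, "MANIFEST.txt"))

  invisible(structure(list(out_dir = out_dir, config = config,
                           seeds = seeds, design = design, cohort = cohort,
                           fits = fits, selection = selection,
                           group = group,
                           artifacts = file.path(out_dir,
                                                 c(artifacts, "MANIFEST.txt"))),
                      class = "pipeline_run"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run in %s (master seed %d)\n", x$out_dir,
              x$config$seed))
  cat("artifacts:\n")
  cat(paste0("  ", basename(x$artifacts), collapse = "\n"), "\n")
  if (!is.null(x$selection)) {
    cat(sprintf("best model: %s (CV), %s (BIC)\n", x$selection$best_cv,
                x$selection$best_bic))
  }
  w <- x$group$welch_guilt
  cat(sprintf("Welch contrast on beta(Guilt), men - women: t(%.1f) = %.2f, p = %.4f\n",
              w$df, w$statistic, w$p_value))
  invisible(x)
}
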