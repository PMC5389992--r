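#' Configuration for the full synthetic-study pipeline
#'
#' Bundles every knob the pipeline needs: the task design, the
#' learning-rate/RT coupling, the group-level truth used to draw synthetic
#' subjects, the priors, the sampler settings and the master seed. The
#' defaults describe the reference study: 20 subjects whose probit-scale
#' parameters scatter (SD 0.5) around group means matching learning rates
#' of 0.12/0.11 and an inverse temperature of 4.65.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param group_means_natural Named vector `alpha_high, alpha_low, beta` on
#'   the natural scale; converted to probit-scale group means.
#' @param group_sds_probit Probit-scale between-subject SDs (length 3).
#' @param design A [task_design()].
#' @param coupling A [coupling_spec()].
#' @param priors A [prior_spec()].
#' @param sampler List with `n_chains`, `n_warmup`, `n_samples`, `thin`.
#' @param capture_fit_scope Which fit feeds the capture correlations
#'   (`"AB_only"`, as in the reference analysis, or `"all_pairs"`).
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 20L,
                            group_means_natural = c(alpha_high = 0.12,
                                                    alpha_low = 0.11,
                                                    beta = 4.65),
                            group_sds_probit = c(0.5, 0.5, 0.5),
                            design = task_design(),
                            coupling = coupling_spec(),
                            priors = prior_spec(),
                            sampler = list(n_chains = 2L, n_warmup = 500L,
                                           n_samples = 500L, thin = 12L),
                            capture_fit_scope = "AB_only",
                            seed = 1L) {
  stopifnot(inherits(design, "task_design"), inherits(coupling, "coupling_spec"),
            inherits(priors, "prior_spec"))
  gm <- group_means_natural
  if (!all(c("alpha_high", "alpha_low", "beta") %in% names(gm))) {
    stop("group_means_natural must name alpha_high, alpha_low, beta", call. = FALSE)
  }
  if (length(group_sds_probit) != 3L || any(group_sds_probit <= 0)) {
    stop("group_sds_probit must be 3 positive numbers", call. = FALSE)
  }
  if (!capture_fit_scope %in% c("AB_only", "all_pairs")) {
    stop("capture_fit_scope must be AB_only or all_pairs", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  structure(list(
    n_subjects = n_subjects,
    group_means_natural = gm,
    group_means_probit = c(probit_inverse(gm[["alpha_high"]], "alpha"),
                           probit_inverse(gm[["alpha_low"]], "alpha"),
                           probit_inverse(gm[["beta"]], "beta")),
    group_sds_probit = group_sds_probit,
    design = design,
    coupling = coupling,
    priors = priors,
    sampler = sampler,
    capture_fit_scope = capture_fit_scope,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

config_as_list <- function(config) {
  rapply(unclass(config), function(x) x, how = "replace")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config_as_list(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

artifact_paths <- function(out_dir) {
  file.path(out_dir, c(
    config = "config.json",
    learning = "learning_trials.csv",
    capture = "capture_trials.csv",
    true_params = "true_params.json",
    exclusion = "exclusion.json",
    comparison = "comparison.json",
    curves = "curves.csv",
    capture_report = "capture_report.json",
    inputs_csv = "correlation_inputs.csv"
  )) |> stats::setNames(c("config", "learning", "capture", "true_params",
                          "exclusion", "comparison", "curves",
                          "capture_report", "inputs_csv"))
}

fit_paths <- function(out_dir, scope, rates) {
  base <- sprintf("fit_%s_%da", if (scope == "AB_only") "ab" else "all", rates)
  list(csv = file.path(out_dir, paste0(base, "_draws.csv")),
       json = file.path(out_dir, paste0(base, "_summary.json")))
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing artifact ", basename(path), "; run stage '", produced_by,
         "' first", call. = FALSE)
  }
  path
}

#' Run one pipeline stage (or the whole chain)
#'
#' Stages: `simulate` writes the two trial CSVs and the ground-truth
#' parameter sidecar; `fit` runs the hierarchical fits (dual- and
#' single-rate, AB-only and all-pairs scopes) and persists draws plus
#' summaries; `compare` writes the BIC comparison; `ppc` the
#' posterior-predictive learning curves; `capture` the chance-performer
#' exclusion and the correlation battery; `all` runs the full chain.
#' Every JSON artifact records the config hash and master seed.
#'
#' @param stage One of `"simulate"`, `"fit"`, `"compare"`, `"ppc"`,
#'   `"capture"`, `"all"`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a character vector of artifact paths written.
#' @export
run_stage <- function(stage = c("all", "simulate", "fit", "compare", "ppc",
                                "capture"),
                      config = pipeline_config(), out_dir) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- artifact_paths(out_dir)
  hash <- config_hash(config)
  stamp <- list(config_md5 = hash, seed = config$seed)
  written <- character(0)
  jsonlite::write_json(c(config_as_list(config), stamp), paths[["config"]],
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  if (stage %in% c("simulate", "all")) {
    params <- draw_subject_params(config$group_means_probit,
                                  config$group_sds_probit,
                                  config$n_subjects, seed = config$seed)
    learning <- simulate_learning_task(params, config$design,
                                       seed = config$seed + 1000L)
    capture <- simulate_capture_task(params, config$design, config$coupling,
                                     seed = config$seed + 2000L)
    write_learning_trials(learning, paths[["learning"]])
    write_capture_trials(capture, paths[["capture"]])
    jsonlite::write_json(c(list(params = params), stamp),
                         paths[["true_params"]], auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    written <- c(written, paths[c("learning", "capture", "true_params")])
  }

  if (stage %in% c("fit", "all")) {
    learning <- read_learning_trials(
      require_artifact(paths[["learning"]], "simulate"))
    for (scope in c("AB_only", "all_pairs")) {
      for (rates in c(2L, 1L)) {
        fit <- run_sampler(
          learning, config$priors,
          model_spec(n_learning_rates = rates, fit_scope = scope),
          n_chains = config$sampler$n_chains,
          n_warmup = config$sampler$n_warmup,
          n_samples = config$sampler$n_samples,
          thin = config$sampler$thin,
          seed = config$seed + 100L * rates + if (scope == "AB_only") 10L else 20L
        )
        fp <- fit_paths(out_dir, scope, rates)
        write_fit(fit, fp$csv, fp$json)
        saveRDS(fit, sub("\\.csv$", ".rds", fp$csv))
        written <- c(written, fp$csv, fp$json)
      }
    }
  }

  load_fit <- function(scope, rates) {
    fp <- fit_paths(out_dir, scope, rates)
    readRDS(require_artifact(sub("\\.csv$", ".rds", fp$csv), "fit"))
  }

  if (stage %in% c("compare", "all")) {
    learning <- read_learning_trials(
      require_artifact(paths[["learning"]], "simulate"))
    cmp <- compare_models(learning,
                          load_fit("all_pairs", 2L), load_fit("all_pairs", 1L))
    jsonlite::write_json(
      c(list(bic_group_2alpha = cmp$bic_group_2alpha,
             bic_group_1alpha = cmp$bic_group_1alpha,
             bic_individual_mean_2alpha = cmp$bic_individual_mean_2alpha,
             bic_individual_mean_1alpha = cmp$bic_individual_mean_1alpha,
             preferred = cmp$preferred), stamp),
      paths[["comparison"]], auto_unbox = TRUE, digits = NA)
    written <- c(written, paths[["comparison"]])
  }

  if (stage %in% c("ppc", "all")) {
    learning <- read_learning_trials(
      require_artifact(paths[["learning"]], "simulate"))
    fit <- load_fit("AB_only", 2L)
    ab_design <- task_design(pairs = "AB",
                             high_reward_prob = c(AB = config$design$high_reward_prob[["AB"]]),
                             trials_per_pair = config$design$trials_per_pair,
                             n_blocks = config$design$n_blocks)
    ppc <- posterior_predictive_curves(fit, learning, ab_design,
                                       n_reps = 50L, seed = config$seed + 3000L)
    utils::write.csv(ppc$curves, paths[["curves"]], row.names = FALSE)
    written <- c(written, paths[["curves"]])
  }

  if (stage %in% c("capture", "all")) {
    learning <- read_learning_trials(
      require_artifact(paths[["learning"]], "simulate"))
    capture <- read_capture_trials(
      require_artifact(paths[["capture"]], "simulate"))
    excl <- exclude_chance_performers(learning, config$design)
    fit <- load_fit(config$capture_fit_scope, 2L)
    keep <- excl$retained
    cs <- condition_means(capture[capture$subject_id %in% keep, ])
    inputs <- correlation_inputs(fit, cs,
                                 learning[learning$subject_id %in% keep, ])
    report <- capture_learning_report(inputs)
    utils::write.csv(inputs, paths[["inputs_csv"]], row.names = FALSE)
    jsonlite::write_json(c(list(exclusion = excl$report), stamp),
                         paths[["exclusion"]], auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    jsonlite::write_json(c(unclass(report), stamp), paths[["capture_report"]],
                         auto_unbox = TRUE, digits = NA)
    written <- c(written,
                 paths[c("exclusion", "inputs_csv", "capture_report")])
  }

  invisible(unname(c(paths[["config"]], written)))
}

#' Run the full pipeline
#'
#' Convenience wrapper for `run_stage("all", ...)`: simulate both tasks,
#' filter chance performers, fit the dual- and single-rate models under
#' both fit scopes, compare them by BIC, simulate posterior-predictive
#' learning curves and produce the capture correlation report.
#'
#' @inheritParams run_stage
#' @return Invisibly, the artifact paths written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  run_stage("all", config, out_dir)
}
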