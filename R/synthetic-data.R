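#' Draw subject parameters from group-level normal distributions
#'
#' Each subject's probit-scale parameter vector z' = (z_alpha_high,
#' z_alpha_low, z_beta) is sampled independently from
#' Normal(`group_means_probit`, `group_sds_probit`); natural-scale
#' parameters follow through the probit link (learning rates Phi(z'),
#' inverse temperature 100 * Phi(z')).
#'
#' @param group_means_probit Numeric vector of 3 probit-scale means, ordered
#'   (alpha_high, alpha_low, beta).
#' @param group_sds_probit Numeric vector of 3 positive probit-scale SDs.
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed.
#' @return Data frame with one row per subject: `subject_id`, natural-scale
#'   `alpha_high`, `alpha_low`, `beta`, and probit-scale `z_alpha_high`,
#'   `z_alpha_low`, `z_beta`.
#' @export
draw_subject_params <- function(group_means_probit, group_sds_probit,
                                n_subjects, seed = 1L) {
  stopifnot(length(group_means_probit) == 3L, length(group_sds_probit) == 3L)
  if (any(group_sds_probit <= 0)) {
    stop("group_sds_probit must be strictly positive", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  set.seed(seed)
  z <- matrix(stats::rnorm(3L * n_subjects,
                           mean = rep(group_means_probit, each = n_subjects),
                           sd = rep(group_sds_probit, each = n_subjects)),
              nrow = n_subjects)
  data.frame(
    subject_id = sprintf("s%02d", seq_len(n_subjects)),
    alpha_high = probit_link(z[, 1], "alpha"),
    alpha_low = probit_link(z[, 2], "alpha"),
    beta = probit_link(z[, 3], "beta"),
    z_alpha_high = z[, 1],
    z_alpha_low = z[, 2],
    z_beta = z[, 3],
    stringsAsFactors = FALSE
  )
}

params_row_to_subject <- function(params, i) {
  subject_params(z_probit = c(params$z_alpha_high[i],
                              params$z_alpha_low[i],
                              params$z_beta[i]))
}

#' Simulate the value-based learning task for a group of subjects
#'
#' For every subject the three stimulus pairs are interleaved in randomized
#' order within equal-composition blocks; on each trial the agent chooses by
#' the softmax rule, the reward is Bernoulli from the chosen stimulus's
#' schedule (e.g. A pays the high reward with probability 0.8, B with 0.2),
#' and only the chosen stimulus's expected value is updated. Subject i uses
#' seed `seed + i - 1`, so a single subject's table can be reproduced with
#' [simulate_agent_choices()].
#'
#' @param params Parameter table from [draw_subject_params()] (or any data
#'   frame with the same columns).
#' @param design A [task_design()].
#' @param seed Integer master seed.
#' @param spec A [model_spec()]; supplies the initial Q-value.
#' @return Learning-trial data frame, `nrow = n_subjects * n_pairs *
#'   trials_per_pair`.
#' @export
simulate_learning_task <- function(params, design = task_design(), seed = 1L,
                                   spec = model_spec()) {
  if (is.null(nrow(params)) || nrow(params) < 1L) {
    stop("params must contain at least one subject", call. = FALSE)
  }
  out <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    out[[i]] <- simulate_agent_choices(
      params_row_to_subject(params, i), design, spec,
      seed = seed + i - 1L, subject_id = params$subject_id[i]
    )
  }
  do.call(rbind, out)
}

#' Simulate the attentional-capture task
#'
#' Allocates `capture_trials` per subject across the distractor conditions
#' (`none`, `high`, `low`) in the proportions the design specifies, shuffled
#' over trials. RTs are Normal(`baseline_rt_ms`, `rt_noise_sd_ms`); trials
#' with a high-value-color distractor are slowed by `slowing_slope_high *
#' alpha_high` ms and low-value-color trials by `slowing_slope_low *
#' alpha_low` ms. RTs are truncated below at 1 ms and correctness is
#' Bernoulli(1 - `error_rate`).
#'
#' @inheritParams simulate_learning_task
#' @param coupling A [coupling_spec()].
#' @return Capture-trial data frame with columns `subject_id, trial_index,
#'   condition, correct, rt_ms`.
#' @export
simulate_capture_task <- function(params, design = task_design(),
                                  coupling = coupling_spec(), seed = 1L) {
  if (is.null(nrow(params)) || nrow(params) < 1L) {
    stop("params must contain at least one subject", call. = FALSE)
  }
  fr <- design$capture_condition_fractions
  counts <- round(fr * design$capture_trials)
  out <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    set.seed(seed + i - 1L)
    cond <- sample(rep(names(counts), counts))
    shift <- ifelse(cond == "high",
                    coupling$slowing_slope_high * params$alpha_high[i],
                    ifelse(cond == "low",
                           coupling$slowing_slope_low * params$alpha_low[i], 0))
    rt <- stats::rnorm(length(cond), coupling$baseline_rt_ms + shift,
                       coupling$rt_noise_sd_ms)
    out[[i]] <- data.frame(
      subject_id = params$subject_id[i],
      trial_index = seq_along(cond),
      condition = cond,
      correct = stats::runif(length(cond)) >= coupling$error_rate,
      rt_ms = pmax(rt, 1),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Read and write trial tables
#'
#' Plain-CSV persistence for the two trial tables with the canonical column
#' sets (`subject_id,trial_index,pair,chosen,unchosen,reward,omitted` and
#' `subject_id,trial_index,condition,correct,rt_ms`).
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @return The table (readers), or the path invisibly (writers).
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
write_learning_trials <- function(trials, path) {
  validate_learning_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_learning_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr$omitted <- as.logical(tr$omitted)
  validate_learning_trials(tr)
  tr
}

#' @rdname trial_io
#' @export
write_capture_trials <- function(trials, path) {
  needed <- c("subject_id", "trial_index", "condition", "correct", "rt_ms")
  stopifnot(all(needed %in% names(trials)))
  utils::write.csv(trials[, needed], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_capture_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr$correct <- as.logical(tr$correct)
  if (any(tr$rt_ms <= 0)) stop("rt_ms must be positive", call. = FALSE)
  tr
}
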