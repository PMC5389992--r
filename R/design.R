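#' Task design for the probabilistic selection and capture tasks
#'
#' Describes the structure of the value-based learning task (stimulus pairs
#' with fixed high-reward probabilities, trials per pair, block structure)
#' and of the subsequent attentional-capture search task (trial count and
#' distractor-condition mix). The defaults reproduce the standard design:
#' three pairs AB/CD/EF rewarded 80:20, 70:30 and 60:40, 100 trials per pair
#' delivered in 5 blocks of 60, and 120 capture trials of which half contain
#' no distractor and the rest split evenly between the high-value and
#' low-value distractor colors.
#'
#' @param pairs Character vector of two-letter pair labels; stimuli are the
#'   individual letters. Default `c("AB", "CD", "EF")`.
#' @param high_reward_prob Named numeric vector, one probability in (0.5, 1]
#'   per pair: the probability that choosing the first (better) stimulus of
#'   the pair yields the high reward. The second stimulus yields the high
#'   reward with one minus this probability.
#' @param trials_per_pair Trials per pair per subject (default 100).
#' @param n_blocks Number of learning blocks; `trials_per_pair` must be
#'   divisible by `n_blocks`. Pairs are shuffled uniformly within blocks that
#'   contain equal numbers of each pair.
#' @param capture_trials Number of capture-task trials per subject.
#' @param capture_condition_fractions Named fractions for conditions
#'   `none`, `high`, `low`; must sum to 1 and yield integer trial counts.
#' @param choice_deadline_ms Response deadline in the learning task (ms);
#'   recorded for completeness, used only when `omission_prob > 0`.
#' @param omission_prob Probability that a learning trial is omitted
#'   ("too slow"); omitted trials carry no choice or reward and are skipped
#'   by the likelihood. Default 0.
#' @return An object of class `task_design`.
#' @export
task_design <- function(pairs = c("AB", "CD", "EF"),
                        high_reward_prob = c(AB = 0.80, CD = 0.70, EF = 0.60),
                        trials_per_pair = 100L,
                        n_blocks = 5L,
                        capture_trials = 120L,
                        capture_condition_fractions = c(none = 0.5, high = 0.25, low = 0.25),
                        choice_deadline_ms = 1250,
                        omission_prob = 0) {
  stopifnot(is.character(pairs), length(pairs) >= 1L)
  if (any(nchar(pairs) != 2L)) {
    stop("each pair label must be two stimulus letters, e.g. 'AB'", call. = FALSE)
  }
  stim <- unlist(strsplit(pairs, ""))
  if (anyDuplicated(stim)) {
    stop("stimulus letters must be unique across pairs", call. = FALSE)
  }
  high_reward_prob <- high_reward_prob[pairs]
  if (anyNA(high_reward_prob)) {
    stop("high_reward_prob must name every pair", call. = FALSE)
  }
  if (any(high_reward_prob <= 0.5) || any(high_reward_prob > 1)) {
    stop("high_reward_prob must lie in (0.5, 1]", call. = FALSE)
  }
  trials_per_pair <- as.integer(trials_per_pair)
  n_blocks <- as.integer(n_blocks)
  if (trials_per_pair < 1L) stop("trials_per_pair must be positive", call. = FALSE)
  if (n_blocks < 1L || trials_per_pair %% n_blocks != 0L) {
    stop("trials_per_pair must be divisible by n_blocks", call. = FALSE)
  }
  capture_trials <- as.integer(capture_trials)
  if (capture_trials < 1L) stop("capture_trials must be positive", call. = FALSE)
  fr <- capture_condition_fractions
  if (is.null(names(fr)) || !setequal(names(fr), c("none", "high", "low"))) {
    stop("capture_condition_fractions must be named none/high/low", call. = FALSE)
  }
  fr <- fr[c("none", "high", "low")]
  if (abs(sum(fr) - 1) > 1e-12) {
    stop("capture_condition_fractions must sum to 1", call. = FALSE)
  }
  if (any(abs(fr * capture_trials - round(fr * capture_trials)) > 1e-9)) {
    stop("capture_condition_fractions must give integer trial counts", call. = FALSE)
  }
  if (choice_deadline_ms <= 0) stop("choice_deadline_ms must be positive", call. = FALSE)
  if (omission_prob < 0 || omission_prob >= 1) {
    stop("omission_prob must be in [0, 1)", call. = FALSE)
  }
  structure(list(
    pairs = pairs,
    stimuli = stim,
    high_reward_prob = high_reward_prob,
    trials_per_pair = trials_per_pair,
    n_blocks = n_blocks,
    capture_trials = capture_trials,
    capture_condition_fractions = fr,
    choice_deadline_ms = choice_deadline_ms,
    omission_prob = omission_prob
  ), class = "task_design")
}

#' Coupling between learning rates and capture-task slowing
#'
#' Generative specification tying each synthetic subject's learning rates to
#' their reaction times in the capture task. No-distractor trials have RTs
#' drawn from Normal(`baseline_rt_ms`, `rt_noise_sd_ms`); a high-value-color
#' distractor adds `slowing_slope_high * alpha_high` ms and a low-value-color
#' distractor adds `slowing_slope_low * alpha_low` ms. This linear coupling
#' is a deliberately simple stand-in whose only contract is that a planted
#' learning-rate/slowing relationship be recoverable by the correlation
#' analyses downstream.
#'
#' @param baseline_rt_ms Mean no-distractor RT (ms).
#' @param slowing_slope_high Slowing per unit of `alpha_high` (ms).
#' @param slowing_slope_low Slowing per unit of `alpha_low` (ms).
#' @param rt_noise_sd_ms Trial-level RT noise SD (ms), > 0.
#' @param error_rate Probability of an incorrect response, in [0, 0.5).
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(baseline_rt_ms = 650,
                          slowing_slope_high = 400,
                          slowing_slope_low = 100,
                          rt_noise_sd_ms = 30,
                          error_rate = 0.08) {
  if (baseline_rt_ms <= 0) stop("baseline_rt_ms must be positive", call. = FALSE)
  if (rt_noise_sd_ms <= 0) stop("rt_noise_sd_ms must be positive", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)", call. = FALSE)
  }
  structure(list(
    baseline_rt_ms = baseline_rt_ms,
    slowing_slope_high = slowing_slope_high,
    slowing_slope_low = slowing_slope_low,
    rt_noise_sd_ms = rt_noise_sd_ms,
    error_rate = error_rate
  ), class = "coupling_spec")
}

#' Q-learning model specification
#'
#' @param n_learning_rates 2 for the dual-rate model (separate learning
#'   rates after high- and low-value outcomes) or 1 for the shared-rate
#'   control model.
#' @param q_init Initial expected value for every stimulus, in [0, 1].
#'   With rewards coded 0/1 the midpoint 0.5 makes the first choice of any
#'   pair unbiased.
#' @param fit_scope `"all_pairs"` to use every trial, `"AB_only"` to fit the
#'   model to AB trials alone (the pair later used in the capture task).
#'   Under `"AB_only"`, CD/EF trials are dropped entirely: they share no
#'   stimuli with AB, so they cannot move AB values.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(n_learning_rates = 2L,
                       q_init = 0.5,
                       fit_scope = c("all_pairs", "AB_only")) {
  n_learning_rates <- as.integer(n_learning_rates)
  if (!n_learning_rates %in% c(1L, 2L)) {
    stop("n_learning_rates must be 1 or 2", call. = FALSE)
  }
  if (q_init < 0 || q_init > 1) stop("q_init must be in [0, 1]", call. = FALSE)
  fit_scope <- match.arg(fit_scope)
  structure(list(
    n_learning_rates = n_learning_rates,
    q_init = q_init,
    fit_scope = fit_scope
  ), class = "model_spec")
}

#' Priors for the hierarchical model
#'
#' Group-level means of the probit-scale parameters receive a
#' Normal(`mean_mu`, `mean_sd`) prior and group-level standard deviations a
#' Uniform(`sd_lower`, `sd_upper`) prior. The defaults are N(0, 1) and an
#' effectively unbounded-below uniform, U(0.001, 1.5) — the standard
#' group-SD prior in the probit-link hierarchical construction this model
#' family descends from. A narrower variant that forces group SDs above 1
#' (`sd_lower = 1`) appears in parts of the literature; it prevents the
#' group distribution from adapting to homogeneous samples and leaves
#' subject parameters essentially unpooled, so it is not the default, but
#' every bound is overridable.
#'
#' @param mean_mu,mean_sd Normal prior on group means (probit scale).
#' @param sd_lower,sd_upper Uniform prior support for group SDs; both must
#'   be positive with `sd_lower < sd_upper`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mean_mu = 0, mean_sd = 1, sd_lower = 0.001, sd_upper = 1.5) {
  if (mean_sd <= 0) stop("mean_sd must be positive", call. = FALSE)
  if (sd_lower <= 0 || sd_upper <= 0 || sd_lower >= sd_upper) {
    stop("need 0 < sd_lower < sd_upper", call. = FALSE)
  }
  structure(list(
    mean_mu = mean_mu, mean_sd = mean_sd,
    sd_lower = sd_lower, sd_upper = sd_upper
  ), class = "prior_spec")
}

pair_of_stimulus <- function(design, stimulus) {
  hit <- vapply(design$pairs, function(p) {
    stimulus %in% strsplit(p, "")[[1]]
  }, logical(1))
  design$pairs[hit][1]
}

#' Per-stimulus high-reward probabilities implied by a design
#'
#' The first letter of each pair is the better stimulus: choosing it yields
#' the high reward with the pair's scheduled probability; choosing the
#' second letter yields it with one minus that probability.
#'
#' @param design A [task_design()].
#' @return Named numeric vector of P(high reward | chosen stimulus).
#' @export
stimulus_reward_probs <- function(design) {
  probs <- numeric(0)
  for (p in design$pairs) {
    letters2 <- strsplit(p, "")[[1]]
    probs[letters2[1]] <- design$high_reward_prob[[p]]
    probs[letters2[2]] <- 1 - design$high_reward_prob[[p]]
  }
  probs
}
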