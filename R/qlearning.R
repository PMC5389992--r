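#' Probit link between unbounded and natural parameter scales
#'
#' Subject-level parameters live on an unbounded probit scale z' and are
#' mapped to their natural scales deterministically: learning rates as
#' Phi(z') in (0, 1) and the inverse temperature as 100 * Phi(z') in
#' (0, 100), where Phi is the standard normal CDF. Both maps are strictly
#' increasing.
#'
#' @param z Numeric vector on the probit scale (finite).
#' @param kind `"alpha"` (range 0-1) or `"beta"` (range 0-100).
#' @return Natural-scale values.
#' @seealso [probit_inverse()]
#' @export
probit_link <- function(z, kind = c("alpha", "beta")) {
  kind <- match.arg(kind)
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  p <- stats::pnorm(z)
  if (kind == "beta") 100 * p else p
}

#' Inverse probit link
#'
#' @param x Natural-scale values: in (0, 1) for `kind = "alpha"`, in
#'   (0, 100) for `kind = "beta"`.
#' @inheritParams probit_link
#' @return Probit-scale values z' such that `probit_link(z', kind) == x`.
#' @export
probit_inverse <- function(x, kind = c("alpha", "beta")) {
  kind <- match.arg(kind)
  if (kind == "beta") x <- x / 100
  if (any(x <= 0 | x >= 1)) {
    stop("natural-scale value outside the open range of the link", call. = FALSE)
  }
  stats::qnorm(x)
}

#' Subject parameter set for the Q-learning model
#'
#' Bundles the natural-scale parameters (alpha_high, alpha_low, beta) with
#' their probit-scale counterparts. Supply either scale; the other is
#' filled in through the link.
#'
#' @param alpha_high Learning rate after high-value outcomes, in [0, 1].
#' @param alpha_low Learning rate after low-value outcomes, in [0, 1].
#' @param beta Softmax inverse temperature, in [0, 100].
#' @param z_probit Optional numeric vector `(z_alpha_high, z_alpha_low,
#'   z_beta)`; when given, natural-scale values are derived from it.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(alpha_high = NULL, alpha_low = NULL, beta = NULL,
                           z_probit = NULL) {
  if (is.null(z_probit)) {
    stopifnot(!is.null(alpha_high), !is.null(alpha_low), !is.null(beta))
    if (alpha_high < 0 || alpha_high > 1 || alpha_low < 0 || alpha_low > 1) {
      stop("learning rates must lie in [0, 1]", call. = FALSE)
    }
    if (beta < 0 || beta > 100) stop("beta must lie in [0, 100]", call. = FALSE)
    z_probit <- c(
      stats::qnorm(min(max(alpha_high, 1e-12), 1 - 1e-12)),
      stats::qnorm(min(max(alpha_low, 1e-12), 1 - 1e-12)),
      stats::qnorm(min(max(beta / 100, 1e-12), 1 - 1e-12))
    )
  } else {
    stopifnot(length(z_probit) == 3L, all(is.finite(z_probit)))
    alpha_high <- probit_link(z_probit[1], "alpha")
    alpha_low <- probit_link(z_probit[2], "alpha")
    beta <- probit_link(z_probit[3], "beta")
  }
  structure(list(
    alpha_high = alpha_high, alpha_low = alpha_low, beta = beta,
    z_probit = as.numeric(z_probit)
  ), class = "subject_params")
}

#' Single Q-value update
#'
#' Applies the delta rule to the chosen stimulus's expected value:
#' `q + alpha * (r - q)`, where the learning rate is `alpha_high` after a
#' high reward (r = 1) and `alpha_low` after a low reward (r = 0). With one
#' learning rate (`spec$n_learning_rates == 1`) `alpha_high` is used for
#' both outcomes. Only the chosen stimulus is ever updated.
#'
#' @param q_chosen Current expected value of the chosen stimulus, in [0, 1].
#' @param reward 0 (low) or 1 (high).
#' @param params A [subject_params()].
#' @param spec A [model_spec()].
#' @return List with `q` (updated value) and `delta` (prediction error
#'   r - q).
#' @export
q_update <- function(q_chosen, reward, params, spec = model_spec()) {
  if (!reward %in% c(0, 1)) stop("reward must be 0 or 1", call. = FALSE)
  if (q_chosen < 0 || q_chosen > 1) stop("q_chosen must be in [0, 1]", call. = FALSE)
  alpha <- if (spec$n_learning_rates == 1L) {
    params$alpha_high
  } else if (reward == 1) params$alpha_high else params$alpha_low
  delta <- reward - q_chosen
  list(q = q_chosen + alpha * delta, delta = delta)
}

#' Softmax choice probability for a two-alternative trial
#'
#' Probability of choosing the first of two presented stimuli:
#' `exp(beta * q_first) / (exp(beta * q_first) + exp(beta * q_second))`,
#' computed by subtracting the larger exponent so large `beta * q` cannot
#' overflow.
#'
#' @param q_first,q_second Expected values of the two stimuli.
#' @param beta Inverse temperature in [0, 100].
#' @return Probability in (0, 1).
#' @export
choice_prob <- function(q_first, q_second, beta) {
  if (beta < 0 || beta > 100) stop("beta must be in [0, 100]", call. = FALSE)
  a <- beta * q_first
  b <- beta * q_second
  m <- max(a, b)
  ea <- exp(a - m)
  ea / (ea + exp(b - m))
}

validate_learning_trials <- function(trials, require_one_subject = FALSE) {
  needed <- c("subject_id", "trial_index", "pair", "chosen", "unchosen",
              "reward", "omitted")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("learning-trial table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (require_one_subject && length(unique(trials$subject_id)) > 1L) {
    stop("expected trials from a single subject", call. = FALSE)
  }
  keep <- !trials$omitted
  if (any(is.unsorted(trials$trial_index[keep]))) {
    # per-subject ordering is what matters; check within subject
    by_subj <- split(trials$trial_index[keep], trials$subject_id[keep])
    if (any(vapply(by_subj, is.unsorted, logical(1)))) {
      stop("trials must be sorted by trial_index within subject", call. = FALSE)
    }
  }
  if (!all(trials$reward[keep] %in% c(0, 1))) {
    stop("reward must be coded 0/1", call. = FALSE)
  }
  invisible(trials)
}

#' Log-likelihood of one subject's choice sequence
#'
#' Walks the subject's trials in order, computing the softmax probability of
#' each observed choice from the current Q-values of the two presented
#' stimuli and then updating the chosen stimulus's value by the delta rule.
#' All Q-values start at `spec$q_init`. Omitted trials contribute no
#' likelihood factor and no update. Under `fit_scope = "AB_only"` non-AB
#' trials are excluded entirely. Choice probabilities are floored at 1e-12
#' before taking logs.
#'
#' @param trials Learning-trial table for a single subject (columns
#'   `subject_id, trial_index, pair, chosen, unchosen, reward, omitted`),
#'   sorted by `trial_index`.
#' @param params A [subject_params()].
#' @param spec A [model_spec()].
#' @return The summed log choice probability (a single number <= 0).
#' @export
sequence_loglik <- function(trials, params, spec = model_spec()) {
  validate_learning_trials(trials, require_one_subject = TRUE)
  trials <- trials[!trials$omitted, , drop = FALSE]
  if (spec$fit_scope == "AB_only") {
    trials <- trials[trials$pair == "AB", , drop = FALSE]
  }
  if (nrow(trials) == 0L) return(0)
  stim <- sort(unique(c(trials$chosen, trials$unchosen)))
  ch <- match(trials$chosen, stim) - 1L
  un <- match(trials$unchosen, stim) - 1L
  cpp_seq_loglik(ch, un, as.integer(trials$reward), length(stim),
                 params$alpha_high,
                 if (spec$n_learning_rates == 1L) params$alpha_high else params$alpha_low,
                 params$beta, spec$q_init)
}

#' Final Q-values after walking a subject's trials
#'
#' Runs the same value-update pass as [sequence_loglik()] and returns the
#' terminal expected value of every stimulus — e.g. the subject's estimated
#' belief about the high-value color at the end of learning.
#'
#' @inheritParams sequence_loglik
#' @return Named numeric vector of final Q-values.
#' @export
q_final_values <- function(trials, params, spec = model_spec()) {
  validate_learning_trials(trials, require_one_subject = TRUE)
  trials <- trials[!trials$omitted, , drop = FALSE]
  if (spec$fit_scope == "AB_only") {
    trials <- trials[trials$pair == "AB", , drop = FALSE]
  }
  stim <- sort(unique(c(trials$chosen, trials$unchosen)))
  q <- stats::setNames(rep(spec$q_init, length(stim)), stim)
  for (i in seq_len(nrow(trials))) {
    upd <- q_update(q[[trials$chosen[i]]], trials$reward[i], params, spec)
    q[[trials$chosen[i]]] <- upd$q
  }
  q
}

#' Simulate one agent's choices on the learning task
#'
#' Forward-generative twin of [sequence_loglik()]: on every trial the agent
#' chooses between the two presented stimuli through the softmax rule
#' applied to its current Q-values, the reward is drawn from the chosen
#' stimulus's schedule, and the chosen value is updated by the delta rule.
#' Shares its code path with [simulate_learning_task()]: simulating subject
#' i of a parameter table with seed `seed + i - 1` reproduces that
#' subject's rows exactly.
#'
#' @param params A [subject_params()].
#' @param design A [task_design()].
#' @param spec A [model_spec()] (supplies `q_init` and the rate count).
#' @param seed Integer seed.
#' @param subject_id Identifier written into the table.
#' @return A learning-trial data frame.
#' @export
simulate_agent_choices <- function(params, design = task_design(),
                                   spec = model_spec(), seed = 1L,
                                   subject_id = "s01") {
  set.seed(seed)
  simulate_subject_trials(params, design, spec, subject_id)
}

# One subject's trial table using the current RNG stream.
simulate_subject_trials <- function(params, design, spec, subject_id) {
  per_block <- design$trials_per_pair %/% design$n_blocks
  pair_seq <- unlist(lapply(seq_len(design$n_blocks), function(b) {
    sample(rep(design$pairs, per_block))
  }))
  n <- length(pair_seq)
  rew_prob <- stimulus_reward_probs(design)
  q <- stats::setNames(rep(spec$q_init, length(design$stimuli)), design$stimuli)
  chosen <- character(n); unchosen <- character(n)
  reward <- integer(n); omitted <- logical(n)
  for (t in seq_len(n)) {
    st <- strsplit(pair_seq[t], "")[[1]]
    if (design$omission_prob > 0 && stats::runif(1) < design$omission_prob) {
      omitted[t] <- TRUE
      chosen[t] <- NA_character_; unchosen[t] <- NA_character_
      reward[t] <- NA_integer_
      next
    }
    p_first <- choice_prob(q[[st[1]]], q[[st[2]]], params$beta)
    pick_first <- stats::runif(1) < p_first
    ch <- if (pick_first) st[1] else st[2]
    un <- if (pick_first) st[2] else st[1]
    r <- as.integer(stats::runif(1) < rew_prob[[ch]])
    q[[ch]] <- q_update(q[[ch]], r, params, spec)$q
    chosen[t] <- ch; unchosen[t] <- un; reward[t] <- r
  }
  data.frame(
    subject_id = subject_id,
    trial_index = seq_len(n),
    pair = pair_seq,
    chosen = chosen,
    unchosen = unchosen,
    reward = reward,
    omitted = omitted,
    stringsAsFactors = FALSE
  )
}
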