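#' Bayesian Information Criterion
#'
#' `-2 * loglik + k * log(n_obs)`.
#'
#' @param loglik Log-likelihood at the point estimate.
#' @param k Number of free parameters (>= 1).
#' @param n_obs Number of observations (>= 1).
#' @return The BIC value; lower is preferred.
#' @export
bic <- function(loglik, k, n_obs) {
  if (k < 1 || n_obs < 1) stop("k and n_obs must be >= 1", call. = FALSE)
  -2 * loglik + k * log(n_obs)
}

#' Compare the dual-rate and single-rate models by BIC
#'
#' Evaluates every subject's choice log-likelihood at a per-subject point
#' estimate under each fitted model, then computes (a) individual BICs —
#' per-subject trial count as n, 3 free parameters per subject for the
#' dual-rate model and 2 for the single-rate model — and (b) a group BIC
#' from the summed log-likelihood, total trial count, and summed parameter
#' count. The preferred model is the one with the lower group BIC.
#'
#' BIC is defined on the maximized likelihood, so by default each
#' subject's natural-scale posterior modes are refined by a short
#' maximum-likelihood optimization (`estimates = "mle"`). Hierarchical
#' shrinkage pulls posterior modes toward the group centre, which costs
#' the richer model more likelihood than the restricted one and biases
#' the comparison toward fewer parameters; `estimates = "posterior_mode"`
#' skips the refinement and scores the raw modes.
#'
#' @param data Learning-trial table both models were fit to.
#' @param fit_2a `qfit` of the dual-rate model.
#' @param fit_1a `qfit` of the single-rate model.
#' @param estimates `"mle"` (default) or `"posterior_mode"`.
#' @return An object of class `fit_comparison`: per-model group BIC, mean
#'   individual BIC, per-subject log-likelihoods and BICs, parameter
#'   counts, and the `preferred` label (`"2alpha"` or `"1alpha"`).
#' @export
compare_models <- function(data, fit_2a, fit_1a,
                           estimates = c("mle", "posterior_mode")) {
  estimates <- match.arg(estimates)
  if (fit_2a$spec$n_learning_rates != 2L || fit_1a$spec$n_learning_rates != 1L) {
    stop("fit_2a must be the dual-rate fit and fit_1a the single-rate fit",
         call. = FALSE)
  }
  if (!identical(fit_2a$subject_ids, fit_1a$subject_ids)) {
    stop("fits were not run on the same subjects", call. = FALSE)
  }
  if (fit_2a$spec$fit_scope != fit_1a$spec$fit_scope) {
    stop("fits use different scopes", call. = FALSE)
  }
  ids <- fit_2a$subject_ids
  k_per <- c(`2alpha` = 3L, `1alpha` = 2L)
  per_subject <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (model in c("2alpha", "1alpha")) {
    fit <- if (model == "2alpha") fit_2a else fit_1a
    ll <- numeric(length(ids))
    for (i in seq_along(ids)) {
      sm <- fit$subject_modes[fit$subject_modes$subject_id == ids[i], ]
      sp <- if (model == "2alpha") {
        subject_params(alpha_high = sm$alpha_high, alpha_low = sm$alpha_low,
                       beta = sm$beta)
      } else {
        subject_params(alpha_high = sm$alpha, alpha_low = sm$alpha,
                       beta = sm$beta)
      }
      tr <- data[data$subject_id == ids[i], , drop = FALSE]
      if (estimates == "mle") {
        two <- model == "2alpha"
        z0 <- if (two) sp$z_probit else sp$z_probit[c(1, 3)]
        negll <- function(z) {
          zz <- if (two) z else c(z[1], z[1], z[2])
          -sequence_loglik(tr, subject_params(z_probit = zz), fit$spec)
        }
        opt <- stats::optim(z0, negll, method = "Nelder-Mead")
        ll[i] <- -opt$value
      } else {
        ll[i] <- sequence_loglik(tr, sp, fit$spec)
      }
    }
    n_i <- fit$n_trials_per_subject[ids]
    per_subject[[paste0("loglik_", model)]] <- ll
    per_subject[[paste0("bic_", model)]] <-
      mapply(bic, ll, k_per[[model]], n_i)
  }
  n_total <- sum(fit_2a$n_trials_per_subject)
  res <- list(per_subject = per_subject)
  for (model in c("2alpha", "1alpha")) {
    ll_sum <- sum(per_subject[[paste0("loglik_", model)]])
    res[[paste0("bic_group_", model)]] <-
      bic(ll_sum, k_per[[model]] * length(ids), n_total)
    res[[paste0("bic_individual_mean_", model)]] <-
      mean(per_subject[[paste0("bic_", model)]])
    res[[paste0("loglik_", model)]] <- ll_sum
    res[[paste0("k_", model)]] <- k_per[[model]] * length(ids)
  }
  res$preferred <- if (res$bic_group_2alpha <= res$bic_group_1alpha) "2alpha" else "1alpha"
  structure(res, class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat("BIC model comparison (lower is better)\n")
  cat(sprintf("  group BIC:      2alpha = %.1f, 1alpha = %.1f\n",
              x$bic_group_2alpha, x$bic_group_1alpha))
  cat(sprintf("  mean indiv BIC: 2alpha = %.1f, 1alpha = %.1f\n",
              x$bic_individual_mean_2alpha, x$bic_individual_mean_1alpha))
  cat("  preferred:", x$preferred, "\n")
  invisible(x)
}

#' Posterior-predictive learning curves for P(A|AB)
#'
#' Simulates the learning task for every subject at their natural-scale
#' posterior-mode parameters, bins AB trials into blocks, and returns the
#' simulated choice-A rate per block (averaged over `n_reps` replicate
#' runs) next to the observed rate, with group means and SEM.
#'
#' @param fit A `qfit`.
#' @param data Observed learning-trial table (for the observed curve).
#' @param design The [task_design()] to simulate under.
#' @param n_reps Replicate simulated task runs per subject.
#' @param seed Integer seed.
#' @param block_size AB trials per block (default 20, five blocks over 100).
#' @return List with `curves` (data frame `subject_id, block, observed,
#'   simulated_mean`) and `group` (data frame `block, observed_mean,
#'   observed_sem, simulated_mean, simulated_sem`).
#' @export
posterior_predictive_curves <- function(fit, data, design = task_design(),
                                        n_reps = 100L, seed = 1L,
                                        block_size = 20L) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  ids <- fit$subject_ids
  two_rates <- fit$spec$n_learning_rates == 2L
  curve_of <- function(tr) {
    ab <- tr[!tr$omitted & tr$pair == "AB", , drop = FALSE]
    ab <- ab[order(ab$trial_index), , drop = FALSE]
    block <- ceiling(seq_len(nrow(ab)) / block_size)
    tapply(ab$chosen == "A", block, mean)
  }
  n_blocks <- design$trials_per_pair %/% block_size
  rows <- list()
  for (i in seq_along(ids)) {
    sm <- fit$subject_modes[fit$subject_modes$subject_id == ids[i], ]
    sp <- if (two_rates) {
      subject_params(alpha_high = sm$alpha_high, alpha_low = sm$alpha_low,
                     beta = sm$beta)
    } else {
      subject_params(alpha_high = sm$alpha, alpha_low = sm$alpha, beta = sm$beta)
    }
    sim <- matrix(NA_real_, n_reps, n_blocks)
    for (r in seq_len(n_reps)) {
      tr <- simulate_agent_choices(sp, design, fit$spec,
                                   seed = seed + (i - 1L) * n_reps + r - 1L,
                                   subject_id = ids[i])
      sim[r, ] <- curve_of(tr)
    }
    obs <- curve_of(data[data$subject_id == ids[i], , drop = FALSE])
    rows[[i]] <- data.frame(
      subject_id = ids[i], block = seq_len(n_blocks),
      observed = as.numeric(obs)[seq_len(n_blocks)],
      simulated_mean = colMeans(sim),
      stringsAsFactors = FALSE
    )
  }
  curves <- do.call(rbind, rows)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  group <- do.call(rbind, lapply(split(curves, curves$block), function(d) {
    data.frame(block = d$block[1],
               observed_mean = mean(d$observed), observed_sem = sem(d$observed),
               simulated_mean = mean(d$simulated_mean),
               simulated_sem = sem(d$simulated_mean))
  }))
  rownames(group) <- NULL
  list(curves = curves, group = group)
}
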