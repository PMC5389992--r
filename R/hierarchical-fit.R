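param_names_for <- function(spec) {
  if (spec$n_learning_rates == 2L) c("alpha_high", "alpha_low", "beta")
  else c("alpha", "beta")
}

param_kind_for <- function(spec) {
  if (spec$n_learning_rates == 2L) c("alpha", "alpha", "beta")
  else c("alpha", "beta")
}

# Flatten a multi-subject learning-trial table into the integer arrays the
# C++ kernels expect, honouring fit scope and omissions.
build_fit_data <- function(data, spec) {
  validate_learning_trials(data)
  data <- data[!data$omitted, , drop = FALSE]
  if (spec$fit_scope == "AB_only") {
    data <- data[data$pair == "AB", , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("no trials left after filtering", call. = FALSE)
  subject_ids <- unique(data$subject_id)
  stim <- sort(unique(c(data$chosen, data$unchosen)))
  idx <- split(seq_len(nrow(data)), factor(data$subject_id, levels = subject_ids))
  ord <- unlist(lapply(idx, function(ix) ix[order(data$trial_index[ix])]),
                use.names = FALSE)
  data <- data[ord, , drop = FALSE]
  n_per <- vapply(idx, length, integer(1))
  list(
    subject_ids = subject_ids,
    stimuli = stim,
    offsets = as.integer(c(0L, cumsum(n_per))),
    chosen = match(data$chosen, stim) - 1L,
    unchosen = match(data$unchosen, stim) - 1L,
    reward = as.integer(data$reward),
    n_trials_per_subject = as.integer(n_per)
  )
}

#' Joint log-posterior density of the hierarchical Q-learning model
#'
#' Evaluates, up to nothing (all normalising constants of the priors are
#' included), the sum of every subject's choice log-likelihood at their
#' probit-linked parameters, the group-level normal densities of the
#' subject z' values, the normal prior on the group means and the uniform
#' prior on the group SDs. Returns `-Inf` whenever a group SD falls outside
#' the uniform support.
#'
#' @param data Learning-trial table for all subjects.
#' @param state List with `z` (matrix, subjects x parameters, probit scale),
#'   `mu` (group means) and `delta` (group SDs), parameters ordered
#'   (alpha_high, alpha_low, beta) — or (alpha, beta) for the
#'   single-rate model.
#' @param priors A [prior_spec()].
#' @param spec A [model_spec()].
#' @return A single number (log density).
#' @export
log_posterior <- function(data, state, priors = prior_spec(),
                          spec = model_spec()) {
  P <- length(param_names_for(spec))
  z <- as.matrix(state$z)
  if (ncol(z) != P || length(state$mu) != P || length(state$delta) != P) {
    stop("state dimensions do not match the model spec", call. = FALSE)
  }
  subject_ids <- unique(data$subject_id)
  if (nrow(z) != length(subject_ids)) {
    stop("state has ", nrow(z), " subjects but data has ",
         length(subject_ids), call. = FALSE)
  }
  if (any(state$delta < priors$sd_lower | state$delta > priors$sd_upper)) {
    return(-Inf)
  }
  ll <- 0
  for (i in seq_along(subject_ids)) {
    sp <- if (P == 3L) {
      subject_params(z_probit = z[i, ])
    } else {
      subject_params(z_probit = c(z[i, 1], z[i, 1], z[i, 2]))
    }
    tr <- data[data$subject_id == subject_ids[i], , drop = FALSE]
    ll <- ll + sequence_loglik(tr, sp, spec)
  }
  lp <- ll
  for (p in seq_len(P)) {
    lp <- lp + sum(stats::dnorm(z[, p], state$mu[p], state$delta[p], log = TRUE))
  }
  lp <- lp + sum(stats::dnorm(state$mu, priors$mean_mu, priors$mean_sd, log = TRUE))
  lp + P * stats::dunif(priors$sd_lower, priors$sd_lower, priors$sd_upper, log = TRUE)
}

#' Split-chain potential scale reduction factor (Rhat)
#'
#' Gelman-Rubin convergence diagnostic computed on split chains: each chain
#' is halved, and the between- to within-half variance ratio gives
#' `sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate mixed chains.
#'
#' @param chains A list of equal-length numeric vectors (one per chain), or
#'   a matrix with one column per chain. A single chain is allowed — it is
#'   split in half.
#' @return The split-Rhat statistic (>= 1 up to floating error; `NA` for
#'   zero-variance chains).
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (!is.list(chains)) chains <- list(chains)
  lens <- vapply(chains, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all chains must have equal length", call. = FALSE)
  }
  n <- lens[1]
  if (n < 4L) stop("chains must have at least 4 draws", call. = FALSE)
  half <- n %/% 2L
  halves <- unlist(lapply(chains, function(x) {
    list(x[seq_len(half)], x[(n - half + 1):n])
  }), recursive = FALSE)
  m <- length(halves)
  nn <- half
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Posterior mode by kernel density estimation
#'
#' The point estimate reported for every parameter: the location of the
#' maximum of a Gaussian kernel density estimate (bandwidth by the
#' normal-reference rule) evaluated on a 512-point grid spanning the sample
#' range.
#'
#' @param samples Numeric vector of at least 100 posterior draws.
#' @return The grid point of maximal estimated density.
#' @export
posterior_mode <- function(samples) {
  if (length(samples) < 100L) {
    stop("posterior_mode needs at least 100 samples", call. = FALSE)
  }
  r <- range(samples)
  if (r[1] == r[2]) return(r[1])
  d <- stats::density(samples, bw = "nrd0", kernel = "gaussian",
                      n = 512, from = r[1], to = r[2])
  d$x[which.max(d$y)]
}

#' Fit the hierarchical Q-learning model by MCMC
#'
#' Samples the posterior of the probit-scale hierarchical model — subject
#' parameters z' under group-level Normal(mu, delta) distributions with a
#' N(0, 1) prior on group means and a U(1, 1.5) prior on group SDs — using
#' a Metropolis-within-Gibbs sampler: random-walk updates for each subject
#' parameter, conjugate Gibbs draws for the group means and reflected
#' random-walk updates for the group SDs, with proposal scales adapted
#' during warmup. Convergence is assessed by split-Rhat on every parameter;
#' the fit is flagged converged when the maximum Rhat is below 1.05.
#'
#' @param data Learning-trial table for all subjects.
#' @param priors A [prior_spec()].
#' @param spec A [model_spec()] selecting rate count and fit scope.
#' @param n_chains Number of chains (>= 2).
#' @param n_warmup Adaptation/warmup sweeps per chain.
#' @param n_samples Kept draws per chain.
#' @param thin Keep every `thin`-th post-warmup sweep.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @return An object of class `qfit`: list with `draws` (data frame of
#'   kept draws, probit scale, with `chain` and `iter` columns), `rhat`
#'   (named vector), `converged`, `group_modes` (natural-scale KDE modes of
#'   the group-mean parameters), `subject_modes` (data frame of
#'   natural-scale subject modes), `subject_ids`, `spec`, `priors` and the
#'   sampler settings.
#' @export
run_sampler <- function(data, priors = prior_spec(), spec = model_spec(),
                        n_chains = 4L, n_warmup = 1000L, n_samples = 1000L,
                        thin = 4L, seed = 1L) {
  if (n_chains < 2L) stop("n_chains must be >= 2", call. = FALSE)
  fd <- build_fit_data(data, spec)
  P <- length(param_names_for(spec))
  N <- length(fd$subject_ids)
  cols <- c(paste0("mu_", param_names_for(spec)),
            paste0("delta_", param_names_for(spec)),
            as.vector(t(outer(fd$subject_ids, param_names_for(spec),
                              function(s, p) paste0("z_", p, "_", s)))))
  draws <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    m <- cpp_mcmc_chain(fd$offsets, fd$chosen, fd$unchosen, fd$reward,
                        length(fd$stimuli), P, spec$q_init,
                        priors$mean_mu, priors$mean_sd,
                        priors$sd_lower, priors$sd_upper,
                        as.integer(n_warmup), as.integer(n_samples),
                        as.integer(thin))
    colnames(m) <- cols
    draws[[ch]] <- data.frame(chain = ch, iter = seq_len(nrow(m)), m,
                              check.names = FALSE)
  }
  draws <- do.call(rbind, draws)

  rh <- vapply(cols, function(cn) {
    rhat(matrix(draws[[cn]], ncol = n_chains))
  }, numeric(1))
  converged <- all(!is.na(rh)) && max(rh, na.rm = TRUE) < 1.05
  if (!converged) {
    warning("max split-Rhat ", round(max(rh, na.rm = TRUE), 3),
            " >= 1.05; chains may not have mixed", call. = FALSE)
  }

  kinds <- param_kind_for(spec)
  group_modes <- stats::setNames(vapply(seq_len(P), function(p) {
    posterior_mode(probit_link(draws[[paste0("mu_", param_names_for(spec)[p])]],
                               kinds[p]))
  }, numeric(1)), param_names_for(spec))

  subject_modes <- data.frame(subject_id = fd$subject_ids,
                              stringsAsFactors = FALSE)
  for (p in seq_len(P)) {
    pn <- param_names_for(spec)[p]
    subject_modes[[pn]] <- vapply(fd$subject_ids, function(s) {
      posterior_mode(probit_link(draws[[paste0("z_", pn, "_", s)]], kinds[p]))
    }, numeric(1))
  }

  structure(list(
    draws = draws,
    rhat = rh,
    converged = converged,
    group_modes = group_modes,
    subject_modes = subject_modes,
    subject_ids = fd$subject_ids,
    n_trials_per_subject = stats::setNames(fd$n_trials_per_subject,
                                           fd$subject_ids),
    spec = spec,
    priors = priors,
    settings = list(n_chains = n_chains, n_warmup = n_warmup,
                    n_samples = n_samples, thin = thin, seed = seed)
  ), class = "qfit")
}

#' @export
print.qfit <- function(x, ...) {
  cat("Hierarchical Q-learning fit (",
      x$spec$n_learning_rates, " learning rate",
      if (x$spec$n_learning_rates > 1) "s", ", scope ", x$spec$fit_scope,
      ")\n", sep = "")
  cat("  subjects: ", length(x$subject_ids),
      "; chains: ", x$settings$n_chains,
      " x ", x$settings$n_samples, " kept draws\n", sep = "")
  cat("  max split-Rhat: ", round(max(x$rhat, na.rm = TRUE), 4),
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  cat("  group-level posterior modes (natural scale):\n")
  print(round(x$group_modes, 4))
  invisible(x)
}

#' Persist a fit's draws and summaries
#'
#' Writes the kept draws to CSV (one row per draw, chain id column) and the
#' diagnostics plus natural-scale posterior modes to JSON.
#'
#' @param fit A `qfit` object.
#' @param draws_csv,summary_json Output paths.
#' @return Invisibly, the summary list.
#' @export
write_fit <- function(fit, draws_csv, summary_json) {
  utils::write.csv(fit$draws, draws_csv, row.names = FALSE)
  summ <- list(
    rhat = as.list(fit$rhat),
    max_rhat = max(fit$rhat, na.rm = TRUE),
    converged = fit$converged,
    group_modes = as.list(fit$group_modes),
    subject_modes = fit$subject_modes,
    settings = fit$settings,
    spec = unclass(fit$spec)
  )
  jsonlite::write_json(summ, summary_json, auto_unbox = TRUE, digits = NA)
  invisible(summ)
}
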