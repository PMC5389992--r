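test_that("log_posterior composes likelihood, group model and priors", {
  pri <- prior_spec(sd_lower = 1, sd_upper = 1.5)
  one <- data.frame(subject_id = "s", trial_index = 1L, pair = "AB",
                    chosen = "A", unchosen = "B", reward = 1L, omitted = FALSE)
  state <- list(z = matrix(0, 1, 3), mu = rep(0, 3), delta = rep(1.25, 3))
  # closed form: first-trial symmetry + three normal densities at each level
  # + the uniform density 1/0.5 per SD
  expect_equal(log_posterior(one, state, pri),
               log(0.5) + 3 * dnorm(0, 0, 1.25, log = TRUE) +
                 3 * dnorm(0, 0, 1, log = TRUE) + 3 * log(2),
               tolerance = 1e-12)
  # SD outside the uniform support
  bad <- state; bad$delta <- c(0.9, 1.25, 1.25)
  expect_equal(log_posterior(one, bad, pri), -Inf)
  # dimension mismatch
  expect_error(log_posterior(one, list(z = matrix(0, 2, 3), mu = rep(0, 3),
                                       delta = rep(1.25, 3)), pri),
               "subjects")
})

test_that("log_posterior likelihood term equals summed sequence_loglik", {
  set.seed(21)
  p <- draw_subject_params(c(-1, -1, -1.5), c(.3, .3, .3), 5, seed = 1)
  tr <- simulate_learning_task(p, task_design(), seed = 2)
  z <- as.matrix(p[, c("z_alpha_high", "z_alpha_low", "z_beta")])
  colnames(z) <- NULL
  pri <- prior_spec(sd_lower = 1, sd_upper = 1.5)
  state <- list(z = z, mu = rep(0, 3), delta = rep(1.2, 3))
  ll <- sum(vapply(seq_len(5), function(i) {
    sequence_loglik(tr[tr$subject_id == p$subject_id[i], ],
                    params_row_to_subject(p, i))
  }, numeric(1)))
  prior_part <- sum(dnorm(z, 0, 1.2, log = TRUE)) +
    3 * dnorm(0, 0, 1, log = TRUE) + 3 * log(2)
  expect_equal(log_posterior(tr, state, pri), ll + prior_part,
               tolerance = 1e-10)
  # exchanging subject order leaves the density unchanged
  ord <- c(3, 1, 5, 2, 4)
  tr2 <- do.call(rbind, lapply(p$subject_id[ord],
                               function(s) tr[tr$subject_id == s, ]))
  state2 <- list(z = z[ord, ], mu = rep(0, 3), delta = rep(1.2, 3))
  expect_equal(log_posterior(tr2, state2, pri), log_posterior(tr, state, pri),
               tolerance = 1e-10)
})

test_that("split-Rhat behaves like a scale-reduction diagnostic", {
  x <- rnorm(1000)
  # identical chains mix perfectly (split formula gives sqrt((n-1)/n))
  expect_lt(abs(rhat(list(x, x)) - 1), 2e-3)
  # well-separated chains are flagged far above 1
  set.seed(5)
  expect_gt(rhat(list(rnorm(1000, 0), rnorm(1000, 5))), 1.5)
  # iid chains from one distribution sit in the unit neighbourhood
  set.seed(6)
  r <- rhat(lapply(1:4, function(i) rnorm(1000)))
  expect_gte(r, 0.99)
  expect_lte(r, 1.02)
  expect_error(rhat(list(rnorm(10), rnorm(11))), "equal length")
})

test_that("posterior_mode finds the KDE peak", {
  set.seed(31)
  x <- rnorm(10000, 0.12, 0.01)
  expect_lt(abs(posterior_mode(x) - 0.12), 0.005)
  expect_equal(posterior_mode(rep(3.3, 200)), 3.3)
  # global mode of a bimodal mixture
  xm <- c(rnorm(7000, 0, 0.01), rnorm(3000, 1, 0.01))
  expect_equal(posterior_mode(xm), 0, tolerance = 0.02)
  expect_error(posterior_mode(rnorm(50)), "100")
})

test_that("run_sampler validates inputs", {
  p <- draw_subject_params(c(-1, -1, -1.5), c(.2, .2, .2), 3, seed = 1)
  tr <- simulate_learning_task(p, ab_design(20L), seed = 2)
  expect_error(run_sampler(tr, n_chains = 1), "n_chains")
})

test_that("the sampler is reproducible and self-consistent on a small fit", {
  p <- draw_subject_params(ref_ab_means_probit, c(.1, .1, .1), 5, seed = 3)
  tr <- simulate_learning_task(p, ab_design(60L), seed = 4)
  fit1 <- suppressWarnings(
    run_sampler(tr, spec = model_spec(fit_scope = "AB_only"), n_chains = 2,
                n_warmup = 200, n_samples = 200, thin = 2, seed = 99))
  fit2 <- suppressWarnings(
    run_sampler(tr, spec = model_spec(fit_scope = "AB_only"), n_chains = 2,
                n_warmup = 200, n_samples = 200, thin = 2, seed = 99))
  expect_identical(fit1$draws, fit2$draws)
  expect_equal(nrow(fit1$draws), 2 * 200)
  expect_true(all(c("mu_alpha_high", "delta_beta", "z_beta_s01") %in%
                    names(fit1$draws)))
  # group SDs respect the uniform support
  expect_true(all(fit1$draws$delta_alpha_high >= 0.001 &
                    fit1$draws$delta_alpha_high <= 1.5))
  # natural-scale modes live on their scales
  expect_true(fit1$group_modes[["alpha_high"]] > 0 &&
                fit1$group_modes[["alpha_high"]] < 1)
  expect_true(fit1$group_modes[["beta"]] > 0 &&
                fit1$group_modes[["beta"]] < 100)
})

test_that("the sampler matches an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  # small fixture: 8 subjects x 40 AB trials, moderate settings; the two
  # samplers must agree on posterior means within MC error
  p <- draw_subject_params(ref_ab_means_probit, c(.2, .2, .2), 8, seed = 13)
  tr <- simulate_learning_task(p, ab_design(40L), seed = 14)
  fit <- suppressWarnings(
    run_sampler(tr, spec = model_spec(fit_scope = "AB_only"), n_chains = 2,
                n_warmup = 600, n_samples = 500, thin = 6, seed = 15))
  mine <- colMeans(fit$draws[, c("mu_alpha_high", "mu_alpha_low", "mu_beta")])

  N <- 8; T <- 40
  ch <- r <- matrix(NA, N, T)
  for (i in 1:N) {
    d <- tr[tr$subject_id == p$subject_id[i], ]
    ch[i, ] <- ifelse(d$chosen == "A", 1, 2)
    r[i, ] <- d$reward
  }
  mod <- "
  model {
    for (pp in 1:3) { mu[pp] ~ dnorm(0,1); delta[pp] ~ dunif(0.001,1.5); tau[pp] <- pow(delta[pp],-2) }
    for (i in 1:N) {
      for (pp in 1:3) { z[i,pp] ~ dnorm(mu[pp], tau[pp]) }
      aH[i] <- phi(z[i,1]); aL[i] <- phi(z[i,2]); beta[i] <- 100*phi(z[i,3])
      Q[i,1,1] <- 0.5; Q[i,1,2] <- 0.5
      for (t in 1:T) {
        pch[i,t] <- 1/(1+exp(-beta[i]*(Q[i,t,ch[i,t]] - Q[i,t,3-ch[i,t]])))
        ones[i,t] ~ dbern(pch[i,t])
        alpha[i,t] <- aH[i]*r[i,t] + aL[i]*(1-r[i,t])
        for (s in 1:2) {
          Q[i,t+1,s] <- Q[i,t,s] + equals(s, ch[i,t]) * alpha[i,t] * (r[i,t]-Q[i,t,s])
        }
      }
    }
  }"
  jm <- rjags::jags.model(textConnection(mod),
                          data = list(N = N, T = T, ch = ch, r = r,
                                      ones = matrix(1, N, T)),
                          n.chains = 2, n.adapt = 500, quiet = TRUE)
  update(jm, 500, progress.bar = "none")
  s <- rjags::coda.samples(jm, "mu", n.iter = 2000, thin = 2,
                           progress.bar = "none")
  theirs <- colMeans(as.matrix(s))
  expect_equal(unname(mine), unname(theirs), tolerance = 0.15)
})
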