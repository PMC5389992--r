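# Independent oracles: deliberately naive re-implementations used to verify
# the package's computational kernels. They share no code with the package
# internals beyond base R.

# trial-by-trial walk with explicit delta-rule and softmax arithmetic
oracle_loglik <- function(trials, alpha_high, alpha_low, beta, q_init = 0.5,
                          ab_only = FALSE) {
  trials <- trials[!trials$omitted, , drop = FALSE]
  if (ab_only) trials <- trials[trials$pair == "AB", , drop = FALSE]
  q <- new.env()
  for (s in unique(c(trials$chosen, trials$unchosen))) assign(s, q_init, q)
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    qc <- get(trials$chosen[i], q)
    qu <- get(trials$unchosen[i], q)
    p <- exp(beta * qc) / (exp(beta * qc) + exp(beta * qu))
    ll <- ll + log(max(p, 1e-12))
    a <- if (trials$reward[i] == 1) alpha_high else alpha_low
    assign(trials$chosen[i], qc + a * (trials$reward[i] - qc), q)
  }
  ll
}

# brute-force sums-of-squares decomposition for a one-way within-subject design
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(m[, j]) - grand)^2
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(m[i, ]) - grand)^2
  ss_tot <- sum((m - grand)^2)
  ss_res <- ss_tot - ss_cond - ss_subj
  F <- (ss_cond / (k - 1)) / (ss_res / ((k - 1) * (n - 1)))
  list(F = F, p = pf(F, k - 1, (k - 1) * (n - 1), lower.tail = FALSE),
       peta = ss_cond / (ss_cond + ss_res))
}

# residualize-then-correlate route to the partial correlation on ranks
oracle_partial_spearman <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- residuals(lm(rx ~ rz))
  ey <- residuals(lm(ry ~ rz))
  cor(ex, ey)
}

oracle_bic <- function(ll, k, n) -2 * ll + k * log(n)

# random subject parameter draws on legal ranges
random_params <- function() {
  subject_params(alpha_high = runif(1), alpha_low = runif(1),
                 beta = runif(1, 0, 20))
}

# small random single-subject trial table
random_trials <- function(n = 30, pairs = c("AB", "CD", "EF")) {
  pr <- sample(pairs, n, replace = TRUE)
  first <- runif(n) < 0.5
  ch <- un <- character(n)
  for (i in 1:n) {
    st <- strsplit(pr[i], "")[[1]]
    ch[i] <- if (first[i]) st[1] else st[2]
    un[i] <- if (first[i]) st[2] else st[1]
  }
  data.frame(subject_id = "sx", trial_index = 1:n, pair = pr, chosen = ch,
             unchosen = un, reward = rbinom(n, 1, 0.5), omitted = FALSE,
             stringsAsFactors = FALSE)
}

ref_ab_means_probit <- c(qnorm(0.12), qnorm(0.11), qnorm(4.65 / 100))
ref_all_means_probit <- c(qnorm(0.18), qnorm(0.08), qnorm(4.95 / 100))

ab_design <- function(trials_per_pair = 100L) {
  task_design(pairs = "AB", high_reward_prob = c(AB = 0.8),
              trials_per_pair = trials_per_pair, n_blocks = 5L)
}
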