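# rlcap — reward-learning rates and value-driven attentional capture

Colors that predicted reward during instrumental learning capture
attention afterwards: a task-irrelevant distractor in a previously
high-valued color slows visual search. `rlcap` is an R package for the
computational analysis that links the *rate* of reward learning to the
*magnitude* of that capture. It is aimed at cognitive
scientists/psychologists working with probabilistic selection tasks
followed by additional-singleton search tasks, and ships a synthetic-data
generator so the entire pipeline runs (and is tested) without any raw
participant data.

## The model

Trial-by-trial choices in a probabilistic selection task (pairs AB, CD,
EF rewarded 80:20, 70:30, 60:40) are modelled with Q-learning using
separate learning rates for high- and low-value outcomes. Only the chosen
stimulus *i* is updated:

    Q_i(t+1) = Q_i(t) + alpha_High * (r - Q_i(t))   if r = 1
    Q_i(t+1) = Q_i(t) + alpha_Low  * (r - Q_i(t))   if r = 0

and choice is a softmax with inverse temperature beta in [0, 100]:

    P_A(t) = exp(beta * Q_t(A)) / (exp(beta * Q_t(A)) + exp(beta * Q_t(B)))

Parameters are estimated hierarchically: each subject's probit-scale
vector z' = (alpha'_H, alpha'_L, beta') is drawn from group-level normals
with means mu ~ N(0, 1) and SDs delta ~ U(0, 1.5); natural scales are
alpha = Phi(z') and beta = 100 * Phi(z'). Sampling is by an adaptive
Metropolis-within-Gibbs scheme (Rcpp core) with split-Rhat diagnostics
and KDE posterior modes; a single-learning-rate control model is compared
by individual and group BIC; posterior-predictive learning curves check
fit quality. The capture side implements the behavioural statistics:
chance-performer exclusion, condition RT means and slowing scores,
repeated-measures ANOVA with linear trend, Bonferroni-corrected paired
t-tests, and Spearman / partial Spearman correlations between fitted
learning rates and distractor slowing.

See `vignettes/value-capture-modelling.Rmd` for the full account of the
model, priors, sampler and design choices.

## Worked example

Simulate a 20-subject study, fit the dual-rate model to AB trials, and
run the capture battery:

```r
library(rlcap)

params <- draw_subject_params(
  c(probit_inverse(0.12, "alpha"), probit_inverse(0.11, "alpha"),
    probit_inverse(4.65, "beta")),      # group means, probit scale
  c(0.5, 0.5, 0.5), n_subjects = 20, seed = 21)
design   <- task_design()
learning <- simulate_learning_task(params, design, seed = 22)
capture  <- simulate_capture_task(params, design, coupling_spec(), seed = 23)

excl <- exclude_chance_performers(learning, design)
learning <- learning[learning$subject_id %in% excl$retained, ]
capture  <- capture[capture$subject_id %in% excl$retained, ]

fit <- run_sampler(learning, spec = model_spec(fit_scope = "AB_only"),
                   n_chains = 2, n_warmup = 500, n_samples = 500,
                   thin = 12, seed = 24)
print(fit)
#> Hierarchical Q-learning fit (2 learning rates, scope AB_only)
#>   subjects: 19; chains: 2 x 500 kept draws
#>   max split-Rhat: 1.0156 (converged)
#>   group-level posterior modes (natural scale):
#> alpha_high  alpha_low       beta
#>     0.1153     0.0915     6.3668

cs <- condition_means(capture)
m  <- as.matrix(cs[, c("mean_rt_none", "mean_rt_low", "mean_rt_high")])
colnames(m) <- c("none", "low", "high")
rm_anova_oneway(m)   # F(2, 36) = 25.05, p = 1.5e-07, partial eta^2 = 0.58
linear_trend(m)      # F(1, 18) = 30.83, p = 2.9e-05

print(capture_learning_report(correlation_inputs(fit, cs, learning)))
#> Capture-learning correlation battery (n = 19, scope AB_only)
#>   slowing_high ~ alpha_high | alpha_low  rho =  0.569, p = 0.01368
#>   slowing_low  ~ alpha_high              rho =  0.375, p = 0.1132
#>   slowing_diff ~ alpha_diff              rho =  0.498, p = 0.02992
#>   control: AB accuracy                   rho =  0.176, p = 0.4709
#>   control: final Q(A)                    rho =  0.475, p = 0.03966
#>   slowing_diff ~ alpha_diff (LOO)        rho =  0.498, p = 0.03525
```

One synthetic subject performed at chance and was excluded; the group
posterior modes sit near the generating means (alpha_High 0.12,
alpha_Low 0.11, beta 4.65); the ANOVA and linear trend show the planted
RT cost of value-laden distractors; and the partial rank correlation
recovers the planted link between high-value learning rate and
high-value slowing. Individual correlations at n = 19 are noisy — a
different seed can miss significance, which is exactly the sampling
variability the end-to-end tests quantify over 50 replicates.

The whole chain (simulate → exclude → four fits → BIC comparison →
posterior-predictive curves → capture report) is also available as

```r
run_pipeline(pipeline_config(seed = 1), "out/")
```

or from a shell via `Rscript inst/scripts/rlcap-pipeline.R --stage all
--seed 1 --out out/`.

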