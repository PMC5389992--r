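---
title: "Modelling reward learning and value-driven attentional capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reward learning and value-driven attentional capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Stimuli that have been paired with reward capture attention involuntarily:
a color that predicted high reward during an instrumental learning phase
slows visual search later, even when it is task-irrelevant. `rlcap`
implements the computational analysis that links *how fast* an individual
learns from high- versus low-value outcomes to *how much* capture that
individual later shows.

The pipeline has two behavioural stages:

1. **Probabilistic selection (learning) task.** Three color pairs AB, CD,
   EF are presented in randomized order (100 trials per pair, five blocks
   of 60 with equal pair composition). Choosing A yields the high-value
   outcome with probability 0.8 (B: 0.2); CD is 70:30 and EF 60:40.
   Outcomes are coded `r = 1` (high) or `r = 0` (low).
2. **Attentional-capture (additional-singleton) task.** 120 search trials;
   half contain no colored distractor, a quarter contain a distractor in
   the previously high-valued A color, a quarter in the low-valued B
   color. The per-subject *slowing score* is the mean correct-trial RT
   difference between a distractor condition and the no-distractor
   baseline.

## The Q-learning model

Each stimulus $i \in \{A,\dots,F\}$ carries an expected value $Q_i$,
updated only when chosen:

$$Q_i(t+1) = Q_i(t) + \begin{cases}
\alpha_{High}\,[r_i(t) - Q_i(t)] & \text{if } r = 1\\
\alpha_{Low}\,[r_i(t) - Q_i(t)] & \text{if } r = 0
\end{cases}$$

with learning rates $0 \le \alpha \le 1$. Choice between the two presented
stimuli is a softmax on their values,

$$P_A(t) = \frac{\exp(\beta Q_t(A))}{\exp(\beta Q_t(A)) + \exp(\beta Q_t(B))},$$

with inverse temperature $0 \le \beta \le 100$. A control model with a
single learning rate shared across outcomes is identical otherwise.

All Q-values start at 0.5 — the midpoint of the 0/1 outcome code, making
the first encounter of every pair an unbiased coin flip. The model never
states its own initialization, so this is a package choice; because
rewards are bounded in $\{0,1\}$ the update keeps every $Q$ in $[0,1]$
forever, which the test suite fuzz-checks.

Two fit scopes are supported: `all_pairs` uses every trial; `AB_only`
restricts the likelihood to AB trials (the colors reused in the capture
task). Since CD/EF share no stimuli with AB, their trials cannot move AB
values and are dropped entirely under `AB_only`.

## Hierarchical Bayesian estimation

Subject parameters are modelled on an unbounded probit scale
$z' = (\alpha'_{H}, \alpha'_{L}, \beta')$ with deterministic links
$\alpha = \Phi(z')$ and $\beta = 100\,\Phi(z')$. Each $z'_i$ is drawn from
a group-level normal with mean $\mu_{z'}$ and SD $\delta_{z'}$;
$\mu_{z'} \sim N(0,1)$ and $\delta_{z'} \sim U(\ell, 1.5)$.

**The group-SD prior.** The package default is $\ell = 0.001$, i.e.
effectively $U(0, 1.5)$, the standard choice in the probit-link
hierarchical construction this model family descends from. A variant with
$\ell = 1$ circulates in the applied literature; implementing it showed
that it forbids the group distribution from adapting to a homogeneous
sample: subjects are left essentially unpooled, their individually
ill-identified likelihoods drift along the $\alpha$–$\beta$ trade-off
ridge, and the $N(0,1)$ prior on $\mu_{\beta'}$ then drags the group
estimate of $\beta$ far upward. We verified with an independent sampler
(JAGS) that this is a property of that posterior, not of our code, and
kept the adapting prior as default. `prior_spec(sd_lower = 1)` restores
the narrow variant.

**Sampling.** The posterior is sampled by an own-written
Metropolis-within-Gibbs scheme (Rcpp core):

* componentwise random-walk updates of each subject's $z'$ (scales
  adapted toward 44% acceptance during warmup);
* a per-subject *joint* adaptive-Metropolis proposal using the empirical
  covariance accumulated in warmup, which moves along the correlated
  $\alpha$–$\beta$ ridge;
* conjugate Gibbs draws for the group means;
* slice sampling for the group SDs on their bounded support;
* group *translation* and *rescale* moves that shift or scale
  $\mu_{z'}$/$\delta_{z'}$ together with all subject parameters while the
  standardized offsets stay fixed — the centered/non-centered
  interleaving that removes the funnel-shaped slow directions of tightly
  pooled hierarchies.

Defaults are 4 chains, 1000 warmup sweeps, 1000 kept draws with thinning
4; all randomness flows through R's RNG, so a seed makes fits exactly
reproducible. Convergence is monitored with split-chain $\widehat R$ on
every parameter and a fit is flagged converged only if
$\max \widehat R < 1.05$ (the operationalization of "all close to 1").
Point estimates are kernel-density posterior modes: Gaussian kernel,
normal-reference bandwidth, 512-point grid over the sample range,
evaluated on the natural scale.

In a recovery experiment at the reference group modes
($\alpha_{High} = 0.12$, $\alpha_{Low} = 0.11$, $\beta = 4.65$; 20
subjects × 100 AB trials, probit-scale spread 0.1, 2 chains × 500 kept
draws) the group modes land within ±0.05 ($\alpha_{High}$), ±0.08
($\alpha_{Low}$) and ±1.5 ($\beta$) of truth with $\max \widehat R <
1.05$; the acceptance script reruns exactly this experiment.

## Model comparison and posterior predictions

The dual-rate and single-rate models are compared with
$\mathrm{BIC} = -2\log L + k\ln n$ at the individual level (per-subject
trial count, $k = 3$ vs $2$) and the group level (summed log-likelihood,
total trials, summed $k$). Because BIC is defined on the *maximized*
likelihood, `compare_models()` by default refines each subject's
natural-scale posterior modes with a short per-subject ML optimization
before scoring. This matters: hierarchical shrinkage pulls point
estimates toward the group centre and costs the three-parameter model
systematically more likelihood than the two-parameter one, enough to
flip the preferred model on data where the true-parameter likelihood
margin is decisively in favour of two rates. The unrefined variant
remains available (`estimates = "posterior_mode"`).

Posterior-predictive checks simulate the learning task at each subject's
fitted parameters and compare the simulated probability of choosing A on
AB trials, in five blocks of 20, against the observed curve
(`posterior_predictive_curves()`).

## The capture statistics

`capture_stats` reproduces the behavioural battery:

* **Exclusion.** A subject is excluded when a one-sided exact binomial
  test of their pooled choose-better rate against 0.5 is non-significant
  at 0.05 — the operational form of "chance-level performance".
* **Condition summaries.** Correct-trial RT means per distractor
  condition; slowing scores `high - none`, `low - none`, `high - low`;
  accuracy over all trials. No RT trimming is applied (none is specified
  for the source task; both choices are overridable).
* **One-way repeated-measures ANOVA** over the three distractor
  conditions by sums-of-squares partition, uncorrected degrees of
  freedom $(2, n-1 \cdot 2)$, partial $\eta^2 = SS_c/(SS_c+SS_r)$.
* **Linear trend** with contrast $(-1, 0, +1)$ over none < low < high,
  reported as $F = t^2$ on $(1, n-1)$.
* **Bonferroni-corrected paired t-tests** for the three condition pairs.
* **Correlation battery**: Spearman correlations are Pearson correlations
  of mid-ranks with t-approximate two-sided p-values; the partial
  variant controls a third ranked variable with $n-3$ degrees of
  freedom. The battery relates high-value slowing to
  $\hat\alpha_{High}$ (partialling $\hat\alpha_{Low}$), low-value
  slowing to $\hat\alpha_{High}$, the slowing difference to
  $\hat\alpha_{High} - \hat\alpha_{Low}$, runs the two control
  correlations (AB accuracy, final $Q_A$), and repeats the
  difference-score correlation after dropping the lowest
  $\hat\alpha$-difference subject.

## What the synthetic-data generator does and does not emulate

The generator reproduces the *structure* the analysis relies on: exact
trial counts and block composition, the Bernoulli reward schedules, choice
behaviour generated by the same Q-learning process the model assumes, and
capture RTs whose condition effects are a linear function of the
subject's true learning rates
(`rt = baseline + slope * alpha + noise`, defaults 650 ms baseline,
400 ms/unit for $\alpha_{High}$ on high-value trials, 100 ms/unit for
$\alpha_{Low}$ on low-value trials, 30 ms trial noise, 8% errors —
matching accuracy levels typical of this search task (~0.90) and producing slowing
effects of realistic tens-of-ms magnitude). The linear RT coupling is a
deliberate artifact: its only contract is that planted
learning-rate–slowing relationships are recoverable by the correlation
battery, which is what makes the pipeline testable end to end.

It does **not** emulate real RT distributions (no right skew, no
sequential effects), real lapses or omissions (an omission probability
knob exists but defaults to 0, as no omission rates are published), or
any perceptual/oculomotor process in the search task. Passing tests
therefore certify the statistical machinery, not the psychology: with
real data the model-misfit questions (is learning really delta-rule? is
slowing really linear in $\alpha$?) remain open.

Default group-truth for pipeline simulations: natural-scale means
$\alpha_{High} = 0.12$, $\alpha_{Low} = 0.11$, $\beta = 4.65$ (the
reference fit-to-AB modes) with probit-scale between-subject SD 0.5 —
enough individual variation for rank correlations over 20 subjects to be
meaningful.

## Numerical choices and degenerate inputs

* Choice probabilities are computed by subtracting the larger exponent
  (no overflow at $\beta = 100$) and floored at $10^{-12}$ before logs.
* Zero-variance contrast scores in `linear_trend()` return a documented
  `degenerate` flag ($F = \infty$, $p = 0$ when the mean is nonzero).
* Constant slowing scores short-circuit `capture_learning_report()` with
  a `degenerate` result instead of propagating NaNs.
* `posterior_mode()` of constant samples returns the constant.
* Identical seeds give byte-identical trial tables and draws; chain $c$
  of a fit uses `seed + c - 1`.

## Problem sizes

The bundled tests and the acceptance script run the recovery experiment
at 20 subjects × 100 AB trials with 2 chains × 500 kept draws (thinning
12), model comparison over 20 replicate data sets at 2 × 300 kept draws
(thinning 3), and the end-to-end coupling recovery over 50 replicate
pipelines at 2 × 200 kept draws. These sizes were chosen so that each
experiment's Monte-Carlo error is comfortably inside the tolerances being
asserted while a full run stays a desk-scale computation.

## Known limitations

* The sampler is a random-walk scheme; for much larger designs (hundreds
  of subjects) a gradient-based sampler would scale better.
* BIC model comparison uses point-estimate likelihoods; fully Bayesian
  alternatives (WAIC/LOO, Bayes factors) are deliberately out of scope.
* The random-effects exceedance-probability flavour of group BIC is not
  implemented; the group BIC is the summed-likelihood form.
* Subject exclusion uses the pooled choose-better rate; per-pair
  exclusion rules would behave differently for subjects who learn only
  the easy pair.
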