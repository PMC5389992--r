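#' Exclude subjects performing at chance in the learning task
#'
#' Pools every subject's non-omitted trials and tests the overall rate of
#' choosing the better stimulus of each pair (the one with the higher
#' scheduled reward probability) against 0.5 with a one-sided exact
#' binomial test. Subjects whose p-value is not below `alpha_level` are
#' excluded from all downstream analyses.
#'
#' @param learning Learning-trial table.
#' @param design The [task_design()] the data were collected under.
#' @param alpha_level Significance level (default 0.05).
#' @return List with `retained` (subject ids), `excluded` (subject ids) and
#'   `report` (data frame `subject_id, n_better, n_trials, p_value,
#'   retained`).
#' @export
exclude_chance_performers <- function(learning, design = task_design(),
                                      alpha_level = 0.05) {
  validate_learning_trials(learning)
  learning <- learning[!learning$omitted, , drop = FALSE]
  better <- vapply(design$pairs, function(p) strsplit(p, "")[[1]][1],
                   character(1))
  ids <- unique(learning$subject_id)
  if (length(ids) < 1L) stop("need at least one subject", call. = FALSE)
  rep_rows <- lapply(ids, function(s) {
    tr <- learning[learning$subject_id == s, ]
    x <- sum(tr$chosen %in% better)
    n <- nrow(tr)
    p <- stats::binom.test(x, n, p = 0.5, alternative = "greater")$p.value
    data.frame(subject_id = s, n_better = x, n_trials = n, p_value = p,
               retained = p < alpha_level, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  list(retained = report$subject_id[report$retained],
       excluded = report$subject_id[!report$retained],
       report = report)
}

#' Per-subject condition RT means and slowing scores
#'
#' RT means use correct trials only; accuracy is computed over all trials.
#' Slowing scores are differences of condition means against the
#' no-distractor baseline: `slowing_high = mean_rt_high - mean_rt_none`,
#' `slowing_low = mean_rt_low - mean_rt_none`, and `slowing_diff =
#' mean_rt_high - mean_rt_low`.
#'
#' @param capture Capture-trial table (`subject_id, trial_index, condition,
#'   correct, rt_ms`).
#' @return Data frame with one row per subject: condition means, slowing
#'   scores and per-condition accuracies.
#' @export
condition_means <- function(capture) {
  conds <- c("none", "high", "low")
  ids <- unique(capture$subject_id)
  rows <- lapply(ids, function(s) {
    tr <- capture[capture$subject_id == s, ]
    missing <- setdiff(conds, unique(tr$condition))
    if (length(missing)) {
      stop("subject ", s, " lacks condition(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    m <- vapply(conds, function(cc) {
      mean(tr$rt_ms[tr$condition == cc & tr$correct])
    }, numeric(1))
    acc <- vapply(conds, function(cc) mean(tr$correct[tr$condition == cc]),
                  numeric(1))
    data.frame(subject_id = s,
               mean_rt_none = m[["none"]], mean_rt_high = m[["high"]],
               mean_rt_low = m[["low"]],
               slowing_high = m[["high"]] - m[["none"]],
               slowing_low = m[["low"]] - m[["none"]],
               slowing_diff = m[["high"]] - m[["low"]],
               acc_none = acc[["none"]], acc_high = acc[["high"]],
               acc_low = acc[["low"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

as_condition_matrix <- function(values) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) stop("need a subject x condition matrix", call. = FALSE)
  if (anyNA(values)) stop("condition table must be complete", call. = FALSE)
  values
}

#' One-way repeated-measures ANOVA
#'
#' Classical sums-of-squares partition for a complete subject-by-condition
#' table: total variability splits into subject, condition and residual
#' (subject-by-condition) parts; `F = MS_condition / MS_residual` with
#' degrees of freedom `(levels - 1, (levels - 1) * (subjects - 1))`, and
#' partial eta squared is `SS_condition / (SS_condition + SS_residual)`.
#' No sphericity correction is applied.
#'
#' @param values Matrix or data frame, one row per subject and one column
#'   per condition, at least 2 of each.
#' @return List with `F`, `df_effect`, `df_error`, `p` and
#'   `partial_eta_sq`.
#' @export
rm_anova_oneway <- function(values) {
  values <- as_condition_matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  grand <- mean(values)
  ss_cond <- n * sum((colMeans(values) - grand)^2)
  ss_subj <- k * sum((rowMeans(values) - grand)^2)
  ss_total <- sum((values - grand)^2)
  ss_resid <- ss_total - ss_cond - ss_subj
  df_effect <- k - 1L
  df_error <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df_effect
  ms_resid <- ss_resid / df_error
  F <- if (ms_resid == 0) {
    if (ms_cond == 0) 0 else Inf
  } else ms_cond / ms_resid
  list(F = F,
       df_effect = df_effect,
       df_error = df_error,
       p = stats::pf(F, df_effect, df_error, lower.tail = FALSE),
       partial_eta_sq = if (ss_cond + ss_resid == 0) 0 else ss_cond / (ss_cond + ss_resid))
}

#' Linear trend across three ordered conditions
#'
#' Scores every subject on the contrast (-1, 0, +1) over the ordered
#' conditions (by default none < low < high) and tests the mean contrast
#' against zero with a one-sample test reported as `F = t^2` on
#' `(1, subjects - 1)` degrees of freedom. Partial eta squared is
#' `t^2 / (t^2 + df)`. If the contrast scores have zero variance with a
#' nonzero mean, `F = Inf` and `p = 0` are returned with a `degenerate`
#' flag.
#'
#' @param values Matrix or data frame, one row per subject, exactly 3
#'   condition columns.
#' @param order Column names or indices giving the low-to-high ordering;
#'   default `c("none", "low", "high")` when those names exist, otherwise
#'   columns 1:3 as given.
#' @return List with `F`, `df_effect`, `df_error`, `p`, `partial_eta_sq`
#'   and `degenerate`.
#' @export
linear_trend <- function(values, order = NULL) {
  values <- as_condition_matrix(values)
  if (ncol(values) != 3L) stop("linear_trend needs exactly 3 conditions", call. = FALSE)
  if (is.null(order)) {
    order <- if (all(c("none", "low", "high") %in% colnames(values))) {
      c("none", "low", "high")
    } else seq_len(3L)
  }
  values <- values[, order, drop = FALSE]
  contrast <- as.numeric(values %*% c(-1, 0, 1))
  n <- length(contrast)
  if (n < 2L) stop("need >= 2 subjects", call. = FALSE)
  s <- stats::sd(contrast)
  m <- mean(contrast)
  degenerate <- s == 0
  if (degenerate) {
    F <- if (m == 0) 0 else Inf
    p <- if (m == 0) 1 else 0
  } else {
    tval <- m / (s / sqrt(n))
    F <- tval^2
    p <- stats::pf(F, 1, n - 1, lower.tail = FALSE)
  }
  list(F = F, df_effect = 1L, df_error = n - 1L, p = p,
       partial_eta_sq = if (is.infinite(F)) 1 else F / (F + (n - 1L)),
       degenerate = degenerate)
}

#' Bonferroni-corrected pairwise paired t-tests
#'
#' Paired t-tests for every pair of condition columns; each p-value is
#' multiplied by the number of pairs and capped at 1.
#'
#' @param values Matrix or data frame, one row per subject, >= 2 condition
#'   columns.
#' @return Data frame with one row per pair: `pair, t, df, p_raw,
#'   p_bonferroni`.
#' @export
pairwise_bonferroni <- function(values) {
  values <- as_condition_matrix(values)
  k <- ncol(values)
  if (k < 2L) stop("need >= 2 conditions", call. = FALSE)
  cn <- colnames(values)
  if (is.null(cn)) cn <- paste0("c", seq_len(k))
  combos <- utils::combn(k, 2)
  n_pairs <- ncol(combos)
  rows <- lapply(seq_len(n_pairs), function(j) {
    i1 <- combos[1, j]; i2 <- combos[2, j]
    d <- values[, i1] - values[, i2]
    if (stats::sd(d) == 0) {
      tval <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      p <- if (mean(d) == 0) 1 else 0
      df <- length(d) - 1L
    } else {
      tt <- stats::t.test(values[, i1], values[, i2], paired = TRUE)
      tval <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    }
    data.frame(pair = paste(cn[i1], cn[i2], sep = "-"), t = tval, df = df,
               p_raw = p, p_bonferroni = min(1, p * n_pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), with a
#' two-sided p-value from the t approximation `t = rho * sqrt((n - 2) /
#' (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 5.
#' @return List with `rho`, `p` and `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 5L) stop("need at least 5 observations", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms all three vectors and computes the first-order partial
#' Pearson correlation on the ranks,
#' `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`, with a
#' two-sided p-value from the t approximation on `n - 3` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors to correlate.
#' @param z Control vector; must not be constant.
#' @return List with `rho`, `p` and `n`.
#' @export
partial_spearman_cor <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stop("x, y and z must have equal length", call. = FALSE)
  }
  if (n < 6L) stop("need at least 6 observations", call. = FALSE)
  if (stats::sd(z) == 0) stop("control vector is constant", call. = FALSE)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r_xy <- stats::cor(rx, ry); r_xz <- stats::cor(rx, rz); r_yz <- stats::cor(ry, rz)
  denom <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  if (denom == 0) stop("control is perfectly rank-correlated with x or y", call. = FALSE)
  rho <- (r_xy - r_xz * r_yz) / denom
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 3) / (1 - rho^2))
    2 * stats::pt(abs(tval), n - 3, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

#' Build the per-subject inputs for the correlation battery
#'
#' Aligns a fit's subject-level posterior modes with the capture-task
#' summary and the learning data, adding the difference score
#' `alpha_diff = alpha_high - alpha_low`, each subject's AB accuracy
#' (share of AB trials where A was chosen) and the model-implied belief in
#' the A color at the end of learning (final Q-value of A at the subject's
#' posterior-mode parameters).
#'
#' @param fit A dual-rate `qfit`.
#' @param capture_summary Output of [condition_means()].
#' @param learning Learning-trial table.
#' @return Data frame, one row per subject present in all three sources.
#' @export
correlation_inputs <- function(fit, capture_summary, learning) {
  if (fit$spec$n_learning_rates != 2L) {
    stop("correlation inputs need the dual-rate fit", call. = FALSE)
  }
  ids <- intersect(fit$subject_ids, capture_summary$subject_id)
  if (length(ids) == 0L) stop("no common subjects between fit and capture", call. = FALSE)
  sm <- fit$subject_modes[match(ids, fit$subject_modes$subject_id), ]
  cs <- capture_summary[match(ids, capture_summary$subject_id), ]
  ab_acc <- vapply(ids, function(s) {
    tr <- learning[learning$subject_id == s & !learning$omitted &
                     learning$pair == "AB", ]
    mean(tr$chosen == "A")
  }, numeric(1))
  final_q_a <- vapply(seq_along(ids), function(i) {
    tr <- learning[learning$subject_id == ids[i], ]
    sp <- subject_params(alpha_high = sm$alpha_high[i],
                         alpha_low = sm$alpha_low[i], beta = sm$beta[i])
    q_final_values(tr, sp, fit$spec)[["A"]]
  }, numeric(1))
  data.frame(
    subject_id = ids,
    alpha_high = sm$alpha_high,
    alpha_low = sm$alpha_low,
    alpha_diff = sm$alpha_high - sm$alpha_low,
    beta = sm$beta,
    slowing_high = cs$slowing_high,
    slowing_low = cs$slowing_low,
    slowing_diff = cs$slowing_diff,
    ab_accuracy = ab_acc,
    final_q_a = final_q_a,
    fit_scope = fit$spec$fit_scope,
    stringsAsFactors = FALSE
  )
}

#' Learning-rate / attentional-capture correlation battery
#'
#' The full set of relationships between model parameters and capture-task
#' slowing: (1) partial Spearman correlation of high-value slowing with
#' `alpha_high`, controlling for `alpha_low`; (2) Spearman correlation of
#' low-value slowing with `alpha_high`; (3) Spearman correlation of the
#' high-minus-low slowing difference with the learning-rate difference
#' score `alpha_diff`; (4) control correlations of high-value slowing with
#' AB accuracy and with the final Q-value of the A color; (5) a
#' leave-one-out repeat of (3) after removing the subject with the lowest
#' `alpha_diff`.
#'
#' @param inputs Data frame from [correlation_inputs()].
#' @return An object of class `capture_report`: named list of correlation
#'   results plus a `degenerate` flag set when any slowing score is
#'   constant across subjects.
#' @export
capture_learning_report <- function(inputs) {
  needed <- c("alpha_high", "alpha_low", "alpha_diff", "slowing_high",
              "slowing_low", "slowing_diff", "ab_accuracy", "final_q_a")
  missing <- setdiff(needed, names(inputs))
  if (length(missing)) {
    stop("inputs lack columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  degenerate <- stats::sd(inputs$slowing_high) == 0 ||
    stats::sd(inputs$slowing_low) == 0 || stats::sd(inputs$slowing_diff) == 0
  if (degenerate) {
    return(structure(list(degenerate = TRUE, n = nrow(inputs)),
                     class = "capture_report"))
  }
  loo <- inputs[-which.min(inputs$alpha_diff), ]
  structure(list(
    degenerate = FALSE,
    n = nrow(inputs),
    fit_scope = if (!is.null(inputs$fit_scope)) inputs$fit_scope[1] else NA,
    slowing_high_vs_alpha_high =
      partial_spearman_cor(inputs$slowing_high, inputs$alpha_high,
                           inputs$alpha_low),
    slowing_low_vs_alpha_high =
      spearman_cor(inputs$slowing_low, inputs$alpha_high),
    slowing_diff_vs_alpha_diff =
      spearman_cor(inputs$slowing_diff, inputs$alpha_diff),
    control_ab_accuracy =
      spearman_cor(inputs$slowing_high, inputs$ab_accuracy),
    control_final_q_a =
      spearman_cor(inputs$slowing_high, inputs$final_q_a),
    slowing_diff_vs_alpha_diff_loo =
      spearman_cor(loo$slowing_diff, loo$alpha_diff)
  ), class = "capture_report")
}

#' @export
print.capture_report <- function(x, ...) {
  if (x$degenerate) {
    cat("Capture-learning report: degenerate (constant slowing scores), n =",
        x$n, "\n")
    return(invisible(x))
  }
  cat("Capture-learning correlation battery (n = ", x$n, ", scope ",
      x$fit_scope, ")\n", sep = "")
  fmt <- function(lbl, r) {
    cat(sprintf("  %-38s rho = %6.3f, p = %.4g\n", lbl, r$rho, r$p))
  }
  fmt("slowing_high ~ alpha_high | alpha_low", x$slowing_high_vs_alpha_high)
  fmt("slowing_low  ~ alpha_high", x$slowing_low_vs_alpha_high)
  fmt("slowing_diff ~ alpha_diff", x$slowing_diff_vs_alpha_diff)
  fmt("control: AB accuracy", x$control_ab_accuracy)
  fmt("control: final Q(A)", x$control_final_q_a)
  fmt("slowing_diff ~ alpha_diff (LOO)", x$slowing_diff_vs_alpha_diff_loo)
  invisible(x)
}
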