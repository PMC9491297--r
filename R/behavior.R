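# Model-independent and model-derived behavioral statistics: diagnostic
# first-generalization trials, conditional repeat probabilities,
# psychometric choice/RT regressions, group tests, and posterior
# predictive checks.

# per-(block, category) action mapping inferred from the trial table:
# the rewarded action of state A (constant within a block by design)
.block_maps <- function(record) {
  # state A trials exist in every block (quartet structure); take the first
  idx <- tapply(seq_len(nrow(record)),
                paste(record$block, record$category),
                function(ii) ii[record$state[ii] == 1L][1])
  data.frame(block = record$block[unlist(idx)],
             category = record$category[unlist(idx)],
             map = record$rewarded_action[unlist(idx)])
}

#' Select the first-generalization diagnostic trials of a record
#'
#' For every newly mapped (block, category) contingency -- the first block
#' of each run plus each block where that category's action mapping was
#' remapped -- the first trial on which the subject earned a reward in the
#' category defines the reference (state, action); the next trial
#' presenting the category's complementary state is the diagnostic trial,
#' scored correct when the complementary action was chosen. Under the
#' default design this yields up to 2 categories x 2 new contingencies x 4
#' runs = 16 trials. With `strict = TRUE`, diagnostics are dropped when the
#' complementary state already received direct feedback pushing in the
#' same direction as generalization would (an unrewarded choice of its
#' incorrect action earlier in the contingency); missed diagnostic trials
#' are dropped, not deferred.
#'
#' @param record a behavioral record.
#' @param strict apply the optional direct-feedback exclusion? The default keeps
#'   every next-encounter diagnostic (16 per complete session).
#' @return data.frame with one row per diagnostic trial: `run`, `block`,
#'   `category`, `trial` (global index), `correct`.
#' @export
select_first_generalization_trials <- function(record, strict = FALSE) {
  maps <- .block_maps(record)
  out <- list()
  blocks <- unique(record[, c("run", "block", "block_in_run")])
  blocks <- blocks[order(blocks$block), ]
  for (cat in 1:2) {
    prev_map <- NA_integer_
    prev_run <- -1L
    for (bi in seq_len(nrow(blocks))) {
      b <- blocks$block[bi]
      m <- maps$map[maps$block == b & maps$category == cat]
      is_new <- blocks$run[bi] != prev_run || !identical(m, prev_map)
      prev_map <- m; prev_run <- blocks$run[bi]
      if (!is_new) next
      idx <- which(record$block == b & record$category == cat)
      rw <- idx[record$reward[idx] == 1 & !record$missed[idx]]
      if (!length(rw)) next
      t1 <- rw[1]
      s1 <- record$state[t1]; a1 <- record$chosen_action[t1]
      diag_idx <- idx[idx > t1 & record$state[idx] == 3L - s1]
      if (!length(diag_idx)) next
      td <- diag_idx[1]
      if (record$missed[td]) next
      if (strict) {
        pre <- idx[idx < t1 & record$state[idx] == 3L - s1 &
                   !record$missed[idx]]
        # unrewarded choice of the complementary state's incorrect action
        # (= the reference action) is direct feedback in the same direction
        if (any(record$chosen_action[pre] == a1 & record$reward[pre] == 0))
          next
      }
      out[[length(out) + 1L]] <- data.frame(
        run = record$run[td], block = b, category = cat,
        trial = record$trial[td],
        correct = record$chosen_action[td] == 3L - a1)
    }
  }
  if (!length(out))
    return(data.frame(run = integer(0), block = integer(0),
                      category = integer(0), trial = integer(0),
                      correct = logical(0)))
  do.call(rbind, out)
}

#' First-generalization accuracy of a record
#' @inheritParams select_first_generalization_trials
#' @return list with `accuracy` and `n_trials`.
#' @export
first_generalization_accuracy <- function(record, strict = FALSE) {
  d <- select_first_generalization_trials(record, strict = strict)
  list(accuracy = if (nrow(d)) mean(d$correct) else NA_real_,
       n_trials = nrow(d))
}

#' Conditional probabilities of repeating the prior relevant action
#'
#' For each executed trial, the most recent executed trial of the same
#' state and the most recent executed trial of the category's other state
#' serve as antecedents; each is binned by whether it was rewarded, and the
#' current choice counts as a repeat when it matches that antecedent's
#' action. Trials lacking an antecedent are excluded from the respective
#' bin. The interaction statistic is the same-state reward effect minus the
#' other-state reward effect.
#'
#' @param record a behavioral record.
#' @return list with `p` (2 x 2 matrix, rows same/other, cols
#'   reward/no-reward), `n` (counts), `interaction`.
#' @export
conditional_repeat_probabilities <- function(record) {
  n <- nrow(record)
  rep_ct <- matrix(0, 2, 2, dimnames = list(c("same", "other"),
                                            c("reward", "noreward")))
  tot_ct <- rep_ct
  last <- matrix(NA_integer_, 2, 2)  # last executed trial per (cat, state)
  for (t in seq_len(n)) {
    if (record$missed[t]) next
    cat <- record$category[t]; s <- record$state[t]
    for (kind in 1:2) {  # 1 same state, 2 other state
      ante <- last[cat, if (kind == 1) s else 3L - s]
      if (!is.na(ante)) {
        col <- if (record$reward[ante] == 1) 1L else 2L
        tot_ct[kind, col] <- tot_ct[kind, col] + 1
        if (record$chosen_action[t] == record$chosen_action[ante])
          rep_ct[kind, col] <- rep_ct[kind, col] + 1
      }
    }
    last[cat, s] <- t
  }
  p <- rep_ct / ifelse(tot_ct > 0, tot_ct, NA)
  list(p = p, n = tot_ct,
       interaction = (p["same", "reward"] - p["same", "noreward"]) -
                     (p["other", "reward"] - p["other", "noreward"]))
}

#' Replay a record under fitted parameters to recover latent traces
#'
#' Deterministically re-runs the model's updates over the record's
#' choice/outcome stream and attaches the latent trace columns
#' (preparatory-state value, decision-time action values, prediction
#' errors, policy probability).
#'
#' @inheritParams negative_log_likelihood
#' @return the record with trace columns replaced/added.
#' @export
replay_record <- function(record, spec, params = numeric(0),
                          backend = "cpp", control = list()) {
  if (is.character(spec)) spec <- model_spec(spec)
  full <- resolve_params(spec, params)
  eng <- grl_engine(record, spec, full, mode = "replay",
                    chosen = record$chosen_action, reward = record$reward,
                    missed = record$missed, traces = TRUE,
                    control = control, backend = backend)
  for (cn in names(eng$traces)) record[[cn]] <- eng$traces[[cn]]
  record
}

# normalized action-value difference signed toward the previous action;
# returns per-trial covariate plus the repeat indicator
.psychometric_frame <- function(record) {
  dq <- record$q_left - record$q_right
  mx <- max(abs(dq), na.rm = TRUE)
  dqn <- if (is.finite(mx) && mx > 0) dq / mx else dq * 0
  n <- nrow(record)
  prev <- NA_integer_
  x <- rep(NA_real_, n); y <- rep(NA, n)
  for (t in seq_len(n)) {
    if (record$missed[t]) next
    if (!is.na(prev)) {
      sgn <- if (record$chosen_action[prev] == 1L) 1 else -1
      x[t] <- sgn * dqn[t]
      y[t] <- record$chosen_action[t] == record$chosen_action[prev]
    }
    prev <- t
  }
  keep <- !is.na(x)
  data.frame(x = x[keep], y = y[keep], dqn_abs = abs(dqn)[keep],
             rt = record$rt[keep])
}

#' Psychometric choice regression: repeat probability vs value difference
#'
#' Logistic regression of repeating the most recent action (independent of
#' state) on the subject-normalized action-value difference signed toward
#' the previous action; a positive slope means value differences steer
#' repetition. Requires trace columns (see [replay_record()]).
#'
#' @param record record with `q_left`/`q_right` traces.
#' @return list with `slope`, `intercept`, `n`, `flagged` (degenerate
#'   all-repeat/never-repeat subjects are flagged and their slope is `NA`).
#' @export
psychometric_choice <- function(record) {
  d <- .psychometric_frame(record)
  if (nrow(d) < 8 || length(unique(d$y)) < 2 || stats::sd(d$x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, n = nrow(d),
                flagged = TRUE))
  fit <- stats::glm(y ~ x, data = d, family = stats::binomial())
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = nrow(d), flagged = FALSE)
}

#' Psychometric RT regression: reaction time vs absolute value difference
#'
#' Linear regression of RT on the normalized absolute action-value
#' difference; the speed hypothesis is a negative slope (faster when values
#' are well separated).
#'
#' @inheritParams psychometric_choice
#' @return list with `slope`, `intercept`, `n`, `flagged`.
#' @export
psychometric_rt <- function(record) {
  d <- .psychometric_frame(record)
  d <- d[!is.na(d$rt), ]
  if (nrow(d) < 8 || stats::sd(d$dqn_abs) == 0)
    return(list(slope = if (nrow(d) > 1 && stats::sd(d$rt) == 0) 0 else NA_real_,
                intercept = NA_real_, n = nrow(d), flagged = TRUE))
  if (stats::sd(d$rt) == 0)
    return(list(slope = 0, intercept = d$rt[1], n = nrow(d), flagged = FALSE))
  fit <- stats::lm(rt ~ dqn_abs, data = d)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = nrow(d), flagged = FALSE)
}

#' One-tailed one-sample t-test with degenerate-input flagging
#' @param x numeric sample; @param mu null value;
#' @param alternative `"greater"` or `"less"`.
#' @return list `estimate`, `t`, `df`, `p`, `flagged`.
#' @export
one_sample_t <- function(x, mu = 0, alternative = "greater") {
  x <- x[is.finite(x)]
  if (length(x) < 2 || stats::sd(x) == 0)
    return(list(estimate = mean(x), t = NA_real_, df = NA_real_,
                p = NA_real_, flagged = TRUE))
  tt <- stats::t.test(x, mu = mu, alternative = alternative)
  list(estimate = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, flagged = FALSE)
}

#' One-tailed independent-samples t-test (pooled variance)
#' @param x,y the two groups; @param alternative direction for `x - y`.
#' @return list `estimate` (mean difference), `t`, `df`, `p`, `flagged`.
#' @export
two_sample_t <- function(x, y, alternative = "greater") {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    return(list(estimate = mean(x) - mean(y), t = NA_real_, df = NA_real_,
                p = NA_real_, flagged = TRUE))
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0)
    return(list(estimate = mean(x) - mean(y), t = 0, df = length(x) +
                  length(y) - 2, p = 0.5, flagged = TRUE))
  tt <- stats::t.test(x, y, alternative = alternative, var.equal = TRUE)
  list(estimate = unname(diff(rev(tt$estimate))), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, flagged = FALSE)
}

#' One-tailed Pearson correlation test
#' @param x,y paired samples; @param alternative direction of `r`.
#' @return list `r`, `t`, `df`, `p`, `flagged`.
#' @export
pearson_cor <- function(x, y, alternative = "greater") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_,
                flagged = TRUE))
  ct <- stats::cor.test(x, y, alternative = alternative, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, flagged = FALSE)
}

#' Group tests of first-generalization accuracy
#'
#' One-tailed one-sample t-tests against the 50% chance level within each
#' generalizer group (Discriminative above, Associative below,
#' Nongeneralizer below), one-tailed two-sample tests between groups
#' (Discriminative > Nongeneralizer > Associative), and the Pearson
#' correlation between accuracy and the negated state-generalization weight
#' (more negative `g_s` is hypothesized to yield higher accuracy).
#'
#' @param accuracy per-subject first-generalization accuracies.
#' @param group per-subject labels from [classify_generalizer()].
#' @param g_s per-subject fitted state-generalization weights.
#' @return list of test results; groups of fewer than 2 subjects are
#'   skipped with a flag.
#' @export
first_generalization_tests <- function(accuracy, group, g_s = NULL) {
  grab <- function(g) accuracy[group == g]
  res <- list(
    discriminative_vs_chance = one_sample_t(grab("Discriminative"), 0.5, "greater"),
    nongeneralizer_vs_chance = one_sample_t(grab("Nongeneralizer"), 0.5, "less"),
    associative_vs_chance = one_sample_t(grab("Associative"), 0.5, "less"),
    disc_vs_assoc = two_sample_t(grab("Discriminative"), grab("Associative"), "greater"),
    disc_vs_non = two_sample_t(grab("Discriminative"), grab("Nongeneralizer"), "greater")
  )
  if (!is.null(g_s))
    res$accuracy_vs_neg_gs <- pearson_cor(accuracy, -g_s, "greater")
  res
}

#' Posterior predictive check over a cohort
#'
#' For each subject, simulates `n_sims` data sets from the supplied model
#' (with that subject's fitted parameters) yoked to the subject's own
#' record, then averages the first-generalization accuracy and conditional
#' repeat probabilities across simulations. The same statistics computed on
#' the source records sit alongside for comparison.
#'
#' @param records list of source behavioral records.
#' @param params_list per-subject named free-parameter vectors.
#' @param spec model label or [model_spec()] used to simulate.
#' @param n_sims simulations per subject.
#' @param seed master seed.
#' @param strict passed to the diagnostic-trial selector.
#' @return list with `source` and `simulated` per-subject data.frames
#'   (`first_gen_acc`, repeat-bin probabilities, `interaction`).
#' @export
posterior_predictive_check <- function(records, params_list, spec,
                                       n_sims = 100L, seed = 1L,
                                       strict = FALSE) {
  if (is.character(spec)) spec <- model_spec(spec)
  stat_one <- function(rec) {
    fg <- first_generalization_accuracy(rec, strict = strict)
    cr <- conditional_repeat_probabilities(rec)
    data.frame(first_gen_acc = fg$accuracy, n_diag = fg$n_trials,
               same_reward = cr$p["same", "reward"],
               same_noreward = cr$p["same", "noreward"],
               other_reward = cr$p["other", "reward"],
               other_noreward = cr$p["other", "noreward"],
               interaction = cr$interaction)
  }
  source_stats <- do.call(rbind, lapply(records, stat_one))
  source_stats$subject <- seq_along(records)
  sim_stats <- do.call(rbind, lapply(seq_along(records), function(i) {
    per_sim <- do.call(rbind, lapply(seq_len(n_sims), function(k) {
      rec <- run_agent(spec = spec, params = params_list[[i]],
                       mode = "yoked", ref = records[[i]],
                       seed = as.integer((seed + 104729 * i + k) %%
                                         .Machine$integer.max),
                       traces = FALSE, rt = NULL)
      stat_one(rec)
    }))
    out <- as.data.frame(t(colMeans(per_sim, na.rm = TRUE)))
    out$subject <- i
    out
  }))
  list(source = source_stats, simulated = sim_stats)
}
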