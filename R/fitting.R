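# Subject-level maximum-likelihood fitting, AICc model comparison, and
# group classification.

# bounded <-> unconstrained transforms used by the simplex optimizer
.to_natural <- function(x, type) {
  switch(type,
    unit = stats::plogis(x),
    negunit = -stats::plogis(x),
    signed = 2 * stats::plogis(x) - 1,
    halfunit = 0.5 + 0.5 * stats::plogis(x),
    positive = exp(x),
    real = x)
}
.to_unconstrained <- function(v, type) {
  switch(type,
    unit = stats::qlogis(v),
    negunit = stats::qlogis(-v),
    signed = stats::qlogis((v + 1) / 2),
    halfunit = stats::qlogis((v - 0.5) * 2),
    positive = log(v),
    real = v)
}

#' Negative log-likelihood of a behavioral record under a model
#'
#' Replays the record's outcome stream deterministically through the
#' model's update equations and sums `-log` of the policy probability of
#' each executed choice. Missed trials contribute no likelihood term and no
#' action-dependent updates (the cue-locked state-value update still
#' applies); an empty record has likelihood 1 (NLL 0).
#'
#' @param record a `grl_record` or data.frame with the trial columns plus
#'   `chosen_action`, `reward`, `missed`.
#' @param spec model label or [model_spec()].
#' @param params named free-parameter vector (checked against bounds).
#' @param backend `"cpp"` or `"r"`.
#' @param control engine options.
#' @return NLL in nats.
#' @export
negative_log_likelihood <- function(record, spec, params = numeric(0),
                                    backend = "cpp", control = list()) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (nrow(record) == 0) return(0)
  full <- resolve_params(spec, params)
  missed <- if ("missed" %in% names(record)) record$missed else
    is.na(record$chosen_action)
  grl_engine(record, spec, full, mode = "replay",
             chosen = record$chosen_action, reward = record$reward,
             missed = missed, control = control, backend = backend)$nll
}

#' Corrected Akaike information criterion
#'
#' `AICc = 2k + 2 NLL + 2k(k + 1) / (n - k - 1)`; infinite when the
#' correction denominator is not positive.
#'
#' @param nll negative log-likelihood in nats; @param k free parameters;
#' @param n number of likelihood-contributing trials.
#' @export
aicc <- function(nll, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  2 * k + 2 * nll + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a model to a record by maximum likelihood
#'
#' Randomly seeded restarts of the Nelder-Mead simplex on an unconstrained
#' reparameterization (logit for interval-bounded parameters, log for the
#' temperature); estimates are reported back-transformed into natural
#' space. The best NLL across restarts wins, ties going to the solution
#' reached in fewer iterations. The zero-parameter chance model and the
#' one-parameter intercept model use their closed-form optima.
#'
#' @inheritParams negative_log_likelihood
#' @param n_restarts number of restarts (first starts mid-range, the rest
#'   uniform in bounds); deterministic given `seed`.
#' @param seed restart-schedule seed.
#' @return object of class `grl_fit`: `model_id`, `params` (free, natural
#'   space), `nll`, `deviance`, `aicc`, `df`, `n`, `convergence` (TRUE when
#'   at least one restart converged), `n_restarts`.
#' @export
fit_mle <- function(record, spec, n_restarts = 50L, seed = 1L,
                    backend = "cpp", control = list()) {
  if (is.character(spec)) spec <- model_spec(spec)
  ok <- !record$missed
  n_trials <- sum(ok)
  finish <- function(pars, nll, conv) {
    structure(list(model_id = spec$model_id, params = pars, nll = nll,
                   deviance = 2 * nll, aicc = aicc(nll, spec$df, n_trials),
                   df = spec$df, n = n_trials, convergence = conv,
                   n_restarts = n_restarts), class = "grl_fit")
  }
  if (spec$model_id == "chance")
    return(finish(numeric(0), n_trials * log(2), TRUE))
  if (spec$model_id == "intercept") {
    k <- sum(record$chosen_action[ok] == 1L)
    p <- if (n_trials > 0) k / n_trials else 0.5
    nll <- 0
    if (k > 0) nll <- nll - k * log(p)
    if (n_trials - k > 0) nll <- nll - (n_trials - k) * log(1 - p)
    return(finish(c(p_left = p), nll, TRUE))
  }
  types <- .par_transform[spec$free]
  objective <- function(theta) {
    v <- mapply(.to_natural, theta, types)
    names(v) <- spec$free
    negative_log_likelihood(record, spec, v, backend = backend,
                            control = control)
  }
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      v <- vapply(spec$free, function(p) {
        r <- .par_sample_range[[p]]
        if (i == 1) mean(r) else stats::runif(1, r[1], r[2])
      }, numeric(1))
      mapply(.to_unconstrained, v, types)
    })
  })
  best <- NULL
  any_conv <- FALSE
  for (th0 in starts) {
    o <- tryCatch(
      stats::optim(th0, objective, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(o)) next
    conv <- o$convergence == 0
    any_conv <- any_conv || conv
    if (is.null(best) || o$value < best$value ||
        (o$value == best$value && o$counts[1] < best$counts[1])) best <- o
  }
  if (is.null(best))
    return(finish(stats::setNames(rep(NA_real_, spec$df), spec$free), Inf, FALSE))
  est <- mapply(.to_natural, best$par, types)
  names(est) <- spec$free
  finish(est, best$value, any_conv)
}

#' @export
print.grl_fit <- function(x, ...) {
  cat(sprintf("grl_fit %s: NLL %.2f, AICc %.2f (df %d, n %d)\n",
              x$model_id, x$nll, x$aicc, x$df, x$n))
  if (length(x$params)) print(round(x$params, 4))
  invisible(x)
}

#' Fit and compare a set of models across subjects
#'
#' Per subject and model: NLL, deviance, AICc, and the deviance residual
#' relative to the hysteresis baseline both without penalty
#' (`2 NLL_hyst - 2 NLL_model`) and with the AICc penalty
#' (`AICc_hyst - AICc_model`, positive = better than hysteresis). The
#' per-subject winner is the AICc minimizer, ties broken toward fewer
#' degrees of freedom.
#'
#' @param records list of behavioral records.
#' @param model_ids character vector of model labels (the hysteresis model
#'   is added automatically when absent, as the residual baseline).
#' @inheritParams fit_mle
#' @return list with `fits` (subject x model list), `table` (long
#'   data.frame), and `winners` (per-subject winning label).
#' @export
compare_models <- function(records, model_ids, n_restarts = 10L, seed = 1L,
                           backend = "cpp", control = list()) {
  if (!"hysteresis" %in% model_ids) model_ids <- c(model_ids, "hysteresis")
  fits <- lapply(seq_along(records), function(i) {
    fs <- lapply(model_ids, function(m)
      fit_mle(records[[i]], m, n_restarts = n_restarts,
              seed = seed + i, backend = backend, control = control))
    names(fs) <- model_ids
    fs
  })
  rows <- do.call(rbind, lapply(seq_along(fits), function(i) {
    hy <- fits[[i]][["hysteresis"]]
    do.call(rbind, lapply(fits[[i]], function(f) data.frame(
      subject = i, model_id = f$model_id, df = f$df, nll = f$nll,
      deviance = f$deviance, aicc = f$aicc,
      resid_deviance = hy$deviance - f$deviance,
      resid_aicc = hy$aicc - f$aicc)))
  }))
  rownames(rows) <- NULL
  winners <- vapply(fits, function(fs) {
    a <- vapply(fs, function(f) f$aicc, numeric(1))
    d <- vapply(fs, function(f) f$df, numeric(1))
    names(fs)[order(a, d)][1]
  }, character(1))
  list(fits = fits, table = rows, winners = winners)
}

# eligible (non-first-encounter, non-missed) correctness of a record;
# per-run first exposures are excluded when cue ids are run-specific
# (fresh cues each run), session-first exposures otherwise
.eligible_correct <- function(record) {
  per_run <- any(grepl("^r\\d+_", record$cue_id))
  key <- if (per_run) paste(record$run, record$cue_id) else record$cue_id
  first <- !duplicated(key)
  keep <- !first & !record$missed
  list(correct = record$chosen_action[keep] == record$rewarded_action[keep],
       n = sum(keep))
}

#' Overall accuracy of a record
#'
#' Proportion of choices of the action that could have been rewarded,
#' excluding missed trials and initial encounters with novel cues.
#' @param record a behavioral record.
#' @export
record_accuracy <- function(record) {
  e <- .eligible_correct(record)
  if (e$n == 0) return(NA_real_)
  mean(e$correct)
}

#' Classify a subject as Good learner, Poor learner, or Nonlearner
#'
#' Good: accuracy above the 50% chance level by a one-tailed exact binomial
#' test at alpha = .05 (excluding first encounters with novel cues).
#' Otherwise Poor when the best learning model improves on the hysteresis
#' baseline (by AICc, or by a likelihood-ratio test for `method = "lrt"`),
#' else Nonlearner.
#'
#' @param record behavioral record.
#' @param fits named list of `grl_fit`s including `"hysteresis"` and at
#'   least one learning model.
#' @param method `"aicc"` (default) or `"lrt"`.
#' @param alpha test level.
#' @return list with `group`, `accuracy`, `binom_p`, `n_eligible`.
#' @export
classify_learner <- function(record, fits, method = c("aicc", "lrt"),
                             alpha = 0.05) {
  method <- match.arg(method)
  e <- .eligible_correct(record)
  if (e$n == 0)
    return(list(group = "unclassifiable", accuracy = NA_real_,
                binom_p = NA_real_, n_eligible = 0L))
  p <- stats::binom.test(sum(e$correct), e$n, p = 0.5,
                         alternative = "greater")$p.value
  if (p < alpha)
    return(list(group = "Good", accuracy = mean(e$correct), binom_p = p,
                n_eligible = e$n))
  hy <- fits[["hysteresis"]]
  learn <- fits[setdiff(names(fits), c("hysteresis", "intercept", "chance"))]
  better <- if (method == "aicc") {
    any(vapply(learn, function(f) f$aicc < hy$aicc, logical(1)))
  } else {
    any(vapply(learn, function(f) {
      ddf <- f$df - hy$df
      if (ddf <= 0) return(f$nll < hy$nll)
      stats::pchisq(2 * (hy$nll - f$nll), ddf, lower.tail = FALSE) < alpha
    }, logical(1)))
  }
  list(group = if (better) "Poor" else "Nonlearner",
       accuracy = mean(e$correct), binom_p = p, n_eligible = e$n)
}

#' Classify generalization strategy from a fitted state-generalization weight
#'
#' Discriminative for `g_s < 0`, Associative for `g_s > 0`, Nongeneralizer
#' within the tolerance band `|g_s| <= eps` (bounded optimization rarely
#' lands exactly on zero).
#'
#' @param fit a `grl_fit` of a model with free `g_s`, or a numeric `g_s`.
#' @param eps tolerance around zero.
#' @export
classify_generalizer <- function(fit, eps = 1e-3) {
  g <- if (is.numeric(fit)) fit else unname(fit$params["g_s"])
  if (is.na(g)) return(NA_character_)
  if (abs(g) <= eps) "Nongeneralizer"
  else if (g < 0) "Discriminative" else "Associative"
}

#' Reward sensitivity of a fitted GRL instantiation
#'
#' `log(alpha * (1 - g_a - g_s + g_s * g_a) / tau)`: the log ratio between
#' the summed magnitudes of the four generalized value updates and the
#' softmax temperature. A nonpositive argument (e.g., `alpha = 0`) returns
#' `-Inf` as a flagged sentinel.
#'
#' @param params named vector with `alpha`, `g_a`, `g_s`, `tau` (missing
#'   generalization weights default to 0).
#' @export
reward_sensitivity <- function(params) {
  ga <- if ("g_a" %in% names(params)) params[["g_a"]] else 0
  gs <- if ("g_s" %in% names(params)) params[["g_s"]] else 0
  arg <- params[["alpha"]] * (1 - ga - gs + gs * ga) / params[["tau"]]
  if (arg <= 0) return(-Inf)
  log(arg)
}

#' Model recovery: simulate from one model, refit a model set
#'
#' @param generator model label generating the cohort.
#' @param n_subjects cohort size.
#' @param param_sampler per-subject generating-parameter sampler.
#' @param model_ids candidate set to refit.
#' @inheritParams compare_models
#' @param config base task configuration.
#' @return `compare_models()` result plus `winner_counts`.
#' @export
model_recovery <- function(generator, n_subjects, param_sampler, model_ids,
                           config = task_config(), n_restarts = 10L,
                           seed = 1L, backend = "cpp") {
  recs <- simulate_cohort(n_subjects, generator, param_sampler,
                          config = config, seed = seed, traces = FALSE,
                          rt = NULL, backend = backend)
  cmp <- compare_models(recs, model_ids, n_restarts = n_restarts,
                        seed = seed + 1L, backend = backend)
  cmp$generator <- generator
  cmp$winner_counts <- sort(table(cmp$winners), decreasing = TRUE)
  cmp
}

#' Parameter recovery for a model with free parameters
#'
#' Simulates agents with known parameter draws, refits the same model, and
#' tabulates truth against estimate.
#'
#' @inheritParams model_recovery
#' @param model model label to simulate from and refit.
#' @return data.frame, one row per subject x parameter, columns `subject`,
#'   `param`, `truth`, `estimate`.
#' @export
parameter_recovery <- function(model, n_subjects, param_sampler,
                               config = task_config(), n_restarts = 10L,
                               seed = 1L, backend = "cpp") {
  spec <- model_spec(model)
  truths <- list()
  sampler_logged <- function(i) {
    p <- param_sampler(i)
    truths[[i]] <<- p
    p
  }
  recs <- simulate_cohort(n_subjects, spec, sampler_logged, config = config,
                          seed = seed, traces = FALSE, rt = NULL)
  do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    f <- fit_mle(recs[[i]], spec, n_restarts = n_restarts, seed = seed + i)
    data.frame(subject = i, param = names(truths[[i]]),
               truth = unname(truths[[i]]),
               estimate = unname(f$params[names(truths[[i]])]))
  }))
}
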