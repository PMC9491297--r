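# Model zoo: generalized reinforcement learning (GRL) family, metastate
# belief learners (SPE, HMM), dual-systems mixtures, and the
# hysteresis/intercept/chance baselines.
#
# Conventions used throughout: actions 1 = left, 2 = right; states 1 = A,
# 2 = B; categories 1, 2; metastate hypotheses 1 = "AL/BR", 2 = "AR/BL".

# canonical parameter union, in fixed order
.par_names <- c("alpha", "g_a", "g_s", "g_sa", "lambda", "tau",
                "beta0", "lambda_beta", "beta_r",
                "alpha_spe", "theta0", "theta1", "w_mb", "p_left")

# optimizer transform class per parameter
.par_transform <- c(
  alpha = "unit", g_a = "negunit", g_s = "signed", g_sa = "negunit",
  lambda = "unit", tau = "positive", beta0 = "real", lambda_beta = "unit",
  beta_r = "real", alpha_spe = "unit", theta0 = "halfunit", theta1 = "unit",
  w_mb = "unit", p_left = "unit")

# restart-sampling ranges in natural space (real-line parameters get a
# finite practical range; bounded parameters use their bounds' interior)
.par_sample_range <- list(
  alpha = c(0.05, 0.95), g_a = c(-0.95, -0.05), g_s = c(-0.95, 0.95),
  g_sa = c(-0.95, -0.05), lambda = c(0.05, 0.95), tau = c(0.1, 3),
  beta0 = c(-1, 1), lambda_beta = c(0.05, 0.95), beta_r = c(-1, 1),
  alpha_spe = c(0.05, 0.95), theta0 = c(0.55, 0.95), theta1 = c(0.02, 0.5),
  w_mb = c(0.05, 0.95), p_left = c(0.05, 0.95))

.bias_pars <- c("tau", "beta0", "lambda_beta", "beta_r")

.model_table <- list(
  "A0|S0"    = list(free = c("alpha", .bias_pars), fixed = c(g_a = 0, g_s = 0, g_sa = 0), mb = "none", w = "mf"),
  "A-|S0"    = list(free = c("alpha", .bias_pars), fixed = c(g_a = -1, g_s = 0, g_sa = -1), mb = "none", w = "mf"),
  "AX|S0"    = list(free = c("alpha", "g_a", .bias_pars), fixed = c(g_s = 0), mb = "none", w = "mf", tie = "gsa_ga"),
  "A0|S+"    = list(free = c("alpha", .bias_pars), fixed = c(g_a = 0, g_s = 1, g_sa = 0), mb = "none", w = "mf"),
  "A0|S-"    = list(free = c("alpha", .bias_pars), fixed = c(g_a = 0, g_s = -1, g_sa = 0), mb = "none", w = "mf"),
  "A0|SY"    = list(free = c("alpha", "g_s", .bias_pars), fixed = c(g_a = 0, g_sa = 0), mb = "none", w = "mf"),
  "A-|S+"    = list(free = c("alpha", .bias_pars), fixed = c(g_a = -1, g_s = 1, g_sa = -1), mb = "none", w = "mf"),
  "A-|S-"    = list(free = c("alpha", .bias_pars), fixed = c(g_a = -1, g_s = -1, g_sa = -1), mb = "none", w = "mf"),
  "AW|SW"    = list(free = c("alpha", "g_s", .bias_pars), fixed = NULL, mb = "none", w = "mf", tie = "shared_g"),
  "AX|SY"    = list(free = c("alpha", "g_a", "g_s", .bias_pars), fixed = NULL, mb = "none", w = "mf", tie = "gsa_ga"),
  "AX|SY|Z"  = list(free = c("alpha", "g_a", "g_s", "g_sa", .bias_pars), fixed = NULL, mb = "none", w = "mf"),
  "SPE"      = list(free = c("alpha_spe", .bias_pars), fixed = c(alpha = 0, g_a = 0, g_s = 0, g_sa = 0), mb = "spe", w = "mb"),
  "SPE+RL"   = list(free = c("alpha", "alpha_spe", "w_mb", .bias_pars), fixed = c(g_a = 0, g_s = 0, g_sa = 0), mb = "spe", w = "dual"),
  "HMM0"     = list(free = c("theta0", .bias_pars), fixed = c(alpha = 0, g_a = 0, g_s = 0, g_sa = 0, theta1 = 0), mb = "hmm", w = "mb"),
  "HMM"      = list(free = c("theta0", "theta1", .bias_pars), fixed = c(alpha = 0, g_a = 0, g_s = 0, g_sa = 0), mb = "hmm", w = "mb"),
  "HMM0+RL"  = list(free = c("alpha", "theta0", "w_mb", .bias_pars), fixed = c(g_a = 0, g_s = 0, g_sa = 0, theta1 = 0), mb = "hmm", w = "dual"),
  "HMM+RL"   = list(free = c("alpha", "theta0", "theta1", "w_mb", .bias_pars), fixed = c(g_a = 0, g_s = 0, g_sa = 0), mb = "hmm", w = "dual"),
  "hysteresis" = list(free = .bias_pars, fixed = c(alpha = 0, g_a = 0, g_s = 0, g_sa = 0), mb = "none", w = "mf"),
  "intercept"  = list(free = "p_left", fixed = NULL, mb = "none", w = "static"),
  "chance"     = list(free = character(0), fixed = c(p_left = 0.5), mb = "none", w = "static")
)

#' Model registry
#'
#' Lists every model in the zoo with its class and degrees of freedom. The
#' GRL labels encode the treatment of the action- and state-generalization
#' weights: `A0`/`A-`/`AX` for absent, fixed at -1, or free action
#' generalization and `S0`/`S+`/`S-`/`SY` for absent, fixed at +1, fixed at
#' -1, or free state generalization. `AX|SY|Z` adds a free interaction
#' weight, `AW|SW` shares a single weight across both dimensions. `SPE` and
#' `HMM`/`HMM0` are the metastate belief learners; `+RL` marks dual-systems
#' mixtures with basic reinforcement learning.
#'
#' @return data.frame with columns `model_id`, `df`, `class`.
#' @export
grl_models <- function() {
  ids <- names(.model_table)
  data.frame(
    model_id = ids,
    df = vapply(ids, function(i) length(.model_table[[i]]$free), integer(1)),
    class = vapply(ids, function(i) {
      m <- .model_table[[i]]
      if (i %in% c("hysteresis", "intercept", "chance")) "baseline"
      else if (m$w == "dual") "dual"
      else if (m$mb != "none") "model-based"
      else "model-free"
    }, character(1)),
    row.names = NULL)
}

#' Resolve a model label into a model specification
#'
#' @param model_id one of the labels listed by [grl_models()].
#' @return list with `model_id`, `free` (free parameter names), `fixed`
#'   (named fixed values), `df`, `mb` (`"none"`, `"spe"`, `"hmm"`), and `w`
#'   (`"mf"`, `"mb"`, `"dual"`, `"static"`).
#' @export
model_spec <- function(model_id) {
  if (!model_id %in% names(.model_table))
    stop("unknown model label '", model_id, "'; valid labels: ",
         paste(names(.model_table), collapse = ", "))
  m <- .model_table[[model_id]]
  list(model_id = model_id, free = m$free, fixed = m$fixed,
       df = length(m$free), mb = m$mb, w = m$w,
       tie = if (is.null(m$tie)) "none" else m$tie)
}

#' Expand free parameters into the full parameter vector of a model
#'
#' Applies the model's fixed values and tie rules (`g_sa = g_a` for the
#' 7-parameter family, the shared weight `g_a = min(0, g_s)` for `AW|SW`)
#' and sets the model-based weight implied by the model class. The
#' eligibility weight `lambda` is fixed at 0.5 throughout.
#'
#' @param spec a [model_spec()].
#' @param params named numeric vector over (a subset of) the free
#'   parameters; anything missing falls back to a neutral default.
#' @return full named parameter vector.
#' @export
resolve_params <- function(spec, params = numeric(0)) {
  full <- c(alpha = 0, g_a = 0, g_s = 0, g_sa = 0, lambda = 0.5, tau = 1,
            beta0 = 0, lambda_beta = 0, beta_r = 0, alpha_spe = 0,
            theta0 = 0.5, theta1 = 0, w_mb = 0, p_left = 0.5)
  if (!is.null(spec$fixed)) full[names(spec$fixed)] <- spec$fixed
  if (length(params)) {
    bad <- setdiff(names(params), spec$free)
    if (length(bad)) stop("not free parameters of ", spec$model_id, ": ",
                          paste(bad, collapse = ", "))
    full[names(params)] <- params
  }
  if (spec$tie == "gsa_ga") full["g_sa"] <- full["g_a"]
  if (spec$tie == "shared_g") {
    full["g_a"] <- min(0, full["g_s"])
    full["g_sa"] <- full["g_a"]
  }
  full["w_mb"] <- switch(spec$w, mf = 0, mb = 1, static = 0, full["w_mb"])
  .check_bounds(full)
  full
}

.check_bounds <- function(p) {
  stopifnot(p["alpha"] >= 0, p["alpha"] <= 1,
            p["g_a"] >= -1, p["g_a"] <= 0,
            p["g_s"] >= -1, p["g_s"] <= 1,
            p["g_sa"] >= -1, p["g_sa"] <= 0,
            p["lambda"] >= 0, p["lambda"] <= 1,
            p["lambda_beta"] >= 0, p["lambda_beta"] <= 1,
            p["alpha_spe"] >= 0, p["alpha_spe"] <= 1,
            p["theta0"] >= 0.5, p["theta0"] <= 1,
            p["theta1"] >= 0, p["theta1"] <= 1,
            p["w_mb"] >= 0, p["w_mb"] <= 1,
            p["p_left"] >= 0, p["p_left"] <= 1)
  if (p["tau"] <= 0) stop("parameter error: softmax temperature tau must be > 0")
  invisible(p)
}

#' Fresh cached-value agent state
#'
#' `V` is the value of the preparatory (inter-trial) state, `Q` the table of
#' action values over the four active states of the current run (category x
#' state x action), `beta` the per-action cumulative hysteresis bias, `N`
#' the within-run action counter.
#' @return list state.
#' @export
agent_state <- function() {
  list(V = 0, Q = array(0, dim = c(2, 2, 2)), beta = c(0, 0), N = 0L)
}

#' Fresh metastate belief state
#'
#' Per category, a uniform distribution over the two metastate hypotheses
#' "AL/BR" and "AR/BL".
#' @return 2 x 2 matrix, rows = categories, cols = hypotheses.
#' @export
belief_state <- function() {
  matrix(0.5, nrow = 2, ncol = 2,
         dimnames = list(c("cat1", "cat2"), c("AL/BR", "AR/BL")))
}

# hypothesis 1 ("AL/BR") is congruent with (s, a) being rewarded when the
# pair is (A, left) or (B, right)
.congruent_h1 <- function(state, action) {
  (state == 1L & action == 1L) | (state == 2L & action == 2L)
}

#' Infer the metastate hypothesis consistent with an observation
#'
#' Maps a state-action-outcome triple onto the hypothesis ("AL/BR" = 1 or
#' "AR/BL" = 2) under which that outcome is the expected one, plus its
#' complement.
#'
#' @param state 1 (A) or 2 (B); @param action 1 (left) or 2 (right);
#' @param reward 0 or 1.
#' @return list with `hat` and `alt` hypothesis indices.
#' @export
consistent_hypothesis <- function(state, action, reward) {
  if (!reward %in% c(0, 1)) stop("input error: reward must be 0 or 1")
  hat <- if (.congruent_h1(state, action) == (reward == 1)) 1L else 2L
  list(hat = hat, alt = 3L - hat)
}

#' Softmax action probabilities of the (dual-systems) policy
#'
#' The exponent for each action is `(w_mb * Q_mb + (1 - w_mb) * Q) +
#' beta(a) + beta_r * I_right(a)`, divided by the temperature `tau`; the
#' maximum exponent is subtracted before exponentiation so the result is
#' invariant to common additive shifts. Pure model-free models have
#' `w_mb = 0`, pure model-based models `w_mb = 1`; the intercept and chance
#' baselines bypass the softmax with a constant choice probability.
#'
#' @param state an [agent_state()].
#' @param category,st the current cue's category and state indices.
#' @param spec a [model_spec()]; @param params full vector from
#'   [resolve_params()].
#' @param belief a [belief_state()] holding the decision-time beliefs
#'   (current probabilities for SPE, the propagated prior for the HMM).
#' @return probability vector `c(left, right)` summing to 1.
#' @export
policy_probabilities <- function(state, category, st, spec, params,
                                 belief = NULL) {
  if (spec$w == "static") {
    p <- unname(params["p_left"])
    return(c(p, 1 - p))
  }
  if (params["tau"] <= 0) stop("parameter error: tau must be > 0")
  q_mf <- state$Q[category, st, ]
  q_mb <- c(0, 0)
  if (spec$mb != "none" && !is.null(belief)) {
    q_mb <- c(model_based_q(belief, category, st, 1L),
              model_based_q(belief, category, st, 2L))
  }
  w <- unname(params["w_mb"])
  x <- (w * q_mb + (1 - w) * q_mf + state$beta +
        unname(params["beta_r"]) * c(0, 1)) / unname(params["tau"])
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' State-value-prediction error update at cue onset
#'
#' On the transition from the preparatory state to the active state, the
#' SVPE is the best available action value minus the cached preparatory
#' value (discounting omitted), and the preparatory value moves toward it
#' with learning rate `alpha`.
#'
#' @inheritParams policy_probabilities
#' @return list with updated `state` and `delta_v`.
#' @export
svpe_update <- function(state, category, st, params) {
  delta_v <- max(state$Q[category, st, ]) - state$V
  state$V <- state$V + unname(params["alpha"]) * delta_v
  list(state = state, delta_v = delta_v)
}

# value clamp used by the generalized and eligibility updates
.clamp01 <- function(x) max(0, min(1, x))

#' Outcome-driven value updates with generalization and eligibility
#'
#' Applies, in order: the direct delta update of the chosen pair; the
#' eligibility-trace relay of the outcome prediction error to the
#' preparatory state (weight `lambda * alpha`, clamped); the counterfactual
#' update of the nonchosen action (weight `g_a * alpha`, clamped); the
#' update of the complementary state's same action (weight `g_s * alpha`,
#' clamped); and the interactive update of the complementary state's
#' complementary action (weight `g_s * g_sa * alpha`, clamped; `g_sa = g_a`
#' in the 7-parameter family). Values of pairs outside the current category
#' are untouched. Direct updates are not clamped: with rewards in \{0, 1\}
#' and values initialized in [0, 1] they cannot leave the unit interval,
#' which is asserted.
#'
#' @inheritParams policy_probabilities
#' @param action chosen action (1/2); @param reward 0 or 1.
#' @return list with updated `state` and `delta_q`.
#' @export
outcome_update <- function(state, category, st, action, reward, params) {
  if (!reward %in% c(0, 1)) stop("input error: reward must be 0 or 1")
  a <- action; ac <- 3L - action
  sc <- 3L - st
  al <- unname(params["alpha"])
  delta_q <- reward - state$Q[category, st, a]
  state$Q[category, st, a] <- state$Q[category, st, a] + al * delta_q
  stopifnot(state$Q[category, st, a] >= -1e-12, state$Q[category, st, a] <= 1 + 1e-12)
  state$V <- .clamp01(state$V + unname(params["lambda"]) * al * delta_q)
  state$Q[category, st, ac] <-
    .clamp01(state$Q[category, st, ac] + unname(params["g_a"]) * al * delta_q)
  state$Q[category, sc, a] <-
    .clamp01(state$Q[category, sc, a] + unname(params["g_s"]) * al * delta_q)
  state$Q[category, sc, ac] <-
    .clamp01(state$Q[category, sc, ac] +
             unname(params["g_s"]) * unname(params["g_sa"]) * al * delta_q)
  list(state = state, delta_q = delta_q)
}

#' Hysteresis bias update after an executed action
#'
#' Implemented as the recursion `beta(a) <- lambda_beta * beta(a) +
#' beta0 * 1[a == a_t]`, which equals the closed-form exponentially decayed
#' sum over the run's action history.
#'
#' @inheritParams outcome_update
#' @return updated state (with incremented action counter).
#' @export
hysteresis_update <- function(state, action, params) {
  state$N <- state$N + 1L
  state$beta <- unname(params["lambda_beta"]) * state$beta
  state$beta[action] <- state$beta[action] + unname(params["beta0"])
  state
}

#' Closed-form hysteresis bias after a sequence of actions
#'
#' Direct evaluation of the decayed sum over the action history; the
#' recursive [hysteresis_update()] must agree with this exactly.
#'
#' @param actions integer vector of executed actions (1/2).
#' @inheritParams outcome_update
#' @return bias vector `c(left, right)`.
#' @export
hysteresis_closed_form <- function(actions, params) {
  n <- length(actions)
  beta <- c(0, 0)
  if (n == 0) return(beta)
  for (a in 1:2) {
    i <- 0:(n - 1)
    beta[a] <- sum(unname(params["beta0"]) * unname(params["lambda_beta"])^i *
                   (actions[n - i] == a))
  }
  beta
}

#' Delta-rule update of metastate beliefs (SPE learner)
#'
#' The metastate-prediction error is one minus the probability currently
#' assigned to the observation's consistent hypothesis; that hypothesis is
#' incremented by `alpha_spe` times the error and the alternative
#' proportionally decremented, keeping the category's probabilities summing
#' to exactly one.
#'
#' @param belief a [belief_state()]; @param category category index.
#' @param h_hat consistent-hypothesis index from [consistent_hypothesis()].
#' @inheritParams policy_probabilities
#' @return list with updated `belief` and `delta_spe`.
#' @export
spe_update <- function(belief, category, h_hat, params) {
  alt <- 3L - h_hat
  a <- unname(params["alpha_spe"])
  d <- 1 - belief[category, h_hat]
  belief[category, h_hat] <- belief[category, h_hat] + a * d
  belief[category, alt] <- belief[category, alt] - a * belief[category, alt]
  list(belief = belief, delta_spe = d)
}

#' Propagate the HMM posterior into the next trial's prior
#'
#' Mixes each hypothesis with its complement at the believed reversal rate
#' `theta1`; `HMM0` fixes `theta1 = 0` so the prior equals the posterior.
#'
#' @inheritParams spe_update
#' @return updated belief matrix (the propagated prior for `category`).
#' @export
hmm_propagate_prior <- function(belief, category, params) {
  t1 <- unname(params["theta1"])
  p <- belief[category, ]
  belief[category, ] <- t1 * rev(p) + (1 - t1) * p
  belief
}

#' Bayesian posterior update of the HMM belief
#'
#' The likelihood of the observed outcome is `theta0` under the consistent
#' hypothesis and `1 - theta0` under the alternative; the posterior is the
#' normalized product with the prior, floored at 1e-12 against degenerate
#' normalizers.
#'
#' @inheritParams spe_update
#' @param st,action,reward the observed state, action and outcome.
#' @return updated belief matrix.
#' @export
hmm_posterior_update <- function(belief, category, st, action, reward, params) {
  h <- consistent_hypothesis(st, action, reward)
  t0 <- unname(params["theta0"])
  lik <- c(0, 0)
  lik[h$hat] <- t0
  lik[h$alt] <- 1 - t0
  post <- lik * belief[category, ]
  z <- sum(post)
  if (z < 1e-12) post <- c(0.5, 0.5) else post <- post / z
  belief[category, ] <- post
  belief
}

#' Model-based action value from metastate beliefs
#'
#' The probability, under the category's current belief, of the hypothesis
#' congruent with `(state, action)` being the rewarded pairing.
#'
#' @inheritParams hmm_posterior_update
#' @param a action index.
#' @return scalar value in [0, 1].
#' @export
model_based_q <- function(belief, category, st, a) {
  h <- if (.congruent_h1(st, a)) 1L else 2L
  unname(belief[category, h])
}

#' Expected reward of an action under the HMM's generative model
#'
#' `theta0 * P(congruent) + (1 - theta0) * P(incongruent)`. This
#' expectation is reported for completeness (e.g., as a regressor); it is
#' not the input to the action-selection policy, which uses
#' [model_based_q()].
#'
#' @inheritParams model_based_q
#' @export
expected_reward <- function(belief, category, st, a, params) {
  t0 <- unname(params["theta0"])
  pc <- model_based_q(belief, category, st, a)
  t0 * pc + (1 - t0) * (1 - pc)
}
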