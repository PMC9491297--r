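# Reference per-trial engine, written against the single-trial operations
# in models.R. The compiled engine in src/engine.cpp mirrors this loop
# operation-for-operation; the test suite asserts bit-level agreement
# between the two routes.

.engine_control_defaults <- function(control = list()) {
  defaults <- list(
    q_reset_per_run = TRUE,       # run start re-initializes the Q table
    belief_reset_per_run = TRUE,  # and the metastate beliefs
    v_reset_per_run = FALSE,      # preparatory-state value persists
    svpe_on_missed = TRUE,        # the cue was seen even when no response came
    p_floor = 1e-12               # per-trial likelihood floor
  )
  utils::modifyList(defaults, control)
}

# One pass over a trial table. mode = "replay" evaluates the likelihood of
# given choices; mode = "simulate" samples choices from the policy using
# the uniform draws `u`.
grl_engine_r <- function(trials, spec, params, mode = c("replay", "simulate"),
                         chosen = NULL, reward = NULL, missed = NULL,
                         u = NULL, traces = TRUE, control = list()) {
  mode <- match.arg(mode)
  ctl <- .engine_control_defaults(control)
  n <- nrow(trials)
  if (mode == "replay") {
    stopifnot(length(chosen) == n, length(reward) == n)
    if (is.null(missed)) missed <- is.na(chosen)
  } else {
    stopifnot(length(u) == n)
    chosen <- integer(n); reward <- integer(n); missed <- rep(FALSE, n)
  }
  static <- spec$w == "static"
  st <- agent_state()
  bel <- belief_state()
  nll <- 0
  tr_v <- tr_dv <- tr_dq <- tr_pl <- tr_ql <- tr_qr <- rep(NA_real_, n)
  prev_run <- -1L
  for (t in seq_len(n)) {
    run <- trials$run[t]; cat <- trials$category[t]; s <- trials$state[t]
    if (run != prev_run) {
      if (ctl$q_reset_per_run) st$Q[] <- 0
      st$beta <- c(0, 0); st$N <- 0L
      if (ctl$belief_reset_per_run) bel[] <- 0.5
      if (ctl$v_reset_per_run) st$V <- 0
      prev_run <- run
    }
    if (!static && (ctl$svpe_on_missed || !missed[t])) {
      up <- svpe_update(st, cat, s, params)
      st <- up$state
      tr_dv[t] <- up$delta_v
    }
    if (!static && spec$mb == "hmm") bel <- hmm_propagate_prior(bel, cat, params)
    p <- policy_probabilities(st, cat, s, spec, params,
                              belief = if (spec$mb == "none") NULL else bel)
    tr_v[t] <- st$V; tr_ql[t] <- st$Q[cat, s, 1]; tr_qr[t] <- st$Q[cat, s, 2]
    tr_pl[t] <- p[1]
    if (mode == "simulate") {
      chosen[t] <- if (u[t] < p[1]) 1L else 2L
      reward[t] <- as.integer(chosen[t] == trials$rewarded_action[t] &&
                              trials$reward_available[t])
    }
    if (missed[t]) next
    a <- chosen[t]
    nll <- nll - log(max(p[a], ctl$p_floor))
    if (!static) {
      st <- hysteresis_update(st, a, params)
      up <- outcome_update(st, cat, s, a, reward[t], params)
      st <- up$state
      tr_dq[t] <- up$delta_q
      if (spec$mb == "spe") {
        h <- consistent_hypothesis(s, a, reward[t])
        bel <- spe_update(bel, cat, h$hat, params)$belief
      } else if (spec$mb == "hmm") {
        bel <- hmm_posterior_update(bel, cat, s, a, reward[t], params)
      }
    }
  }
  out <- list(nll = nll, chosen = chosen, reward = reward, missed = missed)
  if (traces)
    out$traces <- data.frame(v0 = tr_v, q_left = tr_ql, q_right = tr_qr,
                             delta_v = tr_dv, delta_q = tr_dq, p_left = tr_pl)
  out
}

# Fast path: compiled engine with the same contract. trials must carry
# run, category, state, rewarded_action, reward_available.
grl_engine <- function(trials, spec, params, mode = c("replay", "simulate"),
                       chosen = NULL, reward = NULL, missed = NULL,
                       u = NULL, traces = FALSE, control = list(),
                       backend = c("cpp", "r")) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  if (backend == "r")
    return(grl_engine_r(trials, spec, params, mode, chosen, reward, missed,
                        u, traces, control))
  ctl <- .engine_control_defaults(control)
  n <- nrow(trials)
  if (mode == "replay") {
    stopifnot(length(chosen) == n, length(reward) == n)
    if (is.null(missed)) missed <- is.na(chosen)
    ch <- as.integer(ifelse(is.na(chosen), 0L, chosen))
    rw <- as.integer(ifelse(is.na(reward), 0L, reward))
    uu <- numeric(0)
  } else {
    stopifnot(length(u) == n)
    ch <- integer(0); rw <- integer(0); missed <- rep(FALSE, n)
    uu <- as.numeric(u)
  }
  mb_code <- match(spec$mb, c("none", "spe", "hmm")) - 1L
  res <- engine_cpp(
    as.integer(trials$run), as.integer(trials$category),
    as.integer(trials$state), as.integer(trials$rewarded_action),
    as.integer(trials$reward_available),
    as.numeric(params[.par_names]),
    mb_code, as.integer(spec$w == "static"),
    match(mode, c("replay", "simulate")) - 1L,
    ch, rw, as.integer(missed), uu,
    as.integer(ctl$q_reset_per_run), as.integer(ctl$belief_reset_per_run),
    as.integer(ctl$v_reset_per_run), as.integer(ctl$svpe_on_missed),
    as.numeric(ctl$p_floor), as.integer(traces))
  out <- list(nll = res$nll, chosen = res$chosen, reward = res$reward,
              missed = missed)
  if (traces)
    out$traces <- data.frame(v0 = res$v0, q_left = res$q_left,
                             q_right = res$q_right, delta_v = res$delta_v,
                             delta_q = res$delta_q, p_left = res$p_left)
  out
}
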