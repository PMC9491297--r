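#' Run a model through a session (free-running or yoked)
#'
#' In free mode the agent's own choices are resolved against the session's
#' pre-scheduled reward availability. In yoked mode a reference behavioral
#' record pins the trial sequence and reward contingencies (the reference's
#' `rewarded_action` and `reward_available` columns) while the simulated
#' agent's own choice still determines whether the scheduled reward is
#' earned; with the schedule carried in every record the two modes share
#' one mechanism, differing only in where the trial table comes from.
#'
#' @param session a [generate_session()] result (free mode), or `NULL` when
#'   yoking to `ref`.
#' @param spec a [model_spec()] or model label.
#' @param params named vector of the model's free parameters.
#' @param mode `"free"` or `"yoked"`.
#' @param ref a behavioral record to yoke to (required for `"yoked"`).
#' @param seed integer seed for the choice draws (and synthetic RT noise).
#' @param traces record latent traces (preparatory value, decision-time Q,
#'   prediction errors, policy probability)?
#' @param rt synthetic reaction-time generator settings, a list with `a`
#'   (intercept, s), `b` (value-difference slope, s) and `sd` (Gaussian
#'   noise, s); RTs are truncated to [0.2, 2] s. Set to `NULL` to skip RT
#'   generation. This generator exists to exercise the RT regression
#'   machinery; it is not part of the fitted models.
#' @param control engine options (run resets, likelihood floor).
#' @param backend `"cpp"` (default) or `"r"` reference engine.
#' @return a behavioral record: data.frame of class `grl_record` with the
#'   trial columns plus `chosen_action`, `missed`, `reward`, `rt` and, if
#'   requested, trace columns.
#' @export
run_agent <- function(session = NULL, spec, params = numeric(0),
                      mode = c("free", "yoked"), ref = NULL, seed = 1L,
                      traces = TRUE, rt = list(a = 0.8, b = 0.3, sd = 0.15),
                      control = list(), backend = "cpp") {
  mode <- match.arg(mode)
  if (is.character(spec)) spec <- model_spec(spec)
  full <- resolve_params(spec, params)
  trials <- if (mode == "yoked") {
    if (is.null(ref)) stop("yoked mode requires a reference record")
    as.data.frame(ref)[, !(names(ref) %in%
      c("chosen_action", "missed", "reward", "rt",
        "v0", "q_left", "q_right", "delta_v", "delta_q", "p_left"))]
  } else {
    if (is.null(session)) stop("free mode requires a session")
    session$trials
  }
  need <- c("run", "category", "state", "rewarded_action", "reward_available")
  miss_cols <- setdiff(need, names(trials))
  if (length(miss_cols))
    stop("session/record mismatch: missing columns ",
         paste(miss_cols, collapse = ", "))
  n <- nrow(trials)
  res <- with_seed(seed, {
    u <- stats::runif(n)
    eng <- grl_engine(trials, spec, full, mode = "simulate", u = u,
                      traces = TRUE, control = control, backend = backend)
    if (!is.null(rt)) {
      dq <- abs(eng$traces$q_left - eng$traces$q_right)
      mx <- max(dq, na.rm = TRUE)
      dqn <- if (is.finite(mx) && mx > 0) dq / mx else dq * 0
      eng$rt <- pmin(2, pmax(0.2, rt$a - rt$b * dqn +
                                  stats::rnorm(n, 0, rt$sd)))
    }
    eng
  })
  rec <- trials
  rec$chosen_action <- res$chosen
  rec$missed <- res$missed
  rec$reward <- res$reward
  rec$rt <- if (is.null(rt)) NA_real_ else res$rt
  if (traces) rec <- cbind(rec, res$traces)
  attr(rec, "model_id") <- spec$model_id
  attr(rec, "params") <- full
  class(rec) <- c("grl_record", class(rec))
  rec
}

#' Simulate a cohort of independent subjects
#'
#' Each subject gets its own session (fresh design seed) and an independent
#' parameter draw from `param_sampler`.
#'
#' @param n_subjects number of simulated subjects; 0 returns an empty list.
#' @param spec model label or [model_spec()] shared by the cohort.
#' @param param_sampler `function(i)` returning a named vector of free
#'   parameters for subject `i` (must respect bounds).
#' @param config base [task_config()]; each subject's session re-seeds it.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param ... passed to [run_agent()].
#' @return list of `grl_record`s.
#' @export
simulate_cohort <- function(n_subjects, spec, param_sampler,
                            config = task_config(), seed = 1L, ...) {
  if (n_subjects == 0) return(list())
  if (is.character(spec)) spec <- model_spec(spec)
  lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    cfg$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    sess <- generate_session(cfg)
    pars <- with_seed(cfg$seed + 7L, param_sampler(i))
    run_agent(sess, spec, pars, mode = "free", seed = cfg$seed + 13L, ...)
  })
}
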