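# Shared fixtures, built in code at test time.

fix_session <- function(seed = 42L, variant = "3FH") {
  generate_session(task_config(seed = seed, variant = variant))
}

# canonical discriminative-generalizer parameters (strong learner)
fix_grl_params <- function() {
  c(alpha = 0.5, g_a = -0.7, g_s = -0.8, tau = 0.3,
    beta0 = -0.1, lambda_beta = 0.5, beta_r = 0.1)
}

fix_record <- function(seed = 42L, params = fix_grl_params(),
                       model = "AX|SY", ...) {
  run_agent(fix_session(seed), model, params, seed = seed + 1L, ...)
}

# deterministic record of an agent that always takes the rewarded action
omniscient_record <- function(session) {
  rec <- session$trials
  rec$chosen_action <- rec$rewarded_action
  rec$missed <- FALSE
  rec$reward <- as.integer(rec$reward_available)
  rec$rt <- 0.5
  rec
}

# record with a fixed constant action
fixed_action_record <- function(session, action = 1L) {
  rec <- session$trials
  rec$chosen_action <- action
  rec$missed <- FALSE
  rec$reward <- as.integer(rec$reward_available & rec$rewarded_action == action)
  rec$rt <- 0.5
  rec
}

# tiny hand-built trial table (one run, one block) for unit fixtures
toy_trials <- function(category, state, rewarded_action, reward_available,
                       run = 1L, block = 1L) {
  n <- length(category)
  data.frame(run = run, block = block, block_in_run = 1L,
             trial_in_block = seq_len(n), quartet = (seq_len(n) - 1L) %/% 4L + 1L,
             category = category, state = state,
             rewarded_action = rewarded_action,
             reward_available = reward_available,
             iti = 3, trial = seq_len(n),
             cue_id = sprintf("r%d_c%ds%d", run, category, state),
             onset = (seq_len(n) - 1L) * 9, isi = 3)
}
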