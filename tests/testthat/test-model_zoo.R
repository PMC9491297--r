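spec_grl <- model_spec("AX|SY")

test_that("model registry matches the designed degrees of freedom", {
  m <- grl_models()
  df <- setNames(m$df, m$model_id)
  expect_equal(df[["A0|S0"]], 5L); expect_equal(df[["A-|S0"]], 5L)
  expect_equal(df[["AX|S0"]], 6L); expect_equal(df[["A0|S+"]], 5L)
  expect_equal(df[["A0|S-"]], 5L); expect_equal(df[["A0|SY"]], 6L)
  expect_equal(df[["A-|S+"]], 5L); expect_equal(df[["A-|S-"]], 5L)
  expect_equal(df[["AW|SW"]], 6L); expect_equal(df[["AX|SY"]], 7L)
  expect_equal(df[["AX|SY|Z"]], 8L)
  expect_equal(df[["SPE"]], 5L); expect_equal(df[["SPE+RL"]], 7L)
  expect_equal(df[["HMM0"]], 5L); expect_equal(df[["HMM"]], 6L)
  expect_equal(df[["HMM0+RL"]], 7L); expect_equal(df[["HMM+RL"]], 8L)
  expect_equal(df[["hysteresis"]], 4L)
  expect_equal(df[["intercept"]], 1L); expect_equal(df[["chance"]], 0L)
  expect_error(model_spec("nope"), "valid labels")
})

test_that("softmax policy reduces to the logistic form with the expected values", {
  st <- agent_state()
  p <- policy_probabilities(st, 1L, 1L, spec_grl,
                            resolve_params(spec_grl, c(tau = 0.5)))
  expect_equal(p, c(0.5, 0.5))

  st$Q[1, 1, ] <- c(0.75, 0.25)
  p <- policy_probabilities(st, 1L, 1L, spec_grl,
                            resolve_params(spec_grl, c(tau = 0.5)))
  expect_equal(p[1], 1 / (1 + exp(-1)), tolerance = 1e-12)

  # uniform limit at high temperature
  p_hot <- policy_probabilities(st, 1L, 1L, spec_grl,
                                resolve_params(spec_grl, c(tau = 1e8)))
  expect_equal(p_hot, c(0.5, 0.5), tolerance = 1e-7)

  # shift invariance of the exponent
  st2 <- st; st2$beta <- st$beta + 100
  p_shift <- policy_probabilities(st2, 1L, 1L, spec_grl,
                                  resolve_params(spec_grl, c(tau = 0.5)))
  expect_equal(p_shift, p, tolerance = 1e-12)

  expect_error(resolve_params(spec_grl, c(tau = -1)), "tau")
})

test_that("cue-locked state-value update implements the reduced delta rule", {
  st <- agent_state()
  st$Q[1, 1, ] <- c(0.6, 0.2)
  up <- svpe_update(st, 1L, 1L, resolve_params(spec_grl, c(alpha = 0.5)))
  expect_equal(up$delta_v, 0.6)
  expect_equal(up$state$V, 0.3)

  up0 <- svpe_update(agent_state(), 1L, 1L,
                     resolve_params(spec_grl, c(alpha = 0.5)))
  expect_equal(up0$delta_v, 0)
  expect_equal(up0$state$V, 0)

  st2 <- agent_state(); st2$V <- 0.5; st2$Q[1, 1, ] <- c(0.5, 0.1)
  expect_equal(svpe_update(st2, 1L, 1L,
                           resolve_params(spec_grl, c(alpha = 0.5)))$delta_v, 0)
})

test_that("generalized outcome update matches the hand-worked clamped example", {
  # representative fitted parameters of a strong discriminative generalizer
  p <- resolve_params(spec_grl, c(alpha = 0.318, g_a = -0.710, g_s = -0.808,
                                  tau = 0.408, beta0 = -0.067,
                                  lambda_beta = 0.753, beta_r = 0.178))
  st <- agent_state()
  up <- outcome_update(st, 1L, 1L, 1L, 1L, p)
  expect_equal(up$delta_q, 1)
  q <- up$state$Q
  expect_equal(q[1, 1, 1], 0.318, tolerance = 1e-10)
  expect_equal(q[1, 1, 2], 0)                 # f(-0.710 * 0.318) clamps to 0
  expect_equal(q[1, 2, 1], 0)                 # f(-0.808 * 0.318) clamps to 0
  expect_equal(q[1, 2, 2], 0.808 * 0.710 * 0.318, tolerance = 1e-10)
  # eligibility relay to the preparatory state, lambda = 0.5
  expect_equal(up$state$V, 0.5 * 0.318, tolerance = 1e-10)
  # other category untouched
  expect_true(all(q[2, , ] == 0))
})

test_that("outcome update nests the no-generalization and matched cases", {
  p0 <- resolve_params(spec_grl, c(alpha = 0.4, g_a = 0, g_s = 0, tau = 1))
  up <- outcome_update(agent_state(), 1L, 1L, 1L, 1L, p0)
  expect_equal(up$state$Q[1, 1, 1], 0.4)
  expect_true(all(up$state$Q[-1] == 0) || sum(up$state$Q != 0) == 1L)

  st <- agent_state(); st$Q[1, 1, 1] <- 1
  up2 <- outcome_update(st, 1L, 1L, 1L, 1L, p0)
  expect_equal(up2$delta_q, 0)
  expect_equal(up2$state$Q, st$Q)
  expect_error(outcome_update(st, 1L, 1L, 1L, 2, p0), "input error")
})

test_that("one rewarded observation raises exactly the congruent complementary pair", {
  p <- resolve_params(spec_grl, c(alpha = 0.5, g_a = -1, g_s = -1, tau = 1))
  up <- outcome_update(agent_state(), 1L, 1L, 2L, 1L, p)  # state A, right, reward
  q <- up$state$Q[1, , ]
  expect_gt(q[1, 2], 0)     # chosen pair (A, right)
  expect_gt(q[2, 1], 0)     # congruent pair (B, left)
  expect_equal(q[1, 1], 0)  # incongruent pairs stay at the floor
  expect_equal(q[2, 2], 0)
})

test_that("hysteresis recursion equals the closed-form decayed sum", {
  p <- resolve_params(model_spec("hysteresis"),
                      c(tau = 1, beta0 = 0.2, lambda_beta = 0.5, beta_r = 0))
  st <- agent_state()
  for (a in c(1L, 1L, 2L)) st <- hysteresis_update(st, a, p)
  expect_equal(st$beta, c(0.15, 0.2), tolerance = 1e-12)
  expect_equal(st$beta, hysteresis_closed_form(c(1L, 1L, 2L), p))

  # pure one-back when the decay base is 0
  p0 <- resolve_params(model_spec("hysteresis"),
                       c(tau = 1, beta0 = 0.3, lambda_beta = 0, beta_r = 0))
  st0 <- agent_state()
  for (a in c(2L, 1L)) st0 <- hysteresis_update(st0, a, p0)
  expect_equal(st0$beta, c(0.3, 0))

  # random action strings up to length 400
  set.seed(9)
  for (rep in 1:10) {
    pr <- resolve_params(model_spec("hysteresis"),
                         c(tau = 1, beta0 = runif(1, -1, 1),
                           lambda_beta = runif(1), beta_r = 0))
    acts <- sample(1:2, sample(50:400, 1), replace = TRUE)
    str <- agent_state()
    for (a in acts) str <- hysteresis_update(str, a, pr)
    expect_equal(str$beta, hysteresis_closed_form(acts, pr),
                 tolerance = 1e-10)
  }
})

test_that("consistent-hypothesis rule matches the 8-case mapping", {
  # hypothesis 1 = "AL/BR", hypothesis 2 = "AR/BL"
  expect_equal(consistent_hypothesis(1L, 1L, 1)$hat, 1L)  # (A, L, reward)
  expect_equal(consistent_hypothesis(1L, 1L, 0)$hat, 2L)  # (A, L, no reward)
  expect_equal(consistent_hypothesis(1L, 2L, 1)$hat, 2L)
  expect_equal(consistent_hypothesis(1L, 2L, 0)$hat, 1L)
  expect_equal(consistent_hypothesis(2L, 1L, 1)$hat, 2L)
  expect_equal(consistent_hypothesis(2L, 1L, 0)$hat, 1L)
  expect_equal(consistent_hypothesis(2L, 2L, 1)$hat, 1L)
  expect_equal(consistent_hypothesis(2L, 2L, 0)$hat, 2L)
  for (s in 1:2) for (a in 1:2) for (r in 0:1) {
    h <- consistent_hypothesis(s, a, r)
    expect_equal(h$alt, 3L - h$hat)
  }
  expect_error(consistent_hypothesis(1L, 1L, 2), "input error")
})

test_that("metastate delta rule moves beliefs and preserves unit sums", {
  p <- resolve_params(model_spec("SPE"), c(alpha_spe = 0.4, tau = 1))
  up <- spe_update(belief_state(), 1L, 1L, p)
  expect_equal(up$delta_spe, 0.5)
  expect_equal(unname(up$belief[1, ]), c(0.7, 0.3), tolerance = 1e-12)
  expect_equal(unname(up$belief[2, ]), c(0.5, 0.5))

  p0 <- resolve_params(model_spec("SPE"), c(alpha_spe = 0, tau = 1))
  expect_equal(spe_update(belief_state(), 1L, 1L, p0)$belief, belief_state())

  b1 <- belief_state(); b1[1, ] <- c(1, 0)
  up1 <- spe_update(b1, 1L, 1L, p)
  expect_equal(up1$delta_spe, 0)
  expect_equal(up1$belief, b1)

  # unit sums under random update sequences
  set.seed(2)
  b <- belief_state()
  for (i in 1:2000) {
    pa <- resolve_params(model_spec("SPE"), c(alpha_spe = runif(1), tau = 1))
    b <- spe_update(b, sample(1:2, 1), sample(1:2, 1), pa)$belief
    expect_equal(unname(rowSums(b)), c(1, 1), tolerance = 1e-12)
    expect_true(all(b >= 0 & b <= 1))
  }
})

test_that("HMM prior propagation mixes hypotheses at the reversal rate", {
  p <- resolve_params(model_spec("HMM"), c(theta0 = 0.8, theta1 = 0.1, tau = 1))
  b <- belief_state(); b[1, ] <- c(0.8, 0.2)
  out <- hmm_propagate_prior(b, 1L, p)
  expect_equal(unname(out[1, ]), c(0.74, 0.26), tolerance = 1e-12)

  p0 <- resolve_params(model_spec("HMM"), c(theta0 = 0.8, theta1 = 0, tau = 1))
  expect_equal(hmm_propagate_prior(b, 1L, p0), b)

  p5 <- resolve_params(model_spec("HMM"), c(theta0 = 0.8, theta1 = 0.5, tau = 1))
  expect_equal(unname(hmm_propagate_prior(b, 1L, p5)[1, ]), c(0.5, 0.5))
})

test_that("HMM Bayes update integrates the consistency likelihood", {
  p <- resolve_params(model_spec("HMM0"), c(theta0 = 0.8, tau = 1))
  out <- hmm_posterior_update(belief_state(), 1L, 1L, 1L, 1, p)
  expect_equal(unname(out[1, ]), c(0.8, 0.2), tolerance = 1e-12)

  p5 <- resolve_params(model_spec("HMM0"), c(theta0 = 0.5, tau = 1))
  expect_equal(hmm_posterior_update(belief_state(), 1L, 1L, 1L, 1, p5),
               belief_state())

  b <- belief_state(); b[1, ] <- c(1, 0)
  expect_equal(unname(hmm_posterior_update(b, 1L, 1L, 1L, 1, p)[1, ]), c(1, 0))
  # degenerate normalizer guard: all prior mass on the inconsistent side
  p1 <- resolve_params(model_spec("HMM0"), c(theta0 = 1, tau = 1))
  b0 <- belief_state(); b0[1, ] <- c(0, 1)
  out0 <- hmm_posterior_update(b0, 1L, 1L, 1L, 1, p1)
  expect_equal(unname(out0[1, ]), c(0.5, 0.5))
})

test_that("model-based value mirrors the metastate case table", {
  b <- belief_state(); b[1, ] <- c(0.7, 0.3)
  expect_equal(model_based_q(b, 1L, 1L, 1L), 0.7)  # (A, L) congruent AL/BR
  expect_equal(model_based_q(b, 1L, 2L, 2L), 0.7)  # (B, R) congruent AL/BR
  expect_equal(model_based_q(b, 1L, 1L, 2L), 0.3)
  expect_equal(model_based_q(b, 1L, 2L, 1L), 0.3)
  expect_equal(model_based_q(belief_state(), 1L, 1L, 1L), 0.5)
})

test_that("expected reward folds consistency beliefs into the prediction", {
  p <- resolve_params(model_spec("HMM0"), c(theta0 = 0.8, tau = 1))
  b <- belief_state(); b[1, ] <- c(1, 0)
  expect_equal(expected_reward(b, 1L, 1L, 1L, p), 0.8)
  expect_equal(expected_reward(belief_state(), 1L, 1L, 1L, p), 0.5)
  p5 <- resolve_params(model_spec("HMM0"), c(theta0 = 0.5, tau = 1))
  expect_equal(expected_reward(b, 1L, 1L, 1L, p5), 0.5)
})

test_that("clamped values stay within the unit interval under random streams", {
  set.seed(11)
  for (rep in 1:20) {
    p <- resolve_params(model_spec("AX|SY|Z"),
                        c(alpha = runif(1), g_a = -runif(1), g_s = runif(1, -1, 1),
                          g_sa = -runif(1), tau = runif(1, 0.1, 2),
                          beta0 = runif(1, -1, 1), lambda_beta = runif(1),
                          beta_r = runif(1, -1, 1)))
    st <- agent_state()
    for (i in 1:200) {
      st <- outcome_update(st, sample(1:2, 1), sample(1:2, 1),
                           sample(1:2, 1), sample(0:1, 1), p)$state
      expect_true(all(st$Q >= 0 & st$Q <= 1))
      expect_true(st$V >= 0 && st$V <= 1)
    }
  }
})

test_that("deterministic reward drives the chosen value to 1 monotonically", {
  p <- resolve_params(spec_grl, c(alpha = 0.3, g_a = 0, g_s = 0, tau = 1))
  st <- agent_state()
  q_prev <- 0
  for (i in 1:50) {
    st <- outcome_update(st, 1L, 1L, 1L, 1L, p)$state
    expect_gte(st$Q[1, 1, 1], q_prev)
    q_prev <- st$Q[1, 1, 1]
  }
  expect_equal(q_prev, 1, tolerance = 1e-6)
})
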