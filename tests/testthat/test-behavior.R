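test_that("diagnostic selector applies the first-generalization rule on a toy block", {
  # category 1, mapping LR (state A rewards left, B rewards right)
  tt <- toy_trials(category = rep(1L, 6), state = c(1L, 2L, 1L, 2L, 1L, 2L),
                   rewarded_action = c(1L, 2L, 1L, 2L, 1L, 2L),
                   reward_available = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  rec <- tt
  rec$chosen_action <- c(2L, 1L, 1L, 2L, 1L, 2L)  # first reward at t3 (A, left)
  rec$reward <- as.integer(rec$chosen_action == rec$rewarded_action)
  rec$missed <- FALSE
  d <- select_first_generalization_trials(rec)
  expect_equal(nrow(d), 1L)
  expect_equal(d$trial, 4L)      # next encounter with state B
  expect_true(d$correct)         # complementary action (right) was chosen

  rec2 <- rec
  rec2$chosen_action[4] <- 1L    # same action instead -> incorrect
  rec2$reward[4] <- 0L
  d2 <- select_first_generalization_trials(rec2)
  expect_false(d2$correct)
})

test_that("complete default sessions yield exactly 16 diagnostic trials", {
  for (seed in c(1L, 33L, 64L)) {
    s <- generate_session(task_config(seed = seed))
    rec <- omniscient_record(s)
    d <- select_first_generalization_trials(rec)
    expect_equal(nrow(d), 16L)
    expect_true(all(d$correct))
    expect_equal(first_generalization_accuracy(rec)$n_trials, 16L)
  }
})

test_that("repeat-probability bins match a manual six-trial tally", {
  tt <- toy_trials(category = rep(1L, 6), state = c(1L, 2L, 1L, 2L, 1L, 2L),
                   rewarded_action = rep(c(1L, 2L), 3),
                   reward_available = rep(TRUE, 6))
  rec <- tt
  rec$chosen_action <- c(1L, 1L, 1L, 2L, 2L, 2L)
  rec$reward <- c(1L, 0L, 0L, 1L, 0L, 1L)
  rec$missed <- FALSE
  cr <- conditional_repeat_probabilities(rec)
  expect_equal(unname(cr$p["same", "reward"]), 1)
  expect_equal(unname(cr$p["same", "noreward"]), 0)
  expect_equal(unname(cr$p["other", "reward"]), 1)
  expect_equal(unname(cr$p["other", "noreward"]), 2 / 3)
  expect_equal(unname(cr$n["other", "noreward"]), 3)
  expect_equal(cr$interaction, (1 - 0) - (1 - 2 / 3), tolerance = 1e-12)
})

test_that("interaction statistic flips sign when reward labels are inverted", {
  rec <- fix_record(44L)
  cr <- conditional_repeat_probabilities(rec)
  rec_flip <- rec
  rec_flip$reward <- 1L - rec_flip$reward
  cr_flip <- conditional_repeat_probabilities(rec_flip)
  expect_equal(cr_flip$interaction, -cr$interaction, tolerance = 1e-12)
  # bins partition their eligible trials
  expect_equal(sum(cr$n["same", ]) + sum(cr$n["other", ]),
               sum(cr$n))
})

test_that("discriminative agents produce the repeat-bin crossover", {
  rec <- fix_record(55L, params = c(alpha = 0.5, tau = 0.1, beta0 = 0,
                                    lambda_beta = 0.5, beta_r = 0),
                    model = "A-|S-")
  cr <- conditional_repeat_probabilities(rec)
  expect_gt(cr$p["same", "reward"], cr$p["same", "noreward"])
  expect_lt(cr$p["other", "reward"], cr$p["other", "noreward"])
  expect_gt(cr$interaction, 0.3)

  rec_c <- run_agent(fix_session(55L), "chance", seed = 1L)
  cr_c <- conditional_repeat_probabilities(rec_c)
  expect_true(all(abs(cr_c$p - 0.5) < 0.15))
})

test_that("psychometric choice regression recovers the value-repetition link", {
  rec <- fix_record(66L)
  pc <- psychometric_choice(rec)
  expect_false(pc$flagged)
  expect_gt(pc$slope, 0)

  # permuting the value traces across trials destroys the slope
  set.seed(1)
  rec_perm <- rec
  idx <- sample(nrow(rec))
  rec_perm$q_left <- rec$q_left[idx]
  rec_perm$q_right <- rec$q_right[idx]
  pc_perm <- psychometric_choice(rec_perm)
  expect_lt(abs(pc_perm$slope), abs(pc$slope) / 2)

  # chance agent carries flat values: degenerate, flagged
  rec_c <- run_agent(fix_session(66L), "chance", seed = 2L)
  expect_true(psychometric_choice(rec_c)$flagged)
})

test_that("psychometric RT regression recovers the generator's slope sign", {
  rec_b <- fix_record(71L)  # default RT generator has b > 0
  rt_b <- psychometric_rt(rec_b)
  expect_false(rt_b$flagged)
  expect_lt(rt_b$slope, 0)

  rec_0 <- run_agent(fix_session(71L), "AX|SY", fix_grl_params(), seed = 72L,
                     rt = list(a = 0.8, b = 0, sd = 0.15))
  rt_0 <- psychometric_rt(rec_0)
  expect_lt(abs(rt_0$slope), abs(rt_b$slope))

  rec_const <- rec_b
  rec_const$rt <- 0.7
  expect_equal(psychometric_rt(rec_const)$slope, 0)
})

test_that("group tests behave on textbook fixtures and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  tt <- two_sample_t(x, x, alternative = "greater")
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 0.5)

  expect_equal(pearson_cor(x, x)$r, 1)
  # hand-computed five-point Pearson correlation
  y <- c(2, 1, 4, 3, 6)
  expect_equal(pearson_cor(x, y)$r, 2 / sqrt(2 * 2.96), tolerance = 1e-10)

  expect_true(one_sample_t(rep(1, 5), 0.5)$flagged)
  expect_true(pearson_cor(x, rep(1, 5))$flagged)
  expect_true(two_sample_t(x, 1)$flagged)
})

test_that("first-generalization group tests wire the directed hypotheses", {
  set.seed(3)
  acc <- c(rnorm(8, 0.8, 0.05), rnorm(8, 0.3, 0.05), rnorm(3, 0.5, 0.05))
  grp <- c(rep("Discriminative", 8), rep("Associative", 8),
           rep("Nongeneralizer", 3))
  gs <- c(rnorm(8, -0.7, 0.1), rnorm(8, 0.6, 0.1), rnorm(3, 0, 0.02))
  res <- first_generalization_tests(acc, grp, gs)
  expect_lt(res$discriminative_vs_chance$p, 0.05)
  expect_lt(res$associative_vs_chance$p, 0.05)
  expect_lt(res$disc_vs_assoc$p, 0.05)
  expect_gt(res$accuracy_vs_neg_gs$r, 0.5)
  expect_lt(res$accuracy_vs_neg_gs$p, 0.05)
})

test_that("posterior predictive check reproduces its own generating model", {
  s <- fix_session(81L)
  rec <- run_agent(s, "AX|SY", fix_grl_params(), seed = 82L, rt = NULL)
  ppc <- posterior_predictive_check(list(rec), list(fix_grl_params()),
                                    "AX|SY", n_sims = 40L, seed = 5L)
  expect_equal(ppc$simulated$first_gen_acc, ppc$source$first_gen_acc,
               tolerance = 0.2)
  expect_equal(ppc$simulated$interaction, ppc$source$interaction,
               tolerance = 0.25)
  # basic RL yoked to the same record cannot generalize at first opportunity
  ppc_rl <- posterior_predictive_check(
    list(rec), list(c(alpha = 0.5, tau = 0.3, beta0 = -0.1,
                      lambda_beta = 0.5, beta_r = 0.1)),
    "A0|S0", n_sims = 40L, seed = 5L)
  expect_lt(ppc_rl$simulated$first_gen_acc, 0.55)
  expect_lt(ppc_rl$simulated$first_gen_acc, ppc$simulated$first_gen_acc)
})
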