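test_that("default session has the designed structural counts", {
  s <- fix_session(7L)
  expect_equal(nrow(s$trials), 384L)
  expect_equal(nrow(s$blocks), 12L)
  expect_equal(length(unique(s$trials$run)), 4L)
  expect_true(all(table(s$trials$block) == 32L))
  # equal state exposure: 8 trials per (category, state) per block
  expect_true(all(table(s$trials$block, paste(s$trials$category,
                                              s$trials$state)) == 8L))
  expect_true(s$audit$ok)
})

test_that("fixed-action policies earn exactly half of scheduled rewards", {
  for (seed in c(1L, 23L, 99L)) {
    s <- fix_session(seed)
    total <- sum(s$trials$reward_available)
    for (a in 1:2) {
      yield <- sum(s$trials$reward_available & s$trials$rewarded_action == a)
      expect_identical(2L * yield, total)
    }
  }
})

test_that("runs carry exact reward quarters and per-run category halves", {
  s <- fix_session(11L)
  tr <- s$trials
  total <- sum(tr$reward_available)
  per_run <- tapply(tr$reward_available, tr$run, sum)
  expect_true(all(abs(per_run - total / 4) <= 1))
  for (r in 1:4) {
    i <- tr$run == r
    expect_equal(2 * sum(tr$reward_available[i & tr$category == 1L]),
                 sum(tr$reward_available[i]))
  }
})

test_that("quartet and no-consecutive-cue constraints hold across many seeds", {
  for (seed in 1:40) {
    s <- generate_session(task_config(seed = seed))
    tr <- s$trials
    code <- 2L * (tr$category - 1L) + tr$state
    qid <- paste(tr$block, tr$quartet)
    expect_true(all(tapply(code, qid, function(x) all(sort(x) == 1:4))))
    same_run <- tr$run[-1] == tr$run[-nrow(tr)]
    expect_false(any(tr$cue_id[-1][same_run] ==
                     tr$cue_id[-nrow(tr)][same_run]))
  }
})

test_that("remapping toggles exactly one category per transition, each once per run", {
  s <- fix_session(5L)
  bl <- s$blocks
  for (r in 1:4) {
    rb <- bl[bl$run == r, ]
    f1 <- diff(rb$map_cat1) != 0
    f2 <- diff(rb$map_cat2) != 0
    expect_true(all(xor(f1, f2)))
    expect_equal(sum(f1), 1L)
    expect_equal(sum(f2), 1L)
    expect_equal(sort(rb$remapped_category[-1]), 1:2)
  }
})

test_that("block probabilities are exact sixteenths with opposite rewarded actions", {
  s <- fix_session(13L)
  tr <- s$trials
  for (b in 1:12) for (cat in 1:2) {
    iA <- tr$block == b & tr$category == cat & tr$state == 1L
    iB <- tr$block == b & tr$category == cat & tr$state == 2L
    # one rewarded action per state, opposite between paired states
    expect_equal(length(unique(tr$rewarded_action[iA])), 1L)
    expect_equal(unique(tr$rewarded_action[iA]),
                 3L - unique(tr$rewarded_action[iB]))
    # counts in sixteenths of the 8-trial exposure: k/16 * 8 integer
    expect_true(sum(tr$reward_available[iA]) %in% 0:8)
  }
  # the designed numerators appear: 16/16 and 10/16 in unequal blocks,
  # split halves of 7/16 (6, 8) and 13/16 (12, 14)
  counts <- as.matrix(s$blocks[, c("n11", "n12", "n21", "n22")])
  expect_true(all(counts %in% c(3L, 4L, 5L, 6L, 7L, 8L)))
  expect_true(all(rowSums(counts) == 20L))
})

test_that("odd net probabilities average over their block pair", {
  s <- fix_session(17L)
  bl <- s$blocks
  for (lev in c("cat1", "cat2")) {
    lesser <- if (lev == "cat1") c("n21", "n22") else c("n11", "n12")
    rows <- bl[bl$condition_3 == lev, lesser]
    # each lesser-category state nets 7/16 across its four blocks: 3.5/block
    expect_equal(colMeans(rows), c(3.5, 3.5), ignore_attr = TRUE)
  }
  eq <- bl[bl$condition_3 == "equal", ]
  for (cat in 1:2) {
    hi <- ifelse(eq$condition_2 == 1L, eq[[paste0("n", cat, "1")]],
                 eq[[paste0("n", cat, "2")]])
    lo <- ifelse(eq$condition_2 == 1L, eq[[paste0("n", cat, "2")]],
                 eq[[paste0("n", cat, "1")]])
    expect_equal(mean(hi), 6.5)  # net 13/16 of 8
    expect_equal(mean(lo), 3.5)  # net 7/16 of 8
  }
})

test_that("schedule_rewards places exact counts and rejects impossible ones", {
  set.seed(1)
  expect_equal(sum(schedule_rewards(8L, 5L)), 5L)  # 10/16 over 8 trials
  expect_equal(sum(schedule_rewards(8L, 0L)), 0L)
  expect_error(schedule_rewards(8L, 9L), "design error")
  expect_error(schedule_rewards(8L, 3.5), "design error")
})

test_that("invalid configurations raise design errors", {
  expect_error(task_config(trials_per_block = 30L), "design error")
  expect_error(task_config(blocks_per_run = 4L), "design error")
  expect_error(task_config(n_runs = 3L), "design error")
})

test_that("validate_counterbalancing fails loudly on corrupted sessions", {
  s <- fix_session(3L)
  expect_true(validate_counterbalancing(s)$ok)

  # flipping the run's last block remaps category 1 twice and category 2
  # never within the run
  s_bad <- s
  s_bad$blocks$map_cat1[3] <- 3L - s_bad$blocks$map_cat1[3]
  s_bad$blocks$map_cat2[3] <- 3L - s_bad$blocks$map_cat2[3]
  a <- validate_counterbalancing(s_bad)
  expect_false(a$ok)
  expect_false(a$checks$pass[a$checks$check == "single_remapping_per_transition"])

  # unbalanced action yield
  s_bad2 <- s
  flip <- s_bad2$trials$block == 1L
  s_bad2$trials$rewarded_action[flip] <- 1L
  a2 <- validate_counterbalancing(s_bad2)
  expect_false(a2$checks$pass[a2$checks$check == "fixed_action_half_yield"])
})

test_that("7CM variant keeps constant cues; 3FH refreshes them per run", {
  s7 <- generate_session(task_config(seed = 4L, variant = "7CM"))
  expect_equal(length(unique(s7$trials$cue_id)), 4L)
  s3 <- generate_session(task_config(seed = 4L, variant = "3FH"))
  expect_equal(length(unique(s3$trials$cue_id)), 16L)
})

test_that("session generation is deterministic given the seed", {
  a <- generate_session(task_config(seed = 8L))
  b <- generate_session(task_config(seed = 8L))
  expect_identical(a$trials, b$trials)
  expect_identical(a$blocks, b$blocks)
})
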