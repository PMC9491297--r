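#' Task configuration for the hierarchical reversal-learning session
#'
#' Builds the design parameters of a counterbalanced session: 4 runs of 3
#' blocks of 32 trials by default, two cue categories with two states each,
#' two actions (left/right), and reward probabilities expressed in
#' sixteenths. The `variant` only changes cue-identity bookkeeping: `"3FH"`
#' assigns four fresh cue ids at every run start, `"7CM"` keeps the same
#' four cue ids for the whole session.
#'
#' @param n_runs number of runs; must be a positive multiple of 4 so that
#'   the 3 x 4 condition cross can be completed within each 4-run cycle.
#' @param blocks_per_run blocks per run; must be 3 (one block per level of
#'   the category-value condition).
#' @param trials_per_block trials per block; must be divisible by 4 with
#'   `trials_per_block / 4` a multiple of 8 so that all scheduled reward
#'   probabilities in sixteenths resolve to integer counts.
#' @param variant `"3FH"` (per-run cues) or `"7CM"` (constant cues).
#' @param seed integer seed driving every random element of the design.
#' @return object of class `grl_task_config`.
#' @export
task_config <- function(n_runs = 4L, blocks_per_run = 3L,
                        trials_per_block = 32L,
                        variant = c("3FH", "7CM"), seed = 1L) {
  variant <- match.arg(variant)
  n_runs <- as.integer(n_runs)
  blocks_per_run <- as.integer(blocks_per_run)
  trials_per_block <- as.integer(trials_per_block)
  if (n_runs < 4L || n_runs %% 4L != 0L)
    stop("design error: n_runs must be a positive multiple of 4")
  if (blocks_per_run != 3L)
    stop("design error: blocks_per_run must be 3 (one block per category-value level)")
  if (trials_per_block %% 4L != 0L)
    stop("design error: trials_per_block must be divisible by 4 for equal state exposure")
  t_s <- trials_per_block %/% 4L
  if (t_s %% 8L != 0L)
    stop("design error: trials per state must be a multiple of 8 so that k/16 schedules give integer reward counts")
  structure(list(
    n_runs = n_runs, blocks_per_run = blocks_per_run,
    trials_per_block = trials_per_block,
    n_categories = 2L, states_per_category = 2L,
    actions = c("left", "right"), probability_grid = 16L,
    variant = variant, seed = as.integer(seed)
  ), class = "grl_task_config")
}

# condition-4 mappings: index 1..4 <-> (map_cat1, map_cat2), 1 = "LR"
# (state A rewards left, B right), 2 = "RL" (reversed)
.c4_grid <- cbind(map1 = c(1L, 1L, 2L, 2L), map2 = c(1L, 2L, 1L, 2L))

.c4_label <- function(i) {
  lab <- c("LR", "RL")
  paste0(lab[.c4_grid[i, 1]], "&", lab[.c4_grid[i, 2]])
}

# run a block of code under a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# neighbors / diagonal of a mapping index on the 2x2 flip graph
.c4_neighbors <- function(i) {
  m <- .c4_grid[i, ]
  n1 <- which(.c4_grid[, 1] != m[1] & .c4_grid[, 2] == m[2])
  n2 <- which(.c4_grid[, 1] == m[1] & .c4_grid[, 2] != m[2])
  c(n1, n2)
}
.c4_diag <- function(i) which(.c4_grid[, 1] != .c4_grid[i, 1] &
                              .c4_grid[, 2] != .c4_grid[i, 2])

# Sample a 4-run schedule of condition_3 levels and condition_4 chains such
# that (a) each run's 3 mappings form a single-flip chain remapping each
# category exactly once, (b) the 12 (condition_3, condition_4) cells of the
# session are fully crossed, (c) each condition_3 level appears once per run.
.sample_schedule <- function(max_tries = 500L) {
  lev <- c("cat1", "cat2", "equal")
  for (tr in seq_len(max_tries)) {
    omitted <- sample(4L)            # mapping omitted from each run's chain
    chains <- lapply(omitted, function(o) {
      ends <- .c4_neighbors(o)
      mid <- .c4_diag(o)
      if (runif(1) < 0.5) ends <- rev(ends)
      c(ends[1], mid, ends[2])
    })
    for (tr2 in seq_len(100L)) {
      c3 <- replicate(4L, sample(lev), simplify = FALSE)
      cells <- unlist(lapply(1:4, function(r) paste(c3[[r]], chains[[r]])))
      if (!anyDuplicated(cells)) {
        return(list(c3 = c3, c4 = chains))
      }
    }
  }
  stop("design error: could not satisfy the 3 x 4 counterbalancing cross")
}

# per-block reward-count table for one 4-run cycle, given schedule.
# Returns a data.frame of blocks or NULL if the fixed-action balance
# rejection fails for this draw.
.sample_block_counts <- function(schedule, t_s, max_tries = 5000L) {
  c3 <- unlist(schedule$c3)            # length 12, run-major
  c4 <- unlist(schedule$c4)
  run <- rep(1:4, each = 3L)
  u <- t_s / 8L                        # count units: numerator k -> k * u / 2
  cnt <- function(k) as.integer(k * u / 2)   # k in sixteenths, even k
  for (tr in seq_len(max_tries)) {
    # condition_2: which state is higher valued; 2:1 quota within each run
    c2 <- integer(12)
    for (r in 1:4) {
      maj <- sample(1:2, 1)
      v <- c(maj, maj, 3L - maj)
      c2[run == r] <- sample(v)
    }
    # half-splits: for each condition_3 level pick which 2 of its 4 blocks
    # take the upper half of each odd probability
    n <- matrix(0L, nrow = 12, ncol = 4)  # columns: (cat1 A, cat1 B, cat2 A, cat2 B)
    for (levname in c("cat1", "cat2", "equal")) {
      idx <- which(c3 == levname)
      if (levname == "equal") {
        for (cat in 1:2) {
          hi_first <- sample(c(TRUE, TRUE, FALSE, FALSE))  # (14,6) vs (12,8)
          for (j in seq_along(idx)) {
            b <- idx[j]
            hs <- c2[b]; ls <- 3L - hs
            kk <- if (hi_first[j]) c(14L, 6L) else c(12L, 8L)
            n[b, (cat - 1L) * 2L + hs] <- cnt(kk[1])
            n[b, (cat - 1L) * 2L + ls] <- cnt(kk[2])
          }
        }
      } else {
        g <- if (levname == "cat1") 1L else 2L   # greater category
        l <- 3L - g
        a_hi <- sample(c(TRUE, TRUE, FALSE, FALSE)) # lesser cat state A takes 8/16
        for (j in seq_along(idx)) {
          b <- idx[j]
          hs <- c2[b]; ls <- 3L - hs
          n[b, (g - 1L) * 2L + hs] <- cnt(16L)
          n[b, (g - 1L) * 2L + ls] <- cnt(10L)
          kk <- if (a_hi[j]) c(8L, 6L) else c(6L, 8L)
          n[b, (l - 1L) * 2L + 1L] <- cnt(kk[1])
          n[b, (l - 1L) * 2L + 2L] <- cnt(kk[2])
        }
      }
    }
    # fixed-action balance: total scheduled rewards reachable by always-left
    left <- 0L
    for (b in 1:12) {
      maps <- .c4_grid[c4[b], ]
      for (cat in 1:2) {
        ls_state <- if (maps[cat] == 1L) 1L else 2L  # state whose reward is left
        left <- left + n[b, (cat - 1L) * 2L + ls_state]
      }
    }
    if (left * 2L == sum(n)) {
      return(data.frame(
        run = run, block_in_run = rep(1:3, 4),
        condition_3 = c3, condition_2 = c2, condition_4 = c4,
        map_cat1 = .c4_grid[c4, 1], map_cat2 = .c4_grid[c4, 2],
        n11 = n[, 1], n12 = n[, 2], n21 = n[, 3], n22 = n[, 4]
      ))
    }
  }
  NULL
}

#' Order one block's trials into randomized, counterbalanced quartets
#'
#' Each quartet of 4 consecutive trials contains each (category, state) pair
#' exactly once, and no cue may repeat on consecutive trials, including
#' across quartet (and block) boundaries via `prev_last`.
#'
#' @param n_quartets number of quartets (trials / 4).
#' @param prev_last integer 1..4 coding the (category, state) pair of the
#'   immediately preceding trial, or `NA` at a boundary with no constraint.
#' @param max_tries retry budget per quartet before raising a design error.
#' @return integer vector of pair codes 1..4, where code = 2*(category-1) + state.
#' @export
order_trials <- function(n_quartets, prev_last = NA_integer_, max_tries = 100L) {
  out <- integer(0)
  last <- prev_last
  for (q in seq_len(n_quartets)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      perm <- sample(4L)
      if (is.na(last) || perm[1] != last) { ok <- TRUE; break }
    }
    if (!ok) stop("design error: no-consecutive-cue constraint unsatisfiable within retry budget")
    out <- c(out, perm)
    last <- perm[4]
  }
  out
}

#' Place an exact number of scheduled rewards among a state's trials
#'
#' The schedule is exact-count, not Bernoulli: `count` of the `n_trials`
#' positions are flagged reward-available, uniformly at random.
#'
#' @param n_trials number of trials of this state in the block.
#' @param count integer number of scheduled rewards.
#' @return logical vector of length `n_trials`.
#' @export
schedule_rewards <- function(n_trials, count) {
  if (count != as.integer(count) || count < 0 || count > n_trials)
    stop("design error: reward count must be an integer in [0, n_trials]")
  avail <- rep(FALSE, n_trials)
  if (count > 0) avail[sample.int(n_trials, count)] <- TRUE
  avail
}

#' Generate a complete counterbalanced session
#'
#' Draws the block conditions (category-value relation, higher-valued state,
#' action mapping), resolves exact reward counts in sixteenths including the
#' paired half-splits of odd probabilities, orders trials in quartets with
#' no consecutive cue repeats, and pre-schedules reward availability. The
#' construction guarantees that a constant-action chooser would earn exactly
#' half of all scheduled rewards, that each category precedes exactly half
#' of each run's rewards, and that each run carries exactly one quarter of
#' the session's rewards.
#'
#' @param config a [task_config()].
#' @return object of class `grl_session`: list with `config`, `blocks`
#'   (one row per block), `trials` (one row per trial) and `audit`
#'   (the [validate_counterbalancing()] report).
#' @export
generate_session <- function(config = task_config()) {
  stopifnot(inherits(config, "grl_task_config"))
  with_seed(config$seed, .generate_session_impl(config))
}

.generate_session_impl <- function(config) {
  t_s <- config$trials_per_block %/% 4L
  n_cycles <- config$n_runs %/% 4L
  blocks <- NULL
  for (cy in seq_len(n_cycles)) {
    repeat {
      sched <- .sample_schedule()
      bl <- .sample_block_counts(sched, t_s)
      if (!is.null(bl)) break
    }
    bl$run <- bl$run + (cy - 1L) * 4L
    blocks <- rbind(blocks, bl)
  }
  blocks$block <- seq_len(nrow(blocks))
  blocks$condition_4_label <- .c4_label(blocks$condition_4)
  # remapped category relative to the previous block within the run
  blocks$remapped_category <- NA_integer_
  for (b in which(blocks$block_in_run > 1L)) {
    ch1 <- blocks$map_cat1[b] != blocks$map_cat1[b - 1]
    ch2 <- blocks$map_cat2[b] != blocks$map_cat2[b - 1]
    blocks$remapped_category[b] <- if (ch1 && !ch2) 1L else if (ch2 && !ch1) 2L else NA_integer_
  }

  trials <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    prev_last <- NA_integer_
    if (blocks$block_in_run[b] > 1L) {
      tb <- trials[[b - 1L]]
      prev_last <- 2L * (tb$category[nrow(tb)] - 1L) + tb$state[nrow(tb)]
    }
    codes <- order_trials(t_s, prev_last)   # t_s quartets of the 4 (category, state) pairs
    category <- (codes - 1L) %/% 2L + 1L
    state <- (codes - 1L) %% 2L + 1L
    map <- c(blocks$map_cat1[b], blocks$map_cat2[b])
    rewarded_action <- ifelse(map[category] == 1L, state, 3L - state)
    counts <- matrix(as.integer(unlist(blocks[b, c("n11", "n12", "n21", "n22")])),
                     nrow = 2, byrow = TRUE)
    avail <- logical(length(codes))
    for (cat in 1:2) for (s in 1:2) {
      idx <- which(category == cat & state == s)
      avail[idx] <- schedule_rewards(length(idx), counts[cat, s])
    }
    iti <- sample(seq(3, 7, by = 1 / 3), length(codes), replace = TRUE)
    trials[[b]] <- data.frame(
      run = blocks$run[b], block = blocks$block[b],
      block_in_run = blocks$block_in_run[b],
      trial_in_block = seq_along(codes),
      quartet = (seq_along(codes) - 1L) %/% 4L + 1L,
      category = category, state = state,
      rewarded_action = rewarded_action, reward_available = avail,
      iti = iti
    )
  }
  trials <- do.call(rbind, trials)
  trials$trial <- seq_len(nrow(trials))
  trials$cue_id <- if (config$variant == "3FH") {
    sprintf("r%d_c%ds%d", trials$run, trials$category, trials$state)
  } else {
    sprintf("c%ds%d", trials$category, trials$state)
  }
  # cue onset bookkeeping: 2 s cue + 3 s ISI + 1 s outcome + jittered ITI
  dur <- 2 + 3 + 1 + trials$iti
  trials$onset <- stats::ave(dur, trials$run, FUN = function(x) cumsum(c(0, x[-length(x)])))
  trials$isi <- 3

  session <- structure(list(config = config, blocks = blocks, trials = trials),
                       class = "grl_session")
  session$audit <- validate_counterbalancing(session)
  if (!session$audit$ok)
    stop("internal design error: generated session failed its counterbalancing audit")
  session
}

#' @export
print.grl_session <- function(x, ...) {
  cat(sprintf("grl_session: %d trials, %d blocks, %d runs (variant %s, seed %d)\n",
              nrow(x$trials), nrow(x$blocks), x$config$n_runs,
              x$config$variant, x$config$seed))
  cat(sprintf("scheduled rewards: %d (left-action yield %d)\n",
              sum(x$trials$reward_available),
              sum(x$trials$reward_available & x$trials$rewarded_action == 1L)))
  invisible(x)
}

#' Audit the counterbalancing invariants of a session
#'
#' Reports boolean checks with supporting counts: total trial/block counts,
#' quartet composition, the no-consecutive-cue constraint, exact scheduled
#' counts per (block, state), fixed-action reward balance, per-run reward
#' quarters (to within one scheduled reward), per-run category halves, the
#' single-remapping schedule, and the condition quotas.
#'
#' @param session a `grl_session` (generated or hand-built with the same
#'   fields).
#' @return list with `ok` (all checks passed) and `checks`, a data.frame of
#'   named checks with pass flags and observed/expected values.
#' @export
validate_counterbalancing <- function(session) {
  tr <- session$trials
  bl <- session$blocks
  cfg <- session$config
  checks <- list()
  add <- function(name, pass, observed, expected) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass,
      observed = as.character(observed), expected = as.character(expected))
  }

  n_expect <- cfg$n_runs * cfg$blocks_per_run * cfg$trials_per_block
  add("total_trials", nrow(tr) == n_expect, nrow(tr), n_expect)
  add("total_blocks", nrow(bl) == cfg$n_runs * cfg$blocks_per_run,
      nrow(bl), cfg$n_runs * cfg$blocks_per_run)

  # quartets contain each (category, state) once
  code <- 2L * (tr$category - 1L) + tr$state
  qid <- paste(tr$block, tr$quartet)
  qok <- all(tapply(code, qid, function(x) length(x) == 4 && all(sort(x) == 1:4)))
  add("quartet_composition", qok, qok, TRUE)

  # no consecutive cue within a run
  rep_ok <- !any(tr$cue_id[-1] == tr$cue_id[-nrow(tr)] &
                 tr$run[-1] == tr$run[-nrow(tr)])
  add("no_consecutive_cue", rep_ok, rep_ok, TRUE)

  # scheduled counts per (block, category, state) match the block table
  cnt_ok <- TRUE
  for (b in seq_len(nrow(bl))) {
    for (cat in 1:2) for (s in 1:2) {
      idx <- tr$block == bl$block[b] & tr$category == cat & tr$state == s
      want <- bl[b, c("n11", "n12", "n21", "n22")][[(cat - 1L) * 2L + s]]
      if (sum(tr$reward_available[idx]) != want) cnt_ok <- FALSE
    }
  }
  add("scheduled_counts_exact", cnt_ok, cnt_ok, TRUE)

  total <- sum(tr$reward_available)
  left <- sum(tr$reward_available & tr$rewarded_action == 1L)
  add("fixed_action_half_yield", 2L * left == total, left, total / 2)

  per_run <- tapply(tr$reward_available, tr$run, sum)
  add("run_reward_quarters", all(abs(per_run - total / cfg$n_runs) <= 1),
      paste(per_run, collapse = ","), total / cfg$n_runs)

  cat_half <- TRUE
  for (r in unique(tr$run)) {
    i <- tr$run == r
    c1 <- sum(tr$reward_available[i & tr$category == 1L])
    if (2L * c1 != sum(tr$reward_available[i])) cat_half <- FALSE
  }
  add("category_half_per_run", cat_half, cat_half, TRUE)

  # remapping: exactly one category flips at each within-run transition and
  # each category flips once per run
  remap_ok <- TRUE
  for (r in unique(bl$run)) {
    rb <- bl[bl$run == r, ]
    rb <- rb[order(rb$block_in_run), ]
    if (nrow(rb) < 2) next
    f1 <- diff(rb$map_cat1) != 0
    f2 <- diff(rb$map_cat2) != 0
    if (!all(xor(f1, f2)) || sum(f1) != 1L || sum(f2) != 1L) remap_ok <- FALSE
  }
  add("single_remapping_per_transition", remap_ok, remap_ok, TRUE)

  # condition quotas (per 4-run cycle)
  c3_ok <- all(tapply(bl$condition_3, bl$run,
                      function(x) length(unique(x)) == 3L))
  add("condition3_counterbalanced_per_run", c3_ok, c3_ok, TRUE)
  cross_ok <- TRUE
  for (cy in seq_len(cfg$n_runs %/% 4L)) {
    i <- bl$run > (cy - 1L) * 4L & bl$run <= cy * 4L
    cross_ok <- cross_ok &&
      !anyDuplicated(paste(bl$condition_3[i], bl$condition_4[i]))
  }
  add("condition3x4_full_cross", cross_ok, cross_ok, TRUE)
  c2_ok <- all(tapply(bl$condition_2, bl$run,
                      function(x) sort(table(factor(x, 1:2)))[1] == 1L))
  add("condition2_two_to_one_per_run", c2_ok, c2_ok, TRUE)

  checks <- do.call(rbind, checks)
  list(ok = all(checks$pass), checks = checks)
}
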