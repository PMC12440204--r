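test_that("a dyad is bit-for-bit reproducible from its seed", {
  cfg <- tiny_config(rounds = 150)
  a <- run_dyad(cfg, seed = 99, keep_q_history = TRUE)
  b <- run_dyad(cfg, seed = 99, keep_q_history = TRUE)
  expect_identical(a, b)
  c <- run_dyad(cfg, seed = 100)
  expect_false(identical(a$b_action, c$b_action) && identical(a$d_action, c$d_action))
  # sampled thirst is part of the same deterministic stream
  cfg_s <- tiny_config(game_params(r = 0.5, U = 0.2, V = 0.2, p = 0.5), rounds = 150)
  expect_identical(run_dyad(cfg_s, 7)$thirsty, run_dyad(cfg_s, 7)$thirsty)
  expect_gt(mean(run_dyad(cfg_s, 7)$thirsty), 0.3)
})

test_that("stored rewards equal game-core recomputation from the stored actions", {
  for (game in case_games) {
    cfg <- tiny_config(game, rounds = 200)
    rec <- run_dyad(cfg, seed = 17)
    pay <- individual_payoffs(rec$b_action, rec$d_action, rec$thirsty, game)
    fit <- inclusive_fitness(pay$P_B, pay$P_D, game$r)
    expect_equal(rec$F_B, fit$F_B)
    expect_equal(rec$F_D, fit$F_D)
  }
})

test_that("the first explore_rounds rounds are all flagged exploratory", {
  cfg <- tiny_config(rounds = 120)
  rec <- run_dyad(cfg, seed = 3)
  expect_true(all(rec$explored_b[1:50]))
  expect_true(all(rec$explored_d[1:50]))
  # after the phase the flag frequency tracks the 2/N schedule
  eps <- epsilon_at(51:120, cfg$donor)
  n_flag <- sum(rec$explored_d[51:120]) + sum(rec$explored_b[51:120])
  expect_lt(n_flag, 2 * sum(eps) + 4 * sqrt(2 * sum(eps)) + 1)
})

test_that("frozen agents (alpha = 0) leave their Q-tables at zero", {
  cfg <- tiny_config(
    beneficiary = agent_config("beneficiary", alpha = 0),
    donor = agent_config("donor", alpha = 0))
  rec <- run_dyad(cfg, seed = 21)
  expect_true(all(rec$q_b == 0))
  expect_true(all(rec$q_d == 0))
})

test_that("stepping play_round reproduces run_dyad exactly", {
  cfg <- tiny_config(rounds = 80, base_seed = 0)
  seed <- 12
  rec <- run_dyad(cfg, seed)
  set.seed(seed)
  b0 <- sample.int(3, 1); d0 <- sample.int(2, 1)
  state <- encode_state(b_actions[b0], d_actions[d0])
  b_agent <- list(config = cfg$beneficiary, qtable = new_qtable(cfg$beneficiary))
  d_agent <- list(config = cfg$donor, qtable = new_qtable(cfg$donor))
  ab <- character(80); ad <- character(80)
  for (t in 1:80) {
    step <- play_round(b_agent, d_agent, state, thirsty = FALSE,
                       params = cfg$game, round = t)
    b_agent <- step$b_agent; d_agent <- step$d_agent; state <- step$next_state
    ab[t] <- step$outcome$b_action; ad[t] <- step$outcome$d_action
  }
  expect_identical(ab, rec$b_action)
  expect_identical(ad, rec$d_action)
  expect_equal(b_agent$qtable, rec$q_b)
  expect_equal(d_agent$qtable, rec$q_d)
  expect_identical(state, rec$final_state)
})

test_that("play_round under forced greedy policies yields the one-shot fitness cell", {
  g <- case_games$case2
  b_agent <- list(config = agent_config("beneficiary", explore_rounds = 0),
                  qtable = new_qtable(agent_config("beneficiary")))
  d_agent <- list(config = agent_config("donor", explore_rounds = 0),
                  qtable = new_qtable(agent_config("donor")))
  b_agent$qtable[, "N"] <- 5   # make N / G dominant everywhere
  d_agent$qtable[, "G"] <- 5
  step <- play_round(b_agent, d_agent, "NK", thirsty = FALSE, params = g,
                     round = 1000)  # epsilon ~ 0.002; greedy with prob ~1
  expect_equal(step$outcome$b_action, "N")
  expect_equal(step$outcome$d_action, "G")
  expect_equal(step$outcome$F_B, 1 + g$r * g$U)
  expect_equal(step$outcome$F_D, g$U + g$r)
  expect_equal(step$next_state, "NG")
})

test_that("a myopic learner converges to the best response against a static opponent", {
  # oracle: enumerate the donor's one-round inclusive fitness against a
  # permanently weak-signalling, not-thirsty beneficiary
  for (case in c("case1", "case2")) {
    g <- case_games[[case]]
    keep <- inclusive_fitness(g$V * (1 - g$c_weak), 1, g$r)$F_D
    give <- inclusive_fitness(1 * (1 - g$c_weak), g$U, g$r)$F_D
    best <- if (give > keep) "G" else "K"
    cfg <- experiment_config(
      g, beneficiary = static_policy("W", "beneficiary"),
      donor = agent_config("donor", alpha = 0.5, gamma = 0),
      rounds = 400, n_runs = 1, base_seed = 1)
    rec <- run_dyad(cfg, seed = 2)
    visited <- unique(tail(paste0(rec$b_action, rec$d_action), 100))
    greedy <- colnames(rec$q_d)[apply(rec$q_d[visited, , drop = FALSE], 1, which.max)]
    expect_true(all(greedy == best))
    expect_equal(classify(rec)[["donor"]], if (best == "G") "GG" else "KK")
    # the static seat is classified from its own fixed sequence
    expect_equal(classify(rec)[["beneficiary"]], "WW")
  }
})

test_that("experiment summaries aggregate run classifications and seeds", {
  cfg <- tiny_config(rounds = 150, n_runs = 6, base_seed = 400)
  ex <- run_experiment(cfg, keep_records = TRUE)
  expect_equal(nrow(ex$labels), 6)
  expect_equal(ex$labels$seed, 401:406)
  # n_runs = 1: the summary is the single record's classification
  cfg1 <- tiny_config(rounds = 150, n_runs = 1, base_seed = 400)
  ex1 <- run_experiment(cfg1)
  rec <- run_dyad(cfg1, seed = 401)
  expect_equal(ex1$labels$beneficiary, classify(rec)[["beneficiary"]])
  expect_equal(ex1$labels$donor, classify(rec)[["donor"]])
  # per-role proportions sum to one
  for (role in c("beneficiary", "donor"))
    expect_equal(sum(ex$proportions$proportion[ex$proportions$role == role]), 1)
  # window-averaged Q means equal the mean over kept records
  mats <- lapply(ex$records, `[[`, "q_d_window")
  expect_equal(ex$q_mean_d, Reduce(`+`, mats) / length(mats))
})

test_that("experiment configuration violations are reported with their keys", {
  g <- case_games$case1
  expect_error(experiment_config(g, rounds = 40), "explore_rounds")
  expect_error(experiment_config(g, n_runs = 0), "n_runs")
  expect_error(experiment_config(g, q_window = 0), "q_window")
  # an over-long averaging window is capped at the horizon
  expect_equal(experiment_config(g, rounds = 80, q_window = 100)$q_window, 80L)
  expect_error(
    experiment_config(g, beneficiary = agent_config("donor"),
                      donor = agent_config("donor")),
    "role")
  err <- tryCatch(experiment_config(g, rounds = 10, n_runs = 0),
                  error = conditionMessage)
  expect_match(err, "rounds")
  expect_match(err, "n_runs")
})

test_that("two-round memory runs on the 36-state space and classifies", {
  cfg <- tiny_config(
    rounds = 200,
    beneficiary = agent_config("beneficiary", memory = 2),
    donor = agent_config("donor", memory = 2))
  rec <- run_dyad(cfg, seed = 31)
  expect_equal(nrow(rec$q_d), 36)
  expect_match(rec$final_state, "^[NWS][KG]\\.[NWS][KG]$")
  expect_true(all(classify(rec) %in% c(strategy_labels("beneficiary"),
                                       strategy_labels("donor"))))
})

test_that("a thirst-observing beneficiary tracks state-dependent rewards", {
  g <- game_params(r = 0.5, U = 0.2, V = 0.2, p = 0.5)
  cfg <- experiment_config(
    g, beneficiary = agent_config("beneficiary", observe_thirst = TRUE),
    donor = agent_config("donor"), rounds = 200, n_runs = 1, base_seed = 1)
  rec <- run_dyad(cfg, seed = 4)
  expect_equal(nrow(rec$q_b), 12)
  expect_true(any(rec$q_b[1:6, ] != 0) && any(rec$q_b[7:12, ] != 0))
  expect_identical(run_dyad(cfg, 4)$q_b, rec$q_b)
})
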