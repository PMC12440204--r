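# Simulation engine: seeded dyadic interactions and batched experiments.

#' Experiment configuration
#'
#' @param game A [game_params()] object.
#' @param beneficiary,donor [agent_config()] objects (or [static_policy()]
#'   objects for non-learning baselines) for the two seats.
#' @param rounds Rounds per dyad; default 500.
#' @param n_runs Number of independent dyads per experiment; default 1000.
#' @param base_seed Seed ledger base: run `i` is seeded with
#'   `base_seed + i`.
#' @param thirst `"auto"` (fixed at the game's `p` when `p` is 0 or 1,
#'   sampled otherwise), `"fixed0"`, `"fixed1"`, or `"sampled"`.
#' @param q_window Number of final rounds over which converged Q-values
#'   are averaged; default 100.
#' @return An object of class `"sps_config"`.
#' @examples
#' cfg <- experiment_config(game_params(r = 0.5, U = 0.2, V = 0.2),
#'                          rounds = 200, n_runs = 10)
#' @export
experiment_config <- function(game,
                              beneficiary = agent_config("beneficiary"),
                              donor = agent_config("donor"),
                              rounds = 500L, n_runs = 1000L, base_seed = 1L,
                              thirst = c("auto", "fixed0", "fixed1", "sampled"),
                              q_window = 100L) {
  thirst <- match.arg(thirst)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (!inherits(game, "sps_game")) note("game: must be a game_params() object")
  for (seat in c("beneficiary", "donor")) {
    a <- get(seat)
    if (!inherits(a, "sps_agent_config") && !inherits(a, "sps_static"))
      note(sprintf("%s: must be an agent_config() or static_policy()", seat))
    else if (!is.null(a$role) && a$role != seat)
      note(sprintf("%s: agent role is '%s'", seat, a$role))
  }
  if (!is.numeric(rounds) || rounds < 1) note("rounds: must be a positive integer")
  if (!is.numeric(n_runs) || n_runs < 1) note("n_runs: must be >= 1")
  if (!is.numeric(base_seed) || !is.finite(base_seed))
    note("base_seed: must be a finite integer")
  for (seat in c("beneficiary", "donor")) {
    a <- get(seat)
    if (inherits(a, "sps_agent_config") && is.numeric(rounds) &&
        rounds <= a$explore_rounds)
      note(sprintf("rounds: must exceed %s explore_rounds (%d)", seat, a$explore_rounds))
  }
  if (!is.numeric(q_window) || q_window < 1)
    note("q_window: must be a positive integer")
  if (length(problems))
    stop("invalid experiment configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  if (thirst == "auto")
    thirst <- if (game$p <= 0) "fixed0" else if (game$p >= 1) "fixed1" else "sampled"
  structure(
    list(game = game, beneficiary = beneficiary, donor = donor,
         rounds = as.integer(rounds), n_runs = as.integer(n_runs),
         base_seed = as.integer(base_seed), thirst = thirst,
         q_window = as.integer(min(q_window, rounds))),
    class = "sps_config")
}

#' @export
print.sps_config <- function(x, ...) {
  cat(sprintf("Experiment: %d runs x %d rounds, thirst %s, base seed %d\n",
              x$n_runs, x$rounds, x$thirst, x$base_seed))
  print(x$game)
  for (seat in c("beneficiary", "donor")) {
    a <- x[[seat]]
    if (inherits(a, "sps_static"))
      cat(sprintf("  %s: static policy (%s)\n", seat, paste(a$actions, collapse = ",")))
    else
      cat(sprintf("  %s: Q-learning, alpha = %g, gamma = %g, explore %d rounds, decay %s, memory %d\n",
                  seat, a$alpha, a$gamma, a$explore_rounds, a$epsilon_decay, a$memory))
  }
  invisible(x)
}

# internal: per-seat loop state used by both play_round and run_dyad
agent_is_static <- function(a) inherits(a, "sps_static")

#' Play a single round
#'
#' Both agents select an action from the shared observation state (the
#' previous round's joint action), payoffs and inclusive fitness follow
#' from the game parameters, and both Q-learning agents update the entry
#' they just played using their inclusive fitness as reward. The next
#' state is the encoding of this round's joint action.
#'
#' Random draws (exploration, tie-breaks) consume the R RNG in the fixed
#' order beneficiary then donor, matching [run_dyad()].
#'
#' @param b_agent,d_agent Lists `list(config = agent_config(), qtable = ...)`,
#'   or [static_policy()] objects.
#' @param state Current observation state label.
#' @param thirsty Logical thirst state for this round.
#' @param params A [game_params()] object.
#' @param round Round number (drives the exploration schedule).
#' @param thirsty_next Thirst state of the following round (only relevant
#'   when the beneficiary observes thirst); defaults to `thirsty`.
#' @return A list with `outcome` (actions, exploration flags, payoffs and
#'   inclusive fitness), updated `b_agent` and `d_agent`, and `next_state`.
#' @export
play_round <- function(b_agent, d_agent, state, thirsty, params, round = 1L,
                       thirsty_next = thirsty) {
  pick <- function(agent, role) {
    if (agent_is_static(agent)) {
      acts <- agent$actions
      list(action = acts[((round - 1L) %% length(acts)) + 1L], explored = FALSE)
    } else {
      st <- state
      if (isTRUE(agent$config$observe_thirst) && thirsty)
        st <- paste0(state, "+T")
      eps <- epsilon_at(round, agent$config)
      sel <- select_action(agent$qtable, st, eps)
      list(action = sel$action, explored = sel$explored)
    }
  }
  b <- pick(b_agent, "beneficiary")
  d <- pick(d_agent, "donor")
  pay <- individual_payoffs(b$action, d$action, thirsty, params)
  fit <- inclusive_fitness(pay$P_B, pay$P_D, params$r)
  mem <- function(agent) if (agent_is_static(agent)) 1L else agent$config$memory
  next_b <- encode_state(c(strsplit_state_b(state), b$action),
                         c(strsplit_state_d(state), d$action), mem(b_agent))
  next_d <- encode_state(c(strsplit_state_b(state), b$action),
                         c(strsplit_state_d(state), d$action), mem(d_agent))
  if (!agent_is_static(b_agent)) {
    st <- state; nx <- next_b
    if (isTRUE(b_agent$config$observe_thirst)) {
      if (thirsty) st <- paste0(state, "+T")
      if (thirsty_next) nx <- paste0(next_b, "+T")
    }
    b_agent$qtable <- q_update(b_agent$qtable, st, b$action, fit$F_B, nx,
                               b_agent$config)
  }
  if (!agent_is_static(d_agent))
    d_agent$qtable <- q_update(d_agent$qtable, state, d$action, fit$F_D, next_d,
                               d_agent$config)
  list(outcome = list(b_action = b$action, d_action = d$action,
                      explored_b = b$explored, explored_d = d$explored,
                      thirsty = thirsty, P_B = pay$P_B, P_D = pay$P_D,
                      F_B = fit$F_B, F_D = fit$F_D),
       b_agent = b_agent, d_agent = d_agent, next_state = next_d)
}

# split a (possibly m > 1) state label into per-round action vectors
strsplit_state_b <- function(state) {
  parts <- strsplit(state, ".", fixed = TRUE)[[1]]
  substr(parts, 1L, 1L)
}
strsplit_state_d <- function(state) {
  parts <- strsplit(state, ".", fixed = TRUE)[[1]]
  substr(parts, 2L, 2L)
}

#' Run one seeded dyad
#'
#' Runs `config$rounds` sequential rounds between the two configured
#' agents. All randomness flows from a single R RNG stream seeded with
#' `seed` and consumed in a fixed order (pre-game history, then the
#' thirst sequence when sampled, then per round the beneficiary's and the
#' donor's draws), so a record is bit-for-bit reproducible from its seed.
#'
#' The round-1 observation state is produced by seeding the pre-game
#' history with `m` uniformly random joint actions, keeping the state
#' space at exactly `6^m`.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed for this dyad.
#' @param keep_q_history If `TRUE`, store per-round snapshots of both
#'   Q-tables (arrays rounds x states x actions).
#' @return An object of class `"sps_dyad"`: per-round actions,
#'   exploration flags, thirst states and inclusive-fitness rewards, the
#'   final and window-averaged Q-tables, the final observation state and
#'   the seed used.
#' @examples
#' cfg <- experiment_config(game_params(r = 0.5, U = 0.2, V = 0.2),
#'                          rounds = 100, n_runs = 1)
#' rec <- run_dyad(cfg, seed = 7)
#' table(rec$d_action[51:100])
#' @export
run_dyad <- function(config, seed, keep_q_history = FALSE) {
  stopifnot(inherits(config, "sps_config"))
  game <- config$game
  rounds <- config$rounds
  qwin <- min(config$q_window, rounds)
  set.seed(seed)

  b_cfg <- config$beneficiary; d_cfg <- config$donor
  b_static <- agent_is_static(b_cfg); d_static <- agent_is_static(d_cfg)
  mem <- if (b_static && d_static) 1L else
    max(if (!b_static) b_cfg$memory else 1L, if (!d_static) d_cfg$memory else 1L)
  if (!b_static && !d_static && b_cfg$memory != d_cfg$memory)
    stop("agents with different memory lengths are not supported", call. = FALSE)

  n_states <- 6L^mem
  b_thirst <- !b_static && isTRUE(b_cfg$observe_thirst)
  q_b <- if (!b_static) new_qtable(b_cfg)
  q_d <- if (!d_static) new_qtable(d_cfg)

  # pre-game history: m random joint actions
  state <- 0L
  for (i in seq_len(mem)) {
    b0 <- sample.int(3L, 1L); d0 <- sample.int(2L, 1L)
    state <- if (i == 1L) joint_index(b0, d0) else
      shift_state(state, joint_index(b0, d0), mem)
  }

  thirsty_seq <- switch(config$thirst,
    fixed0 = rep(FALSE, rounds + 1L),
    fixed1 = rep(TRUE, rounds + 1L),
    sampled = stats::runif(rounds + 1L) < game$p)

  eps_b <- if (!b_static) epsilon_at(seq_len(rounds), b_cfg)
  eps_d <- if (!d_static) epsilon_at(seq_len(rounds), d_cfg)
  costs <- game$costs; U <- game$U; V <- game$V; r <- game$r
  a_b <- if (!b_static) b_cfg$alpha; g_b <- if (!b_static) b_cfg$gamma
  a_d <- if (!d_static) d_cfg$alpha; g_d <- if (!d_static) d_cfg$gamma
  b_seq <- if (b_static) match(b_cfg$actions, b_actions)
  d_seq <- if (d_static) match(d_cfg$actions, d_actions)

  ab <- integer(rounds); ad <- integer(rounds)
  eb <- logical(rounds); ed <- logical(rounds)
  fb <- numeric(rounds); fd <- numeric(rounds)
  qb_win <- if (!b_static) q_b * 0
  qd_win <- if (!d_static) q_d * 0
  hist_b <- if (keep_q_history && !b_static)
    array(0, c(rounds, nrow(q_b), 3L), dimnames = list(NULL, rownames(q_b), b_actions))
  hist_d <- if (keep_q_history && !d_static)
    array(0, c(rounds, n_states, 2L), dimnames = list(NULL, rownames(q_d), d_actions))

  for (t in seq_len(rounds)) {
    thirsty <- thirsty_seq[t]
    row_b <- if (b_thirst && thirsty) state + n_states else state

    if (b_static) {
      bi <- b_seq[((t - 1L) %% length(b_seq)) + 1L]; xb <- FALSE
    } else if (eps_b[t] > 0 && stats::runif(1) < eps_b[t]) {
      bi <- sample.int(3L, 1L); xb <- TRUE
    } else {
      qrow <- q_b[row_b, ]; cand <- which(qrow >= max(qrow))
      bi <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      xb <- FALSE
    }
    if (d_static) {
      di <- d_seq[((t - 1L) %% length(d_seq)) + 1L]; xd <- FALSE
    } else if (eps_d[t] > 0 && stats::runif(1) < eps_d[t]) {
      di <- sample.int(2L, 1L); xd <- TRUE
    } else {
      qrow <- q_d[state, ]; cand <- which(qrow >= max(qrow))
      di <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      xd <- FALSE
    }

    P_D <- if (di == 2L) U else 1
    s_B <- if (di == 2L) 1 else if (thirsty) 0 else V
    P_B <- s_B * (1 - costs[[bi]])
    F_B <- P_B + r * P_D
    F_D <- P_D + r * P_B

    state_next <- shift_state(state, joint_index(bi, di), mem)
    if (!b_static) {
      row_next <- if (b_thirst && thirsty_seq[t + 1L]) state_next + n_states else state_next
      q_b[row_b, bi] <- q_b[row_b, bi] +
        a_b * (F_B + g_b * max(q_b[row_next, ]) - q_b[row_b, bi])
    }
    if (!d_static)
      q_d[state, di] <- q_d[state, di] +
        a_d * (F_D + g_d * max(q_d[state_next, ]) - q_d[state, di])

    ab[t] <- bi; ad[t] <- di; eb[t] <- xb; ed[t] <- xd
    fb[t] <- F_B; fd[t] <- F_D
    if (t > rounds - qwin) {
      if (!b_static) qb_win <- qb_win + q_b
      if (!d_static) qd_win <- qd_win + q_d
    }
    if (keep_q_history) {
      if (!b_static) hist_b[t, , ] <- q_b
      if (!d_static) hist_d[t, , ] <- q_d
    }
    state <- state_next
  }

  structure(
    list(seed = seed,
         b_action = b_actions[ab], d_action = d_actions[ad],
         explored_b = eb, explored_d = ed,
         thirsty = thirsty_seq[seq_len(rounds)],
         F_B = fb, F_D = fd,
         q_b = q_b, q_d = q_d,
         q_b_window = if (!b_static) qb_win / qwin,
         q_d_window = if (!d_static) qd_win / qwin,
         q_b_history = hist_b, q_d_history = hist_d,
         final_state = state_labels(mem)[((state - 1L) %% n_states) + 1L],
         memory = mem, config = config),
    class = "sps_dyad")
}

#' @export
print.sps_dyad <- function(x, ...) {
  n <- length(x$b_action)
  cl <- classify(x)
  cat(sprintf("Dyad record: %d rounds, seed %d; learned strategies B = %s, D = %s\n",
              n, x$seed, cl[["beneficiary"]], cl[["donor"]]))
  invisible(x)
}

#' Run a batch of independent dyads
#'
#' Runs `n_runs` dyads seeded `base_seed + 1, ..., base_seed + n_runs`,
#' classifies each run's learned strategies, and aggregates strategy
#' proportions and converged Q-value statistics.
#'
#' @param config An [experiment_config()].
#' @param method Strategy readout passed to [classify()].
#' @param keep_records Keep the individual dyad records in the result.
#' @param trajectories If `TRUE`, also accumulate the across-run mean
#'   Q-value of every (state, action) at every round.
#' @param progress Print a progress line every 100 runs.
#' @return An object of class `"sps_experiment"` with elements `labels`
#'   (one row per run: seed and both strategy labels), `proportions`
#'   (per-role label distributions), `q_mean_b` / `q_mean_d` (across-run
#'   means of the window-averaged Q-tables), optional `traj_b` / `traj_d`,
#'   and the fully resolved `config`.
#' @examples
#' cfg <- experiment_config(game_params(r = 0.5, U = 0.2, V = 0.2),
#'                          rounds = 150, n_runs = 20, base_seed = 42)
#' run_experiment(cfg)
#' @export
run_experiment <- function(config, method = c("policy", "realized"),
                           keep_records = FALSE, trajectories = FALSE,
                           progress = FALSE) {
  stopifnot(inherits(config, "sps_config"))
  method <- match.arg(method)
  n <- config$n_runs
  b_lab <- character(n); d_lab <- character(n)
  q_mean_b <- NULL; q_mean_d <- NULL
  traj_b <- NULL; traj_d <- NULL
  records <- if (keep_records) vector("list", n)
  for (i in seq_len(n)) {
    rec <- run_dyad(config, seed = config$base_seed + i,
                    keep_q_history = trajectories)
    cl <- classify(rec, method = method)
    b_lab[i] <- cl[["beneficiary"]]; d_lab[i] <- cl[["donor"]]
    if (!is.null(rec$q_b_window))
      q_mean_b <- if (is.null(q_mean_b)) rec$q_b_window else q_mean_b + rec$q_b_window
    if (!is.null(rec$q_d_window))
      q_mean_d <- if (is.null(q_mean_d)) rec$q_d_window else q_mean_d + rec$q_d_window
    if (trajectories) {
      if (!is.null(rec$q_b_history))
        traj_b <- if (is.null(traj_b)) rec$q_b_history else traj_b + rec$q_b_history
      if (!is.null(rec$q_d_history))
        traj_d <- if (is.null(traj_d)) rec$q_d_history else traj_d + rec$q_d_history
      rec$q_b_history <- NULL; rec$q_d_history <- NULL
    }
    if (keep_records) records[[i]] <- rec
    if (progress && i %% 100L == 0L)
      message(sprintf("run %d / %d", i, n))
  }
  labels <- data.frame(run = seq_len(n), seed = config$base_seed + seq_len(n),
                       beneficiary = b_lab, donor = d_lab,
                       stringsAsFactors = FALSE)
  structure(
    list(labels = labels,
         proportions = strategy_proportions(labels),
         q_mean_b = if (!is.null(q_mean_b)) q_mean_b / n,
         q_mean_d = if (!is.null(q_mean_d)) q_mean_d / n,
         traj_b = if (!is.null(traj_b)) traj_b / n,
         traj_d = if (!is.null(traj_d)) traj_d / n,
         method = method, config = config,
         records = if (keep_records) records),
    class = "sps_experiment")
}

#' @export
print.sps_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Experiment summary: %d runs x %d rounds (%s readout)\n",
              cfg$n_runs, cfg$rounds, x$method))
  print(cfg$game)
  for (role in c("beneficiary", "donor")) {
    pr <- x$proportions[x$proportions$role == role, ]
    if (!nrow(pr)) next
    top <- pr[which.max(pr$proportion), ]
    cat(sprintf("  %s: top strategy %s (%.1f%%)\n",
                role, top$label, 100 * top$proportion))
  }
  invisible(x)
}
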