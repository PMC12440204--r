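# Tabular Q-learning agents: configuration, observation-state encoding,
# epsilon-greedy selection with the paper-style exploration schedule, and
# the one-step Q update. Static (non-learning) policies live here too.

#' Configuration of a learning agent
#'
#' @param role `"beneficiary"` or `"donor"`.
#' @param alpha Learning rate, in `[0, 1]`; 0 freezes the table (a
#'   non-learning agent useful as a baseline).
#' @param gamma Discount rate, in `[0, 1)`.
#' @param explore_rounds Number of initial fully exploratory rounds
#'   (epsilon = 1); default 50.
#' @param epsilon_decay Post-exploration schedule: `"2/N"` (default,
#'   epsilon = `min(1, 2 / round)`), `"constant"` (fixed at
#'   `epsilon_constant`) or `"zero"` (pure greedy).
#' @param epsilon_constant Exploration probability used by the
#'   `"constant"` schedule.
#' @param memory Number of past joint actions the agent conditions on
#'   (`m >= 1`); the observation space has `6^m` states.
#' @param observe_thirst Logical; if `TRUE` (beneficiary only) the current
#'   thirst state is appended to the observation, doubling the state space.
#'   Off by default: the replication presets hold thirst fixed.
#' @return An object of class `"sps_agent_config"`.
#' @examples
#' agent_config("donor", alpha = 0.9, gamma = 0.1)
#' @export
agent_config <- function(role = c("beneficiary", "donor"),
                         alpha = 0.9, gamma = 0.1,
                         explore_rounds = 50L,
                         epsilon_decay = c("2/N", "constant", "zero"),
                         epsilon_constant = 0.004,
                         memory = 1L,
                         observe_thirst = FALSE) {
  role <- match.arg(role)
  epsilon_decay <- match.arg(epsilon_decay)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma < 1,
            is.numeric(explore_rounds), explore_rounds >= 0,
            is.numeric(memory), memory >= 1,
            is.numeric(epsilon_constant), epsilon_constant >= 0, epsilon_constant <= 1,
            is.logical(observe_thirst))
  if (observe_thirst && role == "donor")
    stop("the donor never observes the beneficiary's state", call. = FALSE)
  structure(
    list(role = role, alpha = alpha, gamma = gamma,
         explore_rounds = as.integer(explore_rounds),
         epsilon_decay = epsilon_decay, epsilon_constant = epsilon_constant,
         memory = as.integer(memory), observe_thirst = observe_thirst),
    class = "sps_agent_config")
}

#' Exploration probability at a given round
#'
#' Rounds up to `explore_rounds` are fully exploratory (epsilon = 1);
#' afterwards the default schedule decays as 2 divided by the number of
#' rounds played, capped at 1.
#'
#' @param round Round number(s), `>= 1`.
#' @param config An [agent_config()].
#' @return Numeric vector of exploration probabilities in `[0, 1]`.
#' @examples
#' cfg <- agent_config("donor")
#' epsilon_at(c(10, 100, 500), cfg)  # 1, 0.02, 0.004
#' @export
epsilon_at <- function(round, config) {
  stopifnot(inherits(config, "sps_agent_config"))
  if (any(round < 1)) stop("round numbers start at 1", call. = FALSE)
  late <- switch(config$epsilon_decay,
                 "2/N" = pmin(1, 2 / round),
                 "constant" = rep(config$epsilon_constant, length(round)),
                 "zero" = rep(0, length(round)))
  ifelse(round <= config$explore_rounds, 1, late)
}

# joint action index in 1:6 from beneficiary (1:3) and donor (1:2) indices
joint_index <- function(b_idx, d_idx) (b_idx - 1L) * 2L + d_idx

# labels of the 6^m joint-action observation states, oldest round first
state_labels <- function(memory = 1L) {
  joint <- as.vector(t(outer(b_actions, d_actions, paste0)))  # NK NG WK WG SK SG
  labs <- joint
  if (memory > 1L) {
    for (i in seq_len(memory - 1L))
      labs <- as.vector(t(outer(labs, joint, paste, sep = ".")))
  }
  labs
}

#' Encode an action history as an observation state
#'
#' The observation state of both agents is the joint action (beneficiary,
#' donor) of each of the last `m` rounds; with `m = 1` there are exactly
#' six states `NK, NG, WK, WG, SK, SG`.
#'
#' @param b_history,d_history Character vectors of past beneficiary and
#'   donor actions, oldest first, of equal length `>= m`.
#' @param memory Memory length `m`.
#' @return The state label (character scalar); the full label set is the
#'   `6^m` combinations in fixed order.
#' @examples
#' encode_state("N", "G")            # "NG"
#' encode_state(c("N", "S"), c("G", "K"), memory = 2)  # "NG.SK"
#' @export
encode_state <- function(b_history, d_history, memory = 1L) {
  n <- length(b_history)
  stopifnot(length(d_history) == n)
  if (n < memory) stop("history shorter than the agent's memory", call. = FALSE)
  if (!all(b_history %in% b_actions) || !all(d_history %in% d_actions))
    stop("unknown action in history", call. = FALSE)
  keep <- (n - memory + 1L):n
  paste(paste0(b_history[keep], d_history[keep]), collapse = ".")
}

# integer state update: drop oldest joint digit, append the new one
shift_state <- function(state, joint_new, memory) {
  if (memory == 1L) return(joint_new)
  ((state - 1L) %% 6L^(memory - 1L)) * 6L + joint_new
}

#' Create a zeroed Q-table
#'
#' Rows are observation states, columns the agent's own actions; all
#' entries start at 0. With `observe_thirst` the beneficiary's state space
#' is doubled, the extra block being the thirsty replicate of each state.
#'
#' @param config An [agent_config()].
#' @return A numeric matrix with labelled dimnames.
#' @export
new_qtable <- function(config) {
  stopifnot(inherits(config, "sps_agent_config"))
  states <- state_labels(config$memory)
  if (config$observe_thirst)
    states <- c(states, paste0(states, "+T"))
  acts <- if (config$role == "beneficiary") b_actions else d_actions
  matrix(0, nrow = length(states), ncol = length(acts),
         dimnames = list(states, acts))
}

#' Write a Q-table as CSV
#'
#' @param qtable A Q-table matrix (states x actions).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qtable <- function(qtable, path) {
  utils::write.csv(data.frame(state = rownames(qtable), qtable,
                              check.names = FALSE, row.names = NULL),
                   path, row.names = FALSE)
  invisible(path)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` the agent explores uniformly over its action
#' set; otherwise it picks an action maximising the Q-value in the current
#' state, breaking exact ties uniformly at random. Draws come from the
#' R random number generator, so results are reproducible under
#' [set.seed()].
#'
#' @param qtable A Q-table matrix.
#' @param state State label (row name) or row index.
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return A list with `action` (column label), `index` and `explored`
#'   (logical flag marking an exploratory move).
#' @export
select_action <- function(qtable, state, epsilon) {
  if (is.character(state)) {
    state <- match(state, rownames(qtable))
    if (is.na(state)) stop("unknown state", call. = FALSE)
  }
  k <- ncol(qtable)
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    idx <- sample.int(k, 1L)
    explored <- TRUE
  } else {
    row <- qtable[state, ]
    cand <- which(row >= max(row))
    idx <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    explored <- FALSE
  }
  list(action = colnames(qtable)[idx], index = as.integer(idx), explored = explored)
}

#' One-step Q-learning update
#'
#' Applies
#' `Q(s, a) <- Q(s, a) + alpha * (R + gamma * max_a' Q(s', a') - Q(s, a))`,
#' evaluating the maximum over the next state's row on the pre-update
#' table. Only the `(s, a)` entry changes.
#'
#' @param qtable A Q-table matrix.
#' @param state,action Row and column of the entry to update (label or index).
#' @param reward One-round reward (here: the agent's inclusive fitness).
#' @param next_state The state the agent will act in next.
#' @param config An [agent_config()] providing `alpha` and `gamma`.
#' @return The updated Q-table.
#' @examples
#' cfg <- agent_config("donor", alpha = 0.9, gamma = 0.1)
#' q <- new_qtable(cfg)
#' q_update(q, "NK", "G", reward = 0.7, next_state = "NG", cfg)["NK", "G"] # 0.63
#' @export
q_update <- function(qtable, state, action, reward, next_state, config) {
  stopifnot(inherits(config, "sps_agent_config"), is.finite(reward))
  qtable[state, action] <- qtable[state, action] +
    config$alpha * (reward + config$gamma * max(qtable[next_state, ]) -
                      qtable[state, action])
  qtable
}

#' Static (non-learning) policy
#'
#' A fixed action or fixed repeating action sequence, usable in either
#' seat of a dyad in place of a learning agent.
#'
#' @param actions Character vector of actions cycled through in order.
#' @param role `"beneficiary"` or `"donor"`.
#' @return An object of class `"sps_static"`.
#' @examples
#' static_policy("W", "beneficiary")        # always signal weakly
#' static_policy(c("K", "K", "G"), "donor") # cycle keep, keep, give
#' @export
static_policy <- function(actions, role = c("beneficiary", "donor")) {
  role <- match.arg(role)
  valid <- if (role == "beneficiary") b_actions else d_actions
  if (!length(actions) || !all(actions %in% valid))
    stop("invalid action sequence for this role", call. = FALSE)
  structure(list(actions = actions, role = role), class = "sps_static")
}
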