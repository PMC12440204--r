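# Shared fixture builders. Everything is generated in code; the "cases"
# mirror the three canonical parameter sets of the replication presets.

case_games <- list(
  case1 = game_params(r = 0.5, U = 0.2, V = 0.2),
  case2 = game_params(r = 0.8, U = 0.9, V = 0.1),
  case3 = game_params(r = 0.9, U = 0.95, V = 0.75))

# a short, cheap experiment used by unit tests
tiny_config <- function(game = case_games$case1, rounds = 120L, n_runs = 5L,
                        base_seed = 101L, ...) {
  experiment_config(game, rounds = rounds, n_runs = n_runs,
                    base_seed = base_seed, ...)
}

# random valid game parameters, for property-style loops
random_game <- function() {
  cw <- runif(1, 0.05, 0.5)
  game_params(r = runif(1), U = runif(1, 0.01, 0.99), V = runif(1, 0.01, 0.99),
              p = runif(1), c_weak = cw, c_strong = runif(1, cw + 0.01, 1))
}

# maximum one-round absolute inclusive fitness attainable under a game
max_abs_reward <- function(game) {
  grid <- expand.grid(b = b_actions, d = d_actions, thirsty = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  pay <- individual_payoffs(grid$b, grid$d, grid$thirsty, game)
  fit <- inclusive_fitness(pay$P_B, pay$P_D, game$r)
  max(abs(c(fit$F_B, fit$F_D)))
}
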