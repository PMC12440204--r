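test_that("survival payoffs follow the game's rules, with multiplicative signal cost", {
  g <- game_params(r = 0.5, U = 0.2, V = 0.2)
  # thirsty and refused: beneficiary gets nothing, donor keeps full survival
  expect_equal(individual_payoffs("N", "K", TRUE, g), list(P_B = 0, P_D = 1))
  # given the resource: survival 1 regardless of state; donor drops to U
  expect_equal(individual_payoffs("N", "G", FALSE, g), list(P_B = 1, P_D = 0.2))
  expect_equal(individual_payoffs("N", "G", TRUE, g), list(P_B = 1, P_D = 0.2))
  # not thirsty, refused, weak signal: V scaled by (1 - c_weak)
  expect_equal(individual_payoffs("W", "K", FALSE, g),
               list(P_B = 0.2 * 0.75, P_D = 1))
  # strong signal costs more than weak
  expect_lt(individual_payoffs("S", "G", FALSE, g)$P_B,
            individual_payoffs("W", "G", FALSE, g)$P_B)
  expect_error(individual_payoffs("X", "K", TRUE, g), "action")
})

test_that("inclusive fitness couples payoffs through relatedness", {
  expect_equal(inclusive_fitness(1, 0.9, r = 0.8), list(F_B = 1.72, F_D = 1.7))
  g <- game_params(r = 0.8, U = 0.9, V = 0.1)
  pay <- individual_payoffs("N", "G", FALSE, g)
  fit <- inclusive_fitness(pay$P_B, pay$P_D, g$r)
  expect_equal(fit$F_B, 1 + g$r * g$U)
  expect_equal(fit$F_D, g$U + g$r)
  # zero relatedness: inclusive fitness reduces to individual payoff
  expect_equal(inclusive_fitness(0.3, 0.7, r = 0), list(F_B = 0.3, F_D = 0.7))
})

test_that("fitness matrix reproduces the symbolic one-shot cells for random parameters", {
  set.seed(7)
  ok <- vapply(1:1000, function(i) {
    g <- random_game()
    c <- g$c_weak
    thirsty <- fitness_matrix(g, thirsty = TRUE, cost = c)
    sated <- fitness_matrix(g, thirsty = FALSE, cost = c)
    near <- function(a, b) abs(a - b) < 1e-12
    all(
      near(thirsty$F_B["Signal", "Keep"], g$r),
      near(thirsty$F_D["Signal", "Keep"], 1),
      near(thirsty$F_B["Signal", "Give"], 1 - c + g$r * g$U),
      near(thirsty$F_D["Signal", "Give"], g$U + g$r * (1 - c)),
      near(thirsty$F_B["Not signal", "Keep"], g$r),
      near(thirsty$F_D["Not signal", "Keep"], 1),
      near(thirsty$F_B["Not signal", "Give"], 1 + g$r * g$U),
      near(thirsty$F_D["Not signal", "Give"], g$U + g$r),
      near(sated$F_B["Signal", "Keep"], g$r + g$V * (1 - c)),
      near(sated$F_D["Signal", "Keep"], 1 + g$r * g$V * (1 - c)),
      near(sated$F_B["Not signal", "Keep"], g$r + g$V),
      near(sated$F_D["Not signal", "Keep"], 1 + g$r * g$V),
      # give cells do not depend on the thirst state
      sated$F_B[, "Give"] == thirsty$F_B[, "Give"],
      sated$F_D[, "Give"] == thirsty$F_D[, "Give"])
  }, logical(1))
  expect_true(all(ok))
})

test_that("zero signal cost removes the signalling penalty", {
  g <- game_params(r = 0.6, U = 0.4, V = 0.3)
  for (th in c(TRUE, FALSE)) {
    fm <- fitness_matrix(g, thirsty = th, cost = 0)
    expect_equal(fm$F_B["Signal", ], fm$F_B["Not signal", ])
    expect_equal(fm$F_D["Signal", ], fm$F_D["Not signal", ])
  }
})

test_that("the beneficiary never gains by signalling: F_B(N) >= F_B(W) >= F_B(S)", {
  set.seed(11)
  ok <- vapply(1:300, function(i) {
    g <- random_game()
    all(vapply(d_actions, function(d) all(vapply(c(TRUE, FALSE), function(th) {
      pay <- individual_payoffs(c("N", "W", "S"), d, th, g)
      f <- inclusive_fitness(pay$P_B, pay$P_D, g$r)$F_B
      s_B <- if (d == "G") 1 else if (th) 0 else g$V
      weak <- f[1] >= f[2] && f[2] >= f[3]
      strict <- s_B == 0 || (f[1] > f[2] && f[2] > f[3])
      weak && strict
    }, logical(1))), logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("giving threshold agrees with brute-force expected-fitness comparison", {
  # oracle: against a never-signalling beneficiary, giving yields U + r and
  # keeping yields 1 + r * (1 - p) * V in expectation over the thirst state
  grid <- expand.grid(r = seq(0.05, 1, by = 0.05),
                      U = seq(0.05, 0.95, by = 0.1),
                      V = seq(0.05, 0.95, by = 0.1),
                      p = c(0, 0.25, 0.5, 0.75, 1))
  ok <- vapply(seq_len(nrow(grid)), function(i) {
    g <- game_params(r = grid$r[i], U = grid$U[i], V = grid$V[i], p = grid$p[i])
    pay_g <- individual_payoffs("N", "G", FALSE, g)
    give <- inclusive_fitness(pay_g$P_B, pay_g$P_D, g$r)$F_D
    keep_t <- inclusive_fitness(0, 1, g$r)$F_D
    keep_n <- inclusive_fitness(g$V, 1, g$r)$F_D
    keep <- g$p * keep_t + (1 - g$p) * keep_n
    ts <- threshold_satisfied(g)
    # margin * (1 - V + pV) is algebraically the fitness difference;
    # knife-edge grid points (difference ~ 0) are boundary ties
    if (abs(give - keep) < 1e-12) TRUE
    else identical(ts$satisfied, give > keep) &&
      abs(ts$margin * (1 - g$V + g$p * g$V) - (give - keep)) < 1e-9
  }, logical(1))
  expect_true(all(ok))
})

test_that("at p = 1 the threshold reduces to r > 1 - U", {
  for (U in c(0.1, 0.5, 0.9)) {
    g <- game_params(r = 0.5, U = U, V = 0.3, p = 1)
    expect_equal(threshold_satisfied(g)$threshold, 1 - U)
    expect_equal(threshold_satisfied(g)$margin, g$r - (1 - U))
  }
  # U -> 1 limit: the threshold vanishes, any positive r satisfies it
  g <- game_params(r = 0.01, U = 1 - 1e-9, V = 0.5, p = 0.5)
  expect_true(threshold_satisfied(g)$satisfied)
  expect_equal(threshold_satisfied(g)$margin, g$r, tolerance = 1e-6)
})

test_that("predicted equilibrium matches the canonical parameter cases", {
  expect_equal(unname(predicted_equilibrium(case_games$case1)), c("N", "K"))
  expect_equal(unname(predicted_equilibrium(case_games$case2)), c("N", "G"))
  expect_equal(unname(predicted_equilibrium(case_games$case3)), c("N", "G"))
  expect_false(threshold_satisfied(case_games$case1)$satisfied)
  expect_true(threshold_satisfied(case_games$case2)$satisfied)
  expect_true(threshold_satisfied(case_games$case3)$satisfied)
})

test_that("game parameter invariants are enforced", {
  expect_error(game_params(r = 0.5, U = 1.2, V = 0.2), "U")
  expect_error(game_params(r = 1.5, U = 0.5, V = 0.2), "r")
  expect_error(game_params(r = 0.5, U = 0.5, V = 0), "V")
  expect_error(game_params(r = 0.5, U = 0.5, V = 0.2, c_weak = 0.8), "cost")
  expect_silent(game_params(r = 0, U = 0.5, V = 0.5, p = 1))
})

test_that("fitness matrices export as labelled tables", {
  fm <- fitness_matrix(case_games$case1, thirsty = FALSE)
  df <- as.data.frame(fm)
  expect_setequal(df$b_action, c("Signal", "Not signal"))
  expect_setequal(df$d_action, c("Keep", "Give"))
  path <- tempfile(fileext = ".csv")
  write_fitness_matrix(fm, path)
  back <- read.csv(path)
  expect_equal(back$F_D, df$F_D)
  unlink(path)
})
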