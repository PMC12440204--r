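# Core of the Sir Philip Sidney game: survival payoffs, signal costs,
# inclusive fitness, and the analytic threshold for the donor's equilibrium.

#' Beneficiary and donor action sets
#'
#' The beneficiary (signaller) chooses among `"N"` (not signal), `"W"`
#' (weak signal, cost `c_weak`) and `"S"` (strong signal, cost `c_strong`).
#' The donor (receiver) chooses between `"K"` (keep the resource) and
#' `"G"` (give it away).
#'
#' @format Character vectors of action codes, in the fixed order used for
#'   state encoding and pattern canonicalisation (`N < W < S`, `K < G`).
#' @export
b_actions <- c("N", "W", "S")

#' @rdname b_actions
#' @export
d_actions <- c("K", "G")

#' Game parameters for the Sir Philip Sidney game
#'
#' Bundles the biological constants of the game: the probability `p` that
#' the beneficiary is in need (thirsty), the donor's survival `U` after
#' giving the resource away, the not-thirsty beneficiary's survival `V`
#' without the resource, the relatedness coefficient `r` coupling the two
#' players' payoffs, and the two discrete signal costs.
#'
#' @param r Relatedness coefficient, in `[0, 1]`.
#' @param U Donor survival after giving, in `(0, 1)`.
#' @param V Survival of a not-thirsty beneficiary without the resource,
#'   in `(0, 1)`.
#' @param p Probability that the beneficiary is thirsty, in `[0, 1]`.
#'   Defaults to 0 (the not-thirsty state used by the replication presets).
#' @param c_weak Cost of a weak signal, default 0.25.
#' @param c_strong Cost of a strong signal, default 0.75. Costs must
#'   satisfy `0 < c_weak < c_strong <= 1`.
#'
#' @return An object of class `"sps_game"`: a validated list with the
#'   fields above plus `costs`, the per-action cost lookup
#'   `c(N = 0, W = c_weak, S = c_strong)`.
#' @examples
#' game_params(r = 0.8, U = 0.9, V = 0.1)
#' @export
game_params <- function(r, U, V, p = 0, c_weak = 0.25, c_strong = 0.75) {
  problems <- character(0)
  note <- function(bad, msg) if (bad) problems <<- c(problems, msg)
  vals <- list(r = r, U = U, V = V, p = p, c_weak = c_weak, c_strong = c_strong)
  for (nm in names(vals))
    note(!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L || !is.finite(vals[[nm]]),
         sprintf("%s must be a finite numeric scalar", nm))
  if (!length(problems)) {
    note(U <= 0 || U >= 1, "U must satisfy 0 < U < 1")
    note(V <= 0 || V >= 1, "V must satisfy 0 < V < 1")
    note(r < 0 || r > 1, "r must lie in [0, 1]")
    note(p < 0 || p > 1, "p must lie in [0, 1]")
    note(c_weak <= 0 || c_strong <= c_weak || c_strong > 1,
         "signal costs must satisfy 0 < c_weak < c_strong <= 1")
  }
  if (length(problems)) stop(paste(problems, collapse = "; "), call. = FALSE)
  structure(
    list(r = r, U = U, V = V, p = p, c_weak = c_weak, c_strong = c_strong,
         costs = c(N = 0, W = c_weak, S = c_strong)),
    class = "sps_game")
}

#' @export
print.sps_game <- function(x, ...) {
  cat(sprintf(
    "Sir Philip Sidney game: r = %g, U = %g, V = %g, p = %g, costs (W, S) = (%g, %g)\n",
    x$r, x$U, x$V, x$p, x$c_weak, x$c_strong))
  ts <- threshold_satisfied(x)
  cat(sprintf("Donor threshold r > %.4g: %s (margin %+.4g); predicted equilibrium {%s}\n",
              ts$threshold, if (ts$satisfied) "satisfied" else "not satisfied",
              ts$margin, paste(predicted_equilibrium(x), collapse = ",")))
  invisible(x)
}

#' Individual survival payoffs for one round
#'
#' The donor survives with probability 1 when keeping and `U` when giving.
#' The beneficiary's base survival is 1 when given the resource (whatever
#' its state), 0 when thirsty and refused, and `V` when not thirsty and
#' refused; the signal cost is applied multiplicatively, so the realised
#' payoff is `s_B * (1 - c)` for base survival `s_B` and cost `c` of the
#' chosen signal.
#'
#' @param b_action Beneficiary action, `"N"`, `"W"` or `"S"` (vectorised).
#' @param d_action Donor action, `"K"` or `"G"` (vectorised).
#' @param thirsty Logical; is the beneficiary thirsty this round?
#' @param params A [game_params()] object.
#' @return A list with numeric components `P_B` and `P_D`.
#' @examples
#' g <- game_params(r = 0.5, U = 0.2, V = 0.2)
#' individual_payoffs("N", "K", thirsty = TRUE, g)   # (0, 1)
#' individual_payoffs("W", "K", thirsty = FALSE, g)  # (V * (1 - c_weak), 1)
#' @export
individual_payoffs <- function(b_action, d_action, thirsty, params) {
  stopifnot(inherits(params, "sps_game"))
  if (!all(b_action %in% b_actions)) stop("unknown beneficiary action")
  if (!all(d_action %in% d_actions)) stop("unknown donor action")
  give <- d_action == "G"
  P_D <- ifelse(give, params$U, 1)
  s_B <- ifelse(give, 1, ifelse(thirsty, 0, params$V))
  P_B <- s_B * (1 - params$costs[b_action])
  list(P_B = unname(P_B), P_D = unname(P_D))
}

#' Inclusive fitness of both players
#'
#' Each player's inclusive fitness is its own survival payoff plus the
#' partner's payoff weighted by the relatedness coefficient:
#' `F_B = P_B + r * P_D` and `F_D = P_D + r * P_B`.
#'
#' @param P_B,P_D Individual payoffs (vectorised).
#' @param r Relatedness coefficient in `[0, 1]`.
#' @return A list with numeric components `F_B` and `F_D`.
#' @examples
#' inclusive_fitness(1, 0.9, r = 0.8)  # (1.72, 1.7)
#' @export
inclusive_fitness <- function(P_B, P_D, r) {
  stopifnot(is.numeric(r), r >= 0, r <= 1)
  list(F_B = P_B + r * P_D, F_D = P_D + r * P_B)
}

#' Inclusive-fitness matrix of the one-shot game
#'
#' Tabulates both players' inclusive fitness over the two-by-two game
#' between a signalling beneficiary (at a single cost `cost`) or a
#' non-signalling one, and a keeping or giving donor, conditional on the
#' beneficiary's state.
#'
#' @param params A [game_params()] object.
#' @param thirsty Logical; the beneficiary's state the matrix conditions on.
#' @param cost Signal cost used for the `Signal` row; defaults to `c_weak`.
#' @return An object of class `"sps_fitness_matrix"`: a list of two 2 x 2
#'   numeric matrices `F_B` and `F_D` with rows `Signal`, `Not signal` and
#'   columns `Keep`, `Give`.
#' @examples
#' fitness_matrix(game_params(r = 0.5, U = 0.2, V = 0.2), thirsty = TRUE)
#' @export
fitness_matrix <- function(params, thirsty, cost = params$c_weak) {
  stopifnot(inherits(params, "sps_game"), is.logical(thirsty), length(thirsty) == 1L)
  b <- c("W", "N")  # a single generic signal row, then the no-signal row
  grid <- expand.grid(b = b, d = c("K", "G"), stringsAsFactors = FALSE)
  pars <- params
  pars$costs[["W"]] <- cost
  pay <- individual_payoffs(grid$b, grid$d, thirsty, pars)
  fit <- inclusive_fitness(pay$P_B, pay$P_D, params$r)
  dn <- list(c("Signal", "Not signal"), c("Keep", "Give"))
  structure(
    list(F_B = matrix(fit$F_B, 2, 2, dimnames = dn),
         F_D = matrix(fit$F_D, 2, 2, dimnames = dn),
         params = params, thirsty = thirsty, cost = cost),
    class = "sps_fitness_matrix")
}

#' @export
print.sps_fitness_matrix <- function(x, ...) {
  cat(sprintf("Inclusive fitness (F_B, F_D), %s beneficiary, signal cost c = %g\n",
              if (x$thirsty) "thirsty" else "not-thirsty", x$cost))
  cells <- matrix(sprintf("%.4g, %.4g", x$F_B, x$F_D), 2, 2, dimnames = dimnames(x$F_B))
  print(cells, quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.sps_fitness_matrix <- function(x, ...) {
  grid <- expand.grid(b_action = rownames(x$F_B), d_action = colnames(x$F_B),
                      stringsAsFactors = FALSE)
  data.frame(grid, F_B = as.vector(x$F_B), F_D = as.vector(x$F_D))
}

#' Write a fitness matrix as labelled CSV
#'
#' @param x An [fitness_matrix()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fitness_matrix <- function(x, path) {
  stopifnot(inherits(x, "sps_fitness_matrix"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Donor giving threshold
#'
#' Given a beneficiary that never signals, the donor's expected inclusive
#' fitness favours giving exactly when `r > (1 - U) / (1 - V + p * V)`:
#' giving yields `U + r` while keeping yields `1 + r * (1 - p) * V`.
#'
#' @param params A [game_params()] object.
#' @return A list with `satisfied` (logical), `margin`
#'   (`r - threshold`; positive when satisfied) and `threshold`.
#' @examples
#' threshold_satisfied(game_params(r = 0.5, U = 0.2, V = 0.2))$satisfied  # FALSE
#' threshold_satisfied(game_params(r = 0.8, U = 0.9, V = 0.1))$satisfied  # TRUE
#' @export
threshold_satisfied <- function(params) {
  stopifnot(inherits(params, "sps_game"))
  threshold <- (1 - params$U) / (1 - params$V + params$p * params$V)
  margin <- params$r - threshold
  list(satisfied = margin > 0, margin = margin, threshold = threshold)
}

#' Predicted equilibrium strategy pair
#'
#' The beneficiary never has an incentive to pay a positive signal cost,
#' so its equilibrium component is always `"N"`; the donor gives exactly
#' when the relatedness threshold is satisfied.
#'
#' @param params A [game_params()] object.
#' @return A named character vector
#'   `c(beneficiary = "N", donor = "G" or "K")`.
#' @examples
#' predicted_equilibrium(game_params(r = 0.9, U = 0.95, V = 0.75))  # {N,G}
#' @export
predicted_equilibrium <- function(params) {
  donor <- if (threshold_satisfied(params)$satisfied) "G" else "K"
  c(beneficiary = "N", donor = donor)
}
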