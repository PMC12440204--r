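# Strategy taxonomy: classify a run's learned behaviour into the cyclic
# pattern catalogue and summarise converged Q-values across runs.

B_CATALOGUE <- c("N" = "NN", "W" = "WW", "S" = "SS",
                 "NW" = "NW", "NS" = "NS", "WS" = "WS",
                 "NWS" = "NWS", "NSW" = "NSW")
D_CATALOGUE <- c("K" = "KK", "G" = "GG", "KG" = "GK", "KKG" = "KKG")

#' All strategy labels of a role's taxonomy
#'
#' @param role `"beneficiary"` or `"donor"`.
#' @return Character vector of labels, ending with `"OTHER"`.
#' @export
strategy_labels <- function(role = c("beneficiary", "donor")) {
  role <- match.arg(role)
  unname(c(if (role == "beneficiary") B_CATALOGUE else D_CATALOGUE, "OTHER"))
}

# canonical rotation: lexicographically minimal under the fixed action
# order N < W < S (beneficiary) / K < G (donor)
canonical_rotation <- function(pattern) {
  k <- length(pattern)
  if (k <= 1L) return(pattern)
  ord <- match(pattern, c("N", "W", "S", "K", "G"))
  rots <- vapply(seq_len(k), function(i) {
    idx <- c(i:k, seq_len(i - 1L))
    paste(sprintf("%02d", ord[idx]), collapse = "")
  }, "")
  best <- order(rots)[1]
  pattern[c(best:k, seq_len(best - 1L))]
}

#' Extract the minimal repeating pattern from an action sequence
#'
#' Looks at the final `window` rounds and searches for the smallest
#' period `k <= max_period` with which the sequence is exactly periodic.
#' Moves flagged as exploratory are masked: they match any action and do
#' not count as evidence, so a rare exploratory move neither breaks a
#' cycle nor shifts its phase. The period is returned in canonical
#' rotation (starting from the action earliest in the fixed order
#' `N < W < S` / `K < G`); aperiodic sequences yield `"OTHER"`.
#'
#' @param actions Character vector of one agent's per-round actions.
#' @param explored Logical vector of exploration flags (same length);
#'   `NULL` means no move was exploratory.
#' @param window Number of final rounds examined; default 50.
#' @param max_period Longest period searched; default 3, the length of
#'   the longest catalogued cycles.
#' @return Character vector: the canonical period, or the scalar `"OTHER"`.
#' @examples
#' extract_pattern(rep(c("G", "K"), 25))            # c("K", "G")
#' extract_pattern(rep(c("K", "K", "G"), 17))       # c("K", "K", "G")
#' @export
extract_pattern <- function(actions, explored = NULL, window = 50L,
                            max_period = 3L) {
  n <- length(actions)
  stopifnot(window >= 1)
  window <- min(window, n)
  keep <- (n - window + 1L):n
  x <- actions[keep]
  known <- if (is.null(explored)) rep(TRUE, window) else !explored[keep]
  if (!any(known))
    stop("no non-exploratory rounds in the classification window", call. = FALSE)
  for (k in seq_len(max_period)) {
    # each residue class mod k must be constant on its unmasked entries
    period <- character(k)
    ok <- TRUE
    for (j in seq_len(k)) {
      vals <- unique(x[known & (seq_len(window) - 1L) %% k == (j - 1L)])
      if (length(vals) > 1L) { ok <- FALSE; break }
      period[j] <- if (length(vals)) vals else NA_character_
    }
    if (ok && !anyNA(period))
      return(canonical_rotation(period[seq_len(min(k, window))]))
  }
  "OTHER"
}

#' Map a periodic pattern to its strategy label
#'
#' Patterns are looked up in the role's catalogue (`NN`, `NW`, `WW`, `NS`,
#' `WS`, `NWS`, `NSW`, `SS` for the beneficiary; `KK`, `GK`, `GG`, `KKG`
#' for the donor); cyclic order distinguishes `NWS` from `NSW`. Anything
#' not catalogued is `"OTHER"`.
#'
#' @param pattern A pattern from [extract_pattern()].
#' @param role `"beneficiary"` or `"donor"`.
#' @return A strategy label (character scalar).
#' @examples
#' label_strategy(c("K", "G"), "donor")       # "GK"
#' label_strategy(c("N", "S", "W"), "beneficiary")  # "NSW"
#' @export
label_strategy <- function(pattern, role = c("beneficiary", "donor")) {
  role <- match.arg(role)
  if (length(pattern) == 1L && pattern == "OTHER") return("OTHER")
  key <- paste(canonical_rotation(pattern), collapse = "")
  cat <- if (role == "beneficiary") B_CATALOGUE else D_CATALOGUE
  if (key %in% names(cat)) unname(cat[[key]]) else "OTHER"
}

# deterministic greedy rollout of the learned policies; returns the two
# agents' action sequences well inside the joint-policy cycle
policy_rollout <- function(record, steps_tail = 24L) {
  cfg <- record$config
  mem <- record$memory
  n_states <- 6L^mem
  labels <- state_labels(mem)
  state <- match(record$final_state, labels)
  b_static <- is.null(record$q_b); d_static <- is.null(record$q_d)
  thirsty <- cfg$thirst == "fixed1"
  b_thirst <- !b_static && isTRUE(cfg$beneficiary$observe_thirst)
  b_seq <- if (b_static) match(cfg$beneficiary$actions, b_actions)
  d_seq <- if (d_static) match(cfg$donor$actions, d_actions)
  n_steps <- n_states * (if (b_static) length(b_seq) else 1L) *
    (if (d_static) length(d_seq) else 1L) + steps_tail
  ab <- integer(n_steps); ad <- integer(n_steps)
  t0 <- cfg$rounds
  for (i in seq_len(n_steps)) {
    bi <- if (b_static) b_seq[((t0 + i - 1L) %% length(b_seq)) + 1L] else
      which.max(record$q_b[if (b_thirst && thirsty) state + n_states else state, ])
    di <- if (d_static) d_seq[((t0 + i - 1L) %% length(d_seq)) + 1L] else
      which.max(record$q_d[state, ])
    ab[i] <- bi; ad[i] <- di
    state <- shift_state(state, joint_index(bi, di), mem)
  }
  tail_idx <- (n_steps - steps_tail + 1L):n_steps
  list(b = b_actions[ab[tail_idx]], d = d_actions[ad[tail_idx]])
}

#' Classify a dyad's learned strategies
#'
#' Two readouts are available. `"policy"` (the default) rolls the two
#' learned greedy policies forward deterministically from the final
#' observation state and classifies the resulting joint-action cycle:
#' this reads off the strategy the agents have converged to, unperturbed
#' by residual exploration. `"realized"` instead classifies the actions
#' actually played in the final `window` rounds after removing moves
#' flagged exploratory.
#'
#' @param record An [run_dyad()] record.
#' @param method `"policy"` or `"realized"`.
#' @param window Classification window for the realized readout.
#' @return Named character vector `c(beneficiary = , donor = )`.
#' @export
classify <- function(record, method = c("policy", "realized"), window = 50L) {
  stopifnot(inherits(record, "sps_dyad"))
  method <- match.arg(method)
  if (method == "policy") {
    cyc <- policy_rollout(record)
    b_pat <- extract_pattern(cyc$b, window = length(cyc$b))
    d_pat <- extract_pattern(cyc$d, window = length(cyc$d))
  } else {
    b_pat <- extract_pattern(record$b_action, record$explored_b, window)
    d_pat <- extract_pattern(record$d_action, record$explored_d, window)
  }
  c(beneficiary = label_strategy(b_pat, "beneficiary"),
    donor = label_strategy(d_pat, "donor"))
}

#' Strategy-label distribution over runs
#'
#' @param x An `sps_experiment`, a labels data frame with `beneficiary`
#'   and `donor` columns, or a list of [run_dyad()] records (classified
#'   with the default readout).
#' @return A data frame with columns `role`, `label`, `count`,
#'   `proportion`; proportions sum to 1 within each role.
#' @export
strategy_proportions <- function(x) {
  if (inherits(x, "sps_experiment")) x <- x$labels
  if (is.list(x) && !is.data.frame(x) && length(x) &&
      inherits(x[[1]], "sps_dyad")) {
    cl <- vapply(x, classify, character(2))
    x <- data.frame(beneficiary = cl["beneficiary", ], donor = cl["donor", ],
                    stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), nrow(x) > 0)
  out <- do.call(rbind, lapply(c("beneficiary", "donor"), function(role) {
    tab <- table(factor(x[[role]], levels = strategy_labels(role)))
    data.frame(role = role, label = names(tab), count = as.integer(tab),
               proportion = as.numeric(tab) / nrow(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Modal strategy of a role
#'
#' @param proportions A [strategy_proportions()] data frame or an
#'   `sps_experiment`.
#' @param role `"beneficiary"` or `"donor"`.
#' @return List with `label` and `proportion` of the single modal label.
#' @export
top_strategy <- function(proportions, role = c("beneficiary", "donor")) {
  role <- match.arg(role)
  if (inherits(proportions, "sps_experiment")) proportions <- proportions$proportions
  pr <- proportions[proportions$role == role, ]
  top <- pr[which.max(pr$proportion), ]
  list(label = top$label, proportion = top$proportion)
}

#' Converged Q-value summary
#'
#' Averages each (state, action) Q-value over runs (each run contributing
#' its mean over the final `q_window` rounds), takes the unweighted grand
#' mean across states for every action, and, for the donor, reports the
#' gap `grand mean Q(G) - grand mean Q(K)`.
#'
#' @param x An `sps_experiment` or a list of [run_dyad()] records.
#' @param role `"beneficiary"` or `"donor"`.
#' @return An object of class `"sps_qsummary"`: `per_state` (states x
#'   actions matrix), `grand_mean` (named per-action vector) and `gap`
#'   (donor only, `NA` otherwise).
#' @export
q_summary <- function(x, role = c("donor", "beneficiary")) {
  role <- match.arg(role)
  slot <- if (role == "donor") "q_d_window" else "q_b_window"
  if (inherits(x, "sps_experiment")) {
    per_state <- if (role == "donor") x$q_mean_d else x$q_mean_b
  } else {
    stopifnot(is.list(x), length(x) > 0, inherits(x[[1]], "sps_dyad"))
    mats <- lapply(x, `[[`, slot)
    if (any(vapply(mats, is.null, TRUE)))
      stop("Q snapshots missing (static agent in this seat?)", call. = FALSE)
    per_state <- Reduce(`+`, mats) / length(mats)
  }
  if (is.null(per_state)) stop("no Q-values recorded for this role", call. = FALSE)
  grand <- colMeans(per_state)
  gap <- if (role == "donor") unname(grand["G"] - grand["K"]) else NA_real_
  structure(list(per_state = per_state, grand_mean = grand, gap = gap,
                 role = role),
            class = "sps_qsummary")
}

#' @export
print.sps_qsummary <- function(x, ...) {
  cat(sprintf("Converged Q-values (%s), grand means: %s\n", x$role,
              paste(sprintf("%s = %.3f", names(x$grand_mean), x$grand_mean),
                    collapse = ", ")))
  if (!is.na(x$gap)) cat(sprintf("  gap Q(G) - Q(K) = %.3f\n", x$gap))
  print(round(x$per_state, 3))
  invisible(x)
}

#' Learning-rate / discount-rate sweep
#'
#' Re-runs an experiment on a grid of learning and discount rates (shared
#' by both agents) and tabulates each role's strategy distribution per
#' combination, highlighting the proportion of the donor strategy
#' predicted by the relatedness threshold.
#'
#' @param config An [experiment_config()]; its agents' `alpha` and
#'   `gamma` are overridden on the grid.
#' @param alphas,gammas Grid values; defaults `{0.1, 0.5, 0.9}` and
#'   `{0.1, 0.9}`.
#' @param method Strategy readout passed to [run_experiment()].
#' @param progress Print one line per grid cell.
#' @return An object of class `"sps_sweep"`: `table` (columns `lr`, `dr`,
#'   `role`, `label`, `proportion`), `target` (the donor label predicted
#'   by the threshold), `floor` / `floor_at` (minimum target proportion
#'   and the combination attaining it), `peak` / `peak_at`.
#' @export
sweep_table <- function(config, alphas = c(0.1, 0.5, 0.9),
                        gammas = c(0.1, 0.9),
                        method = c("policy", "realized"),
                        progress = FALSE) {
  stopifnot(inherits(config, "sps_config"))
  method <- match.arg(method)
  target <- if (predicted_equilibrium(config$game)[["donor"]] == "K") "KK" else "GG"
  grid <- expand.grid(lr = alphas, dr = gammas)
  rows <- vector("list", nrow(grid))
  tprop <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$beneficiary$alpha <- grid$lr[i]; cfg$beneficiary$gamma <- grid$dr[i]
    cfg$donor$alpha <- grid$lr[i]; cfg$donor$gamma <- grid$dr[i]
    ex <- run_experiment(cfg, method = method)
    pr <- ex$proportions
    rows[[i]] <- data.frame(lr = grid$lr[i], dr = grid$dr[i], pr,
                            stringsAsFactors = FALSE)
    hit <- pr$role == "donor" & pr$label == target
    tprop[i] <- if (any(hit)) pr$proportion[hit] else 0
    if (progress)
      message(sprintf("LR = %.1f, DR = %.1f: donor %s = %.3f",
                      grid$lr[i], grid$dr[i], target, tprop[i]))
  }
  i_min <- which.min(tprop); i_max <- which.max(tprop)
  structure(
    list(table = do.call(rbind, rows), target = target,
         floor = tprop[i_min], floor_at = c(lr = grid$lr[i_min], dr = grid$dr[i_min]),
         peak = tprop[i_max], peak_at = c(lr = grid$lr[i_max], dr = grid$dr[i_max])),
    class = "sps_sweep")
}

#' @export
print.sps_sweep <- function(x, ...) {
  cat(sprintf("LR x DR sweep; donor target strategy %s\n", x$target))
  cat(sprintf("  floor: %.1f%% at (LR = %.1f, DR = %.1f); peak: %.1f%% at (LR = %.1f, DR = %.1f)\n",
              100 * x$floor, x$floor_at[["lr"]], x$floor_at[["dr"]],
              100 * x$peak, x$peak_at[["lr"]], x$peak_at[["dr"]]))
  invisible(x)
}
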