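# Replication presets, config-file validation and result export.

PRESET_GAMES <- list(
  case1 = c(r = 0.5, V = 0.2, U = 0.2),   # threshold not satisfied -> {N,K}
  case2 = c(r = 0.8, V = 0.1, U = 0.9),   # satisfied, wide margin   -> {N,G}
  case3 = c(r = 0.9, V = 0.75, U = 0.95)) # satisfied, near the limit -> {N,G}

#' Replication presets
#'
#' Builds an [experiment_config()] bound to one of the study conditions:
#' `case1` (r = 0.5, V = 0.2, U = 0.2; giving threshold not satisfied),
#' `case2` (r = 0.8, V = 0.1, U = 0.9; satisfied with a wide margin),
#' `case3` (r = 0.9, V = 0.75, U = 0.95; satisfied but close to the
#' limit), plus configuration variants: `static_opponent` (case 1 with a
#' permanently weak-signalling beneficiary), `memory_m` (case 1 with
#' two-round memory) and `exploration_variant` (case 1 with a 100-round
#' exploratory phase). Defaults: learning rate 0.9, discount rate 0.1,
#' 500 rounds, 1000 runs, 50 exploratory rounds, not-thirsty state.
#'
#' @param name Preset name.
#' @param lr,dr Learning and discount rates shared by both agents.
#' @param rounds,n_runs,base_seed Passed to [experiment_config()].
#' @param p Thirst probability (0 or 1 fix the state; otherwise sampled).
#' @param memory Memory length for `memory_m`; default 2.
#' @return An `sps_config`.
#' @examples
#' replication_preset("case2", n_runs = 10, rounds = 200)
#' @export
replication_preset <- function(name = c("case1", "case2", "case3",
                                        "static_opponent", "memory_m",
                                        "exploration_variant"),
                               lr = 0.9, dr = 0.1,
                               rounds = 500L, n_runs = 1000L, base_seed = 1L,
                               p = 0, memory = 2L) {
  name <- match.arg(name)
  base_case <- if (name %in% names(PRESET_GAMES)) name else "case1"
  g <- PRESET_GAMES[[base_case]]
  game <- game_params(r = g[["r"]], U = g[["U"]], V = g[["V"]], p = p)
  mk <- function(role, explore = 50L, mem = 1L)
    agent_config(role, alpha = lr, gamma = dr, explore_rounds = explore,
                 memory = mem)
  beneficiary <- mk("beneficiary"); donor <- mk("donor")
  if (name == "static_opponent")
    beneficiary <- static_policy("W", "beneficiary")
  if (name == "memory_m") {
    beneficiary <- mk("beneficiary", mem = memory)
    donor <- mk("donor", mem = memory)
  }
  if (name == "exploration_variant") {
    beneficiary <- mk("beneficiary", explore = 100L)
    donor <- mk("donor", explore = 100L)
  }
  experiment_config(game, beneficiary = beneficiary, donor = donor,
                    rounds = rounds, n_runs = n_runs, base_seed = base_seed)
}

#' Run a replication preset and export results
#'
#' Runs the preset for both the not-thirsty (p = 0) and thirsty (p = 1)
#' beneficiary state by default, prints the analytic threshold verdict
#' and the top learned strategies, and optionally writes `runs.csv`,
#' `proportions.csv`, `qsummary.csv` and `summary.json` into `out_dir`
#' (suffixed `_p0` / `_p1`).
#'
#' @param name Preset name, see [replication_preset()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   file export.
#' @param p Thirst settings to run; default `c(0, 1)`.
#' @param method Strategy readout, see [classify()].
#' @param quiet Suppress console summary.
#' @param ... Passed to [replication_preset()] (`lr`, `dr`, `rounds`,
#'   `n_runs`, `base_seed`, `memory`).
#' @return Invisibly, a named list of `sps_experiment` objects (one per
#'   `p` setting), or the `sps_sweep` for the `"sweep"` preset.
#' @export
run_preset <- function(name, out_dir = NULL, p = c(0, 1),
                       method = c("policy", "realized"), quiet = FALSE, ...) {
  method <- match.arg(method)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (identical(name, "sweep")) {
    cfg <- replication_preset("case1", p = p[1], ...)
    sw <- sweep_table(cfg, method = method, progress = !quiet)
    if (!quiet) print(sw)
    if (!is.null(out_dir))
      utils::write.csv(sw$table, file.path(out_dir, "sweep.csv"), row.names = FALSE)
    return(invisible(sw))
  }
  out <- list()
  for (pv in p) {
    cfg <- replication_preset(name, p = pv, ...)
    ex <- run_experiment(cfg, method = method)
    tag <- sprintf("p%g", pv)
    out[[tag]] <- ex
    if (!quiet) {
      ts <- threshold_satisfied(cfg$game)
      cat(sprintf("\n== %s (p = %g) ==\n", name, pv))
      cat(sprintf("threshold r > %.4g %s (margin %+.3f); predicted equilibrium {%s}\n",
                  ts$threshold, if (ts$satisfied) "satisfied" else "not satisfied",
                  ts$margin, paste(predicted_equilibrium(cfg$game), collapse = ",")))
      for (role in c("beneficiary", "donor")) {
        top <- top_strategy(ex, role)
        cat(sprintf("  %s top strategy: %s (%.1f%% of %d runs)\n",
                    role, top$label, 100 * top$proportion, cfg$n_runs))
      }
    }
    if (!is.null(out_dir)) export_experiment(ex, out_dir, suffix = paste0("_", tag))
  }
  invisible(out)
}

#' Write an experiment's result bundle
#'
#' @param ex An `sps_experiment`.
#' @param out_dir Output directory.
#' @param suffix Appended to each file stem.
#' @return Invisibly, the paths written.
#' @export
export_experiment <- function(ex, out_dir, suffix = "") {
  stopifnot(inherits(ex, "sps_experiment"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    runs = file.path(out_dir, paste0("runs", suffix, ".csv")),
    proportions = file.path(out_dir, paste0("proportions", suffix, ".csv")),
    qsummary = file.path(out_dir, paste0("qsummary", suffix, ".csv")),
    summary = file.path(out_dir, paste0("summary", suffix, ".json")))
  utils::write.csv(ex$labels, paths[["runs"]], row.names = FALSE)
  utils::write.csv(ex$proportions, paths[["proportions"]], row.names = FALSE)
  qs <- do.call(rbind, lapply(c("beneficiary", "donor"), function(role) {
    m <- if (role == "donor") ex$q_mean_d else ex$q_mean_b
    if (is.null(m)) return(NULL)
    grid <- expand.grid(state = rownames(m), action = colnames(m),
                        stringsAsFactors = FALSE)
    data.frame(agent = role, grid, mean_q = as.vector(m))
  }))
  utils::write.csv(qs, paths[["qsummary"]], row.names = FALSE)
  cfg <- ex$config
  summary <- list(
    game = cfg$game[c("r", "U", "V", "p", "c_weak", "c_strong")],
    rounds = cfg$rounds, n_runs = cfg$n_runs, base_seed = cfg$base_seed,
    seeds = range(ex$labels$seed), thirst = cfg$thirst, method = ex$method,
    threshold = threshold_satisfied(cfg$game),
    predicted_equilibrium = as.list(predicted_equilibrium(cfg$game)),
    proportions = ex$proportions,
    donor_q_gap = if (!is.null(ex$q_mean_d)) q_summary(ex, "donor")$gap)
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Validate a plain-text experiment configuration
#'
#' Parses a YAML-style `key: value` configuration and builds an
#' [experiment_config()], reporting every constraint violation at once
#' with the offending key. Recognised keys: `r`, `U`, `V`, `p`, `c_weak`,
#' `c_strong`, `lr` (or `alpha`), `dr` (or `gamma`), `explore_rounds`,
#' `memory`, `rounds`, `n_runs`, `base_seed`, `thirst`.
#'
#' @param text Configuration text, or a path to a file containing it.
#' @return A validated `sps_config`; errors aggregate all failures.
#' @examples
#' validate_config("r: 0.8\nU: 0.9\nV: 0.1\nn_runs: 10\nrounds: 200")
#' @export
validate_config <- function(text) {
  raw <- if (length(text) == 1L && file.exists(text)) yaml::read_yaml(text)
         else yaml::yaml.load(paste(text, collapse = "\n"))
  if (!is.list(raw)) stop("configuration must be key: value pairs", call. = FALSE)
  known <- c("r", "U", "V", "p", "c_weak", "c_strong", "lr", "alpha", "dr",
             "gamma", "explore_rounds", "memory", "rounds", "n_runs",
             "base_seed", "thirst")
  unknown <- setdiff(names(raw), known)
  problems <- character(0)
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  grab <- function(key, alt = NULL, default = NULL) {
    if (!is.null(raw[[key]])) raw[[key]]
    else if (!is.null(alt) && !is.null(raw[[alt]])) raw[[alt]]
    else default
  }
  game <- tryCatch(
    game_params(r = grab("r", default = 0.5), U = grab("U", default = 0.5),
                V = grab("V", default = 0.5), p = grab("p", default = 0),
                c_weak = grab("c_weak", default = 0.25),
                c_strong = grab("c_strong", default = 0.75)),
    error = function(e) { problems <<- c(problems, conditionMessage(e)); NULL })
  agents <- lapply(c("beneficiary", "donor"), function(role) tryCatch(
    agent_config(role, alpha = grab("lr", "alpha", 0.9),
                 gamma = grab("dr", "gamma", 0.1),
                 explore_rounds = grab("explore_rounds", default = 50L),
                 memory = grab("memory", default = 1L)),
    error = function(e) {
      problems <<- c(problems, paste0(role, ": ", conditionMessage(e))); NULL
    }))
  cfg <- NULL
  if (is.null(problems) || !length(problems)) {
    cfg <- tryCatch(
      experiment_config(game, beneficiary = agents[[1]], donor = agents[[2]],
                        rounds = grab("rounds", default = 500L),
                        n_runs = grab("n_runs", default = 1000L),
                        base_seed = grab("base_seed", default = 1L),
                        thirst = grab("thirst", default = "auto")),
      error = function(e) { problems <<- c(problems, conditionMessage(e)); NULL })
  } else {
    # still surface config-level violations alongside parameter ones
    if (!is.null(game) && !any(vapply(agents, is.null, TRUE)))
      tryCatch(experiment_config(game, beneficiary = agents[[1]],
                                 donor = agents[[2]],
                                 rounds = grab("rounds", default = 500L),
                                 n_runs = grab("n_runs", default = 1000L),
                                 base_seed = grab("base_seed", default = 1L),
                                 thirst = grab("thirst", default = "auto")),
               error = function(e) problems <<- c(problems, conditionMessage(e)))
  }
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  cfg
}
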