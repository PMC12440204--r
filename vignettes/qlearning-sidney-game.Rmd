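---
title: "Q-learning dynamics in the Sir Philip Sidney game"
author: "spsgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Q-learning dynamics in the Sir Philip Sidney game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spsgame)
```

## The model

The Sir Philip Sidney game is a two-player signalling game from
behavioural ecology. A *beneficiary* (B) may or may not need an
indivisible resource — conventionally water — held by a *donor* (D). B is
thirsty with probability $p$ and knows its state; D observes B's actions
but never its state. B chooses among three actions: not signalling (`N`,
cost 0), a weak signal (`W`, cost $c_w = 0.25$) or a strong signal (`S`,
cost $c_s = 0.75$). D either gives the resource (`G`) or keeps it (`K`).

Survival payoffs: D survives with probability 1 when keeping and $U \in
(0,1)$ when giving. B's base survival is 1 when given the resource, 0
when thirsty and refused, and $V \in (0,1)$ when not thirsty and refused.
Signal cost is applied multiplicatively, $P_B = s_B\,(1 - c)$: this is
the reading forced by the one-shot matrix cell $V(1-c)$ for a signalling,
not-thirsty, refused beneficiary, and it reproduces the thirsty
keep-cell $(r, 1)$ since $s_B = 0$ there. Because the players are kin
with relatedness $r$, each is rewarded by *inclusive fitness*,

$$F_i = P_i + r\,P_j,$$

not by individual payoff. Comparing B's rows of the one-shot matrices
shows that for any $c > 0$ signalling strictly lowers $F_B$ whenever base
survival is positive, so B's equilibrium action is always `N`. Given a
never-signalling partner, D prefers giving exactly when

$$r > \frac{1 - U}{1 - V + pV},$$

which the package exposes as `threshold_satisfied()` (returning the
margin $r - \text{threshold}$ so near-threshold cases can be quantified)
and `predicted_equilibrium()`. A side note on the source inequalities:
the one-shot comparison $1 + rU > 1 - c + rU$ only holds for $c > 0$, so
the package enforces $c > 0$ and $0 < V < 1$ throughout.

```{r threshold}
g <- game_params(r = 0.9, U = 0.95, V = 0.75)
threshold_satisfied(g)
fitness_matrix(g, thirsty = FALSE)
```

## Learning agents

Both players are tabular Q-learners. The observation state of *both*
agents is the joint action of the previous $m$ rounds (default $m = 1$:
six states `NK … SG`). The donor does not observe the beneficiary's
current-round signal before acting — although the game tree is
sequential, the learners interact through last-round memory, which is
what a six-state donor table implies. Thirst is not part of the default
observation because the replication settings fix $p$ at 0 or 1; a
configuration flag (`observe_thirst`) appends it to the beneficiary's
state for $0 < p < 1$.

After each round both agents update the entry they played:

$$Q_t(s,a) = Q_{t-1}(s,a) + \alpha\left(R_t + \gamma \max_{a'}
Q_{t-1}(s', a') - Q_{t-1}(s,a)\right),$$

with the reward $R_t$ being the agent's inclusive fitness for the round
and $s'$ the state formed by the joint action just played. Tables start
at zero. Exploration is $\varepsilon$-greedy: the first 50 rounds are
fully exploratory ($\varepsilon = 1$), after which $\varepsilon =
\min(1, 2/N)$ with $N$ the round number — about 4.6 expected exploratory
moves per agent over rounds 51–500. Ties among maximal Q-values are
broken uniformly at random during play. A dyad plays 500 rounds, which
lets the $\gamma = 0.1$ Q-values converge; an experiment is 1000
independent dyads, and these sizes are the package defaults.

### Randomness and reproducibility

Each dyad consumes a single R RNG stream seeded with `base_seed + i` for
run $i$, in a fixed order: the $m$ random joint actions seeding the
pre-game history, then the thirst sequence (when sampled), then per
round the beneficiary's draws followed by the donor's. A single seeded
stream rather than per-agent streams keeps the engine idiomatic R
(there is one global RNG) while preserving bit-for-bit reproducibility,
which is what the seed ledger is for; the fixed consumption order is the
contract that makes `play_round()` stepping and `run_dyad()` identical.

## Reading off the learned strategy

The published taxonomy labels each run by the cyclic pattern the agent
settles into (`NN`, `NW`, …, `KK`, `GK`, `KKG`). Two readouts are
implemented:

* **Policy readout** (default): roll both final greedy policies forward
  deterministically from the final observation state and classify each
  agent's action cycle (periods up to 3; anything longer is `OTHER`).
  This is "the strategy the agent has learned" in the literal sense and
  is immune to residual exploration noise.
* **Realized readout**: classify the actions actually played in the
  final 50 rounds. Rounds flagged exploratory are treated as wildcards
  (they match any action) rather than deleted — deleting a round from an
  alternation phase-shifts the remainder and destroys exact
  periodicity, which would misroute genuinely periodic runs to `OTHER`.

The policy readout is the default because the realized window remains
vulnerable to one-round greedy deviations caused by the *partner's*
(unflagged) exploration: with the $2/N$ schedule those deviations push
several percent of alternating donors into `OTHER`, visibly distorting
the near-threshold case's strategy distribution. The choice matters at
the few-percentage-point level; both readouts are exported so the
sensitivity can be checked directly (`classify(rec, method =
"realized")`).

Converged Q-values are summarised as the per-(state, action) mean over
runs of the per-run average over the final 100 rounds; the donor's "gap"
statistic is the unweighted grand mean over states of $Q(\cdot, G)$
minus that of $Q(\cdot, K)$.

## The three replication cases

```{r cases, eval = FALSE}
run_preset("case3", n_runs = 1000)  # prints both p = 0 and p = 1 summaries
```

| case | $r$ | $V$ | $U$ | threshold | prediction |
|------|-----|-----|-----|-----------|------------|
| 1 | 0.5 | 0.2 | 0.2 | not met | \{N,K\} |
| 2 | 0.8 | 0.1 | 0.9 | met, wide margin | \{N,G\} |
| 3 | 0.9 | 0.75 | 0.95 | met, near the limit | \{N,G\} |

Presets default to the not-thirsty state ($p = 0$): the published
strategy distributions for the near-threshold case are only consistent
with that setting, and the donor-side reward gap there ($1.85$ vs
$1.675$ for giving vs keeping at $p = 0$, but $1.85$ vs $1$ at $p = 1$)
makes the learned proportions strongly $p$-dependent near the
threshold. The *modal* strategy is $p$-invariant in all three cases —
that is the form of the "$p$ does not matter" robustness the test suite
asserts — but proportion-level agreement between $p = 0$ and $p = 1$
only holds away from the threshold.

## What the simulations do and do not show

The synthetic experiments emulate kin dyads repeatedly playing the
discrete game under stationary parameters. They do not emulate
populations (no matchmaking, no replicator dynamics, no generational
inheritance of tables), continuous signal intensities, or state-dependent
signalling need beyond the two-point thirst distribution, so passing
tests support claims about dyadic learning equilibria only.

Two published statistics resist replication under these dynamics, and
the package reports its own computed values rather than adjusting
toward the printed ones:

* The **case 2 Q-gap** computes to about 0.50 here against a printed
  0.410 (the case 3 analogue matches, 0.13 vs 0.139). The gap's size is
  governed by how often late exploration refreshes rarely visited
  states; every consistent averaging span (final value, last-100 mean,
  post-exploration mean, whole-run mean) lands in 0.47–0.51, and the
  only schedule that reproduces 0.41 (no post-exploration exploration
  at all) breaks the alternation statistics elsewhere.
* The **sweep floor**: with $\gamma = 0.9$ the bootstrap term dominates
  the one-round reward differences and, at $\alpha$ up to 0.9, the
  donor's policy flip-flops well past round 500; always-keep proportions
  for the high-discount column come out near 50–67% rather than the
  printed minimum of 80.9%. The qualitative orderings (low discount
  beats high discount at every learning rate; the minimum sits in the
  high-discount column) do reproduce.

## Numerical choices

* Exploration schedule: $\varepsilon = \min(1, 2/N)$, $N$ = rounds
  played. Alternative readings (constant $2/500$; $\varepsilon$
  *reduced by* $2/N$ per round; restarting the counter after round 50)
  were examined and each degrades the overall fit of the strategy
  distributions, so the plain reading stands.
* Classification window (realized readout): final 50 rounds, matching
  the longest stretch that is almost surely free of exploration at the
  end-of-run rate $\varepsilon = 0.004$; maximum detected period 3 (the
  longest catalogued cycle); canonical form of a cycle is its
  lexicographically minimal rotation under `N < W < S` / `K < G`.
* Q-window: converged values average the final 100 rounds; with
  convergence by round ~50 underway and $\alpha = 0.9$, the final 100
  rounds are statistically stationary for $\gamma = 0.1$.
* Degenerate inputs: `alpha = 0` yields a frozen (non-learning) agent;
  `explore_rounds = 0` starts greedy with the $2/N$ cap still giving
  $\varepsilon = 1$ on round 1; an all-exploratory classification
  window is an error rather than a silent `OTHER`.
* The deterministic policy rollout breaks Q-ties by the first action in
  column order — a readout should not be stochastic; during play,
  ties are broken uniformly at random.

## Limitations

Tabular agents with one-round memory cannot represent
history-contingent strategies longer than the state space allows;
memory $m > 1$ is supported (`memory = 2` gives 36 states) but the
catalogue of labelled strategies stays the published one, so richer
cycles fall into `OTHER`. The near-threshold regime is intrinsically
noisy: proportions there move by several points across seed sets and
across defensible readout choices, and comparisons in that regime
should always be made at fixed seeds with the readout stated.
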