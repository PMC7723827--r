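---
title: "Measuring navigational disorientation from node-graph event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring navigational disorientation from node-graph event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lostness)
```

## The measure

Educational games with node-based locomotion restrict players to discrete,
linked positions, so a play session is a walk on a spatial node graph. When
the learning content has to be *found* — items scattered through the
environment, each at a known node — navigational efficiency becomes a
meaningful, unobtrusive indicator of how well the player is coping: a
disoriented player burns working memory on wayfinding instead of on the
content. The lostness statistic, originally developed for hypertext
usability, quantifies this from three counts on a path segment:

* `R` — the minimum number of node entries needed (shortest-route length),
* `S` — the total number of node entries the player actually made,
* `N` — the number of distinct nodes among those entries,

combined as

$$L = \left(\frac{N}{S} - 1\right)^2 + \left(\frac{R}{N} - 1\right)^2 .$$

The first addend measures *repetition* (re-entering already visited nodes),
the second *detours* (entering nodes off the minimum route). A perfect walk
(`R = S = N`) scores 0; the statistic is bounded above by 2 and, for any
finite counts with `R <= N <= S`, stays strictly below it (the supremum over
all valid triples with counts up to 50 is about 1.474, approaching 2 only as
segments grow without bound).

Two whole-game aggregates are computed per player:

* **Global (task-scoped) lostness** `L_G`: the formula is evaluated per task
  over the window from `task_start` to `task_complete`, and per-task values
  are averaged weighted by each task's number of objectives `x_t`, so complex
  gathering tasks are not masked by simple ones. Events inside overlapping
  task windows are counted in *every* open window; this double counting is an
  inherent property of the task-scoped measure (players interleaving tasks
  look artificially lost), which is precisely why the objective-scoped
  measure below exists. We keep the behavior rather than "fixing" it.
* **Local (objective-scoped) lostness** `L_L`: the session is split at
  `objective_complete` events, counting from the start of the game and
  resetting the counters at each completion. `R` for a segment is the BFS
  shortest-hop distance from the previous completion node to the node where
  the objective was achieved. The per-segment `R`, `S`, `N` are summed and
  the formula is applied once to the sums — the whole game treated as one
  long task. Algebraically this equals the plain statistic on component-wise
  summed counts, an identity the test suite checks on random segment lists.

## Counting conventions

The counts are defined on *node entries*, excluding the segment's starting
node: one move to an adjacent node gives `R = S = N = 1`. Nothing in the
measure's definition fixes whether the starting node counts; what matters is
that one convention is applied to all three counters so the two ratios stay
comparable, and the entry convention is the one under which a single hop is
one unit for all three. Every `move` event counts as an entry; `pickup` and
`inspect` events count only if they change the player's node (turning an
item over in the hand is not movement). Item nodes (interactables, objects)
are ordinary visitable nodes: they sit in the same graph as locations and
cost an entry like any other node.

`N` is distinct-per-segment: uniqueness resets with the counters at each
objective completion. Degenerate segments (an objective completed with no
movement, e.g. two objectives achieved back-to-back at one node) contribute
zeros to the local sums but are *flagged*, not scored: reporting 0 would
make "no navigation" indistinguishable from "perfect navigation".
Everything after the final task's completion (free exploration) is outside
both measures. Incomplete tasks are excluded from the global aggregate —
the task window is defined by its completion.

### When the minimum route itself revisits nodes

For a whole task the minimum route visits several targets, and in branchy
worlds (items hanging off a hub room) the optimal route is forced to
re-enter the hub. A player walking it exactly then has `S = R` but `N < R`:
the unique count falls below the "minimum entries" count and the statistic
charges perfect play with repetition and detour terms. This is an honest
artifact of transplanting a hypertext formula (where optimal reading paths
rarely revisit) onto spatial graphs. The package's position:

* `lostness()` is strict by default and rejects `R > N` as inconsistent —
  for objective-to-objective segments this can never legitimately occur,
  since any walk from *a* to *b* enters at least `d(a, b)` distinct nodes.
* Task segments are evaluated tolerantly and carry a `forced_revisit` flag
  so downstream users can see which tasks are affected.

## Minimum routes

Per-segment `R` values come from breadth-first search with neighbors
expanded in lexicographic node-id order, making path reconstruction
deterministic. Per-task `R` values minimize the total hop count over all
orders of visiting the task's targets: exact permutation search up to 8
targets (tasks in this genre are small), a nearest-neighbor heuristic with
a warning beyond that. A `manual_R` override per task is supported for the
convention of measuring `R` from a hand-played perfect run; an override
below the computed minimum is accepted with a warning. The BFS layer is
cross-checked in the test suite against exhaustive simple-path enumeration
and against an independent graph library.

## The simulator

The study design this package emulates measured humans; raw logs of that
kind are rarely shareable, so the simulator provides synthetic cohorts with
known ground truth.

**Worlds.** `generate_world()` builds a location backbone (random spanning
tree plus shortcut edges with probability 0.15 per pair) with item nodes as
leaves, and chains tasks so each starts where the previous one ends. Each
task's objectives are presented in the optimal visiting order from its
start — the order a well-designed game nudges players toward. The default
world (12 locations, 4 tasks, 3 objectives each) is a small manor-house
scale chosen to match the genre.

**Agents.** `simulate_playthrough()` walks an epsilon-greedy policy: with
probability `1 - wander_prob` the deterministic BFS next hop toward the
current target, otherwise a uniformly random neighbor. This is the minimal
single-parameter policy spanning perfect navigation (`wander_prob = 0`,
which yields local lostness exactly 0) to a pure random walk. It is a
device for planting ground truth, not a cognitive model: real players show
systematic search strategies, landmark memory, and learning over time,
none of which the policy has. Passing tests therefore demonstrate that the
measures behave correctly on controlled walks, not that they are valid for
human data.

**Cohorts.** `simulate_cohort()` draws each player's `wander_prob`
uniformly from `[0, 0.6]` (no distributional information about individual
differences exists for the emulated design; this default spans attentive to
fairly chaotic play and is exposed in the configuration), simulates the
playthrough, computes both lostness measures, and draws presence,
engagement and cognitive interest as truncated normals on the 1–5 scale
with means 3.179, 2.976, 3.667 and SDs 0.450, 0.563, 0.693 — configuration
defaults emulating the reference cohort's questionnaire summaries, not
claims about new data.

Knowledge is generated from a planted linear model on z-scores:

$$\eta = \beta_L\, z(L_L) + \beta_P\, z(\text{presence}) +
\beta_I\, z(\text{interest}) + \sigma \varepsilon,$$

with defaults $\beta_L = -0.667$, $\beta_P = -0.399$, $\beta_I = 0.346$.
The standardized latent is pushed through a probit link,
$p_i = \Phi(\mu_0 + \tau \eta)$ with $\mu_0 = \Phi^{-1}(0.576)$, and the
knowledge score is the proportion correct over 24 simulated true/false
items (12 keyed true, 8 spatial). Two numerical choices matter:

* **Noise calibration.** $\sigma$ is chosen analytically (via the probit
  slope linearization) so that the multiple correlation of *observed*
  knowledge on the predictors targets 0.752 by default, accounting for the
  binomial item noise. A consequence worth stating plainly: because the
  planted betas alone would imply a multiple correlation of
  $\sqrt{0.667^2 + 0.399^2 + 0.346^2} \approx 0.85$, calibrating the total
  correlation to 0.752 attenuates the *fitted* standardized betas by the
  factor $0.752/0.85 \approx 0.88$ — the expected fitted local-lostness
  beta is about $-0.59$, not $-0.667$. The recovery tests assert a ±0.1
  band around the planted value, which this sits inside.
* **Item slope** $\tau$ (default 0.5). A 24-item Bernoulli instrument puts
  a hard ceiling of $\tau\phi(\mu_0)/\sqrt{\tau^2\phi(\mu_0)^2 + p(1-p)/24}$
  on the achievable multiple correlation; $\tau = 0.5$ puts that ceiling
  near 0.89 so the 0.752 target is feasible. The cost is a knowledge-score
  SD (~0.22) larger than the ~0.12 typical of real cohorts — real test
  items are correlated within person, which a conditional-independence item
  model cannot reproduce at matching variance. Settings that exceed the
  ceiling raise a configuration error before any simulation; setting
  `item_noise = FALSE` reports the continuous probit probability instead,
  which removes the ceiling (useful for noiseless-limit checks).

All randomness flows from one explicit seed, and the RNG state of the
caller is restored afterwards; identical seeds give byte-identical worlds,
logs and cohort files.

## Validation statistics

The analysis pipeline on a cohort table mirrors the standard small-sample
workflow for this design: means/SDs, pairwise-complete Pearson correlations
with two-sided p-values, simultaneous-entry (ENTER) OLS on z-scored
variables reporting standardized betas, VIFs, the multiple correlation and
overall F; Shapiro–Wilk normality checks (advisory only); a paired t test
comparing the two lostness measures per player; and a one-sided outlier
screen excluding values more than 2 SD *above* the mean of local lostness
(high lostness indicates a participant who never engaged; low lostness is
not suspect, hence one-sided). Missing data are deleted listwise for the
regression and pairwise for correlations, with a message. No
multiple-testing correction is applied by default, matching practice for
these exploratory designs; p-values are two-sided throughout.

## Problem sizes used by the checks

The shipped checks run at deliberately modest scale, chosen to exercise the
claims rather than to stress hardware: exhaustive enumeration of all 22,100
valid count triples up to 50; 1,000 random graphs of at most 8 nodes
against the simple-path enumeration oracle; 10,000 random segment lists for
the summed-counts identity; 200 agents per wander level for the
monotonicity check; 500 simulated cohorts of n = 24 (plus 60 of n = 200)
for recovery of the planted beta; and 1,000 null cohorts for the F-test
calibration.

## Known limitations

* The agent policy has no memory or strategy; cohort-level findings on
  synthetic data transfer to humans only insofar as the planted model does.
* The global measure's double counting under interleaved tasks is kept by
  design (see above); the chained-task simulator never interleaves, so
  synthetic global lostness is cleaner than real-world global lostness
  would be.
* Locked-door mechanics (edges conditionally traversable until a task is
  done) are not modeled; the graph is static and purely topological, with
  no geometry or travel times.
* Whether the original task-level `R` convention counted the starting node
  is not documented anywhere authoritative; the entry convention here is
  internally consistent across all three counters, which is what the ratios
  require, but absolute values may differ by a small offset from other
  implementations.
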