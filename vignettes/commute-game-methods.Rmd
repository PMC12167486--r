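---
title: "Models and methods of the commuting route-choice game"
author: "commutegame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the commuting route-choice game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commutegame)
```

## The game

`commutegame` simulates and analyses a repeated commuting route-choice game:
15 users travel daily between two origin–destination (OD) pairs over a
one-way network. OD1 (9 users) chooses between its local road **Local1** and
a shared **Expressway**; OD2 (6 users) between **Local2** and the same
expressway. A simulated day has K = 4 decision intervals (the initial
departure choice plus three ramp switch opportunities), and a trial runs
D = 40 consecutive days — 160 decisions per agent. Feedback is
instantaneous: at interval *t* + 1 every agent sees interval *t*'s per-route
user counts and travel times, its own previous route, and the interval
index. Days are continuous: the first interval of a day observes the last
interval of the previous one, and a route change across the boundary counts
as a switch. Ramps are free and switching itself costs nothing.

Travel cost on route *j* follows the Bureau of Public Roads (BPR)
volume-delay function

$$c_j(n_j) = a_j \left(1 + \alpha \left(\frac{n_j}{s_j}\right)^{\beta}\right),$$

with free-flow time $a_j$ (minutes), capacity $s_j$ (users) and shape
parameters $\alpha, \beta$. The canonical configuration uses
$a = 15, \alpha = 0.15, s = 5, \beta = 4$ for both locals and
$a = 5, \alpha = 0.075, s = 3, \beta = 4$ for the expressway: the
expressway is nominally faster but far more congestible (high risk / high
reward), the locals slower but stable. Expressway occupancy pools both OD
groups — that is what couples the two otherwise independent populations.

Every agent in an interval incurs the full BPR cost of its chosen route at
that interval's realized occupancy; a day's cost is the sum of its four
interval costs. These conventions reproduce the benchmark magnitudes: the
user-equilibrium state costs about 240.2 minutes of total travel per
interval (≈ 16 minutes per user, ≈ 64 per user-day).

## Equilibrium analysis

Because users are atomic (integer occupancies), the package works with the
discrete versions of the two classical reference states, both certified by
exhaustive enumeration of all $(9+1)(6+1) = 70$ integer splits:

* **User equilibrium (UE)** — no single user can *strictly* reduce their
  travel time by unilaterally switching to the other route on their menu,
  the deviation being priced at the destination route's occupancy plus one
  (`is_user_equilibrium()`). The weak inequality matters: in the discrete
  game the UE routes need not have exactly equal costs (the canonical UE
  has 15.92 on the locals against 16.12 on the expressway), so the
  continuous "equal travel times" reading cannot be taken literally.
* **System optimum (SO)** — the split minimizing total system travel time
  $\sum_j n_j c_j(n_j)$.

```{r equilibria}
net <- canonical_network()
solve_user_equilibrium(net)[[1]]
solve_system_optimum(net)
```

The canonical network has exactly one UE, with 7 expressway users; the SO
places 5 users on each route and saves about 28 minutes of total travel per
interval relative to the UE. `solve_user_equilibrium()` returns *all*
equilibria in lexicographic enumeration order (discrete games may have
several, or none — an empty result is reported, not raised); downstream
metrics use the first. Exact cost ties in the SO search keep the
lexicographically first assignment. Costs are computed in full floating
point; printed two-decimal reference values are matched in tests with absolute
tolerance 0.02 because printed roundings are not always consistent with the
formula (e.g. 16.116 printed as 16.11 while the per-user mean 16.012 is
printed as 16.00).

## Agent policies

All policies implement one protocol: given the observation of the previous
interval, return a route on the agent's two-route menu. At the very first
interval there is no history; observations carry zero counts/costs plus a
no-history flag, and all stochastic policies then choose uniformly at
random (fixed agents use their pin). This sentinel is a declared design
choice — participants receive no pre-trial information.

* **Fixed** agents always play a pinned route; `pinned_roster()` turns any
  assignment into a benchmark roster that holds the system at that state.
* **Archetype** agents implement win-stay/lose-shift behavior through two
  conditional probabilities: `c_minus` = P(switch | previous route was the
  *worse* of the two, i.e. had the longer previous-interval travel time)
  and `s_minus` = P(stay | previous route was the *better*). Exact
  previous-cost ties mean "neither worse nor better": the agent stays, and
  the interval is excluded from classifier conditioning. The four pure
  vertices of the `(c_minus, s_minus)` square are the decision-type
  archetypes: **naive** (1,1) always takes the previously cheaper route,
  **strategic** (0,0) always the previously costlier one, **exploratory**
  (1,0) switches every interval, **status quo** (0,1) never switches. A
  symmetric noise `eps` flips the realized action with probability
  ε ∈ [0, 0.5), which moves the planted probabilities toward 0.5 by exactly
  ε(1 − 2·vertex) — the property the estimator-bias tests use.
* **Best response** agents anticipate their own move: sitting on route *r*,
  they compare staying (previous cost of *r*) against joining the
  alternative at its previous occupancy plus one, and act on a profitable
  deviation with probability `p_act` (default 0.5). The inertia is
  essential: a deterministic simultaneous best reply mass-migrates and
  oscillates forever, while probabilistic better replies make the discrete
  UE absorbing — once reached, no deviation is profitable and everyone
  stays. A 15-agent best-response population reliably absorbs into the UE
  well before day 30.
* **RL** agents are independent advantage actor-critic learners (below).
* **LLM adapter** agents render the observation as a textual feedback
  message (counts and travel times for both menu routes, own previous
  route, interval index), query a pluggable response provider, and parse a
  route name back, with one re-ask on an unparseable reply and an error
  preserving the transcript after that. Tests use `mock_responder()` /
  `scripted_responder()`; live model backends are deliberately out of
  scope.

## Independent actor-critic learning

The reinforcement-learning agents follow the independent advantage
actor-critic (IA2C) scheme: each of the 15 agents owns a private actor
(softmax over {local, expressway}) and critic, and treats everyone else as
part of the environment. The observation is encoded as 7 features scaled to
roughly unit range: own-local count / OD demand, expressway count / total
demand, both previous travel times / their free-flow times, a one-hot of
the own previous route, and the interval index / horizon. The reward is the
negative travel cost of the chosen route (scaled by 0.01): the experimental
formulation states the reward through the travel cost of the chosen route
with agents minimizing individual travel time, and a sign flip embeds that
objective in a conventional reward-maximizing actor-critic. Updates are
online one-step temporal-difference advantage updates with an entropy
bonus.

Defaults (`rl_hyperparams()`): two tanh hidden layers of width 64 for both
networks, Adam at 3e-4 decayed linearly to 10%, discount 0.99, entropy
coefficient 0.01 annealed to zero over the first 80% of training, and 3000
pretraining episodes, each one full 40-day (160-step) trial. The experimental
protocol pretrains and then freezes its agents, and the package mirrors
that protocol: `rl_pretrain()` runs self-play training (compiled, about
ten minutes on one CPU), and deployment via `rl_agent()`/`rl_roster()`
uses the frozen greedy action with no parameter updates. Training emits the
mean per-interval system travel time per episode as a diagnostic curve and
errors out on non-finite values.

Under the default seed the frozen population reproduces the discrete UE
exactly (mean per-interval system cost 240.18). One caveat deserves
emphasis: *system* cost does not decrease monotonically over training.
Mid-training, partially random policies spread load more evenly than the
equilibrium and push the sampled system cost below the UE total; as the
selfish policies crystallize, the system cost climbs back up to the UE
value. This is the price of anarchy at work — individual returns improve
while their sum worsens — so learning-curve diagnostics should expect a
dip-and-rise shape, not monotone descent.

## Metrics

* **Sørensen–Dice convergence.** For each interval the realized route-count
  vector is compared against the UE and SO reference vectors with
  $\mathrm{SDC}(a,b) = 2\sum_j \min(a_j,b_j) / (\sum_j a_j + \sum_j b_j)$,
  giving the UESDC and SOSDC series (1 = exact match; it is a similarity
  coefficient, not a metric). The headline series aggregates counts over OD
  groups into 3-component route vectors, matching how the reference states
  are tabulated; `resolution = "od"` keeps the expressway split by OD for
  a stricter 4-component variant. The SDC of the SO vector against the UE
  vector is 13/15 ≈ 0.867, a useful floor when reading the series.
* **Moving averages** (20-interval and 10-day conventions) are trailing
  means; the first window − 1 points average the available prefix, a
  declared convention since edge handling is otherwise unspecified.
* **Switch dynamics.** A switch is a record whose route differs from the
  agent's immediately preceding interval (day boundaries included),
  attributed to the later interval's day. `switch_stats()` reports
  per-agent-day counts, the per-day population mean and per-agent daily
  switch frequencies.
* **Cost–switch regression.** Ordinary least squares of per-agent mean
  daily cost on per-agent total switches (one point per agent; at least 3
  agents, non-degenerate switch variance required). A steeper positive
  slope reads as a less stable system.
* **Occupancy series** keep OD resolution so OD1/OD2 views are derivable,
  and summarize the final intervals (default 10) for comparison against
  the UE and SO points.

## Decision-type classification

For one agent and an interval window, every interval after the window's
first yields a transition event: the *condition* compares the previous
interval's travel times of the agent's two menu routes (recomputed from the
log's own occupancies — the log is self-contained), and the *action* is
switch or stay. `estimate_type_vector()` turns events into the empirical
`(c_minus, s_minus)` pair; the complements satisfy C− + S+ = C+ + S− = 1 by
construction. Tie conditions carry no weight. A condition that never
occurred gives no evidence of switching, so its component is imputed to the
non-switching value (`c_minus` → 0, `s_minus` → 1) and flagged.
`classify_type()` assigns the nearest vertex in Euclidean distance, with
distance ties broken in the fixed order status quo > naive > strategic >
exploratory — deterministic, and favoring the modal empirical class at
maximal ambiguity (0.5, 0.5). `windowed_type_table()` applies this per
agent per window; the windows `1:40` and `121:160` reproduce the customary
early (days 1–10) versus late (days 31–40) comparison. Classification is
assumed stationary within a window (short-term consistency), and uses
per-interval transitions, including the day-boundary one.

## Synthetic populations and what they do (not) show

`population_spec()` plants a mixture of the four archetypes with a common
noise level; `generate_roster()` converts proportions to integer counts by
largest-remainder rounding (15 agents cannot represent arbitrary
percentages exactly), lays types out in a fixed label order and assigns OD
groups by agent-id order, recording everything in a ground-truth manifest.
`generate_trials()` runs independently seeded trials;
`recovery_experiment()` closes the loop by classifying the generated logs
and scoring them against the manifest. Everything is deterministic given
the master seed.

The generator emulates the *structure* of the experimental trial logs — 15
agents (9/6 OD split), 160 intervals, BPR-priced choices, populations drawn
from planted type mixtures — not the content of human or language-model
behavior: there is no within-agent drift between types, no prospect-like
risk weighting, no inter-individual parameter heterogeneity beyond the
four vertices plus symmetric noise. Recovery results therefore validate the
pipeline (generator → engine → classifier), not the behavioral fidelity of
the archetypes to any empirical population.

One genuine identifiability limit surfaces at ε = 0: with the first
interval as the only randomness, the population dynamics lock into
deterministic cycles, and an agent can spend the whole trial under a single
condition (e.g. always on the worse route). Its trajectory is then
consistent with more than one archetype — an always-switching
always-on-the-worse-route agent looks exactly like a naive one — and no
imputation rule can separate them. Recovery is exact for every agent whose
trajectory visited both conditions; with any ε ≥ 0.05 the cycles break and
full-window recovery is empirically perfect. The property suite asserts
the qualified forms, and noise-monotonicity of recovery accuracy is
checked across ε ∈ {0.05, 0.2, 0.45}, where both conditioning cells stay
populated.

## Numerical and testing choices

* Enumeration order (and hence all tie-breaks) is lexicographic in each
  OD's count on the first menu route, first OD slowest.
* Trial logs serialize costs with 17 significant digits so the CSV
  round-trip is bit-exact; the header is fixed.
* Published two-decimal table values are asserted with absolute tolerance
  0.02 (see above); everything else uses exact or standard numerical
  tolerances.
* Test problem sizes are chosen to keep the default suite fast while
  exercising full-scale behavior where it matters: unit tests use 2–10-day
  trials and 20–300 pretraining episodes; the acceptance suite runs full
  160-interval trials, a 5-trial recovery experiment and one full
  3000-episode pretraining.
* Inferential statistics (ANOVA and friends) are deliberately not wrapped:
  standard R routines (`aov`, `kruskal.test`, `wilcox.test`) apply
  directly to the tidy tables the metrics return.

## Known limitations

* Only two-route menus per OD and a single shared route are supported — the
  enumeration solvers and the binary action space rely on it. No
  continuous (fractional-flow) solvers, no elastic demand, no link-level
  topology, no travel-time noise, no heterogeneous values of time.
* The LLM adapter is a protocol, not a behavioral model; replaying or
  mocking responses is the supported mode.
* Decision-type classification inherits the identifiability limit above
  whenever the dynamics starve one conditioning cell; the imputation flags
  (`imputed_c`, `imputed_s`) mark exactly those cases and should be
  consulted before reading individual labels.
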