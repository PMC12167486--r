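# commutegame

Simulation and analysis of a repeated commuting route-choice game — the
kind of day-to-day collaborative decision problem where every commuter's
route choice shifts the travel times everyone else experiences the next
morning.

The package is aimed at researchers in computational behavioral science
and transportation who want a tested, reusable implementation of this
experimental paradigm: the congestion game itself, reference equilibria,
pluggable agent policies (behavioral archetypes, inertial best response,
independent actor-critic reinforcement learners, a mockable text-protocol
adapter), the full metric pipeline, and a synthetic-population generator
for parameter-recovery studies — no external data required.

## The model

15 users commute between two origin–destination pairs: OD1 (9 users)
chooses between **Local1** and a shared **Expressway**, OD2 (6 users)
between **Local2** and the same expressway. A trial lasts 40 days of 4
decision intervals each (160 choices per agent), with instantaneous
feedback of the previous interval's per-route counts and travel times.
Travel cost follows the Bureau of Public Roads volume-delay function

    c_j(n_j) = a_j * (1 + alpha * (n_j / s_j)^beta)

with a = 15, α = 0.15, s = 5, β = 4 on the locals and a = 5, α = 0.075,
s = 3, β = 4 on the expressway: nominally fast but highly congestible
versus slow but stable.

Two reference states anchor the analysis, both certified by exhaustive
enumeration of the 70 integer splits:

* **User equilibrium (UE)** — no single user can strictly cut their travel
  time by unilaterally switching routes (deviations priced at destination
  occupancy + 1): occupancies (4, 7, 4), costs 15.92 / 16.12 / 15.92
  min, mean 16.01 min/user.
* **System optimum (SO)** — minimal total travel time: occupancies
  (5, 5, 5), costs 17.25 / 7.89 / 17.25 min, mean 14.13 min/user.

Convergence of a trial toward either state is measured per interval by the
Sørensen–Dice coefficient between realized and reference route-count
vectors (UESDC / SOSDC). Individual behavior is classified from
conditional switch probabilities — C− = P(switch | previously on the worse
route), S− = P(stay | previously on the better route) — into four
decision types: naive (1,1), strategic (0,0), exploratory (1,0), status
quo (0,1).

## Worked example

```r
library(commutegame)

net <- canonical_network()
solve_user_equilibrium(net)[[1]]
#> UE state (certified)
#>   Local1      4 users  15.92 min
#>   Expressway  7 users  16.12 min
#>   Local2      4 users  15.92 min
#>   system: 15 users, total 240.18, mean 16.01 min/user

# a synthetic population: 40% status quo, 22.7% naive, 17.3% strategic,
# 20% exploratory, with 5% action noise
spec <- population_spec(c(status_quo = 0.4, naive = 0.227,
                          strategic = 0.173, exploratory = 0.2),
                        noise_eps = 0.05, seed = 7)
log <- generate_trials(net, spec, n_trials = 1, seed = 7)$logs[[1]]

mean(convergence_series(log, net)$uesdc[121:160])
#> [1] 0.8352632
mean(interval_system_cost(log)$total_cost)
#> [1] 411.596
mean(switch_stats(log)$per_agent$daily_mean)
#> [1] 1.655

windowed_type_table(log, net)$proportions
#> recovers the planted mixture in both windows:
#> status_quo 0.4, naive 0.2, strategic 0.2, exploratory 0.2
```

Reading: this noisy mixed population hovers near but below equilibrium
(UESDC 0.84 against 1.0 for a perfectly equilibrated system), pays ~412
minutes of total travel per interval against the 240.18 UE benchmark, and
its members switch routes 1.7 times per day. The classifier recovers the
planted type proportions exactly in both the early (days 1–10) and late
(days 31–40) windows.

Best-response populations absorb into the UE; pretrained frozen
actor-critic rosters (`rl_pretrain()`, ~10 min on one CPU) reproduce it
exactly:

```r
fit <- rl_pretrain(net, rl_hyperparams(), seed = 1)
mean(interval_system_cost(run_trial(net, rl_roster(net, fit),
                                    days = 40, seed = 1))$total_cost)
#> [1] 240.183   # the UE total
```

A thin command-line front end over the same functions lives in
`inst/cli/commute.R` (subcommands `equilibria`, `simulate`, `synth`,
`metrics`, `classify`).

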