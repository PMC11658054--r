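# queenrelay

Tools for studying how the honeybee queen's non-volatile fertility signal —
the queen pheromone gathered by retinue workers that lick and antennate her —
spreads through a colony via "messenger" workers. The package takes per-frame
bee trajectories (automated tracking at 2 frames/s), detects the
transmission-relevant physical contacts, and simulates stochastic pheromone
transfer over the time-ordered contact sequence, from which it derives the
field's standard analyses:

* **Contact geometry** — each bee is a trapezium centred on its tag, wider at
  the head than the tail; a contact is any frame in which one bee's head half
  overlaps a nestmate's body (flank-to-flank and tail-to-tail proximity is
  excluded), and the *inspecting* bee (facing its partner) is the pheromone
  receiver.
* **Queen movement states** — a two-state hidden Markov model (zero-inflated
  gamma step lengths, von Mises turning angles) segments daily queen
  trajectories into stationary (S) and travelling (T) bouts.
* **Transmission engine** — the queen is a constant source with surface load
  λ_Q; workers start as empty sinks. During a contact of duration τ the
  receiver extracts pheromone at a first-order rate (licking faster than
  antennation, drawn per contact from a logistic lick-probability curve
  p(τ) = p_max / (1 + e^{−(τ−τ0)/s})); worker donors deplete as
  λ₀(1 − e^{−kτ}) while the queen is clamped (kλ_Qτ); half of every transfer
  is ingested and lost; surface loads decay exponentially. A worker is
  *informed* while its load exceeds λ_min = 9.03 pg, *directly* informed
  while most of its load came from the queen herself.
* **Audience dynamics** — audience size A(t), coverage S(t) (mean pairwise
  distance, shortest path around the comb edge for cross-side pairs) and
  load L(t); within-bout, daily, in-silico queen-removal (half-lives),
  direct-transmission-only and forward-versus-time-reversed experiments.
* **Orientation responses** — the specified-direction Rayleigh statistic
  ρ = Σ cos(θ − μ)/n for receiver orientations toward messengers, pre/post
  and load-decile difference maps and angular transects, a calibrated
  worker-to-queen attraction test, and pre/post-retinue mobility curves.
* **Network roles** — daily contact networks, soft (overlapping) communities
  by symmetric non-negative factorisation with N_A/N_B/F labelling, the
  nurse bridging score H′ (renormalised binary entropy of the two nurse
  affiliations), simulation-averaged relay networks Q_{i→j}, age-cohort flow
  networks and a David's-score donation hierarchy.
* **Messaging syndrome** — six per-bee-day messaging metrics,
  within-day quantile transformation, pooled PCA, and Savitzky–Golay-smoothed
  developmental trajectories with a maximum-curvature inflection age.
* **Synthetic colonies** — a seeded generator producing ground-truthed
  trajectory datasets (two-state queen, staggered age cohorts, broodnest
  patches on both comb sides, retinue turnover, post-retinue excitation) so
  every stage is testable end-to-end without external data.

See `vignettes/queenrelay-methods.Rmd` for the models, assumptions,
parameter choices and limitations.

## Worked example

A 30-minute synthetic colony with three worker cohorts (aged 7, 4 and 1
days), contact detection, queen-state segmentation and a transmission
ensemble:

```r
library(queenrelay)

cfg <- colony_config(
  cohort_schedule = data.frame(day = c(0, 3, 6), size = 8),
  day_length_s = 1800,
  worker_age_profiles = modifyList(colony_config()$worker_age_profiles,
                                   list(forager_transition_age = 6)),
  seed = 42)
sim <- simulate_colony_day(cfg, day = 7)
#> colony_day: C1 day 7 - 24 workers, 3600 frames

contacts <- detect_contacts(sim$traj, sim$bees)
nrow(contacts)
#> [1] 393
head(contacts[contacts$i == "Q", c("i", "j", "t_start_s", "t_end_s")], 3)
#>    i       j t_start_s t_end_s
#> 1  Q W06_005         0    30.0
#> 7  Q W03_005        21    31.0
#> 11 Q W03_001        38    38.5

steps <- trajectory_to_steps(sim$traj[sim$traj$bee_id == "Q", ])
fit <- fit_two_state_hmm(steps, n_restarts = 2, seed = 1)
fit
#> Two-state movement HMM (3599 steps), logLik 854.5
#>   step mean (BL/frame): S = 0.0207  T = 0.252
#>   turn kappa:           S = 0.477  T = 7.9
table(filter_bouts(decode_bouts(fit, steps))$state)
#>  S  T
#> 18 16

params <- transmission_params(n_sims = 20)
ens <- run_ensemble(contacts, sim$bees, params, seed = 1,
                    grid_times = seq(0, 1800, 300))
round(audience_curves(ens, sim$traj), 2)
#>    t_s    A  S_bl   L_pg n_informed
#> 1    0 0.00    NA     NA          0
#> 2  300 0.29  6.83 272.70          7
#> 3  600 0.33  8.13 263.51          8
#> 4  900 0.33  5.48 726.99          8
#> 5 1200 0.38  9.25 543.84          9
#> 6 1500 0.38 12.46 645.64          9
#> 7 1800 0.42 13.68 959.84         10
```

The fitted state means recover the generating values (0.02 and 0.25
BL/frame) to within a few percent; over half an hour the simulated audience
grows to 42% of the workers, spreading from the retinue (S ≈ 7 BL) across
the comb (S ≈ 14 BL) while the mean load of informed bees rises.

Two analytic anchors used throughout:

```r
bridging_score(1/3, 1/3)   # equal nurse affiliations -> 1
#> [1] 1
rayleigh_rho(c(0.3, 1.2), c(0.3, 1.2))  # perfectly aligned receivers -> 1
#> [1] 1
```

A thin command-line wrapper over the same functions lives in
`inst/scripts/queenrelay.R` (subcommands `contacts`, `queen-states`,
`transmit`).

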