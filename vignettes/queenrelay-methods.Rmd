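---
title: "Modelling queen pheromone relay in honeybee colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling queen pheromone relay in honeybee colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

A mated honeybee queen advertises her presence with a non-volatile cuticular
pheromone blend. Workers that lick or antennate her in the retinue pick up
small amounts and carry them through the hive, where further worker-to-worker
contacts relay the signal onward. `queenrelay` implements the full analysis
chain for studying this relay from automatically tracked trajectories: contact
detection from trapezoidal body models, a two-state movement model for the
queen, a stochastic transmission simulation over the time-ordered contact
sequence, and the derived analyses (audience dynamics, in-silico queen
removal, receiver orientation fields, soft community structure, relay
networks and the developmental trajectory of worker "messaging").

This vignette is the package's own account of the models, their assumptions,
the tunable parameters, and the design decisions taken where several
reasonable choices existed.

## Spatial units and data model

All positions are measured in worker body lengths (BL) on a double-sided comb
(default 64 x 44 BL), tracked at 2 frames/s. A trajectory table has one row
per bee per frame: `bee_id, time_s, x, y, heading_rad, side`. Headings are
CCW radians from +x in [0, 2*pi); `side` is 0 or 1. The two comb sides are
treated as two 2-D planes joined at the frame edge: cross-side distances use
the shortest straight-line path around an edge (implemented by reflecting one
endpoint across each of the four edges and minimising), and side switches in
the synthetic colonies happen only within 1 BL of the comb boundary.

## Contact geometry

A bee body is a trapezium centred on its tag, long axis along the heading,
wider at the head (antennal reach) than the tail. Worker defaults are length
1.0 BL, head width 0.55 BL, tail width 0.35 BL; the queen is scaled 1.5x.
Exact dimensions are not critical and are config-exposed
(`body_dims()`) - only the relative properties (head wider than tail, queen
longer than worker) carry meaning.

A frame is a contact frame for a pair when the *head half* of either bee's
trapezium (the front half, split at the tag line) intersects the other's full
trapezium. This keeps head-to-head and head-to-body encounters - the ones
during which licking/antennation can transfer pheromone - and discards
flank-to-flank and tail-to-tail proximity. Intersections use a
separating-axis test, vectorised over frames after a coarse distance gate;
the test suite checks exact agreement with an independent vertex-in-polygon /
edge-crossing oracle over all pairs and frames of a random colony.

Consecutive contact frames merge into one contact; a dropout of at most
`gap_tol` frames (default 1) is bridged as tracking noise; longer gaps and
side switches split the contact. Durations are therefore multiples of the
frame interval. Per frame we also classify *inspection*: bee i inspects bee j
when i's head half intersects j and j lies within +/-90 degrees of i's
heading. The inspector is the pheromone *receiver*. The facing half-angle is
deliberately the full frontal half-plane - the behavioural dichotomy is
"faced toward" versus "faced away", and a narrower cone would add an
unsupported parameter.

## Queen movement states

Queens alternate between a slow, tortuous *stationary* (S) state and a fast,
straight *travelling* (T) state. `fit_two_state_hmm()` fits a two-state
hidden Markov model to the step-length/turning-angle decomposition of a daily
trajectory: zero-inflated gamma step lengths (tracking produces exact zero
steps when the tag does not move) and von Mises turning angles per state.
The likelihood is maximised directly (BFGS over unconstrained
transformations) from moment-based initialisations with random restarts
(default 10); the forward, forward-backward and Viterbi recursions run in
compiled code, so a full 24-h track (172,800 steps) fits in seconds per
restart. States are labelled so S always has the smaller fitted mean step
length, which also breaks likelihood ties.

Bouts are maximal same-state runs of the Viterbi path; their confidence is
the mean per-frame posterior of the decoded state, which is how we read "HMM
state probability". `filter_bouts()` drops bouts shorter than 10 s or with
confidence below 0.75 and caps the analysis horizon of long bouts at 305 s.
Step lengths enter the likelihood untransformed (square-root transforms are
for display only). Parameter recovery on simulated tracks is within a few
percent at 24 h; the test suite enforces 15%.

## The transmission model

Pheromone spread is simulated as a diffusive process on the time-ordered
contact sequence:

* the queen is the only source; her surface load `lambda_queen` is constant
  (production balances removal);
* workers start at zero and acquire load by inspecting the queen or a loaded
  nestmate; the inspector is the receiver. Mutual inspection transfers from
  the higher-load to the lower-load bee; exact ties give symmetric
  half-transfers computed from the pre-contact state;
* each contact is a licking contact with probability
  `p(tau) = p_max / (1 + exp(-(tau - tau0)/s))` - a single Bernoulli draw per
  contact is the model's only stochastic element (a per-frame redraw variant
  is selectable);
* extraction is first order: a worker donor depletes,
  `removed = lambda0 (1 - exp(-k tau))` (diminishing returns), while the
  queen's load is clamped, `removed = k lambda_queen tau`;
* transmission is leaky: the receiver ingests half of every transfer, so its
  cuticle gains `removed / 2`;
* worker surface loads decay exponentially at `decay_rate` between events;
* a worker is *informed* while its load exceeds the sensitivity threshold
  `lambda_min` = 9.03 pg; informed bees are *directly informed* while their
  queen-derived pool exceeds the worker-derived pool (worker-donor transfers
  credit the worker-derived pool regardless of the donor's own mix).

Integration is event-driven: loads are updated lazily, and each contact's
transfer is applied when the contact completes. Processing contacts in
end-time order keeps every per-bee load history time-sorted even when
contacts overlap, and makes load series exact closed-form evaluations
(`loads_at()` reproduces pure decay to 1e-12). Ensembles
(`run_ensemble()`, default 100 replicates) return per-time ensemble-mean
loads - informed status is computed on the ensemble mean, matching how the
audience measures are averaged across runs - and the per-pair mean
transferred volumes `Q[i -> j]` (summed removed amounts over replicates / S)
that weight relay networks.

### The calibrated default profile

The transfer-rate literature gives orders of magnitude, not a usable
parameter set, so the defaults ship as a calibrated profile
(`transmission_params()`): `lambda_queen` = 5000 pg, `k_lick` = 0.03/s,
`k_ant` = 0.008/s, `decay_rate` = 5.8e-4/s (~20 min surface half-life), lick
curve `p_max` = 0.8, `tau0` = 20 s, `s` = 5 s. The profile encodes the
transmission regime the relay phenomenon requires: a ~30 s licking retinue
contact loads a messenger ~250-fold above `lambda_min`, so even a 2-s
antennation of a fresh messenger informs the receiver (audience growth then
tracks contact rates, and one further hop straddles the threshold), while
secondary receivers sit only a few-fold above threshold, so the informed
population decays away on the tens-of-minutes scale once the queen stops
feeding the network. Every value is overridable, and none of the package's
algorithms depends on the profile.

## Audience dynamics and in-silico experiments

`audience_curves()` reports, per time step, the informed proportion A(t) of
tagged workers, the mean pairwise (cross-side-aware) distance S(t) among
informed workers (undefined below two), and their mean load L(t). Grand
means across colonies always take exactly one value per colony
(`aggregate_curves()`).

The experiments edit the contact sequence and rerun the ensemble:
within-bout runs zero all loads at each filtered bout's start and follow the
bout-relative clock to at most 305 s; the daily run uses contacts that start
and finish inside the day; queen removal deletes queen-worker contacts from
noon (configurable) and measures each group's informed-count half-life by
linear interpolation between grid samples; direct-only deletes all
worker-to-worker contacts. The forward/reverse experiment takes each genuine
retinue visit (queen contacts of at least `min_duration` = 25 s - sub-second
brushes load a worker too lightly to relay anything), seeds the focal worker
with the expected load it acquired, and compares audience growth over the
five minutes of contacts after the visit against the time-reversed five
minutes before it (event order inverted, durations preserved, same seed
load, worker-worker contacts only), reporting the relative difference.

A subtlety worth stating: donor depletion means that removing worker-to-worker
contacts does not *provably* lower every load (a messenger that never donates
retains more), so "direct-only audience <= full audience" is an empirical
property of the relay regime - it holds throughout our study-scale runs, as
in the real-data analyses - rather than a theorem.

## Orientation responses

The specified-direction Rayleigh statistic is
`rho = sum(cos(theta - mu)) / n`, where `theta` is the receiver's body
orientation and `mu` the direction from the receiver to the nearest point of
the messenger's trapezium boundary ("nearest body part"). Samples are
collected in the messenger frame (messenger at origin, heading +x) for all
workers within 2 BL during the five minutes before a queen contact (aligned
on contact start) and after it (aligned on contact end), so the contact
itself contaminates neither window. Difference maps bin the messenger frame
(0.2 BL cells over +/-2 BL; cells below 50 samples per stratum are masked)
and subtract the reference stratum's mean rho per cell: minute-k post minus
minute-k pre, or top load decile minus all post-retinue samples. Angular
transects bin clockwise position angle (24 bins) with SEs across colonies.

The worker-to-queen attraction test compares observed simultaneous
worker-queen distances (queen stationary only, so attraction is
attributable to the worker) against the distribution of distances over all
frame pairs. The default test is a one-tailed Wilcoxon rank-sum of the
thinned observed distances (one frame per 60 s, to tame autocorrelation)
against the expected sample. A quantile-matched signed-rank variant
(`paired = TRUE`) is provided for comparability but is anticonservative -
matched order statistics violate the signed-rank exchangeability assumption -
and the package's null-calibration tests demonstrate this; the rank-sum
default calibrates correctly on independent mean-reverting tracks.

Pre/post mobility curves align per-frame speed, unsigned turning angle and
side-switch indicators on the contact start (pre) and end (post), truncate
windows at neighbouring queen contacts, and report the post-minus-pre
difference at matched |t|.

## Network roles

Daily contact networks count contacts per pair. Soft communities come from a
symmetric non-negative factorisation A ~ H H' of the degree-normalised
adjacency (D^-1/2 A D^-1/2 - the normalisation keeps dense forager hubs from
swamping the factorisation), by multiplicative updates from random restarts;
rows of H are renormalised to affiliation scores summing to one. This is a
static per-day stand-in for temporally smoothed soft community detection:
the temporal coupling term links days, but every metric used downstream is
per-day. Labelling is deterministic: F is the community whose members (by
strongest affiliation) are oldest (ties broken by entrance-corner occupancy),
and N_A the nurse community holding more occupants of broodnest patch A.
Nurses are bees with N_A + N_B > 2/3, foragers F > 2/3.

The bridging score is the normalised entropy of the two nurse affiliations
*after renormalising them to sum to one* - necessary because affiliation
triples like (1/3, 1/3, 1/3) must still score H' = 1. Relay networks take
the ensemble pair flows as directed weighted edges; out-degree counts
receivers with positive flow. Cohort coarse-graining sums flows between age
cohorts (callows of 0-2 days pooled), keeps each pair's net flow in its
positive direction, and ranks cohorts by David's score on the dyadic
donation proportions `P[a,b] = gross(a->b) / (gross(a->b) + gross(b->a))`,
ties broken by total out-flow.

## The messaging syndrome

Six per-bee-day metrics: attraction effect (negated median distance
difference, so larger = more attracted - effect sizes, not p-values, because
p-values conflate sample size), queen-contact count, combined nurse
affiliation, bridging score, relay out-degree, and out- minus in-degree.
Each metric is quantile-transformed within colony-day (`rank/(n+1)`, mean
ranks for ties, constant days to 0.5), pooled, and decomposed by centred
PCA; the sign convention fixes the PC1 loading of out-degree positive.
Cohort-day mean scores averaged per age give each colony an age path, which
is Savitzky-Golay smoothed (window 7, order 3) and summarised by the age of
maximum discrete curvature of the smoothed 2-D path - the "inflection
point"; near-straight paths are flagged weak rather than assigned a
meaningless maximum.

## The synthetic colony generator

Every analysis stage is testable without downloads because
`simulate_colony_day()` generates ground-truthed colonies with the
statistical structure the analyses assume. Defaults mirror the study design
(24-h days at 2 frames/s, eight cohorts of 290 callows three days apart, a
64 x 44 BL double-sided comb); tests run far smaller colonies (8-16 bees per
cohort, 20 min to 3 h of simulated time) to stay fast.

The queen follows a two-state correlated random walk (zero-inflated gamma
steps, von Mises turns; dwell means 60 s/44 s give a long-run stationary
fraction of ~0.58), softly confined to the broodnest area. Workers hold
private home sites inside one of two broodnest patches (one per side) and
move by biased correlated random walks whose drift mixes home fidelity
(declining with age), queen attraction (peaking at 3-4 days), and, past the
forager transition age, a pull toward entrance-corner rest sites. Retinue
behaviour is explicit: queen-seeking motivation switches on sporadically
(mean ~10 min), attracted bees within reach join the court, halt facing the
queen for a ~45 s stint, then depart *excited* - 4 minutes of doubled-speed,
straightened runs ranging over the whole patch - with a refractory period
before they seek her again. Foragers lose broodnest fidelity, rest on a
gradient of sites between entrance and brood margin (the receiver-bee
minority sits closest), and make ~2 brood-area excursions per hour.

What passing tests on these colonies do and do not show: the generator
reproduces the *mechanisms* (state-dependent encounter statistics, retinue
turnover, post-retinue excitation, age structure, two-patch community
structure) at perhaps a hundredth of real colony density. Density matters:
with few bees on a large comb, the crowd around a stationary queen can
dominate raw encounter *rates*, and the travelling-queen rate advantage only
expresses cleanly in the sparser low-motivation configurations, although the
encounter-duration ordering (stationary longer) and all audience-growth
orderings are robust across our scales. Cross-side transmission is weak at
test scale (side switches are rare events at the comb edge), so informed
fractions are best compared within a side or against same-scale baselines.
No real tracking artefacts (detection dropouts, identity swaps, barcode
errors) are simulated beyond optional per-frame gaps.

A separate lightweight generator (`simulate_syndrome_rows()`) draws the six
syndrome metrics directly from age profiles with a planted regime change
(default age 4) plus noise; it exercises the quantile-PCA-inflection chain
at demographic scale without simulating weeks of trajectories.

## Numerical choices and degenerate inputs

* Zero steps get an explicit probability mass; turning angles are undefined
  (and dropped from the likelihood) next to zero steps and across track
  gaps.
* Bout boundaries come from the Viterbi path, confidence from posteriors;
  bouts tile the track exactly.
* Empty contact sets, bouts without contacts, groups with no members and
  uninformed groups at removal all return empty/flat/NA results rather than
  errors; a queen as prospective receiver is a no-op.
* Ensemble replicates derive per-replicate seeds from one master seed, so
  every experiment is reproducible end-to-end; identical configuration and
  seed give byte-identical synthetic colonies.
* The half-life interpolates linearly between grid samples; informed counts
  are step functions so this is exact up to grid resolution.
* Problem sizes: unit tests use 20-30 min colonies of ~25-50 bees; the
  end-to-end audience experiments use a 3-h, 49-bee colony; HMM parameter
  recovery uses a full simulated 24-h queen track.

## Known limitations

* The transmission defaults are a calibrated profile (above), not measured
  rate constants; conclusions about absolute loads should not be drawn from
  them.
* The soft community stage assumes k = 3 communities; the model-selection
  question is out of scope.
* Mixed-model and GAM(M) inference on the derived quantities is out of
  scope; the package reports means, SEs and simple paired tests.
* The generator's side-switching is a teleport at the comb edge, and
  density is far below real colonies (see above).
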