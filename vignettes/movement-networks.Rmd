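---
title: "From detections to movement networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From detections to movement networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishconn)
```

`fishconn` turns passive acoustic telemetry detection logs into movement
networks and temperature-driven inference for coastal fish. This vignette
explains the models and procedures behind each stage, the parameters that
matter, and the choices made where the underlying methodology leaves room —
so that results are interpretable and reproducible rather than dependent on
unstated conventions.

## The data model

The atomic datum is a **detection**: a time-stamped record of an implanted
ultrasonic transmitter heard by a moored receiver. An array of 11 receivers
across two fjord sites (one open coastal site, one protected inner site)
observes a cohort of tagged juvenile/subadult Atlantic cod over roughly five
months spanning a summer-to-winter sea-surface-temperature (SST) decline.
From detections we derive **movements** — a detection at one receiver
followed by the fish's next detection at a different receiver — and from
movements, weighted networks whose nodes are receivers.

## Quality control

**Clock drift.** Receiver clocks drift roughly linearly over a deployment.
Given the clock error measured at retrieval, `correct_time_drift()` shifts
each timestamp by the retrieval offset scaled by the fraction of the
deployment elapsed. The sign convention treats a positive offset as a fast
receiver clock, so recorded times are pulled back; records outside the
deployment interval are flagged and left untouched rather than extrapolated.

**False detections.** Acoustic code collisions produce occasional spurious
records, typically isolated single hits. `flag_false_detections()` marks a
detection invalid when fewer than `min_neighbors` (default 1) other
detections of the same transmitter occur at the same receiver within
`± window` (default 1 h). This is the conservative short-interval screening
rule widely used for coded transmitters; the underlying screening literature
specifies no single parameterisation, so both knobs are explicit
configuration. The filter only annotates and recomputes flags from the full
record set, making it idempotent.

**Post-release window.** The first 24 h of each fish's record are removed
(`remove_postrelease()`) to avoid behaviour distorted by anaesthesia and
handling.

## Movements, residency and mobility

`extract_movements()` collapses runs of same-receiver detections and emits
one movement per transition between runs. Transit time runs from the *last*
detection at the origin to the *first* at the destination — the standard
residence-event convention; the methodology's looser phrase ("subsequent
detection") is compatible with either endpoint, and the last-to-first choice
is what makes the short-transit filter meaningful. Movements faster than
4 min are removed as artefacts of overlapping detection ranges. Removal
never splices the flanking detections into a new movement: adjacency is
fixed before filtering, because chaining would fabricate paths the fish was
never observed to take.

Two per-fish indices summarise behaviour:

* **Residency index** `RI = days detected / days monitored` in [0, 1].
  "Days detected" counts distinct calendar dates (in a configurable local
  timezone, default Europe/Stockholm) with at least one valid detection.
  "Days monitored" is the whole-day difference from release date to study
  end; this matches the published cohort arithmetic (release 15 Aug 2015 to
  study end 18 Jan 2016 gives 156 days) and deliberately does *not*
  subtract the 24-h post-release window.
* **Movement index** `MI = movements / days detected`, computed after the
  4-min filter (the filter defines which movements are real, so the index
  should count only those).

Cohort exclusions (`exclude_fish()`) drop fish with no post-release
detections (left the array immediately) and fish with no extracted
movements, reporting a per-fish reason.

## Networks and weekly connectivity metrics

`build_network()` counts movements into edge weights over a **fixed** vertex
set: isolated receivers stay in the graph so that node counts — and the
triad-census denominator `choose(11, 3) = 165` — are constant across
windows. Directed networks are used for seasonal aggregation and motifs;
undirected networks for node-based metrics:

* **node strength** — summed incident edge weight (total movements touching
  a receiver);
* **degree** — number of distinct neighbours.

`weekly_metrics()` evaluates both on exact 7 × 24 h windows from a
configurable start instant (reference design: 25 Aug 2015, the last release
date) and sums across receivers. Summing per *endpoint* means every
undirected edge contributes twice to the weekly totals; the convention is
fixed and documented so model coefficients are comparable run to run. A
trailing partial week is dropped. Weeks with no movements produce 0/0 rows
and are kept — those zeros are exactly what the zero-inflated degree model
needs to see.

## Triad census

Connectivity substructure is measured by the census of the 16 directed-triad
isomorphism classes (Davis–Leinhardt MAN scheme: `003` … `300`,
`triad_classes()`). The census is authored here from first principles:
`classify_triad()` resolves the mutual/asymmetric/null dyad counts of a
3-node subgraph and disambiguates the 021, 111, 030 and 120 families by
in/out-degree pattern; `triad_census16()` precomputes the class of all 64
labelled 3-node digraphs once and classifies every node triple by table
lookup. Edge weights are binarised (an ordered pair is connected iff at
least one movement used it); the census counts *structure*, not traffic
volume. Two independent checks guard the implementation in the test suite: a
brute-force permutation-matching oracle, and the long-established census in
igraph.

`monthly_motif_series()` builds each fish's directed monthly network and its
census, joined to monthly mean SST; `motif_temperature_model()` fits each
class count with the negative binomial mixed model below. Classes that
geography makes impossible (no movement path exists) never vary and are
reported as non-estimable rather than fitted.

## Count mixed models

Weekly node strength is modelled as negative binomial (NB2, variance
`mu + mu^2/theta`) with a log link, environmental fixed effects and a
per-fish normal random intercept; weekly degree adds an intercept-only
structural-zero mixture on the logit scale (ZINB), because a fish that
simply was not moving that week generates zeros in excess of the count
process. Fitting is by maximum likelihood through `glmmTMB`, the standard
fitter for exactly this model family; the package surfaces tidy coefficient
tables, the dispersion `theta`, the random-intercept SD, the zero-inflation
probability, and an explicit convergence flag (degenerate inputs yield a
flagged result, never a silent crash). The zero-inflation component is
intercept-only by design: no covariate structure for structural zeros is
assumed anywhere in the analysis.

Predictors are screened for collinearity with the variance inflation factor
(`vif_screen()`, VIF_j = 1/(1 − R²_j), threshold 3), dropping the worst
offender iteratively. The screen takes a `protect` argument, used by the
pipeline to protect SST: when a seasonal covariate (PAR, sea level) is
collinear with SST, the analysis must keep its predictor of interest and
drop the proxy — an unprotected greedy rule could otherwise discard SST
itself. Wind speed is log-transformed and PAR square-root transformed
before screening; wind direction enters as a linear term in degrees (a
sin/cos circular encoding would be statistically cleaner but would change
the meaning of the published-style per-degree coefficient, so it is not the
default).

## Comparison tests

Seasonal differences in relative daily movement (movements per day divided
by fish detected that day; days with no detected fish are missing, not
zero) are tested with **Welch's heteroscedastic F** and the
**Games–Howell** post hoc procedure
(`q = |m_i − m_j| / sqrt((s²_i/n_i + s²_j/n_j)/2)` against the studentized
range with Welch–Satterthwaite df) — variances differ strongly between a
mobile summer and a still winter, so classical ANOVA assumptions fail by
construction. Note the Welch F reduces *exactly* to the classical F only
for two groups; for k ≥ 3 the denominator correction makes it slightly
smaller even under perfect homoscedasticity.

Site contrasts use Welch's t (residency) and the Wilcoxon rank-sum test
(movement counts). Size–behaviour relationships use a tie-corrected
Spearman correlation with a permutation p-value (exhaustive for n ≤ 9,
Monte Carlo otherwise) — at cohort sizes of a few dozen fish the asymptotic
approximation is not trustworthy.

## The synthetic telemetry generator

Because raw telemetry from the motivating study is not redistributed with
the package, `simulate_telemetry()` generates data with the statistical
structure the analysis assumes, plus the ground truth needed for recovery
tests. Its defaults *are* the reference study conditions and are not tuned
per run:

| parameter | default | rationale |
|---|---|---|
| `n_fish` | 48 | tagged cohort size |
| receivers | 11 in two sites | array size; ranges 216 m (unvegetated), 94–114 m (seagrass) |
| study period | 2015-08-15 – 2016-01-18 | five-month tracking window |
| `interval_bounds` | 30–90 s | transmitter duty cycle |
| SST curve | logistic 17.1 → 3.0 °C, midpoint day 81, scale 18 d, noise SD 1.2 | seasonal-window means ≈ 16.3 / 9.4 / 3.7 °C |
| `beta_sst` | 0.262 | log-linear SST effect on movement rate, matching the connectivity-model scale |
| `beta0` | −4.5 | ~0.7 movements/day for an average fish at 16 °C |
| `ranef_sd` | 1.0 | strong between-fish mobility heterogeneity (RI spread ~0.01–0.99) |
| `emigration_hazard` | 0.015 d⁻¹ | mean residency ≈ 60 d; ~10% of fish persist the full study, matching a mean RI near 0.38 |
| `detection_prob` | 0.6 | ranges are defined at 60% detection efficiency |
| `dead_time_s` | 60 | undetectable inter-zone transit |

Fish occupy discrete receiver *zones* rather than continuous space: the
analysis only ever observes receiver-level presence, so continuous-space
simulation would add cost without adding testable structure. The movement
process is a continuous-time jump process with piecewise-constant daily
intensity `exp(beta0 + b_i + beta_sst · SST(day))`; destinations are uniform
over graph neighbours, with dense links within each site and only two
corridor pairs between sites (reproducing the geography-limited motif
repertoire). Emigration and mortality are deliberately not distinguished.
Transmissions occur at uniform random intervals within the duty-cycle
bounds, beginning at zone entry, and are detected independently with the
zone detection probability.

What the generator does **not** emulate: tides, diel activity cycles,
depth-dependent detection efficiency, range collapse in storms, code
collisions between co-located tags, or behaviourally informed habitat
choice. Passing tests therefore demonstrate that the pipeline recovers the
structure this model encodes — not that it is robust to every artefact of
real field data.

## Problem sizes and numerical choices

The test suite exercises the pipeline at reduced scale — typically 6–10
fish with 5–15 min ping intervals — which preserves every code path while
keeping detection volumes small; the generator's defaults are exercised in
the end-to-end acceptance checks. Seasonal-contrast checks are evaluated on
the generator's true movements and occupancy (fish detected per day is, at
30–90 s ping intervals, equal to fish present per day with probability
essentially 1, so the truth-level ratio is the same quantity without
simulating millions of pings). Parameter-recovery checks simulate weekly
counts directly from the NB-GLMM generative process at the reference design
(40 fish × 21 weeks, slope 0.25) — that is the model the fitter claims to
estimate, so it is the correct recovery target.

Other numerical conventions: rounding to 2 decimals is a reporting-layer
concern (indices are computed exactly); weeks are exact 7 × 24 h blocks;
movements are assigned to windows by departure time; monthly censuses use
the calendar month of departure; permutation p-values use the
`(1 + #extreme)/(1 + n)` estimator for sampled permutations and the plain
proportion for exhaustive enumeration.

## Known limitations

* Movement is only observable between receivers; residency within one
  receiver's range produces no edges, so a highly resident fish can have
  MI ≈ 0 while being continuously present.
* The census treats all months on the fixed 11-node array; if a receiver
  were lost mid-study the 165-triad denominator would no longer be
  comparable across months.
* The ZINB's structural-zero probability is global, not seasonal; strongly
  seasonal zero generation is absorbed partly by the count process.
* Wind direction as a linear covariate is physically awkward (0° ≡ 360°);
  use the transform layer to add sin/cos terms if the circular structure
  matters for your array.
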