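# fishconn

Movement networks and environmental drivers from passive acoustic
telemetry.

## What problem this solves

Coastal fish tracked with implanted ultrasonic transmitters leave a trail
of time-stamped *detections* on an array of moored receivers. Turning that
raw log into ecological inference — who moved where, how residency and
mobility vary between individuals, how connectivity across the array
responds to the environment — requires a chain of decisions that are easy
to get silently wrong: clock-drift correction, false-detection screening,
post-release filtering, movement definition, network construction, and
count models that respect both overdispersion and repeated measures per
fish.

`fishconn` implements that chain end to end for a two-site fjord array
design (11 receivers, a cohort of juvenile/subadult Atlantic cod tracked
across a summer-to-winter temperature decline), and ships a stochastic
generator of synthetic detection logs with the same statistical structure,
so every stage is testable without access to restricted field data.

The analytical core:

* **Movements**: consecutive detections of a fish at two different
  receivers, transit measured last-at-origin to first-at-destination,
  transits < 4 min discarded as detection-range overlap (without splicing
  their endpoints).
* **Indices** per fish: residency index `RI = days detected / days
  monitored` ∈ [0, 1]; movement index `MI = movements / days detected`.
* **Networks**: weighted directed (seasonal aggregation, motifs) and
  undirected (weekly node strength and degree, summed across the fixed
  11-receiver vertex set).
* **Triad census**: counts of the 16 directed-triad isomorphism classes
  (MAN scheme, `003` … `300`) over all `C(11,3) = 165` node triples, per
  fish and month — implemented from first principles via the dyad decision
  table and verified against brute-force enumeration.
* **Models**: NB2 mixed model with log link and per-fish random intercept
  for weekly node strength (`strength ~ SST + log wind speed + wind
  direction`); zero-inflated NB for weekly degree; VIF screening
  (threshold 3) of environmental covariates; Welch ANOVA + Games–Howell
  for seasonal contrasts of relative daily movement; Welch t / Wilcoxon
  for site contrasts; permutation Spearman for size–behaviour
  correlations.

## Worked example

Simulate a small cohort and run the full pipeline:

```r
library(fishconn)

cfg <- sim_config(n_fish = 8, interval_bounds = c(300, 900))
bundle <- simulate_telemetry(cfg, seed = 42)
res <- run_pipeline(bundle, pipeline_config())

head(res$summary, 5)
#>   transmitter_id site days_detected days_monitored n_movements residency_index movement_index
#> 1           1001   II            83            149          55          0.5570         0.6627
#> 2           1002   II            36            154          28          0.2338         0.7778
#> 3           1003   II             4            147           3          0.0272         0.7500
#> 4           1004   II            84            156          23          0.5385         0.2738
#> 5           1005   II           147            147          11          1.0000         0.0748
```

Each row is one fish: a fish detected on 83 of its 149 monitored days has
RI 0.56 (present more than half its days at liberty), and its 55 movements
over 83 detected days give MI 0.66 (moderately mobile). The weekly
node-strength model recovers the temperature dependence the generator
encodes (`beta_sst = 0.262` by default; here estimated from 8 fish):

```r
res$models$strength$coefficients
#>             term estimate      se      z        p
#> 1    (Intercept) -4.37612 0.80528 -5.434 5.50e-08
#> 2            sst  0.36234 0.03062 11.832 2.67e-32
#> 3 log_wind_speed  0.16726 0.24833  0.674 5.01e-01
#> 4 wind_direction  0.00118 0.00109  1.079 2.80e-01

res$vif$retained
#> [1] "sst" "log_wind_speed" "wind_direction"   # sqrt_par, sea_level dropped (VIF > 3)
```

On the log-link scale a +1 °C week multiplies expected weekly node
strength by `exp(0.36) ≈ 1.44`; wind terms are null, as simulated. The
seasonal contrast of relative daily movements (movements per day / fish
detected per day) is strongly ordered summer > autumn > winter:

```r
res$comparisons$season_welch
#> Welch F = 57.06 (df 2, 93.5), p = 6.4e-17
res$comparisons$season_posthoc
#>   group1 group2   diff     q   df  p_value
#> 1 autumn summer  0.643 10.77 80.5 1.38e-10
#> 2 autumn winter -0.259  6.26 95.0 7.48e-05
#> 3 summer winter -0.902 15.12 76.2 0.00e+00
```

Monthly triad censuses per fish always total 165; pooling this run's
cohort-months shows the null triad (`003`) dominating and higher-order
motifs rare — connectivity is sparse and geography-limited:

```r
colSums(res$motifs[triad_classes()])
#>  003  012  102 021D 021U 021C 111D 111U 030T 030C  201 120D 120U 120C  210  300
#> 6354  901  345   21   16   82   38   37   12   18   23    5    8   25   24   11
```

The published per-fish summary of the reference cohort ships with the
package for index arithmetic checks:

```r
ref <- reference_cohort_summary()
round(mean(residency_index(ref$days_detected, ref$days_monitored)), 2)
#> [1] 0.38
```

## Documentation

See the vignette `vignettes/movement-networks.Rmd` for the methods:
QC rules, index definitions, network and census conventions, model
specification, and what the synthetic generator does and does not emulate.
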