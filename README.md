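# smoscreen

Analysis toolkit for FACS-based high-throughput screens of a fluorescent
**Smoothened (Smo) activation sensor** — a cpGFP cassette in the Smo
cytoplasmic tail that fluoresces only in the active conformation, read out
per cell in a clonal *Drosophila* S2 reporter line stimulated with Hedgehog
(Hh) conditioned medium. It is written for screeners and cell biologists who
need to go from raw per-well cytometry events to gated, QC'd, normalized,
target-class-aggregated hit tables, and to quantify the single-cell dose
response of the sensor.

The package covers the full analysis path, plus a ground-truth simulator so
every stage is testable without instrument data:

* **Simulation** — event-level wells, dilution series and 384-well screens
  with log-normal off/on fluorescence states, log-normally distributed
  per-cell activation thresholds (an event at dose *d* is "on" with
  probability `plnorm(d, mu_theta, sigma_theta)`), debris scatter
  populations, and multiplicative compound effects with a truth manifest.
* **Gating** — robust Mahalanobis ellipse on log FSC/SSC learned from
  control wells (`fit_gate`), applied per plate (`apply_gate`), with the
  strict inclusion rule that a well counts only if **more than 50%** of its
  events are in the gate.
* **Per-well statistics** — exact gated median fluorescence and the
  dual-control **normalized response**
  `100 * (treat − neg_ctrl) / (pos_ctrl − neg_ctrl)` (%), so the stimulated
  control is 100% and the unstimulated control 0%; Mann-Whitney U
  comparisons (exact permutation null for small samples).
* **Screen analysis** — per-target-class aggregation with a minimum cluster
  size of 3, cluster medians, Spearman concordance between conditions, and
  up/down hit calls (defaults: up ≥ 150%, down ≤ 80%, i.e. ≥ 20% reduction
  of the stimulated response) with per-compound consistency fractions.
* **Dose response** — EM mixture fits on log fluorescence, ΔBIC bimodality
  decisions, responder fractions, and weighted least-squares recovery of the
  activation-threshold distribution `F(d; mu_theta, sigma_theta)` from a
  dilution series, with bootstrap confidence intervals and closed-form
  saturation doses.
* **I/O** — FCS 3.0 and a long CSV event dialect, plate-map and annotation
  readers with strict validation, JSON gate audit files, and a one-call
  pipeline (`run_pipeline`) plus a thin `exec/smoscreen` command line
  (`simulate`, `screen`, `dose`).

## Worked example

Simulate a dilution series, gate it, and recover the threshold distribution:

```r
library(smoscreen)

cfg   <- population_config(n_events = 10000)   # defaults: thresholds lognormal(log 0.05, 0.73)
doses <- c(0, parse_dilution_ratio(c("1:100", "1:50", "1:20", "1:10",
                                     "1:5", "1:3", "1:2", "1:1")))
tabs  <- simulate_dilution_series(cfg, doses, seed = 5)
gate  <- fit_gate(tabs[[1]], coverage_quantile = 0.9)  # gate on the dose-0 well
rf    <- dilution_responder_fractions(tabs, doses, gate = gate)
model <- fit_threshold_distribution(rf, n_boot = 50, seed = 1)
model
#> Activation-threshold distribution: median dose 0.0504 (mu -2.988), sigma 0.723 log units
#>   fitted on 8 wells, weighted RSS 3.479
#>   bootstrap CI (n = 50): mu [-3.008, -2.745], sigma [0.431, 0.734]
saturation_dose(model, 0.95)
#> [1] 0.1654455
```

The fit recovers the generating parameters (true `mu_theta = log(0.05) =
-2.996`, `sigma_theta = 0.73`): the median cell activates at a conditioned
medium fraction of ~0.05, and 95% of cells are activated at a dose of
~0.165 — i.e. the population response saturates close to a 1:5
conditioned:fresh mixing ratio (`parse_dilution_ratio("1:5") = 0.167`).

Per-well screen statistics follow the control conventions exactly:

```r
ctrl <- control_pair(med_pos = 200, med_neg = 100)
normalized_response(c(200, 100, 300), ctrl)
#> [1] 100   0 200
```

A full simulated screen runs end to end with one config:

```r
lay <- make_plate_map(sprintf("cmpd%02d", 1:12), n_pos = 4, n_neg = 4)
ann <- data.frame(compound_id = sprintf("cmpd%02d", 1:12),
                  target_class = rep(c("A", "B", "C", "D"), each = 3))
out <- run_pipeline(list(
  outdir = "run1", seed = 11, simulate = TRUE,
  population = list(n_events = 1000),
  effects = list(list(compound_id = "cmpd01", target_class = "A",
                      effect_on_on_state = 2),
                 list(compound_id = "cmpd02", target_class = "A",
                      effect_on_on_state = 2),
                 list(compound_id = "cmpd03", target_class = "A",
                      effect_on_on_state = 2)),
  plate_map = lay, annotation = ann))
read.csv(file.path(out, "clusters.csv"))
#>   target_class n_compounds median_response concentration stimulated
#> 1            A           3        208.9089            15       TRUE
#> 2            D           3        101.0436            15       TRUE
#> 3            B           3        100.0505            15       TRUE
#> 4            C           3         98.3795            15       TRUE
```

Class A (its compounds double the induced sensor state) tops the cluster
table at ~209% of the Hh-stimulated control; the unperturbed classes sit at
~100%.

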