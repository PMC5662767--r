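---
title: "Models and methods behind smoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoscreen)
```

# The assay and the analysis problem

smoscreen analyses flow-cytometry screens of a fluorescent Smoothened (Smo)
activation sensor: a circularly permutated GFP embedded in the Smo
cytoplasmic tail that fluoresces only in the phosphorylated, active
conformation. A clonal reporter cell line is stimulated with Hedgehog (Hh)
conditioned medium — optionally in the presence of a library compound — and
each well is read out event by event on a cytometer (forward scatter, side
scatter, one fluorescence channel). Three features of the data drive the
design of every module:

1. **Per-cell activation thresholds.** Even in a clonal population,
   individual cells switch their sensor on at different ligand doses.
   Intermediate doses therefore produce *bimodal* fluorescence histograms —
   a low "off" mode and a high "on" mode — and increasing dose moves cells
   between the modes rather than shifting a single mode upward.
2. **Debris and damaged cells** contaminate the event stream and must be
   removed by a scatter gate before any fluorescence statistic is computed.
3. **Plate-to-plate drift** makes raw medians incomparable; every well is
   normalized against the same plate's stimulated and unstimulated controls.

# The generative model (the simulator)

`population_config()` + `simulate_well()` implement the package's explicit
event-level model, which doubles as the ground-truth generator for all tests:

* **Thresholds.** Each viable cell carries an activation threshold drawn
  from a log-normal distribution with parameters `mu_theta`, `sigma_theta`
  on the dose scale, where *dose* is the volume fraction of Hh-conditioned
  medium in $[0,1]$. At dose $d$ a viable event is "on" with probability
  $F_\theta(d) = \mathrm{plnorm}(d;\mu_\theta,\sigma_\theta)$. The assay
  establishes the threshold *phenomenon*, not a parametric form; we chose
  the log-normal as the simplest two-parameter distribution
  with positive support and a heavy right tail that reproduces bimodal
  intermediate-dose histograms. Dose 0 activates nobody *by convention*
  (the CDF is overridden), so unstimulated controls are clean negatives.
* **Fluorescence.** Off- and on-state fluorescence are log-normal
  (`mu_off`, `sigma_off`, `mu_on`, `sigma_on`), the classical model for
  flow-cytometry fluorescence. The defaults put the state medians at 100
  and 1000 arbitrary units with 0.4 log-unit spreads — a 10-fold induction
  window, comfortably more than the 3-scale separation needed for visible
  bimodality.
* **Scatter.** Viable cells and debris each get a bivariate log-normal
  FSC/SSC distribution; debris sits at low scatter, well separated from
  cells. The default debris fraction is 5% of events.
* **Dose calibration.** Defaults are `mu_theta = log(0.05)`,
  `sigma_theta = 0.73`: the median cell activates at a dose of 0.05 and
  95% of cells activate near dose 1/6 — i.e. the response saturates around
  a 1:5 conditioned:fresh mixing ratio, while activation at a 1:100 ratio
  is small but non-zero, matching the qualitative dilution behaviour of the
  assay the package models. `parse_dilution_ratio("a:b")` converts mixing
  ratios to dose fractions as $a/(a+b)$.
* **Acquisition.** 4000 events per well (the screening-mode acquisition
  count); channel values are clipped below at $10^{-6}$ so logs are always
  defined.
* **Compound effects** (`compound_effect()`) multiply the natural-scale
  medians of the off state, on state, and threshold, and add to the debris
  fraction (clamped to $[0, 0.95]$) — enough to encode activators,
  suppressors, sensitizers and toxic compounds with known ground truth.
* **Time courses** are available via `simulate_well(time_h=)`: the on/off
  log-separation scales by the saturating factor $t/(t+\tau)$ with
  $\tau = 6$ h, so signal is weak at 4 h and near-maximal at 24 h. This is
  a descriptive device, not a kinetic model, and is outside the screen path.
* **Reproducibility.** Per-well seeds derive from the master seed by the
  documented integer recurrence in `derive_seed()` (never a language hash),
  and a fixed seed yields bit-identical event tables.

What the simulator deliberately does **not** emulate: cell growth and
division, autocrine ligand production, spectral compensation, multi-colour
panels, doublets, instrument saturation, or within-cell threshold drift over
time (whether a cell's threshold is stable over time is unresolved; we treat
thresholds as fixed per event draw). Passing tests therefore demonstrate
correctness of the *analysis machinery* under a realistic population
structure, not performance on any particular real dataset.

# Gating and QC

Manual scatter gating is replaced by a deterministic stand-in:
`fit_gate()` fits a robust location and dispersion (minimum volume
ellipsoid) to the pooled log-FSC/log-SSC of control wells and sets the gate
radius at the empirical `coverage_quantile` (default 0.90) of the control
events' Mahalanobis distances, using the left-continuous inverse ECDF so the
realized control coverage is within $1/n$ of the request. The gate is fitted
once per plate on the unstimulated controls (configurable via `gate_on`) and
applied to all wells of that plate. Ties at the boundary count as inside.
Rank-deficient control scatter (e.g. identical events) is an explicit error.

The QC rule is the screen's inclusion criterion: a well enters the analysis
only when **strictly more than 50%** of its events fall inside the gate
(`gated_fraction > 0.5`; a well at exactly 0.5 fails).

# Per-well statistics

`median_fluorescence()` is the exact median of in-gate fluorescence
(midpoint convention for even counts), optionally after a seed-deterministic
without-replacement subsample emulating a fixed acquisition count. The
screen statistic is the **normalized response**

$$ R = 100 \cdot \frac{m_{\text{treat}} - m_{\text{neg}}}
                      {m_{\text{pos}} - m_{\text{neg}}} \;[\%], $$

so the stimulated control maps to exactly 100%, the unstimulated control to
0%, activators exceed 100% and suppression below the unstimulated baseline
goes negative (reported as-is, never clamped). Control medians are the
per-plate medians over the respective control wells' medians — robust to one
bad control well; the same pair normalizes stimulated and mock-stimulated
sample wells so both baselines are read on one scale. A plate whose controls
are indistinguishable (relative difference below $10^{-6}$) is a failed
assay, not a divide-by-almost-zero.

Replicate comparisons use the two-sided Mann-Whitney U test
(`compare_to_control()`): for total $n \le 10$ the exact permutation null by
full enumeration of label assignments (valid under ties), otherwise the
normal approximation with tie correction. Screen mode does not require
replicates; the test is exposed for validation experiments.

# Screen aggregation and hit calling

`aggregate_by_target()` groups QC-passing compounds by annotated primary
target class and reports the class median response, suppressing classes with
fewer than `min_cluster_size = 3` members (they remain available in the
suppressed-cluster report so the partition is complete). Compounds measured
at two concentrations are analysed per concentration; pathway-level
regrouping is a user-supplied second annotation column, since the mapping
from vendor annotation to pathway is a curation decision, not an algorithm.

Hit thresholds are not prescribed by the underlying study beyond
"consistent effect"; the defaults are `up_threshold = 150`% and
`down_threshold = 80`% (the latter implements the "reduced the response by
at least 20%" reading on the normalized scale), both configurable.
`call_hits()` also reports the per-cluster fraction of members individually
beyond the threshold — the "15 of 23 compounds" style of consistency
statement. Cluster ranking uses medians without p-values by default; when
`cluster_significance()` is used, Benjamini–Hochberg adjusted values are
reported next to the raw ones. `concordance()` (Spearman over the paired
intersection, with a pairing audit) quantifies agreement between
concentrations or stimulation arms.

# Bimodality, responder fractions, threshold recovery

The single-cell analysis formalizes what the histograms show qualitatively:

* `fit_mixture()` fits a one- or two-component Gaussian mixture to **log**
  fluorescence by EM. Initialization is a deterministic median split;
  convergence at a log-likelihood improvement below $10^{-8}$ or 500
  iterations; component scales floored at $10^{-3}$ log units to prevent
  collapse onto a point. We chose deterministic initialization over random
  restarts for auditability (one optional seeded restart is available). A
  two-component fit whose components are unseparated (below 2 pooled
  scales), near-coincident (< 0.1 log units) or vanishing (< 5% weight) is
  flagged `degenerate_bimodal`: EM on truly unimodal data happily returns
  two overlapping half-components, and the flag marks that those are not
  two modes. Constant data returns a degenerate $k=1$ fit with a warning.
* `bimodality_decision()` calls a well bimodal iff
  $\mathrm{BIC}_1 - \mathrm{BIC}_2 > 10$ *and* the minority weight is at
  least 0.05 *and* the locations are at least 2 pooled scales apart. The
  ΔBIC margin of 10 is the conventional "very strong evidence" cut and
  keeps the simulated false-bimodal rate at 4000 events per well below 5%.
* `responder_fraction()` returns the upper-component weight of a bimodal
  well; a unimodal well is classified against the unstimulated control's
  location (within 2 control scales → fraction 0, otherwise 1), and a
  unimodal well with no reference is explicitly indeterminate (`NA` with a
  warning) rather than silently 0.
* `fit_threshold_distribution()` recovers $(\mu_\theta, \sigma_\theta)$ by
  weighted least squares of the log-normal CDF against per-dose responder
  fractions (weights = events per well), initialized from a probit
  regression of the fractions on log dose and optimized by bounded
  L-BFGS-B ($\sigma_\theta \in [10^{-3}, 10]$). We fit the fraction curve
  rather than a joint likelihood over all events deliberately: the
  two-stage fit is robust to misspecified fluorescence shapes and each
  stage is auditable. It requires at least 4 distinct non-zero doses and
  refuses all-0 or all-1 fraction sets as unidentifiable. Confidence
  intervals are percentile bootstrap over wells (200 replicates), which
  quantifies fit stability across the dilution series rather than per-well
  binomial noise. `saturation_dose(model, level)` is the closed-form
  log-normal quantile.

# Problem sizes and numerical checks used by the test suite

The package's own acceptance checks run the full path at the sizes the
analysis is designed for: dilution series of 8 non-zero doses at 10,000
events per well (50 seeded replicates, requiring both threshold parameters
within 10% relative error in at least 90% of runs), bimodality calls at
4000 events per well over 100 seeds, and 50 replicate 384-well screens at
4000 events per well with one spiked target class that must rank first by
cluster median in at least 95% of screens. Oracle tests pin gate membership
to a brute-force point-in-ellipse enumeration, the exact Mann-Whitney
p-value to a full label-assignment enumeration, and the EM log-likelihood
to a $20\times20\times11$ grid search on a tiny instance.

# File formats and provenance

Events are read and written as FCS 3.0 (list mode, 32-bit float, linear
channels FSC-A/SSC-A/FL1-A; values round-trip to at least 6 significant
figures) or as a long CSV dialect (`well_id, fsc, ssc, fl[, truth_label]`)
that additionally carries simulator ground truth. Plate maps and compound
annotations are CSV with mandatory headers and strict validation (384-well
grid A1–P24, unique wells, known role tokens, numeric concentrations;
duplicates are reported with line numbers). Gates serialize to JSON for
audit. `run_pipeline()` writes every table plus the effective configuration,
package version, seeds and input checksums; reruns with the same seed are
byte-identical.

# Known limitations

* The simulator's on-state location is exactly dose-independent; real
  responders may drift. The threshold-recovery guarantees are statements
  about this generative model.
* The gate is a single ellipse in log-scatter space; it cannot represent
  non-elliptical manual gates or doublet exclusion.
* `responder_fraction()` quantizes unimodal wells to 0 or 1, which slightly
  biases fraction estimates at extreme doses; the CDF fit absorbs this in
  practice (the recovery checks pass with these wells included).
* Two screening concentrations do not support per-compound dose-response
  curves; that is out of scope by design.
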