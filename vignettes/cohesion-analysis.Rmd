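---
title: "Quantifying sister-chromosome cohesion: models, estimators and simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sister-chromosome cohesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesim)
```

## The measurement problem

In *E. coli*, a locus tagged with a fluorescent repressor-operator array
(FROS) appears as one diffraction-limited focus until its two newly
replicated sister copies move farther apart than the optical resolution
limit (~0.23 µm). The interval between locus replication and focus
splitting is the *cohesion period*. It cannot be observed directly in a
single snapshot; `cohesim` implements the two standard indirect readouts:

1. **Batch (asynchronous) cultures** — compare the mean locus copy number
   per cell (qPCR x rifampicin-runoff flow cytometry) with the mean number
   of resolvable foci per cell. More cohesion means fewer foci per copy.
2. **Synchronized (baby-machine) cultures** — follow mean copy number and
   mean foci per cell through the cell cycle and read the cohesion period
   as the time interval between the two cumulative event curves.

## The population model

A steady-state exponentially growing culture has cell-age density
`f(a) = (2 ln 2 / tau) 2^(-a/tau)` on `[0, tau]`: newborns are twice as
frequent as dividers. With one replication round per cycle, a locus
duplicated at age `a_r` has expected copies per cell

```
N = P(age < a_r) * 1 + P(age >= a_r) * 2 = 2^(1 - a_r / tau),
```

and, since sisters resolve into two foci only at age `a_r + Delta`
(`Delta` = cohesion duration), expected foci per cell
`2^(1 - (a_r + Delta)/tau)`. Their ratio — the **copies-per-focus
statistic** — is

```
copies / focus = 2^(Delta / tau),
```

independent of `a_r`, and inverts to `Delta = tau log2(c)`. A locus with
no cohesion gives exactly 1.0. For the wild-type gln locus (1.9
copies/cell, ~1.22 copies/focus at a 119-min doubling time) the inversion
gives ~34 min:

```{r}
cohesion_duration_from_ratio(1.22, generation_time = 119)
```

The synchronized-culture estimate for the same strain is 31 min. The two
readouts carry different systematic errors (detection correction vs curve
normalization) and the package deliberately reports both without
reconciling them; the discrepancy is within the measurement SD of either.

**Assumptions and limits.** The closed forms require a single replication
round per cycle (slow growth) and cohesion that resolves before division
(`a_r + Delta <= tau`). Both violations raise a typed
`cohesim_regime_error` rather than silently approximating; overlapping
rounds and division-spanning cohesion are only handled numerically by the
simulators, which flag `wraparound` in their truth records.

## Focus-detection correction

Fluorescence detection misses a small fraction of cells entirely. Because
every reporter-expressing cell carries at least one labelled locus, an
expressing cell with zero foci is a whole-cell detection failure, so the
inefficiency `i` is estimated as the zero-focus fraction among expressing
cells, and the population mean foci/cell is corrected by `raw / (1 - i)`.
Typical inefficiencies are 1-4%, and corrections stay below ~+0.10
foci/cell:

```{r}
correct_foci_per_cell(1.52, model = 0.94)[c("corrected",
                                            "correction_applied")]
```

Two design choices matter here:

* **Whole-cell failure, not per-focus thinning.** The estimator reads the
  inefficiency off the zero-focus fraction, which is only unbiased if a
  failed cell loses all of its foci at once (out-of-focus plane, poor
  illumination). Independent per-focus loss is available in the simulator
  (`per_focus_miss`) to probe robustness, but the correction model is the
  whole-cell one.
* **Division by efficiency, not additive adjustment.** Under whole-cell
  failure the observed mean is `e` times the true mean, so `raw / e` is
  exact; it also reproduces the documented <= +0.10 correction bound for
  the wild-type inputs.

Non-expressing cells (typically 2-8%) would inflate the zero-focus
fraction, so they are removed first by thresholding background (non-focus)
fluorescence: an exact two-means split on the log scale, accepted only
when the two cluster means are more than 3 pooled within-cluster SDs
apart. The optimal two-means split of a *single* Gaussian mode separates
the cluster means by only ~1.6 SD, so unimodal data are declared
non-separable (all cells kept, with a warning) rather than arbitrarily
split. Ratios that end up below 1 after correction are flagged, never
clamped, so over-correction remains visible.

The correction chain is validated on cohesion-free (stationary-phase)
populations, where corrected foci/cell must equal the independently
measured chromosomes/cell (`stationary_phase_validation()`).

## Copy number from qPCR and runoff histograms

Relative qPCR quantification uses `(1 + E)^(-dCt)` with `E = 1` (perfect
doubling) by default, replicates averaged on the Ct scale before
exponentiation. Runoff histograms (DNA content after blocking new
initiations) develop peaks at integer chromosome equivalents; each bin is
assigned to the nearest allowed peak `n in {1, 2, 4, 8}` when within 25%
relative deviation — that window covers a 3-sigma spread at the typical 8%
peak CV while keeping adjacent catch basins disjoint — and mean origins per
cell is the mass-weighted mean of assigned `n`. Multiplying by the
locus:oriC ratio (e.g. 0.98 for gln) gives locus copies per cell. Mass
not assignable to any peak is reported, warned about above 10%, and never
silently dropped from the bookkeeping. ChIP enrichment uses the
delta-delta-Ct convention with fold `2^(-ddCt)` against the
poorest-binding reference locus, which is 1.0 by construction.

## Synchronized-culture timing

The raw mean-signal curves rise from ~1 per cell toward a plateau as the
synchronous fraction replicates (or segregates) the locus. The package
operationalizes cumulative-curve analysis as:

1. fit a monotone non-decreasing curve to the raw signal (isotonic
   regression; robust to noise, no functional form assumed);
2. rescale so the fitted first-sample value is 0% and the last-sample
   value is 100% (the asynchronous contaminant's total rise is absorbed
   into this normalization);
3. read event times as 50% crossings, and the cohesion period as the
   interval between the replication and segregation crossings.

Crossings interpolate with a monotonicity-preserving (Hyman) cubic spline
when at least 4 samples are available. A straight chord across the steep
part of a sigmoid sampled every 10 min displaces the 50% time by up to
~1 min in a strain-dependent direction — enough to matter against a ±2 min
recovery requirement — and the spline removes almost all of it while
keeping first-crossing semantics on ties. A rise smaller than 4 residual
SDs of the monotone fit is rejected as indistinguishable from noise.

One bias is inherent to normalization: the asynchronous fraction
contributes a *linear ramp*, and rescaling absorbs its total rise but not
its local slope, displacing a crossing by up to ~1.5 min when the event
sits far from the window midpoint. For the cohesion period the two curves
are nearly parallel and the displacement mostly cancels (residual
~0.5-1 min). For B/C/D periods it does not cancel (oriC replicates early,
ter late), but there the generation time is an input, which makes the
ramp slope `(1 - phi)/tau` identifiable: `cell_cycle_periods()` estimates
the synchronous fraction from the curve's relative rise, subtracts the
ramp, and takes crossings on the synchronous component
(`crossing_time_corrected()`), falling back to the naive crossing when
the window spans a full generation or the rise is inconsistent with the
model.

```{r}
p <- cell_cycle_params(119, locus_replication_age = 8.8,
                       cohesion_duration = 31)
tc <- simulate_synchronized_timecourse(p, sample_times = seq(0, 120, 10),
                                       n_cells_per_sample = 1000,
                                       synchrony_fraction = 0.80, seed = 1)
cohesion_period(cumulative_curve(tc$time_min, tc$mean_copy_number),
                cumulative_curve(tc$time_min, tc$mean_foci))
```

## Genome tracks

GATC is the recognition site of Dam methylase and, while hemimethylated
behind the fork, of SeqA — the cohesion timekeeper. The genomics layer
scans circular genomes for motif occurrences (junction-spanning matches
included; GATC is palindromic so forward-strand starts count each site
once; candidate sites containing ambiguous bases are skipped and
tallied), computes per-kb window densities whose counts conserve total
mass under circular tiling, smooths probe tracks with centered circular
moving averages (40-kb chromosome-scale, 5-kb locus-scale; unweighted
probe means, matching common ChIP-chip practice), and reports Spearman
correlations between locus cohesion durations and smoothed binding.
Coordinates are 1-based fully closed internally; bedGraph I/O converts
exactly from the on-disk 0-based half-open convention.

## Time-lapse separation kinetics

Focus splitting is scored at the first frame with two resolvable foci;
transient re-merging does not reset it. Because the pair is invisible
below the resolution limit and moves during the frame interval, the first
post-split distance only bounds the separation speed from below:
`(d_first - 0.23) / frame_interval`. The package therefore reports the
initial velocity two ways — that lower bound, and the regression slope
over the first 20 min — mirroring how fast (>0.4 µm/min) and averaged
(~0.15 µm/min) readings coexist in practice; no attempt is made to map
one onto the other. Late slopes recover the cell elongation rate
(~0.02 µm/min). Distance distributions are summarized by mean and modal
0.2-µm bin (ties toward the smaller distance; a value on a bin boundary
belongs to the lower bin, so a population at exactly 1.0 µm reports a
0.9-µm bin center) with an optional 1-vs-2 component Gaussian-mixture
(BIC-selected) bimodality report.

## What the simulators emulate — and what they do not

Every input the analyzers consume can be generated with a seed, and every
generator is a pure function of its arguments that restores the global
RNG state and attaches a machine-readable `truth` attribute:

* `simulate_async_population()` — exponential-age sampling (inverse CDF
  `a = -tau log2(1 - u/2)`), copy/focus states by age thresholds,
  non-expressing cells as a low lognormal fluorescence mode, whole-cell
  detection failure, optional per-focus thinning.
* `simulate_synchronized_timecourse()` — synchronous fraction (default
  0.80, the baby-machine range being 0.75-0.85) with Gaussian event-time
  spread (SD 5 min, truncated at 0 — chosen once to match observed curve
  steepness and exposed in the interface), asynchronous contaminant with
  uniform replication phases segregating after the same cohesion duration
  (no wraparound, so foci never exceed copies), binomial sampling noise.
* `simulate_qpcr()` / `simulate_chip_qpcr()` — `Ct = intercept -
  log(q)/log(1+E) + noise` (default noise 0.1 cycles, triplicates).
* `simulate_runoff_histogram()` — Gaussian peaks at origin counts with a
  shared CV (default 8%).
* `simulate_genome()` — background sequence with accidental GATCs
  removed, then Poisson GATC planting (multiplied inside designated snap
  windows) so density is under direct control; the derived binding track
  and locus table plant the cohesion-binding relation at the 5-kb scale.
* `simulate_timelapse()` — two-phase separation (default 0.4 µm/min for
  2.5 min, then 0.02 µm/min), localization noise, and emission of
  sub-resolution pairs as a single merged focus.

These generators reproduce the *statistical structure the analysis
assumes*: they do not emulate images, pixel-level focus detection, flow
cytometer optics, amplification curves, replication-fork stochasticity,
or cell-to-cell growth-rate variation. Passing recovery tests on them
shows the estimators are correct under their stated model, not that the
model captures every property of real microscopy data.

## Problem sizes and numerical choices

Recovery tests use 1000 cells per time point at 10-min sampling (the
scale of the real experiments), 10^4-10^5 cells for law-of-large-numbers
checks of the population model, and 50-200 replicate simulations for
bias/SD properties; all complete in seconds. Tolerances follow the error
model of each statistic: 3 binomial SEs for counting estimators, ±2 min
for timing recovery, exactness (1e-9 or machine precision) for closed
forms, inversions and noise-free fixtures. Degenerate inputs are errors
with context (flat curves, all-zero focus counts, unreachable crossing
levels, empty runoff peaks), not NaNs.

## Known limitations

* The closed-form model excludes overlapping replication rounds; fast
  growth regimes need the numeric simulators and an extended model.
* The asynchronous-contaminant ramp correction assumes uniform phases;
  a baby machine with age-structured carryover would need a different
  background model.
* The runoff quantifier assumes synchronous-initiation peak structure
  (`2^n` origins) and a shared CV; severely asynchronous initiation mutants
  violate it and surface as unassigned mass.
* Inter-focus distances are planar (2-D); no 3-D correction is applied.
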