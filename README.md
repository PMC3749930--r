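# cohesim

Quantification of sister-chromosome cohesion in bacteria.

After a replication fork passes a chromosomal locus in *E. coli*, the two
sister copies stay within the ~230 nm resolution limit of fluorescence
microscopy — one focus for two DNA copies — for minutes to tens of minutes
before splitting apart. `cohesim` is for microbiologists and chromosome
biologists who measure that cohesion period with the standard assays:
fluorescent repressor–operator (FROS) focus counting, qPCR and
rifampicin-runoff copy-number determination, baby-machine synchronized
time courses, ChIP-qPCR, genome-scale GATC/binding tracks, and time-lapse
focus tracking.

## The model at the core

In a steady-state exponential culture the cell-age density is
*f*(a) = (2 ln2/τ)·2^(−a/τ) on [0, τ]. For a locus replicated at age
*a_r* with cohesion duration Δ:

- copies per cell  N = 2^(1 − a_r/τ)
- foci per cell  F = 2^(1 − (a_r + Δ)/τ)
- **copies per focus  N/F = 2^(Δ/τ)**, hence Δ = τ·log₂(N/F)

The ratio depends only on Δ: measuring copy number and resolvable foci
per cell independently yields the cohesion duration without
synchronization. In synchronized cultures the period is instead read as
the interval between the 50% crossings of the replication and
segregation cumulative curves. The package implements both estimators,
the detection-efficiency correction of focus counts (divide the mean by
1 − zero-focus fraction among expressing cells), ΔΔCt ChIP enrichment
(fold = 2^(−ΔΔCt)), circular-genome motif/binding scans, and two-phase
separation kinetics — plus seeded generators for every input.

## Worked example: the batch cohesion assay

Simulate a wild-type-like bundle (5000 cells, 1.9 gln copies/cell, 34-min
cohesion at τ = 119 min, 1.4% detection failure, 5% non-expressing cells)
and run the full assay chain — runoff origins/cell × gln:oriC qPCR ratio
for copy number; expression QC, inefficiency estimation and correction
for foci/cell; then the ratio statistic and its model inversion:

```r
library(cohesim)

p <- cell_cycle_params(119, locus_replication_age = 119 * (1 - log2(1.9)),
                       cohesion_duration = 34)
cells  <- simulate_async_population(p, 5000, whole_cell_miss = 0.014,
                                    non_expressing_fraction = 0.05, seed = 90)
runoff <- simulate_runoff_histogram(c("1" = 0.061, "2" = 0.939),
                                    n_cells = 10000, cv = 0.08, seed = 91)
qpcr   <- simulate_qpcr(c(gln = 0.98, oriC = 1), ct_sd = 0.05,
                        replicates = 9, seed = 92)

res <- run_cohesion_assay(cells, runoff,
                          ct_table_record(qpcr, "gln"),
                          ct_table_record(qpcr, "oriC"),
                          generation_time = 119)
res$estimate
#> Cohesion estimate: 1.226 copies/focus (35.0 min)
#>   copies/cell 1.927, foci/cell 1.572 (raw 1.549)
```

Reading: copy number reconstructed to 1.93 per cell; 5.1% of cells were
excluded as non-expressing; the remaining zero-focus fraction gave a 1.4%
detection inefficiency, lifting raw 1.549 foci/cell to 1.572; the
resulting 1.226 copies per focus inverts to a 35-minute cohesion period —
recovering the generator's 34-minute truth within sampling error, and
matching the ~1.22 copies/focus characteristic of wild-type gln.

For synchronized cultures:

```r
tc <- simulate_synchronized_timecourse(p, seq(0, 120, 10),
                                       n_cells_per_sample = 1000,
                                       synchrony_fraction = 0.80, seed = 1)
cohesion_period(cumulative_curve(tc$time_min, tc$mean_copy_number),
                cumulative_curve(tc$time_min, tc$mean_foci))
```

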