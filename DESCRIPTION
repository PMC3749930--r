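Package: cohesim
Title: Quantification of Sister-Chromosome Cohesion in Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring sister-chromosome cohesion in Escherichia
    coli from fluorescent repressor-operator (FROS) focus counts, qPCR and
    rifampicin-runoff copy-number data, synchronized-culture time courses,
    ChIP-qPCR enrichment, genome-scale GATC/binding tracks, and time-lapse
    focus-separation trajectories. Implements the steady-state exponential-age
    population model linking locus replication age and cohesion duration to
    the copies-per-focus statistic, focus-detection efficiency correction,
    cumulative-curve timing of replication and segregation, delta-delta-Ct
    ChIP enrichment, circular-genome motif density and moving-average scans,
    and two-phase separation kinetics, together with seeded synthetic-data
    generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    withr,
    jsonlite,
    mclust,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
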