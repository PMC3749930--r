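# Independent brute-force oracles, written without reference to the package
# implementation: a direct Monte-Carlo population simulator over sampled cell
# ages, and naive O(n*w) recomputations for genome-track operations.

# Inverse-CDF age sampler for the steady-state exponential-age law.
oracle_sample_ages <- function(n, tau) {
  -tau * log2(1 - stats::runif(n) / 2)
}

# Population means by direct enumeration over sampled ages: a cell of age a
# has 2 copies iff a >= ar and 2 resolvable foci iff a >= ar + delta.
oracle_population_means <- function(n, tau, ar, delta) {
  a <- oracle_sample_ages(n, tau)
  copies <- 1 + (a >= ar)
  foci <- 1 + (a >= ar + delta)
  list(copies = mean(copies), foci = mean(foci),
       ratio = mean(copies) / mean(foci),
       se_copies = stats::sd(copies) / sqrt(n),
       se_foci = stats::sd(foci) / sqrt(n))
}

# Naive circular windowed mean: for every probe, average values of probes
# within window/2 circular distance.
oracle_circular_window_mean <- function(pos, val, L, window) {
  h <- window / 2
  vapply(pos, function(p) {
    d <- abs(pos - p)
    d <- pmin(d, L - d)
    mean(val[d <= h])
  }, numeric(1))
}

# Naive motif scan on a character sequence (circular).
oracle_motif_scan <- function(seq_str, motif, circular = TRUE) {
  L <- nchar(seq_str)
  m <- nchar(motif)
  ext <- if (circular) paste0(seq_str, substr(seq_str, 1, m - 1)) else seq_str
  hits <- integer(0)
  for (i in seq_len(L)) {
    if (substr(ext, i, i + m - 1) == motif) hits <- c(hits, i)
  }
  hits
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
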