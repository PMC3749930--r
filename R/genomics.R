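#' A circular-genome coordinate/value track
#'
#' Point-probe representation of a genomic signal (motif counts per kb,
#' log2 IP/input binding ratios, ...): 1-based positions on a circular
#' chromosome with one value per position.
#'
#' @param position 1-based bp coordinates in `[1, genome_length]`, sorted.
#' @param value Finite signal values, one per position.
#' @param genome_length Chromosome length, bp.
#' @param window_bp Optional smoothing-window metadata, bp.
#' @param circular Logical; bacterial chromosomes are circular by default.
#' @return An object of class `genome_track` (a data frame with columns
#'   `position`, `value` and attributes `genome_length`, `window_bp`,
#'   `circular`).
#' @export
genome_track <- function(position, value, genome_length, window_bp = NA,
                         circular = TRUE) {
  stopifnot(length(position) == length(value))
  if (any(position < 1 | position > genome_length))
    stop("positions must lie in [1, genome_length]", call. = FALSE)
  if (is.unsorted(position, strictly = FALSE))
    stop("positions must be sorted", call. = FALSE)
  if (any(!is.finite(value)))
    stop("track values must be finite", call. = FALSE)
  structure(data.frame(position = as.numeric(position),
                       value = as.numeric(value)),
            genome_length = as.numeric(genome_length),
            window_bp = window_bp, circular = circular,
            class = c("genome_track", "data.frame"))
}

track_genome_length <- function(track) attr(track, "genome_length")

#' Positions of a motif on a (circular) genome
#'
#' Scans the forward strand for exact motif matches, including matches that
#' span the origin junction when `circular = TRUE`. GATC, the Dam/SeqA
#' recognition site, is its own reverse complement, so forward-strand
#' matching counts each site exactly once. Candidate sites containing
#' ambiguous bases (e.g. N) are skipped and tallied in the
#' `ambiguous_skipped` attribute.
#'
#' @param sequence A character string or [Biostrings::DNAString] over the
#'   IUPAC alphabet.
#' @param motif Motif to match, default `"GATC"`.
#' @param circular Match across the end-start junction.
#' @return Sorted integer vector of 1-based match start positions, with
#'   attribute `ambiguous_skipped`.
#' @examples
#' motif_positions("GATCGATC", circular = FALSE)  # 1, 5
#' motif_positions("ATCG")                        # 4 (wraps the junction)
#' @export
motif_positions <- function(sequence, motif = "GATC", circular = TRUE) {
  if (nchar(motif) < 1) stop("motif must be non-empty", call. = FALSE)
  seq <- if (inherits(sequence, "DNAString")) sequence
         else Biostrings::DNAString(as.character(sequence))
  L <- length(seq)
  m <- nchar(motif)
  subject <- if (circular && L >= m && m > 1)
    Biostrings::xscat(seq, Biostrings::subseq(seq, 1, m - 1))
  else seq
  pat <- Biostrings::DNAString(motif)
  exact <- Biostrings::start(Biostrings::matchPattern(pat, subject,
                                                      fixed = TRUE))
  loose <- Biostrings::start(Biostrings::matchPattern(pat, subject,
                                                      fixed = FALSE))
  exact <- exact[exact <= L]
  loose <- loose[loose <= L]
  structure(sort(as.integer(exact)),
            ambiguous_skipped = length(loose) - length(exact))
}

#' Motif density in fixed windows along the genome
#'
#' Tiles the genome into consecutive `window_bp` windows (the last window
#' absorbs any remainder so the circular tiling covers every base exactly
#' once) and reports counts per kilobase at the window centers. Window
#' counts sum to the total motif count by construction.
#'
#' @param positions Motif positions (1-based bp).
#' @param genome_length Genome length, bp.
#' @param window_bp Window size, bp.
#' @return A [genome_track()] of counts per kb, with attribute `counts`
#'   holding the raw per-window counts.
#' @export
window_density <- function(positions, genome_length, window_bp = 1000) {
  if (window_bp > genome_length)
    stop("window is larger than the genome", call. = FALSE)
  if (any(positions < 1 | positions > genome_length))
    stop("positions outside [1, genome_length]", call. = FALSE)
  n_win <- max(1L, floor(genome_length / window_bp))
  starts <- (seq_len(n_win) - 1) * window_bp + 1
  ends <- c(starts[-1] - 1, genome_length)
  idx <- pmin((as.numeric(positions) - 1) %/% window_bp + 1, n_win)
  counts <- tabulate(idx, nbins = n_win)
  widths <- ends - starts + 1
  track <- genome_track(position = (starts + ends) / 2,
                        value = counts / (widths / 1000),
                        genome_length = genome_length,
                        window_bp = window_bp)
  attr(track, "counts") <- counts
  track
}

#' Moving average of a genome track
#'
#' Centered moving average over a bp window with circular wraparound: each
#' output value is the unweighted mean of all probe values within
#' `window_bp / 2` bp (circular distance) of the probe position. This is
#' the smoothing used for 40-kb chromosome-scale and 5-kb locus-scale views
#' of ChIP binding tracks. On evenly spaced probes the track mean is
#' preserved exactly.
#'
#' @param track A [genome_track()].
#' @param window_bp Window size, bp (e.g. 40000 or 5000); must not exceed
#'   the genome length.
#' @return A smoothed [genome_track()].
#' @export
moving_average <- function(track, window_bp) {
  stopifnot(inherits(track, "genome_track"))
  L <- track_genome_length(track)
  circular <- isTRUE(attr(track, "circular"))
  if (window_bp > L)
    stop("window is larger than the genome", call. = FALSE)
  pos <- track$position
  val <- track$value
  n <- length(pos)
  h <- window_bp / 2
  if (circular) {
    pos_ext <- c(pos - L, pos, pos + L)
    val_ext <- rep(val, 3)
  } else {
    pos_ext <- pos
    val_ext <- val
  }
  cum <- c(0, cumsum(val_ext))
  eps <- 1e-9
  lo <- findInterval(pos - h - eps, pos_ext) + 1L
  hi <- findInterval(pos + h + eps, pos_ext)
  k <- hi - lo + 1L
  if (any(k < 2))
    stop("fewer than 2 probes in some windows: window too small for the ",
         "probe spacing", call. = FALSE)
  out <- (cum[hi + 1L] - cum[lo]) / k
  sm <- genome_track(pos, out, L, window_bp = window_bp, circular = circular)
  sm
}

#' Rank correlation between locus cohesion and a binding track
#'
#' Looks up the smoothed binding signal at each annotated locus (nearest
#' probe by circular distance) and reports the Spearman rank correlation
#' with the locus cohesion durations, together with the per-locus lookup
#' table.
#'
#' @param loci Data frame with columns `name`, `position` (bp) and
#'   `cohesion_minutes` (at least 4 loci).
#' @param smoothed A smoothed [genome_track()].
#' @return A list with `rho` (Spearman) and `table` (per-locus positions,
#'   cohesion and looked-up signal).
#' @export
cohesion_binding_correlation <- function(loci, smoothed) {
  stopifnot(is.data.frame(loci),
            all(c("name", "position", "cohesion_minutes") %in% names(loci)),
            inherits(smoothed, "genome_track"))
  if (nrow(loci) < 4)
    stop("need at least 4 annotated loci", call. = FALSE)
  L <- track_genome_length(smoothed)
  sig <- vapply(loci$position, function(p) {
    d <- abs(smoothed$position - p)
    d <- pmin(d, L - d)
    smoothed$value[which.min(d)]
  }, numeric(1))
  if (stats::sd(rank(loci$cohesion_minutes)) == 0 ||
      stats::sd(rank(sig)) == 0)
    stop("all ranks tied: rank correlation undefined", call. = FALSE)
  rho <- stats::cor(loci$cohesion_minutes, sig, method = "spearman")
  list(rho = rho,
       table = data.frame(name = loci$name, position = loci$position,
                          cohesion_minutes = loci$cohesion_minutes,
                          signal = sig))
}
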