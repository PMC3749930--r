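#' Cell-cycle and cohesion presets for the characterized strains
#'
#' Ground-truth study conditions for the gln locus in minimal alanine
#' medium: doubling times per strain/temperature, cohesion periods from
#' synchronized-culture analysis, and the locus replication age implied by
#' the 1.9 copies-per-cell anchor (`a_r = tau * (1 - log2(1.9))`).
#' parE10 at 30 C is listed at half its 37 C cohesion period.
#'
#' @return Data frame with columns `strain`, `temperature_c`,
#'   `generation_time`, `cohesion_min`, `replication_age`.
#' @export
cohesion_presets <- function() {
  d <- data.frame(
    strain = c("WT", "WT", "seqA", "mukB", "parE10", "parE10"),
    temperature_c = c(30, 37, 30, 30, 30, 37),
    generation_time = c(119, 98, 134, 211, 147, 174),
    cohesion_min = c(31, 26, 12, 30, 32, 65))
  d$replication_age <- d$generation_time * (1 - log2(1.9))
  d
}

preset_params <- function(strain, temperature_c) {
  p <- cohesion_presets()
  row <- p[p$strain == strain & p$temperature_c == temperature_c, ]
  if (nrow(row) != 1)
    stop("no preset for that strain/temperature", call. = FALSE)
  cell_cycle_params(row$generation_time,
                    locus_replication_age = row$replication_age,
                    cohesion_duration = row$cohesion_min)
}

#' Read / write per-cell observation tables
#'
#' CSV dialect: columns `cell_id`, `background_fluorescence`,
#' `focus_count` (plus any extras, preserved).
#'
#' @param path File path.
#' @param cells Data frame to write.
#' @return `read_cell_table` returns a data frame.
#' @export
read_cell_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "background_fluorescence", "focus_count")
  if (!all(need %in% names(d)))
    stop("cell table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Read / write synchronized time-course tables
#'
#' CSV dialect: columns `time_min`, `mean_copy_number`, `mean_foci`,
#' `n_cells`.
#'
#' @param path File path.
#' @param timecourse Data frame to write.
#' @export
read_timecourse <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "mean_copy_number", "mean_foci", "n_cells")
  if (!all(need %in% names(d)))
    stop("time course must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

#' @rdname read_timecourse
#' @export
write_timecourse <- function(timecourse, path) {
  utils::write.csv(timecourse, path, row.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA (first record)
#'
#' @param path FASTA path; soft-wrapped lines are concatenated.
#' @return Character string of the first sequence.
#' @export
read_genome_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  if (length(s) == 0) stop("no sequences in FASTA", call. = FALSE)
  as.character(s[[1]])
}

#' @rdname read_genome_fasta
#' @param sequence Character sequence to write.
#' @param name Record name.
#' @export
write_genome_fasta <- function(sequence, path, name = "genome") {
  x <- Biostrings::DNAStringSet(sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write bedGraph tracks
#'
#' bedGraph intervals are 0-based half-open on disk; internally the package
#' uses 1-based fully closed coordinates. The conversion (disk `[s, e)` to
#' internal `[s + 1, e]`) is handled by rtracklayer and is exact; a disk
#' interval `[0, 1000)` becomes internal `[1, 1000]`.
#'
#' @param path File path.
#' @return `read_bedgraph` returns a data frame with 1-based closed
#'   `start`, `end` and `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             value = gr$score)
}

#' @rdname read_bedgraph
#' @param intervals Data frame with 1-based closed `start`, `end`, `value`.
#' @param seqname Chromosome name written to disk.
#' @export
write_bedgraph <- function(intervals, path, seqname = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end),
    score = intervals$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Convert a point-probe genome track to bedGraph intervals and back
#'
#' Probes are written as 1-bp intervals at their positions.
#'
#' @param track A [genome_track()].
#' @return Data frame of `start`, `end`, `value` (1-based closed).
#' @export
track_to_intervals <- function(track) {
  data.frame(start = track$position, end = track$position,
             value = track$value)
}

#' Read a trajectory CSV
#'
#' CSV dialect: columns `cell_id`, `time_min`, `focus_index`, `x_um`,
#' `y_um`.
#'
#' @param path File path.
#' @export
read_trajectories <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_min", "focus_index", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stop("trajectory table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  d
}

#' Run the batch-culture cohesion assay end to end
#'
#' Chains the full measurement: (1) mean origins per cell from the runoff
#' histogram times the locus:oriC qPCR ratio gives locus copies per cell;
#' (2) per-cell focus counts pass expression QC, detection-efficiency
#' estimation and correction to give corrected foci per cell; (3) the
#' copies-per-focus statistic and its model inversion give the cohesion
#' duration. Every intermediate value is returned in a provenance list.
#'
#' @param cells Per-cell observation data frame (`cell_id`,
#'   `background_fluorescence`, `focus_count`).
#' @param runoff A [runoff_histogram()].
#' @param qpcr_target,qpcr_reference [qpcr_record()]s for the locus and
#'   oriC in the same sample.
#' @param generation_time Doubling time, minutes (for the model inversion).
#' @param roadblock Optional result of [roadblock_ratio()]; a flagged
#'   roadblock aborts the assay.
#' @return A list with `estimate` (a `cohesion_estimate`) and `provenance`
#'   (all intermediates: ratio, copies, QC partition, detection model,
#'   correction).
#' @export
run_cohesion_assay <- function(cells, runoff, qpcr_target, qpcr_reference,
                               generation_time, roadblock = NULL) {
  if (!is.null(roadblock) && isTRUE(roadblock$flagged))
    stop("replication roadblock flagged at the array site (ratio ",
         sprintf("%.2f", roadblock$ratio), "); assay aborted", call. = FALSE)
  ratio <- relative_ratio(qpcr_target, qpcr_reference)
  copies <- copies_per_cell_from_runoff(runoff, locus_to_oric_ratio = ratio)
  qc <- classify_expressing_cells(cells)
  model <- estimate_detection_efficiency(qc$expressing)
  raw_mean <- mean(qc$expressing$focus_count)
  corr <- correct_foci_per_cell(raw_mean, model)
  est <- batch_cohesion_statistic(copies$copies_per_cell, corr$corrected,
                                  generation_time = generation_time,
                                  foci_per_cell_raw = raw_mean)
  list(estimate = est,
       provenance = list(locus_to_oric_ratio = ratio,
                         runoff = copies,
                         qc = list(fraction_excluded = qc$fraction_excluded,
                                   threshold = qc$threshold),
                         detection = model,
                         correction = corr))
}

#' Write a JSON summary of an analysis result
#'
#' @param x A list (e.g. a `timing_result` or assay provenance).
#' @param path Output path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
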