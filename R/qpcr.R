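#' A qPCR measurement record
#'
#' One sample/target combination with replicate cycle-threshold values and
#' an amplification efficiency. `amplification_efficiency = 1` means perfect
#' doubling each cycle; template quantity is proportional to
#' `(1 + E)^(-Ct)`.
#'
#' @param sample_id Sample identifier.
#' @param target_locus Target locus name.
#' @param replicate_cts Numeric vector of replicate Ct values (cycles),
#'   finite and positive; typically triplicates.
#' @param amplification_efficiency Per-cycle amplification efficiency `E`
#'   in `(0, 1]`.
#' @return An object of class `qpcr_record`.
#' @export
qpcr_record <- function(sample_id, target_locus, replicate_cts,
                        amplification_efficiency = 1) {
  if (length(replicate_cts) < 1)
    stop("at least one replicate Ct is required", call. = FALSE)
  if (any(!is.finite(replicate_cts)) || any(replicate_cts <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  if (amplification_efficiency <= 0 || amplification_efficiency > 1)
    stop("amplification efficiency must lie in (0, 1]", call. = FALSE)
  structure(list(sample_id = sample_id, target_locus = target_locus,
                 replicate_cts = as.numeric(replicate_cts),
                 amplification_efficiency = amplification_efficiency),
            class = "qpcr_record")
}

mean_ct <- function(record, spread_warn = 0.5) {
  cts <- record$replicate_cts
  if (length(cts) > 1 && diff(range(cts)) > spread_warn)
    warning(sprintf("replicate Ct spread %.2f cycles exceeds %.2f for %s/%s",
                    diff(range(cts)), spread_warn,
                    record$sample_id, record$target_locus), call. = FALSE)
  mean(cts)
}

#' Relative quantity of a target vs a reference locus
#'
#' Replicate Cts are averaged first (arithmetic mean), then the ratio of
#' template quantities is `(1 + E_t)^(-Ct_t) / (1 + E_r)^(-Ct_r)`, which for
#' a shared efficiency reduces to `(1 + E)^(-(Ct_t - Ct_r))`. With `E = 1`
#' a one-cycle deficit corresponds to a two-fold quantity difference.
#'
#' @param target,reference [qpcr_record()] objects from the same sample.
#' @param spread_warn Warn when the replicate Ct range exceeds this many
#'   cycles.
#' @return Relative quantity (dimensionless, positive).
#' @examples
#' t <- qpcr_record("s1", "gln", 20.03)
#' r <- qpcr_record("s1", "oriC", 20.00)
#' relative_ratio(t, r)  # ~0.98
#' @export
relative_ratio <- function(target, reference, spread_warn = 0.5) {
  stopifnot(inherits(target, "qpcr_record"), inherits(reference, "qpcr_record"))
  ct_t <- mean_ct(target, spread_warn)
  ct_r <- mean_ct(reference, spread_warn)
  et <- target$amplification_efficiency
  er <- reference$amplification_efficiency
  (1 + et)^(-ct_t) / (1 + er)^(-ct_r)
}

#' A rifampicin-runoff DNA-content histogram
#'
#' After blocking replication initiation, ongoing rounds run to completion
#' so the DNA content distribution develops discrete peaks at integer
#' chromosome equivalents reporting the origins per cell at drug addition
#' (2^n peaks for synchronous initiation).
#'
#' @param bin_centers Strictly increasing fluorescence bin centers. By
#'   convention these are in chromosome-equivalent units (one fully
#'   replicated chromosome = `unit_position`).
#' @param counts Non-negative integer counts per bin, with positive sum.
#' @param peak_assignments Optional integer vector (same length as
#'   `bin_centers`) pre-assigning each bin to an origins-per-cell class
#'   (`NA` for unassigned).
#' @return An object of class `runoff_histogram`.
#' @export
runoff_histogram <- function(bin_centers, counts, peak_assignments = NULL) {
  if (any(diff(bin_centers) <= 0))
    stop("bin centers must be strictly increasing", call. = FALSE)
  if (length(counts) != length(bin_centers))
    stop("counts and bin_centers lengths differ", call. = FALSE)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with positive sum", call. = FALSE)
  if (!is.null(peak_assignments) &&
      length(peak_assignments) != length(bin_centers))
    stop("peak_assignments length must match bin_centers", call. = FALSE)
  structure(list(bin_centers = as.numeric(bin_centers),
                 counts = as.numeric(counts),
                 peak_assignments = peak_assignments),
            class = "runoff_histogram")
}

#' Locus copies per cell from a runoff histogram
#'
#' Quantifies mean origins per cell from the 2^n peak structure of a runoff
#' histogram and converts to locus copies via the locus:oriC qPCR ratio.
#' Each bin is assigned to the nearest allowed peak position `n * unit`
#' (`n` in `peaks`), provided its relative deviation from that position is
#' at most `max_rel_dev`; remaining mass is reported unassigned. Mean
#' origins is the mass-weighted mean of assigned `n`, and
#' `copies/cell = mean origins * locus_to_oric_ratio`.
#'
#' @param hist A [runoff_histogram()].
#' @param locus_to_oric_ratio Relative frequency of the locus per oriC from
#'   qPCR (e.g. 0.98 for gln).
#' @param unit_position Fluorescence position of one chromosome equivalent.
#' @param peaks Allowed origins-per-cell classes.
#' @param max_rel_dev Maximum relative deviation of a bin from its peak
#'   position to be assigned. The default 0.25 covers a 3-sigma spread at
#'   the typical 8% peak CV while keeping the catch basins of adjacent
#'   peaks (n and 2n) disjoint.
#' @return A list with `copies_per_cell`, `origins_per_cell`, `weights`
#'   (named mass fractions per peak), `unassigned_fraction`.
#' @examples
#' h <- runoff_histogram(c(1, 2), c(6, 94))
#' copies_per_cell_from_runoff(h, 0.98)  # (2*0.94 + 1*0.06) * 0.98 = 1.90
#' @export
copies_per_cell_from_runoff <- function(hist, locus_to_oric_ratio = 1,
                                        unit_position = 1,
                                        peaks = c(1, 2, 4, 8),
                                        max_rel_dev = 0.25) {
  stopifnot(inherits(hist, "runoff_histogram"))
  total <- sum(hist$counts)
  if (is.null(hist$peak_assignments)) {
    mu <- peaks * unit_position
    idx <- vapply(hist$bin_centers, function(b) {
      j <- which.min(abs(b - mu))
      if (abs(b - mu[j]) / mu[j] <= max_rel_dev) j else NA_integer_
    }, integer(1))
    assign_n <- ifelse(is.na(idx), NA_real_, peaks[idx])
  } else {
    assign_n <- as.numeric(hist$peak_assignments)
  }
  assigned <- !is.na(assign_n)
  mass_assigned <- sum(hist$counts[assigned])
  if (mass_assigned <= 0)
    stop("no histogram mass near any allowed peak position: ",
         "no resolvable peaks", call. = FALSE)
  unassigned_fraction <- 1 - mass_assigned / total
  if (unassigned_fraction > 0.10)
    warning(sprintf("%.1f%% of histogram mass unassigned to any peak",
                    100 * unassigned_fraction), call. = FALSE)
  w <- tapply(hist$counts[assigned], assign_n[assigned], sum) / mass_assigned
  origins <- sum(as.numeric(names(w)) * w)
  list(copies_per_cell = origins * locus_to_oric_ratio,
       origins_per_cell = origins,
       weights = w,
       unassigned_fraction = unassigned_fraction)
}

#' Absolute quantification against a calibrator standard curve
#'
#' Fits the least-squares line `Ct = m * log10(quantity) + b` through the
#' calibrator dilution points and reads the sample quantity as
#' `10^((Ct - b)/m)`. The implied amplification efficiency
#' `(1 + E) = 10^(-1/m)` is reported (perfect doubling gives slope
#' `-1/log10(2) ~ -3.32`).
#'
#' @param curve_points Data frame with columns `log10_quantity` and `ct`
#'   (at least 3 points).
#' @param sample_ct Sample mean Ct, cycles.
#' @return A list with `quantity`, `slope`, `intercept`, `efficiency`
#'   (implied `E`), `r_squared`.
#' @export
standard_curve_quantification <- function(curve_points, sample_ct) {
  stopifnot(is.data.frame(curve_points),
            all(c("log10_quantity", "ct") %in% names(curve_points)))
  if (nrow(curve_points) < 3)
    stop("need at least 3 standard-curve points", call. = FALSE)
  fit <- stats::lm(ct ~ log10_quantity, data = curve_points)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || m >= 0)
    stop("standard curve slope must be negative", call. = FALSE)
  tss <- sum((curve_points$ct - mean(curve_points$ct))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  if (r2 < 0.98)
    warning(sprintf("standard curve R^2 = %.3f < 0.98", r2), call. = FALSE)
  if (sample_ct < min(curve_points$ct) || sample_ct > max(curve_points$ct))
    warning("sample Ct outside the standard-curve range: extrapolating",
            call. = FALSE)
  list(quantity = 10^((sample_ct - b) / m),
       slope = m, intercept = b,
       efficiency = 10^(-1 / m) - 1,
       r_squared = r2)
}

#' Replication-roadblock check from flanking qPCR segments
#'
#' A repressor-bound operator array can stall replication forks; this shows
#' up as excess DNA immediately upstream of the array. The check computes
#' the upstream:downstream quantity ratio and flags samples whose ratio
#' exceeds a threshold.
#'
#' @param upstream,downstream [qpcr_record()] objects flanking the array.
#' @param flag_threshold Ratios above this raise the roadblock flag.
#' @return A list with `ratio` and the logical `flagged`.
#' @export
roadblock_ratio <- function(upstream, downstream, flag_threshold = 1.5) {
  r <- relative_ratio(upstream, downstream)
  list(ratio = r, flagged = r > flag_threshold)
}

#' ChIP-qPCR fold enrichment by the delta-delta-Ct method
#'
#' For each locus the IP-vs-input amplification difference
#' `dCt = Ct_IP - Ct_input` (replicates averaged first) is referenced to
#' the poorest-binding locus: `ddCt_x = dCt_x - dCt_ref`, and
#' `fold = 2^(-ddCt)`. The reference locus has fold 1 exactly.
#'
#' @param samples Data frame with columns `locus`, `ct_ip`, `ct_input`
#'   (multiple rows per locus are treated as replicates and averaged).
#' @param reference_locus Name of the reference locus (must be present).
#' @return Data frame with columns `locus`, `delta_ct`, `delta_delta_ct`,
#'   `fold`.
#' @examples
#' s <- data.frame(locus = c("dnaB", "gln"),
#'                 ct_ip = c(28, 28 - log2(10)), ct_input = c(20, 20))
#' chip_fold_enrichment(s, "dnaB")  # gln fold = 10
#' @export
chip_fold_enrichment <- function(samples, reference_locus = "dnaB") {
  stopifnot(is.data.frame(samples),
            all(c("locus", "ct_ip", "ct_input") %in% names(samples)))
  if (any(!is.finite(samples$ct_ip)) || any(!is.finite(samples$ct_input)))
    stop("Ct values must be finite", call. = FALSE)
  ip <- tapply(samples$ct_ip, samples$locus, mean)
  input <- tapply(samples$ct_input, samples$locus, mean)
  loci <- names(ip)
  if (!reference_locus %in% loci)
    stop(sprintf("reference locus '%s' not found", reference_locus),
         call. = FALSE)
  dct <- ip - input
  ddct <- dct - dct[[reference_locus]]
  data.frame(locus = loci,
             delta_ct = as.numeric(dct),
             delta_delta_ct = as.numeric(ddct),
             fold = 2^(-as.numeric(ddct)),
             row.names = NULL)
}
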