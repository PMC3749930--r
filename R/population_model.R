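#' Cell-cycle parameters for a chromosomal locus
#'
#' Bundles the quantities that determine steady-state copy number and focus
#' statistics for one locus in an exponentially growing population: the
#' generation (doubling) time tau, the cell age at which the locus is
#' duplicated, and the cohesion duration (interval between duplication and
#' separation of the sister loci into two resolvable foci).
#'
#' @param generation_time Doubling time tau, minutes. Must be positive.
#' @param locus_replication_age Cell age at locus duplication, minutes, in
#'   `[0, generation_time]`.
#' @param cohesion_duration Cohesion period Delta, minutes, `>= 0`.
#' @param b_period,c_period,d_period Optional cell-cycle periods (minutes):
#'   birth-to-initiation, replication, termination-to-division. When all
#'   three are given they must sum to `generation_time` within `tol`.
#' @param fork_speed Replication fork speed, nucleotides per second.
#' @param tol Tolerance for the B+C+D = tau check, minutes.
#' @return An object of class `cell_cycle_params`.
#' @examples
#' cell_cycle_params(119, locus_replication_age = 8.8, cohesion_duration = 31)
#' @export
cell_cycle_params <- function(generation_time,
                              locus_replication_age = 0,
                              cohesion_duration = 0,
                              b_period = NULL, c_period = NULL, d_period = NULL,
                              fork_speed = 700,
                              tol = 1e-6) {
  stopifnot(is.numeric(generation_time), length(generation_time) == 1L,
            is.finite(generation_time))
  if (generation_time <= 0)
    stop("`generation_time` must be positive", call. = FALSE)
  if (locus_replication_age < 0 || locus_replication_age > generation_time)
    stop("`locus_replication_age` must lie in [0, generation_time]",
         call. = FALSE)
  if (cohesion_duration < 0)
    stop("`cohesion_duration` must be >= 0", call. = FALSE)
  if (fork_speed <= 0)
    stop("`fork_speed` must be positive", call. = FALSE)
  if (!is.null(b_period) && !is.null(c_period) && !is.null(d_period)) {
    if (abs(b_period + c_period + d_period - generation_time) > tol)
      stop("B + C + D must equal the generation time", call. = FALSE)
  }
  structure(
    list(generation_time = generation_time,
         locus_replication_age = locus_replication_age,
         cohesion_duration = cohesion_duration,
         b_period = b_period, c_period = c_period, d_period = d_period,
         fork_speed = fork_speed),
    class = "cell_cycle_params")
}

#' @export
print.cell_cycle_params <- function(x, ...) {
  cat("Cell-cycle parameters\n")
  cat(sprintf("  generation time: %.1f min\n", x$generation_time))
  cat(sprintf("  locus replication age: %.1f min\n", x$locus_replication_age))
  cat(sprintf("  cohesion duration: %.1f min\n", x$cohesion_duration))
  invisible(x)
}

stop_regime <- function(msg) {
  stop(structure(class = c("cohesim_regime_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stop_domain <- function(msg) {
  stop(structure(class = c("cohesim_domain_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Steady-state cell-age density of an exponential population
#'
#' In a steady-state exponentially growing culture, newborn cells are twice
#' as frequent as dividing cells, giving the age density
#' `f(a) = (2 log 2 / tau) * 2^(-a/tau)` on `[0, tau]`. This distribution
#' underlies every batch-culture (asynchronous) statistic in the package.
#'
#' @param age Cell age(s), minutes, in `[0, generation_time]`.
#' @param generation_time Doubling time tau, minutes.
#' @return Probability density per minute, same length as `age`.
#' @examples
#' age_density(0, 100)       # 2*log(2)/100
#' integrate(age_density, 0, 100, generation_time = 100)$value  # 1
#' @export
age_density <- function(age, generation_time) {
  if (generation_time <= 0) stop_domain("generation time must be positive")
  if (any(age < 0 | age > generation_time))
    stop_domain("age must lie in [0, generation_time]")
  (2 * log(2) / generation_time) * 2^(-age / generation_time)
}

#' Cumulative distribution of cell age
#'
#' @inheritParams age_density
#' @return `P(A <= age) = 2 (1 - 2^(-age/tau))`.
#' @export
age_cdf <- function(age, generation_time) {
  if (generation_time <= 0) stop_domain("generation time must be positive")
  if (any(age < 0 | age > generation_time))
    stop_domain("age must lie in [0, generation_time]")
  2 * (1 - 2^(-age / generation_time))
}

check_single_round <- function(params) {
  ar <- params$locus_replication_age
  d <- params$cohesion_duration
  tau <- params$generation_time
  if (ar + d > tau)
    stop_regime(paste0(
      "cohesion spans cell division (replication age + cohesion duration > ",
      "generation time); the closed-form model only covers loci that ",
      "resolve before division. Use the numeric simulator for this regime."))
  invisible(params)
}

#' Expected locus copies per cell
#'
#' For a single replication round per cycle, a locus duplicated at age `a_r`
#' is present in 2 copies in cells older than `a_r`, giving a population
#' mean of `N = 2^(1 - a_r/tau)` under the steady-state age distribution.
#'
#' @param params A [cell_cycle_params()] object.
#' @return Mean copies per cell, in `[1, 2]`.
#' @examples
#' p <- cell_cycle_params(119, locus_replication_age = 0.074 * 119)
#' expected_copies_per_cell(p)  # ~1.90
#' @export
expected_copies_per_cell <- function(params) {
  stopifnot(inherits(params, "cell_cycle_params"))
  2^(1 - params$locus_replication_age / params$generation_time)
}

#' Expected resolvable foci per cell
#'
#' Sister loci remain within one diffraction-limited focus for the cohesion
#' duration Delta after duplication, so a cell shows 2 foci only once older
#' than `a_r + Delta`: mean foci per cell is `2^(1 - (a_r + Delta)/tau)`.
#'
#' @inheritParams expected_copies_per_cell
#' @return Mean resolvable foci per cell.
#' @export
expected_foci_per_cell <- function(params) {
  stopifnot(inherits(params, "cell_cycle_params"))
  check_single_round(params)
  2^(1 - (params$locus_replication_age + params$cohesion_duration) /
       params$generation_time)
}

#' Expected copies per focus (the cohesion statistic)
#'
#' The ratio of expected copies per cell to expected foci per cell. The
#' replication-age term cancels, leaving the closed form `2^(Delta/tau)`:
#' the batch-culture copies-per-focus statistic measures the cohesion
#' duration alone, independently of when the locus replicates.
#'
#' @inheritParams expected_copies_per_cell
#' @return Copies per focus, `>= 1`; equals 1 when cohesion is absent.
#' @examples
#' expected_copies_per_focus(cell_cycle_params(90, 0, 7))   # ~1.055
#' expected_copies_per_focus(cell_cycle_params(119, 9, 31)) # ~1.198
#' @export
expected_copies_per_focus <- function(params) {
  stopifnot(inherits(params, "cell_cycle_params"))
  check_single_round(params)
  2^(params$cohesion_duration / params$generation_time)
}

#' Cohesion duration implied by a copies-per-focus ratio
#'
#' Inverts the closed-form model: `Delta = tau * log2(copies_per_focus)`.
#'
#' @param copies_per_focus Observed copies-per-focus ratio, `>= 1`.
#' @param generation_time Doubling time tau, minutes.
#' @return Cohesion duration, minutes.
#' @examples
#' cohesion_duration_from_ratio(1.22, 119)  # ~34 min
#' @export
cohesion_duration_from_ratio <- function(copies_per_focus, generation_time) {
  if (generation_time <= 0) stop_domain("generation time must be positive")
  if (any(copies_per_focus < 1))
    stop_domain(paste0("copies per focus < 1 has no model solution; ",
                       "this usually indicates over-correction of foci counts"))
  generation_time * log2(copies_per_focus)
}

#' Batch-culture cohesion estimate
#'
#' Combines an independently measured mean copy number per cell with a
#' detection-corrected mean foci per cell into the copies-per-focus
#' statistic, optionally inverting it to a cohesion duration.
#'
#' Ratios below 1 (possible after over-correction of focus counts) are
#' flagged, never clamped, so QC problems remain visible downstream.
#'
#' @param copies_per_cell Mean locus copies per cell (qPCR x runoff), `> 0`.
#' @param foci_per_cell_corrected Detection-corrected mean foci per cell, `> 0`.
#' @param generation_time Optional doubling time, minutes; when given, the
#'   ratio is inverted to `cohesion_minutes` (only for ratios `>= 1`).
#' @param foci_per_cell_raw Optional uncorrected mean foci per cell, recorded
#'   for provenance.
#' @return An object of class `cohesion_estimate`: a list with fields
#'   `copies_per_cell`, `foci_per_cell_raw`, `foci_per_cell_corrected`,
#'   `copies_per_focus`, `cohesion_minutes` and the logical `sub_unity` flag.
#' @examples
#' batch_cohesion_statistic(1.9, 1.557, generation_time = 119)
#' @export
batch_cohesion_statistic <- function(copies_per_cell, foci_per_cell_corrected,
                                     generation_time = NULL,
                                     foci_per_cell_raw = NA_real_) {
  if (!is.finite(copies_per_cell) || copies_per_cell <= 0)
    stop_domain("copies per cell must be positive")
  if (!is.finite(foci_per_cell_corrected) || foci_per_cell_corrected <= 0)
    stop_domain("corrected foci per cell must be positive")
  ratio <- copies_per_cell / foci_per_cell_corrected
  sub_unity <- ratio < 1
  if (sub_unity)
    warning("copies per focus < 1: foci counts may be over-corrected",
            call. = FALSE)
  cohesion_minutes <- NA_real_
  if (!is.null(generation_time) && !sub_unity)
    cohesion_minutes <- cohesion_duration_from_ratio(ratio, generation_time)
  structure(
    list(copies_per_cell = copies_per_cell,
         foci_per_cell_raw = foci_per_cell_raw,
         foci_per_cell_corrected = foci_per_cell_corrected,
         copies_per_focus = ratio,
         cohesion_minutes = cohesion_minutes,
         sub_unity = sub_unity),
    class = "cohesion_estimate")
}

#' @export
print.cohesion_estimate <- function(x, ...) {
  cat(sprintf("Cohesion estimate: %.3f copies/focus", x$copies_per_focus))
  if (!is.na(x$cohesion_minutes))
    cat(sprintf(" (%.1f min)", x$cohesion_minutes))
  if (isTRUE(x$sub_unity)) cat("  [FLAG: ratio < 1]")
  cat("\n")
  cat(sprintf("  copies/cell %.3f, foci/cell %.3f (raw %.3f)\n",
              x$copies_per_cell, x$foci_per_cell_corrected,
              x$foci_per_cell_raw))
  invisible(x)
}

#' Relative cohesion time course
#'
#' For a temperature-shift (or similar) experiment measured in a mutant and
#' a matched control, computes at each time point the difference in
#' copies-per-focus between mutant and control, normalized to the difference
#' at the first time point. The first value is exactly 1 by construction.
#'
#' @param series_mutant,series_control Numeric vectors of copies-per-focus
#'   values at matched time points, or lists of `cohesion_estimate` objects.
#' @param tol Baseline differences smaller than this (absolute) are treated
#'   as zero and raise an error.
#' @return Numeric vector of relative cohesion values.
#' @export
relative_cohesion_timecourse <- function(series_mutant, series_control,
                                         tol = 1e-12) {
  as_ratio <- function(s) {
    if (is.list(s)) vapply(s, function(e) e$copies_per_focus, numeric(1))
    else as.numeric(s)
  }
  m <- as_ratio(series_mutant)
  ctl <- as_ratio(series_control)
  if (length(m) != length(ctl))
    stop("mutant and control series must have matched time points",
         call. = FALSE)
  d <- m - ctl
  if (abs(d[1]) <= tol)
    stop_domain(paste0("mutant and control are identical at baseline ",
                       "(difference at t = 0 is zero); relative cohesion ",
                       "is undefined"))
  d / d[1]
}
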