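#' Classify reporter-expressing vs non-expressing cells
#'
#' Cells that fail to express the fluorescent repressor show low background
#' (non-focus) fluorescence and zero foci; leaving them in would inflate the
#' zero-focus fraction and hence the detection-inefficiency estimate. The
#' classifier performs an exact two-means split on log10 background
#' fluorescence (deterministic given the data) and thresholds at the
#' midpoint of the two cluster means. If the two clusters are not separable
#' (mean difference below `sep_factor` pooled within-cluster standard
#' deviations, as for a single Gaussian mode) a warning is raised and all
#' cells are classified as expressing.
#'
#' @param cells Data frame with at least columns `background_fluorescence`
#'   and `focus_count` (one row per cell).
#' @param min_cells Minimum number of cells required.
#' @param sep_factor Separability requirement: a split is accepted when the
#'   cluster-mean gap exceeds `sep_factor` times the pooled within-cluster
#'   SD (a single Gaussian yields a gap of ~1.6 SD under the optimal split,
#'   so the default 3 rejects unimodal data).
#' @return A list with `expressing` and `non_expressing` (row subsets of
#'   `cells`), `threshold` (on the original fluorescence scale, `NA` when no
#'   split was made), and `fraction_excluded`.
#' @export
classify_expressing_cells <- function(cells, min_cells = 20, sep_factor = 3) {
  stopifnot(is.data.frame(cells),
            all(c("background_fluorescence", "focus_count") %in% names(cells)))
  x <- cells$background_fluorescence
  if (length(x) < min_cells)
    stop(sprintf("need at least %d cells to classify expression", min_cells),
         call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("background fluorescence must be finite and non-negative",
         call. = FALSE)
  # log scale; guard zeros with half the smallest positive value
  pos <- x[x > 0]
  if (length(pos) == 0) stop("all background fluorescence values are zero",
                             call. = FALSE)
  lx <- log10(pmax(x, min(pos) / 2))

  sp <- split_two_means(lx)
  separable <- !is.null(sp) &&
    (sp$m2 - sp$m1) > sep_factor * max(sp$pooled_sd, .Machine$double.eps)
  if (!separable) {
    warning("background fluorescence is unimodal: no separable low mode; ",
            "classifying all cells as expressing", call. = FALSE)
    return(list(expressing = cells,
                non_expressing = cells[0, , drop = FALSE],
                threshold = NA_real_,
                fraction_excluded = 0))
  }
  thr_log <- (sp$m1 + sp$m2) / 2
  keep <- lx > thr_log
  list(expressing = cells[keep, , drop = FALSE],
       non_expressing = cells[!keep, , drop = FALSE],
       threshold = 10^thr_log,
       fraction_excluded = mean(!keep))
}

# Exact 1-D 2-means: minimizes total within-cluster sum of squares over all
# splits of the sorted values. Returns cluster means and pooled within SD.
split_two_means <- function(x) {
  n <- length(x)
  if (n < 2) return(NULL)
  xs <- sort(x)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  ss1 <- cs2[k] - cs[k]^2 / k
  ss2 <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  tot <- ss1 + ss2
  kb <- which.min(tot)
  list(m1 = cs[kb] / kb,
       m2 = (cs[n] - cs[kb]) / (n - kb),
       k = kb,
       pooled_sd = sqrt(tot[kb] / n))
}

#' Estimate focus-detection efficiency from the zero-focus fraction
#'
#' Every expressing cell carries at least one copy of the labelled locus, so
#' an expressing cell with zero foci represents a whole-cell detection
#' failure. The inefficiency `i` is estimated as the zero-focus fraction
#' among expressing cells and the efficiency as `e = 1 - i`.
#'
#' @param expressing_cells Data frame of expressing cells with a
#'   `focus_count` column (run [classify_expressing_cells()] first).
#' @return An object of class `detection_model`: list with `inefficiency`,
#'   `efficiency`, `n_cells`, `n_zero`.
#' @export
estimate_detection_efficiency <- function(expressing_cells) {
  stopifnot(is.data.frame(expressing_cells),
            "focus_count" %in% names(expressing_cells))
  fc <- expressing_cells$focus_count
  if (length(fc) < 1) stop("need at least one cell", call. = FALSE)
  n_zero <- sum(fc == 0)
  if (n_zero == length(fc))
    stop("all cells have zero foci: no detectable signal", call. = FALSE)
  i <- n_zero / length(fc)
  structure(list(inefficiency = i, efficiency = 1 - i,
                 n_cells = length(fc), n_zero = n_zero),
            class = "detection_model")
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf(
    "Detection model: efficiency %.3f (inefficiency %.3f; %d/%d zero-focus cells)\n",
    x$efficiency, x$inefficiency, x$n_zero, x$n_cells))
  invisible(x)
}

#' Correct mean foci per cell for detection inefficiency
#'
#' Under the whole-cell failure model a fraction `i` of cells report zero
#' foci regardless of their true focus number, so the observed population
#' mean is `e` times the true mean and the correction divides by the
#' efficiency: `corrected = raw / e`.
#'
#' @param raw_mean Observed mean foci per cell, `>= 0`.
#' @param model A `detection_model` (from [estimate_detection_efficiency()])
#'   or a single numeric efficiency in `(0, 1]`.
#' @return A list with `raw`, `corrected`, `correction_applied`
#'   (`corrected - raw`) and `efficiency`.
#' @examples
#' correct_foci_per_cell(1.52, 0.94)  # correction ~ +0.097
#' @export
correct_foci_per_cell <- function(raw_mean, model) {
  e <- if (inherits(model, "detection_model")) model$efficiency
       else as.numeric(model)
  if (!is.finite(e) || e <= 0 || e > 1)
    stop("efficiency must lie in (0, 1]", call. = FALSE)
  if (!is.finite(raw_mean) || raw_mean < 0)
    stop("raw mean foci per cell must be >= 0", call. = FALSE)
  corrected <- raw_mean / e
  list(raw = raw_mean, corrected = corrected,
       correction_applied = corrected - raw_mean, efficiency = e)
}

#' Validate detection correction on cohesion-free cells
#'
#' In non-replicating (e.g. stationary-phase) cells every chromosome is
#' fully segregated, so the corrected foci-per-cell value should equal the
#' chromosomes-per-cell number measured independently (flow cytometry).
#'
#' @param cells Data frame of expressing cells with `focus_count`.
#' @param chromosomes_per_cell Independent chromosomes-per-cell value.
#' @param model Optional `detection_model` or efficiency; when `NULL` the
#'   model is estimated from `cells`.
#' @param tolerance Absolute tolerance for the pass flag, foci per cell.
#' @return A list with `corrected_foci_per_cell`, `chromosomes_per_cell`,
#'   `abs_difference` and the logical `pass`.
#' @export
stationary_phase_validation <- function(cells, chromosomes_per_cell,
                                        model = NULL, tolerance = 0.05) {
  if (is.null(model)) model <- estimate_detection_efficiency(cells)
  corr <- correct_foci_per_cell(mean(cells$focus_count), model)
  diff <- abs(corr$corrected - chromosomes_per_cell)
  list(corrected_foci_per_cell = corr$corrected,
       chromosomes_per_cell = chromosomes_per_cell,
       abs_difference = diff,
       pass = diff <= tolerance)
}
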