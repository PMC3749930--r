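#' Sample steady-state cell ages
#'
#' Inverse-CDF sampler for the exponential-age distribution:
#' `a = -tau * log2(1 - u/2)` with `u ~ U(0, 1)`.
#'
#' @param n Number of cells.
#' @param generation_time Doubling time tau, minutes.
#' @return Ages in minutes, in `[0, tau)`.
#' @export
sample_cell_ages <- function(n, generation_time) {
  u <- stats::runif(n)
  -generation_time * log2(1 - u / 2)
}

rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Simulate an asynchronous FROS population
#'
#' Draws cell ages from the steady-state exponential-age distribution and
#' assigns each cell a locus copy state (2 copies once older than the locus
#' replication age) and a resolvable-focus state (2 foci once older than
#' replication age + cohesion duration). The observation layer then applies
#' (in order): injection of non-expressing cells (low background
#' fluorescence, zero foci), whole-cell detection failure (all foci missed
#' with probability `whole_cell_miss`), and optional independent per-focus
#' thinning. If cohesion would span division (`a_r + Delta > tau`) the foci
#' split age is capped at `tau` (each daughter inherits a single copy at
#' division) and the truth record flags `wraparound`.
#'
#' @param params A [cell_cycle_params()] object.
#' @param n_cells Number of cells.
#' @param whole_cell_miss Probability that a cell's foci all go undetected.
#' @param per_focus_miss Independent per-focus loss probability (off by
#'   default; the analysis assumes whole-cell failure).
#' @param non_expressing_fraction Fraction of cells not expressing the
#'   fluorescent repressor (typically 2-8%).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return Data frame with columns `cell_id`, `background_fluorescence`,
#'   `focus_count`, `age_min`, with attribute `truth` (list: exact
#'   pre-thinning mean copies and foci among sampled cells, the closed-form
#'   expectations, parameters, seed).
#' @export
simulate_async_population <- function(params, n_cells = 1000,
                                      whole_cell_miss = 0.014,
                                      per_focus_miss = 0,
                                      non_expressing_fraction = 0.05,
                                      seed = 1) {
  stopifnot(inherits(params, "cell_cycle_params"))
  for (p in c(whole_cell_miss, per_focus_miss, non_expressing_fraction))
    if (p < 0 || p >= 1) stop("probabilities must lie in [0, 1)",
                              call. = FALSE)
  tau <- params$generation_time
  ar <- params$locus_replication_age
  delta <- params$cohesion_duration
  split_age <- min(ar + delta, tau)
  wraparound <- ar + delta > tau

  withr::with_seed(seed, {
    age <- sample_cell_ages(n_cells, tau)
    copies <- 1L + (age >= ar)
    foci_true <- 1L + (age >= split_age)

    non_expr <- stats::runif(n_cells) < non_expressing_fraction
    bg <- ifelse(non_expr,
                 stats::rlnorm(n_cells, meanlog = log(10), sdlog = 0.15),
                 stats::rlnorm(n_cells, meanlog = log(100), sdlog = 0.15))
    miss <- stats::runif(n_cells) < whole_cell_miss
    observed <- ifelse(non_expr | miss, 0L, foci_true)
    if (per_focus_miss > 0) {
      kept <- stats::rbinom(n_cells, observed, 1 - per_focus_miss)
      observed <- kept
    }
  })

  out <- data.frame(cell_id = sprintf("cell%05d", seq_len(n_cells)),
                    background_fluorescence = bg,
                    focus_count = observed,
                    age_min = age)
  attr(out, "truth") <- list(
    mean_copies_sampled = mean(copies),
    mean_foci_sampled = mean(foci_true),
    expected_copies = 2^(1 - ar / tau),
    expected_foci = 2^(1 - split_age / tau),
    wraparound = wraparound,
    non_expressing_fraction = non_expressing_fraction,
    n_non_expressing = sum(non_expr),
    n_missed = sum(miss & !non_expr),
    whole_cell_miss = whole_cell_miss,
    params = params, n_cells = n_cells, seed = seed)
  out
}

#' Simulate a baby-machine synchronized time course
#'
#' Each sample time gets an independent cohort of `n_cells_per_sample`
#' cells. A fraction `synchrony_fraction` is synchronous: its locus
#' replication time is Gaussian around the locus replication age (SD
#' `event_sd`, truncated at 0) and its segregation time follows after the
#' cohesion duration. The asynchronous remainder has replication times
#' uniform on `[0, tau]` and segregates after the same cohesion duration
#' (no wraparound, so foci never exceed copies). Mean copy number and mean
#' foci per cell at each time carry the resulting binomial sampling noise.
#'
#' @param params A [cell_cycle_params()] object.
#' @param sample_times Sampling times, minutes after birth.
#' @param n_cells_per_sample Cells per sample.
#' @param synchrony_fraction Synchronous fraction phi in `(0, 1]`
#'   (baby-machine output is typically 0.75-0.85).
#' @param event_sd SD of the synchronous event-time spread, minutes.
#' @param seed Integer seed.
#' @return Data frame with columns `time_min`, `mean_copy_number`,
#'   `mean_foci`, `n_cells`, with attribute `truth`.
#' @export
simulate_synchronized_timecourse <- function(params,
                                             sample_times = seq(0, 120, 10),
                                             n_cells_per_sample = 1000,
                                             synchrony_fraction = 0.80,
                                             event_sd = 5,
                                             seed = 1) {
  stopifnot(inherits(params, "cell_cycle_params"))
  if (synchrony_fraction <= 0 || synchrony_fraction > 1)
    stop("synchrony fraction must lie in (0, 1]", call. = FALSE)
  tau <- params$generation_time
  ar <- params$locus_replication_age
  delta <- params$cohesion_duration

  withr::with_seed(seed, {
    rows <- lapply(sample_times, function(t) {
      n <- n_cells_per_sample
      sync <- stats::runif(n) < synchrony_fraction
      rep_time <- ifelse(sync,
                         rnorm_trunc0(n, ar, event_sd),
                         stats::runif(n, 0, tau))
      seg_time <- rep_time + delta
      data.frame(time_min = t,
                 mean_copy_number = 1 + mean(rep_time <= t),
                 mean_foci = 1 + mean(seg_time <= t),
                 n_cells = n)
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(
    replication_age = ar, cohesion = delta, generation_time = tau,
    synchrony_fraction = synchrony_fraction, event_sd = event_sd,
    seed = seed)
  out
}

#' Simulate qPCR Ct tables for known template quantities
#'
#' Ct values follow `Ct = intercept - log(quantity) / log(1 + E) + noise`
#' so that on noise-free output [relative_ratio()] recovers quantity ratios
#' exactly.
#'
#' @param quantities Named numeric vector of true template quantities.
#' @param efficiency Amplification efficiency `E` in `(0, 1]`.
#' @param ct_sd Gaussian Ct noise SD, cycles.
#' @param intercept Ct of a unit quantity, cycles.
#' @param replicates Replicates per target.
#' @param sample_id Sample identifier.
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `target`, `replicate`,
#'   `ct`, with attribute `truth`.
#' @export
simulate_qpcr <- function(quantities, efficiency = 1, ct_sd = 0.1,
                          intercept = 25, replicates = 3,
                          sample_id = "S1", seed = 1) {
  stopifnot(!is.null(names(quantities)), all(quantities > 0))
  withr::with_seed(seed, {
    rows <- lapply(names(quantities), function(tg) {
      ct0 <- intercept - log(quantities[[tg]]) / log(1 + efficiency)
      data.frame(sample_id = sample_id, target = tg,
                 replicate = seq_len(replicates),
                 ct = ct0 + stats::rnorm(replicates, 0, ct_sd))
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(quantities = quantities,
                             efficiency = efficiency, ct_sd = ct_sd,
                             intercept = intercept, seed = seed)
  out
}

#' Build a qpcr_record from a simulated (or read) Ct table
#'
#' @param ct_table Data frame with columns `sample_id`, `target`, `ct`.
#' @param target Target name to extract.
#' @param efficiency Amplification efficiency for the record.
#' @return A [qpcr_record()].
#' @export
ct_table_record <- function(ct_table, target, efficiency = 1) {
  rows <- ct_table[ct_table$target == target, , drop = FALSE]
  if (nrow(rows) == 0) stop(sprintf("target '%s' not in table", target),
                            call. = FALSE)
  qpcr_record(rows$sample_id[1], target, rows$ct,
              amplification_efficiency = efficiency)
}

#' Simulate ChIP-qPCR Ct pairs for known fold enrichments
#'
#' Input Cts are drawn around a common base; IP Cts are offset by
#' `-log2(fold)` relative to the reference locus so that
#' [chip_fold_enrichment()] recovers the planted folds.
#'
#' @param folds Named numeric vector of true fold enrichments (reference
#'   locus fold 1).
#' @param reference_locus Reference locus name (must be in `folds`).
#' @param ct_input_base Mean input Ct, cycles.
#' @param ct_ip_base Mean IP Ct of the reference locus, cycles.
#' @param ct_sd Gaussian Ct noise SD, cycles.
#' @param replicates Replicates per locus.
#' @param seed Integer seed.
#' @return Data frame with columns `locus`, `replicate`, `ct_ip`,
#'   `ct_input`, with attribute `truth`.
#' @export
simulate_chip_qpcr <- function(folds, reference_locus = "dnaB",
                               ct_input_base = 20, ct_ip_base = 28,
                               ct_sd = 0.1, replicates = 3, seed = 1) {
  stopifnot(!is.null(names(folds)), reference_locus %in% names(folds),
            all(folds > 0))
  withr::with_seed(seed, {
    rows <- lapply(names(folds), function(lc) {
      rel <- folds[[lc]] / folds[[reference_locus]]
      data.frame(locus = lc, replicate = seq_len(replicates),
                 ct_ip = ct_ip_base - log2(rel) +
                   stats::rnorm(replicates, 0, ct_sd),
                 ct_input = ct_input_base + stats::rnorm(replicates, 0, ct_sd))
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(folds = folds, seed = seed)
  out
}

#' Simulate a rifampicin-runoff histogram
#'
#' Cells carry 2^n origins (synchronous initiation); post-runoff DNA
#' content per cell is Gaussian around its origin count with a shared
#' coefficient of variation, binned into a fluorescence histogram in
#' chromosome-equivalent units.
#'
#' @param origins_distribution Named probability vector over origin counts
#'   (names from 1, 2, 4, 8), summing to 1.
#' @param n_cells Number of cells.
#' @param cv Shared coefficient of variation of each peak.
#' @param bin_width Histogram bin width, chromosome equivalents.
#' @param seed Integer seed.
#' @return A [runoff_histogram()] with attribute `truth` (including the
#'   exact sampled mean origins per cell).
#' @export
simulate_runoff_histogram <- function(origins_distribution = c("1" = 0.06,
                                                               "2" = 0.94),
                                      n_cells = 10000, cv = 0.08,
                                      bin_width = 0.02, seed = 1) {
  ns <- as.numeric(names(origins_distribution))
  stopifnot(all(ns %in% c(1, 2, 4, 8)), abs(sum(origins_distribution) - 1) < 1e-8,
            cv > 0)
  withr::with_seed(seed, {
    n_org <- ns[sample.int(length(ns), n_cells, replace = TRUE,
                           prob = origins_distribution)]
    fl <- stats::rnorm(n_cells, mean = n_org, sd = cv * n_org)
  })
  fl <- pmax(fl, bin_width / 2)
  breaks <- seq(0, ceiling(max(fl) / bin_width) * bin_width, by = bin_width)
  h <- graphics::hist(fl, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0 | (h$mids > min(fl) & h$mids < max(fl))
  out <- runoff_histogram(h$mids[keep], h$counts[keep])
  attr(out, "truth") <- list(origins_distribution = origins_distribution,
                             mean_origins_sampled = mean(n_org),
                             mean_origins_expected = sum(ns * origins_distribution),
                             cv = cv, n_cells = n_cells, seed = seed)
  out
}

#' Simulate a circular genome with controlled GATC placement
#'
#' Generates a random background sequence, removes accidental GATC
#' occurrences, then plants GATC sites as a Poisson process at
#' `gatc_rate` per bp (multiplied by `snap_multiplier` inside the given
#' snap windows), so motif density is under direct control. A binding
#' track is derived as the 5-kb moving average of GATC density at regular
#' probe positions plus Gaussian noise, and a locus table is emitted whose
#' cohesion durations increase monotonically with the local (5-kb) density
#' - i.e. the cohesion signal is planted at the 5-kb scale.
#'
#' @param genome_length Genome length, bp (>= 10 kb).
#' @param gatc_rate Background planting rate, sites per bp.
#' @param snap_windows Data frame with `start`, `end` (bp) of high-density
#'   windows, or `NULL`.
#' @param snap_multiplier Density multiplier inside snap windows.
#' @param probe_spacing Binding-track probe spacing, bp.
#' @param track_noise_sd Gaussian noise SD added to the binding track.
#' @param n_loci Number of annotated loci.
#' @param seed Integer seed.
#' @return A list with `sequence` (character), `gatc_positions`, `track`
#'   (noisy binding [genome_track()]), `loci` (data frame with `name`,
#'   `position`, `cohesion_minutes`, `class`), and `truth`.
#' @export
simulate_genome <- function(genome_length = 200000, gatc_rate = 1 / 256,
                            snap_windows = NULL, snap_multiplier = 3,
                            probe_spacing = 500, track_noise_sd = 0.05,
                            n_loci = 12, seed = 1) {
  if (genome_length < 10000)
    stop("genome length must be at least 10 kb", call. = FALSE)
  withr::with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
    # remove accidental GATCs so density is fully controlled
    repeat {
      seq_str <- paste(bases, collapse = "")
      hits <- motif_positions(seq_str, "GATC", circular = TRUE)
      if (length(hits) == 0) break
      swap <- ((hits + 1) - 1) %% genome_length + 1   # the 'A' slot
      bases[swap] <- sample(c("C", "G", "T"), length(swap), replace = TRUE)
    }
    rate <- rep(gatc_rate, genome_length)
    in_snap <- rep(FALSE, genome_length)
    if (!is.null(snap_windows)) {
      for (i in seq_len(nrow(snap_windows))) {
        idx <- snap_windows$start[i]:snap_windows$end[i]
        in_snap[idx] <- TRUE
      }
      rate[in_snap] <- gatc_rate * snap_multiplier
    }
    cand <- which(stats::runif(genome_length) < rate)
    # keep planted sites at least 4 bp apart and clear of the junction
    if (length(cand) > 1) cand <- cand[c(TRUE, diff(cand) >= 4)]
    cand <- cand[cand <= genome_length - 3]
    for (p in cand) bases[p:(p + 3)] <- c("G", "A", "T", "C")
    seq_str <- paste(bases, collapse = "")

    locus_pos <- sort(sample.int(genome_length - 3, n_loci))
    dens <- window_density(motif_positions(seq_str), genome_length,
                           window_bp = probe_spacing)
    sm5 <- moving_average(dens, 5000)
    track <- genome_track(sm5$position,
                          sm5$value + stats::rnorm(nrow(sm5), 0,
                                                   track_noise_sd),
                          genome_length, window_bp = 5000)
  })
  # cohesion planted as a monotone function of local 5-kb density
  local5 <- vapply(locus_pos, function(p) {
    d <- abs(sm5$position - p); d <- pmin(d, genome_length - d)
    sm5$value[which.min(d)]
  }, numeric(1))
  rng <- range(local5)
  scaled <- if (diff(rng) > 0) (local5 - rng[1]) / diff(rng)
            else rep(0.5, n_loci)
  cohesion <- 7 + 23 * scaled   # 7 min (non-snap) up to 30 min (snap)
  cls <- ifelse(in_snap[locus_pos], "snap", "non-snap")
  loci <- data.frame(name = sprintf("locus%02d", seq_len(n_loci)),
                     position = locus_pos,
                     cohesion_minutes = cohesion,
                     class = cls)
  list(sequence = seq_str,
       gatc_positions = motif_positions(seq_str),
       track = track,
       loci = loci,
       truth = list(gatc_rate = gatc_rate, snap_multiplier = snap_multiplier,
                    snap_windows = snap_windows, planted = cand, seed = seed))
}

#' Simulate sister-focus separation time-lapse trajectories
#'
#' Each cell splits its focus at a Gaussian-distributed true time, after
#' which the true inter-sister distance grows in two phases: a fast phase
#' (`fast_rate` for `fast_duration` minutes) followed by growth at the
#' cell-elongation rate. Observed focus positions carry Gaussian noise;
#' when the noisy pair lies within the optical resolution limit it is
#' emitted as a single (merged) focus, so sub-resolution distances never
#' appear in the output.
#'
#' @param n_cells Number of cells.
#' @param split_time_mean,split_time_sd True split-time distribution,
#'   minutes (truncated at 0).
#' @param fast_rate Fast-phase separation speed, um/min.
#' @param fast_duration Fast-phase duration, minutes.
#' @param elongation_rate Slow-phase (cell elongation) speed, um/min.
#' @param frame_interval Imaging interval, minutes.
#' @param total_time Movie length, minutes.
#' @param position_noise_sd Gaussian localization noise per coordinate, um.
#' @param resolution_limit Optical resolution, um.
#' @param seed Integer seed.
#' @return Long-format trajectory data frame (`cell_id`, `time_min`,
#'   `focus_index`, `x_um`, `y_um`) with attribute `truth` (per-cell true
#'   split times and the kinetic parameters).
#' @export
simulate_timelapse <- function(n_cells = 10, split_time_mean = 30,
                               split_time_sd = 8, fast_rate = 0.4,
                               fast_duration = 2.5, elongation_rate = 0.02,
                               frame_interval = 10, total_time = 120,
                               position_noise_sd = 0.03,
                               resolution_limit = 0.23, seed = 1) {
  if (frame_interval <= 0) stop("frame interval must be positive",
                                call. = FALSE)
  frames <- seq(0, total_time, by = frame_interval)
  withr::with_seed(seed, {
    split_true <- rnorm_trunc0(n_cells, split_time_mean, split_time_sd)
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      x0 <- stats::runif(1, 1, 3)
      y0 <- stats::runif(1, 0.4, 0.6)
      cell_rows <- lapply(frames, function(t) {
        dt <- t - split_true[i]
        d_true <- if (dt < 0) 0
                  else fast_rate * min(dt, fast_duration) +
                       elongation_rate * max(0, dt - fast_duration)
        if (d_true == 0) {
          data.frame(cell_id = sprintf("cell%03d", i), time_min = t,
                     focus_index = 1L,
                     x_um = x0 + stats::rnorm(1, 0, position_noise_sd),
                     y_um = y0 + stats::rnorm(1, 0, position_noise_sd))
        } else {
          p1 <- c(x0 - d_true / 2, y0) + stats::rnorm(2, 0, position_noise_sd)
          p2 <- c(x0 + d_true / 2, y0) + stats::rnorm(2, 0, position_noise_sd)
          if (sqrt(sum((p1 - p2)^2)) < resolution_limit) {
            data.frame(cell_id = sprintf("cell%03d", i), time_min = t,
                       focus_index = 1L,
                       x_um = (p1[1] + p2[1]) / 2, y_um = (p1[2] + p2[2]) / 2)
          } else {
            data.frame(cell_id = rep(sprintf("cell%03d", i), 2), time_min = t,
                       focus_index = 1:2,
                       x_um = c(p1[1], p2[1]), y_um = c(p1[2], p2[2]))
          }
        }
      })
      rows[[i]] <- do.call(rbind, cell_rows)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(split_times = split_true,
                             fast_rate = fast_rate,
                             fast_duration = fast_duration,
                             elongation_rate = elongation_rate,
                             frame_interval = frame_interval,
                             position_noise_sd = position_noise_sd,
                             resolution_limit = resolution_limit,
                             seed = seed)
  out
}
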