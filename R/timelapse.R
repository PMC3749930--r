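#' Split trajectory table into per-cell tables
#'
#' @param trajectories Long-format trajectory data frame with columns
#'   `cell_id`, `time_min`, `focus_index`, `x_um`, `y_um`.
#' @return Named list of single-cell data frames.
#' @export
split_trajectories <- function(trajectories) {
  stopifnot(is.data.frame(trajectories),
            all(c("cell_id", "time_min", "focus_index", "x_um", "y_um") %in%
                  names(trajectories)))
  split(trajectories, trajectories$cell_id)
}

frame_table <- function(traj) {
  times <- sort(unique(traj$time_min))
  counts <- vapply(times, function(t) sum(traj$time_min == t), integer(1))
  data.frame(time_min = times, n_foci = counts)
}

frame_distance <- function(traj, t) {
  f <- traj[traj$time_min == t, , drop = FALSE]
  if (nrow(f) < 2) return(NA_real_)
  f <- f[order(f$focus_index), , drop = FALSE]
  sqrt((f$x_um[1] - f$x_um[2])^2 + (f$y_um[1] - f$y_um[2])^2)
}

#' Detect the focus-splitting frame of a trajectory
#'
#' The split time is the first frame at which two resolvable foci appear.
#' Transient re-merging in later frames (sisters drifting back within the
#' optical resolution limit) does not reset the split time, so split
#' detection is monotone: appending frames never changes an already
#' detected split.
#'
#' @param traj Single-cell trajectory data frame (see
#'   [split_trajectories()]).
#' @return Split frame time in minutes, or `NA` if the cell never shows two
#'   foci (a no-split result, not an error).
#' @export
detect_split <- function(traj) {
  if (length(unique(traj$cell_id)) > 1)
    stop("detect_split expects a single cell; see split_trajectories()",
         call. = FALSE)
  ft <- frame_table(traj)
  hit <- which(ft$n_foci >= 2)
  if (length(hit) == 0) return(NA_real_)
  ft$time_min[hit[1]]
}

#' Separation kinetics of one sister-focus trajectory
#'
#' Summarizes post-split inter-focus distances. Because sisters become
#' resolvable only beyond the optical resolution limit, and may already
#' have moved during the frame interval, the first post-split distance
#' gives only a lower bound on the initial separation velocity:
#' `(d_first - resolution_limit) / frame_interval`. Two regression slopes
#' are reported as well: `early_slope` over frames within `early_window`
#' minutes of the split (the ~0.15 um/min scale readout) and `late_slope`
#' over the remaining frames (the cell-elongation rate, ~0.02 um/min).
#'
#' @param traj Single-cell trajectory data frame.
#' @param resolution_limit Optical resolution, um (default 0.23).
#' @param early_window Early-phase regression window after the split,
#'   minutes.
#' @return An object of class `separation_summary`: list with
#'   `split_frame_time`, `distances` (data frame of post-split times and
#'   distances), `initial_velocity_lower_bound`, `early_slope`,
#'   `late_slope`, and `flags` (character vector; `"no_split"` or
#'   `"few_frames"` mark partial summaries).
#' @export
separation_kinetics <- function(traj, resolution_limit = 0.23,
                                early_window = 20) {
  split_t <- detect_split(traj)
  if (is.na(split_t))
    return(structure(list(split_frame_time = NA_real_,
                          distances = data.frame(time_min = numeric(),
                                                 distance_um = numeric()),
                          initial_velocity_lower_bound = NA_real_,
                          early_slope = NA_real_, late_slope = NA_real_,
                          flags = "no_split"),
                     class = "separation_summary"))
  ft <- frame_table(traj)
  frame_interval <- stats::median(diff(ft$time_min))
  post <- ft$time_min[ft$time_min >= split_t]
  d <- vapply(post, function(t) frame_distance(traj, t), numeric(1))
  keep <- !is.na(d)               # re-merged frames carry no distance
  dist_df <- data.frame(time_min = post[keep], distance_um = d[keep])

  flags <- character()
  if (nrow(dist_df) < 3) flags <- c(flags, "few_frames")

  lb <- (dist_df$distance_um[1] - resolution_limit) / frame_interval

  rel_t <- dist_df$time_min - split_t
  early <- rel_t <= early_window
  slope_of <- function(t, y) {
    if (length(t) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(y ~ t))[2])
  }
  structure(list(split_frame_time = split_t,
                 distances = dist_df,
                 initial_velocity_lower_bound = lb,
                 early_slope = slope_of(dist_df$time_min[early],
                                        dist_df$distance_um[early]),
                 late_slope = slope_of(dist_df$time_min[!early],
                                       dist_df$distance_um[!early]),
                 flags = flags),
            class = "separation_summary")
}

#' @export
print.separation_summary <- function(x, ...) {
  cat(sprintf("Separation: split at %.0f min; v0 lower bound %.3f um/min\n",
              x$split_frame_time, x$initial_velocity_lower_bound))
  cat(sprintf("  early slope %.3f um/min, late slope %.3f um/min\n",
              x$early_slope, x$late_slope))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Population inter-focus distance distribution
#'
#' Histogram, mean and modal bin of inter-sister distances from a snapshot
#' of two-focus cells, with an optional two-component Gaussian-mixture
#' bimodality report (non-snap loci typically show a bimodal distribution:
#' an initial separation step and a later larger one).
#'
#' @param distances Numeric vector of inter-focus distances, um (one per
#'   two-focus cell).
#' @param bin_width Histogram bin width, um.
#' @param min_cells Minimum number of cells required.
#' @param bimodality Fit a 1-vs-2 component Gaussian mixture (BIC-selected)
#'   and report the verdict.
#' @return A list with `histogram` (data frame of `bin_center`, `count`),
#'   `mean`, `mode` (center of the most populated bin; ties broken toward
#'   the smaller distance), `bimodal` (logical or `NA` when not assessed)
#'   and `component_means`.
#' @export
distance_distribution <- function(distances, bin_width = 0.2, min_cells = 50,
                                  bimodality = TRUE) {
  distances <- distances[is.finite(distances)]
  if (length(distances) < min_cells)
    stop(sprintf("need at least %d two-focus cells", min_cells),
         call. = FALSE)
  breaks <- seq(0, ceiling(max(distances) / bin_width) * bin_width,
                by = bin_width)
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE)
  centers <- h$mids
  counts <- h$counts
  mode_bin <- centers[which.max(counts)]   # which.max takes the first max

  bimodal <- NA
  comp_means <- NULL
  if (bimodality) {
    fit <- mclust::Mclust(distances, G = 1:2, verbose = FALSE)
    bimodal <- fit$G == 2
    comp_means <- as.numeric(fit$parameters$mean)
  }
  list(histogram = data.frame(bin_center = centers, count = counts),
       mean = mean(distances),
       mode = mode_bin,
       bimodal = bimodal,
       component_means = comp_means)
}
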