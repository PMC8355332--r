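## Single-cell migration statistics from microfluidic track tables.
##
## A track set is a data frame (cell_id, t_min, x_um, y_um).  Velocity is
## the net displacement projected on the channel axis divided by elapsed
## time (the chip measures directed transit through straight channels, so
## net axial motion is the natural observable); a path-length speed is
## available behind a flag.  Velocities are reported in um/h.

#' Construct a track set
#'
#' @param df data frame with columns `cell_id`, `t_min`, `x_um`, `y_um`.
#' @param channel_axis unit vector of the channel direction (default +x).
#' @return a `track_set` data frame.
#' @export
track_set <- function(df, channel_axis = c(1, 0)) {
  need <- c("cell_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("track table must have columns cell_id, t_min, x_um, y_um",
         call. = FALSE)
  df <- df[order(df$cell_id, df$t_min), , drop = FALSE]
  rownames(df) <- NULL
  counts <- table(df$cell_id)
  if (any(counts < 2))
    stop("every track needs at least 2 samples", call. = FALSE)
  bad <- tapply(df$t_min, df$cell_id, function(t) any(diff(t) <= 0))
  if (any(bad))
    stop("per-cell times must be strictly increasing (duplicate timestamps?)",
         call. = FALSE)
  channel_axis <- channel_axis / sqrt(sum(channel_axis^2))
  structure(df, class = c("track_set", "data.frame"),
            channel_axis = channel_axis)
}

#' Net axial migration velocity of one cell track
#'
#' Net displacement between the first and last sample, projected on the
#' channel axis, divided by elapsed time; negative if the net motion is
#' against the axis.  With `path_length = TRUE` the total path length per
#' elapsed time (always non-negative) is returned instead.
#'
#' @param track data frame for a single cell (`t_min`, `x_um`, `y_um`).
#' @param axis channel axis unit vector (default +x).
#' @param path_length use total path length instead of net displacement.
#' @return velocity in um/h.
#' @examples
#' per_cell_velocity(data.frame(t_min = c(0, 60), x_um = c(0, 18.4),
#'                              y_um = c(0, 0)))   # 18.4
#' @export
per_cell_velocity <- function(track, axis = c(1, 0), path_length = FALSE) {
  t <- track$t_min
  if (any(duplicated(t)))
    stop("duplicate timestamps in track", call. = FALSE)
  o <- order(t)
  t <- t[o]; x <- track$x_um[o]; y <- track$y_um[o]
  elapsed_h <- (t[length(t)] - t[1]) / 60
  if (elapsed_h <= 0) stop("track duration must be positive", call. = FALSE)
  if (path_length)
    return(sum(sqrt(diff(x)^2 + diff(y)^2)) / elapsed_h)
  axis <- axis / sqrt(sum(axis^2))
  disp <- c(x[length(x)] - x[1], y[length(y)] - y[1])
  sum(disp * axis) / elapsed_h
}

#' Cohort migration statistics for a track set
#'
#' @param tracks a [track_set] (or plain data frame with the same columns).
#' @param path_length see [per_cell_velocity()].
#' @return a `migration_stats` list: `velocity` (per-cell, um/h), `mean`,
#'   `sd`, `median`, `q1`, `q3`, `n_cells`.
#' @export
cohort_stats <- function(tracks, path_length = FALSE) {
  if (!inherits(tracks, "track_set")) tracks <- track_set(tracks)
  axis <- attr(tracks, "channel_axis")
  ids <- unique(tracks$cell_id)
  if (length(ids) == 0) stop("empty track set", call. = FALSE)
  v <- vapply(ids, function(id)
    per_cell_velocity(tracks[tracks$cell_id == id, , drop = FALSE],
                      axis = axis, path_length = path_length),
    numeric(1))
  qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(velocity = stats::setNames(v, ids),
                 mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 median = qs[2], q1 = qs[1], q3 = qs[3],
                 n_cells = length(v)),
            class = "migration_stats")
}

#' @export
print.migration_stats <- function(x, ...) {
  cat(sprintf("migration: %d cells, mean %.2f +/- %.2f um/h (median %.2f)\n",
              x$n_cells, x$mean, x$sd, x$median))
  invisible(x)
}

#' Migration inhibition percentage
#'
#' @param mean_control control cohort mean velocity, um/h (> 0).
#' @param mean_treated treated cohort mean velocity, um/h.
#' @return 100 (mean_control - mean_treated) / mean_control.
#' @examples
#' inhibition_percent(18.4, 11.2)   # 39.13
#' @export
inhibition_percent <- function(mean_control, mean_treated) {
  if (!is.numeric(mean_control) || mean_control <= 0)
    stop("'mean_control' must be positive", call. = FALSE)
  100 * (mean_control - mean_treated) / mean_control
}
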