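# Per-cell and ensemble migration statistics: path length, net
# displacement, velocity, and the ensemble mean squared displacement with
# its linear fit.

.as_xy <- function(traj) {
  if (is.matrix(traj)) {
    xy <- traj
  } else if (is.data.frame(traj)) {
    stopifnot(all(c("x_um", "y_um") %in% names(traj)))
    if ("frame" %in% names(traj)) traj <- traj[order(traj$frame), ]
    xy <- cbind(traj$x_um, traj$y_um)
  } else stop("trajectory must be a matrix or data frame", call. = FALSE)
  if (nrow(xy) < 2) stop("trajectory needs at least 2 positions", call. = FALSE)
  xy
}

#' Total distance travelled
#'
#' Cumulative path length: the sum of Euclidean frame-to-frame step
#' lengths, in um.
#'
#' @param traj Two-column matrix of positions (um), or a data frame with
#'   `x_um`, `y_um` (ordered by `frame` if present).
#' @return Total distance in um.
#' @export
total_distance <- function(traj) {
  xy <- .as_xy(traj)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Net displacement
#'
#' Straight-line distance between a cell's first and last positions, in
#' um. Always bounded above by [total_distance()], with equality only for
#' ballistic (collinear, same-directed) paths.
#'
#' @inheritParams total_distance
#' @return Net displacement in um.
#' @export
net_displacement <- function(traj) {
  xy <- .as_xy(traj)
  sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
}

#' Migration velocity
#'
#' Two estimators are exposed because published velocity definitions are
#' often implicit: `path_over_time` (default) divides the total path
#' length by the elapsed time; `mean_step_speed` averages per-step speeds.
#' For a uniform frame interval the two are algebraically identical.
#'
#' @inheritParams total_distance
#' @param frame_interval Minutes between consecutive positions.
#' @param mode `"path_over_time"` or `"mean_step_speed"`.
#' @return Velocity in um/h.
#' @export
velocity <- function(traj, frame_interval = 15,
                     mode = c("path_over_time", "mean_step_speed")) {
  mode <- match.arg(mode)
  xy <- .as_xy(traj)
  dt_h <- frame_interval / 60
  steps <- sqrt(rowSums(diff(xy)^2))
  switch(mode,
    path_over_time = sum(steps) / (length(steps) * dt_h),
    mean_step_speed = mean(steps / dt_h))
}

#' Per-cell migration metrics for a tracked cohort
#'
#' @param tracks Tibble with `cell_id`, `frame`, `x_um`, `y_um` and
#'   optionally `group`, `replicate`.
#' @param frame_interval Minutes between frames (taken from the tracks'
#'   attribute when present).
#' @param mode Velocity estimator, see [velocity()].
#' @return Tibble with one row per cell: `velocity_umph`,
#'   `total_distance_um`, `net_displacement_um`, `n_steps`.
#' @export
cell_metrics <- function(tracks, frame_interval = NULL,
                         mode = c("path_over_time", "mean_step_speed")) {
  mode <- match.arg(mode)
  frame_interval <- frame_interval %||% attr(tracks, "frame_interval") %||% 15
  keys <- intersect(c("group", "replicate", "cell_id"), names(tracks))
  dt_h <- frame_interval / 60
  tracks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      n_steps = dplyr::n() - 1L,
      total_distance_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
      net_displacement_um = sqrt((dplyr::last(.data$x_um) - dplyr::first(.data$x_um))^2 +
                                 (dplyr::last(.data$y_um) - dplyr::first(.data$y_um))^2),
      velocity_umph = if (mode == "path_over_time") {
        total_distance_um / (n_steps * dt_h)
      } else {
        mean(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2) / dt_h)
      },
      .groups = "drop")
}

#' Ensemble mean squared displacement
#'
#' For N complete, equal-length trajectories, the ensemble MSD at lag
#' t = k * dt is the mean over cells of the squared displacement from the
#' initial position, `MSD(t) = (1/N) * sum_i ||x_i(t) - x_i(0)||^2`. An
#' ordinary least-squares line (free intercept) is fitted over all lags
#' and the coefficient of determination R^2 reported as the linearity
#' measure; linear growth is the signature of diffusive (random-walk)
#' motion, while directed motion bends the curve upward.
#'
#' @inheritParams cell_metrics
#' @return An object of class `msd_curve`: tibble-convertible lags (h),
#'   MSD (um^2), number of cells, and fit slope (um^2/h), intercept
#'   (um^2) and `r_squared`.
#' @export
ensemble_msd <- function(tracks, frame_interval = NULL) {
  frame_interval <- frame_interval %||% attr(tracks, "frame_interval") %||% 15
  keys <- intersect(c("group", "replicate", "cell_id"), names(tracks))
  if (length(keys) == 0) stop("tracks need a cell identifier", call. = FALSE)
  tracks <- dplyr::arrange(tracks,
    dplyr::across(dplyr::all_of(c(keys, "frame"))))
  counts <- dplyr::count(tracks, dplyr::across(dplyr::all_of(keys)))
  if (nrow(counts) == 0) stop("no trajectories", call. = FALSE)
  len <- unique(counts$n)
  if (length(len) != 1) {
    stop("ragged trajectory lengths; ensemble MSD needs complete tracks",
         call. = FALSE)
  }
  n_cells <- nrow(counts)
  X <- matrix(tracks$x_um, nrow = len)
  Y <- matrix(tracks$y_um, nrow = len)
  disp2 <- sweep(X, 2, X[1, ])^2 + sweep(Y, 2, Y[1, ])^2
  msd <- rowMeans(disp2)[-1]
  lag_h <- seq_len(len - 1) * frame_interval / 60
  fit <- stats::lm(msd ~ lag_h)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((msd - mean(msd))^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, mean(msd)^2)) {
    if (ss_res <= 1e-12) 1 else 0
  } else 1 - ss_res / ss_tot
  structure(
    list(lag_h = lag_h, msd_um2 = msd, n_cells = n_cells,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2),
    class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf(
    "Ensemble MSD: %d cells, %d lags up to %.2f h\n  fit: slope %.3g um^2/h, intercept %.3g um^2, R^2 = %.4f\n",
    x$n_cells, length(x$lag_h), max(x$lag_h), x$slope, x$intercept,
    x$r_squared))
  invisible(x)
}

#' @export
as.data.frame.msd_curve <- function(x, ...) {
  data.frame(lag_h = x$lag_h, msd_um2 = x$msd_um2)
}

#' Classify an MSD curve as random-walk consistent or not
#'
#' A curve is `RANDOM_WALK_CONSISTENT` when the linear fit's R^2 reaches
#' the threshold; the label always accompanies the underlying R^2, never
#' replaces it.
#'
#' @param curve An [ensemble_msd()] result with at least 3 lags.
#' @param r2_threshold Linearity threshold on R^2.
#' @return List with `label`, `r_squared`, `r2_threshold`.
#' @export
classify_motion <- function(curve, r2_threshold = 0.99) {
  stopifnot(inherits(curve, "msd_curve"))
  if (length(curve$lag_h) < 3) stop("need at least 3 lags", call. = FALSE)
  list(label = if (curve$r_squared >= r2_threshold)
         "RANDOM_WALK_CONSISTENT" else "NOT_LINEAR",
       r_squared = curve$r_squared, r2_threshold = r2_threshold)
}
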