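# Track recovery from label movies: per-frame centroid detection, greedy
# nearest-neighbour frame-to-frame linking with a hard distance gate, and
# the trajectory inclusion filters applied before any statistics.

#' Detect labelled-object centroids in one frame
#'
#' One centroid per distinct nonzero label: the unweighted mean of the
#' member pixel centres (0-based indices), converted to um. An empty image
#' yields an empty frame, not an error.
#'
#' @param img Nonnegative integer matrix (label image; 0 = background).
#' @param pixel_size um per pixel.
#' @param frame_index Frame number carried into the result.
#' @return Tibble `frame, label, x_um, y_um` (x along columns, y along
#'   rows).
#' @export
detect_centroids <- function(img, pixel_size = 1, frame_index = 1L) {
  idx <- which(img != 0L)
  if (length(idx) == 0) {
    return(tibble::tibble(frame = integer(), label = integer(),
                          x_um = numeric(), y_um = numeric()))
  }
  lab <- img[idx]
  if (any(lab < 0)) stop("label image must be nonnegative", call. = FALSE)
  nr <- nrow(img)
  ri <- (idx - 1L) %% nr          # 0-based row
  ci <- (idx - 1L) %/% nr         # 0-based col
  y <- tapply(ri, lab, mean) * pixel_size
  x <- tapply(ci, lab, mean) * pixel_size
  tibble::tibble(frame = as.integer(frame_index),
                 label = as.integer(names(x)),
                 x_um = unname(as.numeric(x)), y_um = unname(as.numeric(y)))
}

#' Detect centroids in every frame of a label movie
#'
#' @param movie A `label_movie` (see [render_label_movie()]).
#' @return Tibble of per-frame detections (`frame, label, x_um, y_um`).
#' @export
detect_movie <- function(movie) {
  stopifnot(inherits(movie, "label_movie"))
  dplyr::bind_rows(lapply(seq_along(movie$frames), function(f)
    detect_centroids(movie$frames[[f]], movie$pixel_size, f)))
}

#' Link detections into trajectories
#'
#' Greedy nearest-neighbour linking: for each consecutive frame pair, all
#' candidate (track end, detection) pairs are sorted by ascending distance
#' and accepted greedily while both ends are unassigned and the distance
#' does not exceed `max_step`. Unmatched detections start new tracks;
#' tracks that fail to match are terminated (no gap closing — a track that
#' disappears for one frame is over, and any successor is a new, shorter
#' track that the completeness filter will drop).
#'
#' @param detections Tibble `frame, x_um, y_um` (ignores `label`), frames
#'   consecutively indexed from the first frame present.
#' @param max_step Hard gate in um per frame interval. The default 30 um
#'   per 15-min frame (about 120 um/h) is roughly ten times the calibrated
#'   median cell speed.
#' @return Tibble `cell_id, frame, x_um, y_um` ordered by track and frame.
#' @export
link_trajectories <- function(detections, max_step = 30) {
  frames <- sort(unique(detections$frame))
  if (length(frames) == 0) {
    return(tibble::tibble(cell_id = integer(), frame = integer(),
                          x_um = numeric(), y_um = numeric()))
  }
  det <- split(detections[c("frame", "x_um", "y_um")], detections$frame)
  first <- det[[1]]
  n0 <- nrow(first)
  rows <- list(tibble::tibble(cell_id = seq_len(n0), frame = first$frame,
                              x_um = first$x_um, y_um = first$y_um))
  active_id <- seq_len(n0)
  active_xy <- cbind(first$x_um, first$y_um)
  next_id <- n0 + 1L
  for (fi in seq_along(frames)[-1]) {
    d <- det[[fi]]
    nd <- nrow(d)
    if (length(active_id) == 0L || nd == 0L) {
      assign_track <- rep(NA_integer_, nd)
    } else {
      dx <- outer(active_xy[, 1], d$x_um, "-")
      dy <- outer(active_xy[, 2], d$y_um, "-")
      dist <- sqrt(dx^2 + dy^2)
      ord <- order(dist)
      assign_track <- rep(NA_integer_, nd)
      used_track <- logical(length(active_id))
      for (o in ord) {
        if (dist[o] > max_step) break
        ti <- (o - 1L) %% nrow(dist) + 1L
        di <- (o - 1L) %/% nrow(dist) + 1L
        if (used_track[ti] || !is.na(assign_track[di])) next
        used_track[ti] <- TRUE
        assign_track[di] <- ti
      }
    }
    ids <- integer(nd)
    matched <- !is.na(assign_track)
    ids[matched] <- active_id[assign_track[matched]]
    n_new <- sum(!matched)
    if (n_new > 0) {
      ids[!matched] <- next_id + seq_len(n_new) - 1L
      next_id <- next_id + n_new
    }
    if (nd > 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell_id = ids, frame = d$frame, x_um = d$x_um, y_um = d$y_um)
    }
    active_id <- ids
    active_xy <- cbind(d$x_um, d$y_um)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$cell_id, .data$frame)
}

#' Apply the trajectory inclusion filters
#'
#' Keeps only trajectories that (1) span all `n_frames` frames with no
#' gaps, (2) stay inside the dish for their whole span, (3) do not start
#' in the exclusion band (half-field groups only; whole-dish Control /
#' Uniform groups keep any in-dish start) and (4) show more than
#' `motion_floor` um of total motion (a proxy for nonviable cells; set the
#' floor to 0 to disable). Rejected trajectories carry one machine-readable
#' reason: `INCOMPLETE`, `EXITED_FIELD`, `EXCLUDED_REGION` or `NONVIABLE`,
#' assessed in that order. Region labels come from the first-frame
#' position.
#'
#' @param tracks Tibble with `cell_id, frame, x_um, y_um` and optionally
#'   `group`/`replicate` (positions in um relative to the dish centre).
#' @param n_frames Expected full movie length.
#' @param dish A [dish_geometry()].
#' @param half_field_groups Group names analysed on half-field dishes; for
#'   tracks without a `group` column all tracks are treated as half-field.
#' @param motion_floor Total-motion viability floor in um.
#' @return List with `kept` (tracks tibble plus a per-cell `region`
#'   column) and `rejected` (one row per rejected cell:
#'   `..., cell_id, reject_reason`).
#' @export
filter_trajectories <- function(tracks, n_frames, dish = dish_geometry(),
                                half_field_groups = c("In-field", "Out-of-field"),
                                motion_floor = 0.1) {
  dish <- as_dish_geometry(dish)
  keys <- intersect(c("group", "replicate", "cell_id"), names(tracks))
  per <- tracks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      span_ok = (dplyr::n() == n_frames) &&
        all(diff(as.integer(.data$frame)) == 1L),
      out_dish = any(sqrt(.data$x_um^2 + .data$y_um^2) > dish$diameter / 2 * 1000),
      x0_mm = dplyr::first(.data$x_um) / 1000,
      y0_mm = dplyr::first(.data$y_um) / 1000,
      motion = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
      .groups = "drop")
  per$region <- assign_field(per$x0_mm, per$y0_mm, dish)
  half_field <- if ("group" %in% names(per)) {
    per$group %in% half_field_groups
  } else rep(TRUE, nrow(per))
  reason <- rep(NA_character_, nrow(per))
  reason[!per$span_ok] <- "INCOMPLETE"
  reason[is.na(reason) & per$out_dish] <- "EXITED_FIELD"
  reason[is.na(reason) & half_field & per$region == "EXCLUDED"] <- "EXCLUDED_REGION"
  reason[is.na(reason) & motion_floor > 0 & per$motion <= motion_floor] <- "NONVIABLE"
  per$reject_reason <- reason
  kept_cells <- per[is.na(reason), c(keys, "region")]
  rejected <- per[!is.na(reason), c(keys, "region", "reject_reason")]
  kept <- dplyr::inner_join(tracks, kept_cells, by = keys)
  list(kept = kept, rejected = rejected)
}
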