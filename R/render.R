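# Label-movie rendering: turn trajectories into integer label image
# stacks so the detection + linking stages can be validated round-trip.
# Pixel convention: 0-based indices, pixel (row i, col j) has its centre
# at (x, y) = (j, i) * pixel_size um relative to `origin`.

#' Render trajectories as a label movie
#'
#' Draws every cell as a filled disk carrying its persistent integer label
#' in each frame. The fixture guarantees separability: overlapping disks
#' are rejected rather than merged, because downstream linking assumes one
#' connected component per label.
#'
#' @param tracks Tibble with `cell_id`, `frame`, `x_um`, `y_um` (one cell
#'   id per physical cell; positions must fall inside the image after
#'   um-to-pixel conversion).
#' @param pixel_size um per pixel.
#' @param cell_radius Disk radius in um.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param origin `c(x, y)` um of pixel (0, 0)'s centre; positions are
#'   shifted by `-origin` before rasterisation.
#' @param frame_interval Minutes per frame (carried as metadata).
#' @return A `label_movie`: list of integer matrices plus `pixel_size` and
#'   `frame_interval`.
#' @export
render_label_movie <- function(tracks, pixel_size, cell_radius,
                               image_shape, origin = c(0, 0),
                               frame_interval = 15) {
  stopifnot(all(c("cell_id", "frame", "x_um", "y_um") %in% names(tracks)))
  if (max(tracks$cell_id) > 65535) {
    stop("labels must fit 16-bit (cell_id <= 65535)", call. = FALSE)
  }
  nr <- image_shape[1]; nc <- image_shape[2]
  rad_px <- cell_radius / pixel_size
  frames_idx <- sort(unique(tracks$frame))
  frames <- vector("list", length(frames_idx))
  for (fi in seq_along(frames_idx)) {
    fr <- tracks[tracks$frame == frames_idx[fi], ]
    img <- matrix(0L, nr, nc)
    for (i in seq_len(nrow(fr))) {
      cx <- (fr$x_um[i] - origin[1]) / pixel_size
      cy <- (fr$y_um[i] - origin[2]) / pixel_size
      if (cx < rad_px || cy < rad_px || cx > nc - 1 - rad_px ||
          cy > nr - 1 - rad_px) {
        stop(sprintf("cell %d frame %d does not fit inside the image",
                     fr$cell_id[i], frames_idx[fi]), call. = FALSE)
      }
      rows <- floor(cy - rad_px):ceiling(cy + rad_px)
      cols <- floor(cx - rad_px):ceiling(cx + rad_px)
      dz <- outer((rows - cy)^2, (cols - cx)^2, "+")
      sel <- which(dz <= rad_px^2, arr.ind = TRUE)
      rr <- rows[sel[, 1]] + 1L; cc <- cols[sel[, 2]] + 1L
      idx <- rr + (cc - 1L) * nr
      if (any(img[idx] != 0L)) {
        stop(sprintf("overlapping disks at frame %d (cell %d)",
                     frames_idx[fi], fr$cell_id[i]), call. = FALSE)
      }
      img[idx] <- as.integer(fr$cell_id[i])
    }
    frames[[fi]] <- img
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "label_movie")
}

#' @export
print.label_movie <- function(x, ...) {
  cat(sprintf("Label movie: %d frames of %d x %d px, %g um/px, %g min/frame\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Write / read a label movie as multi-page 16-bit TIFF
#'
#' @param movie A `label_movie`.
#' @param path Output TIFF path.
#' @return `write_label_movie` returns `path` invisibly;
#'   `read_label_movie` returns a `label_movie` (pixel size and frame
#'   interval are not stored in the TIFF and must be supplied).
#' @export
write_label_movie <- function(movie, path) {
  stopifnot(inherits(movie, "label_movie"))
  imgs <- lapply(movie$frames, function(m) m / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_label_movie
#' @param pixel_size,frame_interval Metadata to attach on read.
#' @export
read_label_movie <- function(path, pixel_size = 1, frame_interval = 15) {
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  frames <- lapply(imgs, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "label_movie")
}
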