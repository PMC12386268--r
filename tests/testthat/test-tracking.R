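test_that("centroids are pixel-mean positions per label", {
  img <- matrix(0L, 11, 11)
  img[5:7, 5:7] <- 1L            # 3x3 block, 0-based centre (5, 5)
  d <- detect_centroids(img, pixel_size = 1)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$x_um, d$y_um), c(5, 5))
  # L-tromino at 0-based (row, col) = (0,0), (1,0), (1,1)
  img2 <- matrix(0L, 4, 4)
  img2[1, 1] <- 2L; img2[2, 1] <- 2L; img2[2, 2] <- 2L
  d2 <- detect_centroids(img2)
  expect_equal(d2$y_um, 2 / 3)   # mean row
  expect_equal(d2$x_um, 1 / 3)   # mean col
  # count preservation and pixel-size scaling
  img2[4, 4] <- 7L
  d3 <- detect_centroids(img2, pixel_size = 2)
  expect_equal(nrow(d3), 2)
  expect_equal(d3$x_um[d3$label == 7], 6)
  expect_equal(nrow(detect_centroids(matrix(0L, 5, 5))), 0)
})

test_that("unambiguous detections link into single trajectories", {
  det <- tibble::tibble(frame = 1:97, x_um = cumsum(runif(97, -3, 3)) + 50,
                        y_um = cumsum(runif(97, -3, 3)) + 50)
  tr <- link_trajectories(det, max_step = 30)
  expect_equal(length(unique(tr$cell_id)), 1)
  expect_equal(nrow(tr), 97)
})

test_that("the distance gate prevents cross-cell linking", {
  set.seed(4)
  a <- tibble::tibble(frame = rep(1:50, 2),
                      x_um = c(cumsum(runif(50, -1, 1)),
                               200 + cumsum(runif(50, -1, 1))),
                      y_um = c(cumsum(runif(50, -1, 1)),
                               cumsum(runif(50, -1, 1))))
  tr <- link_trajectories(a, max_step = 10)
  expect_equal(length(unique(tr$cell_id)), 2)
  # each trajectory stays on its side: zero identity switches
  sides <- tapply(tr$x_um, tr$cell_id, function(x) range(x))
  expect_true(all(sapply(sides, function(r) r[2] - r[1] < 50)))
  # no detection is used twice and no track occupies a frame twice
  expect_false(any(duplicated(tr[c("cell_id", "frame")])))
})

test_that("greedy linking matches the brute-force optimal assignment", {
  # 5 cells x 10 frames with separation >= 2x any nearest-neighbour step
  set.seed(9)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (rep in 1:5) {
    tracks <- grid_walk_tracks(n_x = 5, n_y = 1, spacing = 40,
                               n_frames = 10, step_max = 3,
                               seed = 100 + rep)
    det <- tracks[c("frame", "x_um", "y_um")]
    linked <- link_trajectories(det, max_step = 15)
    # brute force: per frame pair, the permutation minimising total distance
    for (f in 1:9) {
      a <- tracks[tracks$frame == f, ]
      b <- tracks[tracks$frame == f + 1, ]
      costs <- sapply(perms(1:5), function(p)
        sum(sqrt((a$x_um - b$x_um[p])^2 + (a$y_um - b$y_um[p])^2)))
      best <- perms(1:5)[[which.min(costs)]]
      # generated tracks are the optimum (identity assignment)
      expect_equal(best, 1:5)
    }
    # and greedy recovered exactly the generated tracks
    expect_equal(length(unique(linked$cell_id)), 5)
    key <- dplyr::arrange(linked, frame, x_um)
    ref <- dplyr::arrange(tracks, frame, x_um)
    expect_equal(key$x_um, ref$x_um)
    expect_equal(key$y_um, ref$y_um)
    per_cell_x <- tapply(linked$x_um, linked$cell_id, function(x)
      max(x) - min(x))
    expect_true(all(per_cell_x < 20))  # no switches across the 40 um grid
  }
})

test_that("render -> detect -> link round-trips 20 cells within a pixel", {
  tracks <- grid_walk_tracks(n_x = 5, n_y = 4, spacing = 100,
                             n_frames = 20, step_max = 2)
  mov <- render_label_movie(tracks, pixel_size = 2, cell_radius = 8,
                            image_shape = c(200, 260))
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_movie(mov, path)
  mov2 <- read_label_movie(path, pixel_size = 2)
  expect_identical(mov2$frames, mov$frames)
  rec <- link_trajectories(detect_movie(mov2), max_step = 10)
  expect_equal(length(unique(rec$cell_id)), 20)
  expect_equal(nrow(rec), nrow(tracks))
  # match recovered to generated tracks by first-frame proximity
  f1 <- rec[rec$frame == 1, ]
  g1 <- tracks[tracks$frame == 1, ]
  map <- sapply(seq_len(nrow(f1)), function(i)
    g1$cell_id[which.min((g1$x_um - f1$x_um[i])^2 + (g1$y_um - f1$y_um[i])^2)])
  expect_equal(sort(map), 1:20)
  rec$orig <- map[match(rec$cell_id, f1$cell_id)]
  mm <- dplyr::inner_join(rec, tracks,
                          by = c(orig = "cell_id", frame = "frame"),
                          suffix = c("", ".gen"))
  expect_equal(nrow(mm), nrow(tracks))
  expect_lt(max(abs(mm$x_um - mm$x_um.gen), abs(mm$y_um - mm$y_um.gen)), 2)
})

test_that("rendering rejects overlapping or out-of-image cells", {
  t2 <- tibble::tibble(cell_id = c(1L, 2L), frame = c(1L, 1L),
                       x_um = c(50, 58), y_um = c(50, 50))
  expect_error(render_label_movie(t2, 1, cell_radius = 6,
                                  image_shape = c(100, 100)), "overlap")
  t3 <- tibble::tibble(cell_id = 1L, frame = 1L, x_um = 2, y_um = 50)
  expect_error(render_label_movie(t3, 1, cell_radius = 6,
                                  image_shape = c(100, 100)), "fit")
})

test_that("trajectory filters apply the published exclusion rules", {
  geom <- dish_geometry()
  n_frames <- 97
  mk <- function(id, group, x0_mm, n = n_frames, stationary = FALSE) {
    step <- if (stationary) 0 else 1
    tibble::tibble(group = group, replicate = 1L, cell_id = id,
                   frame = seq_len(n),
                   x_um = x0_mm * 1000 + step * (seq_len(n) - 1),
                   y_um = rep(0, n))
  }
  tracks <- dplyr::bind_rows(
    mk(1, "In-field", -15),             # kept
    mk(2, "In-field", -15, n = 50),     # incomplete
    mk(3, "Out-of-field", 2),           # starts in the exclusion band
    mk(4, "Control", 2),                # whole-dish group: band is fine
    mk(5, "Out-of-field", 29.99),       # wanders past the rim
    mk(6, "In-field", -15, stationary = TRUE))  # nonviable
  res <- filter_trajectories(tracks, n_frames, geom)
  expect_setequal(unique(res$kept$cell_id), c(1, 4))
  reasons <- setNames(res$rejected$reject_reason, res$rejected$cell_id)
  expect_equal(reasons[["2"]], "INCOMPLETE")
  expect_equal(reasons[["3"]], "EXCLUDED_REGION")
  expect_equal(reasons[["5"]], "EXITED_FIELD")
  expect_equal(reasons[["6"]], "NONVIABLE")
  expect_equal(unique(res$kept$region[res$kept$cell_id == 1]), "IN_FIELD")
  # idempotence: filtering the kept set changes nothing
  again <- filter_trajectories(res$kept[names(tracks)], n_frames, geom)
  expect_equal(nrow(again$rejected), 0)
  expect_equal(dplyr::arrange(again$kept, cell_id, frame)$x_um,
               dplyr::arrange(res$kept, cell_id, frame)$x_um)
  # every rejected cell appears exactly once
  expect_equal(nrow(res$rejected), 4)
  expect_false(any(duplicated(res$rejected$cell_id)))
})
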