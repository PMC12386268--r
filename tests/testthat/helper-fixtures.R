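# Shared fixture builders: tiny configs and trajectory tables assembled in
# code so no binary fixtures are needed.

one_group_config <- function(group = "Control", speed_median = 5,
                             speed_log_sigma = 0.5, persistence = 0,
                             n_cells = 50, n_frames = 97,
                             n_replicates = 1, step_law = "fixed",
                             seed = 1, ...) {
  grp <- list(speed_median = speed_median,
              speed_log_sigma = speed_log_sigma,
              persistence = persistence)
  synthetic_config(
    n_cells_per_group = n_cells, n_replicates = n_replicates,
    n_frames = n_frames, step_law = step_law, seed = seed,
    groups = stats::setNames(list(grp), group), ...)
}

preset_group_config <- function(preset_id, group = "Control", n_cells = 1000,
                                n_frames = 97, seed = 1) {
  sp <- speed_preset(preset_id)
  synthetic_config(
    n_cells_per_group = n_cells, n_replicates = 3, n_frames = n_frames,
    seed = seed,
    groups = stats::setNames(list(sp[c("speed_median", "speed_log_sigma",
                                       "persistence")]), group))
}

# straight-line trajectory as a tibble
ballistic_track <- function(n_steps = 96, step = c(10, 0), start = c(0, 0)) {
  tibble::tibble(cell_id = 1L, frame = seq_len(n_steps + 1),
                 x_um = start[1] + step[1] * (0:n_steps),
                 y_um = start[2] + step[2] * (0:n_steps))
}

# well-separated grid walks for render/link round-trips
grid_walk_tracks <- function(n_x = 5, n_y = 4, spacing = 100, n_frames = 20,
                             step_max = 2, margin = 60, seed = 3) {
  set.seed(seed)
  grid <- expand.grid(x = margin + spacing * (seq_len(n_x) - 1),
                      y = margin + spacing * (seq_len(n_y) - 1))
  dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    tibble::tibble(
      cell_id = i, frame = seq_len(n_frames),
      x_um = cumsum(c(grid$x[i], stats::runif(n_frames - 1, -step_max, step_max))),
      y_um = cumsum(c(grid$y[i], stats::runif(n_frames - 1, -step_max, step_max))))
  }))
}

# asymptotic standard error of a lognormal sample median
lognormal_median_se <- function(m, sigma, n) {
  1 / (2 * stats::dlnorm(m, log(m), sigma) * sqrt(n))
}
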