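# Synthetic trajectory and cell-cycle state generator.
#
# The generator realises the motility model the analysis assumes: each cell
# draws a persistent speed s_i from a lognormal law (median = cohort
# median, log-sigma fitted from the cohort IQR), then performs a 2D walk at
# uniform frame intervals. Step direction is uniform on the circle,
# optionally blended with the previous direction by a persistence weight;
# step length is either exactly s_i * dt ("fixed", the default, which makes
# the path-length velocity estimator recover s_i exactly) or Rayleigh with
# mean s_i * dt ("gaussian", giving i.i.d. per-axis Gaussian steps at
# persistence 0, the textbook diffusive walk).

.known_config_keys <- c(
  "name", "seed", "n_cells_per_group", "n_replicates", "n_frames",
  "frame_interval", "step_law", "cell_radius", "dish", "groups",
  "fucci", "fucci_n", "outputs"
)
.known_group_keys <- c(
  "speed_median", "speed_q1", "speed_q3", "speed_log_sigma",
  "persistence", "region", "n_cells"
)

.region_for_group <- function(group, spec = NULL) {
  if (!is.null(spec$region)) {
    r <- match.arg(spec$region, c("whole", "in_field", "out_of_field"))
    return(r)
  }
  switch(group,
    "Control" = "whole", "Uniform" = "whole",
    "In-field" = "in_field", "Out-of-field" = "out_of_field",
    stop(sprintf(
      "group '%s' has no default region; add a `region` field (whole, in_field, out_of_field)",
      group), call. = FALSE))
}

#' Synthetic experiment configuration
#'
#' Validates and normalises a configuration for the trajectory generator
#' and downstream pipeline. `groups` is a named list; each group needs a
#' `speed_median` (um/h) plus either `speed_log_sigma` or the quartiles
#' `speed_q1`/`speed_q3` it should be fitted from, and may set
#' `persistence` in \[0, 1) (0 = pure random walk) and `region` (start
#' region: `whole`, `in_field`, `out_of_field`; inferred for the canonical
#' group names).
#'
#' @param n_cells_per_group Cells per group (total across replicates).
#' @param n_replicates Independent replicates the cells are split over.
#' @param n_frames Frames per movie; the default 97 covers 24 h at 15-min
#'   intervals including both endpoints.
#' @param frame_interval Minutes between frames.
#' @param step_law `"fixed"` (step length exactly speed * dt) or
#'   `"gaussian"` (Rayleigh step length; i.i.d. Gaussian per-axis steps at
#'   persistence 0).
#' @param cell_radius Cell radius in um (start-position margin and label
#'   rendering).
#' @param dish A [dish_geometry()] or list of its fields.
#' @param groups Named list of per-group parameters (see Details).
#' @param fucci Named list of conditions, each a probability list/vector
#'   over `red`, `yellow`, `green` summing to 1.
#' @param fucci_n Cells scored per FUCCI condition in the pipeline.
#' @param seed Master seed; all per-replicate streams derive from it.
#' @param name Optional experiment name.
#' @param outputs Optional list of output switches (e.g. `write_tracks`).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells_per_group, n_replicates = 3,
                             n_frames = 97, frame_interval = 15,
                             step_law = c("fixed", "gaussian"),
                             cell_radius = 10, dish = dish_geometry(),
                             groups = list(), fucci = list(),
                             fucci_n = 300, seed = 1, name = NULL,
                             outputs = list()) {
  step_law <- match.arg(step_law)
  stopifnot(n_cells_per_group >= 1, n_replicates >= 1)
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  dish <- as_dish_geometry(dish)
  if (length(groups) == 0 || is.null(names(groups))) {
    stop("`groups` must be a non-empty named list", call. = FALSE)
  }
  groups <- lapply(stats::setNames(names(groups), names(groups)), function(g) {
    spec <- groups[[g]]
    unknown <- setdiff(names(spec), .known_group_keys)
    if (length(unknown)) {
      stop(sprintf("unknown keys in group '%s': %s", g,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    if (is.null(spec$speed_median)) {
      stop(sprintf("group '%s' needs a speed_median", g), call. = FALSE)
    }
    if (spec$speed_median < 0) {
      stop("speed_median must be >= 0", call. = FALSE)
    }
    if (is.null(spec$speed_log_sigma)) {
      if (!is.null(spec$speed_q1) && !is.null(spec$speed_q3) &&
          spec$speed_median > 0) {
        spec$speed_log_sigma <- lognormal_sigma_from_iqr(
          spec$speed_median, spec$speed_q1, spec$speed_q3)
      } else {
        spec$speed_log_sigma <- 0
      }
    }
    spec$persistence <- spec$persistence %||% 0
    if (spec$persistence < 0 || spec$persistence >= 1) {
      stop(sprintf("group '%s': persistence must be in [0, 1)", g),
           call. = FALSE)
    }
    spec$region <- .region_for_group(g, spec)
    spec
  })
  fucci <- lapply(fucci, function(p) {
    p <- unlist(p)
    if (!all(c("red", "yellow", "green") %in% names(p))) {
      stop("each FUCCI condition needs red, yellow and green probabilities",
           call. = FALSE)
    }
    p <- p[c("red", "yellow", "green")]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("FUCCI probabilities must be nonnegative and sum to 1",
           call. = FALSE)
    }
    p
  })
  structure(
    list(name = name, seed = as.integer(seed),
         n_cells_per_group = as.integer(n_cells_per_group),
         n_replicates = as.integer(n_replicates),
         n_frames = as.integer(n_frames), frame_interval = frame_interval,
         step_law = step_law, cell_radius = cell_radius, dish = dish,
         groups = groups, fucci = fucci, fucci_n = as.integer(fucci_n),
         outputs = outputs),
    class = "synthetic_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed and a key
#'
#' Deterministic, platform-independent stream splitting: the master seed
#' and key parts are hashed into an integer below 2^31 used to seed the
#' child stream. Identical inputs always give the identical child seed.
#'
#' @param master Integer master seed.
#' @param ... Key parts (coerced to character), e.g. group and replicate.
#' @return An integer seed.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(format(master), vapply(list(...), format, "")),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Uniform start positions (um) inside the group's analyzable sub-region,
# at least `margin_um` from the region edges, by rejection sampling.
sample_start_positions <- function(n, region, dish, margin_um) {
  R_um <- dish$diameter / 2 * 1000 - margin_um
  bx_um <- dish$boundary_x * 1000
  w_um <- dish$exclusion_half_width * 1000
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 32L)
    x <- stats::runif(m, -R_um, R_um)
    y <- stats::runif(m, -R_um, R_um)
    keep <- x^2 + y^2 <= R_um^2
    keep <- keep & switch(region,
      whole = TRUE,
      in_field = x <= bx_um - w_um - margin_um,
      out_of_field = x >= bx_um + w_um + margin_um)
    xs <- c(xs, x[keep]); ys <- c(ys, y[keep])
  }
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# Core walker for one replicate: n cells, F frames. Returns list of
# coordinate matrices (frames x cells).
.walk <- function(n, n_frames, start, speeds_umph, frame_interval,
                  persistence, step_law) {
  L <- speeds_umph * frame_interval / 60    # mean step length, um/frame
  X <- matrix(0, n_frames, n); Y <- matrix(0, n_frames, n)
  X[1, ] <- start[, 1]; Y[1, ] <- start[, 2]
  ang <- stats::runif(n, 0, 2 * pi)
  dx <- cos(ang); dy <- sin(ang)
  ray_sigma <- L * sqrt(2 / pi)             # Rayleigh scale with mean L
  for (k in seq_len(n_frames - 1L)) {
    u <- stats::runif(n, 0, 2 * pi)
    ux <- cos(u); uy <- sin(u)
    if (persistence > 0) {
      wx <- persistence * dx + (1 - persistence) * ux
      wy <- persistence * dy + (1 - persistence) * uy
      nrm <- sqrt(wx^2 + wy^2)
      deg <- nrm < 1e-12
      if (any(deg)) { wx[deg] <- ux[deg]; wy[deg] <- uy[deg]; nrm[deg] <- 1 }
      dx <- wx / nrm; dy <- wy / nrm
    } else {
      dx <- ux; dy <- uy
    }
    len <- if (step_law == "fixed") L else
      ray_sigma * sqrt(-2 * log(stats::runif(n)))
    X[k + 1L, ] <- X[k, ] + dx * len
    Y[k + 1L, ] <- Y[k, ] + dy * len
  }
  list(x = X, y = Y)
}

#' Simulate trajectories for one experimental group
#'
#' Draws one persistent speed per cell from the group's lognormal law,
#' starts cells uniformly in the group's analyzable region of the dish and
#' walks them for `n_frames` frames (see the package model description).
#' Cells are split as evenly as possible over `n_replicates` replicates,
#' each with its own deterministic random stream derived from the master
#' seed, so the output is reproducible and independent of evaluation
#' order.
#'
#' @param config A [synthetic_config()].
#' @param group Name of a configured group.
#' @param n_cells Optional override of `config$n_cells_per_group`.
#' @return A tibble with columns `replicate, group, cell_id, frame, t_min,
#'   x_um, y_um` (one row per cell per frame; positions in um relative to
#'   the dish centre), with the per-cell speed draws attached as the
#'   `cell_params` attribute.
#' @export
simulate_trajectories <- function(config, group, n_cells = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  spec <- config$groups[[group]]
  if (is.null(spec)) {
    stop(sprintf("unknown group '%s'; configured groups: %s", group,
                 paste(names(config$groups), collapse = ", ")), call. = FALSE)
  }
  n_total <- as.integer(n_cells %||% config$n_cells_per_group)
  n_rep <- config$n_replicates
  per_rep <- diff(round(seq(0, n_total, length.out = n_rep + 1L)))
  sigma <- spec$speed_log_sigma
  out <- vector("list", n_rep)
  params <- vector("list", n_rep)
  cell0 <- 0L
  for (r in seq_len(n_rep)) {
    n <- as.integer(per_rep[r])
    if (n == 0L) next
    set.seed(derive_seed(config$seed, "traj", group, r))
    speeds <- if (spec$speed_median > 0) {
      stats::rlnorm(n, meanlog = log(spec$speed_median), sdlog = sigma)
    } else rep(0, n)
    start <- sample_start_positions(n, spec$region, config$dish,
                                    config$cell_radius)
    w <- .walk(n, config$n_frames, start, speeds, config$frame_interval,
               spec$persistence, config$step_law)
    ids <- cell0 + seq_len(n)
    out[[r]] <- tibble::tibble(
      replicate = r, group = group,
      cell_id = rep(ids, each = config$n_frames),
      frame = rep(seq_len(config$n_frames), times = n),
      t_min = (rep(seq_len(config$n_frames), times = n) - 1) *
        config$frame_interval,
      x_um = as.vector(w$x), y_um = as.vector(w$y))
    params[[r]] <- tibble::tibble(group = group, replicate = r,
                                  cell_id = ids, speed_umph = speeds)
    cell0 <- cell0 + n
  }
  res <- dplyr::bind_rows(out)
  attr(res, "cell_params") <- dplyr::bind_rows(params)
  attr(res, "frame_interval") <- config$frame_interval
  attr(res, "n_frames") <- config$n_frames
  res
}

#' Simulate every configured group
#'
#' @inheritParams simulate_trajectories
#' @return A tibble as in [simulate_trajectories()] covering all groups.
#' @export
simulate_cohort <- function(config, n_cells = NULL) {
  parts <- lapply(names(config$groups), function(g)
    simulate_trajectories(config, g, n_cells = n_cells))
  res <- dplyr::bind_rows(parts)
  attr(res, "cell_params") <-
    dplyr::bind_rows(lapply(parts, attr, "cell_params"))
  attr(res, "frame_interval") <- config$frame_interval
  attr(res, "n_frames") <- config$n_frames
  res
}

#' Sample FUCCI cell-cycle states
#'
#' Independent draws of the nuclear FUCCI colour state (`red` = G1,
#' `yellow` = early S, `green` = S/G2/M) from a condition's probability
#' vector.
#'
#' @param n Number of cells.
#' @param distribution Probability vector over `(red, yellow, green)`
#'   (named or positional), nonnegative and summing to 1 within 1e-9.
#' @param seed Integer seed.
#' @return Factor of length `n` with levels `red`, `yellow`, `green`.
#' @export
sample_cellcycle_states <- function(n, distribution, seed = 1) {
  p <- unlist(distribution)
  if (!is.null(names(p)) && all(c("red", "yellow", "green") %in% names(p))) {
    p <- p[c("red", "yellow", "green")]
  }
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("distribution must be 3 nonnegative probabilities summing to 1",
         call. = FALSE)
  }
  set.seed(seed)
  factor(sample(c("red", "yellow", "green"), n, replace = TRUE, prob = p),
         levels = c("red", "yellow", "green"))
}
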