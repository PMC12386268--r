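# End-to-end pipeline: configuration IO, validation, and the
# generate -> (track) -> classify -> measure -> test orchestration with
# machine-readable CSV/JSON outputs and a reproducible run record.

#' Read an experiment configuration
#'
#' Loads a YAML configuration (or takes an already-parsed list) and
#' normalises it through [synthetic_config()]. A top-level `preset` key
#' loads [experiment_preset()] first and overlays the remaining keys.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `synthetic_config`.
#' @export
read_config <- function(config) {
  if (inherits(config, "synthetic_config")) return(config)
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or list", call. = FALSE)
  preset <- config$preset
  config$preset <- NULL
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(preset)) {
    base <- experiment_preset(preset)
    base <- unclass(base)
    for (k in names(config)) base[[k]] <- config[[k]]
    config <- base
    config$dish <- if (inherits(config$dish, "dish_geometry"))
      config$dish else as_dish_geometry(config$dish)
    config$groups <- lapply(config$groups, function(g)
      g[intersect(names(g), .known_group_keys)])
    config$fucci <- lapply(config$fucci, as.list)
  }
  if (inherits(config$dish, "dish_geometry")) config$dish <- unclass(config$dish)
  do.call(synthetic_config, config)
}

#' Validate a configuration without running anything
#'
#' @param config Path to a YAML file, or a list.
#' @return Character vector of findings; empty when the configuration is
#'   valid. Never mutates files.
#' @export
validate_config <- function(config) {
  res <- tryCatch({
    read_config(config)
    character(0)
  }, error = function(e) conditionMessage(e))
  res
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full half-field migration experiment pipeline
#'
#' Generates the configured synthetic cohorts, (optionally) renders and
#' re-tracks label movies, classifies cells into dish regions, applies the
#' trajectory inclusion filters, computes per-cell metrics and per-group
#' ensemble MSD curves, runs Steel's many-to-one comparisons of every
#' non-control group against Control for velocity, total distance and net
#' displacement, scores FUCCI state distributions with a chi-square test
#' when two or more conditions are configured, and writes all stage
#' outputs plus a run record to `out_dir`. A second run with the same
#' configuration and seed reproduces the primary outputs byte for byte.
#'
#' @param config Path to a YAML config, a list, or a `synthetic_config`.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional master-seed override.
#' @param steel_mode `"mvn"` or `"permutation"` for the group comparisons.
#' @param alpha Significance threshold recorded in the stats report.
#' @return Invisibly, the run record (also written as `run_record.json`):
#'   config snapshot, seeds, per-stage counts, rejection tally, output
#'   digests and results.
#' @export
run_experiment <- function(config, out_dir, seed = NULL,
                           steel_mode = c("mvn", "permutation"),
                           alpha = 0.05) {
  steel_mode <- match.arg(steel_mode)
  t0 <- Sys.time()
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tracks <- !isFALSE(cfg$outputs$write_tracks)

  tracks <- simulate_cohort(cfg)
  n_cells_sim <- nrow(dplyr::distinct(
    tracks, .data$group, .data$replicate, .data$cell_id))

  filt <- filter_trajectories(tracks, n_frames = cfg$n_frames,
                              dish = cfg$dish)
  kept <- filt$kept
  reject_tally <- as.list(table(filt$rejected$reject_reason))
  n_cells_kept <- nrow(dplyr::distinct(
    kept, .data$group, .data$replicate, .data$cell_id))

  metrics <- cell_metrics(kept, frame_interval = cfg$frame_interval)
  msd <- lapply(stats::setNames(nm = names(cfg$groups)), function(g) {
    ensemble_msd(kept[kept$group == g, ],
                 frame_interval = cfg$frame_interval)
  })
  motion <- lapply(msd, classify_motion)

  groups <- names(cfg$groups)
  comparisons <- list()
  if ("Control" %in% groups && length(groups) > 1) {
    trt_names <- setdiff(groups, "Control")
    for (metric in c("velocity_umph", "total_distance_um",
                     "net_displacement_um")) {
      ctl <- metrics[[metric]][metrics$group == "Control"]
      trts <- lapply(stats::setNames(nm = trt_names), function(g)
        metrics[[metric]][metrics$group == g])
      st <- steel_test(ctl, trts, mode = steel_mode,
                       seed = derive_seed(cfg$seed, "steel", metric))
      comparisons[[metric]] <- lapply(seq_along(st$treatments), function(i) {
        list(group = st$treatments[i], z = st$z_stats[i],
             p_adjusted = st$p_adjusted[i], method = st$method,
             mc_error = st$mc_error[i],
             significant = st$p_adjusted[i] < alpha)
      })
    }
  }

  fucci_counts <- NULL; fucci_chisq <- NULL; fucci_states <- NULL
  if (length(cfg$fucci) > 0) {
    fucci_states <- dplyr::bind_rows(lapply(names(cfg$fucci), function(cond) {
      st <- sample_cellcycle_states(cfg$fucci_n, cfg$fucci[[cond]],
                                    seed = derive_seed(cfg$seed, "fucci", cond))
      tibble::tibble(condition = cond, cell_id = seq_along(st),
                     state = as.character(st))
    }))
    tab <- table(fucci_states$condition, fucci_states$state)
    fucci_counts <- as.data.frame.matrix(tab)
    if (nrow(tab) >= 2) {
      ch <- chi_square_test(as.matrix(tab))
      fucci_chisq <- list(statistic = ch$statistic, df = ch$df,
                          p = ch$p_value,
                          expected = as.data.frame.matrix(ch$expected))
    }
  }

  summaries <- lapply(
    stats::setNames(nm = c("velocity_umph", "total_distance_um",
                           "net_displacement_um")),
    function(m) summarize_groups(metrics[[m]], metrics$group))

  # --- write outputs -------------------------------------------------
  paths <- character(0)
  if (write_tracks) {
    p <- file.path(out_dir, "tracks.csv")
    readr::write_csv(
      kept[c("replicate", "group", "cell_id", "frame", "t_min",
             "x_um", "y_um")], p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "tracks_rejected.csv")
  readr::write_csv(filt$rejected, p); paths <- c(paths, p)
  p <- file.path(out_dir, "metrics.csv")
  readr::write_csv(metrics[c("replicate", "group", "cell_id",
                             "velocity_umph", "total_distance_um",
                             "net_displacement_um")], p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "msd.csv")
  readr::write_csv(dplyr::bind_rows(lapply(names(msd), function(g)
    tibble::tibble(group = g, lag_h = msd[[g]]$lag_h,
                   msd_um2 = msd[[g]]$msd_um2))), p)
  paths <- c(paths, p)
  if (!is.null(fucci_states)) {
    p <- file.path(out_dir, "fucci_states.csv")
    readr::write_csv(fucci_states, p); paths <- c(paths, p)
  }
  msd_fits <- lapply(names(msd), function(g)
    list(group = g, slope = msd[[g]]$slope, intercept = msd[[g]]$intercept,
         r_squared = msd[[g]]$r_squared, n_cells = msd[[g]]$n_cells,
         motion = motion[[g]]$label))
  p <- .write_json(msd_fits, file.path(out_dir, "msd_fits.json"))
  paths <- c(paths, p)
  stats_report <- list(
    alpha = alpha,
    steel = comparisons,
    chi_square = fucci_chisq,
    summaries = lapply(summaries, function(s)
      lapply(seq_len(nrow(s)), function(i)
        list(group = s$group[i], n = s$n[i], median = s$median[i],
             q1 = s$q1[i], q3 = s$q3[i]))))
  p <- .write_json(stats_report, file.path(out_dir, "stats.json"))
  paths <- c(paths, p)
  qc <- list(analyzable_fraction = analyzable_fraction(cfg$dish),
             cells_simulated = n_cells_sim, cells_kept = n_cells_kept,
             rejected = reject_tally,
             region_counts = as.list(table(
               dplyr::distinct(kept, .data$group, .data$replicate,
                               .data$cell_id, .data$region)$region)))
  p <- .write_json(qc, file.path(out_dir, "qc.json"))
  paths <- c(paths, p)

  record <- list(
    experiment = cfg$name,
    seed = cfg$seed,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    config = list(
      n_cells_per_group = cfg$n_cells_per_group,
      n_replicates = cfg$n_replicates, n_frames = cfg$n_frames,
      frame_interval = cfg$frame_interval, step_law = cfg$step_law,
      groups = cfg$groups, dish = unclass(cfg$dish),
      fucci = lapply(cfg$fucci, as.list), fucci_n = cfg$fucci_n),
    counts = list(simulated = n_cells_sim, kept = n_cells_kept,
                  rejected = reject_tally),
    digests = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                      basename(paths))),
    steel_mode = steel_mode)
  .write_json(record, file.path(out_dir, "run_record.json"))
  record$results <- list(metrics = metrics, msd = msd,
                         summaries = summaries, steel = comparisons,
                         chi_square = fucci_chisq)
  invisible(record)
}
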