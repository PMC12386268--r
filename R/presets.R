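# Calibration presets: per-group speed distributions pinned to the
# published cohort medians and interquartile ranges, plus FUCCI cell-cycle
# state distributions for the untreated and cisplatin-arrested conditions.

# Printed median (Q1-Q3) velocities in um/h for the two experiment series:
# "xray" = half-field X-ray exposure alone, "cisplatin" = cisplatin
# pre-treatment followed by the same exposure.
.speed_calibration <- list(
  "xray-control"          = c(median = 5.73, q1 = 3.31, q3 = 9.49),
  "xray-uniform"          = c(median = 4.99, q1 = 2.90, q3 = 8.36),
  "xray-in-field"         = c(median = 5.86, q1 = 3.35, q3 = 9.78),
  "xray-out-of-field"     = c(median = 4.66, q1 = 2.68, q3 = 7.84),
  "cisplatin-control"     = c(median = 4.83, q1 = 2.66, q3 = 8.11),
  "cisplatin-uniform"     = c(median = 5.28, q1 = 3.05, q3 = 8.86),
  "cisplatin-in-field"    = c(median = 5.03, q1 = 2.92, q3 = 8.21),
  "cisplatin-out-of-field" = c(median = 5.17, q1 = 3.04, q3 = 8.32)
)

# FUCCI state probabilities over (red = G1, yellow = early S,
# green = S/G2/M). The cisplatin green probability 0.703 is the published
# arrest fraction; the remaining mass split and the untreated asynchronous
# profile are package choices (see the methods vignette).
.fucci_presets <- list(
  untreated = c(red = 0.55, yellow = 0.12, green = 0.33),
  cisplatin = c(red = 0.197, yellow = 0.100, green = 0.703)
)

.group_order <- c("Control", "Uniform", "In-field", "Out-of-field")

# Compact aliases accepted wherever a preset id is expected.
.preset_alias <- function(name) {
  name <- sub("^fig2", "xray", name)
  name <- sub("^fig4", "cisplatin", name)
  name
}

.preset_group_key <- function(series, group) {
  paste0(series, "-", tolower(group))
}

#' Lognormal log-scale parameter from a median and interquartile range
#'
#' Fits the log-sigma of a lognormal distribution with fixed median `m` so
#' that its quartiles `m * exp(-z75 * sigma)` and `m * exp(+z75 * sigma)`
#' (z75 = qnorm(0.75)) best match the observed quartiles in least squares
#' over the two log-ratios; the solution is the closed form
#' `log(q3 / q1) / (2 * z75)`.
#'
#' @param median,q1,q3 Observed median and quartiles (same positive units).
#' @return The fitted log-scale sigma (dimensionless).
#' @export
lognormal_sigma_from_iqr <- function(median, q1, q3) {
  stopifnot(q1 > 0, q3 > q1, median > 0)
  log(q3 / q1) / (2 * stats::qnorm(0.75))
}

#' Per-group speed calibration presets
#'
#' Returns the lognormal per-cell speed law calibrated to a published
#' group: the cohort median (um/h), the quartiles it was fitted from, and
#' the fitted log-sigma. Ids are `"<series>-<group>"` with series `"xray"`
#' (no cisplatin) or `"cisplatin"`, and group `"control"`, `"uniform"`,
#' `"in-field"` or `"out-of-field"`; the shorthand series ids `fig2-*` and
#' `fig4-*` are accepted as aliases of `xray-*` and `cisplatin-*`.
#'
#' @param name Preset id, e.g. `"xray-control"`.
#' @return A list with `speed_median`, `speed_q1`, `speed_q3`,
#'   `speed_log_sigma` and `persistence` (0: the calibrated cohorts are
#'   modelled as pure random walks).
#' @export
speed_preset <- function(name) {
  key <- .preset_alias(tolower(name))
  cal <- .speed_calibration[[key]]
  if (is.null(cal)) {
    stop(sprintf("unknown speed preset '%s'; available: %s", name,
                 paste(names(.speed_calibration), collapse = ", ")),
         call. = FALSE)
  }
  list(
    speed_median = unname(cal["median"]),
    speed_q1 = unname(cal["q1"]),
    speed_q3 = unname(cal["q3"]),
    speed_log_sigma = lognormal_sigma_from_iqr(cal["median"], cal["q1"], cal["q3"]),
    persistence = 0
  )
}

#' FUCCI cell-cycle state presets
#'
#' State probabilities over `(red, yellow, green)` = (G1, early S, S/G2/M)
#' nuclear fluorescence. `"cisplatin"` encodes the published G2 arrest:
#' 70.3% of cells green after 5 uM cisplatin for 1 h plus 14 h incubation.
#'
#' @param name `"untreated"` or `"cisplatin"`.
#' @return Named probability vector `(red, yellow, green)`.
#' @export
fucci_preset <- function(name) {
  p <- .fucci_presets[[tolower(name)]]
  if (is.null(p)) {
    stop(sprintf("unknown FUCCI preset '%s'; available: %s", name,
                 paste(names(.fucci_presets), collapse = ", ")), call. = FALSE)
  }
  p
}

#' List shipped preset ids
#' @return List with `speed`, `fucci` and `experiment` preset id vectors.
#' @export
preset_names <- function() {
  list(speed = names(.speed_calibration),
       fucci = names(.fucci_presets),
       experiment = c("xray", "cisplatin"))
}

#' Full experiment configuration presets
#'
#' Builds a complete four-group experiment configuration (Control, Uniform,
#' In-field, Out-of-field) with every group's speed law calibrated to the
#' published cohort statistics of the chosen series, the standard dish
#' geometry, the 15-min / 24-h imaging cadence and the matching FUCCI
#' condition. Fields can then be overridden before running.
#'
#' @param name `"xray"` or `"cisplatin"` (aliases `"fig2"`, `"fig4"`).
#' @param n_cells_per_group,n_replicates,seed Convenience overrides.
#' @return A validated configuration list (see [synthetic_config()]).
#' @export
experiment_preset <- function(name, n_cells_per_group = 100,
                              n_replicates = 3, seed = 1) {
  series <- .preset_alias(tolower(name))
  if (!series %in% c("xray", "cisplatin")) {
    stop(sprintf("unknown experiment preset '%s'; available: xray, cisplatin",
                 name), call. = FALSE)
  }
  groups <- lapply(.group_order, function(g) speed_preset(.preset_group_key(series, g)))
  names(groups) <- .group_order
  fucci_conds <- if (series == "cisplatin") c("untreated", "cisplatin") else "untreated"
  synthetic_config(
    name = series,
    seed = seed,
    n_cells_per_group = n_cells_per_group,
    n_replicates = n_replicates,
    groups = groups,
    dish = dish_geometry(),
    fucci = stats::setNames(
      lapply(fucci_conds, function(cond) as.list(fucci_preset(cond))),
      fucci_conds)
  )
}
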