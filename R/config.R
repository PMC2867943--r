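#' Simulation configuration
#'
#' Assembles everything a run needs: fate probabilities, the cycle-time
#' distribution, division noise, the generative-layer width (the initial
#' file of proliferating basal cells), the target cell count at which
#' development arrests, the areal doubling time (identical for every
#' non-terminated cell), scheduler resolution, initial geometry and the
#' random seed.
#'
#' `doubling_time_hours` defaults to the cycle-time mean so that the average
#' cell exactly doubles its area per cycle; scenarios that alter cycle times
#' without altering the growth rate (e.g. cell-cycle-inhibitor mutants) set
#' it explicitly.
#'
#' @param fate A [fate_probabilities()].
#' @param cycle_dist A [cycle_time_distribution()].
#' @param noise A [division_noise()].
#' @param generative_width Number of generative-layer columns (initial cell
#'   file; default 8).
#' @param target_cells Non-generative cell count at which no new lineages
#'   are founded (default 1600).
#' @param doubling_time_hours Areal doubling time; default the cycle mean.
#' @param dt_hours Scheduler step (default 0.5); must not exceed a quarter
#'   of the mean cycle duration.
#' @param initial_area Area of each initial generative cell (square-micron
#'   scale; default 100).
#' @param initial_aspect Initial length/width ratio (default 2).
#' @param seed Integer random seed.
#' @param stomatal_max_rounds Maximum extra stomatal-lineage division rounds
#'   (default 1).
#' @param noise_free If `TRUE`, cycles are synchronous at the mean duration
#'   and splits are exactly symmetric: the four-size limit.
#' @return An object of class `simulation_config` (a list).
#' @export
simulation_config <- function(fate = fate_probabilities(0.05, 0.15, 0.8, 0.5),
                              cycle_dist = cycle_time_distribution(),
                              noise = division_noise(),
                              generative_width = 8L,
                              target_cells = 1600L,
                              doubling_time_hours = NULL,
                              dt_hours = 0.5,
                              initial_area = 100,
                              initial_aspect = 2,
                              seed = 1L,
                              stomatal_max_rounds = 1L,
                              noise_free = FALSE) {
  fate <- as_fate_probabilities(fate)
  stopifnot(inherits(cycle_dist, "cycle_time_distribution"),
            inherits(noise, "division_noise"))
  if (is.null(doubling_time_hours)) doubling_time_hours <- cycle_dist$mean_hours
  if (generative_width < 1L) stop("generative_width must be >= 1",
                                  call. = FALSE)
  if (target_cells < 1L) stop("target_cells must be >= 1", call. = FALSE)
  if (doubling_time_hours <= 0) stop("doubling_time_hours must be > 0",
                                     call. = FALSE)
  if (dt_hours <= 0) stop("dt_hours must be > 0", call. = FALSE)
  if (dt_hours > cycle_dist$mean_hours / 4) {
    stop("dt_hours must be at most a quarter of the mean cycle duration ",
         "(scheduler resolution)", call. = FALSE)
  }
  if (initial_area <= 0 || initial_aspect <= 0) {
    stop("initial_area and initial_aspect must be positive", call. = FALSE)
  }
  if (stomatal_max_rounds < 0L) stop("stomatal_max_rounds must be >= 0",
                                     call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(
    list(fate = fate, cycle_dist = cycle_dist, noise = noise,
         generative_width = as.integer(generative_width),
         target_cells = as.integer(target_cells),
         doubling_time_hours = doubling_time_hours, dt_hours = dt_hours,
         initial_area = initial_area, initial_aspect = initial_aspect,
         seed = seed, stomatal_max_rounds = as.integer(stomatal_max_rounds),
         noise_free = isTRUE(noise_free)),
    class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration\n")
  print(x$fate)
  print(x$cycle_dist)
  print(x$noise)
  cat(sprintf(
    "  generative width %d | target %d cells | doubling %.3g h | dt %.3g h\n",
    x$generative_width, x$target_cells, x$doubling_time_hours, x$dt_hours))
  cat(sprintf(
    "  initial area %.3g (aspect %.3g) | stomatal rounds <= %d | seed %d%s\n",
    x$initial_area, x$initial_aspect, x$stomatal_max_rounds, x$seed,
    if (x$noise_free) " | NOISE-FREE" else ""))
  invisible(x)
}

config_to_list <- function(config) {
  cd <- config$cycle_dist
  list(
    fate = as.list(unclass(config$fate)),
    cycle_dist = c(
      list(family = cd$family, mean_hours = cd$mean_hours,
           sd_hours = cd$sd_hours),
      if (!is.null(cd$histogram)) list(histogram = cd$histogram,
                                       bin_hours = cd$bin_hours),
      if (!is.null(cd$quantize_hours))
        list(quantize_hours = cd$quantize_hours)),
    noise = unclass(config$noise),
    generative_width = config$generative_width,
    target_cells = config$target_cells,
    doubling_time_hours = config$doubling_time_hours,
    dt_hours = config$dt_hours,
    initial_area = config$initial_area,
    initial_aspect = config$initial_aspect,
    seed = config$seed,
    stomatal_max_rounds = config$stomatal_max_rounds,
    noise_free = config$noise_free)
}

config_from_list <- function(x) {
  allowed <- c("fate", "cycle_dist", "noise", "generative_width",
               "target_cells", "doubling_time_hours", "dt_hours",
               "initial_area", "initial_aspect", "seed",
               "stomatal_max_rounds", "noise_free")
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_sub <- function(part, allowed, label) {
    unknown <- setdiff(names(part), allowed)
    if (length(unknown)) {
      stop("unknown ", label, " keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  args <- list()
  if (!is.null(x$fate)) {
    check_sub(x$fate, c("p1", "p2", "p3", "p_s"), "fate")
    args$fate <- do.call(fate_probabilities, as.list(x$fate))
  }
  if (!is.null(x$cycle_dist)) {
    check_sub(x$cycle_dist,
              c("family", "mean_hours", "sd_hours", "histogram", "bin_hours",
                "quantize_hours"), "cycle_dist")
    args$cycle_dist <- do.call(cycle_time_distribution, as.list(x$cycle_dist))
  }
  if (!is.null(x$noise)) {
    check_sub(x$noise, c("split_sd", "split_min", "split_max"), "noise")
    args$noise <- do.call(division_noise, as.list(x$noise))
  }
  scalars <- intersect(allowed[-(1:3)], names(x))
  args[scalars] <- x[scalars]
  do.call(simulation_config, args)
}

#' Read / write a simulation configuration as JSON
#'
#' The JSON mirrors the [simulation_config()] field names exactly; unknown
#' keys are an error.
#'
#' @param path File path.
#' @return `read_simulation_config()` returns a [simulation_config()];
#'   `write_simulation_config()` returns `path` invisibly.
#' @export
read_simulation_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  config_from_list(x)
}

#' @rdname read_simulation_config
#' @param config A [simulation_config()].
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
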