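# Tissue state and the fixed-step scheduler.
#
# The tissue is stored as an environment of parallel per-cell vectors
# (column store) so that growth can be vectorised; rows are append-only and
# a divided parent is simply flagged dead.  Row order equals cell_id order,
# which fixes the event-processing order and makes seeded runs
# bit-reproducible.

new_tissue_env <- function(config) {
  tis <- new.env(parent = baseenv())
  cap <- 4096L
  tis$n <- 0L
  tis$cap <- cap
  tis$id <- integer(cap); tis$parent <- integer(cap)
  tis$birth <- numeric(cap); tis$ploidy <- integer(cap)
  tis$area <- numeric(cap); tis$len <- numeric(cap); tis$wid <- numeric(cap)
  tis$col <- integer(cap); tis$phase <- character(cap)
  tis$pc <- integer(cap); tis$dur <- numeric(cap); tis$elapsed <- numeric(cap)
  tis$term <- numeric(cap); tis$rounds <- integer(cap); tis$ndiv <- integer(cap)
  tis$alive <- logical(cap)
  tis$time <- 0; tis$next_id <- 1L; tis$n_steps <- 0L
  tis$config <- config
  tis$stop_founders <- FALSE
  tis$n_nongen <- 0L
  tis$n_founders <- 0L
  tis$counts <- c(division = 0L, endocycle = 0L, termination = 0L,
                  stomatal_division = 0L)
  # event log
  ecap <- 4096L
  tis$ev_n <- 0L; tis$ev_cap <- ecap
  tis$ev_time <- numeric(ecap); tis$ev_type <- character(ecap)
  tis$ev_cell <- integer(ecap)
  tis$ev_d1 <- integer(ecap); tis$ev_d2 <- integer(ecap)
  tis$ev_d1area <- numeric(ecap); tis$ev_d2area <- numeric(ecap)
  tis$ev_split <- numeric(ecap); tis$ev_parea <- numeric(ecap)
  tis
}

grow_capacity <- function(tis) {
  add <- tis$cap
  tis$id <- c(tis$id, integer(add)); tis$parent <- c(tis$parent, integer(add))
  tis$birth <- c(tis$birth, numeric(add))
  tis$ploidy <- c(tis$ploidy, integer(add))
  tis$area <- c(tis$area, numeric(add)); tis$len <- c(tis$len, numeric(add))
  tis$wid <- c(tis$wid, numeric(add)); tis$col <- c(tis$col, integer(add))
  tis$phase <- c(tis$phase, character(add)); tis$pc <- c(tis$pc, integer(add))
  tis$dur <- c(tis$dur, numeric(add))
  tis$elapsed <- c(tis$elapsed, numeric(add))
  tis$term <- c(tis$term, numeric(add))
  tis$rounds <- c(tis$rounds, integer(add))
  tis$ndiv <- c(tis$ndiv, integer(add))
  tis$alive <- c(tis$alive, logical(add))
  tis$cap <- tis$cap + add
}

# Quoted blocks evaluated inside the tissue environment so that the
# per-cell vectors are modified in place rather than copied on every write
# (the scheduler's hot path).
ADD_CELL_EXPR <- quote({
  n <- n + 1L
  id[n] <- .cell$cell_id;        parent[n] <- .cell$parent_id
  birth[n] <- .cell$birth_time;  ploidy[n] <- .cell$ploidy
  area[n] <- .cell$area;         len[n] <- .cell$length
  wid[n] <- .cell$width;         col[n] <- .cell$column
  phase[n] <- .cell$phase;       pc[n] <- .cell$patterning_cycle
  dur[n] <- .cell$cycle_duration
  elapsed[n] <- .cell$cycle_elapsed
  term[n] <- NA_real_;           rounds[n] <- .cell$stomatal_rounds_done
  ndiv[n] <- .cell$n_divisions;  alive[n] <- TRUE
  if (.cell$phase != "generative") n_nongen <- n_nongen + 1L
  n
})

add_cell_row <- function(tis, cell) {
  if (tis$n + 1L > tis$cap) grow_capacity(tis)
  tis$.cell <- cell
  eval(ADD_CELL_EXPR, tis)
}

record_event <- function(tis, type, cell_id, d1 = NA_integer_,
                         d2 = NA_integer_, d1area = NA_real_,
                         d2area = NA_real_, split = NA_real_,
                         parea = NA_real_) {
  if (tis$ev_n + 1L > tis$ev_cap) {
    add <- tis$ev_cap
    tis$ev_time <- c(tis$ev_time, numeric(add))
    tis$ev_type <- c(tis$ev_type, character(add))
    tis$ev_cell <- c(tis$ev_cell, integer(add))
    tis$ev_d1 <- c(tis$ev_d1, integer(add))
    tis$ev_d2 <- c(tis$ev_d2, integer(add))
    tis$ev_d1area <- c(tis$ev_d1area, numeric(add))
    tis$ev_d2area <- c(tis$ev_d2area, numeric(add))
    tis$ev_split <- c(tis$ev_split, numeric(add))
    tis$ev_parea <- c(tis$ev_parea, numeric(add))
    tis$ev_cap <- tis$ev_cap + add
  }
  tis$.ev <- list(type, cell_id, d1, d2, d1area, d2area, split, parea)
  eval(RECORD_EVENT_EXPR, tis)
  invisible(tis$ev_n)
}

RECORD_EVENT_EXPR <- quote({
  ev_n <- ev_n + 1L
  ev_time[ev_n] <- time;        ev_type[ev_n] <- .ev[[1]]
  ev_cell[ev_n] <- .ev[[2]]
  ev_d1[ev_n] <- .ev[[3]];      ev_d2[ev_n] <- .ev[[4]]
  ev_d1area[ev_n] <- .ev[[5]];  ev_d2area[ev_n] <- .ev[[6]]
  ev_split[ev_n] <- .ev[[7]];   ev_parea[ev_n] <- .ev[[8]]
  counts[[.ev[[1]]]] <- counts[[.ev[[1]]]] + 1L
})

# light-weight cell_state view of row i (skips constructor validation)
row_cell <- function(tis, i) {
  structure(
    list(cell_id = tis$id[i], parent_id = tis$parent[i],
         birth_time = tis$birth[i], ploidy = tis$ploidy[i],
         area = tis$area[i], length = tis$len[i], width = tis$wid[i],
         column = tis$col[i], phase = tis$phase[i],
         patterning_cycle = tis$pc[i], cycle_duration = tis$dur[i],
         cycle_elapsed = tis$elapsed[i], termination_time = tis$term[i],
         stomatal_rounds_done = tis$rounds[i], n_divisions = tis$ndiv[i]),
    class = "cell_state")
}

#' Initialise a tissue from a simulation configuration
#'
#' Creates the initial file of `generative_width` generative cells (one per
#' lateral column) and seeds R's random number generator with the
#' configuration seed, so that a subsequent sequence of [step_tissue()]
#' calls (or [run_simulation()]) is reproducible.
#'
#' @param config A [simulation_config()].
#' @return A tissue state (environment) of class `tissue_state`.
#' @export
new_tissue <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tis <- new_tissue_env(config)
  W <- config$generative_width
  len0 <- sqrt(config$initial_area * config$initial_aspect)
  wid0 <- config$initial_area / len0
  for (k in seq_len(W)) {
    dur <- if (config$noise_free) config$cycle_dist$mean_hours
           else sample_cycle_time(config$cycle_dist)
    add_cell_row(tis, cell_state(
      cell_id = tis$next_id, parent_id = NA_integer_, birth_time = 0,
      ploidy = 2L, length = len0, width = wid0, column = k - 1L,
      phase = "generative", patterning_cycle = 0L, cycle_duration = dur))
    tis$next_id <- tis$next_id + 1L
  }
  class(tis) <- c("tissue_state", "environment")
  tis
}

# terminate row i at the current tissue time
terminate_row <- function(tis, i) {
  tis$phase[i] <- "terminated"
  tis$term[i] <- tis$time
  record_event(tis, "termination", tis$id[i])
}

# Stomatal-lineage decision for a newly created terminal 2C daughter
# (row i, patterning_cycle == 3).  Declining cells terminate at birth.
birth_decision <- function(tis, i) {
  cfg <- tis$config
  f <- decide_fate(row_cell(tis, i), cfg$fate, cfg$stomatal_max_rounds)
  if (f == "terminate") terminate_row(tis, i)
  invisible(f)
}

# execute the division of row i; returns row indices of the daughters
divide_row <- function(tis, i, orientation, s, stomatal = FALSE) {
  cfg <- tis$config
  parent_area <- tis$area[i]
  ids <- c(tis$next_id, tis$next_id + 1L)
  tis$next_id <- tis$next_id + 2L
  kids <- divide_cell(row_cell(tis, i), orientation, s,
                      cycle_dist = cfg$cycle_dist, child_ids = ids,
                      time = tis$time, noise_free = cfg$noise_free)
  tis$alive[i] <- FALSE
  if (tis$phase[i] != "generative") tis$n_nongen <- tis$n_nongen - 1L
  i1 <- add_cell_row(tis, kids[[1]])
  i2 <- add_cell_row(tis, kids[[2]])
  record_event(tis, if (stomatal) "stomatal_division" else "division",
               tis$id[i], d1 = ids[1], d2 = ids[2],
               d1area = kids[[1]]$area, d2area = kids[[2]]$area, split = s,
               parea = parent_area)
  c(i1, i2)
}

# handle the cycle completion of row i (fixed, documented draw order:
# fate draw; plane tie draw if needed; split draw; daughter 1 duration;
# daughter 2 duration; daughter 1 stomatal draw; daughter 2 stomatal draw)
complete_cycle <- function(tis, i) {
  cfg <- tis$config
  phase <- tis$phase[i]
  if (phase == "generative") {
    if (tis$stop_founders) {
      tis$dur[i] <- Inf   # generative layer idles once the target is reached
      return(invisible())
    }
    # generative divisions are always transverse: the basal daughter stays
    # in the generative layer of its column, the apical one founds a
    # patterning lineage
    s <- if (cfg$noise_free) 0.5 else sample_split_fraction(cfg$noise)
    divide_row(tis, i, "transverse", s)
    tis$n_founders <- tis$n_founders + 1L
    return(invisible())
  }
  if (phase == "endocycling") {
    tis$ploidy[i] <- min(tis$ploidy[i] * 2L, 16L)
    tis$pc[i] <- tis$pc[i] + 1L
    record_event(tis, "endocycle", tis$id[i])
    if (tis$pc[i] >= 3L) {
      terminate_row(tis, i)
    } else {
      tis$dur[i] <- if (cfg$noise_free) cfg$cycle_dist$mean_hours
                    else sample_cycle_time(cfg$cycle_dist)
      tis$elapsed[i] <- 0
    }
    return(invisible())
  }
  # patterning cell
  if (tis$pc[i] >= 3L) {
    # a surviving terminal 2C cell is in its stomatal round: it divides
    plane <- choose_division_plane(row_cell(tis, i), cfg$noise,
                                   cfg$noise_free)
    kids <- divide_row(tis, i, plane$orientation, plane$split_fraction,
                       stomatal = TRUE)
    birth_decision(tis, kids[1])
    birth_decision(tis, kids[2])
    return(invisible())
  }
  f <- decide_fate(row_cell(tis, i), cfg$fate, cfg$stomatal_max_rounds)
  if (f == "endocycle") {
    tis$phase[i] <- "endocycling"
    tis$ploidy[i] <- 4L
    tis$pc[i] <- tis$pc[i] + 1L
    record_event(tis, "endocycle", tis$id[i])
    if (tis$pc[i] >= 3L) {
      terminate_row(tis, i)
    } else {
      tis$dur[i] <- if (cfg$noise_free) cfg$cycle_dist$mean_hours
                    else sample_cycle_time(cfg$cycle_dist)
      tis$elapsed[i] <- 0
    }
  } else {
    plane <- choose_division_plane(row_cell(tis, i), cfg$noise,
                                   cfg$noise_free)
    kids <- divide_row(tis, i, plane$orientation, plane$split_fraction)
    if (tis$pc[kids[1]] >= 3L) {
      birth_decision(tis, kids[1])
      birth_decision(tis, kids[2])
    }
  }
  invisible()
}

# growth (vectorised, in place): same relative rate for every
# non-terminated cell; returns the rows whose cycle completed
GROW_STEP_EXPR <- quote({
  .live <- which(alive[seq_len(n)] & phase[seq_len(n)] != "terminated")
  area[.live] <- area[.live] * .g
  .sg <- sqrt(.g)
  len[.live] <- len[.live] * .sg
  wid[.live] <- wid[.live] * .sg
  elapsed[.live] <- elapsed[.live] + .dt
  time <- time + .dt
  n_steps <- n_steps + 1L
  .live[elapsed[.live] >= dur[.live] - 1e-9]
})

#' Advance a tissue by one scheduler time step
#'
#' All non-terminated cells grow exponentially for `dt` hours and their
#' cycle clocks advance; every cell whose clock has reached its sampled
#' cycle duration then completes its cycle (fate decision, division or
#' endocycle, new cycle). Completions are processed in ascending `cell_id`
#' order and every random draw follows a fixed, documented order, so seeded
#' runs are bit-reproducible. Daughters born during the step start their
#' cycle at the next step.
#'
#' @param tissue A tissue state from [new_tissue()].
#' @param dt Time step in hours; defaults to (and must equal) the
#'   configuration's `dt_hours`.
#' @return The tissue (invisibly); the state is modified in place.
#' @export
step_tissue <- function(tissue, dt = tissue$config$dt_hours) {
  tis <- tissue
  cfg <- tis$config
  if (!isTRUE(all.equal(dt, cfg$dt_hours))) {
    stop("step_tissue must be called with the configured dt_hours",
         call. = FALSE)
  }
  tis$.g <- 2^(dt / cfg$doubling_time_hours)
  tis$.dt <- dt
  due <- eval(GROW_STEP_EXPR, tis)
  for (i in due) complete_cycle(tis, i)
  if (!tis$stop_founders && tis$n_nongen >= cfg$target_cells) {
    tis$stop_founders <- TRUE
  }
  invisible(tis)
}

#' Current cells of a tissue
#'
#' @param tissue A tissue state.
#' @param include_dead Also return rows of cells that have divided (and so
#'   no longer exist).
#' @return A data frame with one row per cell.
#' @export
tissue_cells <- function(tissue, include_dead = FALSE) {
  tis <- tissue
  n <- tis$n
  keep <- if (include_dead) seq_len(n) else which(tis$alive[seq_len(n)])
  data.frame(
    cell_id = tis$id[keep], parent_id = tis$parent[keep],
    birth_time_h = tis$birth[keep], ploidy_c = tis$ploidy[keep],
    area = tis$area[keep], length = tis$len[keep], width = tis$wid[keep],
    column = tis$col[keep], phase = tis$phase[keep],
    patterning_cycle = tis$pc[keep], cycle_duration = tis$dur[keep],
    cycle_elapsed = tis$elapsed[keep], termination_time_h = tis$term[keep],
    stomatal_rounds_done = tis$rounds[keep], n_divisions = tis$ndiv[keep],
    stringsAsFactors = FALSE)
}

#' Terminal cell table of a tissue
#'
#' One record per terminated non-generative cell, with its frozen area and
#' ploidy. This is the simulator's primary output, analogous to measuring
#' every cell of the mature epidermis.
#'
#' @param tissue A tissue state.
#' @return A data frame of class `cell_table` with columns `cell_id`,
#'   `parent_id`, `birth_time_h`, `termination_time_h`, `ploidy_c`, `area`,
#'   `length`, `width`, `column`, `n_divisions`.
#' @export
tissue_cell_table <- function(tissue) {
  tis <- tissue
  n <- tis$n
  keep <- which(tis$alive[seq_len(n)] &
                tis$phase[seq_len(n)] == "terminated")
  out <- data.frame(
    cell_id = tis$id[keep], parent_id = tis$parent[keep],
    birth_time_h = tis$birth[keep], termination_time_h = tis$term[keep],
    ploidy_c = tis$ploidy[keep], area = tis$area[keep],
    length = tis$len[keep], width = tis$wid[keep], column = tis$col[keep],
    n_divisions = tis$ndiv[keep], stringsAsFactors = FALSE)
  class(out) <- c("cell_table", "data.frame")
  out
}

tissue_events <- function(tissue) {
  tis <- tissue
  j <- seq_len(tis$ev_n)
  data.frame(
    time_h = tis$ev_time[j], event = tis$ev_type[j],
    cell_id = tis$ev_cell[j], daughter1_id = tis$ev_d1[j],
    daughter2_id = tis$ev_d2[j], daughter1_area = tis$ev_d1area[j],
    daughter2_area = tis$ev_d2area[j], split_fraction = tis$ev_split[j],
    parent_area = tis$ev_parea[j],
    stringsAsFactors = FALSE)
}

#' Run a full tissue simulation
#'
#' Steps the tissue until the number of non-generative cells (terminated
#' plus in progress) reaches `target_cells`, then lets every in-progress
#' cell run to termination with no further generative divisions, emulating
#' the arrest of sepal development at about the wild-type cell count.
#'
#' @param config A [simulation_config()].
#' @param max_steps Safety cap on scheduler steps; exceeding it raises a
#'   runtime-limit error (a valid configuration terminates long before).
#' @return An object of class `sepal_run`: a list with `cells` (the terminal
#'   [tissue_cell_table()]), `log` (seed, timings, event counts), `events`
#'   (per-event records including daughter areas at each division) and
#'   `config`.
#' @examples
#' run <- run_simulation(scenario_config("lgo", target_cells = 200, seed = 1))
#' table(run$cells$ploidy_c)
#' @export
run_simulation <- function(config, max_steps = 400000L) {
  tis <- new_tissue(config)
  repeat {
    step_tissue(tis)
    if (tis$stop_founders) {
      n <- tis$n
      active <- any(tis$alive[seq_len(n)] &
                    (tis$phase[seq_len(n)] == "patterning" |
                     tis$phase[seq_len(n)] == "endocycling"))
      if (!active) break
    }
    if (tis$n_steps >= max_steps) {
      stop("run_simulation: exceeded ", max_steps,
           " steps without terminating (runtime limit)", call. = FALSE)
    }
  }
  cells <- tissue_cell_table(tis)
  log <- list(
    seed = config$seed,
    target_cells = config$target_cells,
    total_time_h = tis$time,
    n_steps = tis$n_steps,
    n_founders = tis$n_founders,
    n_divisions = unname(tis$counts[["division"]]),
    n_endocycles = unname(tis$counts[["endocycle"]]),
    n_terminations = unname(tis$counts[["termination"]]),
    n_stomatal_divisions = unname(tis$counts[["stomatal_division"]]),
    n_cells_terminal = nrow(cells),
    reached_target = tis$n_nongen >= config$target_cells)
  structure(list(cells = cells, log = log, events = tissue_events(tis),
                 config = config),
            class = "sepal_run")
}

#' @export
print.sepal_run <- function(x, ...) {
  counts <- table(factor(x$cells$ploidy_c, levels = c(2, 4, 8, 16)))
  cat(sprintf(
    "Sepal simulation (seed %d): %d terminal cells in %.0f h (%d founders)\n",
    x$log$seed, x$log$n_cells_terminal, x$log$total_time_h,
    x$log$n_founders))
  cat(sprintf("  ploidy  2C: %d   4C: %d   8C: %d   16C: %d\n",
              counts[["2"]], counts[["4"]], counts[["8"]], counts[["16"]]))
  cat(sprintf("  events: %d divisions, %d endocycles, %d stomatal divisions\n",
              x$log$n_divisions, x$log$n_endocycles,
              x$log$n_stomatal_divisions))
  invisible(x)
}
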