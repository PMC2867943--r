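#' Construct a single epidermal cell
#'
#' A cell is modelled as an axis-aligned rectangle of `length` (apical-basal)
#' by `width` (lateral), with `area = length * width` at all times. Ploidy is
#' the C-value in {2, 4, 8, 16}: 2 unless the cell is endocycling or
#' terminated, doubling with each completed endocycle. `patterning_cycle`
#' counts completed patterning cell cycles (0..3); a cell with three
#' completed cycles is terminated (after at most the optional
#' stomatal-lineage rounds).
#'
#' @param cell_id Integer identifier (unique within a tissue).
#' @param parent_id Integer identifier of the parent, or `NA`.
#' @param birth_time Birth time in hours.
#' @param ploidy C-value, one of 2, 4, 8, 16.
#' @param length,width Rectangle dimensions (> 0); area is their product.
#' @param column Lateral column index of the founding generative cell.
#' @param phase One of `"generative"`, `"patterning"`, `"endocycling"`,
#'   `"terminated"`.
#' @param patterning_cycle Completed patterning cycles (0..3).
#' @param cycle_duration Sampled length of the current cycle in hours.
#' @param cycle_elapsed Time elapsed in the current cycle (hours).
#' @param termination_time Hours, or `NA` while the cell is not terminated.
#' @param stomatal_rounds_done Completed stomatal-lineage division rounds in
#'   this cell's lineage.
#' @param n_divisions Number of divisions between the lineage founder and
#'   this cell.
#' @return An object of class `cell_state` (a list).
#' @export
cell_state <- function(cell_id, parent_id = NA_integer_, birth_time = 0,
                       ploidy = 2L, length = 10, width = 10, column = 0L,
                       phase = "patterning", patterning_cycle = 0L,
                       cycle_duration = 24, cycle_elapsed = 0,
                       termination_time = NA_real_,
                       stomatal_rounds_done = 0L, n_divisions = 0L) {
  phase <- match.arg(phase,
                     c("generative", "patterning", "endocycling", "terminated"))
  if (!ploidy %in% c(2L, 4L, 8L, 16L)) {
    stop("ploidy must be one of 2, 4, 8, 16", call. = FALSE)
  }
  if (length <= 0 || width <= 0) {
    stop("cell dimensions must be positive", call. = FALSE)
  }
  if (ploidy != 2L && !phase %in% c("endocycling", "terminated")) {
    stop("only endocycling or terminated cells can exceed 2C", call. = FALSE)
  }
  if (patterning_cycle < 0L || patterning_cycle > 3L) {
    stop("patterning_cycle must be in 0..3", call. = FALSE)
  }
  if (cycle_duration <= 0) stop("cycle_duration must be > 0", call. = FALSE)
  if (cycle_elapsed < 0 || cycle_elapsed > cycle_duration + 1e-9) {
    stop("cycle_elapsed must lie in [0, cycle_duration]", call. = FALSE)
  }
  structure(
    list(cell_id = as.integer(cell_id), parent_id = as.integer(parent_id),
         birth_time = birth_time, ploidy = as.integer(ploidy),
         area = length * width, length = length, width = width,
         column = as.integer(column), phase = phase,
         patterning_cycle = as.integer(patterning_cycle),
         cycle_duration = cycle_duration, cycle_elapsed = cycle_elapsed,
         termination_time = termination_time,
         stomatal_rounds_done = as.integer(stomatal_rounds_done),
         n_divisions = as.integer(n_divisions)),
    class = "cell_state"
  )
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf(
    "Cell %d [%s] %dC  area %.4g (%.3g x %.3g)  cycle %d (%.3g/%.3g h)\n",
    x$cell_id, x$phase, x$ploidy, x$area, x$length, x$width,
    x$patterning_cycle, x$cycle_elapsed, x$cycle_duration))
  invisible(x)
}

#' Grow a cell exponentially for a time step
#'
#' All non-terminated cells grow at the same relative rate: area doubles
#' every `doubling_time` hours, so a cell that happens to draw a longer cell
#' cycle ends it larger. Growth is isotropic (length and width scale by the
#' square root of the area factor), and the cell's cycle clock advances by
#' `dt`. Terminated cells are returned unchanged (they neither grow nor
#' age).
#'
#' @param cell A [cell_state()].
#' @param dt Time step in hours (>= 0).
#' @param doubling_time Areal doubling time in hours (> 0).
#' @return The grown `cell_state`.
#' @export
grow_cell <- function(cell, dt, doubling_time) {
  if (!is.numeric(dt) || dt < 0) {
    stop("dt must be a nonnegative number of hours", call. = FALSE)
  }
  if (doubling_time <= 0) stop("doubling_time must be > 0", call. = FALSE)
  if (cell$phase == "terminated") return(cell)
  g <- 2^(dt / doubling_time)
  cell$area <- cell$area * g
  cell$length <- cell$length * sqrt(g)
  cell$width <- cell$width * sqrt(g)
  cell$cycle_elapsed <- cell$cycle_elapsed + dt
  cell
}

#' Choose the division plane of a cell
#'
#' Only transverse (splitting the length) or longitudinal (splitting the
#' width) planes are allowed. For each candidate the even-split daughter
#' aspect ratio `r = max(L', W') / min(L', W')` is computed and the plane
#' whose ratio is closest to 2:1 is chosen; "closest" is measured on the log
#' scale, `|log r - log 2|`, which treats r = 1 and r = 4 symmetrically.
#' Exact ties are broken by a single uniform draw (50/50). The split
#' fraction `s` is drawn from the truncated normal described by `noise`
#' (exactly 0.5 when `noise_free` or `split_sd = 0`).
#'
#' @param cell A [cell_state()] in phase `"generative"` or `"patterning"`.
#' @param noise A [division_noise()].
#' @param noise_free If `TRUE`, force an exactly symmetric split.
#' @return A list with `orientation` (`"transverse"` or `"longitudinal"`)
#'   and `split_fraction`.
#' @export
choose_division_plane <- function(cell, noise = division_noise(),
                                  noise_free = FALSE) {
  if (!cell$phase %in% c("generative", "patterning")) {
    stop("choose_division_plane: cell ", cell$cell_id, " is in phase '",
         cell$phase, "' and cannot divide", call. = FALSE)
  }
  if (cell$length <= 0 || cell$width <= 0) {
    stop("choose_division_plane: nonpositive cell dimensions", call. = FALSE)
  }
  aspect_dist <- function(L, W) {
    r <- max(L, W) / min(L, W)
    abs(log(r) - log(2))
  }
  d_trans <- aspect_dist(cell$length / 2, cell$width)
  d_long <- aspect_dist(cell$length, cell$width / 2)
  orientation <- if (abs(d_trans - d_long) < 1e-12) {
    if (stats::runif(1) < 0.5) "transverse" else "longitudinal"
  } else if (d_trans < d_long) "transverse" else "longitudinal"
  s <- if (noise_free) 0.5 else sample_split_fraction(noise)
  list(orientation = orientation, split_fraction = s)
}

#' Execute a cell division
#'
#' Splits a cell into two daughters along the given orientation with areas
#' `s * A` and `(1 - s) * A` (their sum is exactly the parent area). Both
#' daughters are 2C. A generative parent yields one apical patterning
#' daughter (the first, receiving fraction `s`) and one basal daughter that
#' stays in the generative layer in the parent's column; a patterning parent
#' yields two patterning daughters with `patterning_cycle` incremented. A
#' parent dividing in the stomatal-lineage phase (`patterning_cycle == 3`)
#' yields daughters with `stomatal_rounds_done` incremented instead. A fresh
#' cycle duration is sampled independently for each daughter (first daughter
#' first, consuming the random stream in that documented order).
#'
#' @param cell The dividing [cell_state()].
#' @param orientation `"transverse"` (splits length) or `"longitudinal"`
#'   (splits width).
#' @param split_fraction Fraction `s` of the area given to the first
#'   (apical) daughter; must lie strictly in (0, 1).
#' @param cycle_dist A [cycle_time_distribution()] for the daughters' cycle
#'   durations.
#' @param child_ids Integer vector of length 2 with the daughters' ids.
#' @param time Division time in hours (daughters' birth time).
#' @param noise_free If `TRUE`, daughters' cycle durations are set to the
#'   distribution mean (synchronous limit).
#' @return List of two `cell_state` daughters.
#' @export
divide_cell <- function(cell, orientation, split_fraction,
                        cycle_dist = cycle_time_distribution(),
                        child_ids = cell$cell_id + c(1L, 2L),
                        time = cell$birth_time + cell$cycle_elapsed,
                        noise_free = FALSE) {
  s <- split_fraction
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s >= 1) {
    stop("split_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  orientation <- match.arg(orientation, c("transverse", "longitudinal"))
  if (!cell$phase %in% c("generative", "patterning")) {
    stop("divide_cell: cell ", cell$cell_id, " is in phase '", cell$phase,
         "' and cannot divide", call. = FALSE)
  }
  dims <- function(frac) {
    if (orientation == "transverse") c(cell$length * frac, cell$width)
    else c(cell$length, cell$width * frac)
  }
  dur <- function() {
    if (noise_free) cycle_dist$mean_hours else sample_cycle_time(cycle_dist)
  }
  stomatal <- cell$phase == "patterning" && cell$patterning_cycle >= 3L
  child_pc <- if (cell$phase == "generative") 0L
              else min(cell$patterning_cycle + 1L, 3L)
  child_rounds <- cell$stomatal_rounds_done + if (stomatal) 1L else 0L
  child_ndiv <- if (cell$phase == "generative") 0L else cell$n_divisions + 1L
  make_child <- function(id, frac, phase) {
    d <- dims(frac)
    cell_state(cell_id = id, parent_id = cell$cell_id, birth_time = time,
               ploidy = 2L, length = d[1], width = d[2],
               column = cell$column, phase = phase,
               patterning_cycle = if (phase == "generative") 0L else child_pc,
               cycle_duration = dur(), cycle_elapsed = 0,
               stomatal_rounds_done = if (phase == "generative") 0L
                                      else child_rounds,
               n_divisions = if (phase == "generative") 0L else child_ndiv)
  }
  d1 <- make_child(child_ids[1], s, "patterning")
  d2 <- make_child(child_ids[2], 1 - s,
                   if (cell$phase == "generative") "generative"
                   else "patterning")
  # enforce exact area conservation against floating-point drift
  d1$area <- s * cell$area
  d2$area <- cell$area - d1$area
  list(d1, d2)
}
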