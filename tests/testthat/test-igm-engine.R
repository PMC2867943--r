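# Unit tests for the cell-level operations and the tissue scheduler.

test_that("growth doubles area per doubling time, is a semigroup, and spares terminated cells", {
  cell <- cell_state(1, length = 1, width = 1, cycle_duration = 48)
  grown <- grow_cell(cell, dt = 24, doubling_time = 24)
  expect_equal(grown$area, 2)
  expect_equal(grown$length * grown$width, grown$area)
  expect_equal(grown$length / grown$width, cell$length / cell$width)
  expect_equal(grown$cycle_elapsed, 24)

  expect_equal(grow_cell(cell, 0, 24)$area, cell$area)

  half1 <- grow_cell(cell, 12, 24)
  half2 <- grow_cell(half1, 12, 24)
  expect_equal(half2$area, 2, tolerance = 1e-12)

  dead <- cell_state(2, phase = "terminated", termination_time = 10)
  expect_identical(grow_cell(dead, 24, 24), dead)

  expect_error(grow_cell(cell, -1, 24), "nonnegative")
})

test_that("fate decisions follow the patterning rules and are irreversible", {
  fate0 <- fate_probabilities(0, 0, 0, 0)
  fate1 <- fate_probabilities(1, 1, 1, 0)
  for (pc in 0:2) {
    cell <- cell_state(1, patterning_cycle = pc)
    expect_identical(decide_fate(cell, fate0), "divide")
    expect_identical(decide_fate(cell, fate1), "endocycle")
  }
  # committed cells keep endocycling through their third cycle
  endo <- cell_state(1, ploidy = 4, phase = "endocycling",
                     patterning_cycle = 1)
  expect_identical(decide_fate(endo, fate0), "endocycle")
  endo2 <- cell_state(1, ploidy = 8, phase = "endocycling",
                      patterning_cycle = 2)
  expect_identical(decide_fate(endo2, fate0), "endocycle")

  # terminal 2C: stomatal decision, bounded by the allowed rounds
  leaf <- cell_state(1, patterning_cycle = 3)
  expect_identical(decide_fate(leaf, fate_probabilities(0, 0, 0, 1)),
                   "stomatal_divide")
  expect_identical(decide_fate(leaf, fate0), "terminate")
  spent <- cell_state(1, patterning_cycle = 3, stomatal_rounds_done = 1)
  expect_identical(decide_fate(spent, fate_probabilities(0, 0, 0, 1)),
                   "terminate")

  expect_error(decide_fate(cell_state(1, phase = "generative"), fate0),
               "phase")
  expect_error(decide_fate(cell_state(1, phase = "terminated"), fate0),
               "phase")
})

test_that("each stochastic fate decision consumes exactly one uniform variate", {
  fate <- fate_probabilities(0.5, 0.5, 0.5, 0.5)
  cell <- cell_state(1, patterning_cycle = 1)
  set.seed(99)
  decide_fate(cell, fate)
  after <- stats::runif(1)
  set.seed(99)
  expect_identical(after, stats::runif(2)[2])
  # forced outcomes consume none
  endo <- cell_state(1, ploidy = 4, phase = "endocycling",
                     patterning_cycle = 1)
  set.seed(99)
  decide_fate(endo, fate)
  expect_identical(stats::runif(1), {set.seed(99); stats::runif(1)})
})

test_that("division plane minimises the log-distance of the daughter aspect ratio from 2:1", {
  noise <- division_noise()
  # 4x1: transverse daughters are 2x1 (ratio 2, distance 0) -> deterministic
  long_cell <- cell_state(1, length = 4, width = 1)
  for (seed in 1:5) {
    set.seed(seed)
    expect_identical(choose_division_plane(long_cell, noise)$orientation,
                     "transverse")
  }
  # wide cell: mirrored case
  wide_cell <- cell_state(1, length = 1, width = 4)
  set.seed(1)
  expect_identical(choose_division_plane(wide_cell, noise)$orientation,
                   "longitudinal")
  # 1x1 (both give ratio 2) and 2x1 (ratios 1 and 4, equidistant in log):
  # ties resolved by the random stream, so both orientations occur
  for (dims in list(c(1, 1), c(2, 1))) {
    cell <- cell_state(1, length = dims[1], width = dims[2])
    seen <- vapply(1:40, function(s) {
      set.seed(s)
      choose_division_plane(cell, noise)$orientation
    }, "")
    expect_setequal(unique(seen), c("transverse", "longitudinal"))
  }
  # split fraction respects truncation and the noise-free override
  set.seed(7)
  s <- replicate(500, choose_division_plane(long_cell, noise)$split_fraction)
  expect_true(all(s >= noise$split_min & s <= noise$split_max))
  expect_gt(stats::sd(s), 0)
  expect_identical(
    choose_division_plane(long_cell, noise, noise_free = TRUE)$split_fraction,
    0.5)
  expect_error(
    choose_division_plane(cell_state(1, ploidy = 4, phase = "endocycling",
                                     patterning_cycle = 1), noise),
    "cannot divide")
})

test_that("divide_cell conserves area exactly and assigns daughter roles", {
  dist <- cycle_time_distribution("lognormal", 24, 0)
  cell <- cell_state(10, length = 5, width = 2, patterning_cycle = 1,
                     n_divisions = 2)
  kids <- divide_cell(cell, "transverse", 0.5, dist, child_ids = c(11, 12))
  expect_identical(kids[[1]]$area + kids[[2]]$area, cell$area)
  expect_equal(kids[[1]]$area, 5)

  kids <- divide_cell(cell, "transverse", 0.55, dist, child_ids = c(11, 12))
  expect_equal(kids[[1]]$area, 5.5)
  expect_equal(kids[[2]]$area, 4.5)
  expect_equal(kids[[1]]$width, cell$width)   # transverse splits length
  expect_equal(kids[[1]]$patterning_cycle, 2L)
  expect_equal(kids[[1]]$n_divisions, 3L)
  expect_equal(kids[[1]]$ploidy, 2L)
  expect_equal(kids[[1]]$cycle_elapsed, 0)

  gen <- cell_state(1, length = 4, width = 2, phase = "generative",
                    column = 3)
  gk <- divide_cell(gen, "transverse", 0.5, dist, child_ids = c(2, 3))
  expect_identical(gk[[1]]$phase, "patterning")
  expect_identical(gk[[2]]$phase, "generative")
  expect_identical(gk[[2]]$column, 3L)
  expect_identical(gk[[1]]$patterning_cycle, 0L)

  stoma <- cell_state(5, patterning_cycle = 3)
  sk <- divide_cell(stoma, "longitudinal", 0.5, dist, child_ids = c(6, 7))
  expect_identical(sk[[1]]$patterning_cycle, 3L)
  expect_identical(sk[[1]]$stomatal_rounds_done, 1L)

  expect_error(divide_cell(cell, "transverse", 0, dist), "strictly in")
  expect_error(divide_cell(cell, "transverse", 1, dist), "strictly in")
})

test_that("cycle-time sampling matches its parameterisation", {
  # degenerate distribution returns the mean exactly
  expect_identical(
    sample_cycle_time(cycle_time_distribution("lognormal", 24, 0)), 24)
  expect_identical(
    sample_cycle_time(cycle_time_distribution("gamma", 30, 0)), 30)

  set.seed(1)
  x <- sample_cycle_time(cycle_time_distribution("lognormal", 24, 9), 1e5)
  expect_lt(abs(mean(x) - 24), 0.2)       # law of large numbers
  expect_lt(abs(stats::sd(x) - 9), 0.2)
  expect_true(all(x > 0))

  set.seed(1)
  g <- sample_cycle_time(cycle_time_distribution("gamma", 24, 9), 1e5)
  expect_lt(abs(mean(g) - 24), 0.2)

  q <- sample_cycle_time(
    cycle_time_distribution("lognormal", 24, 9, quantize_hours = 6), 1000)
  expect_true(all(q %% 6 == 0) && all(q > 0))

  hist <- data.frame(bin_start_hours = c(12, 18, 24),
                     probability = c(0.25, 0.5, 0.25))
  emp <- cycle_time_distribution("empirical", histogram = hist)
  set.seed(2)
  e <- sample_cycle_time(emp, 2e4)
  expect_true(all(e >= 12 & e <= 30))
  expect_lt(abs(mean(e >= 18 & e < 24) - 0.5), 0.02)

  expect_error(cycle_time_distribution("empirical"), "histogram")
  expect_error(cycle_time_distribution("lognormal", -2, 1), "positive")
  expect_error(
    cycle_time_distribution("empirical",
      histogram = data.frame(bin_start_hours = 0, probability = 0.5)),
    "sum to 1")
})

test_that("the scheduler grows cells between events and divides the generative file on cycle completion", {
  cfg <- scenario_config("wildtype", noise_free = TRUE, seed = 1,
                         target_cells = 50)
  tis <- new_tissue(cfg)
  expect_equal(nrow(tissue_cells(tis)), 8)

  step_tissue(tis)   # mid-cycle: only areas and clocks change
  cells <- tissue_cells(tis)
  expect_equal(nrow(cells), 8)
  expect_equal(cells$area, rep(100 * 2^(0.5 / 24), 8))
  expect_equal(cells$cycle_elapsed, rep(0.5, 8))

  # one full synchronous cycle: every generative cell divides once
  for (i in seq_len(24 / 0.5 - 1)) step_tissue(tis)
  cells <- tissue_cells(tis)
  expect_equal(sum(cells$phase == "generative"), 8)
  expect_equal(sum(cells$phase == "patterning"), 8)
  # one generative cell per column, conserved
  expect_setequal(cells$column[cells$phase == "generative"], 0:7)

  expect_error(step_tissue(tis, dt = 1), "configured dt_hours")
})

test_that("the smallest runs are hand-traceable", {
  # with asynchronous cycles the first apical daughter founds the only
  # lineage; forced to endoreduplicate at once it becomes one 16C giant
  cfg <- scenario_config("custom", fate = fate_probabilities(1, 1, 1, 0),
                         target_cells = 1, seed = 3)
  run <- run_simulation(cfg)
  expect_equal(nrow(run$cells), 1)
  expect_equal(run$cells$ploidy_c, 16)
  expect_equal(run$cells$n_divisions, 0)

  # commitment at cycle 2 caps terminal ploidy at 8C (never 16C)
  cfg2 <- scenario_config("custom", fate = fate_probabilities(0, 1, 1, 0),
                          target_cells = 1, seed = 3)
  run2 <- run_simulation(cfg2)
  expect_true(all(run2$cells$ploidy_c == 8))

  # with no endoreduplication, each founder yields 8 terminal 2C cells;
  # in the noise-free limit all at exactly the founder's birth area, and
  # a forced-16C run gives exactly three doublings of it
  cfg3 <- scenario_config("custom", fate = fate_probabilities(0, 0, 0, 0),
                          target_cells = 1, seed = 3, noise_free = TRUE)
  run3 <- run_simulation(cfg3)
  expect_true(all(run3$cells$ploidy_c == 2))
  expect_equal(nrow(run3$cells) %% 8, 0)
  expect_equal(run3$cells$area, rep(100, nrow(run3$cells)),
               tolerance = 1e-9)
  cfg4 <- scenario_config("custom", fate = fate_probabilities(1, 1, 1, 0),
                          target_cells = 1, seed = 3, noise_free = TRUE)
  run4 <- run_simulation(cfg4)
  expect_true(all(run4$cells$ploidy_c == 16))
  expect_equal(run4$cells$area, rep(800, nrow(run4$cells)),
               tolerance = 1e-9)
})

test_that("divisions conserve area and endocycling cells never divide", {
  run <- run_simulation(small_config())
  div <- run$events[run$events$event %in% c("division", "stomatal_division"), ]
  expect_gt(nrow(div), 100)
  expect_true(all(abs(div$daughter1_area + div$daughter2_area -
                      div$parent_area) <= 1e-9 * div$parent_area))
  # irreversibility: no cell divides after an endocycle event
  endo_ids <- run$events$cell_id[run$events$event == "endocycle"]
  expect_length(intersect(endo_ids, div$cell_id), 0)
  # ploidy cap and admissible values
  expect_true(all(run$cells$ploidy_c %in% c(2, 4, 8, 16)))
})

test_that("seeded runs are bit-reproducible and seeds matter", {
  r1 <- run_simulation(small_config())
  r2 <- run_simulation(small_config())
  expect_identical(r1$cells, r2$cells)
  expect_identical(r1$events, r2$events)
  r3 <- run_simulation(scenario_config("wildtype", target_cells = 200,
                                       seed = 43))
  expect_false(identical(r1$cells, r3$cells))
})
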