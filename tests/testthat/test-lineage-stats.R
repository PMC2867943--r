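# Measurement utilities: cell-table summaries, distribution comparisons,
# and the tracked-lineage statistics with their synthetic fixture.

test_that("cell-table summaries report fractions, per-ploidy spread and giant cells", {
  one <- data.frame(cell_id = 1L, parent_id = NA_integer_, birth_time_h = 0,
                    termination_time_h = 72, ploidy_c = 16L, area = 800,
                    length = 40, width = 20, column = 0L, n_divisions = 0L)
  s <- summarize_cell_table(one)
  expect_equal(as.numeric(unclass(s$fractions)), c(0, 0, 0, 1))
  expect_equal(s$by_ploidy$cv_area[s$by_ploidy$ploidy_c == 16], 0)
  expect_equal(s$giant_cells, 1)
  expect_equal(s$distinct_sizes, 1)

  expect_error(summarize_cell_table(one[0, ]), "empty")

  # a noisy run: every ploidy class has spread, and mean area increases
  # strictly with ploidy (earlier committers grow for longer)
  run <- run_simulation(scenario_config("wildtype", target_cells = 600,
                                        seed = 8))
  s2 <- summarize_cell_table(run$cells)
  bp <- s2$by_ploidy[s2$by_ploidy$n > 1, ]
  expect_true(all(bp$cv_area > 0))
  expect_true(all(diff(bp$mean_area) > 0))
})

test_that("distinct-size clustering counts well-separated area groups", {
  expect_equal(count_distinct_sizes(c(1, 1, 1)), 1)
  expect_equal(count_distinct_sizes(c(1, 2, 4, 8) * 100), 4)
  expect_equal(count_distinct_sizes(c(1, 1 + 1e-9, 2)), 2)
  expect_equal(count_distinct_sizes(numeric(0)), 0)
})

test_that("area-distribution comparison is a symmetric KS test on log2 areas", {
  set.seed(1)
  a <- stats::rlnorm(300, 5, 0.6)
  expect_equal(compare_area_distributions(a, a)$D, 0)
  expect_equal(compare_area_distributions(a, a)$p_value, 1)

  b <- stats::rlnorm(200, 5.5, 0.6)
  ab <- compare_area_distributions(a, b)
  ba <- compare_area_distributions(b, a)
  expect_equal(ab$D, ba$D)
  expect_true(ab$D > 0 && ab$D <= 1)

  expect_error(compare_area_distributions(numeric(0), a), "empty")
  expect_error(compare_area_distributions(a, c(b, -1)), "positive")
})

test_that("wild-type and giant-cell-free runs differ in the upper size tail", {
  wt <- run_simulation(scenario_config("wildtype", target_cells = 500,
                                       seed = 21))
  lgo <- run_simulation(scenario_config("lgo", target_cells = 500,
                                        seed = 22))
  expect_equal(sum(lgo$cells$ploidy_c == 16), 0)
  cmp <- compare_area_distributions(wt$cells$area, lgo$cells$area)
  expect_gt(cmp$D, 0.1)
  expect_gt(stats::quantile(wt$cells$area, 0.999),
            stats::quantile(lgo$cells$area, 0.999))
})

test_that("the lineage fixture emulates windowed live imaging", {
  # zero-length window: founders only, no divisions
  t0 <- generate_lineage_fixture(n_initial = 5, duration_hours = 0, seed = 1)
  expect_equal(sort(unique(t0$cell_id)), 1:5)
  expect_true(all(t0$time_h == 0))
  expect_false(any(t0$fate == "divided"))

  # determinism
  ta <- generate_lineage_fixture(n_initial = 20, seed = 9)
  tb <- generate_lineage_fixture(n_initial = 20, seed = 9)
  expect_identical(ta, tb)

  # a 72-h window at mean cycle 24 h: lineage depths of 1-4 divisions
  # predominate among end-of-window cells
  tab <- generate_lineage_fixture(n_initial = 60, seed = 10)
  cells <- tab[!duplicated(tab$cell_id), c("cell_id", "parent_id")]
  depth <- integer(max(cells$cell_id))
  depth[cells$cell_id[is.na(cells$parent_id)]] <- 0L
  for (i in seq_len(nrow(cells))) {
    p <- cells$parent_id[i]
    if (!is.na(p)) depth[cells$cell_id[i]] <- depth[p] + 1L
  }
  leaves <- tab$cell_id[!duplicated(tab$cell_id) & tab$fate != "divided"]
  expect_gt(mean(depth[leaves] %in% 1:4), 0.8)

  # committed cells never divide and are labelled as endoreduplicating
  te <- generate_lineage_fixture(n_initial = 40, p_endo = 0.5, seed = 11)
  endo_ids <- unique(te$cell_id[te$fate == "endoreduplicating"])
  expect_gt(length(endo_ids), 0)
  expect_false(any(te$parent_id %in% endo_ids))
})

test_that("cycle times are measured per internal edge with censoring handled", {
  # constant 24-h cycles land entirely in the 24-h histogram bin
  const <- generate_lineage_fixture(
    n_initial = 15, cycle_dist = cycle_time_distribution("lognormal", 24, 0),
    split_sd = 0, seed = 2)
  ct <- cycle_times_from_lineage(const)
  expect_true(all(ct$durations == 24))
  expect_equal(sum(ct$histogram$count), ct$n)
  expect_equal(ct$histogram$count[ct$histogram$bin_start_hours == 24], ct$n)

  # a never-dividing (endoreduplicating) cell contributes no duration
  endo <- generate_lineage_fixture(n_initial = 10, p_endo = 1, seed = 3)
  expect_error(daughter_asymmetry(endo), "no division")
  expect_equal(cycle_times_from_lineage(endo)$n, 0)

  # malformed parentage errors name the offending cell
  bad <- data.frame(cell_id = c(1, 2), parent_id = c(NA, 99),
                    time_h = c(0, 6), area = c(1, 1),
                    fate = c("divided", "censored"))
  expect_error(cycle_times_from_lineage(bad), "missing parent 99")
  bad2 <- data.frame(cell_id = 1, parent_id = NA, time_h = 0, area = 1,
                     fate = "divided")
  expect_error(cycle_times_from_lineage(bad2), "no recorded daughters")
})

test_that("cycle-time distributions are recovered across a parameter grid", {
  # guard against right-censoring selection: only cells first seen early
  # enough that almost any cycle could complete in-window are measured
  for (ms in list(c(18, 6.75), c(24, 9), c(30, 11.25))) {
    d <- cycle_time_distribution("lognormal", ms[1], ms[2])
    tab <- generate_lineage_fixture(n_initial = 300, cycle_dist = d,
                                    duration_hours = 3 * ms[1], seed = 6)
    rec <- cycle_times_from_lineage(tab, max_birth_h = ms[1])
    expect_gt(rec$n, 300)
    expect_lt(abs(rec$mean_hours - ms[1]), 1.5 * ms[1] / 24)
  }
  # at n >= 500 measured cycles the 24/9 setting recovers the mean to 1.5 h
  tab <- generate_lineage_fixture(n_initial = 450, seed = 4)
  rec <- cycle_times_from_lineage(tab, max_birth_h = 24)
  expect_gte(rec$n, 500)
  expect_lt(abs(rec$mean_hours - 24), 1.5)
  # without the guard, branching + windowing select for short cycles
  raw <- cycle_times_from_lineage(tab)
  expect_lt(raw$mean_hours, rec$mean_hours)
})

test_that("daughter asymmetry recovers twice the split-fraction SD", {
  eq <- generate_lineage_fixture(n_initial = 15, split_sd = 0, seed = 2)
  expect_equal(daughter_asymmetry(eq)$sd, 0)

  for (ssd in c(0.03, 0.05)) {
    tab <- generate_lineage_fixture(n_initial = 250, split_sd = ssd,
                                    seed = 12)
    da <- daughter_asymmetry(tab)
    expect_gt(da$n, 1000)
    expect_lt(abs(da$sd - 2 * ssd), 0.1 * 2 * ssd)
  }
  # the in vivo regime: split_sd 0.0425 gives the measured 8.5%
  tab <- generate_lineage_fixture(n_initial = 200, split_sd = 0.0425,
                                  seed = 5)
  expect_lt(abs(daughter_asymmetry(tab)$sd - 0.085), 0.0085)
})
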