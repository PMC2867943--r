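#' Summarise a terminal cell table
#'
#' Computes the ploidy fractions, per-ploidy area statistics (mean, SD,
#' CV), the giant-cell count (operationally: 16C records), and the number
#' of distinct terminal sizes under a relative clustering tolerance. The
#' distinct-size count is meaningful for noise-free runs, where the model
#' produces cells in exactly four sizes (ratios 1:2:4:8 for 2C:4C:8C:16C);
#' for noisy runs it simply reports the number of area clusters at the
#' tolerance and is not a biological quantity.
#'
#' @param table A `cell_table` data frame (see [tissue_cell_table()]).
#' @param distinct_tol Relative tolerance for clustering areas (default
#'   1e-6).
#' @return A list of class `cell_table_summary` with `n_cells`,
#'   `fractions` ([ploidy_fractions()]), `by_ploidy` (data frame),
#'   `distinct_sizes`, `giant_cells` and `mean_area`.
#' @export
summarize_cell_table <- function(table, distinct_tol = 1e-6) {
  if (is.null(table) || nrow(table) == 0L) {
    stop("summarize_cell_table: empty cell table", call. = FALSE)
  }
  stopifnot(all(c("ploidy_c", "area") %in% names(table)))
  lev <- c(2L, 4L, 8L, 16L)
  ploidy <- factor(table$ploidy_c, levels = lev)
  counts <- table(ploidy)
  fr <- as.numeric(counts) / nrow(table)
  by_ploidy <- do.call(rbind, lapply(lev, function(pl) {
    a <- table$area[table$ploidy_c == pl]
    if (length(a) == 0L) {
      data.frame(ploidy_c = pl, n = 0L, mean_area = NA_real_,
                 sd_area = NA_real_, cv_area = NA_real_)
    } else {
      m <- mean(a)
      s <- if (length(a) > 1L) stats::sd(a) else 0
      data.frame(ploidy_c = pl, n = length(a), mean_area = m, sd_area = s,
                 cv_area = s / m)
    }
  }))
  structure(
    list(n_cells = nrow(table),
         fractions = ploidy_fractions(fr[1], fr[2], fr[3], fr[4]),
         by_ploidy = by_ploidy,
         distinct_sizes = count_distinct_sizes(table$area, distinct_tol),
         giant_cells = sum(table$ploidy_c == 16L),
         mean_area = mean(table$area)),
    class = "cell_table_summary")
}

#' @export
print.cell_table_summary <- function(x, ...) {
  cat(sprintf("Cell table: %d cells, mean area %.4g, %d giant (16C) cells\n",
              x$n_cells, x$mean_area, x$giant_cells))
  print(x$fractions)
  cat(sprintf("  distinct sizes (rel. tol): %d\n", x$distinct_sizes))
  print(x$by_ploidy, row.names = FALSE)
  invisible(x)
}

#' Count distinct values under a relative tolerance
#'
#' Single-linkage clustering of sorted values: a new cluster starts
#' whenever the relative gap to the previous value exceeds `tol`.
#'
#' @param x Positive numeric values.
#' @param tol Relative gap threshold.
#' @return Integer number of clusters.
#' @export
count_distinct_sizes <- function(x, tol = 1e-6) {
  if (length(x) == 0L) return(0L)
  a <- sort(x)
  if (length(a) == 1L) return(1L)
  gaps <- diff(a) / a[-length(a)]
  sum(gaps > tol) + 1L
}

#' Compare two cell-area distributions
#'
#' Two-sample Kolmogorov-Smirnov test on log2-transformed areas (the scale
#' on which the size classes are equispaced). The statistic is symmetric in
#' its arguments and zero iff the empirical distributions coincide.
#'
#' @param a,b Numeric vectors of positive cell areas.
#' @return A list with `D`, `p_value`, `n_a`, `n_b`.
#' @export
compare_area_distributions <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("compare_area_distributions: empty input", call. = FALSE)
  }
  if (any(a <= 0) || any(b <= 0)) {
    stop("areas must be positive", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(log2(a), log2(b)))
  list(D = unname(ks$statistic), p_value = unname(ks$p.value),
       n_a = length(a), n_b = length(b))
}

validate_lineage_table <- function(table) {
  need <- c("cell_id", "parent_id", "time_h", "area", "fate")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("lineage table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$area <= 0, na.rm = TRUE)) {
    stop("lineage table areas must be positive", call. = FALSE)
  }
  invisible(table)
}

# per-cell first appearance, fate and parent from a long lineage table
lineage_cells <- function(table) {
  first <- tapply(table$time_h, table$cell_id, min)
  ids <- as.integer(names(first))
  o <- match(ids, table$cell_id)
  data.frame(cell_id = ids, parent_id = table$parent_id[o],
             fate = table$fate[o], first_time = as.numeric(first))
}

#' Cell-cycle times from a tracked-lineage table
#'
#' A duration is measured for every internal edge of the lineage forest:
#' for each non-root cell with fate `"divided"`, the time from its first
#' appearance to the first appearance of its daughters. Cells that never
#' divide within the observation window (censored, endoreduplicating or
#' guard cells) contribute no duration, as do the roots, whose birth was
#' not observed.
#'
#' Because lineages branch, the cells near the end of the window are the
#' majority, and excluding their unfinished cycles selects for short
#' cycles. `max_birth_h` restricts the measurement to cells first seen
#' early enough that almost any cycle length could complete within the
#' window, removing that selection bias; leave `NULL` to measure every
#' internal edge (the raw, window-truncated histogram).
#'
#' @param table A long-format lineage table (columns `cell_id`,
#'   `parent_id`, `time_h`, `area`, `fate`).
#' @param bin_hours Histogram bin width in hours (default 6, the imaging
#'   resolution).
#' @param max_birth_h Optional upper bound on a cell's first appearance
#'   time for it to be measured.
#' @return A list with `durations` (named by cell id), `histogram` (data
#'   frame `bin_start_hours`, `bin_end_hours`, `count`), `n` and
#'   `mean_hours`.
#' @export
cycle_times_from_lineage <- function(table, bin_hours = 6,
                                     max_birth_h = NULL) {
  validate_lineage_table(table)
  cells <- lineage_cells(table)
  nonroot <- cells[!is.na(cells$parent_id), ]
  bad <- !(nonroot$parent_id %in% cells$cell_id)
  if (any(bad)) {
    stop("malformed parentage: cell ", nonroot$cell_id[which(bad)[1]],
         " references missing parent ", nonroot$parent_id[which(bad)[1]],
         call. = FALSE)
  }
  child_first <- tapply(cells$first_time, cells$parent_id, min)
  divided_all <- cells[cells$fate == "divided", ]
  no_kids <- !(divided_all$cell_id %in% names(child_first))
  if (any(no_kids)) {
    stop("malformed parentage: cell ", divided_all$cell_id[which(no_kids)[1]],
         " has fate 'divided' but no recorded daughters", call. = FALSE)
  }
  # roots are excluded: their birth was not observed
  divided <- divided_all[!is.na(divided_all$parent_id), ]
  durations <- numeric(0)
  if (nrow(divided)) {
    cf <- child_first[as.character(divided$cell_id)]
    durations <- as.numeric(cf) - divided$first_time
    names(durations) <- divided$cell_id
    if (!is.null(max_birth_h)) {
      durations <- durations[divided$first_time <= max_birth_h]
    }
  }
  if (length(durations)) {
    edges <- seq(0, max(durations) + bin_hours, by = bin_hours)
    counts <- as.integer(table(cut(durations, edges, right = FALSE)))
    hist <- data.frame(bin_start_hours = edges[-length(edges)],
                       bin_end_hours = edges[-1], count = counts)
  } else {
    hist <- data.frame(bin_start_hours = numeric(0),
                       bin_end_hours = numeric(0), count = integer(0))
  }
  list(durations = durations, histogram = hist, n = length(durations),
       mean_hours = if (length(durations)) mean(durations) else NA_real_)
}

#' Daughter-size asymmetry from a tracked-lineage table
#'
#' For every division with both daughters' first-timepoint areas recorded,
#' computes the relative deviation d = 2 a1 / (a1 + a2) - 1 of one daughter
#' from the half-size (a1 being the lower-id daughter; d is symmetric about
#' zero, so the labelling is immaterial for the reported spread). Since the
#' two daughters of one division grow at the same relative rate, the ratio
#' at their first common timepoint equals the ratio at division. Returns
#' the standard deviation about zero, sqrt(mean(d^2)), which for a split
#' fraction with SD `split_sd` recovers `2 * split_sd` (e.g. 10% at the
#' model default 0.05, 8.5% at the in vivo value 0.0425).
#'
#' @inheritParams cycle_times_from_lineage
#' @return A list with `sd` (the reported asymmetry), `n` divisions and
#'   the per-division `deviations`.
#' @export
daughter_asymmetry <- function(table) {
  validate_lineage_table(table)
  o <- order(table$cell_id, table$time_h)
  firsts <- table[o, ][!duplicated(table$cell_id[o]), ]
  kids <- firsts[!is.na(firsts$parent_id), ]
  kids <- kids[order(kids$parent_id, kids$cell_id), ]
  sib_n <- table(kids$parent_id)
  pairs <- kids[kids$parent_id %in% names(sib_n)[sib_n == 2L], ]
  devs <- numeric(0)
  if (nrow(pairs)) {
    i1 <- seq(1L, nrow(pairs), by = 2L)
    a1 <- pairs$area[i1]
    a2 <- pairs$area[i1 + 1L]
    devs <- 2 * a1 / (a1 + a2) - 1
  }
  if (length(devs) == 0L) {
    stop("daughter_asymmetry: no division with both daughters recorded",
         call. = FALSE)
  }
  list(sd = sqrt(mean(devs^2)), n = length(devs), deviations = devs)
}

#' Generate a synthetic tracked-lineage table
#'
#' Emulates the structure of live-imaging lineage data: a small population
#' of cells founded at time zero grows exponentially (area doubling every
#' `doubling_time_hours`), divides after individually sampled cycle
#' durations with slightly asymmetric splits, and is observed on a fixed
#' sampling grid until the window closes. Cells may instead commit to
#' endoreduplication with probability `p_endo` per cycle and then grow
#' without further division. The output is the long-format lineage table
#' consumed by [cycle_times_from_lineage()] and [daughter_asymmetry()];
#' this is synthetic stand-in data for testing those measurement
#' utilities, not an output of the tissue simulator.
#'
#' Fates: `"divided"` (division observed in-window), `"endoreduplicating"`
#' (committed, never divides), `"censored"` (window closed mid-cycle). A
#' cell whose entire life falls between two grid points (possible only for
#' cycles shorter than the sampling interval) is invisible to imaging; its
#' subtree is dropped, as it would be in real tracking.
#'
#' @param n_initial Number of founder cells at time zero.
#' @param cycle_dist A [cycle_time_distribution()].
#' @param split_sd Division split-fraction SD (see [division_noise()]).
#' @param duration_hours Observation window length (default 72).
#' @param sampling_interval_h Grid spacing in hours (default 6).
#' @param doubling_time_hours Areal doubling time (default the cycle mean).
#' @param p_endo Per-cycle probability of committing to endoreduplication.
#' @param initial_area Mean founder area; founders vary lognormally (CV
#'   0.2) about it.
#' @param seed Integer seed.
#' @return A long-format lineage table (data frame).
#' @export
generate_lineage_fixture <- function(n_initial = 30L,
                                     cycle_dist = cycle_time_distribution(),
                                     split_sd = 0.05,
                                     duration_hours = 72,
                                     sampling_interval_h = 6,
                                     doubling_time_hours = NULL,
                                     p_endo = 0,
                                     initial_area = 100,
                                     seed = 1L) {
  stopifnot(inherits(cycle_dist, "cycle_time_distribution"))
  if (duration_hours < 0) stop("duration_hours must be >= 0", call. = FALSE)
  if (sampling_interval_h <= 0) stop("sampling_interval_h must be > 0",
                                     call. = FALSE)
  if (is.null(doubling_time_hours)) {
    doubling_time_hours <- cycle_dist$mean_hours
  }
  noise <- division_noise(split_sd = split_sd)
  set.seed(as.integer(seed))
  grid <- seq(0, duration_hours, by = sampling_interval_h)
  rows <- list()
  next_id <- 1L
  # queue entries: id, parent, birth, birth_area
  queue <- lapply(seq_len(n_initial), function(i) {
    a0 <- initial_area * stats::rlnorm(1, -0.5 * log(1.04), sqrt(log(1.04)))
    e <- list(id = next_id + i - 1L, parent = NA_integer_, birth = 0,
              area = a0)
    e
  })
  next_id <- next_id + n_initial
  emit <- function(e, end_time, fate) {
    tp <- grid[grid >= e$birth - 1e-9 & grid < end_time - 1e-9]
    if (fate != "divided") {
      tp <- grid[grid >= e$birth - 1e-9 & grid <= end_time + 1e-9]
    }
    if (length(tp) == 0L) return(NULL)  # invisible to the sampling grid
    list(cell_id = rep(e$id, length(tp)),
         parent_id = rep(e$parent, length(tp)), time_h = tp,
         area = e$area * 2^((tp - e$birth) / doubling_time_hours),
         fate = rep(fate, length(tp)))
  }
  head <- 1L
  while (head <= length(queue)) {
    e <- queue[[head]]
    head <- head + 1L
    committed <- p_endo > 0 && stats::runif(1) < p_endo
    if (committed) {
      rec <- emit(e, duration_hours, "endoreduplicating")
      if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
      next
    }
    d <- sample_cycle_time(cycle_dist)
    if (e$birth + d > duration_hours) {
      rec <- emit(e, duration_hours, "censored")
      if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
      next
    }
    rec <- emit(e, e$birth + d, "divided")
    if (is.null(rec)) next  # invisible cell: drop its subtree
    rows[[length(rows) + 1L]] <- rec
    s <- sample_split_fraction(noise)
    a_div <- e$area * 2^(d / doubling_time_hours)
    queue <- c(queue, list(
      list(id = next_id, parent = e$id, birth = e$birth + d, area = s * a_div),
      list(id = next_id + 1L, parent = e$id, birth = e$birth + d,
           area = (1 - s) * a_div)))
    next_id <- next_id + 2L
  }
  if (length(rows) == 0L) {
    return(data.frame(cell_id = integer(0), parent_id = integer(0),
                      time_h = numeric(0), area = numeric(0),
                      fate = character(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    cell_id = unlist(lapply(rows, `[[`, "cell_id")),
    parent_id = unlist(lapply(rows, `[[`, "parent_id")),
    time_h = unlist(lapply(rows, `[[`, "time_h")),
    area = unlist(lapply(rows, `[[`, "area")),
    fate = unlist(lapply(rows, `[[`, "fate")),
    stringsAsFactors = FALSE)
  out[order(out$cell_id, out$time_h), , drop = FALSE]
}
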