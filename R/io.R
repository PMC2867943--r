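# File formats: CSV tables and JSON reports.

CELL_TABLE_COLS <- c("cell_id", "parent_id", "birth_time_h",
                     "termination_time_h", "ploidy_c", "area", "length",
                     "width", "column", "n_divisions")

#' Read / write terminal cell tables as CSV
#'
#' The CSV carries exactly the columns of [tissue_cell_table()].
#'
#' @param table A `cell_table` data frame.
#' @param path File path.
#' @return `read_cell_table()` returns a `cell_table`;
#'   `write_cell_table()` returns `path` invisibly.
#' @export
write_cell_table <- function(table, path) {
  stopifnot(all(CELL_TABLE_COLS %in% names(table)))
  utils::write.csv(table[, CELL_TABLE_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(CELL_TABLE_COLS, names(out))
  if (length(miss)) {
    stop("not a cell table (missing column(s): ",
         paste(miss, collapse = ", "), "): ", path, call. = FALSE)
  }
  if (!all(out$ploidy_c %in% c(2L, 4L, 8L, 16L))) {
    stop("cell table contains ploidy values outside {2, 4, 8, 16}: ", path,
         call. = FALSE)
  }
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Read / write ploidy fractions as CSV
#'
#' Two columns: `ploidy_c` (2, 4, 8, 16) and `fraction`. Missing ploidy
#' rows are treated as unobserved; a complete table must sum to 1.
#'
#' @param x A [ploidy_fractions()] object (for writing).
#' @param path File path.
#' @return `read_ploidy_fractions()` returns a [ploidy_fractions()].
#' @export
read_ploidy_fractions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ploidy_c", "fraction") %in% names(df))) {
    stop("ploidy-fraction CSV needs columns ploidy_c and fraction: ", path,
         call. = FALSE)
  }
  bad <- which(!df$ploidy_c %in% c(2, 4, 8, 16))
  if (length(bad)) {
    stop("ploidy-fraction CSV row ", bad[1], " has invalid ploidy_c ",
         df$ploidy_c[bad[1]], call. = FALSE)
  }
  if (anyDuplicated(df$ploidy_c)) {
    stop("ploidy-fraction CSV has duplicate ploidy_c rows", call. = FALSE)
  }
  f <- stats::setNames(rep(NA_real_, 4),
                       c("f2", "f4", "f8", "f16"))
  f[paste0("f", df$ploidy_c)] <- df$fraction
  do.call(ploidy_fractions, as.list(f))
}

#' @rdname read_ploidy_fractions
#' @export
write_ploidy_fractions <- function(x, path) {
  x <- as_ploidy_fractions(x)
  keep <- !is.na(x)
  df <- data.frame(ploidy_c = c(2L, 4L, 8L, 16L)[keep],
                   fraction = as.numeric(x[keep]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write long-format lineage tables as CSV
#'
#' Columns: `cell_id`, `parent_id`, `time_h`, `area`, `fate`.
#'
#' @param table A lineage table data frame.
#' @param path File path.
#' @return `read_lineage_table()` returns the validated data frame.
#' @export
write_lineage_table <- function(table, path) {
  validate_lineage_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lineage_table
#' @export
read_lineage_table <- function(path) {
  validate_lineage_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write the event log of a run as CSV
#'
#' Columns `time_h`, `event` (division, endocycle, termination,
#' stomatal_division) and `cell_id`.
#'
#' @param run A `sepal_run` from [run_simulation()].
#' @param path File path.
#' @export
write_event_log <- function(run, path) {
  stopifnot(inherits(run, "sepal_run"))
  utils::write.csv(run$events[, c("time_h", "event", "cell_id")], path,
                   row.names = FALSE)
  invisible(path)
}

# md5 of the canonical JSON rendering of a configuration
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_to_list(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

# run summary as a plain list, ready for JSON
run_summary_list <- function(run) {
  s <- summarize_cell_table(run$cells)
  counts <- as.list(table(factor(run$cells$ploidy_c,
                                 levels = c(2, 4, 8, 16))))
  names(counts) <- paste0("n_", c(2, 4, 8, 16), "c")
  fr <- as.list(unclass(s$fractions))
  list(seed = run$config$seed,
       config_hash = config_hash(run$config),
       n_cells = s$n_cells,
       counts = counts,
       fractions = fr,
       distinct_sizes = s$distinct_sizes,
       giant_cells = s$giant_cells,
       mean_area = s$mean_area,
       total_time_h = run$log$total_time_h,
       n_founders = run$log$n_founders,
       events = list(divisions = run$log$n_divisions,
                     endocycles = run$log$n_endocycles,
                     stomatal_divisions = run$log$n_stomatal_divisions))
}
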