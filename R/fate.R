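#' Per-cycle endoreduplication probabilities
#'
#' Bundle of the four fate probabilities of the patterning model. At the
#' completion of patterning cycle k (k = 1, 2, 3) a 2C cell enters the
#' endocycle with probability `p1`, `p2` or `p3` respectively, and otherwise
#' divides; a cell that has completed all three patterning cycles as a 2C
#' cell performs an extra (stomatal-lineage) division with probability `p_s`.
#' Endocycle entry is irreversible.
#'
#' @param p1,p2,p3 Probability of entering the endocycle at the completion of
#'   the first, second and third patterning cycle.
#' @param p_s Probability that a terminal 2C cell performs one extra
#'   stomatal-lineage division (per allowed round).
#' @return An object of class `fate_probabilities` (named numeric vector).
#' @examples
#' fate_probabilities(0.05, 0.14, 0.8, 0.55)
#' @export
fate_probabilities <- function(p1, p2, p3, p_s = 0) {
  p <- c(p1 = p1, p2 = p2, p3 = p3, p_s = p_s)
  if (!is.numeric(p) || length(p) != 4L || anyNA(p)) {
    stop("fate probabilities must be four non-missing numbers", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) {
    bad <- names(p)[p < 0 | p > 1]
    stop("fate probabilities must lie in [0, 1]; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(p, class = "fate_probabilities")
}

#' @export
print.fate_probabilities <- function(x, ...) {
  cat("Fate probabilities (endocycle entry per patterning cycle):\n")
  cat(sprintf("  p1 = %.4g  p2 = %.4g  p3 = %.4g  p_s = %.4g\n",
              x[["p1"]], x[["p2"]], x[["p3"]], x[["p_s"]]))
  invisible(x)
}

as_fate_probabilities <- function(x) {
  if (inherits(x, "fate_probabilities")) return(x)
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x))) names(x) <- c("p1", "p2", "p3", "p_s")[seq_along(x)]
  ps <- if ("p_s" %in% names(x)) x[["p_s"]] else 0
  fate_probabilities(x[["p1"]], x[["p2"]], x[["p3"]], ps)
}

#' Decide the fate of a cell at the completion of a cell cycle
#'
#' Implements the stochastic decision of the patterning model. The cell is
#' taken to have just completed patterning cycle `k = patterning_cycle + 1`.
#' A 2C patterning cell enters the endocycle with probability `p[k]` and
#' otherwise divides. An endocycling cell always continues to endocycle
#' (irreversible commitment) until its third patterning cycle completes, at
#' which point it terminates. A 2C cell whose lineage has already completed
#' all three patterning cycles (`patterning_cycle == 3`) faces the
#' stomatal-lineage decision: it divides once more with probability `p_s`,
#' provided fewer than `stomatal_max_rounds` such rounds have occurred in its
#' lineage, and otherwise terminates. That call is made at the cell's birth,
#' i.e. at the instant the third patterning cycle completed, so a declining
#' cell terminates at its birth area (this is what preserves the noise-free
#' 1:2:4:8 four-size limit).
#'
#' Each stochastic decision consumes exactly one uniform variate from R's
#' global random number stream; forced outcomes consume none. This is part of
#' the reproducibility contract of the simulator.
#'
#' @param cell A [cell_state()].
#' @param fate A [fate_probabilities()] object.
#' @param stomatal_max_rounds Maximum number of extra stomatal-lineage
#'   division rounds per lineage (default 1).
#' @return One of `"divide"`, `"endocycle"`, `"stomatal_divide"`,
#'   `"terminate"`.
#' @export
decide_fate <- function(cell, fate, stomatal_max_rounds = 1L) {
  fate <- as_fate_probabilities(fate)
  if (!cell$phase %in% c("patterning", "endocycling")) {
    stop("decide_fate: cell ", cell$cell_id, " is in phase '", cell$phase,
         "'; only patterning or endocycling cells decide fates",
         call. = FALSE)
  }
  if (cell$phase == "endocycling") {
    # committed: endocycle until three patterning cycles are complete.  The
    # cycle that brings patterning_cycle to 3 is still an endocycle (the
    # final ploidy doubling); the scheduler then freezes the cell.
    if (cell$patterning_cycle >= 3L) return("terminate")
    return("endocycle")
  }
  if (cell$patterning_cycle >= 3L) {
    # stomatal-lineage decision for a terminal 2C cell
    if (cell$stomatal_rounds_done >= stomatal_max_rounds) return("terminate")
    u <- stats::runif(1)
    return(if (u < fate[["p_s"]]) "stomatal_divide" else "terminate")
  }
  k <- cell$patterning_cycle + 1L
  u <- stats::runif(1)
  if (u < fate[[c("p1", "p2", "p3")[k]]]) "endocycle" else "divide"
}
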