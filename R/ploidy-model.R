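#' Terminal ploidy fractions
#'
#' Flow-cytometry-style fractions of 2C/4C/8C/16C cells. Partially observed
#' inputs (e.g. only `f16` and `f8`) are allowed by leaving the other
#' entries `NA`; a complete vector must sum to 1.
#'
#' @param f2,f4,f8,f16 Fractions in `[0, 1]` or `NA` if unobserved.
#' @return An object of class `ploidy_fractions` (named numeric vector
#'   `c(f2, f4, f8, f16)`).
#' @export
ploidy_fractions <- function(f2 = NA_real_, f4 = NA_real_, f8 = NA_real_,
                             f16 = NA_real_) {
  f <- c(f2 = f2, f4 = f4, f8 = f8, f16 = f16)
  obs <- !is.na(f)
  if (!any(obs)) stop("at least one fraction must be observed", call. = FALSE)
  if (any(f[obs] < 0) || any(f[obs] > 1)) {
    stop("ploidy fractions must lie in [0, 1]", call. = FALSE)
  }
  if (all(obs) && abs(sum(f) - 1) > 1e-8) {
    stop("complete ploidy fractions must sum to 1 (got ",
         format(sum(f)), ")", call. = FALSE)
  }
  if (sum(f[obs]) > 1 + 1e-8) {
    stop("observed ploidy fractions exceed 1 in total", call. = FALSE)
  }
  structure(f, class = "ploidy_fractions")
}

#' @export
print.ploidy_fractions <- function(x, ...) {
  cat("Ploidy fractions:\n")
  lab <- c("2C", "4C", "8C", "16C")
  cat(paste(sprintf("  %-3s %s", lab,
                    ifelse(is.na(x), "(unobserved)",
                           sprintf("%6.2f%%", 100 * x))),
            collapse = "\n"), "\n")
  invisible(x)
}

as_ploidy_fractions <- function(x) {
  if (inherits(x, "ploidy_fractions")) return(x)
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x))) names(x) <- c("f2", "f4", "f8", "f16")[seq_along(x)]
  args <- as.list(x[intersect(c("f2", "f4", "f8", "f16"), names(x))])
  do.call(ploidy_fractions, args)
}

# expected number of final cells per terminal 2C leaf after r stomatal
# rounds; a cell that declines a round terminates, daughters of a division
# proceed to the next round
stomatal_multiplier <- function(p_s, rounds) {
  m <- 1
  for (r in seq_len(rounds)) m <- (1 - p_s) + 2 * p_s * m
  m
}

#' Expected terminal cells per lineage founder, by ploidy
#'
#' Closed form of the branching ("population") model: each lineage founder
#' runs three patterning cycles, entering the endocycle at cycle k with
#' probability `p_k` (irreversibly) and otherwise dividing into two. A cell
#' committing at cycle 1 ends 16C; at cycle 2, 8C; at cycle 3, 4C; a never
#' committing cell ends 2C, and each terminal 2C cell doubles through the
#' optional stomatal-lineage rounds with probability `p_s` per round. With
#' q_k = 1 - p_k:
#' n16 = p1, n8 = 2*q1*p2, n4 = 4*q1*q2*p3, n2 = 8*q1*q2*q3*m(p_s, rounds),
#' where m is the expected stomatal multiplier (1 + p_s for one round).
#'
#' @param fate A [fate_probabilities()].
#' @param stomatal_rounds Number of stomatal-lineage rounds modelled.
#' @return Named numeric vector `c(n2, n4, n8, n16, total)`.
#' @export
expected_terminal_counts <- function(fate, stomatal_rounds = 1L) {
  fate <- as_fate_probabilities(fate)
  p1 <- fate[["p1"]]; p2 <- fate[["p2"]]; p3 <- fate[["p3"]]
  q1 <- 1 - p1; q2 <- 1 - p2; q3 <- 1 - p3
  n16 <- p1
  n8 <- 2 * q1 * p2
  n4 <- 4 * q1 * q2 * p3
  n2 <- 8 * q1 * q2 * q3 * stomatal_multiplier(fate[["p_s"]], stomatal_rounds)
  c(n2 = n2, n4 = n4, n8 = n8, n16 = n16, total = n2 + n4 + n8 + n16)
}

#' Expected terminal ploidy fractions
#'
#' Normalises [expected_terminal_counts()]; exact closed form, no sampling.
#' Simulated terminal ploidy fractions converge to these values as the cell
#' count grows.
#'
#' @inheritParams expected_terminal_counts
#' @return A [ploidy_fractions()] object.
#' @examples
#' expected_ploidy_fractions(fate_probabilities(0.5, 0.5, 0.5, 0))
#' # fractions (2C, 4C, 8C, 16C) = (0.4, 0.2, 0.2, 0.2)
#' @export
expected_ploidy_fractions <- function(fate, stomatal_rounds = 1L) {
  n <- expected_terminal_counts(fate, stomatal_rounds)
  if (n[["total"]] <= 0) {
    stop("degenerate fate probabilities: no terminal cells expected",
         call. = FALSE)
  }
  f <- n[c("n2", "n4", "n8", "n16")] / n[["total"]]
  ploidy_fractions(f[[1]], f[[2]], f[[3]], f[[4]])
}

#' Fit fate probabilities to observed ploidy fractions
#'
#' Inverse of [expected_ploidy_fractions()]: finds the free fate
#' probabilities minimising the squared error between expected and observed
#' fractions over the unit box (or, with `objective = "multinomial"`, the
#' multinomial negative log-likelihood at `n_nuclei` nuclei). Parameters
#' named in `fixed` are held at the supplied values; unobserved (`NA`)
#' fractions are simply dropped from the objective, so partially observed
#' data (e.g. only the 16C and 8C fractions, the paper's caveat being that
#' observed 4C conflates endoreduplicated cells with mitotic G2 cells) can
#' be fitted provided enough parameters are fixed.
#'
#' The number of free parameters must not exceed the number of independent
#' constraints (the number of observed fractions, minus one when all four
#' are observed since they sum to 1).
#'
#' @param observed A [ploidy_fractions()] object (possibly partial), or a
#'   named vector with entries among `f2`, `f4`, `f8`, `f16`.
#' @param stomatal_rounds Stomatal-lineage rounds assumed by the model.
#' @param fixed Named list of parameters to hold fixed, e.g.
#'   `list(p3 = 0.8, p_s = 0.55)`.
#' @param objective `"ls"` (least squares on fractions, the default) or
#'   `"multinomial"` (negative log-likelihood; requires complete observed
#'   fractions and `n_nuclei`).
#' @param n_nuclei Total nuclei counted, for the multinomial objective.
#' @return An object of class `fate_fit`: estimates (full
#'   [fate_probabilities()]), residuals on the observed classes, objective
#'   value, convergence flag and settings.
#' @examples
#' truth <- fate_probabilities(0.2, 0.4, 0.7, 0)
#' obs <- expected_ploidy_fractions(truth)
#' fit_probabilities(obs, fixed = list(p_s = 0))$estimates
#' @export
fit_probabilities <- function(observed, stomatal_rounds = 1L,
                              fixed = list(),
                              objective = c("ls", "multinomial"),
                              n_nuclei = NULL) {
  observed <- as_ploidy_fractions(observed)
  objective <- match.arg(objective)
  pars <- c("p1", "p2", "p3", "p_s")
  if (length(fixed) && (is.null(names(fixed)) ||
                        !all(names(fixed) %in% pars))) {
    stop("fixed must be a named list with names among p1, p2, p3, p_s",
         call. = FALSE)
  }
  fixed <- unlist(fixed)
  free <- setdiff(pars, names(fixed))
  if ("p_s" %in% free && stomatal_rounds == 0L) {
    stop("p_s has no effect with stomatal_rounds = 0; fix it", call. = FALSE)
  }
  obs_mask <- !is.na(observed)
  n_constraints <- sum(obs_mask) - if (all(obs_mask)) 1L else 0L
  if (length(free) > n_constraints) {
    stop("underdetermined fit: ", length(free), " free parameters (",
         paste(free, collapse = ", "), ") but only ", n_constraints,
         " independent constraints; fix more parameters or observe more ",
         "fractions", call. = FALSE)
  }
  if (objective == "multinomial") {
    if (!all(obs_mask)) {
      stop("the multinomial objective requires complete observed fractions",
           call. = FALSE)
    }
    if (is.null(n_nuclei) || n_nuclei <= 0) {
      stop("the multinomial objective requires n_nuclei > 0", call. = FALSE)
    }
  }
  zero_obs <- names(observed)[which(obs_mask & observed == 0)]
  if (length(zero_obs) && length(free)) {
    warning("observed fraction(s) exactly zero (",
            paste(zero_obs, collapse = ", "),
            "); parameters driving them sit on the boundary", call. = FALSE)
  }

  full_p <- function(theta) {
    p <- c(theta, fixed)[pars]
    names(p) <- pars
    p
  }
  obj <- function(theta) {
    p <- full_p(theta)
    f <- unclass(expected_ploidy_fractions(
      fate_probabilities(p[["p1"]], p[["p2"]], p[["p3"]], p[["p_s"]]),
      stomatal_rounds))
    if (objective == "ls") {
      sum((f[obs_mask] - observed[obs_mask])^2)
    } else {
      -sum(n_nuclei * observed * log(pmax(f, 1e-300)))
    }
  }

  if (length(free) == 0L) {
    theta <- numeric(0)
    best <- list(par = theta, objective = obj(theta), convergence = 0L)
  } else {
    starts <- as.matrix(do.call(
      expand.grid, rep(list(c(0.15, 0.5, 0.85)), length(free))))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      th0 <- starts[i, ]
      names(th0) <- free
      res <- stats::nlminb(
        th0, function(th) { names(th) <- free; obj(th) },
        lower = rep(0, length(free)), upper = rep(1, length(free)),
        control = list(abs.tol = 0, rel.tol = 1e-14, x.tol = 1e-14,
                       eval.max = 1000, iter.max = 500))
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    names(best$par) <- free
  }
  p <- full_p(best$par)
  est <- fate_probabilities(p[["p1"]], p[["p2"]], p[["p3"]], p[["p_s"]])
  expected <- expected_ploidy_fractions(est, stomatal_rounds)
  residuals <- unclass(expected) - unclass(observed)
  structure(
    list(estimates = est, free = free, fixed = fixed,
         observed = observed, expected = expected,
         residuals = residuals[obs_mask],
         objective_value = best$objective,
         objective = objective,
         converged = identical(best$convergence, 0L) ||
                     best$convergence == 0,
         stomatal_rounds = stomatal_rounds),
    class = "fate_fit")
}

#' @export
print.fate_fit <- function(x, ...) {
  cat("Fate-probability fit (", x$objective, " objective)\n", sep = "")
  print(x$estimates)
  cat("  free: ", paste(x$free, collapse = ", "),
      if (length(x$fixed)) paste0("  fixed: ",
        paste(names(x$fixed), "=", signif(x$fixed, 4), collapse = ", ")),
      "\n", sep = "")
  cat(sprintf("  objective %.3e (%sconverged), residuals: %s\n",
              x$objective_value, if (x$converged) "" else "NOT ",
              paste(sprintf("%s=%.2e", names(x$residuals), x$residuals),
                    collapse = " ")))
  invisible(x)
}

#' Bootstrap confidence intervals for fitted fate probabilities
#'
#' Resamples multinomial nuclei counts at the observed fractions (the
#' unobserved remainder, if any, forms an extra class), refits the free
#' parameters for each replicate, and returns percentile intervals.
#'
#' @inheritParams fit_probabilities
#' @param n_nuclei Number of nuclei counted (the sampling depth).
#' @param reps Bootstrap replicates (>= 100 recommended; >= 2 required).
#' @param seed Integer seed for reproducibility.
#' @param level Confidence level (default 0.95).
#' @return An object of class `fate_boot`: matrix `ci` (rows: free
#'   parameters; columns: lower, estimate, upper), the replicate draws, and
#'   settings.
#' @export
bootstrap_fit <- function(observed, n_nuclei, reps = 1000L, seed = 1L,
                          stomatal_rounds = 1L, fixed = list(),
                          level = 0.95) {
  observed <- as_ploidy_fractions(observed)
  if (n_nuclei <= 0) stop("n_nuclei must be positive", call. = FALSE)
  if (reps < 2L) stop("reps must be at least 2", call. = FALSE)
  obs_mask <- !is.na(observed)
  probs <- observed[obs_mask]
  remainder <- 1 - sum(probs)
  if (remainder > 1e-12) probs <- c(probs, .rest = remainder)
  point <- fit_probabilities(observed, stomatal_rounds, fixed)
  free <- point$free
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, nrow = reps, ncol = length(free),
                  dimnames = list(NULL, free))
  for (r in seq_len(reps)) {
    counts <- stats::rmultinom(1, n_nuclei, probs)[, 1]
    frac <- counts / n_nuclei
    boot_obs <- unclass(observed)
    boot_obs[obs_mask] <- frac[seq_len(sum(obs_mask))]
    fit <- fit_probabilities(as_ploidy_fractions(boot_obs),
                             stomatal_rounds, fixed)
    draws[r, ] <- unclass(fit$estimates)[free]
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha)))
  ci <- cbind(lower = ci[, 1],
              estimate = unclass(point$estimates)[free],
              upper = ci[, 2])
  structure(list(ci = ci, draws = draws, point = point,
                 n_nuclei = n_nuclei, reps = reps, seed = seed,
                 level = level),
            class = "fate_boot")
}

#' @export
print.fate_boot <- function(x, ...) {
  cat(sprintf("Bootstrap fit: %d replicates at n = %d nuclei (%.0f%% CI)\n",
              x$reps, x$n_nuclei, 100 * x$level))
  print(round(x$ci, 5))
  invisible(x)
}
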