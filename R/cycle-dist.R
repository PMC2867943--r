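#' Cell-cycle-time distribution
#'
#' Describes the distribution from which individual cell-cycle durations are
#' drawn, reproducing the cell-cycle asynchrony seen in live imaging. Three
#' families are supported: `"lognormal"` and `"gamma"` are parameterised by
#' their natural-scale mean and standard deviation in hours; `"empirical"`
#' samples from a binned histogram (a bin is drawn with its probability, then
#' a uniform offset within the bin), matching the 6-h resolution of live
#' imaging data.
#'
#' @param family One of `"lognormal"`, `"gamma"`, `"empirical"`.
#' @param mean_hours Mean cycle duration in hours (> 0). Ignored for the
#'   empirical family.
#' @param sd_hours Standard deviation in hours (>= 0). `sd_hours = 0`
#'   degenerates to a point mass at `mean_hours`.
#' @param histogram For the empirical family: a data frame with columns
#'   `bin_start_hours` and `probability` (6-h bins by convention);
#'   probabilities must sum to 1.
#' @param bin_hours Width of the empirical histogram bins (default 6).
#' @param quantize_hours Optional positive step; sampled durations are
#'   rounded up to the nearest multiple (e.g. 6 to mimic the 6-h imaging
#'   resolution). Default `NULL` (off).
#' @return An object of class `cycle_time_distribution`.
#' @examples
#' cycle_time_distribution("lognormal", mean_hours = 24, sd_hours = 9)
#' @export
cycle_time_distribution <- function(family = c("lognormal", "gamma", "empirical"),
                                    mean_hours = 24, sd_hours = 9,
                                    histogram = NULL, bin_hours = 6,
                                    quantize_hours = NULL) {
  family <- match.arg(family)
  if (family == "empirical") {
    if (is.null(histogram)) {
      stop("empirical cycle-time family requires a histogram", call. = FALSE)
    }
    histogram <- as.data.frame(histogram)
    need <- c("bin_start_hours", "probability")
    if (!all(need %in% names(histogram))) {
      stop("histogram must have columns bin_start_hours and probability",
           call. = FALSE)
    }
    if (any(histogram$probability < 0) ||
        abs(sum(histogram$probability) - 1) > 1e-9) {
      stop("histogram probabilities must be nonnegative and sum to 1",
           call. = FALSE)
    }
    if (any(histogram$bin_start_hours < 0)) {
      stop("histogram bins must start at nonnegative hours", call. = FALSE)
    }
    if (bin_hours <= 0) stop("bin_hours must be positive", call. = FALSE)
    p <- histogram$probability
    mids <- histogram$bin_start_hours + bin_hours / 2
    mean_hours <- sum(p * mids)
    sd_hours <- sqrt(sum(p * (mids - mean_hours)^2) + bin_hours^2 / 12)
  } else {
    if (!is.numeric(mean_hours) || mean_hours <= 0) {
      stop("mean_hours must be a positive number of hours", call. = FALSE)
    }
    if (!is.numeric(sd_hours) || sd_hours < 0) {
      stop("sd_hours must be a nonnegative number of hours", call. = FALSE)
    }
  }
  if (!is.null(quantize_hours) &&
      (!is.numeric(quantize_hours) || quantize_hours <= 0)) {
    stop("quantize_hours must be NULL or a positive step", call. = FALSE)
  }
  structure(
    list(family = family, mean_hours = mean_hours, sd_hours = sd_hours,
         histogram = histogram, bin_hours = bin_hours,
         quantize_hours = quantize_hours),
    class = "cycle_time_distribution"
  )
}

#' @export
print.cycle_time_distribution <- function(x, ...) {
  cat(sprintf("Cycle-time distribution: %s (mean %.3g h, sd %.3g h)%s\n",
              x$family, x$mean_hours, x$sd_hours,
              if (is.null(x$quantize_hours)) ""
              else sprintf(", quantized to %g h", x$quantize_hours)))
  invisible(x)
}

#' Sample cell-cycle durations
#'
#' Draws `n` durations from a [cycle_time_distribution()]. With
#' `sd_hours = 0` the mean is returned exactly. If `quantize_hours` is set,
#' samples are rounded up to the nearest multiple so that every duration is a
#' positive multiple of the step. Sampled values are strictly positive.
#'
#' @param dist A [cycle_time_distribution()].
#' @param n Number of draws (default 1).
#' @return Numeric vector of durations in hours.
#' @export
sample_cycle_time <- function(dist, n = 1L) {
  if (!inherits(dist, "cycle_time_distribution")) {
    stop("dist must be a cycle_time_distribution", call. = FALSE)
  }
  m <- dist$mean_hours
  s <- dist$sd_hours
  x <- switch(dist$family,
    lognormal = {
      if (s == 0) rep(m, n) else {
        sdlog <- sqrt(log(1 + (s / m)^2))
        stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
      }
    },
    gamma = {
      if (s == 0) rep(m, n) else {
        stats::rgamma(n, shape = (m / s)^2, rate = m / s^2)
      }
    },
    empirical = {
      h <- dist$histogram
      i <- sample.int(nrow(h), n, replace = TRUE, prob = h$probability)
      h$bin_start_hours[i] + stats::runif(n) * dist$bin_hours
    }
  )
  if (!is.null(dist$quantize_hours)) {
    q <- dist$quantize_hours
    x <- ceiling(x / q) * q
  }
  pmax(x, .Machine$double.eps)
}
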