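# Gaussian tuning banks, Poisson encoding and likelihood-based decoding.
#
# Each detector i has mean response f_i(s) = A * exp(-(s - c_i)^2 / (2*sd^2));
# a population response is one independent Poisson draw per detector. The
# Poisson log-likelihood of a response r at stimulus s is
#   sum_i [ r_i * log f_i(s) - f_i(s) - log(r_i!) ],
# with log f floored (f is never exactly zero analytically, but it underflows
# in far tails) so log-likelihoods stay finite.

.LOG_F_FLOOR <- 1e-12

#' Bank of Gaussian tuning curves
#'
#' Evenly spaced Gaussian tuning curves covering a range of one optical
#' variable. For `n_peaks >= 2` the centers include both endpoints; a single
#' peak sits at the range midpoint. All curves share one width and one peak
#' mean spike count (amplitude).
#'
#' @param variable Label, `"gamma"` or `"gamma_dot"`.
#' @param range Length-2 numeric, the covered stimulus range (lo < hi).
#' @param n_peaks Number of tuning curves (>= 1).
#' @param sd Tuning width in the variable's units (> 0).
#' @param amplitude Peak mean spike count per observation window (> 0, or 0
#'   for a silent bank, used in degenerate tests).
#' @return An object of class `tuning_bank` with fields `variable`, `range`,
#'   `centers`, `sd`, `amplitude`.
#' @examples
#' bk <- tuning_bank("gamma_dot", c(0.1, 2.2), 15, 0.1, 50)
#' diff(bk$centers)[1] # 0.15
#' @export
tuning_bank <- function(variable = c("gamma", "gamma_dot"), range, n_peaks, sd,
                        amplitude) {
  variable <- match.arg(variable)
  if (!is.numeric(range) || length(range) != 2L || !all(is.finite(range)) ||
      range[2] <= range[1])
    stop("`range` must be c(lo, hi) with hi > lo")
  if (!is.numeric(n_peaks) || length(n_peaks) != 1L || n_peaks < 1 ||
      n_peaks != round(n_peaks))
    stop("`n_peaks` must be a positive integer")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("`sd` must be a single positive number")
  if (!is.numeric(amplitude) || length(amplitude) != 1L || !is.finite(amplitude) ||
      amplitude < 0)
    stop("`amplitude` must be a single non-negative number")
  centers <- if (n_peaks == 1L) mean(range) else
    seq(range[1], range[2], length.out = n_peaks)
  structure(
    list(variable = variable, range = as.numeric(range), centers = centers,
         sd = sd, amplitude = amplitude),
    class = "tuning_bank"
  )
}

#' @export
print.tuning_bank <- function(x, ...) {
  cat(sprintf(
    "<tuning_bank> %s: %d peaks on [%.3g, %.3g], sd %.3g, amplitude %.3g\n",
    x$variable, length(x$centers), x$range[1], x$range[2], x$sd, x$amplitude
  ))
  invisible(x)
}

# mean-response matrix for a vector of stimuli: length(stimuli) x n_detectors
.mean_response_matrix <- function(bank, stimuli) {
  d <- outer(stimuli, bank$centers, "-")
  bank$amplitude * exp(-d^2 / (2 * bank$sd^2))
}

#' Mean population response to a stimulus
#'
#' Evaluates every tuning curve of a bank at one stimulus value. The stimulus
#' may lie outside the bank's range; responses simply decay in the Gaussian
#' tails.
#'
#' @param bank A [tuning_bank()].
#' @param stimulus A single stimulus value in the bank's units.
#' @return Numeric vector of mean spike counts, one per tuning curve.
#' @export
mean_response <- function(bank, stimulus) {
  stopifnot(inherits(bank, "tuning_bank"))
  if (!is.numeric(stimulus) || length(stimulus) != 1L || !is.finite(stimulus))
    stop("`stimulus` must be a single finite number")
  drop(.mean_response_matrix(bank, stimulus))
}

#' Encode a stimulus as a noisy population response
#'
#' Draws one independent Poisson spike count per tuning curve, with means
#' given by [mean_response()]. With `seed` supplied the draw is fully
#' reproducible; with `seed = NULL` the current RNG stream is used (and
#' advanced), which is how the trial simulator interleaves the two banks
#' under one per-trial seed.
#'
#' @inheritParams mean_response
#' @param seed Optional integer seed for this draw.
#' @return An object of class `population_response`: integer `counts`, plus
#'   the generating `bank`, `stimulus` and `seed` for provenance.
#' @export
encode <- function(bank, stimulus, seed = NULL) {
  stopifnot(inherits(bank, "tuning_bank"))
  if (!is.null(seed)) set.seed(seed)
  mu <- mean_response(bank, stimulus)
  counts <- stats::rpois(length(mu), mu)
  structure(
    list(counts = as.integer(counts), bank = bank, stimulus = stimulus,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "population_response"
  )
}

#' @export
print.population_response <- function(x, ...) {
  cat(sprintf("<population_response> %s, %d detectors: %s\n",
              x$bank$variable, length(x$counts),
              paste(x$counts, collapse = " ")))
  invisible(x)
}

# Spike counts are integers when drawn by encode(); bare numeric vectors may
# be real-valued so that expected (noise-free) responses r_i = f_i(s*) can be
# scored in stationarity analyses.
.response_counts <- function(response, bank) {
  counts <- if (inherits(response, "population_response")) response$counts
            else response
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("response counts must be non-negative numbers")
  if (length(counts) != length(bank$centers))
    stop(sprintf("response length (%d) does not match bank size (%d)",
                 length(counts), length(bank$centers)))
  as.numeric(counts)
}

#' Poisson log-likelihood of a population response
#'
#' Log-probability of observing the response's spike counts if the true
#' stimulus were `stimulus`, under independent Poisson noise around the
#' tuning-curve means. Vectorized over `stimulus`. The `log(counts!)` term is
#' computed through `lgamma` and retained, so values are true log-probabilities
#' (it cancels in any argmax).
#'
#' @param bank A [tuning_bank()].
#' @param response A `population_response` from [encode()] or a bare count
#'   vector matching the bank.
#' @param stimulus Stimulus value(s) at which to evaluate the likelihood.
#' @return Numeric vector of log-likelihoods, one per stimulus.
#' @export
log_likelihood <- function(bank, response, stimulus) {
  stopifnot(inherits(bank, "tuning_bank"))
  counts <- .response_counts(response, bank)
  if (!is.numeric(stimulus) || any(!is.finite(stimulus)))
    stop("`stimulus` must be finite numeric")
  f <- .mean_response_matrix(bank, stimulus)   # |stimulus| x n_det
  logf <- log(pmax(f, .LOG_F_FLOOR))
  drop(logf %*% counts) - rowSums(f) - sum(lgamma(counts + 1))
}

#' Maximum-likelihood decoding over a stimulus grid
#'
#' Grid search for the stimulus maximizing [log_likelihood()] over an evenly
#' spaced grid covering the bank's range. Ties break deterministically toward
#' the smaller stimulus value.
#'
#' @inheritParams log_likelihood
#' @param grid_step Grid spacing in the bank's units; must be positive and
#'   smaller than the bank range. Default 0.001, fine relative to the tuning
#'   width 0.1.
#' @return The decoded stimulus value (a single number).
#' @export
mle_decode <- function(bank, response, grid_step = 0.001) {
  stopifnot(inherits(bank, "tuning_bank"))
  width <- diff(bank$range)
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0 ||
      grid_step >= width)
    stop("`grid_step` must be positive and smaller than the bank range")
  s <- seq(bank$range[1], bank$range[2], by = grid_step)
  if (s[length(s)] < bank$range[2]) s <- c(s, bank$range[2])
  ll <- log_likelihood(bank, response, s)
  s[which.max(ll)]  # first max on an ascending grid = smallest stimulus
}
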