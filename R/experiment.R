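# The trial-level simulation and the prior-mean sweep.
#
# Each trial draws one horizontal velocity uniformly from the grid (gravity
# fixed at the encoding value, 1g by default), computes gamma and gamma_dot at
# the decision time, Poisson-encodes each on its bank under a per-trial seed,
# and decodes velocity four ways: {MLE, Bayes-with-prior} x {gamma, gamma_dot}.
# The sweep re-decodes the *same* encoded responses at every assumed prior
# mean (common random numbers), so the curves differ only through the prior.

.hash_obj <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# Simulate stimuli and responses once; precompute, per variable, the
# log-likelihood of every trial's response at each of the grid candidates'
# optical values (rows = trials, cols = candidates in tie-break order).
.simulate_responses <- function(n_trials, grid, banks, t, seed,
                                encoding_gravity) {
  stopifnot(inherits(grid, "trajectory_grid"))
  if (!setequal(names(banks), c("gamma", "gamma_dot")))
    stop("`banks` must be a named list with elements `gamma` and `gamma_dot`")
  for (v in names(banks)) {
    if (!inherits(banks[[v]], "tuning_bank") || banks[[v]]$variable != v)
      stop(sprintf("banks$%s must be a tuning_bank for variable `%s`", v, v))
  }
  set.seed(seed)
  v_true <- sample(grid$velocities, n_trials, replace = TRUE)
  response_seed <- sample.int(.Machine$integer.max, n_trials, replace = TRUE)
  stim <- list(
    gamma = .gamma_of(encoding_gravity, v_true, t),
    gamma_dot = .gamma_dot_of(encoding_gravity, v_true, t)
  )
  cand <- list(
    gamma = .candidate_table(grid, t, "gamma"),
    gamma_dot = .candidate_table(grid, t, "gamma_dot")
  )
  nc <- nrow(cand$gamma)
  counts <- list(
    gamma = matrix(0L, n_trials, length(banks$gamma$centers)),
    gamma_dot = matrix(0L, n_trials, length(banks$gamma_dot$centers))
  )
  loglik <- list(
    gamma = matrix(NA_real_, n_trials, nc),
    gamma_dot = matrix(NA_real_, n_trials, nc)
  )
  for (i in seq_len(n_trials)) {
    # one seed per trial; the second bank continues the same stream, so the
    # two draws are independent but jointly reproducible from response_seed
    rg <- encode(banks$gamma, stim$gamma[i], seed = response_seed[i])
    rgd <- encode(banks$gamma_dot, stim$gamma_dot[i], seed = NULL)
    counts$gamma[i, ] <- rg$counts
    counts$gamma_dot[i, ] <- rgd$counts
    loglik$gamma[i, ] <- .candidate_loglik(cand$gamma, banks$gamma, rg)
    loglik$gamma_dot[i, ] <- .candidate_loglik(cand$gamma_dot, banks$gamma_dot, rgd)
  }
  list(v_true = v_true, response_seed = response_seed, stim = stim,
       cand = cand, counts = counts, loglik = loglik,
       response_hash = .hash_obj(counts))
}

# decisions for all trials of one variable given per-trial candidate scores;
# same tie handling as the single-response readouts (exact optical aliases)
.decide_all <- function(cand, loglik, log_prior = 0) {
  scores <- sweep(loglik, 2L, log_prior, "+")
  idx <- apply(scores, 1L,
               function(s) which(s >= max(s) - .SCORE_TIE_TOL)[1])
  list(v_h = cand$v_h[idx], gravity = cand$gravity[idx])
}

#' Run the trial-level encoding/decoding simulation
#'
#' Simulates `n_trials` trials. In each, a horizontal velocity is sampled
#' uniformly from the grid with gravity fixed at `encoding_gravity`; the two
#' optical variables at time `t` are Poisson-encoded on their banks, and the
#' velocity is read out by the prior-free MLE rule and by the Bayesian rule
#' with the given gravity prior, separately for each decision variable. Fully
#' reproducible from `seed`.
#'
#' @param n_trials Number of trials (>= 0).
#' @param grid A [trajectory_grid()].
#' @param banks Named list of [tuning_bank()]s: `gamma` and `gamma_dot`.
#' @param prior A [gravity_prior()].
#' @param t Decision time in seconds.
#' @param seed Integer master seed; expanded into per-trial encoding seeds.
#' @param encoding_gravity Gravity generating the stimuli (m/s^2).
#' @return A data.frame of class `trial_records`, two rows per trial (one per
#'   decision variable), with columns `trial_id`, `true_velocity`,
#'   `true_gravity`, `variable`, `response_seed`, `decoded_velocity_mle`,
#'   `decoded_velocity_bayes`, `decoded_gravity_mle`, `decoded_gravity_bayes`.
#' @examples
#' sim <- build_simulation()
#' rec <- run_trials(20, sim$grid, sim$banks, sim$prior, t = 0.2, seed = 7)
#' summarize_trials(rec)
#' @export
run_trials <- function(n_trials, grid, banks, prior = gravity_prior(),
                       t = 0.2, seed = 1L, encoding_gravity = 9.820) {
  stopifnot(inherits(prior, "gaussian_belief"))
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 0 ||
      n_trials != round(n_trials))
    stop("`n_trials` must be a single non-negative integer")
  n_trials <- as.integer(n_trials)
  empty <- data.frame(
    trial_id = integer(), true_velocity = numeric(), true_gravity = numeric(),
    variable = character(), response_seed = integer(),
    decoded_velocity_mle = numeric(), decoded_velocity_bayes = numeric(),
    decoded_gravity_mle = numeric(), decoded_gravity_bayes = numeric()
  )
  if (n_trials == 0L) {
    return(structure(empty, class = c("trial_records", "data.frame"),
                     seed = as.integer(seed)))
  }
  sim <- .simulate_responses(n_trials, grid, banks, t, seed, encoding_gravity)
  rows <- lapply(c("gamma", "gamma_dot"), function(v) {
    mle <- .decide_all(sim$cand[[v]], sim$loglik[[v]])
    bay <- .decide_all(sim$cand[[v]], sim$loglik[[v]],
                       stats::dnorm(sim$cand[[v]]$gravity, prior$mean,
                                    prior$sd, log = TRUE))
    data.frame(
      trial_id = seq_len(n_trials), true_velocity = sim$v_true,
      true_gravity = encoding_gravity, variable = v,
      response_seed = sim$response_seed,
      decoded_velocity_mle = mle$v_h, decoded_velocity_bayes = bay$v_h,
      decoded_gravity_mle = mle$gravity, decoded_gravity_bayes = bay$gravity
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$trial_id, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("trial_records", "data.frame"),
            seed = as.integer(seed), response_hash = sim$response_hash)
}

#' @export
as.data.frame.trial_records <- function(x, ...) {
  attr(x, "seed") <- NULL
  attr(x, "response_hash") <- NULL
  class(x) <- "data.frame"
  x
}

#' Fraction of correct velocity decisions per decoder and variable
#'
#' A trial counts as correct when the decoded velocity equals the generating
#' grid velocity exactly (a discrete decision over the velocity grid).
#' Fractions come with binomial standard errors.
#'
#' @param records A `trial_records` data.frame from [run_trials()].
#' @return A data.frame with columns `decoder`, `variable`, `n`, `n_correct`,
#'   `fraction`, `se`. With no records, fractions are `NA` and a warning is
#'   raised rather than reporting zero.
#' @export
summarize_trials <- function(records) {
  if (nrow(records) == 0L) {
    warning("no trial records: fractions are undefined")
    return(data.frame(decoder = character(), variable = character(),
                      n = integer(), n_correct = integer(),
                      fraction = numeric(), se = numeric()))
  }
  cells <- expand.grid(decoder = c("mle", "bayes"),
                       variable = c("gamma", "gamma_dot"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    dec <- cells$decoder[i]; v <- cells$variable[i]
    sub <- records[records$variable == v, , drop = FALSE]
    hit <- sub[[paste0("decoded_velocity_", dec)]] == sub$true_velocity
    n <- nrow(sub); k <- sum(hit); p <- k / n
    data.frame(decoder = dec, variable = v, n = n, n_correct = k,
               fraction = p, se = sqrt(p * (1 - p) / n))
  }))
  rownames(out) <- NULL
  out
}

#' Sweep the assumed gravity-prior mean
#'
#' Simulates one batch of trials (stimuli and Poisson responses fixed by
#' `seed`) and re-decodes it under a Gaussian gravity prior centered at each
#' value of `prior_means` in turn. Because the responses are shared across
#' sweep points, the fraction-correct curves differ only through the assumed
#' prior. The prior-free MLE decision is reported alongside as a baseline
#' (constant across prior means).
#'
#' @param prior_means Assumed prior means to sweep (m/s^2), non-empty.
#' @param prior_sd Prior standard deviation shared across the sweep (m/s^2).
#' @inheritParams run_trials
#' @return An object of class `sweep_result`: list with the tidy data.frame
#'   `table` (columns `prior_mean`, `decoder`, `variable`, `n`, `n_correct`,
#'   `fraction`, `se`), `prior_means`, `n_trials`, `chance_level`
#'   (1 / number of grid velocities), `seed` and `response_hash`.
#' @examples
#' sim <- build_simulation()
#' sw <- prior_sweep(c(8.838, 9.820, 10.802), 0.5, 50,
#'                   sim$grid, sim$banks, seed = 7)
#' sw$table
#' @export
prior_sweep <- function(prior_means, prior_sd = 0.5, n_trials = 1000,
                        grid = trajectory_grid(),
                        banks = build_simulation()$banks,
                        t = 0.2, seed = 1L, encoding_gravity = 9.820) {
  if (!is.numeric(prior_means) || length(prior_means) == 0L ||
      any(!is.finite(prior_means)) || any(prior_means <= 0))
    stop("`prior_means` must be a non-empty vector of positive numbers")
  if (!is.numeric(prior_sd) || length(prior_sd) != 1L || prior_sd <= 0)
    stop("`prior_sd` must be a single positive number")
  sim <- .simulate_responses(n_trials, grid, banks, t, seed, encoding_gravity)
  .cell <- function(prior_mean, decoder, v, v_hat) {
    hit <- v_hat == sim$v_true
    n <- length(hit); k <- sum(hit); p <- if (n > 0) k / n else NA_real_
    data.frame(prior_mean = prior_mean, decoder = decoder, variable = v,
               n = n, n_correct = k, fraction = p,
               se = if (n > 0) sqrt(p * (1 - p) / n) else NA_real_)
  }
  rows <- list()
  for (pm in prior_means) {
    for (v in c("gamma", "gamma_dot")) {
      mle <- .decide_all(sim$cand[[v]], sim$loglik[[v]])
      bay <- .decide_all(sim$cand[[v]], sim$loglik[[v]],
                         stats::dnorm(sim$cand[[v]]$gravity, pm, prior_sd,
                                      log = TRUE))
      rows[[length(rows) + 1L]] <- .cell(pm, "mle", v, mle$v_h)
      rows[[length(rows) + 1L]] <- .cell(pm, "bayes", v, bay$v_h)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(
    list(table = tab, prior_means = as.numeric(prior_means),
         n_trials = as.integer(n_trials),
         chance_level = 1 / length(grid$velocities),
         seed = as.integer(seed), response_hash = sim$response_hash),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d prior means x {mle, bayes} x {gamma, gamma_dot}, %d trials, chance %.3g\n",
              length(x$prior_means), x$n_trials, x$chance_level))
  print(utils::head(x$table, 8), row.names = FALSE)
  if (nrow(x$table) > 8) cat("  ...\n")
  invisible(x)
}

#' Write simulation results to disk
#'
#' `format = "csv"` writes the tidy table (one row per trial record, or per
#' prior-mean x decoder x variable cell for sweeps). `format = "json"` writes
#' a provenance-bearing summary: the seed, the full configuration (when
#' supplied) with its hash, and the aggregated fractions, plus the table
#' itself so the file round-trips.
#'
#' @param x A `trial_records` data.frame or a `sweep_result`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @param cfg Optional [sim_config()] embedded in JSON output for provenance.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json"), cfg = NULL) {
  format <- match.arg(format)
  if (inherits(x, "sweep_result")) {
    tab <- x$table
    seed <- x$seed
    summary <- x$table
    kind <- "sweep"
    extra <- list(prior_means = x$prior_means, n_trials = x$n_trials,
                  chance_level = x$chance_level)
  } else if (inherits(x, "trial_records")) {
    tab <- as.data.frame(x)
    seed <- attr(x, "seed")
    summary <- if (nrow(tab) > 0) summarize_trials(x) else NULL
    kind <- "trials"
    extra <- list()
  } else {
    stop("`x` must be a `trial_records` or `sweep_result` object")
  }
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    payload <- c(
      list(kind = kind, seed = seed,
           config = if (!is.null(cfg)) unclass(validate_config(cfg)),
           config_hash = if (!is.null(cfg)) config_hash(cfg),
           summary = summary, table = tab),
      extra
    )
    jsonlite::write_json(payload[!vapply(payload, is.null, logical(1))], path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Plot fraction-correct curves from a prior-mean sweep
#'
#' Draws fraction correct against the assumed prior mean, one curve per
#' decoder x decision-variable combination, with the chance level shaded.
#' Requires ggplot2.
#'
#' @param sweep A `sweep_result`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sweep requires the ggplot2 package")
  tab <- sweep$table
  tab$curve <- paste(tab$decoder, tab$variable, sep = " / ")
  ggplot2::ggplot(tab, ggplot2::aes(x = prior_mean, y = fraction,
                                    colour = curve)) +
    ggplot2::geom_hline(yintercept = sweep$chance_level, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "assumed gravity prior mean (m/s^2)",
                  y = "fraction of correct velocity estimates",
                  colour = NULL) +
    ggplot2::ylim(0, 1)
}
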