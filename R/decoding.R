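# Mapping decoded optical values back to trajectories, velocity readout with
# and without the gravity prior, and conjugate Gaussian fusion.
#
# The readouts score every grid trajectory by the Poisson log-likelihood of the
# observed response evaluated at that candidate's optical value at the decision
# time; the Bayesian readout adds the log density of a Gaussian gravity prior
# at the candidate's gravity (a candidate-level MAP rule that reduces to pure
# MLE under a flat prior). Ties break toward lower gravity, then lower
# velocity, so runs are exactly reproducible.

#' Gaussian prior over gravitational acceleration
#'
#' @param mean Prior mean in m/s^2.
#' @param sd Prior standard deviation in m/s^2 (> 0). The default 0.5 encodes
#'   a strong (lifelong-experience) earth-gravity prior.
#' @return An object of class `c("gravity_prior", "gaussian_belief")`.
#' @export
gravity_prior <- function(mean = 9.820, sd = 0.5) {
  b <- gaussian_belief(mean, sd)
  class(b) <- c("gravity_prior", class(b))
  b
}

#' Gaussian belief over a scalar world state
#'
#' A mean/sd pair used for prior, likelihood and posterior in conjugate
#' Gaussian fusion.
#'
#' @param mean Scalar mean.
#' @param sd Positive scalar standard deviation.
#' @export
gaussian_belief <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("`mean` must be a single finite number")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("`sd` must be a single positive number")
  structure(list(mean = mean, sd = sd), class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("<%s> mean %.4g, sd %.4g\n", class(x)[1], x$mean, x$sd))
  invisible(x)
}

#' Precision-weighted fusion of two Gaussian beliefs
#'
#' Conjugate combination of a Gaussian prior and a Gaussian likelihood:
#' posterior precision is the sum of the precisions and the posterior mean is
#' the precision-weighted average of the two means. The posterior mean always
#' lies between the input means and the posterior sd is strictly smaller than
#' both input sds. With a very small prior sd (a strong prior) the posterior
#' stays close to the prior regardless of the likelihood.
#'
#' @param prior,likelihood [gaussian_belief()] objects.
#' @return The posterior as a `gaussian_belief`.
#' @examples
#' gaussian_fuse(gaussian_belief(0, 1), gaussian_belief(1, 1)) # mean 0.5
#' @export
gaussian_fuse <- function(prior, likelihood) {
  stopifnot(inherits(prior, "gaussian_belief"), inherits(likelihood, "gaussian_belief"))
  wp <- 1 / prior$sd^2
  wl <- 1 / likelihood$sd^2
  gaussian_belief(
    mean = (wp * prior$mean + wl * likelihood$mean) / (wp + wl),
    sd = sqrt(1 / (wp + wl))
  )
}

# candidates ordered for deterministic tie-breaks: lower gravity, then lower
# velocity (the grid is already built in that order), with their optical value
# at the decision time
.candidate_table <- function(grid, t, variable) {
  tr <- grid$trajectories
  tr$value <- if (variable == "gamma") .gamma_of(tr$gravity, tr$v_h, t)
              else .gamma_dot_of(tr$gravity, tr$v_h, t)
  tr[order(tr$gravity, tr$v_h), , drop = FALSE]
}

#' Candidate trajectories compatible with a decoded optical value
#'
#' Returns every grid trajectory whose optical value at time `t` lies within a
#' relative margin of the estimate: `|value - estimate| <= margin * estimate`.
#' This is the diagnostic candidate set behind the ambiguity argument (many
#' gravity/velocity pairs share nearly the same optical value); it is not the
#' decision rule.
#'
#' @param grid A [trajectory_grid()].
#' @param estimate Decoded optical value (> 0).
#' @param t Decision time in seconds.
#' @param variable `"gamma"` or `"gamma_dot"`.
#' @param margin Relative tolerance (fraction, >= 0); default 0.10.
#' @return An object of class `candidate_set`: list with a data.frame
#'   `members` (columns `gravity`, `v_h`, `value`), plus `estimate`,
#'   `variable`, `margin`, `t`. The set may be empty.
#' @export
match_candidates <- function(grid, estimate, t, variable = c("gamma", "gamma_dot"),
                             margin = 0.10) {
  stopifnot(inherits(grid, "trajectory_grid"))
  variable <- match.arg(variable)
  if (!is.numeric(estimate) || length(estimate) != 1L || estimate <= 0)
    stop("`estimate` must be a single positive number")
  if (!is.numeric(margin) || length(margin) != 1L || margin < 0)
    stop("`margin` must be a single non-negative number")
  cand <- .candidate_table(grid, .check_time(t), variable)
  keep <- abs(cand$value - estimate) <= margin * estimate
  structure(
    list(members = cand[keep, , drop = FALSE], estimate = estimate,
         variable = variable, margin = margin, t = t),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d of the grid trajectories within %.0f%% of %s = %.4g\n",
              nrow(x$members), 100 * x$margin, x$variable, x$estimate))
  if (nrow(x$members)) print(x$members, row.names = FALSE)
  invisible(x)
}

# Shared argmax over candidate scores; cand must be sorted (gravity, v_h).
# Several grid trajectories share the exact same g/v_h ratio and hence the
# exact same optical value (the core ambiguity), so their scores tie to the
# last bit; scores within .SCORE_TIE_TOL of the maximum are treated as tied
# and resolved by the lower-gravity, lower-velocity ordering.
.SCORE_TIE_TOL <- 1e-9
.readout_from_scores <- function(cand, scores) {
  i <- which(scores >= max(scores) - .SCORE_TIE_TOL)[1]
  list(v_h = cand$v_h[i], gravity = cand$gravity[i], value = cand$value[i],
       score = scores[i])
}

# log-likelihood of a response at every candidate's optical value
.candidate_loglik <- function(cand, bank, response) {
  log_likelihood(bank, response, cand$value)
}

#' Maximum-likelihood velocity readout (no gravity prior)
#'
#' Scores every grid trajectory by the Poisson log-likelihood of the response
#' at that candidate's optical value at time `t` and returns the best one
#' (a flat prior over gravity and velocity). Ties break toward lower gravity,
#' then lower velocity.
#'
#' @param grid A [trajectory_grid()].
#' @param bank The [tuning_bank()] the response was generated on.
#' @param response A `population_response` or count vector.
#' @param t Decision time in seconds.
#' @param variable `"gamma"` or `"gamma_dot"`.
#' @return A list with the decided `v_h`, `gravity`, the candidate's optical
#'   `value` and its `score` (log-likelihood).
#' @export
mle_velocity_readout <- function(grid, bank, response, t,
                                 variable = c("gamma", "gamma_dot")) {
  stopifnot(inherits(grid, "trajectory_grid"))
  variable <- match.arg(variable)
  cand <- .candidate_table(grid, .check_time(t), variable)
  if (nrow(cand) == 0L) stop("trajectory grid is empty")
  .readout_from_scores(cand, .candidate_loglik(cand, bank, response))
}

#' Bayesian velocity readout with a gravity prior
#'
#' As [mle_velocity_readout()], but each candidate's log-likelihood is
#' augmented with the log density of a Gaussian gravity prior at the
#' candidate's gravity (candidate-level MAP). With a very wide prior the
#' decision equals the pure MLE readout; with a very narrow prior the decision
#' is confined to the grid gravity closest to the prior mean.
#'
#' @inheritParams mle_velocity_readout
#' @param prior A [gravity_prior()] (or any `gaussian_belief` over gravity).
#' @export
bayes_velocity_readout <- function(grid, bank, response, t,
                                   variable = c("gamma", "gamma_dot"),
                                   prior = gravity_prior()) {
  stopifnot(inherits(grid, "trajectory_grid"), inherits(prior, "gaussian_belief"))
  variable <- match.arg(variable)
  cand <- .candidate_table(grid, .check_time(t), variable)
  if (nrow(cand) == 0L) stop("trajectory grid is empty")
  scores <- .candidate_loglik(cand, bank, response) +
    stats::dnorm(cand$gravity, prior$mean, prior$sd, log = TRUE)
  .readout_from_scores(cand, scores)
}
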