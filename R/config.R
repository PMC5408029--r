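# Validated simulation configuration. Defaults reproduce the printed study
# conditions: 8 velocities x 7 gravities (56 trajectories), observation time
# 0.2 s, tuning banks (11 peaks on [0, 1.0] rad) and (15 peaks on
# [0.1, 2.2] rad/s) with SD 0.1, 1000 trials, strong gravity prior SD 0.5.

.config_fields <- c(
  "velocities", "gravities", "encoding_gravity", "t_obs",
  "gamma_bank", "gamma_dot_bank", "grid_step", "margin",
  "prior_mean", "prior_sd", "sweep_means", "n_trials", "seed"
)
.bank_fields <- c("range", "n_peaks", "sd", "amplitude")

#' Simulation configuration
#'
#' Builds and validates the full parameter set of the ideal-observer
#' simulation. The defaults are the study conditions: a 56-trajectory grid
#' (velocities 3-10 m/s, gravities 0.7-1.3 x 9.820 m/s^2), observation time
#' 0.2 s, Gaussian tuning banks of 11 peaks on [0, 1.0] rad and 15 peaks on
#' [0.1, 2.2] rad/s (SD 0.1, peak mean count 50), 1000 trials, and a strong
#' gravity prior N(9.820, 0.5^2).
#'
#' @param velocities Horizontal-speed grid (m/s), strictly increasing.
#' @param gravities Gravity grid (m/s^2), strictly increasing.
#' @param encoding_gravity Gravity used to generate stimuli (m/s^2); 1g.
#' @param t_obs Decision time after motion onset (s).
#' @param gamma_bank,gamma_dot_bank Lists with `range`, `n_peaks`, `sd`,
#'   `amplitude` for the two tuning banks.
#' @param grid_step Stimulus grid step for [mle_decode()].
#' @param margin Relative margin for [match_candidates()].
#' @param prior_mean,prior_sd Gravity prior parameters (m/s^2).
#' @param sweep_means Prior means swept by [prior_sweep()]; default 0.7g to
#'   1.3g in 0.05g steps.
#' @param n_trials Number of simulated trials.
#' @param seed Integer master seed.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(velocities = .default_velocities(),
                       gravities = .default_gravities(),
                       encoding_gravity = 9.820,
                       t_obs = 0.2,
                       gamma_bank = list(range = c(0, 1.0), n_peaks = 11,
                                         sd = 0.1, amplitude = 50),
                       gamma_dot_bank = list(range = c(0.1, 2.2), n_peaks = 15,
                                             sd = 0.1, amplitude = 50),
                       grid_step = 0.001,
                       margin = 0.10,
                       prior_mean = 9.820,
                       prior_sd = 0.5,
                       sweep_means = round(seq(0.7, 1.3, by = 0.05) * 9.820, 4),
                       n_trials = 1000,
                       seed = 1L) {
  cfg <- structure(
    list(velocities = as.numeric(velocities), gravities = as.numeric(gravities),
         encoding_gravity = encoding_gravity, t_obs = t_obs,
         gamma_bank = gamma_bank, gamma_dot_bank = gamma_dot_bank,
         grid_step = grid_step, margin = margin,
         prior_mean = prior_mean, prior_sd = prior_sd,
         sweep_means = as.numeric(sweep_means),
         n_trials = n_trials, seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks field presence, types and value constraints; rejects unknown
#' fields. Errors name the offending field.
#'
#' @param cfg A `sim_config` or plain named list.
#' @return The validated `sim_config`, invisibly usable in pipelines.
#' @export
validate_config <- function(cfg) {
  nm <- names(cfg)
  unknown <- setdiff(nm, .config_fields)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.config_fields, nm)
  if (length(missing))
    stop("missing config field(s): ", paste(missing, collapse = ", "))
  .pos_scalar <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("config field `%s` must be a single positive number", field))
  }
  # grid axes are validated by trajectory_grid
  trajectory_grid(cfg$velocities, cfg$gravities)
  .pos_scalar(cfg$encoding_gravity, "encoding_gravity")
  .pos_scalar(cfg$t_obs, "t_obs")
  for (bk in c("gamma_bank", "gamma_dot_bank")) {
    b <- cfg[[bk]]
    if (!is.list(b) || !setequal(names(b), .bank_fields))
      stop(sprintf("config field `%s` must be a list with fields %s",
                   bk, paste(.bank_fields, collapse = ", ")))
    # full constraint check via the constructor
    tuning_bank(sub("_bank$", "", bk), b$range, b$n_peaks, b$sd, b$amplitude)
  }
  .pos_scalar(cfg$grid_step, "grid_step")
  if (!is.numeric(cfg$margin) || length(cfg$margin) != 1L || cfg$margin < 0)
    stop("config field `margin` must be a single non-negative number")
  .pos_scalar(cfg$prior_mean, "prior_mean")
  .pos_scalar(cfg$prior_sd, "prior_sd")
  if (!is.numeric(cfg$sweep_means) || length(cfg$sweep_means) == 0L ||
      any(cfg$sweep_means <= 0))
    stop("config field `sweep_means` must be a non-empty positive numeric vector")
  if (!is.numeric(cfg$n_trials) || length(cfg$n_trials) != 1L ||
      cfg$n_trials < 0 || cfg$n_trials != round(cfg$n_trials))
    stop("config field `n_trials` must be a single non-negative integer")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L ||
      cfg$seed != round(cfg$seed))
    stop("config field `seed` must be a single integer")
  if (!inherits(cfg, "sim_config")) class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d trajectories (%d velocities x %d gravities), t = %g s\n",
    "  banks: gamma %d peaks on [%g, %g]; gamma_dot %d peaks on [%g, %g]; sd %g; amplitude %g\n",
    "  prior N(%g, %g^2); %d trials; seed %d\n"),
    length(x$velocities) * length(x$gravities), length(x$velocities),
    length(x$gravities), x$t_obs,
    x$gamma_bank$n_peaks, x$gamma_bank$range[1], x$gamma_bank$range[2],
    x$gamma_dot_bank$n_peaks, x$gamma_dot_bank$range[1], x$gamma_dot_bank$range[2],
    x$gamma_bank$sd, x$gamma_bank$amplitude,
    x$prior_mean, x$prior_sd, x$n_trials, x$seed))
  invisible(x)
}

#' Load a configuration from YAML (or return the defaults)
#'
#' Reads a YAML file whose keys mirror the [sim_config()] arguments, fills
#' unspecified fields with the defaults, validates strictly (unknown keys are
#' an error) and returns the config. With `path = NULL` the default study
#' conditions are returned.
#'
#' @param path Path to a YAML config file, or `NULL` for defaults.
#' @return A validated `sim_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(sim_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .config_fields)
  if (length(unknown))
    stop("unknown config field(s) in ", path, ": ", paste(unknown, collapse = ", "))
  for (bk in intersect(c("gamma_bank", "gamma_dot_bank"), names(raw)))
    raw[[bk]]$range <- as.numeric(raw[[bk]]$range)
  do.call(sim_config, raw)
}

#' Save a configuration to YAML
#'
#' @param cfg A `sim_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization; used in provenance blocks so a
#' result file can be traced to the exact parameter set that produced it.
#'
#' @param cfg A `sim_config`.
#' @return A 32-character hex string.
#' @export
config_hash <- function(cfg) {
  cfg <- validate_config(cfg)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Build the pieces of a simulation from its configuration
#'
#' @param cfg A `sim_config`.
#' @return A list with `grid` ([trajectory_grid()]), `banks` (named list of
#'   [tuning_bank()]s for `gamma` and `gamma_dot`) and `prior`
#'   ([gravity_prior()]).
#' @export
build_simulation <- function(cfg = sim_config()) {
  cfg <- validate_config(cfg)
  list(
    grid = trajectory_grid(cfg$velocities, cfg$gravities),
    banks = list(
      gamma = tuning_bank("gamma", cfg$gamma_bank$range, cfg$gamma_bank$n_peaks,
                          cfg$gamma_bank$sd, cfg$gamma_bank$amplitude),
      gamma_dot = tuning_bank("gamma_dot", cfg$gamma_dot_bank$range,
                              cfg$gamma_dot_bank$n_peaks, cfg$gamma_dot_bank$sd,
                              cfg$gamma_dot_bank$amplitude)
    ),
    prior = gravity_prior(cfg$prior_mean, cfg$prior_sd)
  )
}
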