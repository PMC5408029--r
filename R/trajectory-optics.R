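# Trajectory family and the two optical variables.
#
# Geometry: a point target travels a symmetric parabola head-on toward the
# observer, who stands at the landing point with the eye at launch height.
# Horizontal speed v_h is constant (no drag); t is measured from motion onset,
# so the elevation angle gamma starts at exactly 0. Under this geometry
#   tan(gamma(t)) = g*t / (2*v_h),
# the unique closed form consistent with a symmetric parabola of flight time
# 2*v_h*tan(theta)/... observed from its landing point. All angles in radians.

#' Parabolic trajectory
#'
#' A head-on parabolic trajectory parameterized by gravitational acceleration
#' and constant horizontal speed. The observer is at the landing point with the
#' eye at launch height, so the elevation angle is 0 at motion onset.
#'
#' @param gravity Gravitational acceleration in m/s^2 (positive scalar).
#' @param v_h Horizontal speed in m/s (positive scalar).
#' @return An object of class `trajectory` with fields `gravity` and `v_h`.
#' @examples
#' tr <- trajectory(9.820, 6)
#' elevation_angle(tr, 0.2)
#' @export
trajectory <- function(gravity, v_h) {
  if (!is.numeric(gravity) || length(gravity) != 1L || !is.finite(gravity) || gravity <= 0)
    stop("`gravity` must be a single positive number (m/s^2)")
  if (!is.numeric(v_h) || length(v_h) != 1L || !is.finite(v_h) || v_h <= 0)
    stop("`v_h` must be a single positive number (m/s)")
  structure(list(gravity = gravity, v_h = v_h), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> g = %.3f m/s^2, v_h = %.2f m/s\n", x$gravity, x$v_h))
  invisible(x)
}

.check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("time `t` must be non-negative and finite")
  t
}

# internal vectorized forms over (g, v, t)
.gamma_of <- function(g, v, t) atan(g * t / (2 * v))
.gamma_dot_of <- function(g, v, t) 2 * g * v / (g^2 * t^2 + 4 * v^2)

#' Elevation angle of a head-on parabolic trajectory
#'
#' The angle between the observer's straight-ahead gaze and the line of sight
#' to the target, `atan(g * t / (2 * v_h))`. Strictly increasing in `t`,
#' increasing in gravity and decreasing in horizontal speed.
#'
#' @param traj A [trajectory()].
#' @param t Time since motion onset in seconds (vectorized, non-negative).
#' @return Elevation angle(s) in radians, in `[0, pi/2)`.
#' @export
elevation_angle <- function(traj, t) {
  stopifnot(inherits(traj, "trajectory"))
  .gamma_of(traj$gravity, traj$v_h, .check_time(t))
}

#' Rate of change of the elevation angle
#'
#' Time derivative of [elevation_angle()]:
#' `2 * g * v_h / (g^2 * t^2 + 4 * v_h^2)` (rad/s). Strictly positive and,
#' for the speeds used here (v_h > g*t/2), strictly decreasing in `t`.
#'
#' @inheritParams elevation_angle
#' @return Angular rate(s) in rad/s.
#' @export
elevation_rate <- function(traj, t) {
  stopifnot(inherits(traj, "trajectory"))
  .gamma_dot_of(traj$gravity, traj$v_h, .check_time(t))
}

#' Optical variable of a trajectory at a given time
#'
#' Convenience dispatcher returning either the elevation angle (`"gamma"`) or
#' its rate of change (`"gamma_dot"`).
#'
#' @inheritParams elevation_angle
#' @param variable `"gamma"` or `"gamma_dot"`.
#' @export
optical_value <- function(traj, t, variable = c("gamma", "gamma_dot")) {
  variable <- match.arg(variable)
  if (variable == "gamma") elevation_angle(traj, t) else elevation_rate(traj, t)
}

.default_gravities <- function(g1 = 9.820) round(seq(0.7, 1.3, by = 0.1) * g1, 3)
.default_velocities <- function() as.numeric(3:10)

#' Grid of parabolic trajectories
#'
#' Cartesian product of a velocity grid and a gravity grid, in deterministic
#' gravity-major order (all velocities for the lowest gravity first). The
#' defaults combine eight horizontal speeds (3 to 10 m/s in 1 m/s steps) with
#' seven gravities (0.7 to 1.3 times 9.820 m/s^2 in 0.1 steps), i.e. 56
#' trajectories.
#'
#' @param velocities Strictly increasing positive horizontal speeds (m/s).
#' @param gravities Strictly increasing positive accelerations (m/s^2).
#' @return An object of class `trajectory_grid`: a list with `velocities`,
#'   `gravities` and a data.frame `trajectories` with columns `gravity`, `v_h`.
#' @examples
#' g <- trajectory_grid()
#' nrow(g$trajectories) # 56
#' @export
trajectory_grid <- function(velocities = .default_velocities(),
                            gravities = .default_gravities()) {
  .check_axis <- function(x, nm) {
    if (!is.numeric(x) || length(x) == 0L)
      stop(sprintf("`%s` must be a non-empty numeric vector", nm))
    if (any(!is.finite(x)) || any(x <= 0))
      stop(sprintf("`%s` must be strictly positive and finite", nm))
    if (length(x) > 1L && any(diff(x) <= 0))
      stop(sprintf("`%s` must be strictly increasing", nm))
    as.numeric(x)
  }
  velocities <- .check_axis(velocities, "velocities")
  gravities <- .check_axis(gravities, "gravities")
  trajectories <- data.frame(
    gravity = rep(gravities, each = length(velocities)),
    v_h = rep(velocities, times = length(gravities))
  )
  structure(
    list(velocities = velocities, gravities = gravities,
         trajectories = trajectories),
    class = "trajectory_grid"
  )
}

#' @export
print.trajectory_grid <- function(x, ...) {
  cat(sprintf(
    "<trajectory_grid> %d trajectories: %d velocities (%.3g-%.3g m/s) x %d gravities (%.4g-%.4g m/s^2)\n",
    nrow(x$trajectories), length(x$velocities), min(x$velocities), max(x$velocities),
    length(x$gravities), min(x$gravities), max(x$gravities)
  ))
  invisible(x)
}

#' Check that a grid's optical values stay inside the tuning ranges
#'
#' Evaluates the extremes of the elevation angle and its rate over all grid
#' trajectories and an observation window, and reports whether each variable
#' stays inside its tuning-curve range. Both variables are monotone in time
#' (gamma increasing, gamma_dot decreasing), so the extremes are attained at
#' the window endpoints.
#'
#' @param grid A [trajectory_grid()].
#' @param t_window Numeric length-2 observation window `c(t0, t1)`, `t0 <= t1`.
#' @param gamma_range Length-2 admissible range for gamma (rad).
#' @param gamma_dot_range Length-2 admissible range for gamma_dot (rad/s).
#' @return A data.frame with one row per variable: observed `min`/`max`, the
#'   range bounds `lo`/`hi`, and a logical `pass`. An empty grid passes
#'   vacuously (min/max are `NA`).
#' @export
check_ranges <- function(grid, t_window = c(0, 0.2),
                         gamma_range = c(0, 1.0),
                         gamma_dot_range = c(0.1, 2.2)) {
  stopifnot(inherits(grid, "trajectory_grid"))
  if (length(t_window) != 2L || t_window[1] > t_window[2] || any(t_window < 0))
    stop("`t_window` must be c(t0, t1) with 0 <= t0 <= t1")
  tr <- grid$trajectories
  if (nrow(tr) == 0L) {
    return(data.frame(
      variable = c("gamma", "gamma_dot"),
      min = NA_real_, max = NA_real_,
      lo = c(gamma_range[1], gamma_dot_range[1]),
      hi = c(gamma_range[2], gamma_dot_range[2]),
      pass = TRUE
    ))
  }
  ts <- t_window
  gam <- c(.gamma_of(tr$gravity, tr$v_h, ts[1]), .gamma_of(tr$gravity, tr$v_h, ts[2]))
  gd <- c(.gamma_dot_of(tr$gravity, tr$v_h, ts[1]), .gamma_dot_of(tr$gravity, tr$v_h, ts[2]))
  out <- data.frame(
    variable = c("gamma", "gamma_dot"),
    min = c(min(gam), min(gd)),
    max = c(max(gam), max(gd)),
    lo = c(gamma_range[1], gamma_dot_range[1]),
    hi = c(gamma_range[2], gamma_dot_range[2])
  )
  out$pass <- out$min >= out$lo & out$max <= out$hi
  out
}
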