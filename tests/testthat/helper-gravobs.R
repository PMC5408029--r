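# Shared fixtures and independent oracles for the test suite.

# Coordinate-geometry oracle for the elevation angle: simulate the projectile
# in world coordinates (launch at the origin with vertical speed g*T/2 so the
# parabola is symmetric with flight time T; observer at the landing point,
# eye at launch height) and read the angle off the height / remaining
# horizontal distance. Independent of the closed form under test.
oracle_elevation_angle <- function(g, v, t, T_flight = 2) {
  stopifnot(t < T_flight)
  u <- g * T_flight / 2                 # vertical launch speed
  height <- u * t - g * t^2 / 2
  x_remaining <- v * (T_flight - t)     # distance still to cover
  atan2(height, x_remaining)
}

# Central finite difference of the elevation angle.
oracle_elevation_rate <- function(traj, t, h = 1e-6) {
  (elevation_angle(traj, t + h) - elevation_angle(traj, t - h)) / (2 * h)
}

# Brute-force Poisson log-likelihood through stats::dpois (integer counts).
oracle_loglik <- function(bank, counts, stimulus) {
  f <- mean_response(bank, stimulus)
  sum(stats::dpois(counts, f, log = TRUE))
}

# Exhaustive candidate enumeration for the matching rule.
oracle_match <- function(grid, estimate, t, variable, margin) {
  tr <- grid$trajectories
  val <- if (variable == "gamma") {
    atan(tr$gravity * t / (2 * tr$v_h))
  } else {
    2 * tr$gravity * tr$v_h / (tr$gravity^2 * t^2 + 4 * tr$v_h^2)
  }
  tr[abs(val - estimate) <= margin * estimate, , drop = FALSE]
}

# Small-amplitude banks keep Monte-Carlo tests fast without changing the
# study-condition geometry (ranges, peak counts, widths).
test_banks <- function(amplitude = 50) {
  list(
    gamma = tuning_bank("gamma", c(0, 1.0), 11, 0.1, amplitude),
    gamma_dot = tuning_bank("gamma_dot", c(0.1, 2.2), 15, 0.1, amplitude)
  )
}

expected_response <- function(bank, stimulus) mean_response(bank, stimulus)
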