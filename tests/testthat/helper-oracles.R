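# Independent closed-form oracles and small fixtures used across tests.

deg2rad <- function(a) a * pi / 180

# Displacement of an orbiting disc from its centre, straight from the
# parametric circle (clockwise-from-top phase convention, y-up).
oracle_orbit_disp <- function(t, radius, period, direction, phase0) {
  s <- if (direction == "CW") 1 else -1
  a <- deg2rad(phase0 + s * 360 * t / period)
  cbind(radius * sin(a), radius * cos(a))
}

# Perceived displacement under perfect pursuit/efference: the weighted cue
# combination collapses to d_target - (1 - k) * d_inducer.
oracle_percept_disp <- function(t, k, target, inducer) {
  dt_ <- oracle_orbit_disp(t, target$radius, target$period,
                           target$direction, target$phase0)
  di <- oracle_orbit_disp(t, inducer$radius, inducer$period,
                          inducer$direction, inducer$phase0)
  dt_ - (1 - k) * di
}

# Brute-force common period: smallest integer multiple of the target period
# that is also an integer multiple of the inducer period.
oracle_common_period <- function(period_t, period_i, max_mult = 64) {
  for (m in seq_len(max_mult)) {
    L <- m * period_t
    if (abs(L / period_i - round(L / period_i)) < 1e-9) return(L)
  }
  NA_real_
}

# Rebuild a preset at a coarser sampling rate (n samples over the common
# period) to keep property sweeps fast.
preset_coarse <- function(name, n = 180, ...) {
  s <- make_preset(name, ...)
  stimulus_config(s$target, s$inducer_centers, s$inducer_orbit,
                  duration = s$duration, dt = s$duration / n,
                  provenance = s$provenance)
}

# movie2-like stimulus with an arbitrary inducer starting phase.
phase_variant <- function(phase0, n = 360) {
  s <- make_preset("movie2")
  ind <- orbit_spec(radius = s$inducer_orbit$radius,
                    period = s$inducer_orbit$period,
                    direction = s$inducer_orbit$direction, phase0 = phase0)
  stimulus_config(s$target, s$inducer_centers, ind,
                  duration = s$duration, dt = s$duration / n)
}

# Symmetric Hausdorff distance between two point sets.
hausdorff <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}

# Rigidly transform a trajectory (rotate by `angle` degrees CCW, then
# translate), preserving its sampling metadata.
rigid_transform <- function(traj, angle = 0, shift = c(0, 0)) {
  a <- deg2rad(angle)
  x <- traj$x * cos(a) - traj$y * sin(a) + shift[1]
  y <- traj$x * sin(a) + traj$y * cos(a) + shift[2]
  anc <- trajectory_anchor(traj)
  as_trajectory(tibble::tibble(t = traj$t, x = x, y = y),
                frame = trajectory_frame(traj),
                anchor = c(anc[1] * cos(a) - anc[2] * sin(a) + shift[1],
                           anc[1] * sin(a) + anc[2] * cos(a) + shift[2]))
}

all_conditions <- function() {
  list(fixate = viewing_condition("fixate", fixation_point = c(4, 4)),
       pursue_target = viewing_condition("pursue_target"),
       pursue_inducer = viewing_condition("pursue_inducer"))
}

shoelace_area <- function(traj) {
  x <- traj$x; y <- traj$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}
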