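#' Specify a circular orbit
#'
#' An orbit is a uniform circular motion around a fixed centre. Angles follow
#' the display convention used throughout the package: the orbital phase is
#' measured in degrees clockwise from the top (12 o'clock) of the orbit, in
#' mathematical y-up screen coordinates, so a disc with `phase0 = 0` starts at
#' `center + (0, radius)`. "Clockwise" is the viewer's clockwise.
#'
#' @param center Numeric length-2, orbit centre `(x, y)` in screen units.
#' @param radius Orbit radius, screen units, `> 0`.
#' @param period Orbital period in seconds, `> 0`.
#' @param direction `"CW"` (clockwise) or `"CCW"` (counter-clockwise).
#' @param phase0 Starting phase in degrees clockwise from the top of the
#'   orbit; normalised to `[0, 360)`.
#'
#' @return An object of class `orbit_spec`.
#' @examples
#' orbit_spec(radius = 1, period = 4)
#' @export
orbit_spec <- function(center = c(0, 0), radius = 1, period = 4,
                       direction = c("CW", "CCW"), phase0 = 0) {
  direction <- match.arg(direction)
  if (!is.numeric(center) || length(center) != 2 || anyNA(center)) {
    rlang::abort("`center` must be a numeric (x, y) pair.",
                 class = "duelingorbits_invalid_spec")
  }
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0) {
    rlang::abort("`radius` must be a single positive number.",
                 class = "duelingorbits_invalid_spec")
  }
  if (!is.numeric(period) || length(period) != 1 || !is.finite(period) ||
      period <= 0) {
    rlang::abort("`period` must be a single positive number (seconds).",
                 class = "duelingorbits_invalid_spec")
  }
  if (!is.numeric(phase0) || length(phase0) != 1 || !is.finite(phase0)) {
    rlang::abort("`phase0` must be a single finite angle in degrees.",
                 class = "duelingorbits_invalid_spec")
  }
  structure(
    list(center = as.numeric(center), radius = as.numeric(radius),
         period = as.numeric(period), direction = direction,
         phase0 = phase0 %% 360),
    class = "orbit_spec"
  )
}

#' @export
print.orbit_spec <- function(x, ...) {
  cat(sprintf(
    "<orbit_spec> center (%g, %g), radius %g, period %g s, %s, phase0 %g deg\n",
    x$center[1], x$center[2], x$radius, x$period, x$direction, x$phase0))
  invisible(x)
}

direction_sign <- function(direction) if (direction == "CW") 1 else -1

#' Position on an orbit at given times
#'
#' Evaluates the parametric circle
#' `center + radius * (sin(a), cos(a))` with
#' `a = phase0 + s * 360 * t / period` (degrees), where `s = +1` for
#' clockwise and `-1` for counter-clockwise motion. With `phase0 = 0` and
#' `t = 0` this is the top of the orbit.
#'
#' @param spec An [orbit_spec()].
#' @param t Numeric vector of times in seconds, `>= 0`.
#'
#' @return A tibble with columns `x`, `y`, one row per element of `t`.
#' @examples
#' orbit_position(orbit_spec(radius = 2, period = 4), t = c(0, 1, 2))
#' @export
orbit_position <- function(spec, t) {
  stopifnot(inherits(spec, "orbit_spec"))
  if (any(t < 0)) {
    rlang::abort("`t` must be non-negative.", class = "duelingorbits_invalid_spec")
  }
  a <- (spec$phase0 + direction_sign(spec$direction) * 360 * t / spec$period) *
    pi / 180
  tibble::new_tibble(list(x = spec$center[1] + spec$radius * sin(a),
                          y = spec$center[2] + spec$radius * cos(a)),
                     nrow = length(a))
}

trajectory_frames <- c("world", "retinal", "eye_centered", "relative",
                       "perceived")

#' Construct a trajectory from time-stamped points
#'
#' A trajectory is a tibble with columns `t`, `x`, `y` sampled at uniform
#' time steps, carrying a reference-frame label and a nominal anchor point
#' (the path's centre) as attributes. Most users will obtain trajectories
#' from [sample_trajectory()] or [predict_percept()] rather than build them
#' directly; this constructor is the entry point for externally recorded
#' paths (e.g. percept traces read from CSV).
#'
#' @param data A data frame with numeric columns `t`, `x`, `y`, uniformly
#'   sampled with strictly increasing `t`.
#' @param frame Reference-frame label, one of `"world"`, `"retinal"`,
#'   `"eye_centered"`, `"relative"`, `"perceived"`.
#' @param anchor Numeric length-2 nominal centre of the path.
#'
#' @return A `orbit_trajectory` tibble.
#' @export
as_trajectory <- function(data, frame = "world", anchor = c(0, 0)) {
  frame <- match.arg(frame, trajectory_frames)
  data <- tibble::as_tibble(data)
  if (!all(c("t", "x", "y") %in% names(data))) {
    rlang::abort("`data` must have columns t, x, y.",
                 class = "duelingorbits_invalid_trajectory")
  }
  data <- data[c("t", "x", "y")]
  n <- nrow(data)
  if (n < 2) {
    rlang::abort("A trajectory needs at least two samples.",
                 class = "duelingorbits_invalid_trajectory")
  }
  dt <- diff(data$t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt)) {
    rlang::abort("`t` must be strictly increasing and uniformly spaced.",
                 class = "duelingorbits_invalid_trajectory")
  }
  structure(data,
            class = c("orbit_trajectory", class(tibble::tibble())),
            frame = frame, anchor = as.numeric(anchor), dt = mean(dt))
}

new_trajectory <- function(t, x, y, frame, anchor, dt) {
  structure(tibble::new_tibble(list(t = t, x = x, y = y), nrow = length(t)),
            class = c("orbit_trajectory", "tbl_df", "tbl", "data.frame"),
            frame = frame, anchor = as.numeric(anchor), dt = dt)
}

#' @rdname as_trajectory
#' @param traj A trajectory.
#' @export
trajectory_frame <- function(traj) attr(traj, "frame")

#' @rdname as_trajectory
#' @export
trajectory_anchor <- function(traj) attr(traj, "anchor")

#' @export
print.orbit_trajectory <- function(x, ...) {
  a <- trajectory_anchor(x)
  cat(sprintf("<trajectory> frame %s, %d samples, dt %g s, anchor (%g, %g)\n",
              trajectory_frame(x), nrow(x), attr(x, "dt"), a[1], a[2]))
  NextMethod()
}

# displacement of each sample from the path anchor (n x 2 matrix)
displacements <- function(traj) {
  a <- trajectory_anchor(traj)
  cbind(traj$x - a[1], traj$y - a[2])
}

#' Sample an orbit into a world-frame trajectory
#'
#' Uniform half-open sampling of [orbit_position()] on `[0, duration)`:
#' the sample at `t = duration` is excluded so that closed-curve metrics do
#' not see a duplicated endpoint on periodic configurations.
#'
#' @inheritParams orbit_position
#' @param duration Total sampled time, seconds; must be a (near-)integer
#'   multiple of `dt` and at least `dt`.
#' @param dt Sampling step, seconds, `> 0`.
#'
#' @return A world-frame trajectory ([as_trajectory()]) anchored at the
#'   orbit centre.
#' @examples
#' trj <- sample_trajectory(orbit_spec(radius = 1, period = 4), 4, 4 / 360)
#' nrow(trj)
#' @export
sample_trajectory <- function(spec, duration, dt) {
  stopifnot(inherits(spec, "orbit_spec"))
  n <- check_sampling(duration, dt)
  t <- (seq_len(n) - 1) * dt
  p <- orbit_position(spec, t)
  new_trajectory(t, p$x, p$y, "world", spec$center, dt)
}

check_sampling <- function(duration, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    rlang::abort("`dt` must be a single positive number.",
                 class = "duelingorbits_invalid_spec")
  }
  if (!is.numeric(duration) || length(duration) != 1 || duration < dt) {
    rlang::abort("`duration` must be at least one `dt`.",
                 class = "duelingorbits_invalid_spec")
  }
  n <- duration / dt
  if (abs(n - round(n)) > 1e-6) {
    rlang::abort("`duration` must be an integer multiple of `dt`.",
                 class = "duelingorbits_invalid_spec")
  }
  as.integer(round(n))
}

# best rational approximation p/q of x with q <= max_den (continued fractions)
rational_approx <- function(x, max_den = 64L) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(p = p1, q = q1)
}

#' Common repeat period of two orbits
#'
#' The least duration after which both orbits simultaneously return to their
#' initial positions: for periods in a reduced rational ratio `p/q`
#' (`p, q <= 64`) this is `q` target periods (equivalently `p` inducer
#' periods). Speed ratios such as 1.5x or 0.5x therefore repeat over two
#' target orbits.
#'
#' @param target,inducer [orbit_spec()] objects.
#' @param max_den Largest admissible numerator/denominator of the reduced
#'   period ratio.
#'
#' @return The common period in seconds.
#' @examples
#' common_period(orbit_spec(period = 4), orbit_spec(period = 4 * 2 / 3))
#' @export
common_period <- function(target, inducer, max_den = 64L) {
  stopifnot(inherits(target, "orbit_spec"), inherits(inducer, "orbit_spec"))
  ratio <- target$period / inducer$period
  pq <- rational_approx(ratio, max_den)
  if (pq["q"] == 0 || abs(ratio - pq["p"] / pq["q"]) > 1e-9 * ratio ||
      pq["p"] > max_den) {
    rlang::abort(paste0(
      "Period ratio ", format(ratio), " is not a simple rational number; ",
      "use rational speed ratios (reduced fraction with terms <= ", max_den,
      ") so that a common repeat period exists."),
      class = "duelingorbits_irrational_ratio")
  }
  unname(pq["q"]) * target$period
}

#' Assemble a full dueling-orbits stimulus
#'
#' A stimulus is one orbiting target plus any number of synchronous inducers:
#' all inducers share a single orbit template (radius, period, direction,
#' phase) applied at each inducer centre, so they move in lockstep.
#'
#' @param target [orbit_spec()] for the central target.
#' @param inducer_centers Matrix (or list of length-2 vectors) of inducer
#'   orbit centres; may be empty for a target-only display.
#' @param inducer_orbit [orbit_spec()] template shared by all inducers (its
#'   `center` is ignored; each inducer uses its own centre).
#' @param duration Total stimulus duration, seconds. Defaults to the common
#'   repeat period of target and inducers.
#' @param dt Sampling step, seconds. Defaults to `duration / 720`.
#' @param provenance Optional named list recorded with the configuration
#'   (preset name, inferred-parameter flags, ...).
#'
#' @return An object of class `stimulus_config`.
#' @seealso [make_preset()] for the canonical movie configurations.
#' @export
stimulus_config <- function(target, inducer_centers = NULL,
                            inducer_orbit = NULL, duration = NULL, dt = NULL,
                            provenance = list()) {
  stopifnot(inherits(target, "orbit_spec"))
  if (is.list(inducer_centers) && !is.null(inducer_centers)) {
    inducer_centers <- do.call(rbind, inducer_centers)
  }
  n_ind <- if (is.null(inducer_centers)) 0L else nrow(inducer_centers)
  if (n_ind > 0 && !inherits(inducer_orbit, "orbit_spec")) {
    rlang::abort("`inducer_orbit` template is required when inducers are present.",
                 class = "duelingorbits_invalid_spec")
  }
  if (is.null(duration)) {
    duration <- if (n_ind > 0) common_period(target, inducer_orbit)
                else target$period
  }
  if (is.null(dt)) dt <- duration / 720
  n <- check_sampling(duration, dt)
  per_period <- n * target$period / duration
  if (per_period < 64) {
    rlang::abort("Sampling too coarse: need at least 64 samples per target period.",
                 class = "duelingorbits_invalid_spec")
  }
  structure(
    list(target = target, inducer_centers = inducer_centers,
         inducer_orbit = inducer_orbit, duration = duration, dt = dt,
         provenance = provenance),
    class = "stimulus_config")
}

#' @export
print.stimulus_config <- function(x, ...) {
  cat(sprintf("<stimulus_config> %d inducer(s), duration %g s, dt %g s\n",
              n_inducers(x), x$duration, x$dt))
  if (!is.null(x$provenance$preset)) {
    cat("  preset:", x$provenance$preset, "\n")
  }
  cat("  target: "); print(x$target)
  if (n_inducers(x) > 0) {
    cat("  inducer template: "); print(x$inducer_orbit)
  }
  invisible(x)
}

#' @rdname stimulus_config
#' @param stimulus A `stimulus_config`.
#' @export
n_inducers <- function(stimulus) {
  if (is.null(stimulus$inducer_centers)) 0L else nrow(stimulus$inducer_centers)
}

# orbit_spec of inducer i (template re-centred)
inducer_spec <- function(stimulus, i) {
  if (i < 1 || i > n_inducers(stimulus)) {
    rlang::abort(sprintf("Inducer index %d out of range (1..%d).", i,
                         n_inducers(stimulus)),
                 class = "duelingorbits_invalid_spec")
  }
  tmpl <- stimulus$inducer_orbit
  orbit_spec(center = stimulus$inducer_centers[i, ], radius = tmpl$radius,
             period = tmpl$period, direction = tmpl$direction,
             phase0 = tmpl$phase0)
}

#' World-frame trajectories of the stimulus objects
#'
#' @param stimulus A [stimulus_config()].
#' @param what `"target"` or an inducer index (1-4).
#' @return A world-frame trajectory sampled at the stimulus `dt` over its
#'   duration.
#' @export
stimulus_trajectory <- function(stimulus, what = "target") {
  stopifnot(inherits(stimulus, "stimulus_config"))
  spec <- if (identical(what, "target")) stimulus$target
          else inducer_spec(stimulus, as.integer(what))
  sample_trajectory(spec, stimulus$duration, stimulus$dt)
}

preset_names <- c("movie1", "movie2", "movie3", "movie4", "movie5", "movie6")

preset_params <- function(name, period) {
  # inducer period / direction / phase relative to a clockwise target of
  # period `period` starting at the top of its orbit
  switch(name,
    movie1 = NULL,
    movie2 = list(period = period,     direction = "CCW", phase0 = 0,
                  target_period = period, inferred = character()),
    movie3 = list(period = period,     direction = "CCW", phase0 = 180,
                  target_period = period, inferred = character()),
    movie4 = list(period = period,     direction = "CW",  phase0 = 180,
                  target_period = period, inferred = "inducer_phase0"),
    movie5 = list(period = period * 2 / 3, direction = "CCW", phase0 = 0,
                  target_period = period, inferred = "inducer_direction"),
    movie6 = list(period = period,     direction = "CCW", phase0 = 0,
                  target_period = period * 2, inferred = "inducer_direction"))
}

#' Canonical dueling-orbits stimulus presets
#'
#' Builds the six canonical display configurations. The target always orbits
#' clockwise starting at the top of its orbit; the presets vary only the
#' inducers:
#' \describe{
#'   \item{movie1}{target only, no inducers (veridical baseline).}
#'   \item{movie2}{inducers counter-clockwise, equal speed, phase 0
#'     (horizontally elongated percept).}
#'   \item{movie3}{as movie2 with inducer phase offset 180 degrees
#'     (vertically elongated percept).}
#'   \item{movie4}{inducers clockwise (same direction as target), phase 180
#'     (enlarged circular percept).}
#'   \item{movie5}{as movie2 with inducers at 1.5x the target's speed
#'     (5-point-star percept).}
#'   \item{movie6}{as movie2 with the target at half the inducers' speed
#'     (triangular percept).}
#' }
#' Four inducers sit at the cardinal points (top, right, bottom, left) of a
#' ring around the target centre. Parameters never shown on screen (movie4's
#' inducer phase, movie5/6's inducer direction) are fixed at the unique
#' values that reproduce the published percept shapes and flagged as
#' `inferred` in the configuration provenance.
#'
#' @param name Preset id, `"movie1"` to `"movie6"`.
#' @param target_radius Target orbit radius (screen units).
#' @param ring_radius Radius of the ring of inducer centres; default 3x the
#'   target orbit radius.
#' @param inducer_radius Inducer orbit radius; default equal to the target
#'   orbit radius (equal orbit sizes underlie the closed-form aspect-ratio
#'   results).
#' @param period Target orbital period, seconds (movie6 doubles it).
#' @param dt Sampling step; default common period / 720.
#'
#' @return A [stimulus_config()].
#' @examples
#' make_preset("movie2")
#' @export
make_preset <- function(name, target_radius = 1,
                        ring_radius = 3 * target_radius,
                        inducer_radius = target_radius, period = 4,
                        dt = NULL) {
  name <- match.arg(name, preset_names)
  pp <- preset_params(name, period)
  target <- orbit_spec(center = c(0, 0), radius = target_radius,
                       period = if (is.null(pp)) period else pp$target_period,
                       direction = "CW", phase0 = 0)
  prov <- list(preset = name,
               parameters = list(target_radius = target_radius,
                                 ring_radius = ring_radius,
                                 inducer_radius = inducer_radius,
                                 period = period),
               inferred = if (is.null(pp)) character() else pp$inferred)
  if (is.null(pp)) {
    return(stimulus_config(target, duration = period, dt = dt,
                           provenance = prov))
  }
  centers <- rbind(c(0, ring_radius), c(ring_radius, 0),
                   c(0, -ring_radius), c(-ring_radius, 0))
  inducer <- orbit_spec(center = c(0, 0), radius = inducer_radius,
                        period = pp$period, direction = pp$direction,
                        phase0 = pp$phase0)
  stimulus_config(target, centers, inducer, dt = dt, provenance = prov)
}

#' Summary table of the canonical presets
#'
#' @return A tibble with one row per preset and the orbital parameters of
#'   target and inducers (periods in units of the target period of
#'   movies 1-5).
#' @export
preset_table <- function() {
  purrr::map_dfr(preset_names, function(nm) {
    pp <- preset_params(nm, 1)
    tibble::tibble(
      preset = nm,
      n_inducers = if (is.null(pp)) 0L else 4L,
      target_period = if (is.null(pp)) 1 else pp$target_period,
      target_direction = "CW",
      inducer_period = if (is.null(pp)) NA_real_ else pp$period,
      inducer_direction = if (is.null(pp)) NA_character_ else pp$direction,
      inducer_phase0 = if (is.null(pp)) NA_real_ else pp$phase0,
      inferred = if (is.null(pp) || length(pp$inferred) == 0) ""
                 else paste(pp$inferred, collapse = ","))
  })
}
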