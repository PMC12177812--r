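#' Specify how the stimulus is viewed
#'
#' Three viewing modes are modelled: stable peripheral fixation, smooth
#' pursuit of the central target, and smooth pursuit of one of the inducers.
#' Pursuit is modelled as zero-lag sinusoidal tracking with a scalar gain
#' `g`: the eye orbits the pursued object's centre at `g` times the object's
#' orbital radius, optionally delayed by a latency that clamps at stimulus
#' onset. The efference copy of the eye movement is a scaled copy of the eye
#' displacement from its starting position; `efference_gain = 1` is a
#' veridical copy.
#'
#' @param mode `"fixate"`, `"pursue_target"` or `"pursue_inducer"`.
#' @param fixation_point Gaze position in fixate mode (screen units).
#' @param pursuit_gain Pursuit gain `g` in `[0, 1]`; forced to 0 in fixate
#'   mode.
#' @param pursuit_latency Pursuit latency in seconds, `>= 0` and shorter
#'   than the pursued orbit's period.
#' @param efference_gain Gain of the efference copy, in `[0, 1.5]`.
#' @param inducer_index Which inducer is pursued (1-4), pursue_inducer mode
#'   only.
#'
#' @return An object of class `viewing_condition`.
#' @examples
#' viewing_condition("pursue_target", pursuit_gain = 0.9)
#' @export
viewing_condition <- function(mode = c("fixate", "pursue_target",
                                       "pursue_inducer"),
                              fixation_point = c(0, 0), pursuit_gain = 1,
                              pursuit_latency = 0, efference_gain = 1,
                              inducer_index = 1L) {
  mode <- match.arg(mode)
  if (pursuit_gain < 0 || pursuit_gain > 1) {
    rlang::abort("`pursuit_gain` must be in [0, 1].",
                 class = "duelingorbits_invalid_condition")
  }
  if (efference_gain < 0 || efference_gain > 1.5) {
    rlang::abort("`efference_gain` must be in [0, 1.5].",
                 class = "duelingorbits_invalid_condition")
  }
  if (pursuit_latency < 0) {
    rlang::abort("`pursuit_latency` must be non-negative.",
                 class = "duelingorbits_invalid_condition")
  }
  if (mode == "fixate") pursuit_gain <- 0
  structure(
    list(mode = mode, fixation_point = as.numeric(fixation_point),
         pursuit_gain = pursuit_gain, pursuit_latency = pursuit_latency,
         efference_gain = efference_gain,
         inducer_index = as.integer(inducer_index)),
    class = "viewing_condition")
}

#' @export
print.viewing_condition <- function(x, ...) {
  cat(sprintf(
    "<viewing_condition> %s (gain %g, latency %g s, efference gain %g)\n",
    x$mode, x$pursuit_gain, x$pursuit_latency, x$efference_gain))
  invisible(x)
}

#' Simulate the eye trace for a viewing condition
#'
#' Fixation keeps the eye at the fixation point with zero efference. Pursuit
#' places the eye at
#' `eye(t) = c_obj + g * (pos_obj(max(t - tau, 0)) - c_obj)`
#' where `c_obj` is the pursued object's orbit centre. The efference column
#' is `efference_gain` times the eye's displacement from its own starting
#' position.
#'
#' @param condition A [viewing_condition()].
#' @param stimulus A [stimulus_config()].
#'
#' @return An `eye_trace` tibble with columns `t, eye_x, eye_y, eff_x,
#'   eff_y` on the stimulus time base.
#' @export
eye_trace <- function(condition, stimulus) {
  stopifnot(inherits(condition, "viewing_condition"),
            inherits(stimulus, "stimulus_config"))
  n <- check_sampling(stimulus$duration, stimulus$dt)
  t <- (seq_len(n) - 1) * stimulus$dt
  if (condition$mode == "fixate") {
    eye <- cbind(rep(condition$fixation_point[1], n),
                 rep(condition$fixation_point[2], n))
  } else {
    spec <- if (condition$mode == "pursue_target") stimulus$target
            else inducer_spec(stimulus, condition$inducer_index)
    if (condition$pursuit_latency >= spec$period) {
      rlang::abort("`pursuit_latency` must be shorter than the pursued orbit period.",
                   class = "duelingorbits_invalid_condition")
    }
    p <- orbit_position(spec, pmax(t - condition$pursuit_latency, 0))
    g <- condition$pursuit_gain
    eye <- cbind(spec$center[1] + g * (p$x - spec$center[1]),
                 spec$center[2] + g * (p$y - spec$center[2]))
  }
  eff <- condition$efference_gain * sweep(eye, 2, eye[1, ])
  structure(tibble::new_tibble(
    list(t = t, eye_x = eye[, 1], eye_y = eye[, 2],
         eff_x = eff[, 1], eff_y = eff[, 2]), nrow = length(t)),
    class = c("eye_trace", "tbl_df", "tbl", "data.frame"),
    dt = stimulus$dt)
}

check_time_base <- function(a_t, b_t) {
  if (length(a_t) != length(b_t) || max(abs(a_t - b_t)) > 1e-9) {
    rlang::abort("Mismatched time bases.",
                 class = "duelingorbits_time_base_mismatch")
  }
}

#' Reference-frame transforms of a trajectory
#'
#' `retinal_path()` expresses a world trajectory in eye coordinates
#' (world position minus eye position). `eye_centered_path()` reconstructs
#' the eye-centered (geocentric) trajectory by adding the efference copy of
#' the eye movement back onto the retinal path; with a veridical efference
#' copy this equals the world path up to a constant translation.
#' `relative_path()` is the object-relative motion cue: the difference
#' between the eye-centered displacement of the target and of the
#' (synchronous) inducers, re-anchored at the target's path centre.
#'
#' @param world,retinal,target_ec,inducer_ec Trajectories
#'   ([as_trajectory()]).
#' @param eyes An [eye_trace()] on the same time base.
#'
#' @return A trajectory in the corresponding frame.
#' @export
retinal_path <- function(world, eyes) {
  check_time_base(world$t, eyes$t)
  a <- trajectory_anchor(world)
  new_trajectory(world$t, world$x - eyes$eye_x, world$y - eyes$eye_y,
                 "retinal", c(a[1] - eyes$eye_x[1], a[2] - eyes$eye_y[1]),
                 attr(world, "dt"))
}

#' @rdname retinal_path
#' @export
eye_centered_path <- function(retinal, eyes) {
  check_time_base(retinal$t, eyes$t)
  new_trajectory(retinal$t, retinal$x + eyes$eff_x, retinal$y + eyes$eff_y,
                 "eye_centered", trajectory_anchor(retinal),
                 attr(retinal, "dt"))
}

#' @rdname retinal_path
#' @export
relative_path <- function(target_ec, inducer_ec) {
  check_time_base(target_ec$t, inducer_ec$t)
  a <- trajectory_anchor(target_ec)
  d <- displacements(target_ec) - displacements(inducer_ec)
  new_trajectory(target_ec$t, a[1] + d[, 1], a[2] + d[, 2], "relative", a,
                 attr(target_ec, "dt"))
}

#' All model reference frames for a stimulus under a viewing condition
#'
#' Runs the full reference-frame pipeline: world trajectories of target and
#' inducers, the eye trace, retinal and eye-centered paths, and the relative
#' path. Because the inducers move synchronously the relative path is the
#' same whichever inducer it is computed against; this is asserted (to
#' `1e-9` of the target orbit radius) and the first inducer's path is
#' returned.
#'
#' @param stimulus A [stimulus_config()].
#' @param condition A [viewing_condition()].
#'
#' @return A named list: `world_target`, `eyes`, `retinal_target`,
#'   `ec_target`, `ec_inducer`, `relative` (the last two `NULL` for
#'   inducer-free stimuli).
#' @export
percept_frames <- function(stimulus, condition = viewing_condition("fixate")) {
  eyes <- eye_trace(condition, stimulus)
  world_t <- stimulus_trajectory(stimulus, "target")
  ret_t <- retinal_path(world_t, eyes)
  ec_t <- eye_centered_path(ret_t, eyes)
  ec_i <- NULL; rel <- NULL
  if (n_inducers(stimulus) > 0) {
    rels <- lapply(seq_len(n_inducers(stimulus)), function(i) {
      wi <- stimulus_trajectory(stimulus, i)
      relative_path(ec_t, eye_centered_path(retinal_path(wi, eyes), eyes))
    })
    tol <- 1e-9 * stimulus$target$radius
    same <- vapply(rels[-1], function(r) {
      max(abs(r$x - rels[[1]]$x), abs(r$y - rels[[1]]$y)) <= tol
    }, logical(1))
    if (!all(same)) {
      rlang::abort("Relative path differs across inducers; inducers are not synchronous.",
                   class = "duelingorbits_asynchronous_inducers")
    }
    wi1 <- stimulus_trajectory(stimulus, 1)
    ec_i <- eye_centered_path(retinal_path(wi1, eyes), eyes)
    rel <- rels[[1]]
  }
  list(world_target = world_t, eyes = eyes, retinal_target = ret_t,
       ec_target = ec_t, ec_inducer = ec_i, relative = rel)
}
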