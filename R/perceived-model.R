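#' Cue weight from cue reliabilities
#'
#' Standard reliability (inverse-variance) weighting of two motion cues: the
#' weight on the eye-centered path is its precision divided by the summed
#' precisions, `k = precision_ec / (precision_ec + precision_rel)`. Equal
#' reliabilities give `k = 0.5`; as the relative cue becomes unreliable
#' `k` tends to 1 and perception follows the eye-centered (veridical) orbit.
#'
#' @param precision_ec,precision_rel Positive precisions (inverse variances)
#'   of the eye-centered and relative motion cues.
#' @return The cue weight `k` in `(0, 1)`.
#' @examples
#' k_from_reliabilities(3, 1)
#' @export
k_from_reliabilities <- function(precision_ec, precision_rel) {
  if (any(precision_ec <= 0) || any(precision_rel <= 0)) {
    rlang::abort("Precisions must be positive.",
                 class = "duelingorbits_invalid_weight")
  }
  precision_ec / (precision_ec + precision_rel)
}

#' Default cue weight for a viewing condition
#'
#' Gaze biases the weighting: pursuing the target makes the eye-centered cue
#' more reliable (`0.5 < k < 1`), pursuing an inducer favours the relative
#' cue (`0 < k < 0.5`), and stable peripheral fixation weighs the two cues
#' about equally. The defaults are the midpoints of those intervals and can
#' be overridden per mode.
#'
#' @param condition A [viewing_condition()].
#' @param fixate,pursue_target,pursue_inducer Per-mode default weights.
#' @return A cue weight `k` in `[0, 1]`.
#' @examples
#' default_k(viewing_condition("pursue_inducer"))
#' @export
default_k <- function(condition, fixate = 0.5, pursue_target = 0.75,
                      pursue_inducer = 0.25) {
  stopifnot(inherits(condition, "viewing_condition"))
  switch(condition$mode, fixate = fixate, pursue_target = pursue_target,
         pursue_inducer = pursue_inducer)
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0 || k > 1) {
    rlang::abort("`k` must be a single number in [0, 1].",
                 class = "duelingorbits_invalid_weight")
  }
  k
}

#' Predicted perceived trajectory from its two component cues
#'
#' The perceived path is the pointwise weighted average
#' `k * EyeCentered + (1 - k) * Relative` of the displacement of the two
#' cue trajectories from their common anchor, re-anchored at that anchor.
#' `k = 1` reproduces the eye-centered path, `k = 0` the relative path.
#'
#' @param ec Eye-centered target trajectory.
#' @param rel Relative-motion trajectory anchored at the same point; may be
#'   `NULL` (no inducers), in which case the eye-centered path is returned
#'   unchanged apart from its frame label.
#' @param k Cue weight in `[0, 1]`.
#'
#' @return A perceived-frame trajectory.
#' @export
perceived_path <- function(ec, rel, k) {
  check_k(k)
  if (is.null(rel)) {
    return(new_trajectory(ec$t, ec$x, ec$y, "perceived",
                          trajectory_anchor(ec), attr(ec, "dt")))
  }
  check_time_base(ec$t, rel$t)
  a_ec <- trajectory_anchor(ec); a_rel <- trajectory_anchor(rel)
  if (max(abs(a_ec - a_rel)) > 1e-9) {
    rlang::abort("`ec` and `rel` must share an anchor (the target path centre).",
                 class = "duelingorbits_invalid_trajectory")
  }
  d <- k * displacements(ec) + (1 - k) * displacements(rel)
  new_trajectory(ec$t, a_ec[1] + d[, 1], a_ec[2] + d[, 2], "perceived",
                 a_ec, attr(ec, "dt"))
}

#' Predict the perceived target trajectory for a stimulus
#'
#' End-to-end model run: simulates the eye trace for the viewing condition,
#' derives the eye-centered and relative paths ([percept_frames()]), and
#' combines them with weight `k` (defaulting to the condition-specific
#' weight of [default_k()]). The result is re-anchored at the target's
#' world-orbit centre, so for a target-only stimulus with veridical
#' self-motion signals it coincides with the target's world path.
#'
#' @inheritParams percept_frames
#' @param k Cue weight in `[0, 1]`; `NULL` uses [default_k()].
#'
#' @return A perceived-frame trajectory anchored at the target centre.
#' @examples
#' percept <- predict_percept(make_preset("movie2"))
#' shape_metrics(percept)
#' @export
predict_percept <- function(stimulus, condition = viewing_condition("fixate"),
                            k = NULL) {
  if (is.null(k)) k <- default_k(condition)
  check_k(k)
  fr <- percept_frames(stimulus, condition)
  p <- perceived_path(fr$ec_target, fr$relative, k)
  d <- displacements(p)
  ctr <- stimulus$target$center
  new_trajectory(p$t, ctr[1] + d[, 1], ctr[2] + d[, 2], "perceived", ctr,
                 attr(p, "dt"))
}
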