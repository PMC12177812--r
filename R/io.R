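config_to_list <- function(stimulus) {
  tg <- stimulus$target
  out <- list(
    target = list(center = as.list(tg$center), radius = tg$radius,
                  period_s = tg$period, direction = tg$direction,
                  phase0_deg = tg$phase0),
    duration_s = stimulus$duration, dt_s = stimulus$dt)
  if (n_inducers(stimulus) > 0) {
    io <- stimulus$inducer_orbit
    out$inducers <- list(
      centers = apply(stimulus$inducer_centers, 1, as.list, simplify = FALSE),
      orbit = list(radius = io$radius, period_s = io$period,
                   direction = io$direction, phase0_deg = io$phase0))
  }
  if (length(stimulus$provenance) > 0) out$provenance <- stimulus$provenance
  out
}

config_from_list <- function(x) {
  tg <- x$target
  target <- orbit_spec(center = unlist(tg$center), radius = tg$radius,
                       period = tg$period_s, direction = tg$direction,
                       phase0 = tg$phase0_deg)
  centers <- NULL; inducer <- NULL
  if (!is.null(x$inducers)) {
    io <- x$inducers$orbit
    inducer <- orbit_spec(radius = io$radius, period = io$period_s,
                          direction = io$direction, phase0 = io$phase0_deg)
    if (!is.null(x$inducers$centers)) {
      centers <- do.call(rbind, lapply(x$inducers$centers, unlist))
    } else if (!is.null(x$inducers$ring_radius)) {
      R <- x$inducers$ring_radius
      ctr <- unlist(tg$center)
      centers <- cbind(ctr[1] + c(0, R, 0, -R), ctr[2] + c(R, 0, -R, 0))
    } else {
      rlang::abort("Inducer block needs either `centers` or `ring_radius`.",
                   class = "duelingorbits_invalid_config")
    }
  }
  prov <- x$provenance
  if (is.null(prov)) prov <- list()
  stimulus_config(target, centers, inducer, duration = x$duration_s,
                  dt = x$dt_s, provenance = prov)
}

config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml"
  else if (ext == "json") "json"
  else rlang::abort("Config files must end in .json, .yaml or .yml.",
                    class = "duelingorbits_invalid_config")
}

#' Read and write stimulus configuration files
#'
#' Configurations are stored as JSON or YAML (chosen by file extension)
#' with the schema
#' `target{center, radius, period_s, direction, phase0_deg}`,
#' `inducers{centers | ring_radius, orbit{radius, period_s, direction,
#' phase0_deg}}`, `duration_s`, `dt_s`, plus an optional free-form
#' `provenance` block. Writing then reading a configuration reproduces the
#' same stimulus (and hence bit-identical trajectories at a fixed `dt`).
#'
#' @param stimulus A [stimulus_config()].
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_stimulus_config()` returns a [stimulus_config()];
#'   `write_stimulus_config()` returns `path` invisibly.
#' @export
write_stimulus_config <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "stimulus_config"))
  x <- config_to_list(stimulus)
  if (config_format(path) == "yaml") {
    yaml::write_yaml(x, path, precision = 22L)  # doubles must round-trip
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)  # doubles must round-trip
  }
  invisible(path)
}

#' @rdname write_stimulus_config
#' @export
read_stimulus_config <- function(path) {
  x <- if (config_format(path) == "yaml") yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = FALSE)
  config_from_list(x)
}

#' Read and write trajectory CSV files
#'
#' Trajectories travel as a plain CSV with header `t,x,y` plus a JSON
#' sidecar (`<path>.json`) carrying the frame label, anchor, `dt` and any
#' provenance, so a written trajectory reads back with its metadata intact.
#'
#' @param traj A trajectory ([as_trajectory()]).
#' @param path CSV file path; the sidecar is written next to it.
#' @param provenance Optional named list stored in the sidecar.
#' @return `read_trajectory()` returns a trajectory;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path, provenance = list()) {
  readr::write_csv(tibble::tibble(t = traj$t, x = traj$x, y = traj$y), path)
  side <- list(frame = trajectory_frame(traj),
               anchor = as.numeric(trajectory_anchor(traj)),
               dt = attr(traj, "dt"))
  if (length(provenance) > 0) side$provenance <- provenance
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    t = readr::col_double(), x = readr::col_double(),
    y = readr::col_double()))
  sidecar <- paste0(path, ".json")
  frame <- "world"; anchor <- c(0, 0)
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    frame <- side$frame %||% "world"
    anchor <- side$anchor %||% c(0, 0)
  }
  as_trajectory(data, frame = frame, anchor = anchor)
}
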