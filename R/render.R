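#' Rasterisation settings for schematic stimulus movies
#'
#' The renderer draws the stimulus as plain luminance discs on a uniform
#' background, frame by frame, in pixel coordinates. World y-up coordinates
#' are flipped to raster y-down at render time only; all analysis stays
#' y-up. The canvas must be large enough to contain the inducer ring plus
#' the inducer orbit and disc radius at the chosen scale.
#'
#' @param width,height Canvas size in pixels.
#' @param scale Pixels per screen unit.
#' @param fps Frames per second of the rendered movie.
#' @param background Background luminance in `[0, 1]`.
#' @param target_radius_px,inducer_radius_px Disc radii in pixels (inducers
#'   are drawn larger than the target by default).
#' @param target_luminance,inducer_luminance Disc luminances in `[0, 1]`.
#' @param overlay_veridical,overlay_predicted Draw the veridical target
#'   orbit / model-predicted percept as thin curves under the discs.
#'
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(width = 480, height = 480, scale = 50, fps = 30,
                        background = 0.5, target_radius_px = 10,
                        inducer_radius_px = 25, target_luminance = 1,
                        inducer_luminance = 0, overlay_veridical = FALSE,
                        overlay_predicted = FALSE) {
  stopifnot(width >= 16, height >= 16, scale > 0, fps > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 scale = scale, fps = fps, background = background,
                 target_radius_px = target_radius_px,
                 inducer_radius_px = inducer_radius_px,
                 target_luminance = target_luminance,
                 inducer_luminance = inducer_luminance,
                 overlay_veridical = overlay_veridical,
                 overlay_predicted = overlay_predicted),
            class = "render_spec")
}

# world (y-up, origin at stimulus centre) -> raster (col, row), 1-based
world_to_pixel <- function(xy, spec, origin) {
  cbind(spec$width / 2 + spec$scale * (xy[, 1] - origin[1]),
        spec$height / 2 - spec$scale * (xy[, 2] - origin[2]))
}

required_canvas_px <- function(stimulus, spec) {
  extent <- stimulus$target$radius
  if (n_inducers(stimulus) > 0) {
    ring <- max(sqrt(rowSums(sweep(stimulus$inducer_centers, 2,
                                   stimulus$target$center)^2)))
    extent <- max(extent, ring + stimulus$inducer_orbit$radius)
  }
  2 * ceiling(spec$scale * extent + max(spec$target_radius_px,
                                        spec$inducer_radius_px) + 1)
}

draw_disc <- function(img, cx, cy, radius, lum) {
  h <- nrow(img); w <- ncol(img)
  rows <- max(1, floor(cy - radius)):min(h, ceiling(cy + radius))
  cols <- max(1, floor(cx - radius)):min(w, ceiling(cx + radius))
  if (length(rows) == 0 || length(cols) == 0) return(img)
  dd <- outer((rows - cy)^2, (cols - cx)^2, "+")
  img[rows, cols][dd <= radius^2] <- lum
  img
}

draw_curve <- function(img, pix, lum) {
  h <- nrow(img); w <- ncol(img)
  cc <- round(pix[, 1]); rr <- round(pix[, 2])
  keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  img[cbind(rr[keep], cc[keep])] <- lum
  img
}

#' Render a stimulus (and optional percept overlay) to raster frames
#'
#' Produces one grayscale matrix per frame (values in `[0, 1]`, row 1 at the
#' top of the screen), drawing the inducer and target discs at their world
#' positions for each frame time; frame count is `duration * fps`. Output is
#' a pure function of its inputs, so repeated renders are identical.
#'
#' @param stimulus A [stimulus_config()].
#' @param spec A [render_spec()].
#' @param condition Viewing condition used for the predicted-percept
#'   overlay.
#' @param k Cue weight for the overlay; `NULL` uses [default_k()].
#'
#' @return A list of `height x width` numeric matrices.
#' @export
render_frames <- function(stimulus, spec = render_spec(),
                          condition = viewing_condition("fixate"), k = NULL) {
  stopifnot(inherits(stimulus, "stimulus_config"),
            inherits(spec, "render_spec"))
  need <- required_canvas_px(stimulus, spec)
  if (min(spec$width, spec$height) < need) {
    rlang::abort(sprintf(
      "Canvas %dx%d too small for this stimulus at scale %g: need at least %dx%d px.",
      spec$width, spec$height, spec$scale, need, need),
      class = "duelingorbits_canvas_too_small")
  }
  origin <- stimulus$target$center
  n_frames <- max(1L, as.integer(round(stimulus$duration * spec$fps)))
  times <- (seq_len(n_frames) - 1) / spec$fps
  base <- matrix(spec$background, spec$height, spec$width)
  if (spec$overlay_veridical) {
    trj <- stimulus_trajectory(stimulus, "target")
    base <- draw_curve(base, world_to_pixel(cbind(trj$x, trj$y), spec, origin),
                       0.25)
  }
  if (spec$overlay_predicted) {
    p <- predict_percept(stimulus, condition, k)
    base <- draw_curve(base, world_to_pixel(cbind(p$x, p$y), spec, origin),
                       0.75)
  }
  ind_specs <- lapply(seq_len(n_inducers(stimulus)),
                      function(i) inducer_spec(stimulus, i))
  lapply(times, function(tt) {
    img <- base
    for (s in ind_specs) {
      p <- orbit_position(s, tt)
      pix <- world_to_pixel(cbind(p$x, p$y), spec, origin)
      img <- draw_disc(img, pix[1, 1], pix[1, 2], spec$inducer_radius_px,
                       spec$inducer_luminance)
    }
    p <- orbit_position(stimulus$target, tt)
    pix <- world_to_pixel(cbind(p$x, p$y), spec, origin)
    draw_disc(img, pix[1, 1], pix[1, 2], spec$target_radius_px,
              spec$target_luminance)
  })
}

#' Write rendered frames as a PNG sequence
#'
#' @param frames A list of grayscale matrices from [render_frames()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix; frames are `prefix_0001.png`, ...
#' @return The written file paths, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%04d.png", prefix, seq_along(frames)))
  for (i in seq_along(frames)) png::writePNG(frames[[i]], paths[i])
  invisible(paths)
}
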