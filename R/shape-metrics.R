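#' Shape analytics for closed percept paths
#'
#' These metrics quantify the qualitative shape vocabulary of orbiting
#' percepts -- ellipse vs star vs triangle, loops at the corners, convex or
#' concave sides -- on a closed path sampled uniformly over one repeat
#' period (half-open, i.e. without a duplicated endpoint).
#'
#' `lobe_count()` counts radial lobes: strict cyclic local maxima of the
#' distance from the path centroid whose prominence (height above the higher
#' of the two neighbouring radial minima) reaches `prominence` times the
#' mean radius. A circle has 0 lobes, an ellipse 2, a triangular path 3.
#'
#' @param path A trajectory sampled over one repeat period.
#' @param prominence Minimum lobe prominence as a fraction of the mean
#'   radius; lobes shallower than this are treated as numerical ripple.
#' @return `lobe_count()`: a non-negative integer.
#' @examples
#' lobe_count(predict_percept(make_preset("movie5")))
#' @export
lobe_count <- function(path, prominence = 0.01) {
  r <- centroid_radii(path)
  length(radial_peaks(r, prominence * mean(r)))
}

centroid_radii <- function(path) {
  cx <- mean(path$x); cy <- mean(path$y)
  sqrt((path$x - cx)^2 + (path$y - cy)^2)
}

# indices of cyclic strict local maxima of r with prominence >= min_prom;
# prominence is measured against the higher of the two adjacent cyclic minima
# (against the global minimum when there is a single maximum).
radial_peaks <- function(r, min_prom) {
  n <- length(r)
  prv <- r[c(n, seq_len(n - 1))]
  nxt <- r[c(seq.int(2, n), 1)]
  peaks <- which(r > prv & r > nxt)
  if (length(peaks) == 0) return(integer())
  if (length(peaks) == 1) {
    return(if (r[peaks] - min(r) >= min_prom) peaks else integer())
  }
  # minimum of r on the cyclic arc between consecutive peaks
  k <- length(peaks)
  seg_min <- vapply(seq_len(k), function(i) {
    from <- peaks[i]; to <- peaks[if (i == k) 1 else i + 1]
    idx <- if (from < to) seq.int(from, to) else c(seq.int(from, n), seq_len(to))
    min(r[idx])
  }, numeric(1))
  prom <- vapply(seq_len(k), function(i) {
    left <- seg_min[if (i == 1) k else i - 1]
    r[peaks[i]] - max(left, seg_min[i])
  }, numeric(1))
  peaks[prom >= min_prom]
}

#' @rdname lobe_count
#' @details `path_aspect_ratio()` fits the principal axes of the second
#'   central moments of the sample points: the aspect ratio is
#'   `sqrt(lambda_major / lambda_minor)` and the orientation is the angle of
#'   the major eigenvector, degrees counter-clockwise from horizontal in
#'   `[0, 180)`. For a path traversed uniformly in time as
#'   `(A sin wt, B cos wt)` this returns exactly `A/B`. A circle reports
#'   orientation 0 by convention; a collinear path reports an infinite
#'   aspect ratio with the orientation of the line.
#' @return `path_aspect_ratio()`: a list with `aspect_ratio` and
#'   `major_axis_deg`.
#' @export
path_aspect_ratio <- function(path) {
  xy <- cbind(path$x - mean(path$x), path$y - mean(path$y))
  if (nrow(xy) < 3 || max(abs(xy)) == 0) {
    rlang::abort("Aspect ratio is undefined for a degenerate (pointlike) path.",
                 class = "duelingorbits_degenerate_path")
  }
  ev <- eigen(crossprod(xy) / nrow(xy), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  v <- ev$vectors[, 1]
  ang <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  if (lam[2] <= 1e-12 * lam[1]) {
    return(list(aspect_ratio = Inf, major_axis_deg = ang))
  }
  ar <- sqrt(lam[1] / lam[2])
  if (ar - 1 < 1e-9) ang <- 0
  list(aspect_ratio = ar, major_axis_deg = ang)
}

#' @rdname lobe_count
#' @details `self_intersections()` counts transversal crossings between
#'   non-adjacent segments of the closed sampled polyline; crossings of
#'   distinct segment pairs that fall on the same geometric point are
#'   deduplicated (within `1e-9` of the mean radius). A simple closed curve
#'   has 0; each corner loop contributes 1.
#' @return `self_intersections()`: a non-negative integer.
#' @export
self_intersections <- function(path) {
  n <- nrow(path)
  px <- path$x; py <- path$y
  qx <- px[c(seq.int(2, n), 1)]; qy <- py[c(seq.int(2, n), 1)]
  pts_x <- numeric(); pts_y <- numeric()
  # pairwise segment tests, chunked over the first index to bound memory
  chunk <- max(1L, floor(2e6 / n))
  for (start in seq.int(1, n - 2, by = chunk)) {
    is <- seq.int(start, min(start + chunk - 1L, n - 2L))
    grid_i <- rep(is, times = pmax(n - is - 1L, 0L))
    grid_j <- unlist(lapply(is, function(i) seq.int(i + 2L, n)), use.names = FALSE)
    keep <- !(grid_i == 1L & grid_j == n)  # closing segment adjacency
    grid_i <- grid_i[keep]; grid_j <- grid_j[keep]
    if (length(grid_i) == 0) next
    x1 <- px[grid_i]; y1 <- py[grid_i]; x2 <- qx[grid_i]; y2 <- qy[grid_i]
    x3 <- px[grid_j]; y3 <- py[grid_j]; x4 <- qx[grid_j]; y4 <- qy[grid_j]
    d1x <- x2 - x1; d1y <- y2 - y1; d2x <- x4 - x3; d2y <- y4 - y3
    denom <- d1x * d2y - d1y * d2x
    sgx <- x3 - x1; sgy <- y3 - y1
    tt <- (sgx * d2y - sgy * d2x) / denom
    uu <- (sgx * d1y - sgy * d1x) / denom
    hit <- is.finite(tt) & is.finite(uu) & tt > 0 & tt < 1 & uu > 0 & uu < 1
    if (any(hit)) {
      pts_x <- c(pts_x, x1[hit] + tt[hit] * d1x[hit])
      pts_y <- c(pts_y, y1[hit] + tt[hit] * d1y[hit])
    }
  }
  if (length(pts_x) == 0) return(0L)
  tol <- 1e-9 * mean(centroid_radii(path))
  key <- paste(round(pts_x / tol), round(pts_y / tol))
  length(unique(key))
}

#' @rdname lobe_count
#' @details `side_class()` splits the path at its lobe maxima into sides
#'   and measures, for each side, the signed perpendicular deviation of the
#'   side's midpoint from the chord joining its endpoints -- positive when
#'   the side bulges away from the centroid. Sides within `straight_tol`
#'   of the chord (as a fraction of mean radius) are `"straight"`; sides
#'   that disagree aggregate to `"mixed"`. Requires at least 3 lobes.
#' @param straight_tol Deviations below this fraction of the mean radius
#'   classify a side as straight.
#' @return `side_class()`: one of `"convex"`, `"straight"`, `"concave"`,
#'   `"mixed"`.
#' @export
side_class <- function(path, prominence = 0.01, straight_tol = 0.005) {
  r <- centroid_radii(path)
  peaks <- radial_peaks(r, prominence * mean(r))
  k <- length(peaks)
  if (k < 3) {
    rlang::abort("Side classification needs at least 3 lobes.",
                 class = "duelingorbits_too_few_lobes")
  }
  n <- nrow(path)
  cx <- mean(path$x); cy <- mean(path$y)
  classes <- character(k)
  for (i in seq_len(k)) {
    from <- peaks[i]; to <- peaks[if (i == k) 1 else i + 1]
    len <- (to - from) %% n
    mid <- ((from - 1 + len %/% 2) %% n) + 1
    p1 <- c(path$x[from], path$y[from]); p2 <- c(path$x[to], path$y[to])
    m <- c(path$x[mid], path$y[mid])
    u <- p2 - p1
    nrm <- c(-u[2], u[1]) / sqrt(sum(u^2))
    if (sum(nrm * ((p1 + p2) / 2 - c(cx, cy))) < 0) nrm <- -nrm  # away from centroid
    dev <- sum((m - p1) * nrm) / mean(r)
    classes[i] <- if (abs(dev) < straight_tol) "straight"
                  else if (dev > 0) "convex" else "concave"
  }
  if (length(unique(classes)) == 1) classes[1] else "mixed"
}

#' Summarise the shape of a closed path
#'
#' One-row tibble of all shape metrics: lobe count, second-moment aspect
#' ratio and major-axis orientation, self-intersection count, side
#' classification (`NA` when the path has fewer than 3 lobes), and mean
#' centroid distance.
#'
#' @inheritParams lobe_count
#' @inheritParams side_class
#' @return A one-row tibble with columns `lobe_count`, `aspect_ratio`,
#'   `major_axis_deg`, `n_self_intersections`, `side_class`, `mean_radius`.
#' @examples
#' shape_metrics(predict_percept(make_preset("movie3")))
#' @export
shape_metrics <- function(path, prominence = 0.01, straight_tol = 0.005) {
  lobes <- lobe_count(path, prominence)
  ar <- path_aspect_ratio(path)
  sides <- if (lobes >= 3) side_class(path, prominence, straight_tol)
           else NA_character_
  tibble::tibble(
    lobe_count = lobes,
    aspect_ratio = ar$aspect_ratio,
    major_axis_deg = ar$major_axis_deg,
    n_self_intersections = self_intersections(path),
    side_class = sides,
    mean_radius = mean(centroid_radii(path)))
}
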