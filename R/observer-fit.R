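#' Cue weight from a reported ellipse aspect ratio
#'
#' For the equal-speed, opposite-direction configurations the model's
#' perceived path is an ellipse with semi-axes `(2 - k) r` and `k r`, so its
#' aspect ratio is `(2 - k) / k` and the cue weight can be read directly off
#' a reported aspect ratio: `k = 2 / (ar + 1)`. An aspect ratio of 1
#' (veridical circle) gives `k = 1`; strongly elongated percepts such as
#' 7.5:1 give `k` near 0.24.
#'
#' @param ar Observed major/minor aspect ratio, `>= 1`.
#' @param preset The configuration the ratio was observed under; must be an
#'   equal-speed opposite-direction preset (`"movie2"` or `"movie3"`).
#' @return The implied cue weight `k` in `(0, 1]`.
#' @examples
#' k_from_aspect_ratio(3)
#' @export
k_from_aspect_ratio <- function(ar, preset = c("movie2", "movie3")) {
  preset <- match.arg(preset)
  if (any(!is.finite(ar)) || any(ar < 1)) {
    rlang::abort("`ar` must be a finite aspect ratio >= 1.",
                 class = "duelingorbits_invalid_aspect_ratio")
  }
  2 / (ar + 1)
}

#' Simulate a synthetic observer's percept trace
#'
#' Generates the trace a synthetic observer with known cue weight would
#' report: the model-predicted perceived path for `true_k` plus independent
#' zero-mean Gaussian position noise (`noise_sd` per coordinate per sample).
#' Reproducible for a fixed seed; the generating parameters are recorded as
#' attributes for parameter-recovery studies.
#'
#' @inheritParams predict_percept
#' @param true_k Cue weight used to generate the trace.
#' @param noise_sd Positional noise standard deviation, screen units,
#'   `>= 0`.
#' @param seed Integer seed for the noise.
#'
#' @return A tibble with columns `t, x, y` (class `observer_trace`), with
#'   attributes `condition`, `preset`, `true_k`, `noise_sd`, `seed`.
#' @examples
#' simulate_observer(make_preset("movie2"), true_k = 0.5,
#'                   noise_sd = 0.05, seed = 1)
#' @export
simulate_observer <- function(stimulus, condition = viewing_condition("fixate"),
                              true_k = default_k(condition), noise_sd = 0,
                              seed = 1L) {
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    rlang::abort("`noise_sd` must be non-negative.",
                 class = "duelingorbits_invalid_spec")
  }
  p <- predict_percept(stimulus, condition, true_k)
  n <- nrow(p)
  noise <- withr::with_seed(seed, stats::rnorm(2 * n, sd = noise_sd))
  out <- tibble::tibble(t = p$t, x = p$x + noise[seq_len(n)],
                        y = p$y + noise[n + seq_len(n)])
  structure(out, class = c("observer_trace", class(out)),
            condition = condition$mode,
            preset = stimulus$provenance$preset, true_k = true_k,
            noise_sd = noise_sd, seed = seed, dt = attr(p, "dt"))
}

# quadratic-in-k residual terms: obj(k) = mean(|a + k b|^2) where
# a = rel_disp - centred trace, b = ec_disp - rel_disp
fit_terms <- function(trace, stimulus, condition) {
  fr <- percept_frames(stimulus, condition)
  ec <- fr$ec_target
  rel <- if (is.null(fr$relative)) ec else fr$relative
  check_time_base(trace$t, ec$t)
  tr <- cbind(trace$x - mean(trace$x), trace$y - mean(trace$y))
  list(a = displacements(rel) - tr, b = displacements(ec) - displacements(rel))
}

fit_objective <- function(terms) {
  function(k) mean((terms$a[, 1] + k * terms$b[, 1])^2 +
                   (terms$a[, 2] + k * terms$b[, 2])^2)
}

golden_section <- function(f, lo, hi, tol = 1e-5) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- f(x2)
    }
  }
  (lo + hi) / 2
}

fit_k_indices <- function(terms, idx = NULL, grid_step = 0.001, tol = 1e-5) {
  t2 <- if (is.null(idx)) terms
        else list(a = terms$a[idx, , drop = FALSE],
                  b = terms$b[idx, , drop = FALSE])
  obj <- fit_objective(t2)
  grid <- seq(0, 1, by = grid_step)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  k <- golden_section(obj, lo, hi, tol)
  k <- min(max(k, 0), 1)
  list(k = k, mse = obj(k), grid = grid, grid_mse = vals)
}

#' Recover the cue weight k from an observed percept trace
#'
#' Fits the single free parameter of the perceived-path model to a
#' time-locked percept trace: after removing the trace centroid (and the
#' model path's anchor), the mean squared pointwise distance between trace
#' and model prediction is minimised over `k` by a grid search (step
#' `grid_step`) refined by golden-section search to tolerance `tol`.
#' Optionally, a nonparametric bootstrap over time points gives a percentile
#' confidence interval for `k`.
#'
#' @param trace A data frame with columns `t, x, y` on the stimulus time
#'   base (e.g. from [simulate_observer()] or read from CSV).
#' @inheritParams predict_percept
#' @param grid_step Grid resolution of the initial search over `[0, 1]`.
#' @param tol Golden-section refinement tolerance.
#' @param n_boot Number of bootstrap replicates (0 = no interval; otherwise
#'   at least 100).
#' @param conf Confidence level of the percentile interval.
#' @param seed Integer seed for the bootstrap resampling.
#'
#' @return An object of class `orbit_fit` with elements `k_hat`, `rss`,
#'   `mse`, `n`, `n_boot`, `k_ci`, and the grid objective; see
#'   [tidy.orbit_fit()] and [glance.orbit_fit()].
#' @examples
#' stim <- make_preset("movie2")
#' trace <- simulate_observer(stim, true_k = 0.4, noise_sd = 0.05, seed = 2)
#' fit_k(trace, stim)
#' @export
fit_k <- function(trace, stimulus, condition = viewing_condition("fixate"),
                  grid_step = 0.001, tol = 1e-5, n_boot = 0, conf = 0.95,
                  seed = 1L) {
  terms <- fit_terms(trace, stimulus, condition)
  best <- fit_k_indices(terms, NULL, grid_step, tol)
  n <- nrow(terms$a)
  k_ci <- NULL; boot_k <- NULL
  if (n_boot > 0) {
    if (n_boot < 100) {
      rlang::abort("`n_boot` must be at least 100 (or 0 for no interval).",
                   class = "duelingorbits_invalid_spec")
    }
    boot_k <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
      fit_k_indices(terms, sample.int(n, n, replace = TRUE),
                    grid_step, tol)$k
    }, numeric(1)))
    alpha <- (1 - conf) / 2
    k_ci <- unname(stats::quantile(boot_k, c(alpha, 1 - alpha), type = 7))
  }
  structure(
    list(k_hat = best$k, rss = best$mse * n, mse = best$mse, n = n,
         n_boot = n_boot, k_ci = k_ci, conf = conf, boot_k = boot_k,
         k_grid = best$grid, grid_mse = best$grid_mse,
         condition = condition$mode,
         preset = stimulus$provenance$preset %||% NA_character_),
    class = "orbit_fit")
}

#' @rdname fit_k
#' @details `bootstrap_ci()` is a convenience wrapper for `fit_k()` with a
#'   mandatory bootstrap interval.
#' @export
bootstrap_ci <- function(trace, stimulus,
                         condition = viewing_condition("fixate"),
                         n_boot = 200, conf = 0.95, seed = 1L, ...) {
  fit_k(trace, stimulus, condition, n_boot = n_boot, conf = conf,
        seed = seed, ...)
}

#' @export
print.orbit_fit <- function(x, ...) {
  cat(sprintf("<orbit_fit> k_hat = %.4f (mse %.3g over %d samples)\n",
              x$k_hat, x$mse, x$n))
  if (!is.null(x$k_ci)) {
    cat(sprintf("  %g%% bootstrap CI [%.4f, %.4f] (%d replicates)\n",
                100 * x$conf, x$k_ci[1], x$k_ci[2], x$n_boot))
  }
  invisible(x)
}

#' Tidy and summarise cue-weight fits
#'
#' Broom-style accessors: `tidy()` returns one row per fitted parameter
#' (just `k` here) with its estimate and, when bootstrapped, percentile
#' confidence bounds; `glance()` returns a one-row model summary.
#'
#' @param x An `orbit_fit` from [fit_k()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.orbit_fit <- function(x, ...) {
  tibble::tibble(term = "k", estimate = x$k_hat,
                 conf.low = if (is.null(x$k_ci)) NA_real_ else x$k_ci[1],
                 conf.high = if (is.null(x$k_ci)) NA_real_ else x$k_ci[2])
}

#' @rdname tidy.orbit_fit
#' @export
glance.orbit_fit <- function(x, ...) {
  tibble::tibble(k_hat = x$k_hat, rss = x$rss, mse = x$mse, n = x$n,
                 n_boot = x$n_boot, condition = x$condition,
                 preset = x$preset)
}
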