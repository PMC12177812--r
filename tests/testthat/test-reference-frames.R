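test_that("eye traces implement fixation and gain-scaled pursuit", {
  stim <- preset_coarse("movie2")
  r <- stim$target$radius

  fix <- eye_trace(viewing_condition("fixate", fixation_point = c(3, 1)), stim)
  expect_equal(unique(fix$eye_x), 3)
  expect_equal(unique(fix$eye_y), 1)
  expect_true(all(fix$eff_x == 0) && all(fix$eff_y == 0))

  # perfect pursuit reproduces the pursued object's world trajectory
  perfect <- eye_trace(viewing_condition("pursue_target"), stim)
  w <- stimulus_trajectory(stim, "target")
  expect_equal(perfect$eye_x, w$x, tolerance = 1e-12)
  expect_equal(perfect$eye_y, w$y, tolerance = 1e-12)

  # gain 0.5 halves the eye's orbital radius about the pursued centre
  half <- eye_trace(viewing_condition("pursue_target", pursuit_gain = 0.5),
                    stim)
  er <- sqrt((half$eye_x - stim$target$center[1])^2 +
             (half$eye_y - stim$target$center[2])^2)
  expect_equal(er, rep(0.5 * r, nrow(half)), tolerance = 1e-12)
  # and matches direct evaluation of the pursuit formula pointwise
  d <- oracle_orbit_disp(half$t, r, stim$target$period, "CW", 0)
  expect_equal(half$eye_x, stim$target$center[1] + 0.5 * d[, 1],
               tolerance = 1e-12)
  expect_equal(half$eye_y, stim$target$center[2] + 0.5 * d[, 2],
               tolerance = 1e-12)

  # latency delays the eye by a fixed lag, clamping at stimulus onset
  lat <- eye_trace(viewing_condition("pursue_target",
                                     pursuit_latency = 10 * stim$dt), stim)
  expect_equal(lat$eye_x[1], w$x[1])
  expect_equal(lat$eye_x[5], w$x[1])       # still clamped before the lag
  expect_equal(lat$eye_x[31], w$x[21], tolerance = 1e-12)

  expect_error(eye_trace(viewing_condition("pursue_inducer",
                                           inducer_index = 9), stim),
               class = "duelingorbits_invalid_spec")
  expect_error(viewing_condition("fixate", pursuit_gain = 2),
               class = "duelingorbits_invalid_condition")
  expect_error(viewing_condition("fixate", efference_gain = 1.6),
               class = "duelingorbits_invalid_condition")
})

test_that("retinal and eye-centered paths obey the frame arithmetic", {
  stim <- preset_coarse("movie2")
  w <- stimulus_trajectory(stim, "target")

  # fixation translates the world path by minus the fixation point
  fix <- eye_trace(viewing_condition("fixate", fixation_point = c(3, 1)), stim)
  ret <- retinal_path(w, fix)
  expect_equal(ret$x, w$x - 3)
  expect_equal(ret$y, w$y - 1)
  expect_equal(trajectory_anchor(ret), stim$target$center - c(3, 1))
  # zero efference: eye-centered equals retinal
  expect_equal(eye_centered_path(ret, fix)$x, ret$x)

  # perfect pursuit of the target stabilises its retinal image to a point
  pur <- eye_trace(viewing_condition("pursue_target"), stim)
  ret_p <- retinal_path(w, pur)
  expect_lt(max(abs(ret_p$x - ret_p$x[1])), 1e-12)
  expect_lt(max(abs(ret_p$y - ret_p$y[1])), 1e-12)

  # imperfect efference copy shrinks the recovered orbit: gain 0.8 -> 0.8 r
  pur08 <- eye_trace(viewing_condition("pursue_target", efference_gain = 0.8),
                     stim)
  ec08 <- eye_centered_path(retinal_path(w, pur08), pur08)
  cx <- mean(ec08$x); cy <- mean(ec08$y)
  radii <- sqrt((ec08$x - cx)^2 + (ec08$y - cy)^2)
  expect_equal(radii, rep(0.8 * stim$target$radius, nrow(ec08)),
               tolerance = 1e-9)

  # pursuing an inducer with unit gain: the retinal target path is the
  # world-frame difference target - inducer, up to a constant translation
  puri <- eye_trace(viewing_condition("pursue_inducer", inducer_index = 1),
                    stim)
  ret_i <- retinal_path(w, puri)
  wi <- stimulus_trajectory(stim, 1)
  dx <- (w$x - wi$x) - ret_i$x
  dy <- (w$y - wi$y) - ret_i$y
  expect_lt(diff(range(dx)), 1e-12)
  expect_lt(diff(range(dy)), 1e-12)

  # mismatched time bases are refused
  short <- sample_trajectory(stim$target, stim$duration / 2, stim$dt)
  expect_error(retinal_path(short, fix),
               class = "duelingorbits_time_base_mismatch")
})

test_that("frame closure: eye-centered equals world up to translation at unit efference", {
  for (nm in c("movie1", "movie2", "movie3", "movie4", "movie5", "movie6")) {
    stim <- preset_coarse(nm)
    w <- stimulus_trajectory(stim, "target")
    conds <- all_conditions()
    if (n_inducers(stim) == 0) conds$pursue_inducer <- NULL
    for (cond in conds) {
      eyes <- eye_trace(cond, stim)
      # retinal + eye = world, pointwise
      ret <- retinal_path(w, eyes)
      expect_equal(ret$x + eyes$eye_x, w$x, tolerance = 1e-12)
      expect_equal(ret$y + eyes$eye_y, w$y, tolerance = 1e-12)
      # eye-centered = world up to a constant offset
      ec <- eye_centered_path(ret, eyes)
      expect_lt(diff(range(ec$x - w$x)), 1e-9 * stim$target$radius)
      expect_lt(diff(range(ec$y - w$y)), 1e-9 * stim$target$radius)
    }
  }
})

test_that("relative motion cancels common motion and is inducer-invariant", {
  # an inducer orbiting exactly like the target produces zero relative path
  tgt <- orbit_spec(radius = 1, period = 4)
  same <- orbit_spec(radius = 1, period = 4)
  stim <- stimulus_config(tgt, rbind(c(0, 3), c(3, 0)), same)
  fr <- percept_frames(stim, viewing_condition("fixate"))
  expect_lt(max(abs(displacements(fr$relative))), 1e-12)

  # the four synchronous inducers all yield the same relative path
  stim2 <- preset_coarse("movie5")
  eyes <- eye_trace(viewing_condition("fixate"), stim2)
  ec_t <- eye_centered_path(retinal_path(stimulus_trajectory(stim2, "target"),
                                         eyes), eyes)
  rels <- lapply(1:4, function(i) {
    ec_i <- eye_centered_path(retinal_path(stimulus_trajectory(stim2, i),
                                           eyes), eyes)
    relative_path(ec_t, ec_i)
  })
  for (i in 2:4) {
    # equality to machine rounding: the four inducers sit at different
    # centres, so the displacement arithmetic differs in the last ulp
    expect_lt(max(abs(rels[[i]]$x - rels[[1]]$x)), 1e-12)
    expect_lt(max(abs(rels[[i]]$y - rels[[1]]$y)), 1e-12)
  }
})

test_that("equal-speed opposite-direction relative paths are straight segments at half the phase angle", {
  r <- 1
  for (phase in c(0, 30, 90, 150, 180, 240, 330)) {
    stim <- phase_variant(phase, n = 180)
    fr <- percept_frames(stim, viewing_condition("fixate"))
    d <- displacements(fr$relative)
    # principal-axis fit: residual variance along the minor axis ~ 0
    ev <- eigen(crossprod(d) / nrow(d), symmetric = TRUE)
    expect_lt(sqrt(max(ev$values[2], 0)), 1e-9 * r)
    # half-length 2r
    expect_equal(max(sqrt(rowSums(d^2))), 2 * r, tolerance = 1e-3)
    # oriented phase/2 from horizontal, measured clockwise (the same sense
    # as the orbital phase convention)
    ang <- (atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi) %% 180
    expect_equal(ang, (-phase / 2) %% 180, tolerance = 1e-6)
  }
})
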