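make_closed <- function(x, y, frame = "perceived") {
  n <- length(x)
  as_trajectory(tibble::tibble(t = seq_len(n) - 1, x = x, y = y),
                frame = frame, anchor = c(mean(x), mean(y)))
}

circle_path <- function(n = 360, r = 1, ctr = c(0, 0)) {
  a <- 2 * pi * (seq_len(n) - 1) / n
  make_closed(ctr[1] + r * cos(a), ctr[2] + r * sin(a))
}

ellipse_path <- function(A, B, n = 360, rot = 0) {
  a <- 2 * pi * (seq_len(n) - 1) / n
  x <- A * sin(a); y <- B * cos(a)
  th <- rot * pi / 180
  make_closed(x * cos(th) - y * sin(th), x * sin(th) + y * cos(th))
}

test_that("lobe counting distinguishes circle, ellipse, star and triangle", {
  expect_equal(lobe_count(circle_path()), 0L)
  expect_equal(lobe_count(ellipse_path(3, 1)), 2L)
  expect_equal(lobe_count(predict_percept(make_preset("movie5"))), 5L)
  expect_equal(lobe_count(predict_percept(make_preset("movie6"))), 3L)
})

test_that("second-moment aspect ratio is exact for uniform-in-time ellipses", {
  c0 <- path_aspect_ratio(circle_path())
  expect_equal(c0$aspect_ratio, 1, tolerance = 1e-9)
  expect_equal(c0$major_axis_deg, 0)  # convention for round shapes

  for (ab in list(c(3, 1), c(2.5, 2), c(7.5, 1))) {
    e <- path_aspect_ratio(ellipse_path(ab[1], ab[2]))
    expect_equal(e$aspect_ratio, ab[1] / ab[2], tolerance = 1e-9)
    expect_equal(e$major_axis_deg, 0, tolerance = 1e-6)
  }
  rot <- path_aspect_ratio(ellipse_path(3, 1, rot = 37))
  expect_equal(rot$major_axis_deg, 37, tolerance = 1e-6)

  # collinear limit: a segment has infinite aspect ratio and a defined line
  a <- seq(0, 2 * pi, length.out = 129)[-129]
  seg <- make_closed(sin(a) * cos(pi / 6), sin(a) * sin(pi / 6))
  s <- path_aspect_ratio(seg)
  expect_identical(s$aspect_ratio, Inf)
  expect_equal(s$major_axis_deg, 30, tolerance = 1e-6)

  expect_error(path_aspect_ratio(make_closed(rep(1, 8), rep(2, 8))),
               class = "duelingorbits_degenerate_path")
})

test_that("closed form: movie2/movie3 aspect ratio equals (2 - k) / k", {
  for (nm in c("movie2", "movie3")) {
    stim <- make_preset(nm)
    for (k in seq(0.1, 1, by = 0.1)) {
      ar <- path_aspect_ratio(predict_percept(stim, k = k))$aspect_ratio
      expect_equal(ar, (2 - k) / k, tolerance = 1e-6)
    }
  }
})

test_that("self-intersection counting finds transversal polyline crossings", {
  expect_equal(self_intersections(circle_path()), 0L)
  expect_equal(self_intersections(ellipse_path(3, 1)), 0L)

  # figure-eight: one transversal crossing (sampling offset so the crossing
  # falls inside segments, not on a vertex)
  a <- 2 * pi * (seq_len(256) - 0.5) / 256
  eight <- make_closed(sin(2 * a), sin(a))
  expect_equal(self_intersections(eight), 1L)

  # inducer pursuit of the half-speed-target stimulus: a loop per corner
  expect_equal(self_intersections(predict_percept(make_preset("movie6"),
                                                  k = 0.25)), 3L)
})

test_that("corner loops appear exactly below the equal-speed weight k = 0.5", {
  stim <- make_preset("movie6")
  for (k in c(0.2, 0.35, 0.49)) {
    expect_equal(self_intersections(predict_percept(stim, k = k)), 3L)
  }
  for (k in c(0.5, 0.6, 0.9)) {
    expect_equal(self_intersections(predict_percept(stim, k = k)), 0L)
  }
})

test_that("side classification separates straight, convex and concave sides", {
  # equilateral triangle sampled edge by edge: straight sides
  verts <- rbind(c(cos(pi / 2), sin(pi / 2)),
                 c(cos(7 * pi / 6), sin(7 * pi / 6)),
                 c(cos(11 * pi / 6), sin(11 * pi / 6)))
  edge <- function(p, q) {
    s <- seq(0, 1, length.out = 61)[-61]
    cbind(p[1] + s * (q[1] - p[1]), p[2] + s * (q[2] - p[2]))
  }
  tri <- rbind(edge(verts[1, ], verts[2, ]), edge(verts[2, ], verts[3, ]),
               edge(verts[3, ], verts[1, ]))
  tri_path <- make_closed(tri[, 1], tri[, 2])
  expect_equal(lobe_count(tri_path), 3L)
  expect_equal(side_class(tri_path), "straight")

  # rounded triangle when the target is pursued; concave petals when an
  # inducer is pursued
  stim <- make_preset("movie6")
  expect_equal(side_class(predict_percept(stim, k = 0.75)), "convex")
  expect_equal(side_class(predict_percept(stim, k = 0.25)), "concave")

  expect_error(side_class(circle_path()),
               class = "duelingorbits_too_few_lobes")
})

test_that("metrics are invariant under rigid transforms", {
  paths <- list(predict_percept(make_preset("movie5")),
                predict_percept(make_preset("movie6"), k = 0.25),
                predict_percept(make_preset("movie2")))
  for (p in paths) {
    m0 <- shape_metrics(p)
    for (tr in list(c(25, 1.5, -2), c(118, -4, 0.5))) {
      p2 <- rigid_transform(p, tr[1], tr[2:3])
      m1 <- shape_metrics(p2)
      expect_equal(m1$lobe_count, m0$lobe_count)
      expect_equal(m1$n_self_intersections, m0$n_self_intersections)
      expect_equal(m1$aspect_ratio, m0$aspect_ratio, tolerance = 1e-9)
      expect_equal(m1$side_class, m0$side_class)
      if (is.finite(m0$aspect_ratio) && m0$aspect_ratio > 1 + 1e-9) {
        expect_equal(m1$major_axis_deg,
                     (m0$major_axis_deg + tr[1]) %% 180, tolerance = 1e-6)
      }
    }
  }
})

test_that("metrics are stable under 4x oversampling", {
  cases <- list(list("movie2", 0.5), list("movie3", 0.5), list("movie4", 0.5),
                list("movie5", 0.5), list("movie6", 0.5), list("movie6", 0.25))
  for (cs in cases) {
    s720 <- make_preset(cs[[1]])
    s2880 <- make_preset(cs[[1]], dt = s720$duration / 2880)
    m1 <- shape_metrics(predict_percept(s720, k = cs[[2]]))
    m2 <- shape_metrics(predict_percept(s2880, k = cs[[2]]))
    expect_equal(m1$lobe_count, m2$lobe_count)
    expect_equal(m1$n_self_intersections, m2$n_self_intersections)
    expect_equal(m1$side_class, m2$side_class)
    expect_equal(m1$aspect_ratio, m2$aspect_ratio, tolerance = 1e-6)
  }
})
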