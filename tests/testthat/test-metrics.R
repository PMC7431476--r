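test_that("absolute angular error wraps and is bounded", {
  expect_equal(absolute_angular_error(10, 350), 20)
  expect_equal(absolute_angular_error(90, 90), 0)
  # both wrap directions enumerated: |270-80| = 190 -> 360-190 = 170
  expect_equal(absolute_angular_error(270, 80), 170)
  set.seed(13)
  a <- runif(50, 0, 360)
  b <- runif(50, 0, 360)
  cc <- runif(50, -720, 720)
  err <- absolute_angular_error(a, b)
  expect_true(all(err >= 0 & err <= 180))
  expect_equal(err, absolute_angular_error(b, a))
  expect_equal(err, absolute_angular_error(a + cc, b + cc), tolerance = 1e-9)
})

direction_truth <- function(route) {
  lm <- route_landmarks(route)
  pairs <- utils::combn(lm, 2)
  data.frame(from_label = pairs[1, ], to_label = pairs[2, ])
}

test_that("direction scoring converts facing-relative estimates", {
  r <- make_test_route()
  est <- direction_truth(r)
  a <- r$anchors
  # exact responses: relative bearing = true bearing - facing
  est$relative_bearing <- vapply(seq_len(nrow(est)), function(i) {
    from <- a[a$label == est$from_label[i], ]
    to <- a[a$label == est$to_label[i], ]
    normalize_bearing(bearing_between(c(from$x, from$y), c(to$x, to$y)) -
                        from$facing)
  }, numeric(1))
  expect_equal(score_directions(r, est), 0)
  # a constant clockwise offset propagates to the mean error
  est30 <- est
  est30$relative_bearing <- normalize_bearing(est$relative_bearing + 30)
  expect_equal(score_directions(r, est30), 30)
  # randomised responses match a per-pair hand computation
  set.seed(8)
  noisy <- est
  noisy$relative_bearing <- runif(6, 0, 360)
  oracle <- mean(vapply(seq_len(nrow(noisy)), function(i) {
    from <- a[a$label == noisy$from_label[i], ]
    to <- a[a$label == noisy$to_label[i], ]
    correct <- bearing_between(c(from$x, from$y), c(to$x, to$y))
    d <- abs(((from$facing + noisy$relative_bearing[i] - correct) %% 360))
    min(d, 360 - d)
  }, numeric(1)))
  expect_equal(score_directions(r, noisy), oracle)
  expect_error(score_directions(r, est[-1, ]), "missing direction")
})

test_that("distance scoring gives correlations and mean ratios per kind", {
  r <- make_test_route()
  est <- direction_truth(r)
  correct_straight <- vapply(seq_len(nrow(est)), function(i) {
    straight_distance(r, est$from_label[i], est$to_label[i])
  }, numeric(1))
  correct_route <- vapply(seq_len(nrow(est)), function(i) {
    route_distance(r, est$from_label[i], est$to_label[i])
  }, numeric(1))
  exact <- rbind(
    data.frame(est, kind = "route", ratio_to_standard = correct_route / 32),
    data.frame(est, kind = "straight_line",
               ratio_to_standard = correct_straight / 32))
  sc <- score_distances(r, exact, standard_m = 32)
  expect_equal(sc$correlation, c(1, 1))
  expect_equal(sc$mean_ratio, c(1, 1))

  half <- exact
  half$ratio_to_standard <- half$ratio_to_standard / 2
  sc2 <- score_distances(r, half, standard_m = 32)
  expect_equal(sc2$correlation, c(1, 1)) # r is blind to uniform rescaling
  expect_equal(sc2$mean_ratio, c(0.5, 0.5))

  set.seed(4)
  noisy <- exact
  noisy$ratio_to_standard <- noisy$ratio_to_standard * runif(12, 0.6, 1.4)
  sc3 <- score_distances(r, noisy, standard_m = 32)
  straight_rows <- noisy$kind == "straight_line"
  expect_equal(sc3$correlation[sc3$kind == "straight_line"],
               cor(noisy$ratio_to_standard[straight_rows] * 32,
                   correct_straight))
  # correlation invariant to the standard length; ratio scales with it
  sc4 <- score_distances(r, noisy, standard_m = 64)
  expect_equal(sc4$correlation, sc3$correlation)
  expect_equal(sc4$mean_ratio, 2 * sc3$mean_ratio)
})

test_that("pathway completion scores distance, direction and north errors", {
  # E due south of S
  p <- training_path("triangle", rbind(c(0, 0), c(5, -3), c(0, -6)),
                     north_bearing = 0)
  exact <- score_pathway(p, stop_point = c(0, 0), pointed_north = 0)
  expect_equal(unname(exact), c(0, 0, 0))
  # stop 1 m due east of S: 100 cm; hand trigonometry for the angle
  sc <- score_pathway(p, stop_point = c(1, 0), pointed_north = 10)
  expect_equal(unname(sc["distance_deviation_cm"]), 100)
  expect_equal(unname(sc["direction_deviation_deg"]),
               atan2(1, 6) * 180 / pi)
  expect_equal(unname(sc["north_error_deg"]), 10)
  # start_vector variant measures stop -> S against E -> S
  sv <- score_pathway(p, stop_point = c(1, 0), pointed_north = 0,
                      direction_method = "start_vector")
  expect_equal(unname(sv["direction_deviation_deg"]), 90)
  expect_error(score_pathway(p, stop_point = c(0, -6), pointed_north = 0),
               "degenerate return")
})

test_that("noisy agents produce pathway deviations at human magnitudes", {
  spec <- cohort_spec(n_per_condition = 12, seed = 19,
                      conditions = "training")
  exp <- generate_experiment(spec, tasks = "pathway")
  tr <- score_training(exp$responses, exp$paths)
  m1 <- colMeans(tr[tr$trial == 1, c("distance_deviation_cm",
                                     "direction_deviation_deg")])
  # reported human ranges: roughly 100-170 cm and 15-24 degrees
  expect_gt(m1["distance_deviation_cm"], 80)
  expect_lt(m1["distance_deviation_cm"], 200)
  expect_gt(m1["direction_deviation_deg"], 10)
  expect_lt(m1["direction_deviation_deg"], 26)
})

test_that("scores are invariant under rigid motion of the route frame", {
  r <- make_test_route()
  est <- direction_truth(r)
  set.seed(2)
  est$relative_bearing <- runif(6, 0, 360)
  # rotate + translate the whole frame (vertices, anchors, facings)
  th <- 73 * pi / 180
  rot <- function(m) cbind(cos(th) * m[, 1] + sin(th) * m[, 2] + 11,
                           -sin(th) * m[, 1] + cos(th) * m[, 2] - 7)
  a2 <- r$anchors
  xy <- rot(cbind(a2$x, a2$y))
  a2 <- data.frame(label = a2$label, x = xy[, 1], y = xy[, 2],
                   facing = normalize_bearing(a2$facing + 73))
  r2 <- route_map(rot(r$vertices), a2, n_turns = 5)
  expect_equal(score_directions(r2, est), score_directions(r, est),
               tolerance = 1e-9)
})
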