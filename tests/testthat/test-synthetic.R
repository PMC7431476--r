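test_that("generated routes honour length, turn and landmark constraints", {
  for (seed in c(1, 2, 3, 101)) {
    r <- generate_route(seed = seed)
    expect_equal(polyline_length(r$vertices), 450, tolerance = 0.1)
    expect_equal(nrow(r$vertices) - 2L, 5L)        # five interior turns
    expect_equal(length(route_landmarks(r)), 4L)
    expect_equal(nrow(r$anchors), 11L)             # start, goal, 4 L, 5 T
    expect_equal(route_distance(r, "start", "goal"), r$length_m)
  }
  r1 <- generate_route(seed = 1)
  r2 <- generate_route(seed = 2)
  expect_false(identical(r1$vertices, r2$vertices))
  expect_identical(generate_route(seed = 1)$vertices, r1$vertices)
})

test_that("training-path set has 6 of each shape with valid geometry", {
  paths <- generate_training_paths(seed = 3)
  shapes <- vapply(paths, function(p) p$shape, character(1))
  expect_equal(unname(table(shapes)[c("triangle", "quadrilateral", "crossing")]),
               c(6L, 6L, 6L), ignore_attr = TRUE)
  # triangles walk exactly two segments before the return
  for (p in paths[shapes == "triangle"]) {
    expect_equal(nrow(p$vertices) - 1L, 2L)
  }
  # the training_path constructor has already verified the crossing
  # property; re-check one explicitly with the segment-intersection test
  cr <- paths[[which(shapes == "crossing")[1]]]
  n <- nrow(cr$vertices)
  hits <- vapply(seq_len(n - 2L), function(i) {
    cogmapr:::segments_intersect(cr$vertices[n, ], cr$vertices[1, ],
                                 cr$vertices[i, ], cr$vertices[i + 1, ])
  }, logical(1))
  expect_true(any(hits))
})

test_that("wrapped-normal absolute-error mapping matches Monte Carlo", {
  set.seed(77)
  for (s in c(12, 48, 90)) {
    draws <- abs(cogmapr:::rwrapped(2e5, s))
    mom <- wrapped_abs_error_moments(s)
    expect_equal(mom$mean_abs, mean(draws), tolerance = 0.01)
    expect_equal(mom$sd_abs, sd(draws), tolerance = 0.01)
  }
  # inversion round trip in the reporting unit
  for (target in c(5, 27.06, 52.32, 80)) {
    s <- direction_sd_for_mean_abs(target)
    expect_equal(wrapped_abs_error_moments(s)$mean_abs, target,
                 tolerance = 1e-3)
  }
  expect_error(direction_sd_for_mean_abs(92), "89")
})

test_that("a zero-noise cohort scores perfectly on every task", {
  spec <- cohort_spec_zero_noise(n_per_condition = 3, seed = 5)
  exp <- generate_experiment(spec)
  sc <- score_experiment(exp$responses, exp$routes, paths = exp$paths,
                         standard_m = spec$standard_m)
  expect_equal(max(sc$mean_abs_direction_error), 0, tolerance = 1e-9)
  expect_equal(unique(round(sc$mean_route_ratio, 9)), 1)
  expect_equal(unique(round(sc$mean_straight_ratio, 9)), 1)
  expect_equal(min(sc$route_distance_correlation), 1, tolerance = 1e-9)
  expect_equal(min(sc$sketch_bidim_r), 1, tolerance = 1e-9)
  tr <- score_training(exp$responses, exp$paths)
  expect_equal(max(tr$distance_deviation_cm), 0, tolerance = 1e-6)
  expect_equal(max(tr$north_error_deg), 0, tolerance = 1e-9)
})

test_that("scored direction errors hit the specified magnitude", {
  # with no between-subject spread, the cohort mean absolute error should
  # sit close to the requested level (52.32 degrees across sessions)
  spec <- cohort_spec(n_per_condition = 20, seed = 8,
                      conditions = "feedback_only",
                      direction_mean = list(feedback_only = rep(52.32, 6)),
                      direction_subject_sd = c(feedback_only = 0))
  exp <- generate_experiment(spec, tasks = "direction")
  sc <- score_experiment(exp$responses, exp$routes)
  expect_equal(mean(sc$mean_abs_direction_error), 52.32, tolerance = 3)
  # scoring inverts generation: observed mean absolute error over many
  # draws recovers the generating level within 10%
  per_subject <- tapply(sc$mean_abs_direction_error, sc$participant_id, mean)
  expect_lt(abs(mean(per_subject) - 52.32) / 52.32, 0.10)
})

test_that("sketch jitter monotonically degrades bidimensional correlation", {
  mean_r <- function(sd_m, seed) {
    spec <- cohort_spec(n_per_condition = 6, seed = seed,
                        conditions = "feedback_only",
                        sketch_sd_m = rep(sd_m, 6),
                        sketch_subject_sdlog = 0)
    exp <- generate_experiment(spec, tasks = "sketch")
    sc <- score_experiment(exp$responses, exp$routes)
    mean(sc$sketch_bidim_r)
  }
  for (seed in 1:3) {
    rs <- vapply(c(2, 15, 40), mean_r, numeric(1), seed = seed)
    expect_true(all(diff(rs) < 0))
  }
})

test_that("identical seeds reproduce the experiment byte for byte", {
  spec <- cohort_spec(n_per_condition = 3, seed = 42)
  e1 <- generate_experiment(spec)
  e2 <- generate_experiment(spec)
  expect_identical(e1$responses, e2$responses)
  expect_identical(e1$routes[[1]]$vertices, e2$routes[[1]]$vertices)
  e3 <- generate_experiment(cohort_spec(n_per_condition = 3, seed = 43))
  expect_false(identical(e1$responses$value, e3$responses$value))
})

test_that("the average group is observed in session 1 only", {
  spec <- cohort_spec(n_per_condition = 3, seed = 9)
  exp <- generate_experiment(spec, tasks = "direction")
  avg <- exp$responses[exp$responses$condition == "average", ]
  expect_equal(unique(avg$session), 1L)
  poor <- exp$responses[exp$responses$condition != "average", ]
  expect_equal(sort(unique(poor$session)), 1:6)
})

test_that("planting a condition effect shifts only the training mean", {
  spec <- plant_condition_effect(cohort_spec(seed = 1), d = 0.8)
  delta <- attr(spec, "planted_delta")
  expect_gt(delta, 0)
  expect_equal(spec$direction_mean$feedback_only - spec$direction_mean$training,
               rep(delta, 6))
  expect_equal(spec$direction_subject_sd[["training"]],
               spec$direction_subject_sd[["feedback_only"]])
})
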