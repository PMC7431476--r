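test_that("identity fit gives r = 1 with identity parameters", {
  ref <- make_square_config()
  f <- fit_similarity(ref, ref)
  expect_equal(f$r, 1)
  expect_equal(f$scale, 1)
  expect_equal(f$rotation, 0)
  expect_equal(f$translation, c(0, 0))
  expect_equal(f$sse, 0)
  expect_equal(bidim_r(ref, ref), 1)
})

test_that("an exact similarity transform is recovered with r = 1", {
  ref <- make_square_config()
  drawn <- transform_config(ref, scale = 2.5, rotation = 37,
                            translation = c(10, -4))
  f <- fit_similarity(ref, drawn)
  # the fit maps drawn back onto the reference: inverse parameters
  expect_equal(f$r, 1, tolerance = 1e-9)
  expect_equal(f$sse, 0, tolerance = 1e-9)
  expect_equal(f$scale, 1 / 2.5, tolerance = 1e-9)
  expect_equal(f$rotation, -37, tolerance = 1e-9)
  # r^2 = 1 - sse/sst identity on a noisy instance
  set.seed(5)
  noisy <- point_config(drawn$label, drawn$x + rnorm(4, sd = 0.3),
                        drawn$y + rnorm(4, sd = 0.3))
  g <- fit_similarity(ref, noisy)
  expect_equal(g$r^2, 1 - g$sse / g$sst)
})

test_that("closed form matches grid-search and optimiser oracles", {
  ref <- make_square_config()
  set.seed(11)
  drawn <- point_config(ref$label, ref$x + c(0, 0, 0.25, 0), ref$y)
  f <- fit_similarity(ref, drawn)
  expect_equal(f$sse, oracle_similarity_grid(ref, drawn), tolerance = 1e-4)

  for (i in 1:20) {
    n <- sample(4:12, 1)
    r0 <- random_config(n)
    d0 <- transform_config(r0, scale = runif(1, 0.5, 2),
                           rotation = runif(1, 0, 360),
                           translation = rnorm(2, sd = 5))
    d0 <- point_config(d0$label, d0$x + rnorm(n, sd = 1),
                       d0$y + rnorm(n, sd = 1))
    f <- fit_similarity(r0, d0)
    o <- oracle_similarity_sse(r0, d0)
    expect_lte(f$sse, o * (1 + 1e-6) + 1e-12)
    expect_equal(f$sse, o, tolerance = 1e-6)
  }
})

test_that("reflected configurations fit worse unless reflection is allowed", {
  set.seed(3)
  ref <- random_config(6)
  mirrored <- transform_config(ref, reflect = TRUE, rotation = 20,
                               scale = 1.3)
  f_no <- fit_similarity(ref, mirrored)
  f_yes <- fit_similarity(ref, mirrored, allow_reflection = TRUE)
  expect_lt(f_no$r, 1)
  expect_equal(f_yes$r, 1, tolerance = 1e-9)
  expect_true(f_yes$reflected)
  # reflection-allowed fit never does worse
  expect_lte(f_yes$sse, f_no$sse)
})

test_that("independent random configurations give r well below 1", {
  set.seed(21)
  rs <- replicate(300, bidim_r(random_config(10), random_config(10)))
  expect_lt(mean(rs), 0.8)
  expect_true(all(rs >= 0 & rs <= 1))
})

test_that("r is symmetric and similarity invariant", {
  set.seed(9)
  for (i in 1:10) {
    a <- random_config(8)
    b <- random_config(8)
    expect_equal(bidim_r(a, b), bidim_r(b, a), tolerance = 1e-9)
    b2 <- transform_config(b, scale = runif(1, 0.2, 5),
                           rotation = runif(1, 0, 360),
                           translation = rnorm(2, sd = 20))
    a2 <- transform_config(a, scale = runif(1, 0.2, 5),
                           rotation = runif(1, 0, 360))
    expect_equal(bidim_r(a, b2), bidim_r(a, b), tolerance = 1e-9)
    expect_equal(bidim_r(a2, b), bidim_r(a, b), tolerance = 1e-9)
  }
})

test_that("degenerate and incomplete configurations are rejected", {
  ref <- make_square_config()
  expect_error(fit_similarity(ref, point_config(c("a", "b"), 0:1, 0:1)),
               "share labels")
  coincident <- point_config(ref$label, rep(1, 4), rep(2, 4))
  expect_error(fit_similarity(coincident, ref), "reference points")
  expect_error(fit_similarity(ref, coincident), "drawn points")
  # pairwise deletion of missing anchors
  drawn <- ref
  drawn$x[2] <- NA
  expect_warning(f <- fit_similarity(ref, drawn), "missing")
  expect_equal(f$n, 3)
  expect_equal(f$r, 1, tolerance = 1e-9)
  drawn$x[3] <- NA
  expect_error(suppressWarnings(fit_similarity(ref, drawn)), "at least 3")
})

test_that("point configurations round-trip through CSV", {
  cfg <- random_config(5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_point_config(cfg, f)
  cfg2 <- read_point_config(f)
  expect_equal(cfg2$label, cfg$label)
  expect_equal(cfg2$x, cfg$x)
  expect_equal(cfg2$y, cfg$y)
})
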