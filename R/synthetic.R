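# Seeded generator of complete synthetic experiments: routes, training
# paths, cohorts and session-by-session responses with the statistical
# structure the analysis layer assumes.

# ---- wrapped-normal utilities ----------------------------------------------

#' Moments of the absolute angular error under wrapped-normal noise
#'
#' For zero-mean wrapped-normal angular noise with circular SD `sd_deg`,
#' returns the mean and SD of the absolute error `|theta|` (with `theta`
#' wrapped to (-180, 180]), by numerical integration of the wrapped
#' density.  As `sd_deg` grows the distribution approaches circular
#' uniformity and the mean absolute error approaches 90 degrees.
#'
#' This is the bridge between generator noise (an SD in degrees) and the
#' study's reported unit (a mean absolute error in degrees).  The moments
#' are exact: writing `wrap(X) = X - 360k` on each period
#' `(360k - 180, 360k + 180]`, the expectations reduce to closed-form
#' truncated-normal partial moments summed over the periods that carry
#' mass.
#'
#' @param sd_deg Normal SD in degrees before wrapping (vectorised).
#' @return Data frame with columns `sd_deg`, `mean_abs`, `sd_abs`.
#' @export
wrapped_abs_error_moments <- function(sd_deg) {
  one <- function(s) {
    if (s == 0) return(c(0, 0))
    kmax <- ceiling((8 * s + 180) / 360)
    m1 <- 0
    m2 <- 0
    # partial moments of N(0, s) over (l, u)
    p0 <- function(l, u) stats::pnorm(u, 0, s) - stats::pnorm(l, 0, s)
    p1 <- function(l, u) s^2 * (stats::dnorm(l, 0, s) - stats::dnorm(u, 0, s))
    # E[x^2; l, u] = s^2 * P0 + s^2 * (l phi(l) - u phi(u))
    p2 <- function(l, u) {
      s^2 * p0(l, u) + s^2 * (l * stats::dnorm(l, 0, s) -
                                u * stats::dnorm(u, 0, s))
    }
    for (k in -kmax:kmax) {
      c0 <- 360 * k
      l <- c0 - 180
      u <- c0 + 180
      # E[|x - c0|] over (l, u): split at c0
      m1 <- m1 + (c0 * p0(l, c0) - p1(l, c0)) + (p1(c0, u) - c0 * p0(c0, u))
      # E[(x - c0)^2] over (l, u)
      m2 <- m2 + p2(l, u) - 2 * c0 * p1(l, u) + c0^2 * p0(l, u)
    }
    c(m1, sqrt(max(m2 - m1^2, 0)))
  }
  m <- vapply(sd_deg, one, numeric(2))
  data.frame(sd_deg = sd_deg, mean_abs = m[1L, ], sd_abs = m[2L, ])
}

# memoised lookup: monotone map sd -> E|theta| and its inverse
.wrap_cache <- new.env(parent = emptyenv())

wrap_abs_tables <- function() {
  if (is.null(.wrap_cache$fwd)) {
    # the mean absolute error saturates at 90 (circular uniformity); keep
    # the grid where the map is strictly monotone so it can be inverted
    grid <- c(seq(0.5, 30, by = 0.5), seq(31, 120, by = 1),
              seq(122, 220, by = 2))
    mom <- wrapped_abs_error_moments(grid)
    keep <- c(TRUE, diff(mom$mean_abs) > 1e-6) & c(TRUE, diff(grid) > 0) &
      cummax(mom$mean_abs) == mom$mean_abs
    grid <- grid[keep]
    mom <- mom[keep, ]
    .wrap_cache$fwd <- stats::splinefun(c(0, grid), c(0, mom$mean_abs),
                                        method = "hyman")
    .wrap_cache$inv <- stats::splinefun(c(0, mom$mean_abs), c(0, grid),
                                        method = "hyman")
    .wrap_cache$max_mean <- max(mom$mean_abs)
    .wrap_cache$sd_abs <- stats::splinefun(c(0, grid), c(0, mom$sd_abs),
                                           method = "monoH.FC")
  }
  .wrap_cache
}

#' Wrapped-normal SD producing a target mean absolute error
#'
#' Inverse of the `sd -> mean(|theta|)` map of
#' [wrapped_abs_error_moments()], so cohort specifications can be phrased
#' in the study's unit (mean absolute direction error in degrees).
#'
#' @param mean_abs Target mean absolute error(s), degrees in `[0, 89]`.
#' @return Wrapped-normal SD(s) in degrees.
#' @export
direction_sd_for_mean_abs <- function(mean_abs) {
  tabs <- wrap_abs_tables()
  if (any(mean_abs < 0 | mean_abs > 89)) {
    stop("mean absolute errors must lie in [0, 89] degrees ",
         "(90 is the circular-uniform limit)")
  }
  out <- tabs$inv(mean_abs)
  out[mean_abs == 0] <- 0
  pmax(out, 0)
}

# per-draw SD of |theta| at a given mean absolute error, and the sampling SD
# of a mean over n_draws draws
abs_error_sampling_sd <- function(mean_abs, n_draws) {
  tabs <- wrap_abs_tables()
  s <- direction_sd_for_mean_abs(mean_abs)
  tabs$sd_abs(s) / sqrt(n_draws)
}

# ---- geometry generation ----------------------------------------------------

#' Generate a study-style route
#'
#' Random self-avoiding polyline of the stated length with `n_turns`
#' interior turns (turn angles near +/-90 degrees) and `n_landmarks`
#' landmarks placed on distinct segments; turns are labelled `T1..`,
#' landmarks `L1..` in walking order, with facing bearings taken from the
#' walked segment.
#'
#' @param seed Optional integer seed (caller RNG preserved).
#' @param length_m Route length in metres (study routes: 450).
#' @param n_turns Number of interior turns (study routes: 5).
#' @param n_landmarks Number of landmarks (study routes: 4); at most
#'   `n_turns + 1`.
#' @param max_tries Rejection-sampling budget for self-avoidance.
#' @param name Route name.
#' @return A [route_map()].
#' @export
generate_route <- function(seed = NULL, length_m = 450, n_turns = 5,
                           n_landmarks = 4, max_tries = 200,
                           name = "synthetic route") {
  stopifnot(length_m > 0, n_turns >= 0, n_landmarks >= 1,
            n_landmarks <= n_turns + 1)
  gen <- function() {
    n_seg <- n_turns + 1L
    for (try in seq_len(max_tries)) {
      w <- stats::runif(n_seg, 0.6, 1.4)
      seg_len <- length_m * w / sum(w)
      turn <- sample(c(-1, 1), n_turns, replace = TRUE) *
        pmin(pmax(90 + stats::rnorm(n_turns, 0, 10), 60), 120)
      heading <- cumsum(c(stats::runif(1, 0, 360), turn))
      steps <- cbind(seg_len * sin(heading * pi / 180),
                     seg_len * cos(heading * pi / 180))
      v <- rbind(c(0, 0), apply(steps, 2L, cumsum))
      if (self_avoiding(v, clearance = 15)) {
        segs <- sample.int(n_seg, n_landmarks)
        frac <- stats::runif(n_landmarks, 0.3, 0.7)
        lx <- v[segs, 1L] + frac * steps[segs, 1L]
        ly <- v[segs, 2L] + frac * steps[segs, 2L]
        ord <- order(segs)
        anchors <- data.frame(
          label = c("start",
                    paste0("L", seq_len(n_landmarks)),
                    if (n_turns > 0) paste0("T", seq_len(n_turns)),
                    "goal"),
          x = c(v[1L, 1L], lx[ord],
                if (n_turns > 0) v[2:(n_turns + 1L), 1L], v[nrow(v), 1L]),
          y = c(v[1L, 2L], ly[ord],
                if (n_turns > 0) v[2:(n_turns + 1L), 2L], v[nrow(v), 2L]),
          facing = NA_real_)
        return(route_map(v, anchors, name = name, n_turns = n_turns))
      }
    }
    stop("failed to generate a self-avoiding route in ", max_tries, " tries")
  }
  if (is.null(seed)) gen() else with_preserved_seed(seed, gen)
}

# polyline self-avoidance: no proper intersections between non-adjacent
# segments and no non-adjacent vertices closer than `clearance` metres
self_avoiding <- function(v, clearance = 0) {
  n <- nrow(v) - 1L
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (segments_intersect(v[i, ], v[i + 1L, ], v[j, ], v[j + 1L, ])) {
        return(FALSE)
      }
    }
  }
  if (clearance > 0) {
    d <- as.matrix(stats::dist(v))
    adj <- abs(row(d) - col(d)) <= 1L
    if (any(d[!adj] < clearance)) return(FALSE)
  }
  TRUE
}

#' Generate the 18 training paths
#'
#' Six triangle paths (2 walked segments), six quadrilateral paths
#' (3 walked segments) and six crossing paths (return segment crosses an
#' earlier walked segment), at vista scale (segments of roughly 5-10 m),
#' each with a random north bearing.
#'
#' @param seed Optional integer seed.
#' @return Named list of 18 [training_path()] objects
#'   (`tri1..tri6`, `quad1..quad6`, `cross1..cross6`).
#' @export
generate_training_paths <- function(seed = NULL) {
  gen <- function() {
    paths <- list()
    rot <- function(v, a) {
      a <- a * pi / 180
      cbind(v[, 1L] * cos(a) + v[, 2L] * sin(a),
            -v[, 1L] * sin(a) + v[, 2L] * cos(a))
    }
    for (i in 1:6) {
      # triangle: two walked segments, interior turn well away from 0/180
      repeat {
        l1 <- stats::runif(1, 3, 6)
        l2 <- stats::runif(1, 3, 6)
        a <- sample(c(-1, 1), 1) * stats::runif(1, 60, 120)
        v <- rbind(c(0, 0), c(0, l1),
                   c(0, l1) + l2 * c(sin(a * pi / 180), cos(a * pi / 180)))
        if (sqrt(sum((v[3L, ] - v[1L, ])^2)) > 1.5) break
      }
      paths[[paste0("tri", i)]] <- training_path(
        "triangle", rot(v, stats::runif(1, 0, 360)),
        north_bearing = stats::runif(1, 0, 360), name = paste0("tri", i))

      # quadrilateral: three walked segments turning the same way
      repeat {
        lens <- stats::runif(3, 2.5, 5)
        sgn <- sample(c(-1, 1), 1)
        turns <- sgn * stats::runif(2, 70, 110)
        heading <- cumsum(c(0, turns))
        steps <- cbind(lens * sin(heading * pi / 180),
                       lens * cos(heading * pi / 180))
        v <- rbind(c(0, 0), apply(steps, 2L, cumsum))
        e <- v[4L, ]
        closes_clean <- sqrt(sum(e^2)) > 1.5 &&
          !segments_intersect(e, c(0, 0), v[1L, ], v[2L, ]) &&
          !segments_intersect(e, c(0, 0), v[2L, ], v[3L, ]) &&
          !segments_intersect(e, c(0, 0), v[3L, ], v[4L, ])
        if (closes_clean) break
      }
      paths[[paste0("quad", i)]] <- training_path(
        "quadrilateral", rot(v, stats::runif(1, 0, 360)),
        north_bearing = stats::runif(1, 0, 360), name = paste0("quad", i))

      # crossing: hook shape whose return segment crosses the second walked
      # segment by construction
      a <- stats::runif(1, 3, 5)
      b <- stats::runif(1, 2.5, 4)
      cc <- stats::runif(1, 0.8, 1.5)
      d <- stats::runif(1, b / 3, 2 * b / 3)
      v <- rbind(c(0, 0), c(a, 0), c(a, b), c(a + cc, d))
      paths[[paste0("cross", i)]] <- training_path(
        "crossing", rot(v, stats::runif(1, 0, 360)),
        north_bearing = stats::runif(1, 0, 360), name = paste0("cross", i))
    }
    paths
  }
  if (is.null(seed)) gen() else with_preserved_seed(seed, gen)
}

# ---- cohort specification ---------------------------------------------------

#' Specification of a synthetic cohort
#'
#' Defines the design (2 experimental conditions x `n_per_condition`
#' participants x `sessions` weekly sessions, plus an average-sense-of-
#' direction comparison group observed in session 1 only) and the noise
#' parameters of every task.  The defaults emulate the magnitudes of the
#' study population this generator is modelled on: mean absolute direction
#' errors around 40-52 degrees, distance ratios drifting from about 0.78-0.90
#' toward (and past) 1 over six sessions, and sketch-map bidimensional
#' correlations around .90-.95.  Session-level values are linear
#' interpolations between the stated first- and last-session means; see the
#' methods vignette for how the between-subject SDs were calibrated.
#'
#' @param n_per_condition Participants per experimental condition (default
#'   20); the average group also has 20.
#' @param sessions Number of sessions (default 6).
#' @param conditions Conditions to generate; any subset of
#'   `c("feedback_only", "training", "average")`.
#' @param direction_mean Named list: per condition, length-`sessions` vector
#'   (or first/last pair for `average`, a scalar) of mean absolute direction
#'   errors in degrees.
#' @param direction_subject_sd Named vector of between-subject SDs of the
#'   latent mean absolute direction error, degrees.
#' @param route_ratio_mean,straight_ratio_mean Per-session mean distance-
#'   ratio multipliers for the experimental conditions (scalar for average).
#' @param ratio_subject_sd Named list with elements `route` and `straight`:
#'   per condition-class between-subject SD of the ratio multiplier.
#' @param ratio_estimate_sd Within-participant SD of a single distance
#'   estimate's ratio multiplier.
#' @param sketch_sd_m Per-session SD (metres, in route coordinates) of the
#'   isotropic jitter applied to sketch anchor points (scalar for average).
#' @param sketch_subject_sdlog SD of the log-normal participant multiplier
#'   on the sketch jitter.
#' @param pathway_point_sd_deg Per-trial SD (degrees) of the return-heading
#'   error in pathway completion, length 2 (trial 1, trial 2).
#' @param pathway_radial_sd Per-trial SD of the proportional error in the
#'   walked return distance, length 2.
#' @param north_sd_deg SD (degrees) of the north-pointing error.
#' @param standard_m Standard distance in metres.
#' @param route_length_m,n_turns,n_landmarks Route geometry parameters.
#' @param seed Integer seed for the whole experiment.
#' @param average_route_ratio_mean,average_straight_ratio_mean Distance-
#'   ratio multiplier means for the average group (session 1 only).
#' @param average_sketch_sd_m Sketch jitter SD (metres) for the average
#'   group.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_condition = 20,
                        sessions = 6,
                        conditions = c("feedback_only", "training", "average"),
                        direction_mean = list(
                          feedback_only = seq(51.60, 49.84, length.out = sessions),
                          training = seq(44.57, 38.60, length.out = sessions),
                          average = 27.06),
                        direction_subject_sd = c(feedback_only = 16.5,
                                                 training = 11.5,
                                                 average = 15.8),
                        route_ratio_mean = seq(0.78, 1.11, length.out = sessions),
                        straight_ratio_mean = seq(0.90, 1.07, length.out = sessions),
                        ratio_subject_sd = list(route = 0.24, straight = 0.34,
                                                average_route = 0.29,
                                                average_straight = 0.55),
                        ratio_estimate_sd = 0.15,
                        sketch_sd_m = seq(28, 24, length.out = sessions),
                        sketch_subject_sdlog = 0.25,
                        pathway_point_sd_deg = c(19.6, 15.1),
                        pathway_radial_sd = c(0.15, 0.12),
                        north_sd_deg = 22.5,
                        standard_m = 32,
                        route_length_m = 450, n_turns = 5, n_landmarks = 4,
                        seed = 1L,
                        average_route_ratio_mean = 1.02,
                        average_straight_ratio_mean = 1.20,
                        average_sketch_sd_m = 21) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  stopifnot(n_per_condition >= 2, sessions >= 1,
            all(unlist(direction_subject_sd) >= 0),
            ratio_estimate_sd >= 0, all(unlist(sketch_sd_m) >= 0))
  structure(list(
    n_per_condition = n_per_condition, sessions = sessions,
    conditions = conditions,
    direction_mean = direction_mean,
    direction_subject_sd = direction_subject_sd,
    route_ratio_mean = route_ratio_mean,
    straight_ratio_mean = straight_ratio_mean,
    ratio_subject_sd = ratio_subject_sd,
    ratio_estimate_sd = ratio_estimate_sd,
    sketch_sd_m = sketch_sd_m,
    sketch_subject_sdlog = sketch_subject_sdlog,
    pathway_point_sd_deg = pathway_point_sd_deg,
    pathway_radial_sd = pathway_radial_sd,
    north_sd_deg = north_sd_deg,
    standard_m = standard_m,
    route_length_m = route_length_m, n_turns = n_turns,
    n_landmarks = n_landmarks, seed = as.integer(seed),
    average_route_ratio_mean = average_route_ratio_mean,
    average_straight_ratio_mean = average_straight_ratio_mean,
    average_sketch_sd_m = average_sketch_sd_m),
    class = "cohort_spec")
}

#' Zero-noise cohort specification
#'
#' All error parameters zero and all ratio means 1: every scored measure is
#' exact (errors 0, correlations 1), the degenerate reference point for the
#' whole pipeline.
#'
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
cohort_spec_zero_noise <- function(...) {
  args <- list(...)
  sessions <- args$sessions %||% 6
  defaults <- list(
    sessions = sessions,
    direction_mean = list(feedback_only = rep(0, sessions),
                          training = rep(0, sessions), average = 0),
    direction_subject_sd = c(feedback_only = 0, training = 0, average = 0),
    route_ratio_mean = rep(1, sessions),
    straight_ratio_mean = rep(1, sessions),
    ratio_subject_sd = list(route = 0, straight = 0, average_route = 0,
                            average_straight = 0),
    ratio_estimate_sd = 0,
    sketch_sd_m = rep(0, sessions), sketch_subject_sdlog = 0,
    pathway_point_sd_deg = c(0, 0), pathway_radial_sd = c(0, 0),
    north_sd_deg = 0,
    average_route_ratio_mean = 1, average_straight_ratio_mean = 1,
    average_sketch_sd_m = 0)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

#' Plant an exact standardised condition effect on direction errors
#'
#' Adjusts the training-condition direction-error means so that the
#' difference between the feedback-only and training conditions, on the
#' scale actually analysed (each participant's mean absolute direction
#' error across sessions), is `d` standard deviations.  The standardiser
#' combines the between-subject SD of the latent error level with the
#' sampling SD of a participant's observed mean over
#' `6 * sessions` estimate draws, both available in closed form from the
#' wrapped-normal error model; both conditions are given the feedback-only
#' subject SD so the planted effect is a pure mean shift.
#'
#' Because the sampling SD of the observed score depends on the error
#' level itself, the mean shift that yields a given standardised difference
#' is found by a short fixed-point iteration over the pooled SD of the two
#' groups.
#'
#' @param spec A [cohort_spec()].
#' @param d Target standardised mean difference (feedback-only minus
#'   training).
#' @return The modified `cohort_spec`, with the implied true difference in
#'   attribute `"planted_delta"`.
#' @export
plant_condition_effect <- function(spec, d) {
  mu_f <- mean(spec$direction_mean$feedback_only)
  sd_subj <- spec$direction_subject_sd[["feedback_only"]]
  n_draws <- 6 * spec$sessions
  samp_f <- abs_error_sampling_sd(mu_f, n_draws)
  delta <- d * sqrt(sd_subj^2 + samp_f^2)
  for (i in 1:25) {
    samp_t <- abs_error_sampling_sd(max(mu_f - delta, 1), n_draws)
    sd_pooled <- sqrt(sd_subj^2 + (samp_f^2 + samp_t^2) / 2)
    delta_new <- d * sd_pooled
    if (abs(delta_new - delta) < 1e-10) break
    delta <- delta_new
  }
  spec$direction_mean$training <- spec$direction_mean$feedback_only - delta
  spec$direction_subject_sd[["training"]] <- sd_subj
  attr(spec, "planted_delta") <- delta
  spec
}

# ---- response generation ----------------------------------------------------

# truth tables for one route: the 6 landmark pairs with facing bearings,
# true relative directions and true distances
route_truth <- function(route, standard_m) {
  lm <- route_landmarks(route)
  pr <- utils::combn(lm, 2L)
  a <- route$anchors
  i <- match(pr[1L, ], a$label)
  j <- match(pr[2L, ], a$label)
  true_bearing <- bearing_between(cbind(a$x[i], a$y[i]), cbind(a$x[j], a$y[j]))
  data.frame(
    from_label = pr[1L, ], to_label = pr[2L, ],
    facing = a$facing[i],
    true_relative = normalize_bearing(true_bearing - a$facing[i]),
    route_m = a$arc[j] - a$arc[i],
    straight_m = sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2),
    standard_m = standard_m)
}

rwrapped <- function(n, sd) wrap_angle(stats::rnorm(n, 0, sd))

#' Generate synthetic responses for a cohort
#'
#' Builds the tidy response table for every participant and session of the
#' specified cohort, given the experiment geometry.  Direction estimates are
#' true relative bearings plus wrapped-normal noise whose SD is set per
#' participant-session so that the expected absolute error matches the
#' participant's latent error level; distance estimates are true distances
#' times truncated-normal ratio multipliers; sketch anchors are the true
#' configuration under a random similarity transform (page placement) plus
#' isotropic jitter; pathway-completion outcomes are the true return plus
#' bivariate-normal stop error and normal pointing error.  Everything is
#' driven by `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param routes List of [route_map()]s indexed by session (session `i`
#'   uses `routes[[i]]`); generated if `NULL`.
#' @param paths Named list of 18 [training_path()]s (see
#'   [generate_training_paths()]); generated if `NULL`.  Sessions use paths
#'   `tri<i>`, `quad<i>`, `cross<i>`.
#' @param tasks Which tasks to generate; subset of
#'   `c("direction", "distance", "sketch", "pathway")`.
#' @return A list of class `synthetic_experiment` with elements `routes`,
#'   `paths`, `responses` (tidy data.frame), `spec` and `ground_truth`
#'   (per-participant latent parameters).
#' @export
generate_responses <- function(spec, routes = NULL, paths = NULL,
                               tasks = c("direction", "distance", "sketch",
                                         "pathway")) {
  stopifnot(inherits(spec, "cohort_spec"))
  tasks <- match.arg(tasks, several.ok = TRUE)
  with_preserved_seed(spec$seed, function() {
    if (is.null(routes)) {
      routes <- lapply(seq_len(spec$sessions), function(i) {
        generate_route(length_m = spec$route_length_m, n_turns = spec$n_turns,
                       n_landmarks = spec$n_landmarks,
                       name = paste0("route", i))
      })
    }
    if (is.null(paths) && "pathway" %in% tasks &&
        "training" %in% spec$conditions) {
      paths <- generate_training_paths()
    }
    truth <- lapply(routes, route_truth, standard_m = spec$standard_m)

    prefix <- c(feedback_only = "F", training = "T", average = "A")
    rows <- list()
    gt <- list()
    for (cond in spec$conditions) {
      n <- spec$n_per_condition
      ids <- sprintf("%s%02d", prefix[[cond]], seq_len(n))
      sess_set <- if (cond == "average") 1L else seq_len(spec$sessions)

      dm <- spec$direction_mean[[cond]]
      if (length(dm) == 1L) dm <- rep(dm, spec$sessions)
      subj_dir <- stats::rnorm(n, 0, spec$direction_subject_sd[[cond]])
      rr_mean <- if (cond == "average") rep(spec$average_route_ratio_mean,
                                            spec$sessions) else
        spec$route_ratio_mean
      sr_mean <- if (cond == "average") rep(spec$average_straight_ratio_mean,
                                            spec$sessions) else
        spec$straight_ratio_mean
      rs_key <- if (cond == "average") "average_route" else "route"
      ss_key <- if (cond == "average") "average_straight" else "straight"
      subj_rr <- stats::rnorm(n, 0, spec$ratio_subject_sd[[rs_key]])
      subj_sr <- stats::rnorm(n, 0, spec$ratio_subject_sd[[ss_key]])
      sk_sd <- if (cond == "average") rep(spec$average_sketch_sd_m,
                                          spec$sessions) else spec$sketch_sd_m
      subj_sk <- exp(stats::rnorm(n, 0, spec$sketch_subject_sdlog))

      gt[[cond]] <- data.frame(participant_id = ids, condition = cond,
                               direction_offset = subj_dir,
                               route_ratio_offset = subj_rr,
                               straight_ratio_offset = subj_sr,
                               sketch_multiplier = subj_sk)

      for (p in seq_len(n)) {
        for (s in sess_set) {
          tt <- truth[[s]]
          np <- nrow(tt)
          blk <- list()
          if ("direction" %in% tasks) {
            m_abs <- min(max(dm[s] + subj_dir[p], 0), 89)
            sd_i <- direction_sd_for_mean_abs(m_abs)
            blk$dir <- data.frame(
              task = "direction", from_label = tt$from_label,
              to_label = tt$to_label,
              value = normalize_bearing(tt$true_relative + rwrapped(np, sd_i)),
              trial = NA_real_)
          }
          if ("distance" %in% tasks) {
            mult_r <- pmax(rr_mean[s] + subj_rr[p] +
                             stats::rnorm(np, 0, spec$ratio_estimate_sd), 0.05)
            mult_s <- pmax(sr_mean[s] + subj_sr[p] +
                             stats::rnorm(np, 0, spec$ratio_estimate_sd), 0.05)
            blk$dist <- data.frame(
              task = rep(c("route_distance", "straight_distance"), each = np),
              from_label = rep(tt$from_label, 2L),
              to_label = rep(tt$to_label, 2L),
              value = c(tt$route_m * mult_r, tt$straight_m * mult_s) /
                spec$standard_m,
              trial = NA_real_)
          }
          if ("sketch" %in% tasks) {
            anchors <- route_anchors(routes[[s]])
            jit_sd <- sk_sd[s] * subj_sk[p]
            jx <- anchors$x + stats::rnorm(nrow(anchors), 0, jit_sd)
            jy <- anchors$y + stats::rnorm(nrow(anchors), 0, jit_sd)
            page <- transform_config(
              point_config(anchors$label, jx, jy),
              scale = stats::runif(1, 0.0003, 0.0006) * 1000,
              rotation = stats::runif(1, 0, 360),
              translation = stats::runif(2, -50, 50))
            blk$sketch <- data.frame(
              task = rep(c("sketch_x", "sketch_y"), each = nrow(page)),
              from_label = rep(page$label, 2L),
              to_label = NA_character_,
              value = c(page$x, page$y),
              trial = NA_real_)
          }
          if ("pathway" %in% tasks && cond == "training") {
            pnames <- paste0(c("tri", "quad", "cross"), s)
            pw <- lapply(pnames, function(pn) {
              pth <- paths[[pn]]
              do.call(rbind, lapply(1:2, function(tr) {
                # walk the return with a heading error and a proportional
                # distance (radial) error: the stop point then implies the
                # same heading deviation that was sampled
                len <- sqrt(sum((pth$start - pth$end)^2))
                heading <- bearing_between(pth$end, pth$start) +
                  stats::rnorm(1, 0, spec$pathway_point_sd_deg[tr])
                walked <- len * (1 + stats::rnorm(1, 0,
                                                  spec$pathway_radial_sd[tr]))
                stop_pt <- pth$end + max(walked, 0.1 * len) *
                  c(sin(heading * pi / 180), cos(heading * pi / 180))
                north <- pth$north_bearing +
                  stats::rnorm(1, 0, spec$north_sd_deg)
                data.frame(task = c("pathway_stop_x", "pathway_stop_y",
                                    "north_pointing"),
                           from_label = pn, to_label = NA_character_,
                           value = c(stop_pt[1L], stop_pt[2L],
                                     normalize_bearing(north)),
                           trial = tr)
              }))
            })
            blk$pw <- do.call(rbind, pw)
          }
          if (length(blk) > 0L) {
            b <- do.call(rbind, blk)
            b <- cbind(data.frame(participant_id = ids[p], condition = cond,
                                  session = s), b)
            rows[[length(rows) + 1L]] <- b
          }
        }
      }
    }
    responses <- do.call(rbind, rows)
    rownames(responses) <- NULL
    structure(list(routes = routes, paths = paths, responses = responses,
                   spec = spec, ground_truth = do.call(rbind, gt)),
              class = "synthetic_experiment")
  })
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper: geometry plus responses from a single seed.
#'
#' @inheritParams generate_responses
#' @return A `synthetic_experiment` (see [generate_responses()]).
#' @export
generate_experiment <- function(spec, tasks = c("direction", "distance",
                                                "sketch", "pathway")) {
  generate_responses(spec, routes = NULL, paths = NULL, tasks = tasks)
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_experiment: %d routes, %d training paths, ",
                     "%d response rows, seed %d>\n"),
              length(x$routes), length(x$paths %||% list()),
              nrow(x$responses), x$spec$seed))
  invisible(x)
}
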