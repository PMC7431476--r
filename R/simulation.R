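# Monte Carlo simulation of sketch-map drawing: landmark positions are
# reconstructed chain-wise from sampled straight-line-distance ratios and
# direction errors, and each simulated map is scored against the true
# landmark configuration by bidimensional regression.

#' Error model for simulated sketch maps
#'
#' Normal distributions for the straight-line distance ratio
#' (estimated / correct) and the absolute direction error (degrees), with
#' means and SDs taken from observed performance.
#'
#' An absolute error carries no sign, so a convention is needed when the
#' sampled magnitude perturbs a bearing.  `sign_convention = "symmetric"`
#' (default) samples the magnitude from the stated normal truncated at 0 and
#' applies a random sign, the conservative reading; `"positive"` applies
#' every sampled error in the same rotational direction, which rotates the
#' chain coherently and is partially absorbed by the similarity fit.
#'
#' @param ratio_mean,ratio_sd Mean and SD of the straight-line distance
#'   ratio; samples are truncated below at `ratio_floor`.
#' @param direrr_mean,direrr_sd Mean and SD (degrees) of the absolute
#'   direction error; magnitude samples are truncated at 0.
#' @param sign_convention `"symmetric"` or `"positive"`.
#' @param ratio_floor Small positive floor for ratio samples (default 0.01)
#'   preventing degenerate placements.
#' @return A list of class `error_model`.
#' @export
error_model <- function(ratio_mean = 1, ratio_sd = 0,
                        direrr_mean = 0, direrr_sd = 0,
                        sign_convention = c("symmetric", "positive"),
                        ratio_floor = 0.01) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(ratio_sd >= 0, direrr_sd >= 0, ratio_floor > 0)
  structure(list(ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                 direrr_mean = direrr_mean, direrr_sd = direrr_sd,
                 sign_convention = sign_convention,
                 ratio_floor = ratio_floor),
            class = "error_model")
}

#' Estimate an error model from session scores
#'
#' Takes the participant-level mean straight-line distance ratios and mean
#' absolute direction errors of a scored cohort cell (see
#' [score_experiment()]) and returns the [error_model()] with their observed
#' means and SDs.
#'
#' @param scores Data frame with columns `mean_straight_ratio` and
#'   `mean_abs_direction_error` (one row per participant).
#' @param ... Passed on to [error_model()] (e.g. `sign_convention`).
#' @return An [error_model()].
#' @export
error_model_from_scores <- function(scores, ...) {
  stopifnot(all(c("mean_straight_ratio", "mean_abs_direction_error") %in%
                  names(scores)), nrow(scores) >= 2L)
  error_model(ratio_mean = mean(scores$mean_straight_ratio),
              ratio_sd = stats::sd(scores$mean_straight_ratio),
              direrr_mean = mean(scores$mean_abs_direction_error),
              direrr_sd = stats::sd(scores$mean_abs_direction_error), ...)
}

# sample n absolute-error magnitudes with signs per the model's convention
sample_direction_errors <- function(model, n) {
  mag <- pmax(stats::rnorm(n, model$direrr_mean, model$direrr_sd), 0)
  if (model$sign_convention == "symmetric") {
    mag * sample(c(-1, 1), n, replace = TRUE)
  } else {
    mag
  }
}

#' Simulate one sketch map
#'
#' Starting from the first landmark at its true position, each subsequent
#' landmark (in walking order) is placed at a sampled ratio of the true
#' straight-line distance from the previously placed landmark, along the
#' true inter-landmark bearing perturbed by a sampled direction error.
#' Uses the current RNG state; seed control lives in [run_simulation()].
#'
#' @param route A [route_map()] with at least 2 landmarks.
#' @param model An [error_model()].
#' @return A [point_config()] of the simulated landmark positions.
#' @export
simulate_sketch <- function(route, model) {
  stopifnot(inherits(model, "error_model"))
  lm <- route_landmarks(route)
  if (length(lm) < 2L) stop("simulation needs at least 2 landmarks")
  truth <- route_anchors(route, lm)
  n_step <- length(lm) - 1L
  ratios <- pmax(stats::rnorm(n_step, model$ratio_mean, model$ratio_sd),
                 model$ratio_floor)
  errs <- sample_direction_errors(model, n_step)
  if (any(!is.finite(ratios)) || any(!is.finite(errs))) {
    stop("non-finite samples from the error model")
  }
  xs <- numeric(length(lm))
  ys <- numeric(length(lm))
  xs[1L] <- truth$x[1L]
  ys[1L] <- truth$y[1L]
  for (i in seq_len(n_step)) {
    d_true <- sqrt((truth$x[i + 1L] - truth$x[i])^2 +
                     (truth$y[i + 1L] - truth$y[i])^2)
    b_true <- bearing_between(c(truth$x[i], truth$y[i]),
                              c(truth$x[i + 1L], truth$y[i + 1L]))
    b <- (b_true + errs[i]) * pi / 180
    xs[i + 1L] <- xs[i] + ratios[i] * d_true * sin(b)
    ys[i + 1L] <- ys[i] + ratios[i] * d_true * cos(b)
  }
  point_config(lm, xs, ys)
}

# TRUE when the landmark configuration is nearly collinear (max perpendicular
# deviation from the principal axis below tol metres)
landmarks_collinear <- function(truth, tol = 1e-6) {
  xy <- cbind(truth$x - mean(truth$x), truth$y - mean(truth$y))
  sv <- svd(xy)$d
  sv[2L] < tol * max(sv[1L], 1)
}

#' Run the sketch-map Monte Carlo simulation
#'
#' Repeatedly simulates sketch maps with [simulate_sketch()] and scores each
#' against the true landmark configuration with [bidim_r()], returning the
#' per-iteration correlations and their mean.  Fully reproducible given
#' `seed`.
#'
#' @param route A [route_map()].
#' @param model An [error_model()].
#' @param iterations Number of iterations (study default 1000).
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @return A list of class `simulation_result` with `iterations`,
#'   `mean_bidim_r`, `per_iteration_r` and `seed`.
#' @export
run_simulation <- function(route, model, iterations = 1000, seed = NULL) {
  stopifnot(iterations >= 1)
  truth <- route_anchors(route, route_landmarks(route))
  if (landmarks_collinear(truth)) {
    warning("landmarks are (nearly) collinear: fits are reflection-sensitive")
  }
  run <- function() {
    vapply(seq_len(iterations), function(i) {
      bidim_r(truth, simulate_sketch(route, model))
    }, numeric(1))
  }
  r <- if (is.null(seed)) run() else with_preserved_seed(seed, run)
  structure(list(iterations = iterations, mean_bidim_r = mean(r),
                 per_iteration_r = r, seed = seed),
            class = "simulation_result")
}

# run `fn` under set.seed(seed) and restore the caller's RNG state
with_preserved_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %d iterations, mean bidimensional r = %.3f>\n",
              x$iterations, x$mean_bidim_r))
  invisible(x)
}

#' Compare observed sketch-map correlations with a simulation
#'
#' One-sample t test of the participants' Fisher-z-transformed sketch-map
#' correlations against the (z-transformed) simulated mean correlation,
#' asking whether observed maps are more accurate than maps reconstructed
#' from the participants' own distance and direction errors.
#'
#' @param observed_r Bidimensional correlations, one per participant
#'   (length >= 2).
#' @param result A `simulation_result` from [run_simulation()].
#' @return List with `t`, `df`, `p`, `observed_mean_r` (back-transformed
#'   from the mean z) and `simulated_mean_r`.
#' @export
compare_observed_vs_simulated <- function(observed_r, result) {
  stopifnot(inherits(result, "simulation_result"), length(observed_r) >= 2L)
  z <- fisher_z(clamp_r(observed_r))
  mu <- fisher_z(clamp_r(result$mean_bidim_r))
  tt <- one_sample_t(z, mu0 = mu)
  list(t = tt$t, df = tt$df, p = tt$p,
       observed_mean_r = fisher_z_inv(mean(z)),
       simulated_mean_r = result$mean_bidim_r)
}
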