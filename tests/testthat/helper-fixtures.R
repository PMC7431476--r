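# Deterministic fixtures and independent numerical oracles shared by the
# tests.  Everything is built in code; no data files.

# A hand-built staircase route: 6 segments (lengths sum to 450 m), 5 right-
# angle turns, 4 landmarks at segment midpoints.  Simple enough that every
# bearing and distance can be read off by eye.
make_test_route <- function() {
  v <- rbind(c(0, 0), c(0, 80), c(70, 80), c(70, 170), c(130, 170),
             c(130, 250), c(200, 250))
  anchors <- data.frame(
    label = c("start", "L1", "T1", "L2", "T2", "L3", "T3", "T4", "L4",
              "T5", "goal"),
    x = c(0, 0, 0, 35, 70, 70, 70, 130, 165, 130, 200),
    y = c(0, 40, 80, 80, 80, 125, 170, 170, 250, 250, 250),
    facing = NA_real_)
  route_map(v, anchors, name = "staircase", n_turns = 5)
}

make_square_config <- function() {
  point_config(c("a", "b", "c", "d"), c(0, 1, 1, 0), c(0, 0, 1, 1))
}

random_config <- function(n, labels = sprintf("p%02d", seq_len(n))) {
  point_config(labels, stats::rnorm(n, sd = 10), stats::rnorm(n, sd = 10))
}

# independent numerical-optimiser oracle for the similarity fit: minimise
# SSE over (log scale, rotation, translation) with Nelder-Mead from several
# rotation starts, polishing the best solution with a restart
oracle_similarity_sse <- function(reference, drawn) {
  yr <- reference$x; yi <- reference$y
  xr <- drawn$x; xi <- drawn$y
  obj <- function(p) {
    s <- exp(p[1]); th <- p[2]
    rx <- s * (cos(th) * xr - sin(th) * xi) + p[3]
    ry <- s * (sin(th) * xr + cos(th) * xi) + p[4]
    sum((yr - rx)^2 + (yi - ry)^2)
  }
  scale0 <- sqrt(sum((yr - mean(yr))^2 + (yi - mean(yi))^2) /
                   sum((xr - mean(xr))^2 + (xi - mean(xi))^2))
  best <- NULL
  for (th0 in seq(0, 2 * pi, length.out = 9)[-9]) {
    fit <- stats::optim(c(log(scale0), th0, mean(yr), mean(yi)), obj,
                        control = list(maxit = 5000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  polish <- stats::optim(best$par, obj,
                         control = list(maxit = 5000, reltol = 1e-15))
  min(best$value, polish$value)
}

# coarse-to-fine grid-search oracle over (rotation, scale); translation at
# each grid point is the optimal centroid shift
oracle_similarity_grid <- function(reference, drawn, rounds = 4) {
  yr <- reference$x - mean(reference$x); yi <- reference$y - mean(reference$y)
  xr <- drawn$x - mean(drawn$x); xi <- drawn$y - mean(drawn$y)
  sse_at <- function(s, th) {
    rx <- s * (cos(th) * xr - sin(th) * xi)
    ry <- s * (sin(th) * xr + cos(th) * xi)
    sum((yr - rx)^2 + (yi - ry)^2)
  }
  s_lo <- 1e-3; s_hi <- 10; th_lo <- 0; th_hi <- 2 * pi
  for (r in seq_len(rounds)) {
    ss <- seq(s_lo, s_hi, length.out = 60)
    ths <- seq(th_lo, th_hi, length.out = 120)
    g <- expand.grid(s = ss, th = ths)
    vals <- mapply(sse_at, g$s, g$th)
    i <- which.min(vals)
    ds <- diff(ss)[1]; dth <- diff(ths)[1]
    s_lo <- max(g$s[i] - 2 * ds, 1e-4); s_hi <- g$s[i] + 2 * ds
    th_lo <- g$th[i] - 2 * dth; th_hi <- g$th[i] + 2 * dth
  }
  min(vals)
}

# balanced long-format dataset for the split-plot ANOVA
make_long_data <- function(n_per_cond = 5, sessions = 4, effect = 0,
                           session_slope = 0, sd = 1) {
  d <- expand.grid(
    participant_id = sprintf("p%02d", seq_len(2 * n_per_cond)),
    session = seq_len(sessions), stringsAsFactors = FALSE)
  d$condition <- ifelse(
    as.integer(substring(d$participant_id, 2)) <= n_per_cond, "a", "b")
  d$value <- stats::rnorm(nrow(d), sd = sd) +
    effect * (d$condition == "b") + session_slope * d$session
  d
}

# hand-computable 2 x 2 x 2 split-plot toy with frozen sums of squares
toy_split_plot <- function() {
  data.frame(
    participant_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
    condition = rep(c("a", "a", "b", "b"), each = 2),
    session = rep(1:2, 4),
    value = c(1, 2, 3, 4, 5, 7, 6, 9))
}
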