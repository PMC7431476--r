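test_that("Fisher z is odd, increasing, and inverts exactly", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.91), 1.52752, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.05)
  z <- fisher_z(r)
  expect_equal(fisher_z_inv(z), r, tolerance = 1e-12)
  expect_true(all(diff(z) > 0))
  expect_equal(fisher_z(-r), -z)
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("summary-statistic effect sizes and t tests match raw-data twins", {
  # raw vectors with known summaries
  set.seed(31)
  x <- rnorm(20); x <- (x - mean(x)) / sd(x) * 4 + 50   # M = 50, SD = 4
  y <- rnorm(25); y <- (y - mean(y)) / sd(y) * 5 + 46   # M = 46, SD = 5
  d_raw <- cohens_d_pooled(x, y)
  d_sum <- cohens_d_pooled(summary_stat(50, 4, 20), summary_stat(46, 5, 25))
  expect_equal(d_raw, d_sum)
  tt_sum <- independent_t_from_summary(summary_stat(50, 4, 20),
                                       summary_stat(46, 5, 25))
  tt_raw <- t.test(x, y, var.equal = TRUE)
  expect_equal(tt_sum$t, unname(tt_raw$statistic))
  expect_equal(tt_sum$df, unname(tt_raw$parameter))
  expect_equal(tt_sum$p, tt_raw$p.value)
  expect_equal(cohens_d_pooled(x, x), 0)
  expect_error(cohens_d_pooled(summary_stat(1, 0, 5), summary_stat(2, 0, 5)),
               "pooled SD")
})

test_that("one-sample t handles raw, summary and degenerate input", {
  set.seed(32)
  x <- rnorm(15, mean = 0.4)
  ours <- one_sample_t(x, mu0 = 0.1)
  ref <- t.test(x, mu = 0.1)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_equal(ours$d_z, abs(mean(x) - 0.1) / sd(x))
  expect_equal(one_sample_t(summary_stat(5, 2, 10), 5)$t, 0)
  expect_equal(one_sample_t(rep(3, 5), 3)$t, 0)
  expect_error(one_sample_t(rep(3, 5), 4), "infinite")
})

test_that("equal means give t = 0, p = 1", {
  out <- independent_t_from_summary(summary_stat(10, 2, 8),
                                    summary_stat(10, 3, 8))
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
})

test_that("split-plot decomposition matches the frozen hand-computed toy", {
  a <- mixed_anova(toy_split_plot())
  get <- function(eff, col) a[[col]][a$effect == eff]
  # sums of squares worked out by hand from the 8 values
  expect_equal(get("condition", "ss"), 36.125)
  expect_equal(get("subjects_within_condition", "ss"), 6.25)
  expect_equal(get("session", "ss"), 6.125)
  expect_equal(get("condition:session", "ss"), 1.125)
  expect_equal(get("residual", "ss"), 0.25)
  expect_equal(get("condition", "F"), 11.56)
  expect_equal(get("session", "F"), 49)
  expect_equal(get("condition:session", "F"), 9)
  expect_equal(get("condition", "partial_eta_sq"), 36.125 / 42.375)
  expect_equal(get("session", "partial_eta_sq"), 6.125 / 6.375)
  expect_equal(a$df1, c(1, 2, 1, 1, 2))
})

test_that("split-plot F and p agree with aov error strata", {
  for (seed in 1:3) {
    set.seed(seed)
    d <- make_long_data(n_per_cond = sample(3:6, 1),
                        sessions = sample(3:6, 1),
                        effect = rnorm(1), session_slope = rnorm(1, sd = 0.3))
    ours <- mixed_anova(d)
    d$session_f <- factor(d$session)
    o <- summary(aov(value ~ condition * session_f +
                       Error(participant_id / session_f), data = d))
    between <- o[["Error: participant_id"]][[1]]
    within <- o[["Error: participant_id:session_f"]][[1]]
    expect_equal(ours$F[ours$effect == "condition"], between["condition", "F value"])
    expect_equal(ours$p[ours$effect == "condition"], between["condition", "Pr(>F)"])
    expect_equal(ours$F[ours$effect == "session"], within["session_f", "F value"])
    expect_equal(ours$F[ours$effect == "condition:session"],
                 within["condition:session_f", "F value"])
    expect_equal(ours$p[ours$effect == "session"], within["session_f", "Pr(>F)"])
    # conservation: components add up to the total SS
    expect_equal(sum(ours$ss), sum((d$value - mean(d$value))^2),
                 tolerance = 1e-8)
  }
})

test_that("degenerate and malformed designs are handled", {
  d <- make_long_data(4, 3)
  d$value <- 7
  a <- mixed_anova(d)
  expect_equal(a$F[!is.na(a$F)], c(0, 0, 0))
  expect_equal(a$p[!is.na(a$p)], c(1, 1, 1))
  expect_error(mixed_anova(d[-1, ]), "balanced")
  d2 <- make_long_data(1, 3)
  expect_error(mixed_anova(d2), "at least 2 participants")
})

test_that("Greenhouse-Geisser epsilon is bounded and correction only shifts p", {
  set.seed(44)
  d <- make_long_data(8, 5, session_slope = 0.4)
  a0 <- mixed_anova(d)
  eps <- attr(a0, "gg_epsilon")
  expect_gte(eps, 1 / 4)
  expect_lte(eps, 1)
  a1 <- mixed_anova(d, sphericity_correction = TRUE)
  expect_equal(a1$F, a0$F)
  expect_gte(a1$p[a1$effect == "session"], a0$p[a0$effect == "session"])
})

test_that("polynomial contrasts are zero-sum and pairwise orthogonal", {
  for (k in 3:6) {
    orders <- seq_len(min(3, k - 1))
    cs <- lapply(orders, function(o) poly_contrast_coefs(k, o))
    for (ci in cs) expect_equal(sum(ci), 0)
    if (length(cs) > 1) {
      for (i in seq_along(cs)) {
        for (j in seq_along(cs)) {
          if (i < j) expect_equal(sum(cs[[i]] * cs[[j]]), 0)
        }
      }
    }
    # orthogonal to the linear level index too (except the linear itself)
    for (o in orders[-1]) {
      expect_equal(sum(poly_contrast_coefs(k, o) * seq_len(k)), 0)
    }
  }
  expect_equal(poly_contrast_coefs(6, 1), c(-5, -3, -1, 1, 3, 5))
  expect_equal(poly_contrast_coefs(6, 2), c(5, -1, -4, -4, -1, 5))
  expect_equal(poly_contrast_coefs(6, 3), c(-5, 7, 4, -4, -7, 5))
})

test_that("perfectly linear session means kill quadratic and cubic trends", {
  d <- expand.grid(participant_id = sprintf("p%d", 1:6), session = 1:6,
                   stringsAsFactors = FALSE)
  d$condition <- ifelse(as.integer(substring(d$participant_id, 2)) <= 3,
                        "a", "b")
  d$value <- 2 + 3 * d$session
  tr <- trend_contrasts(d)
  expect_identical(tr$ss[tr$order == "quadratic" & tr$effect == "session"], 0)
  expect_identical(tr$ss[tr$order == "cubic" & tr$effect == "session"], 0)
  expect_gt(tr$ss[tr$order == "linear" & tr$effect == "session"], 0)
})

test_that("trend F matches a contrast-regression oracle", {
  set.seed(55)
  d <- make_long_data(n_per_cond = 7, sessions = 6, effect = 1,
                      session_slope = 0.5)
  tr <- trend_contrasts(d)
  m <- with(d, tapply(value, list(participant_id, session), mean))
  cond <- vapply(rownames(m), function(p) d$condition[d$participant_id == p][1],
                 character(1))
  for (o in 1:3) {
    cf <- poly_contrast_coefs(6, o)
    z <- as.numeric(m %*% cf) / sqrt(sum(cf^2))
    # oracle: intercept t test in an lm with sum-to-zero condition coding
    fit <- lm(z ~ C(factor(cond), contr.sum))
    t_int <- summary(fit)$coefficients[1, "t value"]
    F_lm <- anova(fit)["C(factor(cond), contr.sum)", "F value"]
    row_s <- tr[tr$order == c("linear", "quadratic", "cubic")[o] &
                  tr$effect == "session", ]
    row_i <- tr[tr$order == c("linear", "quadratic", "cubic")[o] &
                  tr$effect == "session:condition", ]
    expect_equal(row_s$F, t_int^2, tolerance = 1e-9)
    expect_equal(row_i$F, F_lm, tolerance = 1e-9)
    expect_equal(row_s$df2, 12)
  }
  # single-group (pure repeated measures) design: df2 = N - 1
  d1 <- d[d$condition == "a", ]
  tr1 <- trend_contrasts(d1)
  expect_equal(unique(tr1$df2), 6)
  expect_true(all(tr1$effect == "session"))
  # pooled error term uses the omnibus residual df
  trp <- trend_contrasts(d, error = "pooled")
  expect_equal(unique(trp$df2), (14 - 2) * (6 - 1))
})

test_that("Bonferroni adjustment caps at 1 and flags decisions", {
  out <- bonferroni(c(0.01, 0.04, 0.5), m = 3)
  expect_equal(out$p_adjusted, c(0.03, 0.12, 1))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  expect_error(bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})
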