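# Inferential layer: Fisher z, effect sizes, t tests from raw or summary
# data, balanced split-plot (mixed) ANOVA with partial eta-squared, and
# orthogonal polynomial trend contrasts.

#' Fisher r-to-z transformation and its inverse
#'
#' The variance-stabilising transform `z = artanh(r)` applied to correlation
#' coefficients before averaging or testing; `fisher_z_inv` maps back.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @param z Transformed value(s).
#' @return Transformed (or back-transformed) numeric vector.
#' @export
#' @examples
#' fisher_z_inv(fisher_z(0.91))
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

# clamp correlations away from +/-1 so degenerate (noise-free) data can
# still pass through the z transform
clamp_r <- function(r, eps = 1e-12) pmin(pmax(r, -1 + eps), 1 - eps)

#' Summary statistics triple
#'
#' Container for a printed (mean, SD, n) triple, the input to the
#' summary-statistic tests and effect sizes.
#'
#' @param mean,sd,n Mean, standard deviation (>= 0) and sample size (>= 2).
#' @return A list of class `summary_stat`.
#' @export
summary_stat <- function(mean, sd, n) {
  stopifnot(is.finite(mean), sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stat")
}

as_summary_stat <- function(x) {
  if (inherits(x, "summary_stat")) return(x)
  if (is.numeric(x) && length(x) > 1L) {
    return(summary_stat(mean(x), stats::sd(x), length(x)))
  }
  stop("expected a summary_stat or a numeric vector of length >= 2")
}

#' Cohen's d from two independent groups
#'
#' Standardised mean difference `(mean_a - mean_b) / s_pooled` with the
#' pooled SD using `(n - 1)` weights.
#'
#' @param a,b [summary_stat()] objects (or raw numeric vectors).
#' @return Cohen's d (signed).
#' @export
#' @examples
#' cohens_d_pooled(summary_stat(52.32, 17.66, 20), summary_stat(39.57, 12.70, 20))
cohens_d_pooled <- function(a, b) {
  a <- as_summary_stat(a)
  b <- as_summary_stat(b)
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 == 0) stop("pooled SD is zero: d undefined")
  (a$mean - b$mean) / sqrt(sp2)
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance (Student) two-sample t test computed from (mean, SD, n)
#' triples, with `df = n_a + n_b - 2` and a two-tailed p value.
#'
#' @inheritParams cohens_d_pooled
#' @return List with `t`, `df`, `p`, and `d` (pooled Cohen's d).
#' @export
independent_t_from_summary <- function(a, b) {
  a <- as_summary_stat(a)
  b <- as_summary_stat(b)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) stop("pooled variance is zero: t undefined")
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       d = (a$mean - b$mean) / sqrt(sp2))
}

#' One-sample t test
#'
#' Tests the mean against `mu0`, returning the paired-style effect size
#' `d_z = |mean - mu0| / sd` alongside the test.
#'
#' @param x Raw numeric vector or a [summary_stat()].
#' @param mu0 Null value.
#' @return List with `t`, `df`, `p`, `d_z`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  s <- as_summary_stat(x)
  if (s$sd == 0) {
    if (s$mean == mu0) return(list(t = 0, df = s$n - 1, p = 1, d_z = 0))
    stop("sd is zero with mean != mu0: t is infinite")
  }
  t <- (s$mean - mu0) / (s$sd / sqrt(s$n))
  list(t = t, df = s$n - 1, p = 2 * stats::pt(-abs(t), s$n - 1),
       d_z = abs(s$mean - mu0) / s$sd)
}

#' Bonferroni adjustment
#'
#' Adjusted p values `min(1, m * p)` with a significance decision at
#' `alpha`.
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @param m Number of tests corrected for; must be at least
#'   `length(pvals)`.
#' @param alpha Significance level for the decision column.
#' @return Data frame with columns `p`, `p_adjusted`, `significant`.
#' @export
bonferroni <- function(pvals, m = length(pvals), alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1)) stop("p values must lie in [0, 1]")
  if (m < length(pvals)) stop("m must be at least the number of tests")
  adj <- pmin(1, m * pvals)
  data.frame(p = pvals, p_adjusted = adj, significant = adj < alpha)
}

# ---- split-plot (mixed) ANOVA ----------------------------------------------

# reshape a balanced long table into a participants x sessions matrix plus
# the per-participant condition factor
split_plot_matrix <- function(data, value, participant, condition, session) {
  stopifnot(all(c(value, participant, condition, session) %in% names(data)))
  pid <- as.character(data[[participant]])
  sess <- data[[session]]
  sess_levels <- sort(unique(sess))
  pid_levels <- unique(pid)
  if (nrow(data) != length(pid_levels) * length(sess_levels)) {
    stop("design is not complete and balanced: expected one value per ",
         "participant x session cell")
  }
  Y <- matrix(NA_real_, nrow = length(pid_levels),
              ncol = length(sess_levels),
              dimnames = list(pid_levels, sess_levels))
  Y[cbind(match(pid, pid_levels), match(sess, sess_levels))] <-
    data[[value]]
  if (anyNA(Y)) stop("missing participant x session cells")
  cond <- vapply(pid_levels, function(p) {
    u <- unique(as.character(data[[condition]][pid == p]))
    if (length(u) != 1L) stop("participant '", p, "' appears in >1 condition")
    u
  }, character(1))
  if (any(table(cond) < 2L)) {
    stop("each condition needs at least 2 participants")
  }
  list(Y = Y, cond = factor(cond))
}

#' Split-plot (mixed) ANOVA
#'
#' Classical balanced split-plot decomposition for a design with one
#' between-subjects factor (condition) and one within-subjects factor
#' (session): sums of squares for condition, subjects within condition,
#' session, the condition-by-session interaction, and the within residual.
#' The condition effect is tested against subjects-within-condition; the
#' within effects against the residual.  Partial eta-squared is
#' `SS_effect / (SS_effect + SS_error)` with each effect's own error term.
#'
#' Sphericity is assumed for the default (uncorrected) degrees of freedom,
#' matching common reporting practice; the Greenhouse-Geisser epsilon is
#' always computed and attached as attribute `"gg_epsilon"`, and
#' `sphericity_correction = TRUE` applies it to the within-effect df and
#' p values.
#'
#' Effects whose sum of squares is (numerically) zero are reported with
#' `F = 0`, `p = 1`, including the all-values-identical degenerate case.
#'
#' @param data Long-format data.frame, one row per participant-session.
#' @param value,participant,condition,session Names of the value, subject
#'   identifier, between-factor and within-factor columns.
#' @param sphericity_correction Apply the Greenhouse-Geisser correction to
#'   within-subject effects (default `FALSE`).
#' @return A data.frame of class `anova_table` with columns `effect`, `ss`,
#'   `df1`, `df2`, `ms`, `F`, `p`, `partial_eta_sq`, and attribute
#'   `gg_epsilon`.
#' @export
mixed_anova <- function(data, value = "value", participant = "participant_id",
                        condition = "condition", session = "session",
                        sphericity_correction = FALSE) {
  m <- split_plot_matrix(data, value, participant, condition, session)
  Y <- m$Y
  cond <- m$cond
  N <- nrow(Y)
  k <- ncol(Y)
  c_lv <- levels(cond)
  n_c <- as.numeric(table(cond))

  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  sess_means <- colMeans(Y)
  cond_means <- as.numeric(tapply(subj_means, cond, mean))
  cell_means <- rowsum(Y, cond) / n_c  # conditions x sessions

  ss_cond <- k * sum(n_c * (cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - cond_means[as.integer(cond)])^2)
  ss_sess <- N * sum((sess_means - grand)^2)
  int_dev <- cell_means -
    outer(cond_means, rep(1, k)) -
    outer(rep(1, length(c_lv)), sess_means) + grand
  ss_int <- sum(n_c * rowSums(int_dev^2))
  ss_tot <- sum((Y - grand)^2)
  ss_res <- max(ss_tot - ss_cond - ss_subj - ss_sess - ss_int, 0)

  df <- c(condition = length(c_lv) - 1L,
          subjects = N - length(c_lv),
          session = k - 1L,
          interaction = (length(c_lv) - 1L) * (k - 1L),
          residual = (N - length(c_lv)) * (k - 1L))
  ss <- c(ss_cond, ss_subj, ss_sess, ss_int, ss_res)
  ms <- ss / df

  f_test <- function(ss_eff, df_eff, ss_err, df_err) {
    ss_eff <- unname(ss_eff); df_eff <- unname(df_eff)
    ss_err <- unname(ss_err); df_err <- unname(df_err)
    tol <- 1e-12 * max(ss_tot, 1)
    if (ss_eff <= tol) return(c(F = 0, p = 1))
    if (ss_err <= tol) return(c(F = Inf, p = 0))
    F <- (ss_eff / df_eff) / (ss_err / df_err)
    c(F = F, p = stats::pf(F, df_eff, df_err, lower.tail = FALSE))
  }

  # Greenhouse-Geisser epsilon from the pooled within-condition covariance
  eps <- NA_real_
  if (k > 1L) {
    S <- matrix(0, k, k)
    for (cl in c_lv) {
      Yc <- Y[cond == cl, , drop = FALSE]
      Yc <- sweep(Yc, 2L, colMeans(Yc))
      S <- S + crossprod(Yc)
    }
    S <- S / (N - length(c_lv))
    Sc <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
    denom <- (k - 1) * sum(Sc^2)
    eps <- if (denom > 0) sum(diag(Sc))^2 / denom else 1
    eps <- min(max(eps, 1 / (k - 1)), 1)
  }

  t_cond <- f_test(ss_cond, df[1L], ss_subj, df[2L])
  t_sess <- f_test(ss_sess, df[3L], ss_res, df[5L])
  t_int <- f_test(ss_int, df[4L], ss_res, df[5L])

  df2 <- c(df[2L], NA, df[5L], df[5L], NA)
  Fv <- c(t_cond["F"], NA, t_sess["F"], t_int["F"], NA)
  pv <- c(t_cond["p"], NA, t_sess["p"], t_int["p"], NA)
  if (isTRUE(sphericity_correction) && is.finite(eps)) {
    for (i in c(3L, 4L)) {
      if (is.finite(Fv[i]) && Fv[i] > 0) {
        pv[i] <- stats::pf(Fv[i], eps * df[i], eps * df[5L],
                           lower.tail = FALSE)
      }
    }
  }
  peta <- c(ss_cond / (ss_cond + ss_subj), NA,
            ss_sess / (ss_sess + ss_res), ss_int / (ss_int + ss_res), NA)
  peta[c(1, 3, 4)][ss[c(1, 3, 4)] == 0 & ss[c(2, 5, 5)] == 0] <- 0

  out <- data.frame(
    effect = c("condition", "subjects_within_condition", "session",
               "condition:session", "residual"),
    ss = ss, df1 = as.numeric(df), df2 = df2, ms = ms, F = Fv, p = pv,
    partial_eta_sq = peta)
  rownames(out) <- NULL
  attr(out, "gg_epsilon") <- eps
  attr(out, "sphericity_corrected") <- isTRUE(sphericity_correction)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Orthogonal polynomial coefficients
#'
#' Classical integer orthogonal polynomial contrast coefficients for `k`
#' equally spaced levels (`k` in 3..6); higher `k` falls back to scaled
#' [stats::contr.poly()] columns.  Coefficients of each order sum to zero
#' and are pairwise orthogonal.
#'
#' @param k Number of levels.
#' @param order Polynomial order (1 = linear, 2 = quadratic, 3 = cubic).
#' @return Numeric vector of length `k`.
#' @export
#' @examples
#' poly_contrast_coefs(6, 3) # cubic contrast for 6 sessions
poly_contrast_coefs <- function(k, order) {
  stopifnot(k >= 2, order >= 1, order <= min(3, k - 1))
  tab <- list(
    `3` = list(c(-1, 0, 1), c(1, -2, 1)),
    `4` = list(c(-3, -1, 1, 3), c(1, -1, -1, 1), c(-1, 3, -3, 1)),
    `5` = list(c(-2, -1, 0, 1, 2), c(2, -1, -2, -1, 2), c(-1, 2, 0, -2, 1)),
    `6` = list(c(-5, -3, -1, 1, 3, 5), c(5, -1, -4, -4, -1, 5),
               c(-5, 7, 4, -4, -7, 5)))
  key <- as.character(k)
  if (!is.null(tab[[key]])) return(tab[[key]][[order]])
  stats::contr.poly(k)[, order]
}

#' Polynomial trend contrasts for the within-subject factor
#'
#' Single-df linear/quadratic/cubic contrasts over the (equally spaced)
#' session levels, for designs with an optional between-subjects condition
#' factor.  Each participant's contrast score is
#' `z_i = sum(c_s * y_is) / sqrt(sum(c_s^2))`; the session trend tests the
#' grand mean of `z` and the trend-by-condition interaction tests
#' condition differences in `z`.
#'
#' By default each contrast is tested against its own (contrast-specific)
#' error, the within-condition variance of the contrast scores with
#' `N - c` df — standard repeated-measures practice when sphericity is in
#' doubt.  `error = "pooled"` instead uses the omnibus within-subject
#' residual mean square from the full split-plot decomposition.
#'
#' @inheritParams mixed_anova
#' @param orders Polynomial orders to test (default linear:cubic, limited by
#'   the number of levels).
#' @param error `"contrast_specific"` (default) or `"pooled"`.
#' @return Data frame with one row per order and effect (`session`,
#'   `session:condition`): `order`, `effect`, `ss`, `df1`, `df2`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
trend_contrasts <- function(data, value = "value",
                            participant = "participant_id",
                            condition = "condition", session = "session",
                            orders = 1:3,
                            error = c("contrast_specific", "pooled")) {
  error <- match.arg(error)
  m <- split_plot_matrix(data, value, participant, condition, session)
  Y <- m$Y
  cond <- m$cond
  N <- nrow(Y)
  k <- ncol(Y)
  c_n <- length(levels(cond))
  orders <- orders[orders <= k - 1 & orders <= 3]
  if (length(orders) == 0L) stop("no testable trend orders for k = ", k)
  n_c <- as.numeric(table(cond))

  if (error == "pooled") {
    om <- mixed_anova(data, value, participant, condition, session)
    ms_pooled <- om$ms[om$effect == "residual"]
    df_pooled <- om$df1[om$effect == "residual"]
  }

  ord_names <- c("linear", "quadratic", "cubic")
  out <- do.call(rbind, lapply(orders, function(o) {
    cf <- poly_contrast_coefs(k, o)
    z <- as.numeric(Y %*% cf) / sqrt(sum(cf^2))
    zbar <- mean(z)
    zbar_c <- as.numeric(tapply(z, cond, mean))
    ss_trend <- N * zbar^2
    ss_int <- sum(n_c * (zbar_c - zbar)^2)
    ss_err <- sum((z - zbar_c[as.integer(cond)])^2)
    if (error == "contrast_specific") {
      ms_err <- ss_err / (N - c_n)
      df_err <- N - c_n
    } else {
      ms_err <- ms_pooled
      df_err <- df_pooled
    }
    row <- function(effect, ss, df1) {
      tol <- 1e-12 * max(sum((Y - mean(Y))^2), 1)
      if (ss <= tol) {
        F <- 0; p <- 1
      } else if (ms_err <= tol) {
        F <- Inf; p <- 0
      } else {
        F <- (ss / df1) / ms_err
        p <- stats::pf(F, df1, df_err, lower.tail = FALSE)
      }
      data.frame(order = ord_names[o], effect = effect, ss = ss,
                 df1 = df1, df2 = df_err, F = F, p = p,
                 partial_eta_sq = if (ss + ms_err * df_err > 0)
                   ss / (ss + ms_err * df_err) else 0)
    }
    rbind(row("session", ss_trend, 1),
          if (c_n > 1L) row("session:condition", ss_int, c_n - 1))
  }))
  rownames(out) <- NULL
  out
}
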