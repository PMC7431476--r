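# Scoring of the behavioural tasks: direction estimates, route and
# straight-line distance estimates, sketch maps, pathway completion and
# north pointing.

#' Absolute angular error between two bearings
#'
#' Smallest rotation between the two bearings, in degrees within `[0, 180]`.
#' Symmetric in its arguments and invariant under a common rotation.
#'
#' @param estimated,correct Bearings in degrees (vectorised).
#' @return Absolute angular error(s) in `[0, 180]`.
#' @export
#' @examples
#' absolute_angular_error(10, 350) # 20, across north
absolute_angular_error <- function(estimated, correct) {
  abs(wrap_angle(estimated - correct))
}

#' Score direction estimates on a route
#'
#' Participants imagine standing at one landmark facing as they did when
#' walking, and indicate the direction to another landmark by drawing a line
#' on a circle whose upward line is the facing direction.  Each estimate is
#' therefore an angle relative to the facing bearing at the `from` landmark;
#' it is converted to an absolute compass bearing and compared with the true
#' bearing between the two landmarks.
#'
#' @param route A [route_map()] providing landmark positions and facing
#'   bearings.
#' @param estimates Data frame with columns `from_label`, `to_label` and
#'   `relative_bearing` (degrees clockwise from the facing direction); one
#'   row per landmark pair, all 6 unordered pairs of the 4 landmarks present.
#' @return Mean absolute angular error in degrees.
#' @export
score_directions <- function(route, estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("from_label", "to_label", "relative_bearing") %in%
                  names(estimates)))
  lm <- route_landmarks(route)
  want <- utils::combn(lm, 2L)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- key(estimates$from_label, estimates$to_label)
  missing <- setdiff(key(want[1L, ], want[2L, ]), have)
  if (length(missing) > 0L) {
    stop("missing direction estimate(s) for landmark pair(s): ",
         paste(missing, collapse = ", "))
  }
  err <- vapply(seq_len(nrow(estimates)), function(i) {
    from <- anchor_row(route, estimates$from_label[i])
    correct <- bearing_between(c(from$x, from$y),
                               anchor_row(route, estimates$to_label[i])[, c("x", "y")])
    est_abs <- from$facing + estimates$relative_bearing[i]
    absolute_angular_error(est_abs, correct)
  }, numeric(1))
  mean(err)
}

#' Score distance estimates on a route
#'
#' Distances between the four landmarks (6 pairs) are estimated as ratios to
#' a standard distance walked at the start of each session.  Accuracy is
#' summarised per kind (route vs straight-line) as the Pearson correlation
#' between estimated and correct distances and the mean ratio of estimated
#' to correct distance.
#'
#' @param route A [route_map()].
#' @param estimates Data frame with columns `from_label`, `to_label`,
#'   `kind` (`"route"` or `"straight_line"`) and `ratio_to_standard`
#'   (estimated distance divided by the standard distance, > 0).
#' @param standard_m Length of the standard distance in metres (the study
#'   standard is a 32 m straight path).
#' @return Data frame with one row per kind: `kind`, `correlation`,
#'   `mean_ratio`, `n`.
#' @export
score_distances <- function(route, estimates, standard_m = 32) {
  stopifnot(is.data.frame(estimates), standard_m > 0,
            all(c("from_label", "to_label", "kind", "ratio_to_standard") %in%
                  names(estimates)),
            all(estimates$kind %in% c("route", "straight_line")),
            all(estimates$ratio_to_standard > 0))
  out <- lapply(split(estimates, estimates$kind), function(d) {
    if (nrow(d) < 3L) {
      stop("at least 3 distance estimates per kind are required")
    }
    correct <- vapply(seq_len(nrow(d)), function(i) {
      if (d$kind[i] == "route") {
        route_distance(route, d$from_label[i], d$to_label[i])
      } else {
        straight_distance(route, d$from_label[i], d$to_label[i])
      }
    }, numeric(1))
    if (stats::sd(correct) == 0) {
      stop("correlation undefined: correct distances have zero variance")
    }
    est <- d$ratio_to_standard * standard_m
    data.frame(kind = d$kind[1L],
               correlation = stats::cor(est, correct),
               mean_ratio = mean(est / correct),
               n = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Score one pathway-completion (path-integration) trial
#'
#' After walking a training path blindfolded from `S` to `E`, the
#' participant returns unguided to where they believe `S` is and then points
#' north.  Three scores result: the distance between the stop point and the
#' true start (cm), the angular deviation between the taken and correct
#' return directions (degrees), and the absolute north-pointing error
#' (degrees).
#'
#' @param path A [training_path()].
#' @param stop_point Numeric `c(x, y)` where the participant stopped.
#' @param pointed_north Bearing (degrees, in path coordinates) the
#'   participant pointed to as north.
#' @param direction_method How the return-direction deviation is measured:
#'   `"return_heading"` (default) compares the heading actually taken,
#'   `E -> stop`, with the correct heading `E -> S`; `"start_vector"`
#'   compares the direction of the true start as seen from the stop point,
#'   `stop -> S`, with the correct return heading `E -> S`.
#' @return Named numeric vector `c(distance_deviation_cm,
#'   direction_deviation_deg, north_error_deg)`.
#' @export
score_pathway <- function(path, stop_point, pointed_north,
                          direction_method = c("return_heading",
                                               "start_vector")) {
  direction_method <- match.arg(direction_method)
  stopifnot(inherits(path, "training_path"),
            is.numeric(stop_point), length(stop_point) == 2L,
            all(is.finite(stop_point)))
  s <- path$start
  e <- path$end
  if (all(stop_point == e)) {
    stop("degenerate return: stop point coincides with the path end")
  }
  correct_heading <- bearing_between(e, s)
  taken <- switch(direction_method,
                  return_heading = bearing_between(e, stop_point),
                  start_vector = bearing_between(stop_point, s))
  c(distance_deviation_cm = 100 * sqrt(sum((stop_point - s)^2)),
    direction_deviation_deg = absolute_angular_error(taken, correct_heading),
    north_error_deg = absolute_angular_error(pointed_north,
                                             path$north_bearing))
}

# ---- whole-session / whole-experiment scoring -------------------------------

# extract the sketch point_config for one participant-session block of the
# tidy response table
sketch_from_responses <- function(block) {
  sx <- block[block$task == "sketch_x", ]
  sy <- block[block$task == "sketch_y", ]
  if (nrow(sx) == 0L || nrow(sy) == 0L) return(NULL)
  i <- match(sx$from_label, sy$from_label)
  point_config(sx$from_label, sx$value, sy$value[i])
}

#' Score one participant-session response block
#'
#' @param route The [route_map()] walked in that session.
#' @param block Tidy response rows for one participant and session (see
#'   [read_responses()] for the column layout).
#' @param standard_m Standard distance in metres.
#' @param paths Named list of [training_path()] objects, required when the
#'   block contains pathway-completion responses.
#' @return One-row data.frame of session scores (`mean_abs_direction_error`,
#'   `route_distance_correlation`, `straight_distance_correlation`,
#'   `mean_route_ratio`, `mean_straight_ratio`, `sketch_bidim_r`, and — when
#'   training responses are present — mean `distance_deviation_cm`,
#'   `direction_deviation_deg`, `north_error_deg` over paths and trials).
#' @export
score_session <- function(route, block, standard_m = 32, paths = NULL) {
  out <- data.frame(mean_abs_direction_error = NA_real_,
                    route_distance_correlation = NA_real_,
                    straight_distance_correlation = NA_real_,
                    mean_route_ratio = NA_real_,
                    mean_straight_ratio = NA_real_,
                    sketch_bidim_r = NA_real_,
                    distance_deviation_cm = NA_real_,
                    direction_deviation_deg = NA_real_,
                    north_error_deg = NA_real_)

  dir <- block[block$task == "direction", ]
  if (nrow(dir) > 0L) {
    out$mean_abs_direction_error <- score_directions(
      route, data.frame(from_label = dir$from_label, to_label = dir$to_label,
                        relative_bearing = dir$value))
  }

  dist <- block[block$task %in% c("route_distance", "straight_distance"), ]
  if (nrow(dist) > 0L) {
    est <- data.frame(
      from_label = dist$from_label, to_label = dist$to_label,
      kind = ifelse(dist$task == "route_distance", "route", "straight_line"),
      ratio_to_standard = dist$value)
    sc <- score_distances(route, est, standard_m = standard_m)
    rt <- sc[sc$kind == "route", ]
    st <- sc[sc$kind == "straight_line", ]
    if (nrow(rt) == 1L) {
      out$route_distance_correlation <- rt$correlation
      out$mean_route_ratio <- rt$mean_ratio
    }
    if (nrow(st) == 1L) {
      out$straight_distance_correlation <- st$correlation
      out$mean_straight_ratio <- st$mean_ratio
    }
  }

  sketch <- sketch_from_responses(block)
  if (!is.null(sketch)) {
    ref <- route_anchors(route, sketch$label)
    out$sketch_bidim_r <- bidim_r(ref, sketch)
  }

  pw <- block[startsWith(block$task, "pathway_") | block$task == "north_pointing", ]
  if (nrow(pw) > 0L) {
    if (is.null(paths)) stop("pathway responses present but no training paths given")
    sc <- score_training_block(pw, paths)
    out$distance_deviation_cm <- mean(sc$distance_deviation_cm)
    out$direction_deviation_deg <- mean(sc$direction_deviation_deg)
    out$north_error_deg <- mean(sc$north_error_deg)
  }
  out
}

# one row per path x trial for a participant-session's pathway responses
score_training_block <- function(pw, paths) {
  keys <- unique(pw[, c("from_label", "trial")])
  do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    p <- keys$from_label[i]
    tr <- keys$trial[i]
    rows <- pw[pw$from_label == p & pw$trial == tr, ]
    val <- function(task) rows$value[rows$task == task][1L]
    sc <- score_pathway(paths[[p]],
                        stop_point = c(val("pathway_stop_x"),
                                       val("pathway_stop_y")),
                        pointed_north = val("north_pointing"))
    data.frame(path = p, trial = tr, t(sc))
  }))
}

#' Score a full response table
#'
#' Applies [score_session()] to every participant-session block of a tidy
#' response table, giving the per-participant-session measures analysed by
#' the inferential layer.
#'
#' @param responses Tidy response data.frame with columns `participant_id`,
#'   `condition`, `session`, `task`, `from_label`, `to_label`, `value`,
#'   `trial`.
#' @param routes List of [route_map()] objects indexed by session number.
#' @param paths Optional named list of [training_path()] objects for scoring
#'   pathway-completion responses.
#' @param standard_m Standard distance in metres.
#' @return Data frame with one row per participant-session: identifiers plus
#'   the [score_session()] columns.
#' @export
score_experiment <- function(responses, routes, paths = NULL,
                             standard_m = 32) {
  stopifnot(is.data.frame(responses),
            all(c("participant_id", "condition", "session", "task",
                  "from_label", "to_label", "value", "trial") %in%
                  names(responses)))
  blocks <- split(responses,
                  list(responses$participant_id, responses$session),
                  drop = TRUE)
  out <- do.call(rbind, lapply(blocks, function(b) {
    session <- b$session[1L]
    cbind(data.frame(participant_id = b$participant_id[1L],
                     condition = b$condition[1L],
                     session = session),
          score_session(routes[[session]], b, standard_m = standard_m,
                        paths = paths))
  }))
  out <- out[order(out$condition, out$participant_id, out$session), ]
  rownames(out) <- NULL
  out
}

#' Per-trial training-task scores
#'
#' Scores every pathway-completion trial separately (paths averaged within
#' trial), supporting trial-by-session repeated-measures analyses of the
#' training tasks.
#'
#' @inheritParams score_experiment
#' @return Data frame with one row per participant, session and trial:
#'   `distance_deviation_cm`, `direction_deviation_deg`, `north_error_deg`.
#' @export
score_training <- function(responses, paths) {
  pw <- responses[startsWith(responses$task, "pathway_") |
                    responses$task == "north_pointing", ]
  if (nrow(pw) == 0L) return(NULL)
  blocks <- split(pw, list(pw$participant_id, pw$session), drop = TRUE)
  out <- do.call(rbind, lapply(blocks, function(b) {
    sc <- score_training_block(b, paths)
    agg <- aggregate(sc[, c("distance_deviation_cm", "direction_deviation_deg",
                            "north_error_deg")],
                     by = list(trial = sc$trial), FUN = mean)
    cbind(data.frame(participant_id = b$participant_id[1L],
                     condition = b$condition[1L],
                     session = b$session[1L]),
          agg)
  }))
  rownames(out) <- NULL
  out
}

#' Read / write a tidy response table
#'
#' The CSV layout has one row per elementary response: columns
#' `participant_id`, `condition`, `session`, `task`, `from_label`,
#' `to_label`, `value`, `trial`.  Tasks are `direction` (degrees relative to
#' the facing direction), `route_distance` / `straight_distance` (ratio to
#' the standard distance), `sketch_x` / `sketch_y` (page coordinates of one
#' anchor), `pathway_stop_x` / `pathway_stop_y` (metres, path coordinates)
#' and `north_pointing` (absolute bearing in path coordinates).
#'
#' @param path CSV file path.
#' @param responses Tidy response data.frame.
#' @return `read_responses` returns the data.frame; `write_responses`
#'   returns `path` invisibly.
#' @export
read_responses <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "session", "task", "from_label",
            "to_label", "value", "trial")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("response table lacks column(s): ", paste(miss, collapse = ", "))
  }
  d
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}
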