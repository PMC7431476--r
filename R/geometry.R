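# Planar geometry for walked routes and training paths.
#
# All coordinates are metres in a local planar frame (x east-positive,
# y north-positive); routes are short enough (<= 1 km) that no geodesy is
# needed.  Bearings follow the map/compass convention: degrees clockwise
# from north, normalised to [0, 360).

#' Normalise a bearing to [0, 360)
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Numeric vector of bearings in `[0, 360)`.
#' @export
#' @examples
#' normalize_bearing(c(-90, 370))
normalize_bearing <- function(deg) {
  stopifnot(is.numeric(deg))
  deg %% 360
}

#' Wrap an angle difference to (-180, 180]
#'
#' @param deg Numeric vector of angle differences in degrees.
#' @return Numeric vector in `(-180, 180]`.
#' @export
wrap_angle <- function(deg) {
  w <- deg %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Compass bearing from one point to another
#'
#' Bearing of `b` as seen from `a`, in degrees clockwise from north.
#'
#' @param a,b Points: numeric vectors `c(x, y)` or two-column matrices of
#'   equal row count (vectorised).
#' @return Bearing(s) in `[0, 360)`.
#' @export
#' @examples
#' bearing_between(c(0, 0), c(0, 1)) # due north -> 0
#' bearing_between(c(0, 0), c(1, 0)) # due east  -> 90
bearing_between <- function(a, b) {
  a <- as_xy_matrix(a)
  b <- as_xy_matrix(b)
  dx <- b[, 1] - a[, 1]
  dy <- b[, 2] - a[, 2]
  if (any(dx == 0 & dy == 0)) {
    stop("degenerate geometry: coincident points have no bearing")
  }
  normalize_bearing(atan2(dx, dy) * 180 / pi)
}

# coerce c(x, y) or an n x 2 matrix/data.frame to a matrix
as_xy_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  if (is.null(dim(p))) {
    stopifnot(length(p) == 2L)
    p <- matrix(p, ncol = 2L)
  }
  stopifnot(is.numeric(p), ncol(p) == 2L, all(is.finite(p)))
  p
}

#' Length of a polyline
#'
#' @param vertices Two-column matrix (or data.frame with columns `x`, `y`) of
#'   ordered vertices.
#' @return Total length in metres.
#' @export
#' @examples
#' polyline_length(rbind(c(0, 0), c(3, 4))) # 5
polyline_length <- function(vertices) {
  v <- as_xy_matrix(vertices)
  if (nrow(v) < 2L) stop("a polyline needs at least 2 vertices")
  sum(sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)))
}

# cumulative arc length at each vertex
cum_arc_length <- function(v) {
  seg <- sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# distance from point p to segment (s1, s2) and arc fraction of the foot point
point_segment_projection <- function(p, s1, s2) {
  d <- s2 - s1
  len2 <- sum(d^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - s1) * d) / len2))
  foot <- s1 + t * d
  list(dist = sqrt(sum((p - foot)^2)), t = t)
}

# arc-length position along polyline `v` of the projection of point `p`,
# together with the projection distance and segment index
project_onto_polyline <- function(p, v) {
  arc <- cum_arc_length(v)
  best <- list(dist = Inf, s = NA_real_, seg = NA_integer_)
  for (i in seq_len(nrow(v) - 1L)) {
    pr <- point_segment_projection(p, v[i, ], v[i + 1L, ])
    if (pr$dist < best$dist) {
      best <- list(dist = pr$dist,
                   s = arc[i] + pr$t * (arc[i + 1L] - arc[i]),
                   seg = i)
    }
  }
  best
}

#' Construct a route map
#'
#' A `route_map` is a polyline walked from start to goal together with
#' labelled anchor points (start, goal, landmarks, turns).  Each anchor must
#' lie on the polyline (within `tolerance`); landmarks carry the facing
#' bearing of the walker when first encountering them, which defaults to the
#' bearing of the polyline segment being walked at that anchor.
#'
#' @param vertices Two-column matrix of polyline vertices (start to goal).
#' @param anchors Data frame with columns `label`, `x`, `y` and optionally
#'   `facing` (degrees clockwise from north; `NA` to use the local segment
#'   bearing).
#' @param name Optional route name.
#' @param n_turns Expected number of interior turn vertices, checked when
#'   non-`NULL`.  Study-style routes have 5.
#' @param tolerance Maximum allowed distance (m) from an anchor to the
#'   polyline.  Default 0.5 m accommodates hand-digitised fixtures.
#' @return An object of class `route_map` with the anchors ordered by
#'   walking order and annotated with their arc-length position `arc` and
#'   resolved `facing` bearing.
#' @export
route_map <- function(vertices, anchors, name = "route", n_turns = NULL,
                      tolerance = 0.5) {
  v <- as_xy_matrix(vertices)
  if (nrow(v) < 2L) stop("a route needs at least 2 vertices")
  total <- polyline_length(v)
  if (total <= 0) stop("route polyline has zero length")
  if (!is.null(n_turns) && nrow(v) - 2L != n_turns) {
    stop(sprintf("expected %d interior turn vertices, found %d",
                 n_turns, nrow(v) - 2L))
  }
  stopifnot(is.data.frame(anchors),
            all(c("label", "x", "y") %in% names(anchors)))
  if (anyDuplicated(anchors$label)) stop("anchor labels must be unique")
  if (is.null(anchors$facing)) anchors$facing <- NA_real_

  seg_bearings <- bearing_between(v[-nrow(v), , drop = FALSE],
                                  v[-1L, , drop = FALSE])
  arc <- numeric(nrow(anchors))
  facing <- numeric(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    pr <- project_onto_polyline(c(anchors$x[i], anchors$y[i]), v)
    if (pr$dist > tolerance) {
      stop(sprintf("anchor '%s' lies %.2f m off the polyline (tolerance %.2f m)",
                   anchors$label[i], pr$dist, tolerance))
    }
    arc[i] <- pr$s
    facing[i] <- if (is.na(anchors$facing[i])) seg_bearings[pr$seg] else
      normalize_bearing(anchors$facing[i])
  }
  anchors$arc <- arc
  anchors$facing <- facing
  anchors <- anchors[order(anchors$arc), , drop = FALSE]
  rownames(anchors) <- NULL

  structure(list(name = name, vertices = v, anchors = anchors,
                 length_m = total),
            class = "route_map")
}

#' @export
print.route_map <- function(x, ...) {
  cat(sprintf("<route_map '%s': %.1f m, %d vertices, %d anchors>\n",
              x$name, x$length_m, nrow(x$vertices), nrow(x$anchors)))
  invisible(x)
}

anchor_row <- function(route, label) {
  i <- match(label, route$anchors$label)
  if (is.na(i)) stop(sprintf("unknown anchor label '%s'", label))
  route$anchors[i, , drop = FALSE]
}

#' Anchor coordinates of a route
#'
#' @param route A `route_map`.
#' @param labels Anchor labels; default all anchors in walking order.
#' @return A [point_config()] of the requested anchors.
#' @export
route_anchors <- function(route, labels = route$anchors$label) {
  i <- match(labels, route$anchors$label)
  if (anyNA(i)) stop("unknown anchor label(s): ",
                     paste(labels[is.na(i)], collapse = ", "))
  point_config(labels, route$anchors$x[i], route$anchors$y[i])
}

#' Landmark labels of a route, in walking order
#'
#' Landmarks are the anchors whose labels start with `"L"`.
#'
#' @param route A `route_map`.
#' @return Character vector of landmark labels.
#' @export
route_landmarks <- function(route) {
  a <- route$anchors
  a$label[startsWith(a$label, "L")]
}

#' Along-route distance between two anchors
#'
#' Arc length along the route polyline from anchor `label_a` to anchor
#' `label_b`, which must follow it in walking order.
#'
#' @param route A `route_map`.
#' @param label_a,label_b Anchor labels, `label_a` walked before `label_b`.
#' @return Distance in metres; always at least the straight-line distance.
#' @export
route_distance <- function(route, label_a, label_b) {
  a <- anchor_row(route, label_a)
  b <- anchor_row(route, label_b)
  if (b$arc < a$arc) {
    stop(sprintf("'%s' precedes '%s' in walking order", label_b, label_a))
  }
  b$arc - a$arc
}

#' Straight-line distance between two anchors
#'
#' @inheritParams route_distance
#' @return Euclidean distance in metres.
#' @export
straight_distance <- function(route, label_a, label_b) {
  a <- anchor_row(route, label_a)
  b <- anchor_row(route, label_b)
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

# ---- training paths ---------------------------------------------------------

# TRUE when open segments (p1,p2) and (q1,q2) properly intersect
segments_intersect <- function(p1, p2, q1, q2) {
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  d1 <- cross(q1, q2, p1)
  d2 <- cross(q1, q2, p2)
  d3 <- cross(p1, p2, q1)
  d4 <- cross(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Construct a training path
#'
#' Short vista-scale paths used for pathway-completion (path-integration)
#' practice: walked from start `S` to end `E`, after which the walker must
#' return directly to `S`.  Closing the figure makes a triangle (2 walked
#' segments), a quadrilateral (3 walked segments), or a crossing shape whose
#' return segment `E -> S` crosses an earlier walked segment.
#'
#' @param shape One of `"triangle"`, `"quadrilateral"`, `"crossing"`.
#' @param vertices Two-column matrix of walked vertices from S to E.
#' @param north_bearing Direction of north in path coordinates (degrees);
#'   used to score the north-pointing task.
#' @param name Optional path name.
#' @return An object of class `training_path`.
#' @export
training_path <- function(shape = c("triangle", "quadrilateral", "crossing"),
                          vertices, north_bearing = 0, name = shape) {
  shape <- match.arg(shape)
  v <- as_xy_matrix(vertices)
  if (nrow(v) < 3L) stop("a training path needs at least 2 walked segments")
  n <- nrow(v)
  if (shape == "triangle" && n != 3L) {
    stop("a triangle path has exactly 2 walked segments")
  }
  if (shape == "quadrilateral" && n != 4L) {
    stop("a quadrilateral path has exactly 3 walked segments")
  }
  if (shape == "crossing") {
    s <- v[1L, ]
    e <- v[n, ]
    crosses <- any(vapply(seq_len(n - 2L), function(i) {
      segments_intersect(e, s, v[i, ], v[i + 1L, ])
    }, logical(1)))
    if (!crosses) {
      stop("crossing path: return segment E->S does not cross a walked segment")
    }
  }
  structure(list(name = name, shape = shape, vertices = v,
                 north_bearing = normalize_bearing(north_bearing),
                 start = v[1L, ], end = v[n, ]),
            class = "training_path")
}

#' @export
print.training_path <- function(x, ...) {
  cat(sprintf("<training_path '%s' (%s): %d walked segments>\n",
              x$name, x$shape, nrow(x$vertices) - 1L))
  invisible(x)
}

# ---- file formats -----------------------------------------------------------

#' Write / read a route as JSON
#'
#' The on-disk form is `{name, vertices: [[x, y], ...],
#' anchors: {label: {xy: [x, y], facing: deg}}, n_turns}`; the reader
#' re-validates all route invariants.
#'
#' @param route A `route_map`.
#' @param path File path.
#' @return `read_route_json` returns a `route_map`; `write_route_json`
#'   returns `path` invisibly.
#' @export
write_route_json <- function(route, path) {
  anchors <- lapply(seq_len(nrow(route$anchors)), function(i) {
    list(xy = c(route$anchors$x[i], route$anchors$y[i]),
         facing = route$anchors$facing[i])
  })
  names(anchors) <- route$anchors$label
  obj <- list(name = route$name,
              vertices = unname(apply(route$vertices, 1L, c, simplify = FALSE)),
              anchors = anchors,
              n_turns = nrow(route$vertices) - 2L)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_route_json
#' @export
read_route_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  v <- do.call(rbind, lapply(obj$vertices, function(p) as.numeric(unlist(p))))
  anchors <- data.frame(
    label = names(obj$anchors),
    x = vapply(obj$anchors, function(a) as.numeric(a$xy[[1]]), numeric(1)),
    y = vapply(obj$anchors, function(a) as.numeric(a$xy[[2]]), numeric(1)),
    facing = vapply(obj$anchors, function(a) {
      if (is.null(a$facing)) NA_real_ else as.numeric(a$facing)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  route_map(v, anchors, name = obj$name %||% "route",
            n_turns = obj$n_turns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a route as GeoJSON for visualisation
#'
#' Writes a `FeatureCollection` holding the route polyline (`LineString`)
#' and one labelled `Point` per anchor, in local planar coordinates.
#'
#' @inheritParams write_route_json
#' @return `path`, invisibly.
#' @export
route_to_geojson <- function(route, path) {
  features <- c(
    list(list(type = "Feature",
              properties = list(name = route$name, kind = "route"),
              geometry = list(
                type = "LineString",
                coordinates = unname(apply(route$vertices, 1L, c,
                                           simplify = FALSE))))),
    lapply(seq_len(nrow(route$anchors)), function(i) {
      list(type = "Feature",
           properties = list(label = route$anchors$label[i],
                             facing = route$anchors$facing[i],
                             kind = "anchor"),
           geometry = list(type = "Point",
                           coordinates = c(route$anchors$x[i],
                                           route$anchors$y[i])))
    })
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
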