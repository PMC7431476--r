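# Euclidean bidimensional regression (Tobler) between two labelled planar
# point configurations, used to score sketch maps against a correct map.

#' Construct a labelled point configuration
#'
#' @param label Character vector of unique point labels.
#' @param x,y Numeric coordinates (any planar unit; sketch maps are typically
#'   in arbitrary page units).
#' @return A data.frame of class `point_config` with columns `label`, `x`, `y`.
#' @export
point_config <- function(label, x, y) {
  label <- as.character(label)
  stopifnot(length(label) == length(x), length(x) == length(y))
  if (anyDuplicated(label)) stop("point labels must be unique")
  structure(data.frame(label = label, x = as.numeric(x), y = as.numeric(y),
                       stringsAsFactors = FALSE),
            class = c("point_config", "data.frame"))
}

#' Read / write a point configuration as CSV
#'
#' The file has columns `label,x,y`.
#'
#' @param path File path.
#' @param config A [point_config()].
#' @return `read_point_config` returns a `point_config`;
#'   `write_point_config` returns `path` invisibly.
#' @export
read_point_config <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y") %in% names(d)))
  point_config(d$label, d$x, d$y)
}

#' @rdname read_point_config
#' @export
write_point_config <- function(config, path) {
  utils::write.csv(as.data.frame(config)[, c("label", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Fit a Euclidean bidimensional regression
#'
#' Least-squares similarity transform (uniform scale, rotation, translation;
#' reflections disallowed by default) taking the drawn configuration onto the
#' reference configuration, following Tobler's bidimensional regression.  The
#' bidimensional correlation is `r = sqrt(1 - SSE/SST)` with SST taken about
#' the reference centroid, so `r` lies in `[0, 1]` and equals 1 exactly when
#' the drawn configuration is a similarity transform of the reference.
#'
#' The fit is closed form: writing the centred configurations as complex
#' vectors, the optimal rotation-and-scale is the complex regression slope
#' `sum(Conj(x) * y) / sum(Mod(x)^2)`.
#'
#' Points with missing coordinates in either configuration are dropped
#' pairwise with a warning; at least 3 pairs must remain.
#'
#' @param reference [point_config()] of the true coordinates.
#' @param drawn [point_config()] with the same labels in the same order.
#' @param allow_reflection If `TRUE`, also fit the reflected (indirect)
#'   similarity and keep the better of the two; useful as a diagnostic for
#'   mirror-image sketches.  Default `FALSE`, standard sketch-map practice.
#' @return A list of class `similarity_fit` with elements `scale`,
#'   `rotation` (degrees counterclockwise applied to the drawn configuration),
#'   `translation` (length-2 numeric), `r`, `sse`, `sst`, `n` (pairs used)
#'   and `reflected`.
#' @seealso [bidim_r()] for the correlation alone.
#' @export
#' @examples
#' ref <- point_config(letters[1:4], c(0, 1, 1, 0), c(0, 0, 1, 1))
#' fit_similarity(ref, ref)$r # identity -> 1
fit_similarity <- function(reference, drawn, allow_reflection = FALSE) {
  stopifnot(inherits(reference, "point_config") || is.data.frame(reference),
            inherits(drawn, "point_config") || is.data.frame(drawn))
  if (nrow(reference) != nrow(drawn) ||
      !all(reference$label == drawn$label)) {
    stop("reference and drawn configurations must share labels in order")
  }
  ok <- stats::complete.cases(reference$x, reference$y, drawn$x, drawn$y)
  if (!all(ok)) {
    warning(sprintf("dropping %d point pair(s) with missing coordinates",
                    sum(!ok)))
  }
  if (sum(ok) < 3L) stop("fitting requires at least 3 complete point pairs")

  y <- complex(real = reference$x[ok], imaginary = reference$y[ok])
  x <- complex(real = drawn$x[ok], imaginary = drawn$y[ok])
  yc <- y - mean(y)
  xc <- x - mean(x)
  sst <- sum(Mod(yc)^2)
  ssx <- sum(Mod(xc)^2)
  if (sst == 0) stop("undefined correlation: reference points all coincide")
  if (ssx == 0) stop("degenerate fit: drawn points all coincide")

  solve_slope <- function(xc) {
    b <- sum(Conj(xc) * yc) / sum(Mod(xc)^2)
    list(b = b, sse = sum(Mod(yc - b * xc)^2))
  }
  fit <- solve_slope(xc)
  reflected <- FALSE
  if (allow_reflection) {
    # reflect the drawn configuration about the x axis, then direct fit
    refl <- solve_slope(Conj(xc))
    if (refl$sse < fit$sse) {
      fit <- refl
      xc <- Conj(xc)
      x <- Conj(x)
      reflected <- TRUE
    }
  }
  b <- fit$b
  sse <- max(fit$sse, 0)
  a <- mean(y) - b * mean(x)
  r <- sqrt(max(0, 1 - sse / sst))

  structure(list(scale = Mod(b),
                 rotation = if (Mod(b) > 0) Arg(b) * 180 / pi else NA_real_,
                 translation = c(Re(a), Im(a)),
                 r = r, sse = sse, sst = sst, n = sum(ok),
                 reflected = reflected),
            class = "similarity_fit")
}

#' @export
print.similarity_fit <- function(x, ...) {
  cat(sprintf(paste0("<similarity_fit: r = %.4f, scale = %.4g, ",
                     "rotation = %.2f deg, n = %d%s>\n"),
              x$r, x$scale, x$rotation, x$n,
              if (x$reflected) ", reflected" else ""))
  invisible(x)
}

#' Bidimensional correlation between two configurations
#'
#' Convenience wrapper around [fit_similarity()] returning only the
#' bidimensional correlation coefficient, which ranges from 0 to 1 with
#' larger values indicating greater configural correspondence.
#'
#' @inheritParams fit_similarity
#' @return The correlation `r` in `[0, 1]`.
#' @export
bidim_r <- function(reference, drawn, allow_reflection = FALSE) {
  fit_similarity(reference, drawn, allow_reflection = allow_reflection)$r
}

#' Apply a similarity transform to a point configuration
#'
#' Helper for constructing test cases and simulated sketches: rotates by
#' `rotation` degrees counterclockwise, scales by `scale`, then translates.
#'
#' @param config A [point_config()].
#' @param scale Positive scale factor.
#' @param rotation Rotation in degrees (counterclockwise).
#' @param translation Length-2 numeric offset.
#' @param reflect If `TRUE`, reflect about the x axis first.
#' @return The transformed `point_config`.
#' @export
transform_config <- function(config, scale = 1, rotation = 0,
                             translation = c(0, 0), reflect = FALSE) {
  z <- complex(real = config$x, imaginary = if (reflect) -config$y else config$y)
  b <- scale * exp(1i * rotation * pi / 180)
  w <- b * z + complex(real = translation[1], imaginary = translation[2])
  point_config(config$label, Re(w), Im(w))
}
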