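#' Least-squares circle fit (Taubin method)
#'
#' Fits a circle to 2-D points by Taubin's algebraic method: the data are
#' centered, the design `[ (z - mean z)/(2 sqrt(mean z)), u, v ]` with
#' `z = u^2 + v^2` is decomposed by SVD, and the smallest right singular
#' vector gives the circle parameters. The fit is deterministic, exact on
#' noiseless circles (including the three-point circumcircle), and nearly
#' unbiased at small noise.
#'
#' Interface arcs can be almost flat (the membrane-condensate interface of a
#' partially wetted vesicle): when the fitted radius exceeds
#' `line_radius_factor` times the point-cloud extent the fit degrades
#' numerically, so a total-least-squares line model is returned instead
#' (`is_line = TRUE`), provided `allow_line` is set.
#'
#' @param points A data frame with `x` and `y` columns, or a two-column
#'   matrix; at least 3 points.
#' @param allow_line Return a line model for (near-)collinear points instead
#'   of erroring.
#' @param line_radius_factor Radius-to-extent ratio beyond which the arc is
#'   treated as flat (default 1000). The fallback exists for genuinely flat
#'   interfaces: a chord-end tangent read from a line model is wrong by
#'   `asin(extent / (2 radius))`, so the cut must sit where that error is
#'   negligible (< 0.03 degrees at the default), not merely where the arc
#'   looks shallow.
#' @return A `circle_fit` object: `center` (x, y), `radius`, `rms_residual`,
#'   `is_line`, and for line models `line_point` and `line_dir` (unit
#'   vector); `n` points used.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 100)
#' fit_circle(data.frame(x = 3 + 5 * cos(th), y = -1 + 5 * sin(th)))
#' @export
fit_circle <- function(points, allow_line = TRUE, line_radius_factor = 1000) {
  xy <- as_xy_matrix(points)
  n <- nrow(xy)
  if (n < 3L) abort("Need at least 3 points to fit a circle.")
  ctr <- colMeans(xy)
  u <- xy[, 1] - ctr[1]
  v <- xy[, 2] - ctr[2]
  z <- u^2 + v^2
  zm <- mean(z)
  extent <- max(diff(range(xy[, 1])), diff(range(xy[, 2])))
  if (zm == 0) abort("All points coincide; cannot fit a circle.")

  Z0 <- (z - zm) / (2 * sqrt(zm))
  sv <- svd(cbind(Z0, u, v), nu = 0)
  abc <- sv$v[, 3]
  A <- abc[1] / (2 * sqrt(zm))
  B <- abc[2]
  C <- abc[3]
  D <- -zm * A

  flat <- FALSE
  if (abs(A) < .Machine$double.eps * 1e2) {
    flat <- TRUE
  } else {
    radius <- sqrt(B^2 + C^2 - 4 * A * D) / (2 * abs(A))
    flat <- radius > line_radius_factor * extent
  }

  if (flat) {
    if (!allow_line) abort("Points are (near-)collinear and `allow_line` is FALSE.")
    return(fit_line_tls(xy))
  }

  cx <- -B / (2 * A) + ctr[1]
  cy <- -C / (2 * A) + ctr[2]
  dist_to <- sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2)
  rms <- sqrt(mean((dist_to - radius)^2))
  new_circle_fit(center = c(cx, cy), radius = radius, rms_residual = rms, n = n)
}

# total-least-squares line through the centroid (principal direction)
fit_line_tls <- function(xy) {
  ctr <- colMeans(xy)
  sv <- svd(sweep(xy, 2, ctr), nu = 0)
  dir <- sv$v[, 1]
  nrm <- sv$v[, 2]
  res <- as.vector(sweep(xy, 2, ctr) %*% nrm)
  new_circle_fit(
    center = c(NA_real_, NA_real_), radius = Inf,
    rms_residual = sqrt(mean(res^2)), n = nrow(xy),
    is_line = TRUE, line_point = ctr, line_dir = dir
  )
}

new_circle_fit <- function(center, radius, rms_residual, n,
                           is_line = FALSE, line_point = NULL, line_dir = NULL) {
  structure(
    list(center = center, radius = radius, rms_residual = rms_residual,
         n = n, is_line = is_line, line_point = line_point,
         line_dir = line_dir),
    class = "circle_fit"
  )
}

as_xy_matrix <- function(points) {
  if (is.data.frame(points)) {
    if (is.null(points$x) || is.null(points$y)) {
      abort("`points` must have `x` and `y` columns.")
    }
    xy <- cbind(points$x, points$y)
  } else if (is.matrix(points) && ncol(points) == 2L) {
    xy <- points
  } else {
    abort("`points` must be a data frame with x/y or a two-column matrix.")
  }
  if (anyNA(xy)) abort("`points` contains NA coordinates.")
  storage.mode(xy) <- "double"
  xy
}

#' @export
print.circle_fit <- function(x, ...) {
  if (x$is_line) {
    cat(sprintf(
      "<circle_fit: line> through (%.4g, %.4g), direction (%.4g, %.4g), rms %.3g (n=%d)\n",
      x$line_point[1], x$line_point[2], x$line_dir[1], x$line_dir[2],
      x$rms_residual, x$n
    ))
  } else {
    cat(sprintf(
      "<circle_fit> center (%.4g, %.4g), radius %.4g, rms %.3g (n=%d)\n",
      x$center[1], x$center[2], x$radius, x$rms_residual, x$n
    ))
  }
  invisible(x)
}

#' @export
tidy.circle_fit <- function(x, ...) {
  tibble(
    center_x = x$center[1], center_y = x$center[2], radius = x$radius,
    is_line = x$is_line, rms_residual = x$rms_residual, n = x$n
  )
}

#' @export
glance.circle_fit <- function(x, ...) {
  tibble(rms_residual = x$rms_residual, n = x$n, is_line = x$is_line)
}
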