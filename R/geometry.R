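# Per-plane planar calibration: a 6-parameter affine map fitted from the
# three user-selected point correspondences between the camera image and
# the pre-loaded radiograph.
#
# Conventions: points are length-2 numeric c(x, y), 0-based, origin at the
# top-left pixel corner, x = column (rightward), y = row (downward).
# An affine transform is a 2x3 matrix [[a, b, tx], [c, d, ty]] of class
# "affine2d" mapping (x, y) -> (a x + b y + tx, c x + d y + ty).

#' Construct a 2-D affine transform
#'
#' @param m numeric 2x3 matrix `[[a, b, tx], [c, d, ty]]`.
#' @return An object of class `affine2d` (the matrix itself).
#' @export
affine2d <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 3L)) || any(!is.finite(m)))
    ft_stop("affine transform must be a finite 2x3 matrix",
            "fluorotrack_invalid_input")
  structure(m, class = "affine2d")
}

#' Identity affine transform
#' @return An `affine2d` equal to the identity map.
#' @export
identity_affine <- function() {
  affine2d(cbind(diag(2), c(0, 0)))
}

#' Fit the camera-to-radiograph affine transform from 3 correspondences
#'
#' Three point correspondences exactly determine the 6 parameters of a
#' planar affine map, so the fit is a direct linear solve (two 3x3
#' systems, one per output coordinate), not a least-squares problem.
#'
#' @param src 3x2 matrix of camera points (rows are `(x, y)`).
#' @param dst 3x2 matrix of the matched radiograph points.
#' @return An [affine2d()] transform `t` with `apply_affine(t, src) == dst`
#'   to numerical precision.
#' @details The source triangle must be non-degenerate: if twice its
#'   signed area falls below `1e-6` px^2 a condition of class
#'   `fluorotrack_collinear_points` is raised.
#' @examples
#' tr <- fit_affine(rbind(c(0, 0), c(1, 0), c(0, 1)),
#'                  rbind(c(5, -3), c(6, -3), c(5, -2)))
#' apply_affine(tr, c(2, 2))  # translated by (5, -3)
#' @export
fit_affine <- function(src, dst) {
  src <- as_points3(src, "src")
  dst <- as_points3(dst, "dst")
  # twice the signed triangle area of the source points
  area2 <- (src[2, 1] - src[1, 1]) * (src[3, 2] - src[1, 2]) -
           (src[3, 1] - src[1, 1]) * (src[2, 2] - src[1, 2])
  if (abs(area2) < 1e-6)
    ft_stop("source points are collinear (triangle area below tolerance)",
            "fluorotrack_collinear_points")
  A <- cbind(src, 1)            # 3x3: rows (x, y, 1)
  coef <- solve(A, dst)         # 3x2: columns (a, b, tx) and (c, d, ty)
  affine2d(rbind(c(coef[1, 1], coef[2, 1], coef[3, 1]),
                 c(coef[1, 2], coef[2, 2], coef[3, 2])))
}

#' Apply an affine transform to points
#'
#' @param t an [affine2d()] transform.
#' @param p a length-2 point `c(x, y)` or an n x 2 matrix of points.
#' @return A point (or n x 2 matrix) in the target image.
#' @export
apply_affine <- function(t, p) {
  t <- as_affine(t)
  if (is.null(dim(p))) {
    ft_assert_finite(p, "point")
    if (length(p) != 2L)
      ft_stop("point must have length 2", "fluorotrack_invalid_input")
    return(as.vector(t[, 1:2] %*% p + t[, 3]))
  }
  p <- as.matrix(p)
  ft_assert_finite(p, "points")
  sweep(p %*% t(t[, 1:2, drop = FALSE]), 2, t[, 3], `+`)
}

#' Invert an affine transform
#'
#' Needed to map radiograph annotations back into camera space. Raises a
#' `fluorotrack_singular_transform` condition when the linear part has
#' `|det| < 1e-12`.
#'
#' @param t an [affine2d()] transform.
#' @return The inverse transform.
#' @export
invert_affine <- function(t) {
  t <- as_affine(t)
  L <- t[, 1:2, drop = FALSE]
  if (abs(det(L)) < 1e-12)
    ft_stop("affine transform is singular", "fluorotrack_singular_transform")
  Linv <- solve(L)
  affine2d(cbind(Linv, -Linv %*% t[, 3]))
}

#' Compose two affine transforms
#'
#' @param t2,t1 transforms; the result applies `t1` first, then `t2`.
#' @return The composite transform `t2 %then% t1`.
#' @export
compose_affine <- function(t2, t1) {
  t1 <- as_affine(t1); t2 <- as_affine(t2)
  affine2d(cbind(t2[, 1:2] %*% t1[, 1:2],
                 t2[, 1:2] %*% t1[, 3] + t2[, 3]))
}

#' Read / write a plane calibration as JSON
#'
#' The file holds `plane` ("AP" or "CTL"), the 3 `src` camera points, the
#' 3 matched `dst` radiograph points, the coordinate convention, and the
#' fitted `matrix` (recomputed from the correspondences when absent on
#' input, always present on output).
#'
#' @param path JSON file path.
#' @return `read_calibration`: a list with elements `plane`, `src`, `dst`
#'   (3x2 matrices) and `matrix` (an [affine2d()]).
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::fromJSON(path)
  src <- as_points3(obj$src, "src")
  dst <- as_points3(obj$dst, "dst")
  tr <- if (!is.null(obj$matrix)) affine2d(obj$matrix) else fit_affine(src, dst)
  list(plane = match.arg(obj$plane, c("AP", "CTL")),
       src = src, dst = dst, matrix = tr)
}

#' @rdname read_calibration
#' @param calib a list as returned by [read_calibration()], or with
#'   `matrix` missing (it is fitted before writing).
#' @export
write_calibration <- function(calib, path) {
  tr <- if (!is.null(calib$matrix)) as_affine(calib$matrix) else
    fit_affine(calib$src, calib$dst)
  obj <- list(plane = match.arg(calib$plane, c("AP", "CTL")),
              coords = "0-based, x=column, y=row, origin top-left",
              src = unclass(as_points3(calib$src, "src")),
              dst = unclass(as_points3(calib$dst, "dst")),
              matrix = unclass(tr))
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor",
                       auto_unbox = TRUE)
  invisible(path)
}

as_affine <- function(t) {
  if (inherits(t, "affine2d")) t else affine2d(t)
}

as_points3 <- function(p, what) {
  p <- as.matrix(p)
  if (!all(dim(p) == c(3L, 2L)) || any(!is.finite(p)))
    ft_stop(sprintf("%s must be a finite 3x2 point matrix", what),
            "fluorotrack_invalid_input")
  dimnames(p) <- NULL
  p
}
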