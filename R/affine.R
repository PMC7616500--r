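#' Planar affine transforms (SVG/TrakEM2 convention)
#'
#' A 2D affine transform is held as the six coefficients \code{(a, b, c, d,
#' e, f)} of the SVG / TrakEM2 \code{matrix(a,b,c,d,e,f)} convention, mapping
#' a point \code{(x, y)} to \code{(a*x + c*y + e, b*x + d*y + f)}. Throughout
#' the package \code{x} is the image column and \code{y} the image row, both
#' 0-based full-resolution pixels (the Space Ranger convention).
#'
#' @param a,b,c,d Unitless linear coefficients.
#' @param e,f Pixel translation offsets.
#' @return An object of class \code{affine2d}.
#' @examples
#' t <- affine2d(0, 1, -1, 0, 10, 0)   # 90 degree rotation + translation
#' apply_affine(t, cbind(1, 0))        # -> (10, 1)
#' @export
affine2d <- function(a, b, c, d, e, f) {
  for (nm in c("a", "b", "c", "d", "e", "f")) {
    assert_scalar_number(get(nm), nm)
  }
  det <- a * d - b * c
  if (abs(det) < 1e-12) {
    stop("singular affine transform: determinant a*d - b*c is zero", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d, e = e, f = f),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("affine2d: matrix(%g,%g,%g,%g,%g,%g)\n",
              x$a, x$b, x$c, x$d, x$e, x$f))
  invisible(x)
}

#' @rdname affine2d
#' @export
affine_identity <- function() affine2d(1, 0, 0, 1, 0, 0)

#' @rdname affine2d
#' @param tx,ty Translation in pixels.
#' @export
affine_translation <- function(tx, ty) affine2d(1, 0, 0, 1, tx, ty)

#' @export
as.matrix.affine2d <- function(x, ...) {
  matrix(c(x$a, x$c, x$e,
           x$b, x$d, x$f,
           0,   0,   1), nrow = 3, byrow = TRUE)
}

is_affine2d <- function(x) inherits(x, "affine2d")

#' Apply an affine transform to points
#'
#' @param t An \code{\link{affine2d}} transform.
#' @param points A two-column numeric matrix of \code{(x, y)} coordinates
#'   (column, row order, 0-based pixels).
#' @return A two-column matrix of transformed \code{(x, y)} coordinates.
#' @export
apply_affine <- function(t, points) {
  stopifnot(is_affine2d(t))
  points <- as_points(points)
  x <- points[, 1]; y <- points[, 2]
  cbind(x = t$a * x + t$c * y + t$e,
        y = t$b * x + t$d * y + t$f)
}

as_points <- function(points) {
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 2L) {
    points <- matrix(points, ncol = 2)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L || !is.numeric(points)) {
    stop("`points` must be a two-column numeric matrix of (x, y)", call. = FALSE)
  }
  points
}

#' Invert an affine transform
#'
#' @inheritParams apply_affine
#' @return The inverse \code{affine2d}.
#' @export
affine_invert <- function(t) {
  stopifnot(is_affine2d(t))
  det <- t$a * t$d - t$b * t$c
  ia <- t$d / det; ib <- -t$b / det
  ic <- -t$c / det; id <- t$a / det
  affine2d(ia, ib, ic, id,
           -(ia * t$e + ic * t$f),
           -(ib * t$e + id * t$f))
}

#' Compose two affine transforms (apply `inner` first, then `outer`)
#'
#' @param outer,inner \code{affine2d} transforms.
#' @export
affine_compose <- function(outer, inner) {
  m <- as.matrix(outer) %*% as.matrix(inner)
  affine2d(m[1, 1], m[2, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3])
}

#' Least-squares affine estimation from landmark pairs
#'
#' Substitute for interactive image registration: given at least three
#' non-collinear corresponding point pairs, recovers the affine transform
#' minimising the sum of squared residuals. On noiseless consistent input
#' the generating transform is recovered exactly (residual < 1e-9).
#'
#' @param src,dst Two-column \code{(x, y)} matrices of corresponding points.
#' @return An \code{\link{affine2d}}.
#' @export
estimate_affine_from_landmarks <- function(src, dst) {
  src <- as_points(src); dst <- as_points(dst)
  if (nrow(src) != nrow(dst)) {
    stop("`src` and `dst` must have the same number of landmarks", call. = FALSE)
  }
  if (nrow(src) < 3L) {
    stop("at least 3 landmark pairs are required", call. = FALSE)
  }
  X <- cbind(src[, 1], src[, 2], 1)
  if (qr(X)$rank < 3L) {
    stop("landmarks are collinear: affine transform is not identifiable",
         call. = FALSE)
  }
  cx <- qr.solve(X, dst[, 1])
  cy <- qr.solve(X, dst[, 2])
  affine2d(cx[1], cy[1], cx[2], cy[2], cx[3], cy[3])
}
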