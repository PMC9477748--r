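# Channel registration: estimate and apply the chromatic affine transform
# between the two spectral channels from fiducial-marker calibration data.

#' 2D affine transform
#'
#' @param linear 2x2 matrix (must be invertible).
#' @param translation Numeric length-2 translation (nm).
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(linear = diag(2), translation = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 2, all(is.finite(linear)),
            all(is.finite(translation)))
  if (abs(det(linear)) <= 1e-6)
    stop("affine linear part is singular (|det| <= 1e-6)")
  structure(list(linear = linear, translation = translation),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d: linear [", paste(sprintf("%.6g", t(x$linear)), collapse = ", "),
      "], translation (", x$translation[1], ",", x$translation[2], ") nm\n")
  invisible(x)
}

#' Apply an affine transform to coordinates
#'
#' @param t An [affine2d].
#' @param xy n x 2 matrix of coordinates (nm).
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(t, xy) {
  stopifnot(inherits(t, "affine2d"))
  xy <- matrix(as.numeric(xy), ncol = 2)
  sweep(xy %*% t(t$linear), 2, t$translation, "+")
}

#' Invert an affine transform
#'
#' @param t An [affine2d].
#' @return The inverse [affine2d].
#' @export
invert_affine <- function(t) {
  li <- solve(t$linear)
  affine2d(li, -as.vector(li %*% t$translation))
}

#' Compose two affine transforms
#'
#' @param t1,t2 [affine2d] objects; the result applies `t2` first, then `t1`.
#' @return The composed [affine2d].
#' @export
compose_affine <- function(t1, t2) {
  affine2d(t1$linear %*% t2$linear,
           as.vector(t1$linear %*% t2$translation) + t1$translation)
}

#' Estimate the channel-B to channel-A affine transform from fiducials
#'
#' Least-squares fit of the 6-parameter affine T minimizing
#' \eqn{\sum_i \| T(b_i) - a_i \|^2} over paired fiducial-marker
#' localizations. The full affine family (rather than a similarity) is used
#' because dual-view image splitters introduce scale and shear as well as
#' translation.
#'
#' @param points_a,points_b n x 2 matrices of paired marker positions (nm)
#'   in channels A and B; n >= 3 and not collinear.
#' @return A list with `transform` (the B-to-A [affine2d]) and
#'   `residual_rms` (nm), the RMS of the 2D residual vectors.
#' @export
estimate_affine <- function(points_a, points_b) {
  a <- matrix(as.numeric(points_a), ncol = 2)
  b <- matrix(as.numeric(points_b), ncol = 2)
  if (nrow(a) != nrow(b)) stop("point sets must be paired (equal length)")
  if (nrow(a) < 3)
    stop("identifiability error: need >= 3 fiducial pairs for an affine fit")
  X <- cbind(b, 1)
  if (qr(X)$rank < 3)
    stop("identifiability error: fiducial markers are collinear")
  beta <- qr.solve(X, a)              # 3 x 2: rows (m.1, m.2, t) per output axis
  linear <- t(beta[1:2, , drop = FALSE])
  translation <- as.numeric(beta[3, ])
  fitted <- X %*% beta
  residual_rms <- sqrt(mean(rowSums((a - fitted)^2)))
  list(transform = affine2d(linear, translation), residual_rms = residual_rms)
}

#' Apply an affine transform to a localization table
#'
#' Maps the `x_nm`, `y_nm` coordinates; all other columns are unchanged.
#' By convention the B-to-A transform is applied to the channel-B table
#' before any co-localization.
#'
#' @param table A localization table (see [localization_table()]).
#' @param t An [affine2d].
#' @return The table with transformed coordinates.
#' @export
apply_affine <- function(table, t) {
  stopifnot(inherits(t, "affine2d"))
  if (nrow(table) == 0) return(table)
  xy <- transform_points(t, cbind(table$x_nm, table$y_nm))
  table$x_nm <- xy[, 1]
  table$y_nm <- xy[, 2]
  table
}

#' Write / read an affine transform as JSON
#'
#' Serialized as six numbers: the 2x2 linear part in row-major order, then
#' the translation (nm).
#'
#' @param t An [affine2d].
#' @param path Output / input file path.
#' @return `write_affine` returns `path` invisibly; `read_affine` the
#'   [affine2d].
#' @export
write_affine <- function(t, path) {
  stopifnot(inherits(t, "affine2d"))
  jsonlite::write_json(
    list(linear_row_major = as.numeric(t(t$linear)),
         translation_nm = t$translation),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine2d(matrix(raw$linear_row_major, 2, 2, byrow = TRUE),
           raw$translation_nm)
}
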