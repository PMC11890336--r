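#' Planar homogeneous transform
#'
#' A 2D transform stored as a 3x3 homogeneous matrix together with the model
#' family it belongs to. Transforms map ultrasound (US) physical coordinates
#' to whole-slide-image (WSI) physical coordinates when produced by
#' [estimate_transform()]; the inverse direction is used to carry the
#' histopathological tumor annotation back into the US frame.
#'
#' @param matrix a 3x3 numeric matrix whose last row is (0, 0, 1).
#' @param model one of `"rigid"`, `"similarity"`, `"affine"`.
#' @return An object of class `transform2d`.
#' @examples
#' t1 <- similarity_transform(scale = 0.9, rotation_deg = 10, translation = c(3, 1))
#' apply_transform(t1, cbind(0, 0))
#' @export
transform2d <- function(matrix, model = c("similarity", "rigid", "affine")) {
  model <- match.arg(model)
  if (!is.matrix(matrix) || any(dim(matrix) != c(3L, 3L)) || any(!is.finite(matrix)))
    stop_sp("transform2d: 'matrix' must be a finite 3x3 matrix")
  if (max(abs(matrix[3, ] - c(0, 0, 1))) > 1e-12)
    stop_sp("transform2d: last row must be (0, 0, 1)")
  if (abs(det(matrix[1:2, 1:2])) < 1e-14)
    stop_sp("transform2d: linear block is singular")
  structure(list(matrix = matrix, model = model), class = "transform2d")
}

#' @rdname transform2d
#' @param scale isotropic scale factor (> 0). Scale below 1 models tissue
#'   shrinkage between fresh-specimen ultrasound and fixed histology.
#' @param rotation_deg in-plane rotation, degrees, counter-clockwise.
#' @param translation length-2 numeric, mm.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0, translation = c(0, 0)) {
  assert_scalar_num(scale, "scale", lower = 1e-12)
  assert_scalar_num(rotation_deg, "rotation_deg")
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  m <- rbind(cbind(scale * R, as.numeric(translation)), c(0, 0, 1))
  transform2d(m, model = if (abs(scale - 1) < 1e-15) "rigid" else "similarity")
}

#' Apply a transform to points
#'
#' @param transform a [transform2d()].
#' @param points numeric n x 2 matrix of physical coordinates (mm).
#' @return n x 2 matrix of mapped coordinates.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "transform2d"))
  assert_points(points, "points")
  h <- cbind(points, 1) %*% t(transform$matrix)
  h[, 1:2, drop = FALSE]
}

#' Invert a transform
#' @param transform a [transform2d()].
#' @return The inverse `transform2d` (same model).
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "transform2d"))
  transform2d(solve(transform$matrix), model = transform$model)
}

#' Compose two transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#' @param a,b [transform2d()] objects.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "transform2d"), inherits(b, "transform2d"))
  model <- if (a$model == "affine" || b$model == "affine") "affine"
           else if (a$model == "similarity" || b$model == "similarity") "similarity"
           else "rigid"
  transform2d(a$matrix %*% b$matrix, model = model)
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d: %s>\n", x$model))
  print(round(x$matrix, 6))
  invisible(x)
}

# Decompose the linear block of a similarity transform.
similarity_params <- function(transform) {
  A <- transform$matrix[1:2, 1:2]
  s <- sqrt(abs(det(A)))
  list(scale = s,
       rotation_deg = atan2(A[2, 1], A[1, 1]) * 180 / pi,
       translation = transform$matrix[1:2, 3])
}
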