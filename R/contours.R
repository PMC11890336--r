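#' Tumor annotation contour
#'
#' A closed simple polygon in physical coordinates (mm), tagged with the
#' annotation source and the frame it currently lives in. The
#' histopathological tumor annotation (HTA) originates in the WSI frame at a
#' much finer resolution than ultrasound, so annotations are carried as
#' polygons and rasterized only when a mask is actually needed; this avoids a
#' double interpolation through the coarser ultrasound grid.
#'
#' @param vertices numeric n x 2 matrix (mm), n >= 3, implicitly closed.
#' @param source one of `"HTA"`, `"US_M"`, `"US_Reg"` (histopathological
#'   annotation, manual ultrasound annotation, registered HTA in ultrasound).
#' @param frame one of `"US"`, `"WSI"`.
#' @return An object of class `annotation_contour`.
#' @export
annotation_contour <- function(vertices, source = c("HTA", "US_M", "US_Reg"),
                               frame = c("WSI", "US")) {
  source <- match.arg(source)
  frame <- match.arg(frame)
  assert_points(vertices, "vertices")
  if (nrow(vertices) >= 2 &&
      sqrt(sum((vertices[1, ] - vertices[nrow(vertices), ])^2)) < 1e-12)
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  if (nrow(vertices) < 3L)
    stop_sp("annotation_contour: need at least 3 distinct vertices")
  structure(list(vertices = vertices, source = source, frame = frame),
            class = "annotation_contour")
}

#' @export
print.annotation_contour <- function(x, ...) {
  cat(sprintf("<annotation_contour: %s in %s frame, %d vertices, area %.3f mm^2>\n",
              x$source, x$frame, nrow(x$vertices), polygon_area(x$vertices)))
  invisible(x)
}

#' Map a contour through a transform
#'
#' Applies a planar transform vertex-wise. Affine maps preserve polygon
#' simplicity, so the result remains a valid contour. Use
#' `direction = "inverse"` to carry a WSI-frame annotation into the
#' ultrasound frame through a US-to-WSI registration transform.
#'
#' @param contour an [annotation_contour()].
#' @param transform a [transform2d()].
#' @param direction `"forward"` applies the transform as given,
#'   `"inverse"` applies its inverse.
#' @param source,frame optional new tags for the result; defaults keep the
#'   source and flip the frame when direction is `"inverse"`.
#' @export
transform_contour <- function(contour, transform,
                              direction = c("forward", "inverse"),
                              source = NULL, frame = NULL) {
  stopifnot(inherits(contour, "annotation_contour"))
  direction <- match.arg(direction)
  t_use <- if (direction == "inverse") invert_transform(transform) else transform
  v <- apply_transform(t_use, contour$vertices)
  new_frame <- frame %||% setdiff(c("US", "WSI"), contour$frame)[1]
  annotation_contour(v, source = source %||% contour$source, frame = new_frame)
}

#' Pixel grid specification
#'
#' @param image_size_px integer pair `(rows, cols)`.
#' @param pixel_spacing_mm positive numeric pair `(sx, sy)` or scalar.
#' @param origin_mm physical position of the image corner (mm); pixel
#'   `(i, j)` (1-based row, col) has its center at
#'   `origin + ((j - 0.5) * sx, (i - 0.5) * sy)`.
#' @export
grid_spec <- function(image_size_px, pixel_spacing_mm, origin_mm = c(0, 0)) {
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (any(pixel_spacing_mm <= 0)) stop_sp("grid_spec: pixel spacing must be positive")
  structure(list(size = as.integer(image_size_px),
                 spacing = as.numeric(pixel_spacing_mm),
                 origin = as.numeric(origin_mm)),
            class = "grid_spec")
}

grid_x_centers <- function(g) g$origin[1] + (seq_len(g$size[2]) - 0.5) * g$spacing[1]
grid_y_centers <- function(g) g$origin[2] + (seq_len(g$size[1]) - 0.5) * g$spacing[2]

#' Rasterize a contour onto a pixel grid
#'
#' Scanline even-odd fill against pixel centers: a pixel belongs to the mask
#' when its center lies inside the polygon. Boundary ties are resolved by a
#' half-open convention (a pixel center exactly on the left/top crossing is
#' in, on the right/bottom crossing is out), which makes abutting polygons
#' partition the grid without overlap.
#'
#' @param contour an [annotation_contour()] or a plain n x 2 vertex matrix
#'   in the grid's physical frame.
#' @param grid a [grid_spec()].
#' @return Integer 0/1 matrix of dimension `grid$size`.
#' @export
rasterize_contour <- function(contour, grid) {
  v <- if (inherits(contour, "annotation_contour")) contour$vertices else contour
  assert_points(v, "contour")
  stopifnot(inherits(grid, "grid_spec"))
  mask <- matrix(0L, grid$size[1], grid$size[2])
  if (polygon_area(v) < .Machine$double.eps) {
    warning("rasterize_contour: degenerate (zero-area) contour, returning empty mask")
    return(mask)
  }
  xc <- grid_x_centers(grid)
  yc <- grid_y_centers(grid)
  if (max(v[, 1]) < min(xc) || min(v[, 1]) > max(xc) ||
      max(v[, 2]) < min(yc) || min(v[, 2]) > max(yc)) {
    warning("rasterize_contour: contour lies outside the grid, returning empty mask")
    return(mask)
  }
  n <- nrow(v)
  jn <- c(2:n, 1L)
  # Crossings per scanline: edge (p, q) crosses row y when min(py,qy) <= y < max
  crossings <- vector("list", grid$size[1])
  for (e in seq_len(n)) {
    y1 <- v[e, 2]; y2 <- v[jn[e], 2]
    if (y1 == y2) next
    lo <- min(y1, y2); hi <- max(y1, y2)
    rows <- which(yc >= lo & yc < hi)
    if (!length(rows)) next
    x <- v[e, 1] + (yc[rows] - y1) * (v[jn[e], 1] - v[e, 1]) / (y2 - y1)
    for (k in seq_along(rows))
      crossings[[rows[k]]] <- c(crossings[[rows[k]]], x[k])
  }
  for (i in seq_len(grid$size[1])) {
    cr <- crossings[[i]]
    if (is.null(cr) || length(cr) < 2L) next
    cr <- sort(cr)
    for (p in seq(1L, length(cr) - 1L, by = 2L))
      mask[i, xc >= cr[p] & xc < cr[p + 1L]] <- 1L
  }
  mask
}

#' Extract the 0.5-level contour(s) of a binary mask
#'
#' Marching-squares isocontours at level 0.5, in physical mm, with linear
#' interpolation between pixel centers (sub-pixel boundary). The mask is
#' padded by one zero pixel so that regions touching the image border still
#' produce closed rings.
#'
#' @param mask 0/1 matrix.
#' @param grid a [grid_spec()] matching the mask.
#' @return List of closed vertex matrices (outer rings first by area).
#' @export
mask_to_contours <- function(mask, grid) {
  stopifnot(is.matrix(mask), inherits(grid, "grid_spec"))
  if (!any(mask > 0)) stop_sp("mask_to_contours: mask is empty")
  padded <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  xc <- c(grid$origin[1] - 0.5 * grid$spacing[1], grid_x_centers(grid),
          grid$origin[1] + (grid$size[2] + 0.5) * grid$spacing[1])
  yc <- c(grid$origin[2] - 0.5 * grid$spacing[2], grid_y_centers(grid),
          grid$origin[2] + (grid$size[1] + 0.5) * grid$spacing[2])
  # contourLines wants z[i, j] at (x[i], y[j]); our matrices are (row=y, col=x)
  cl <- grDevices::contourLines(x = xc, y = yc, z = t(padded), levels = 0.5)
  rings <- lapply(cl, function(c1) {
    v <- cbind(c1$x, c1$y)
    if (sqrt(sum((v[1, ] - v[nrow(v), ])^2)) < 1e-12)
      v <- v[-nrow(v), , drop = FALSE]
    v
  })
  rings[order(vapply(rings, polygon_area, 0), decreasing = TRUE)]
}

# Single outer ring; errors when the mask splits into several components.
mask_single_contour <- function(mask, grid, what = "mask") {
  rings <- mask_to_contours(mask, grid)
  if (length(rings) > 1L) {
    areas <- vapply(rings, polygon_area, 0)
    stop_sp("%s has %d boundary components (areas %s mm^2); expected a single connected region",
            what, length(rings), paste(sprintf("%.2f", areas), collapse = ", "))
  }
  rings[[1]]
}
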