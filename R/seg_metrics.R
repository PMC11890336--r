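#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` over same-shape binary masks. Two empty masks
#' are defined to agree perfectly (DSC 1).
#'
#' @param a,b 0/1 arrays (2D or 3D) of identical dimension.
#' @return DSC in [0, 1].
#' @export
dice <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a > 0); nb <- sum(b > 0)
  if (na + nb == 0L) return(1.0)
  2 * sum(a > 0 & b > 0) / (na + nb)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_sp("masks differ in shape: %s vs %s",
            paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
}

# Boundary voxels: mask voxels with at least one face-neighbor outside the
# mask (4-connectivity in 2D, 6-connectivity in 3D); voxels on the array
# edge count as boundary.
boundary_voxels <- function(mask) {
  d <- dim(mask)
  m <- mask > 0
  if (length(d) == 2L) {
    pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
    pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
    core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)]
    nb <- pad[1:d[1], 2:(d[2] + 1L)] & pad[3:(d[1] + 2L), 2:(d[2] + 1L)] &
          pad[2:(d[1] + 1L), 1:d[2]] & pad[2:(d[1] + 1L), 3:(d[2] + 2L)]
    which(core & !nb, arr.ind = TRUE)
  } else if (length(d) == 3L) {
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
    core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
    nb <- pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] & pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
          pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] & pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
          pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] & pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
    which(core & !nb, arr.ind = TRUE)
  } else stop_sp("masks must be 2D or 3D")
}

# Voxel index -> physical mm. Row index follows y, column index x, slice z;
# spacing is (sx, sy[, sz]).
voxels_to_mm <- function(ind, spacing) {
  if (ncol(ind) == 2L) cbind(ind[, 2] * spacing[1], ind[, 1] * spacing[2])
  else cbind(ind[, 2] * spacing[1], ind[, 1] * spacing[2], ind[, 3] * spacing[3])
}

#' Symmetric surface distances
#'
#' Pooled symmetric set of boundary-to-boundary distances: for each boundary
#' voxel of `a` the nearest distance to `b`'s boundary, and vice versa,
#' measured between voxel centers in physical mm (anisotropic spacing
#' honored in 3D).
#'
#' @param a,b 0/1 arrays of identical dimension, both nonempty.
#' @param spacing_mm spacing per axis `(sx, sy)` or `(sx, sy, sz)`; a scalar
#'   is recycled.
#' @return Numeric vector of distances (mm), one per boundary voxel of both
#'   masks.
#' @export
surface_distances <- function(a, b, spacing_mm = 1) {
  check_same_grid(a, b)
  if (!any(a > 0) || !any(b > 0))
    stop_sp("undefined surface distance: empty mask")
  nd <- length(dim(a))
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  if (length(spacing_mm) != nd) stop_sp("spacing_mm must have length 1 or %d", nd)
  ba <- voxels_to_mm(boundary_voxels(a), spacing_mm)
  bb <- voxels_to_mm(boundary_voxels(b), spacing_mm)
  c(nn_distances(ba, bb), nn_distances(bb, ba))
}

#' Average surface distance and 95th-percentile Hausdorff distance
#'
#' `asd` is the mean of the pooled symmetric surface-distance set; `hd95`
#' its 95th percentile (linear interpolation between order statistics, the
#' dominant convention in segmentation evaluation tooling). `hd95` of
#' identical masks is 0; it is bounded above by the full Hausdorff distance.
#'
#' @inheritParams surface_distances
#' @return Distance in mm.
#' @export
asd <- function(a, b, spacing_mm = 1) mean(surface_distances(a, b, spacing_mm))

#' @rdname asd
#' @export
hd95 <- function(a, b, spacing_mm = 1)
  unname(stats::quantile(surface_distances(a, b, spacing_mm), 0.95, type = 7))

#' All segmentation metrics for one region
#'
#' Convenience wrapper extracting one region code from two label maps
#' (0 background, 1 specimen, 2 tumor) and computing DSC, ASD and HD95.
#'
#' @param pred,gt integer label arrays.
#' @param region label value to evaluate (1 specimen, 2 tumor).
#' @param spacing_mm per-axis spacing.
#' @return List with `region`, `dsc`, `asd_mm`, `hd95_mm`.
#' @export
seg_metrics <- function(pred, gt, region = 2L, spacing_mm = 1) {
  a <- (pred == region) * 1L
  b <- (gt == region) * 1L
  dsc <- dice(a, b)
  if (!any(a > 0) || !any(b > 0)) {
    return(list(region = region, dsc = dsc,
                asd_mm = if (dsc == 1) 0 else NA_real_,
                hd95_mm = if (dsc == 1) 0 else NA_real_))
  }
  sd_set <- surface_distances(a, b, spacing_mm)
  list(region = region, dsc = dsc, asd_mm = mean(sd_set),
       hd95_mm = unname(stats::quantile(sd_set, 0.95, type = 7)))
}
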