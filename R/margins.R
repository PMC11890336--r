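#' Sector configuration for margin measurement
#'
#' Margins are measured inside angular wedges about the tumor centroid. The
#' deep sector points along `orientation_deg` (degrees from +x; the default
#' 90 means +y, i.e. downward in image coordinates, away from the mucosal
#' surface at the top of the ultrasound image). Cranial and caudal sectors
#' sit at 90 degrees on either side; the mucosal (superior) sector is not
#' measured. Tumor thickness is taken along the deep axis.
#'
#' @param orientation_deg direction of "deep", degrees from +x.
#' @param sector_half_angle_deg half-opening of each wedge in (0, 90].
#' @param cranial_side `+1` puts cranial at `orientation_deg + 90`
#'   (default), `-1` at `orientation_deg - 90`.
#' @export
sector_config <- function(orientation_deg = 90, sector_half_angle_deg = 45,
                          cranial_side = 1) {
  assert_scalar_num(orientation_deg, "orientation_deg")
  assert_scalar_num(sector_half_angle_deg, "sector_half_angle_deg", 1e-6, 90)
  if (!cranial_side %in% c(-1, 1)) stop_sp("cranial_side must be +1 or -1")
  structure(list(orientation_deg = orientation_deg %% 360,
                 sector_half_angle_deg = sector_half_angle_deg,
                 cranial_side = cranial_side),
            class = "sector_config")
}

sector_center_deg <- function(config, region) {
  switch(region,
         deep = config$orientation_deg,
         cranial = (config$orientation_deg + 90 * config$cranial_side) %% 360,
         caudal = (config$orientation_deg - 90 * config$cranial_side) %% 360,
         stop_sp("unknown region '%s' (want cranial, deep, caudal)", region))
}

contour_vertices <- function(x, name) {
  v <- if (inherits(x, "annotation_contour")) x$vertices else x
  assert_points(v, name)
  v
}

#' Extract the specimen boundary from a mask
#'
#' Sub-pixel boundary polygon of a single connected specimen mask
#' (marching squares at the 0.5 level), in physical mm.
#'
#' @param specimen_mask 0/1 matrix, one connected component.
#' @param grid a [grid_spec()] giving spacing and origin.
#' @return Closed vertex matrix (n x 2, mm).
#' @export
extract_specimen_boundary <- function(specimen_mask, grid) {
  mask_single_contour(specimen_mask, grid, "specimen mask")
}

#' Measure a sector margin
#'
#' Minimum Euclidean distance between the tumor boundary and the specimen
#' boundary, both restricted to the angular wedge of the requested region
#' about the tumor centroid. Both contours are densified to ~0.05 mm arc
#' length first, so the reported minimum is effectively continuous.
#'
#' @param tumor_contour,specimen_contour closed polygons (n x 2 mm matrices
#'   or [annotation_contour()]s) in a common frame.
#' @param region `"cranial"`, `"deep"` or `"caudal"`.
#' @param config a [sector_config()].
#' @return List with `distance_mm`, `tumor_point`, `specimen_point`.
#' @export
measure_margin <- function(tumor_contour, specimen_contour, region,
                           config = sector_config()) {
  tv <- polygon_densify(contour_vertices(tumor_contour, "tumor_contour"))
  sv <- polygon_densify(contour_vertices(specimen_contour, "specimen_contour"))
  cen <- polygon_centroid(tv)
  ctr <- sector_center_deg(config, region) * pi / 180
  half <- config$sector_half_angle_deg * pi / 180
  in_sector <- function(p) {
    ang <- atan2(p[, 2] - cen[2], p[, 1] - cen[1])
    angle_diff(ang, ctr) <= half + 1e-12
  }
  tk <- tv[in_sector(tv), , drop = FALSE]
  sk <- sv[in_sector(sv), , drop = FALSE]
  if (!nrow(tk) || !nrow(sk))
    stop_sp("sector empty: no %s boundary points fall in the %s wedge",
            if (!nrow(tk)) "tumor" else "specimen", region)
  d <- min_pair_distance(tk, sk)
  list(distance_mm = d$distance, tumor_point = d$point_a, specimen_point = d$point_b)
}

#' Measure tumor thickness
#'
#' Maximal tumor extent along the deep axis: the range of the boundary
#' vertices' scalar projections onto the `orientation_deg` direction.
#'
#' @param tumor_contour closed polygon (n x 2 mm) or [annotation_contour()].
#' @param config a [sector_config()] supplying the deep direction.
#' @return Thickness in mm.
#' @export
measure_thickness <- function(tumor_contour, config = sector_config()) {
  v <- polygon_densify(contour_vertices(tumor_contour, "tumor_contour"))
  if (polygon_area(v) < 1e-12) stop_sp("degenerate tumor contour")
  th <- config$orientation_deg * pi / 180
  proj <- v[, 1] * cos(th) + v[, 2] * sin(th)
  max(proj) - min(proj)
}

#' Measure margins and thickness for all annotation sources
#'
#' Produces the per-slide measurement table: cranial, deep and caudal
#' margins plus thickness for each of the three annotation sources — the
#' manual ultrasound annotation (US_M) against the ultrasound specimen
#' boundary, the registered histopathological annotation carried into the
#' ultrasound frame (US_Reg, via the inverse of the best US-to-WSI
#' transform) against the same boundary, and the histopathological
#' annotation measured natively in the WSI frame against the WSI specimen
#' boundary. Missing sources are skipped with a warning.
#'
#' @param pair a slice pair (see [generate_specimen_slice()]).
#' @param registration a `registration_result` from [register_slice_pair()].
#' @param config a [sector_config()].
#' @return data.frame with columns `slide_id`, `source`, `region`,
#'   `value_mm`.
#' @export
measure_all <- function(pair, registration, config = sector_config()) {
  us_boundary <- if (!is.null(pair$us$specimen_mask))
    extract_specimen_boundary(pair$us$specimen_mask, pair$us$grid)
  else pair$us$specimen_contour
  wsi_boundary <- if (!is.null(pair$wsi$specimen_mask))
    extract_specimen_boundary(pair$wsi$specimen_mask, pair$wsi$grid)
  else pair$wsi$specimen_contour
  hta <- pair$wsi$hta_contour %||%
    annotation_contour(pair$wsi$tumor_contour, "HTA", "WSI")
  sources <- list()
  if (!is.null(pair$us$manual_tumor_contour))
    sources$US_M <- list(tumor = pair$us$manual_tumor_contour, boundary = us_boundary)
  else warning("measure_all: no manual US annotation (US_M) available; skipping")
  sources$US_Reg <- list(
    tumor = transform_contour(hta, registration$best_transform,
                              direction = "inverse", source = "US_Reg", frame = "US"),
    boundary = us_boundary)
  sources$WSI <- list(tumor = hta, boundary = wsi_boundary)
  rows <- list()
  for (src in names(sources)) {
    s <- sources[[src]]
    for (rg in c("cranial", "deep", "caudal")) {
      rows[[length(rows) + 1L]] <- data.frame(
        slide_id = pair$id, source = src, region = rg,
        value_mm = measure_margin(s$tumor, s$boundary, rg, config)$distance_mm,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      slide_id = pair$id, source = src, region = "thickness",
      value_mm = measure_thickness(s$tumor, config), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
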