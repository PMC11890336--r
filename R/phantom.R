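#' Synthetic specimen phantom specification
#'
#' Parameters of the paired-slice phantom generator. Each generated pair
#' mimics one ultrasound slice of a resected specimen and its corresponding
#' histology slide: a smooth specimen cross-section containing a tumor blob
#' and up to three collinear fiducial defects along the long axis (cannula
#' tracks), with the histology counterpart produced by a known similarity
#' transform — isotropic shrinkage, in-plane rotation, translation — plus an
#' optional smooth residual deformation. Landmark lists carry Gaussian
#' selection jitter; the "manual" ultrasound tumor annotation carries a
#' smooth radial boundary error.
#'
#' All randomness is drawn from streams split per (patient, slice, purpose),
#' so e.g. raising the annotation noise never reshuffles the landmark jitter.
#'
#' @param seed integer master seed; identical spec + seed gives bit-identical
#'   output.
#' @param n_patients,slices_per_patient study size.
#' @param pixel_spacing_mm in-plane pixel spacing (mm); the study's
#'   ultrasound volumes use 0.076 mm.
#' @param image_size_px integer pair (rows, cols).
#' @param shrinkage_factor isotropic US-to-histology scale in (0, 1];
#'   formalin fixation and paraffin embedding shrink tissue, default 0.90.
#' @param rotation_deg,translation_mm in-plane pose difference between the
#'   modalities.
#' @param residual_deformation_amplitude_mm SD (mm) of the smooth residual
#'   displacement field applied to histology tissue outlines (3 x 3 control
#'   points, Gaussian-interpolated); 0 disables it.
#' @param landmark_jitter_sd_mm per-coordinate SD of landmark selection
#'   jitter, both modalities.
#' @param annotation_noise_sd_mm SD of the radial boundary error of the
#'   manual ultrasound tumor annotation.
#' @param n_fiducials 1, 2 or 3 fiducial markers.
#' @param n_circumferential number of circumferential landmarks (>= 4).
#' @param tumor_radius_range_mm range the tumor's mean radius is drawn from.
#' @param min_clearance_mm minimum allowed tumor-to-specimen-boundary
#'   clearance when placing the tumor.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         n_patients = 8L,
                         slices_per_patient = 4L,
                         pixel_spacing_mm = 0.076,
                         image_size_px = c(420L, 420L),
                         shrinkage_factor = 0.90,
                         rotation_deg = 8,
                         translation_mm = c(2, 1),
                         residual_deformation_amplitude_mm = 0,
                         landmark_jitter_sd_mm = 0.1,
                         annotation_noise_sd_mm = 1.0,
                         n_fiducials = 3L,
                         n_circumferential = 8L,
                         tumor_radius_range_mm = c(2.5, 6.5),
                         min_clearance_mm = 0.8) {
  assert_scalar_num(seed, "seed", 0, 2^31 - 1)
  assert_scalar_num(n_patients, "n_patients", 0)
  assert_scalar_num(slices_per_patient, "slices_per_patient", 0)
  assert_scalar_num(pixel_spacing_mm, "pixel_spacing_mm", 1e-6)
  assert_scalar_num(shrinkage_factor, "shrinkage_factor", 1e-6, 1)
  assert_scalar_num(rotation_deg, "rotation_deg")
  assert_scalar_num(residual_deformation_amplitude_mm, "residual_deformation_amplitude_mm", 0)
  assert_scalar_num(landmark_jitter_sd_mm, "landmark_jitter_sd_mm", 0)
  assert_scalar_num(annotation_noise_sd_mm, "annotation_noise_sd_mm", 0)
  assert_scalar_num(n_fiducials, "n_fiducials", 1, 3)
  assert_scalar_num(n_circumferential, "n_circumferential", 4)
  if (length(translation_mm) != 2L || any(!is.finite(translation_mm)))
    stop_sp("translation_mm must be a finite length-2 vector")
  if (length(image_size_px) != 2L || any(image_size_px < 16))
    stop_sp("image_size_px must be two integers >= 16")
  structure(list(seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 slices_per_patient = as.integer(slices_per_patient),
                 pixel_spacing_mm = pixel_spacing_mm,
                 image_size_px = as.integer(image_size_px),
                 shrinkage_factor = shrinkage_factor,
                 rotation_deg = rotation_deg,
                 translation_mm = as.numeric(translation_mm),
                 residual_deformation_amplitude_mm = residual_deformation_amplitude_mm,
                 landmark_jitter_sd_mm = landmark_jitter_sd_mm,
                 annotation_noise_sd_mm = annotation_noise_sd_mm,
                 n_fiducials = as.integer(n_fiducials),
                 n_circumferential = as.integer(n_circumferential),
                 tumor_radius_range_mm = as.numeric(tumor_radius_range_mm),
                 min_clearance_mm = min_clearance_mm),
            class = "phantom_spec")
}

# purpose codes for RNG streams
.PURPOSE <- c(geometry = 1L, jitter_us = 2L, jitter_wsi = 3L, annotation = 4L,
              deformation = 5L, exclusion = 6L)

# Closed polygon from a radius function r(theta) around a center.
radial_polygon <- function(center, radius_fun, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- radius_fun(th)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Low-frequency radial perturbation multiplier: 1 + sum_k eps_k cos(k th + ph_k).
perturbed_radius <- function(base_fun, eps, phase, harmonics) {
  force(base_fun); force(eps); force(phase); force(harmonics)
  function(th) {
    m <- rep(1, length(th))
    for (i in seq_along(harmonics))
      m <- m + eps[i] * cos(harmonics[i] * th + phase[i])
    base_fun(th) * m
  }
}

# Smooth displacement field: 3x3 Gaussian-weighted control points over the
# image extent, per-component displacements ~ N(0, amp^2). Returns a
# function mapping an n x 2 point matrix to displaced points.
make_deformation <- function(extent_mm, amplitude_mm, seed) {
  if (amplitude_mm <= 0) return(identity)
  cx <- seq(0, extent_mm[1], length.out = 3L)
  cy <- seq(0, extent_mm[2], length.out = 3L)
  ctrl <- as.matrix(expand.grid(x = cx, y = cy))
  disp <- with_stream(seed, matrix(stats::rnorm(18L, 0, amplitude_mm), 9L, 2L))
  sig <- mean(c(diff(cx)[1], diff(cy)[1])) / 1.2
  function(p) {
    w <- exp(-(outer(p[, 1], ctrl[, 1], "-")^2 + outer(p[, 2], ctrl[, 2], "-")^2) / (2 * sig^2))
    w <- w / pmax(rowSums(w), 1e-12)
    p + w %*% disp
  }
}

phantom_grid <- function(spec) grid_spec(spec$image_size_px, spec$pixel_spacing_mm)

# Render a simple intensity image from specimen/tumor masks and fiducials.
render_intensity <- function(grid, specimen, tumor, fiducials_mm, fid_radius_mm,
                             levels = c(bg = 0.05, spec = 0.5, tum = 0.75, fid = 0.95)) {
  img <- matrix(levels[["bg"]], grid$size[1], grid$size[2])
  img[specimen == 1L] <- levels[["spec"]]
  img[tumor == 1L] <- levels[["tum"]]
  xc <- grid_x_centers(grid); yc <- grid_y_centers(grid)
  for (k in seq_len(nrow(fiducials_mm))) {
    d2 <- outer(yc - fiducials_mm[k, 2], xc - fiducials_mm[k, 1],
                function(dy, dx) dy^2 + dx^2)
    img[d2 <= fid_radius_mm^2] <- levels[["fid"]]
  }
  img
}

#' Generate one paired phantom slice
#'
#' Builds the ultrasound-side geometry (specimen blob, tumor blob, fiducial
#' defects, circumferential landmarks), derives the histology side through
#' the known similarity transform (plus residual deformation of tissue
#' outlines when enabled), rasterizes masks, simulates the manual ultrasound
#' tumor annotation, and records the full ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param patient_index,slice_index 1-based indices within the study.
#' @param rasters when `FALSE`, skip mask/image rasterization and the manual
#'   annotation (landmarks and truth only); used for fast registration
#'   sweeps.
#' @return A list with elements `pair` (the slice pair: `us` and `wsi` sides
#'   with grids, masks, landmark tables and contours, plus `id`) and `truth`
#'   (ground-truth transform, jitter-free fiducial positions, true masks,
#'   margins and thickness).
#' @export
generate_specimen_slice <- function(spec, patient_index = 1L, slice_index = 1L,
                                    rasters = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (patient_index < 1 || (spec$n_patients > 0 && patient_index > spec$n_patients))
    stop_sp("patient_index %d out of range", patient_index)
  if (slice_index < 1 || (spec$slices_per_patient > 0 && slice_index > spec$slices_per_patient))
    stop_sp("slice_index %d out of range", slice_index)
  grid <- phantom_grid(spec)
  extent <- rev(grid$size) * grid$spacing            # (x, y) extent in mm
  center <- extent / 2

  g <- with_stream(stream_seed(spec$seed, patient_index, slice_index, .PURPOSE[["geometry"]]), {
    a <- stats::runif(1, 10, 14)
    b <- stats::runif(1, 7, 10)
    eps_s <- stats::runif(3, 0, 0.04)
    ph_s <- stats::runif(3, 0, 2 * pi)
    u_rt <- stats::runif(1)
    eps_t <- stats::runif(3, 0, 0.06)
    ph_t <- stats::runif(3, 0, 2 * pi)
    ang0 <- stats::runif(1, 0, 2 * pi / spec$n_circumferential)
    psi <- stats::runif(30, 0, 2 * pi)
    mfrac <- stats::runif(30, 0, 1)
    list(a = a, b = b, eps_s = eps_s, ph_s = ph_s, u_rt = u_rt, eps_t = eps_t,
         ph_t = ph_t, ang0 = ang0, psi = psi, mfrac = mfrac)
  })

  # tumor mean radius: requested range, capped so the tumor can fit inside
  # this slice's specimen at the requested clearance (1.15 covers the radial
  # perturbation of both outlines)
  rt_lo <- spec$tumor_radius_range_mm[1]
  rt_hi <- min(spec$tumor_radius_range_mm[2],
               (min(g$a, g$b) - spec$min_clearance_mm) / 1.15)
  if (rt_hi < rt_lo)
    stop_sp(paste0("cannot place tumor (requested mean radius >= %.1f mm) inside the ",
                   "specimen (semi-axes %.1f x %.1f mm) at the requested clearance of %.1f mm"),
            rt_lo, g$a, g$b, spec$min_clearance_mm)
  g$rt <- rt_lo + g$u_rt * (rt_hi - rt_lo)

  ellipse_r <- function(th) g$a * g$b / sqrt((g$b * cos(th))^2 + (g$a * sin(th))^2)
  spec_rfun <- perturbed_radius(ellipse_r, g$eps_s, g$ph_s, 2:4)
  specimen_poly <- radial_polygon(center, spec_rfun, 256L)

  tumor_rfun <- perturbed_radius(function(th) rep(g$rt, length(th)), g$eps_t, g$ph_t, 2:4)
  tumor_poly <- NULL
  for (k in seq_along(g$psi)) {
    room <- min(g$a, g$b) - g$rt * 1.06 - spec$min_clearance_mm
    if (room < 0) break
    off <- g$mfrac[k] * room
    cand_center <- center + off * c(cos(g$psi[k]), sin(g$psi[k]))
    cand <- radial_polygon(cand_center, tumor_rfun, 192L)
    th_c <- atan2(cand[, 2] - center[2], cand[, 1] - center[1])
    inside <- sqrt(rowSums((cand - rep(center, each = nrow(cand)))^2)) <
      spec_rfun(th_c) - spec$min_clearance_mm * 0.5
    if (all(inside) &&
        min_pair_distance(cand, specimen_poly)$distance >= spec$min_clearance_mm * 0.5) {
      tumor_poly <- cand
      break
    }
  }
  if (is.null(tumor_poly))
    stop_sp(paste0("cannot place tumor (mean radius %.1f mm) inside the specimen ",
                   "(semi-axes %.1f x %.1f mm) at the requested clearance of %.1f mm"),
            g$rt, g$a, g$b, spec$min_clearance_mm)

  # fiducials along the long (x) axis, collinear
  fid_roles <- switch(spec$n_fiducials,
                      "fiducial_middle",
                      c("fiducial_left", "fiducial_right"),
                      c("fiducial_left", "fiducial_middle", "fiducial_right"))
  fid_x <- switch(spec$n_fiducials, 0, c(-0.55, 0.55), c(-0.55, 0, 0.55)) * g$a
  fid_us <- cbind(center[1] + fid_x, center[2])

  # circumferential landmarks on the specimen boundary
  th_lm <- g$ang0 + (seq_len(spec$n_circumferential) - 1L) * 2 * pi / spec$n_circumferential
  circ_us <- cbind(center[1] + spec_rfun(th_lm) * cos(th_lm),
                   center[2] + spec_rfun(th_lm) * sin(th_lm))

  # ground-truth US -> WSI similarity about the image center
  th <- spec$rotation_deg * pi / 180
  s <- spec$shrinkage_factor
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  b_vec <- center - s * R %*% center + spec$translation_mm
  true_transform <- transform2d(rbind(cbind(s * R, b_vec), c(0, 0, 1)),
                                model = if (s == 1) "rigid" else "similarity")

  deform <- make_deformation(extent, spec$residual_deformation_amplitude_mm,
                             stream_seed(spec$seed, patient_index, slice_index,
                                         .PURPOSE[["deformation"]]))
  specimen_poly_wsi <- deform(apply_transform(true_transform, specimen_poly))
  tumor_poly_wsi <- deform(apply_transform(true_transform, tumor_poly))
  circ_wsi <- deform(apply_transform(true_transform, circ_us))
  fid_wsi <- apply_transform(true_transform, fid_us)   # fiducials are rigid tracks

  jitter <- function(p, purpose) {
    if (spec$landmark_jitter_sd_mm == 0) return(p)
    sd <- spec$landmark_jitter_sd_mm
    p + with_stream(stream_seed(spec$seed, patient_index, slice_index, .PURPOSE[[purpose]]),
                    matrix(stats::rnorm(length(p), 0, sd), nrow(p), 2L))
  }
  lm_us_all <- jitter(rbind(circ_us, fid_us), "jitter_us")
  lm_wsi_all <- jitter(rbind(circ_wsi, fid_wsi), "jitter_wsi")
  labels <- c(sprintf("circumferential_%02d", seq_len(spec$n_circumferential)), fid_roles)
  roles <- c(rep("circumferential", spec$n_circumferential), fid_roles)
  us_landmarks <- landmark_list(labels, roles, lm_us_all[, 1], lm_us_all[, 2], "US")
  wsi_landmarks <- landmark_list(labels, roles, lm_wsi_all[, 1], lm_wsi_all[, 2], "WSI")

  id <- sprintf("P%02d_S%02d", patient_index, slice_index)
  us <- list(grid = grid, landmarks = us_landmarks,
             specimen_contour = specimen_poly, tumor_contour = tumor_poly,
             fiducials_mm = fid_us)
  wsi <- list(grid = grid, landmarks = wsi_landmarks,
              specimen_contour = specimen_poly_wsi, tumor_contour = tumor_poly_wsi,
              fiducials_mm = fid_wsi,
              hta_contour = annotation_contour(tumor_poly_wsi, "HTA", "WSI"))

  us_masks <- wsi_masks <- list(specimen = NULL, tumor = NULL)
  manual_mask <- NULL
  if (rasters) {
    us$specimen_mask <- rasterize_contour(specimen_poly, grid)
    us$tumor_mask <- rasterize_contour(tumor_poly, grid)
    wsi$specimen_mask <- rasterize_contour(specimen_poly_wsi, grid)
    wsi$tumor_mask <- rasterize_contour(tumor_poly_wsi, grid)
    us$image <- render_intensity(grid, us$specimen_mask, us$tumor_mask, fid_us, 0.8)
    wsi$image <- render_intensity(grid, wsi$specimen_mask, wsi$tumor_mask, fid_wsi, 0.8,
                                  levels = c(bg = 1.0, spec = 0.8, tum = 0.55, fid = 1.0))
    manual_mask <- simulate_manual_us_annotation(
      us$tumor_mask, spec$pixel_spacing_mm, spec$annotation_noise_sd_mm,
      stream_seed(spec$seed, patient_index, slice_index, .PURPOSE[["annotation"]]))
    us$manual_tumor_mask <- manual_mask
    us$manual_tumor_contour <- annotation_contour(
      mask_single_contour(manual_mask, grid, "manual annotation"), "US_M", "US")
  }

  sectors <- sector_config()
  true_margins <- vapply(c("cranial", "deep", "caudal"), function(rg) {
    measure_margin(tumor_poly, specimen_poly, rg, sectors)$distance_mm
  }, 0)
  truth <- structure(list(
    true_transform = true_transform,
    fiducial_positions_mm = list(US = fid_us, WSI = fid_wsi),
    circumferential_positions_mm = list(US = circ_us, WSI = circ_wsi),
    true_specimen_mask = list(US = us$specimen_mask, WSI = wsi$specimen_mask),
    true_tumor_mask = list(US = us$tumor_mask, WSI = wsi$tumor_mask),
    true_margins_mm = true_margins,
    true_thickness_mm = measure_thickness(tumor_poly, sectors)),
    class = "phantom_truth")

  list(pair = structure(list(id = id, patient = patient_index, slice = slice_index,
                             us = us, wsi = wsi), class = "slice_pair"),
       truth = truth)
}

#' Simulate a manual ultrasound tumor annotation
#'
#' Perturbs the boundary of a tumor mask by a smooth random radial field
#' (three Fourier harmonics about the region centroid, per-angle SD equal to
#' `noise_sd_mm`), emulating the boundary error of a human annotator working
#' at ultrasound resolution where small irregular growth patterns are hard
#' to delineate.
#'
#' @param true_tumor_mask 0/1 matrix, a single connected region.
#' @param spacing_mm pixel spacing (scalar, isotropic).
#' @param noise_sd_mm radial boundary displacement SD in mm; 0 returns the
#'   input unchanged.
#' @param seed integer seed for the perturbation draw.
#' @return A 0/1 matrix of the same dimension, single connected region.
#' @export
simulate_manual_us_annotation <- function(true_tumor_mask, spacing_mm, noise_sd_mm, seed) {
  if (!any(true_tumor_mask > 0)) stop_sp("simulate_manual_us_annotation: mask is empty")
  grid <- grid_spec(dim(true_tumor_mask), spacing_mm)
  contour <- mask_single_contour(true_tumor_mask, grid, "tumor mask")
  if (noise_sd_mm == 0) return(true_tumor_mask)
  K <- 3L
  coef <- with_stream(seed, matrix(stats::rnorm(2L * K, 0, noise_sd_mm / sqrt(K)), K, 2L))
  cen <- polygon_centroid(contour)
  th <- atan2(contour[, 2] - cen[2], contour[, 1] - cen[1])
  d <- rep(0, length(th))
  for (k in seq_len(K)) d <- d + coef[k, 1] * cos(k * th) + coef[k, 2] * sin(k * th)
  r <- sqrt(rowSums((contour - rep(cen, each = nrow(contour)))^2))
  r_new <- pmax(r + d, 0.2 * r)     # keep the region simple and nonempty
  out_poly <- cbind(cen[1] + r_new * cos(th), cen[2] + r_new * sin(th))
  out <- rasterize_contour(out_poly, grid)
  if (!any(out > 0))
    stop_sp("simulate_manual_us_annotation: perturbation removed the region entirely")
  out
}

#' Generate a full phantom study
#'
#' Produces `n_patients * slices_per_patient` paired slices plus a manifest.
#' A fixed number of slides can be flagged excluded (emulating slides that
#' were subdivided in the pathology lab or contained no tumor); excluded
#' slides stay in the manifest with their reason but are skipped by the
#' downstream analysis.
#'
#' @param spec a [phantom_spec()].
#' @param n_excluded number of slides to flag as excluded (drawn without
#'   replacement from a dedicated RNG stream).
#' @param rasters passed to [generate_specimen_slice()].
#' @param output_dir optional directory; when given, per-slice volumes
#'   (NRRD), histology rasters (PNG), label maps (NRRD), point lists (FCSV +
#'   markups JSON) and the manifest CSV are written there.
#' @return A list of class `phantom_study`: `pairs` (list of
#'   pair/truth elements), `manifest` (data.frame), `spec`.
#' @export
generate_study <- function(spec, n_excluded = 0L, rasters = TRUE, output_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  idx <- expand.grid(slice = seq_len(spec$slices_per_patient),
                     patient = seq_len(spec$n_patients))
  n <- nrow(idx)
  if (spec$n_patients == 0L || spec$slices_per_patient == 0L) {
    manifest <- data.frame(id = character(), patient = integer(), slice = integer(),
                           included = logical(), exclusion_reason = character(),
                           stringsAsFactors = FALSE)
    return(structure(list(pairs = list(), manifest = manifest, spec = spec),
                     class = "phantom_study"))
  }
  if (n_excluded >= n) stop_sp("n_excluded (%d) must be smaller than the study size (%d)", n_excluded, n)
  excl <- integer(0)
  if (n_excluded > 0)
    excl <- with_stream(stream_seed(spec$seed, 0L, 0L, .PURPOSE[["exclusion"]]),
                        sort(sample.int(n, n_excluded)))
  reasons <- rep("", n)
  if (length(excl))
    reasons[excl] <- rep_len(c("subdivided slide", "no tumor on slide"), length(excl))
  pairs <- vector("list", n)
  ids <- character(n)
  for (k in seq_len(n)) {
    pairs[[k]] <- generate_specimen_slice(spec, idx$patient[k], idx$slice[k], rasters = rasters)
    ids[k] <- pairs[[k]]$pair$id
  }
  manifest <- data.frame(id = ids, patient = idx$patient, slice = idx$slice,
                         included = !seq_len(n) %in% excl,
                         exclusion_reason = reasons, stringsAsFactors = FALSE)
  study <- structure(list(pairs = pairs, manifest = manifest, spec = spec),
                     class = "phantom_study")
  if (!is.null(output_dir)) write_study(study, output_dir)
  study
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("<phantom_study: %d slides (%d included), seed %d>\n",
              nrow(x$manifest), sum(x$manifest$included), x$spec$seed))
  invisible(x)
}

# Write study artifacts to disk in the standard formats.
write_study <- function(study, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- study$spec$pixel_spacing_mm
  for (el in study$pairs) {
    p <- el$pair
    base <- file.path(output_dir, p$id)
    if (!is.null(p$us$image))
      write_nrrd(image2d(p$us$image, c(sp, sp)), paste0(base, "_us.nrrd"))
    if (!is.null(p$wsi$image))
      write_raster(image2d(p$wsi$image, c(sp, sp)), paste0(base, "_wsi.png"))
    if (!is.null(p$us$specimen_mask)) {
      lab_us <- p$us$specimen_mask + p$us$tumor_mask        # 0 bg / 1 specimen / 2 tumor
      write_nrrd(image2d(lab_us, c(sp, sp)), paste0(base, "_us_labels.nrrd"))
      lab_wsi <- p$wsi$specimen_mask + p$wsi$tumor_mask
      write_nrrd(image2d(lab_wsi, c(sp, sp)), paste0(base, "_wsi_labels.nrrd"))
    }
    write_pointlist(p$us$landmarks, paste0(base, "_us.fcsv"))
    write_pointlist(p$wsi$landmarks, paste0(base, "_wsi.mrk.json"))
  }
  utils::write.csv(study$manifest, file.path(output_dir, "manifest.csv"), row.names = FALSE)
  invisible(output_dir)
}
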