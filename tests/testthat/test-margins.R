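test_that("specimen boundary extraction matches analytic geometry", {
  g <- grid_spec(c(160L, 160L), 0.25)
  disk <- rasterize_contour(circle_poly(c(20, 20), 10), g)
  ring <- extract_specimen_boundary(disk, g)
  expect_equal(sonopath:::polygon_perimeter(ring), 2 * pi * 10, tolerance = 0.02 * 2 * pi * 10)
  expect_error(extract_specimen_boundary(matrix(0L, 4, 4), grid_spec(c(4L, 4L), 1)),
               "empty")
  two <- matrix(0L, 40, 40); two[5:10, 5:10] <- 1L; two[25:35, 25:35] <- 1L
  expect_error(extract_specimen_boundary(two, grid_spec(c(40L, 40L), 1)),
               "components")
})

test_that("concentric circles give the radius difference in every sector", {
  tum <- circle_poly(c(0, 0), 5)
  spec <- circle_poly(c(0, 0), 10)
  for (rg in c("cranial", "deep", "caudal")) {
    expect_equal(measure_margin(tum, spec, rg)$distance_mm, 5.0, tolerance = 0.02)
  }
})

test_that("a tumor shifted toward deep thins the deep margin and widens the opposite", {
  tum <- circle_poly(c(0, 2), 5)   # shifted 2 mm along +y (deep)
  spec <- circle_poly(c(0, 0), 10)
  expect_equal(measure_margin(tum, spec, "deep")$distance_mm, 3.0, tolerance = 0.02)
  # opposite side: along the axis the gap is 7 mm; a minimum over a wide
  # wedge can only undercut that, and approaches it as the wedge narrows
  flipped_wide <- sector_config(orientation_deg = 270)
  expect_lte(measure_margin(tum, spec, "deep", flipped_wide)$distance_mm, 7.0 + 1e-9)
  flipped_narrow <- sector_config(orientation_deg = 270, sector_half_angle_deg = 5)
  expect_equal(measure_margin(tum, spec, "deep", flipped_narrow)$distance_mm, 7.0,
               tolerance = 0.02)
})

test_that("an empty sector raises an informative error", {
  tum <- circle_poly(c(0, 0), 2)
  arc <- cbind(seq(5, 8, by = 0.1), 0.01 * seq(5, 8, by = 0.1))  # only near +x
  cfg <- sector_config(orientation_deg = 90, sector_half_angle_deg = 20)
  expect_error(measure_margin(tum, arc, "deep", cfg), "sector empty")
})

test_that("thickness is the extent along the configured deep axis", {
  rect <- rbind(c(0, 0), c(4, 0), c(4, 7), c(0, 7))
  expect_equal(measure_thickness(rect, sector_config(orientation_deg = 90)), 7.0)
  expect_equal(measure_thickness(rect, sector_config(orientation_deg = 0)), 4.0)
  circ <- circle_poly(c(3, 3), 4.5)
  for (o in c(0, 33, 90)) {
    expect_equal(measure_thickness(circ, sector_config(orientation_deg = o)), 9.0,
                 tolerance = 1e-3)
  }
})

test_that("margins are invariant under a common rigid motion", {
  out <- generate_specimen_slice(identity_spec(seed = 8), 1, 1, rasters = FALSE)
  tum <- out$pair$us$tumor_contour
  spec <- out$pair$us$specimen_contour
  motion <- similarity_transform(1, 40, c(12, -7))
  base <- vapply(c("cranial", "deep", "caudal"), function(rg)
    measure_margin(tum, spec, rg)$distance_mm, 0)
  moved_cfg <- sector_config(orientation_deg = 90 + 40)
  moved <- vapply(c("cranial", "deep", "caudal"), function(rg)
    measure_margin(apply_transform(motion, tum), apply_transform(motion, spec),
                   rg, moved_cfg)$distance_mm, 0)
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("each margin is bounded by the centroid-to-boundary distance in its sector", {
  for (seed in c(3, 14, 27)) {
    out <- generate_specimen_slice(
      phantom_spec(seed = seed, n_patients = 1, slices_per_patient = 1),
      1, 1, rasters = FALSE)
    tum <- sonopath:::polygon_densify(out$pair$us$tumor_contour)
    spec <- sonopath:::polygon_densify(out$pair$us$specimen_contour)
    cen <- sonopath:::polygon_centroid(tum)
    cfg <- sector_config()
    for (rg in c("cranial", "deep", "caudal")) {
      m <- measure_margin(tum, spec, rg, cfg)$distance_mm
      ctr <- sonopath:::sector_center_deg(cfg, rg) * pi / 180
      ang <- atan2(spec[, 2] - cen[2], spec[, 1] - cen[1])
      sk <- spec[sonopath:::angle_diff(ang, ctr) <= pi / 4, , drop = FALSE]
      centroid_dist <- min(sqrt(rowSums(sweep(sk, 2, cen)^2)))
      expect_lte(m, centroid_dist + 1e-9)
    }
  }
})

test_that("phantom measurements agree with recorded truth within a pixel", {
  out <- generate_specimen_slice(identity_spec(seed = 12), 1, 1)
  reg <- register_slice_pair(out$pair)
  m <- measure_all(out$pair, reg)
  px <- out$pair$us$grid$spacing[1]
  for (src in c("US_M", "US_Reg", "WSI")) {
    rows <- m[m$source == src, ]
    vals <- setNames(rows$value_mm, rows$region)
    expect_equal(unname(vals[c("cranial", "deep", "caudal")]),
                 unname(out$truth$true_margins_mm), tolerance = 2 * px)
    expect_equal(unname(vals["thickness"]), out$truth$true_thickness_mm,
                 tolerance = 2 * px)
  }
})

test_that("pure shrinkage scales every WSI measurement by the shrinkage factor", {
  sp <- posed_spec(seed = 15, shrinkage_factor = 0.9, rotation_deg = 0,
                   translation_mm = c(0, 0))
  out <- generate_specimen_slice(sp, 1, 1)
  reg <- register_slice_pair(out$pair)
  m <- measure_all(out$pair, reg)
  us <- m[m$source == "US_Reg", ]
  wsi <- m[m$source == "WSI", ]
  merged <- merge(us, wsi, by = "region")
  expect_equal(merged$value_mm.y / merged$value_mm.x, rep(0.9, 4), tolerance = 0.02)
})

test_that("a missing manual annotation yields records for the remaining sources", {
  out <- generate_specimen_slice(posed_spec(seed = 16), 1, 1)
  reg <- register_slice_pair(out$pair)
  pair2 <- out$pair
  pair2$us$manual_tumor_contour <- NULL
  expect_warning(m <- measure_all(pair2, reg), "US_M")
  expect_setequal(unique(m$source), c("US_Reg", "WSI"))
  expect_equal(nrow(m), 8L)
})
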