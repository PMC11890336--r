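test_that("estimate_transform recovers a constructed similarity to 1e-9", {
  src <- random_point_set(8, seed = 11)
  truth <- similarity_transform(scale = 0.9, rotation_deg = 30, translation = c(3, 1))
  dst <- apply_transform(truth, src)
  fit <- estimate_transform(src, dst, "similarity")
  expect_lt(max(abs(fit$matrix - truth$matrix)), 1e-9)
  pars <- sonopath:::similarity_params(fit)
  expect_equal(pars$scale, 0.9, tolerance = 1e-9)
  expect_equal(pars$rotation_deg, 30, tolerance = 1e-9)
  expect_equal(unname(pars$translation), c(3, 1), tolerance = 1e-9)

  ident <- estimate_transform(src, src, "similarity")
  expect_lt(max(abs(ident$matrix - diag(3))), 1e-12)
})

test_that("least-squares residual matches a generic numerical optimizer", {
  rms <- function(T, src, dst) sqrt(mean(rowSums((apply_transform(T, src) - dst)^2)))
  for (k in 1:20) {
    set.seed(300 + k)
    n <- sample(4:10, 1)
    src <- random_point_set(n, seed = 300 + k)
    truth <- similarity_transform(runif(1, 0.7, 1.3), runif(1, -90, 90),
                                  runif(2, -5, 5))
    dst <- apply_transform(truth, src) + matrix(rnorm(2 * n, 0, 0.3), n, 2)
    fit <- estimate_transform(src, dst, "similarity")
    obj <- function(par) {
      T <- similarity_transform(exp(par[1]), par[2], par[3:4])
      rms(T, src, dst)
    }
    opt <- optim(c(0, 0, 0, 0), obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 2000))
    expect_lt(rms(fit, src, dst), opt$value + 1e-6)
    expect_equal(rms(fit, src, dst), opt$value, tolerance = 1e-6)
  }
})

test_that("affine fit recovers a constructed affine map and rejects collinear points", {
  A <- matrix(c(0.9, 0.2, -0.1, 1.1), 2, 2)
  src <- random_point_set(7, seed = 21)
  dst <- t(A %*% t(src)) + rep(c(2, -3), each = 7)
  fit <- estimate_transform(src, dst, "affine")
  expect_lt(max(abs(fit$matrix[1:2, 1:2] - A)), 1e-9)
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(estimate_transform(coll, coll, "affine"), "collinear|rank")
})

test_that("reflection-requiring correspondences are rejected for rigid/similarity", {
  src <- random_point_set(6, seed = 31)
  dst <- cbind(-src[, 1], src[, 2])   # mirror
  expect_error(estimate_transform(src, dst, "similarity"), "reflection")
  expect_error(estimate_transform(src, dst, "rigid"), "reflection")
})

test_that("TRE equals the Euclidean formula and averages over markers", {
  ident <- similarity_transform()
  expect_equal(target_registration_error(ident, cbind(1, 2), cbind(4, 6)), 5.0)
  expect_equal(target_registration_error(ident, cbind(1, 2), cbind(1, 2)), 0.0)
  us <- rbind(c(0, 0), c(10, 0))
  wsi <- rbind(c(1, 0), c(10, 3))     # individual errors 1 and 3
  expect_equal(target_registration_error(ident, us, wsi), 2.0)
  expect_error(target_registration_error(ident, us[0, , drop = FALSE],
                                         wsi[0, , drop = FALSE]), "empty")
})

test_that("TRE is invariant under a common rigid motion of both point sets", {
  set.seed(42)
  us <- random_point_set(3, seed = 42)
  wsi <- us + matrix(rnorm(6, 0, 0.5), 3, 2)
  t_est <- similarity_transform(1.05, 12, c(0.3, -0.2))
  tre0 <- target_registration_error(t_est, us, wsi)
  motion <- similarity_transform(1, 37, c(5, -8))
  # move the WSI frame: transform both the targets and the map's output
  t_moved <- compose_transforms(motion, t_est)
  tre1 <- target_registration_error(t_moved, us, apply_transform(motion, wsi))
  expect_equal(tre1, tre0, tolerance = 1e-12)
})

test_that("variant enumeration follows the leave-one-out scheme", {
  circ <- list(us = random_point_set(6, 51), wsi = random_point_set(6, 52))
  fid_us <- random_point_set(3, 53); fid_wsi <- random_point_set(3, 54)
  rownames(fid_us) <- rownames(fid_wsi) <-
    c("fiducial_left", "fiducial_middle", "fiducial_right")
  v <- enumerate_point_list_variants(circ, list(us = fid_us, wsi = fid_wsi))
  expect_length(v, 4L)
  expect_identical(vapply(v, function(x) x$variant_id, 1L), 1:4)
  # variant 1: trains on circumferential only, validates all fiducials
  expect_equal(nrow(v[[1]]$train_us), 6L)
  expect_equal(nrow(v[[1]]$val_us), 3L)
  # variant 3: trains on left+right, validates middle
  expect_equal(v[[3]]$val_us, fid_us["fiducial_middle", , drop = FALSE])
  expect_true(all(c("fiducial_left", "fiducial_right") %in%
                  rownames(v[[3]]$train_us)))
  # leave-one-out honesty: validation rows never appear among training rows
  for (vi in v) {
    for (r in seq_len(nrow(vi$val_us))) {
      hits <- apply(vi$train_us, 1, function(p) all(p == vi$val_us[r, ]))
      expect_false(any(hits))
    }
  }
})

test_that("variant enumeration adapts to fewer fiducials and errors without any", {
  circ <- list(us = random_point_set(5, 61), wsi = random_point_set(5, 62))
  f1u <- random_point_set(1, 63); f1w <- random_point_set(1, 64)
  rownames(f1u) <- rownames(f1w) <- "fiducial_middle"
  v1 <- enumerate_point_list_variants(circ, list(us = f1u, wsi = f1w))
  expect_length(v1, 1L)
  expect_equal(nrow(v1[[1]]$val_us), 1L)

  f2u <- random_point_set(2, 65); f2w <- random_point_set(2, 66)
  rownames(f2u) <- rownames(f2w) <- c("fiducial_left", "fiducial_right")
  v2 <- enumerate_point_list_variants(circ, list(us = f2u, wsi = f2w))
  expect_length(v2, 3L)

  expect_error(enumerate_point_list_variants(circ, list(us = NULL, wsi = NULL)),
               "no validation marker")
  small <- list(us = random_point_set(2, 67), wsi = random_point_set(2, 68))
  expect_error(enumerate_point_list_variants(small, list(us = f2u, wsi = f2w)),
               "at least 3")
})

test_that("noise-free phantom registration is exact with deterministic tie-break", {
  out <- generate_specimen_slice(posed_spec(seed = 3), 1, 1, rasters = FALSE)
  reg <- register_slice_pair(out$pair)
  expect_true(all(reg$per_variant_tre_mm < 1e-9))
  expect_identical(reg$best_variant, 1L)
  expect_lt(max(abs(reg$best_transform$matrix - out$truth$true_transform$matrix)), 1e-9)
})
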