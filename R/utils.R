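# Internal helpers: argument checking, seeded RNG streams, polygon geometry.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sp <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_sp("'%s' must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    stop_sp("'%s' must be in [%g, %g], got %g", name, lower, upper, x)
  invisible(x)
}

assert_points <- function(p, name) {
  if (!is.matrix(p) || ncol(p) != 2L || !is.numeric(p) || any(!is.finite(p)))
    stop_sp("'%s' must be a numeric n x 2 matrix of finite coordinates", name)
  invisible(p)
}

#' @keywords internal
#' @noRd
# Deterministic per-(patient, slice, purpose) seed so that adding noise to
# one stage never reshuffles the draws of another. Purposes are small integer
# codes; the combination stays below 2^31 - 1.
stream_seed <- function(base_seed, patient = 0L, slice = 0L, purpose = 0L) {
  m <- 2147483647
  s <- (as.double(base_seed) %% m)
  s <- (s * 48271 + patient * 104729 + slice * 7919 + purpose * 331) %% m
  as.integer(s)
}

with_stream <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## ---- polygon geometry (vertices: n x 2 matrix in mm, implicitly closed) ----

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

polygon_centroid <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  cr <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(v))
  c(sum((v[, 1] + v[j, 1]) * cr), sum((v[, 2] + v[j, 2]) * cr)) / (6 * a)
}

polygon_perimeter <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(sqrt(rowSums((v[j, , drop = FALSE] - v)^2)))
}

# Resample the closed polygon at approximately uniform arc-length spacing.
polygon_densify <- function(v, step_mm = 0.05) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  seg <- sqrt(rowSums((v[j, , drop = FALSE] - v)^2))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    k <- max(1L, ceiling(seg[i] / step_mm))
    t <- (seq_len(k) - 1L) / k
    out[[i]] <- cbind(v[i, 1] + t * (v[j[i], 1] - v[i, 1]),
                      v[i, 2] + t * (v[j[i], 2] - v[i, 2]))
  }
  do.call(rbind, out)
}

# Minimum distance between two point sets, chunked to bound memory.
min_pair_distance <- function(a, b) {
  best <- Inf
  best_pair <- list(a = a[1, ], b = b[1, ])
  chunk <- max(1L, floor(2e6 / nrow(b)))
  for (s in seq(1L, nrow(a), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(a))
    d2 <- outer(a[idx, 1], b[, 1], "-")^2 + outer(a[idx, 2], b[, 2], "-")^2
    m <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    if (d2[m[1], m[2]] < best^2) {
      best <- sqrt(d2[m[1], m[2]])
      best_pair <- list(a = a[idx[m[1]], ], b = b[m[2], ])
    }
  }
  list(distance = best, point_a = best_pair$a, point_b = best_pair$b)
}

# Directed nearest-neighbour distances from each row of a to the set b.
nn_distances <- function(a, b) {
  out <- numeric(nrow(a))
  chunk <- max(1L, floor(2e6 / nrow(b)))
  for (s in seq(1L, nrow(a), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(a))
    d2 <- outer(a[idx, 1], b[, 1], "-")^2
    for (k in 2:ncol(a)) d2 <- d2 + outer(a[idx, k], b[, k], "-")^2
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

# Smallest absolute angular difference between angles (radians).
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
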