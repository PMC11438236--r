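# Independent oracles and small fixture builders shared across tests.

# Monte-Carlo rejection-sampling oracle for the volume and centroid of the
# convex hull of a point set: sample uniformly in the bounding box, classify
# points by the half-space test (computed here, not by the package's
# hull_contains), and estimate volume = box volume * acceptance rate.
mc_hull_oracle <- function(points, n_samples = 1e5, seed = 1,
                           chunk = 2e5) {
  withr::local_seed(seed)
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  box_vol <- prod(hi - lo)
  # facet planes computed from scratch by an exhaustive O(n^3) plane scan;
  # the package's hull code is never consulted
  planes <- naive_hull_planes(points)
  off <- planes$offsets + 1e-12
  n_in <- 0
  s1 <- c(0, 0, 0)
  s2 <- c(0, 0, 0)
  done <- 0
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    samples <- cbind(stats::runif(m, lo[1], hi[1]),
                     stats::runif(m, lo[2], hi[2]),
                     stats::runif(m, lo[3], hi[3]))
    d <- samples %*% t(planes$normals)
    inside <- rowSums(d > matrix(off, m, length(off), byrow = TRUE)) == 0L
    acc <- samples[inside, , drop = FALSE]
    n_in <- n_in + nrow(acc)
    s1 <- s1 + colSums(acc)
    s2 <- s2 + colSums(acc^2)
    done <- done + m
  }
  p_hat <- n_in / n_samples
  cen <- s1 / n_in
  cen_var <- (s2 - n_in * cen^2) / (n_in - 1)
  list(
    volume = box_vol * p_hat,
    volume_se = box_vol * sqrt(p_hat * (1 - p_hat) / n_samples),
    centroid = cen,
    centroid_se = sqrt(cen_var / n_in),
    n_inside = n_in
  )
}

# Exhaustive facet-plane enumeration: every plane through 3 input points
# with all remaining points on one side is a hull facet plane. O(n^3) in
# the number of points, so only usable for small vertex sets.
naive_hull_planes <- function(points) {
  n <- nrow(points)
  stopifnot(n >= 4, n <= 150)
  normals <- NULL
  offsets <- NULL
  scale <- max(dist(points))
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    u <- points[j, ] - points[i, ]
    v <- points[k, ] - points[i, ]
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    len <- sqrt(sum(nrm^2))
    if (len < 1e-12 * scale^2) next
    nrm <- nrm / len
    d <- points %*% nrm - sum(nrm * points[i, ])
    if (all(d <= 1e-9 * scale)) {
      normals <- rbind(normals, nrm)
      offsets <- c(offsets, sum(nrm * points[i, ]))
    } else if (all(d >= -1e-9 * scale)) {
      normals <- rbind(normals, -nrm)
      offsets <- c(offsets, -sum(nrm * points[i, ]))
    }
  }
  list(normals = normals, offsets = offsets)
}

# seeded random point cloud (unit-ball-ish)
random_cloud <- function(n, seed, scale = c(1, 1, 1), center = c(0, 0, 0)) {
  withr::local_seed(seed)
  g <- matrix(stats::rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2)) * stats::runif(n)^(1 / 3)
  sweep(sweep(g, 2, scale, "*"), 2, center, "+")
}

random_rotation <- function(seed) {
  withr::local_seed(seed)
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# minimal valid segment table for body-model tests
two_segment_body <- function(v1 = 0.01, v2 = 0.02, x1 = 0, x2 = 2,
                             names = c("skull", "trunk"), ...) {
  suppress_canonical_warning(assemble_body(
    tibble::tibble(name = names, volume = c(v1, v2), cx = c(x1, x2),
                   cy = 0, cz = 0),
    ...))
}

suppress_canonical_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("canonical segments", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
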