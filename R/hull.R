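#' Minimum convex hull of a 3D point set
#'
#' Wraps a point cloud (typically the vertices of a skeletal body-segment
#' mesh) in its minimum convex hull (MCH) and computes the exact hull volume
#' and volume-weighted centroid by signed-tetrahedron summation over the
#' oriented boundary triangles. The hull approximates the soft-tissue
#' envelope of a body segment; hull volume times an assumed tissue density
#' gives the segment's mass contribution.
#'
#' Face orientation is normalised so the total signed volume is positive;
#' the winding of any input mesh is not trusted. Coplanar or collinear input
#' is an error, not a zero-volume hull: a silent zero-volume segment would
#' corrupt downstream whole-body mass sums.
#'
#' @param points An n x 3 numeric matrix (or data frame with three numeric
#'   columns) of point coordinates in metres. At least 4 affinely
#'   independent points are required.
#' @return An object of class `convex_hull`: a list with elements
#'   `vertices` (m x 3 matrix, the hull vertices, a subset of the input
#'   points), `faces` (k x 3 integer matrix indexing rows of `vertices`,
#'   wound so face normals point outward), `volume` (m^3), and `centroid`
#'   (length-3 numeric, metres).
#' @examples
#' cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
#' h <- convex_hull(cube)
#' h$volume      # 1
#' h$centroid    # (0.5, 0.5, 0.5)
#' @export
convex_hull <- function(points) {
  points <- as_point_matrix(points)
  n <- nrow(points)
  if (n < 4) {
    stop("degenerate input: need at least 4 points to build a 3D hull, got ", n,
         call. = FALSE)
  }
  res <- .hull_cpp(points)
  if (res$rank < 3) {
    stop("degenerate input: points have affine rank ", res$rank,
         " (< 3); coplanar or collinear point sets have no 3D hull",
         call. = FALSE)
  }
  faces_all <- res$faces
  vol <- signed_volume(points, faces_all)
  if (vol < 0) { # guard; the builder already orients outward
    faces_all <- faces_all[, c(1L, 3L, 2L), drop = FALSE]
    vol <- -vol
  }
  keep <- sort(unique(as.vector(faces_all)))
  remap <- integer(nrow(points))
  remap[keep] <- seq_along(keep)
  faces <- matrix(remap[faces_all], ncol = 3L)
  verts <- points[keep, , drop = FALSE]
  out <- list(
    vertices = verts,
    faces    = faces,
    volume   = vol,
    centroid = tet_centroid(verts, faces, vol)
  )
  class(out) <- "convex_hull"
  out
}

# signed volume of a closed triangulated surface via the divergence theorem:
# sum of signed tetrahedra (face, origin); origin-independent for closed
# surfaces, so no translation is applied first.
signed_volume <- function(verts, faces) {
  a <- verts[faces[, 1L], , drop = FALSE]
  b <- verts[faces[, 2L], , drop = FALSE]
  c_ <- verts[faces[, 3L], , drop = FALSE]
  dets <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
          a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
          a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  sum(dets) / 6
}

tet_centroid <- function(verts, faces, vol) {
  a <- verts[faces[, 1L], , drop = FALSE]
  b <- verts[faces[, 2L], , drop = FALSE]
  c_ <- verts[faces[, 3L], , drop = FALSE]
  dets <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
          a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
          a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  # centroid of tetra (a, b, c, origin) is (a + b + c)/4
  cx <- sum((a[, 1L] + b[, 1L] + c_[, 1L]) / 4 * dets / 6)
  cy <- sum((a[, 2L] + b[, 2L] + c_[, 2L]) / 4 * dets / 6)
  cz <- sum((a[, 3L] + b[, 3L] + c_[, 3L]) / 4 * dets / 6)
  c(cx, cy, cz) / vol
}

#' Volume of a convex hull from its oriented boundary
#'
#' Recomputes the enclosed volume of a `convex_hull` (or any closed,
#' consistently wound triangle surface passed as a `convex_hull`-shaped
#' list) by summing signed tetrahedra against the origin. The result is
#' independent of the choice of origin because the surface is closed.
#'
#' @param hull A `convex_hull` object (see [convex_hull()]).
#' @return Volume in m^3 (coordinates assumed metres).
#' @export
hull_volume <- function(hull) {
  check_hull(hull)
  check_orientation(hull)
  v <- signed_volume(hull$vertices, hull$faces)
  if (v <= 0) {
    stop("orientation error: faces enclose non-positive signed volume", call. = FALSE)
  }
  v
}

#' Volume-weighted centroid of a convex hull
#'
#' Computes the centroid of the enclosed solid (not of the vertex set) by
#' tetrahedral decomposition against the origin. Equivariant under rigid
#' motion of the input.
#'
#' @inheritParams hull_volume
#' @return Length-3 numeric, metres.
#' @export
hull_centroid <- function(hull) {
  check_hull(hull)
  check_orientation(hull)
  v <- signed_volume(hull$vertices, hull$faces)
  if (abs(v) < .Machine$double.xmin) {
    stop("degenerate input: hull has zero volume", call. = FALSE)
  }
  tet_centroid(hull$vertices, hull$faces, v)
}

#' Point-in-hull test
#'
#' Tests whether a point lies inside (or within `tol` of) a convex hull by
#' evaluating every outward face half-space. Boundary points are inside
#' (closure convention).
#'
#' @inheritParams hull_volume
#' @param point Length-3 numeric, or an n x 3 matrix of query points.
#' @param tol Slack in length units (metres); default 1e-9.
#' @return Logical scalar (or vector for a matrix of points).
#' @export
hull_contains <- function(hull, point, tol = 1e-9) {
  check_hull(hull)
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3L)
  hp <- hull_planes(hull)
  # inside iff n.p <= off + tol for all unit-normal half-spaces
  d <- pts %*% t(hp$normals)
  inside <- rowSums(d > matrix(hp$offsets + tol, nrow(pts), nrow(hp$normals),
                               byrow = TRUE)) == 0L
  if (is.matrix(point)) inside else inside[[1L]]
}

# unit outward normals and plane offsets for each face
hull_planes <- function(hull) {
  v <- hull$vertices
  f <- hull$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  nrm <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
               u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
               u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / len
  list(normals = nrm, offsets = rowSums(nrm * a))
}

check_hull <- function(hull) {
  if (!inherits(hull, "convex_hull") &&
      !(is.list(hull) && all(c("vertices", "faces") %in% names(hull)))) {
    stop("expected a `convex_hull` object", call. = FALSE)
  }
  invisible(hull)
}

# a closed, consistently oriented triangle surface has every directed edge
# exactly once and its reverse exactly once
check_orientation <- function(hull) {
  f <- hull$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(e[, 1L], e[, 2L])
  rev_key <- paste(e[, 2L], e[, 1L])
  if (anyDuplicated(key) || !all(rev_key %in% key)) {
    stop("orientation error: faces are not a consistently wound closed surface",
         call. = FALSE)
  }
  invisible(hull)
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 3L || !is.numeric(points)) {
    stop("points must be an n x 3 numeric matrix", call. = FALSE)
  }
  if (anyNA(points)) stop("points contain missing values", call. = FALSE)
  storage.mode(points) <- "double"
  points
}

#' @export
print.convex_hull <- function(x, ...) {
  cat(sprintf("<convex_hull> %d vertices, %d faces, volume %.6g m^3\n",
              nrow(x$vertices), nrow(x$faces), x$volume))
  cat(sprintf("  centroid: (%.6g, %.6g, %.6g) m\n",
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}
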