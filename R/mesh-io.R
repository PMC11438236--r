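#' Read a triangle mesh from OBJ, PLY, or STL
#'
#' Reads one skeletal body-segment mesh. Supported formats: Wavefront OBJ
#' (ascii), PLY (ascii and binary little-endian), and STL (ascii and
#' binary). STL stores one vertex triplet per facet, so coincident vertices
#' are merged with an absolute tolerance of 1e-9 length units before faces
#' are indexed. Coordinates are converted to metres internally (`mm`
#' multiplies by 1e-3 exactly); all downstream volume and centroid
#' computations assume metres.
#'
#' @param path Path to a `.obj`, `.ply`, or `.stl` file.
#' @param units Length unit of the file's coordinates: `"m"` or `"mm"`.
#' @return A `tri_mesh`: list with `vertices` (n x 3 matrix, metres),
#'   `faces` (k x 3 integer matrix), and `units` (always `"m"` after
#'   conversion; the source unit is kept in `source_units`).
#' @export
read_mesh <- function(path, units = c("m", "mm")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    obj = read_obj(path),
    ply = read_ply(path),
    stl = read_stl(path),
    stop("format error: unsupported mesh extension '.", ext,
         "' (expected obj, ply, or stl)", call. = FALSE)
  )
  if (nrow(mesh$vertices) < 4L) {
    stop("degenerate input: mesh has ", nrow(mesh$vertices),
         " vertices; at least 4 are required", call. = FALSE)
  }
  if (nrow(mesh$faces) > 0L &&
      (min(mesh$faces) < 1L || max(mesh$faces) > nrow(mesh$vertices))) {
    stop("format error: face index out of range in ", path, call. = FALSE)
  }
  scale <- if (units == "mm") 1e-3 else 1
  new_tri_mesh(mesh$vertices * scale, mesh$faces, source_units = units)
}

new_tri_mesh <- function(vertices, faces, source_units = "m") {
  structure(
    list(vertices = vertices, faces = faces, units = "m",
         source_units = source_units),
    class = "tri_mesh"
  )
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces (m; read as %s)\n",
              nrow(x$vertices), nrow(x$faces), x$source_units))
  invisible(x)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"), function(tok) {
    as.numeric(tok[2:4])
  }, numeric(3)))
  if (anyNA(verts)) stop("format error: malformed OBJ vertex line", call. = FALSE)
  nv <- nrow(verts)
  faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(tok) {
    idx <- vapply(tok[-1], function(t) as.integer(strsplit(t, "/")[[1]][1]),
                  integer(1))
    idx <- ifelse(idx < 0L, nv + idx + 1L, idx)  # negative = relative index
    if (length(idx) < 3L) stop("format error: OBJ face with < 3 vertices",
                               call. = FALSE)
    fan_triangulate(idx)
  }))
  if (is.null(faces)) faces <- matrix(integer(0), 0, 3)
  list(vertices = verts, faces = faces)
}

fan_triangulate <- function(idx) {
  k <- length(idx)
  if (k == 3L) return(matrix(idx, 1L, 3L))
  cbind(idx[1L], idx[2:(k - 1L)], idx[3:k])
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(raw, off, type) {
  sz <- ply_type_size[[type]]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  val <- readBin(raw[(off + 1L):(off + sz)], what = what, size = sz, n = 1L,
                 endian = "little",
                 signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  list(value = as.numeric(val), off = off + sz)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = file.size(path))
  # header ends at "end_header\n"; scan raw bytes (binary body may hold nuls)
  mark <- grepRaw("end_header", raw_all, fixed = TRUE)
  if (!length(mark)) stop("format error: PLY header not terminated", call. = FALSE)
  nl <- mark + 9L
  while (nl <= length(raw_all) && raw_all[nl] != as.raw(10L)) nl <- nl + 1L
  hdr_len <- nl
  header <- strsplit(rawToChar(raw_all[seq_len(hdr_len)]), "\r?\n")[[1]]
  header <- trimws(header)
  if (!identical(header[1], "ply")) stop("format error: not a PLY file", call. = FALSE)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("format error: unsupported PLY format '", fmt, "'", call. = FALSE)
  }

  # parse element/property structure
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (!all(c("vertex", "face") %in% names(elements))) {
    stop("format error: PLY lacks vertex or face element", call. = FALSE)
  }

  if (fmt == "ascii") {
    body <- strsplit(rawToChar(raw_all[(hdr_len + 1L):length(raw_all)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    li <- 0L
    out <- list()
    for (el in elements) {
      rows <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        li <- li + 1L
        rows[[i]] <- as.numeric(strsplit(trimws(body[li]), "\\s+")[[1]])
      }
      out[[el$name]] <- rows
    }
    vprops <- vapply(elements$vertex$props, `[[`, "", "name")
    vm <- do.call(rbind, out$vertex)
    verts <- vm[, match(c("x", "y", "z"), vprops), drop = FALSE]
    faces <- do.call(rbind, lapply(out$face, function(r) {
      fan_triangulate(as.integer(r[-1]) + 1L)  # PLY is 0-based
    }))
  } else {
    off <- hdr_len
    out <- list()
    for (el in elements) {
      rows <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        vals <- list()
        for (pr in el$props) {
          if (pr$list) {
            cnt <- ply_read_scalar(raw_all, off, pr$count_type)
            off <- cnt$off
            items <- numeric(cnt$value)
            for (j in seq_len(cnt$value)) {
              it <- ply_read_scalar(raw_all, off, pr$type)
              off <- it$off
              items[j] <- it$value
            }
            vals[[pr$name]] <- items
          } else {
            it <- ply_read_scalar(raw_all, off, pr$type)
            off <- it$off
            vals[[pr$name]] <- it$value
          }
        }
        rows[[i]] <- vals
      }
      out[[el$name]] <- rows
    }
    verts <- t(vapply(out$vertex, function(r) c(r$x, r$y, r$z), numeric(3)))
    faces <- do.call(rbind, lapply(out$face, function(r) {
      fan_triangulate(as.integer(r[[1]]) + 1L)
    }))
  }
  if (is.null(faces)) faces <- matrix(integer(0), 0, 3)
  list(vertices = verts, faces = faces)
}

read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = min(file.size(path), 512L))
  head_txt <- suppressWarnings(rawToChar(head_raw[head_raw != as.raw(0)]))
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  merge_triangle_soup(tri, tol = 1e-9)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  v <- t(vapply(strsplit(trimws(vlines), "\\s+"), function(tok) {
    as.numeric(tok[2:4])
  }, numeric(3)))
  if (nrow(v) %% 3L != 0L) {
    stop("format error: ascii STL vertex count not a multiple of 3", call. = FALSE)
  }
  v
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)  # header, ignored
  n <- readBin(con, "integer", size = 4L, n = 1L, endian = "little")
  v <- matrix(NA_real_, n * 3L, 3L)
  for (i in seq_len(n)) {
    rec <- readBin(con, "double", size = 4L, n = 12L, endian = "little")
    v[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", n = 2L)  # attribute byte count
  }
  v
}

# index a triangle soup (3 rows per facet) into shared vertices, merging
# points closer than tol on each coordinate
merge_triangle_soup <- function(tri_verts, tol = 1e-9) {
  key <- paste(round(tri_verts[, 1] / tol), round(tri_verts[, 2] / tol),
               round(tri_verts[, 3] / tol))
  idx <- match(key, key)                  # first occurrence per merged vertex
  keep <- sort(unique(idx))
  remap <- integer(nrow(tri_verts))
  remap[keep] <- seq_along(keep)
  faces <- matrix(remap[idx], ncol = 3L, byrow = TRUE)
  list(vertices = tri_verts[keep, , drop = FALSE], faces = faces)
}

#' Write a triangle mesh to OBJ, PLY, or STL
#'
#' The counterpart of [read_mesh()]. Coordinates are written as stored in
#' the `tri_mesh` (metres). PLY and STL support binary output.
#'
#' @param mesh A `tri_mesh` (or a list with `vertices` and `faces`).
#' @param path Output path; the extension selects the format.
#' @param binary Write binary PLY (little-endian) / binary STL. Ignored for
#'   OBJ.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obj = {
      lines <- c(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
                 sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
      writeLines(lines, path)
    },
    ply = if (binary) write_ply_binary(v, f, path) else write_ply_ascii(v, f, path),
    stl = if (binary) write_stl_binary(v, f, path) else write_stl_ascii(v, f, path),
    stop("format error: unsupported mesh extension '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

ply_header <- function(nv, nf, fmt) {
  c("ply", paste("format", fmt, "1.0"),
    paste("element vertex", nv),
    "property double x", "property double y", "property double z",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header")
}

write_ply_ascii <- function(v, f, path) {
  lines <- c(ply_header(nrow(v), nrow(f), "ascii"),
             sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
             sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  writeLines(lines, path)
}

write_ply_binary <- function(v, f, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(ply_header(nrow(v), nrow(f), "binary_little_endian"), con)
  writeBin(as.vector(t(v)), con, size = 8L, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
  }
}

write_stl_ascii <- function(v, f, path) {
  lines <- c("solid mesh")
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    n <- tri_normal(tri)
    lines <- c(lines,
               sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
               "    outer loop",
               sprintf("      vertex %.17g %.17g %.17g", tri[, 1], tri[, 2], tri[, 3]),
               "    endloop",
               "  endfacet")
  }
  writeLines(c(lines, "endsolid mesh"), path)
}

write_stl_binary <- function(v, f, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    n <- tri_normal(tri)
    writeBin(c(n, as.vector(t(tri))), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
}

tri_normal <- function(tri) {
  u <- tri[2, ] - tri[1, ]
  w <- tri[3, ] - tri[1, ]
  n <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  len <- sqrt(sum(n^2))
  if (len > 0) n / len else c(0, 0, 1)
}

#' Hull volumes and centroids for a set of segment meshes
#'
#' Convenience wrapper: reads each mesh, wraps it in its minimum convex
#' hull, and tabulates volume and centroid per segment. Segment names are
#' taken from the file base names unless `segments` is given.
#'
#' @param files Character vector of mesh paths (one body segment each).
#' @param units Length unit of the mesh coordinates (`"m"` or `"mm"`).
#' @param specimen Specimen identifier recycled into the output.
#' @param segments Optional character vector of segment names.
#' @return A tibble with columns `specimen`, `segment`, `volume_m3`, `cx`,
#'   `cy`, `cz` (centroid, metres).
#' @export
segment_hull_table <- function(files, units = "m", specimen = "specimen",
                               segments = NULL) {
  if (is.null(segments)) {
    segments <- tools::file_path_sans_ext(basename(files))
  }
  purrr::map2_dfr(files, segments, function(f, seg) {
    h <- convex_hull(read_mesh(f, units = units)$vertices)
    tibble::tibble(specimen = specimen, segment = seg,
                   volume_m3 = h$volume,
                   cx = h$centroid[1], cy = h$centroid[2], cz = h$centroid[3])
  })
}
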