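#' Triangle mesh
#'
#' The universal surface representation used throughout the package: a matrix
#' of 3D vertex coordinates (mm) and a matrix of vertex-index triples with
#' consistent outward (counter-clockwise) winding.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, one-based vertex indices.
#' @param validate check invariants (indices in range, no degenerate face).
#' @return An object of class `tooth_mesh` with elements `vertices`, `faces`.
#' @export
tooth_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L,
                     dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3L, dimnames = NULL)
  if (validate) {
    if (nrow(faces) < 1L) stop("empty mesh: no faces")
    if (nrow(vertices) < 3L) stop("empty mesh: fewer than 3 vertices")
    if (anyNA(vertices)) stop("non-finite vertex coordinates")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range")
    if (any(faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
            faces[, 2L] == faces[, 3L]))
      stop("degenerate face: repeated vertex")
  }
  structure(list(vertices = vertices, faces = faces), class = "tooth_mesh")
}

#' @export
print.tooth_mesh <- function(x, ...) {
  cat(sprintf("tooth_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Merge coincident vertices (grid snap at `tol`), drop faces that become
# degenerate and vertices no longer referenced.
#' Weld duplicate vertices and clean a mesh
#'
#' @param mesh a [tooth_mesh()].
#' @param tol welding tolerance in mm; vertices within the same `tol` grid
#'   cell collapse to one.
#' @return cleaned `tooth_mesh`.
#' @export
weld_mesh <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- match(key, key)
  map <- match(first, sort(unique(first)))
  keep <- sort(unique(first))
  v2 <- v[keep, , drop = FALSE]
  f2 <- matrix(map[mesh$faces], ncol = 3L)
  deg <- f2[, 1] == f2[, 2] | f2[, 1] == f2[, 3] | f2[, 2] == f2[, 3]
  f2 <- f2[!deg, , drop = FALSE]
  if (nrow(f2) < 1L) stop("empty mesh after cleanup")
  used <- sort(unique(as.vector(f2)))
  remap <- integer(nrow(v2)); remap[used] <- seq_along(used)
  tooth_mesh(v2[used, , drop = FALSE], matrix(remap[f2], ncol = 3L))
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [tooth_mesh()].
#' @return numeric scalar.
#' @export
mesh_area <- function(mesh) {
  sum(face_areas(mesh))
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Signed enclosed volume of a mesh (mm^3)
#'
#' Positive for watertight meshes with outward-facing winding.
#' @param mesh a [tooth_mesh()].
#' @return numeric scalar.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Area-weighted outward vertex normals
#' @param mesh a [tooth_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  idx <- as.vector(f)
  acc <- rowsum(rbind(fn, fn, fn), group = idx)
  out <- matrix(0, nrow(v), 3L)
  out[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(out^2))
  len[len == 0] <- 1
  out / len
}

## ---- rigid transforms and reflections ------------------------------------

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stop("translation must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation has determinant != +1 (reflections are not rigid)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(sprintf("%.6f", x$translation), collapse = " "),
      "mm\n")
  invisible(x)
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return their composition as a `rigid_transform`.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_rigid <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, -as.vector(rt %*% tf$translation))
}

#' Apply a rigid transform to points or a mesh
#'
#' @param mesh a [tooth_mesh()] or an n x 3 point matrix.
#' @param transform a [rigid_transform()].
#' @return transformed mesh or points.
#' @export
apply_rigid <- function(mesh, transform) {
  if (is.matrix(mesh)) {
    return(mesh %*% t(transform$rotation) +
             matrix(transform$translation, nrow(mesh), 3L, byrow = TRUE))
  }
  v <- mesh$vertices %*% t(transform$rotation) +
    matrix(transform$translation, nrow(mesh$vertices), 3L, byrow = TRUE)
  tooth_mesh(v, mesh$faces, validate = FALSE)
}

#' Reflection plane
#' @param point a 3D point on the plane (mm).
#' @param normal plane normal (normalized internally).
#' @return object of class `reflection_plane`.
#' @export
reflection_plane <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  nl <- sqrt(sum(normal^2))
  if (nl < 1e-12) stop("zero-length plane normal")
  structure(list(point = point, normal = normal / nl),
            class = "reflection_plane")
}

#' Reflect a mesh (or points) across a plane
#'
#' Vertices map to their mirror images; face winding is reversed so that the
#' oriented surface keeps its outward normals (signed volume is preserved).
#'
#' @param mesh a [tooth_mesh()] or n x 3 point matrix.
#' @param plane a [reflection_plane()].
#' @return reflected mesh or points.
#' @export
reflect_mesh <- function(mesh, plane) {
  refl <- function(p) {
    d <- (p - matrix(plane$point, nrow(p), 3L, byrow = TRUE)) %*% plane$normal
    p - 2 * as.vector(d) %o% plane$normal
  }
  if (is.matrix(mesh)) return(refl(mesh))
  tooth_mesh(refl(mesh$vertices), mesh$faces[, c(1L, 3L, 2L), drop = FALSE],
             validate = FALSE)
}

## ---- long axis ------------------------------------------------------------

#' Tooth long axis
#'
#' The imaginary line through the root apex and the middle point of the
#' crown; mirroring and the constrained ICP step are defined relative to it.
#'
#' @param apical_point 3D root apex (mm).
#' @param coronal_point 3D crown midpoint (mm).
#' @return object of class `long_axis`.
#' @export
long_axis <- function(apical_point, coronal_point) {
  apical_point <- as.numeric(apical_point)
  coronal_point <- as.numeric(coronal_point)
  if (sqrt(sum((coronal_point - apical_point)^2)) < 1e-9)
    stop("apical and coronal points coincide")
  structure(list(apical_point = apical_point, coronal_point = coronal_point),
            class = "long_axis")
}

#' Unit direction and anchor of a long axis
#' @param axis a [long_axis()].
#' @return list with `direction` (unit vector, apical to coronal) and
#'   `anchor` (the apical point).
#' @export
long_axis_line <- function(axis) {
  d <- axis$coronal_point - axis$apical_point
  list(direction = d / sqrt(sum(d^2)), anchor = axis$apical_point)
}

## ---- decimation -----------------------------------------------------------

#' Grid vertex-clustering decimation
#'
#' All vertices falling in one cubic grid cell of edge `cell` collapse to
#' their centroid; faces that become degenerate are removed. This is the
#' data-size reduction applied before the pair-matching pipeline when mesh
#' resolution exceeds the working grid (default 1.0 mm).
#'
#' @param mesh a [tooth_mesh()].
#' @param cell grid edge length, mm (> 0).
#' @return decimated `tooth_mesh`.
#' @export
decimate_grid <- function(mesh, cell = 1.0) {
  if (!is.numeric(cell) || length(cell) != 1L || cell <= 0)
    stop("cell must be a positive length in mm")
  v <- mesh$vertices
  key <- paste(floor(v[, 1] / cell), floor(v[, 2] / cell),
               floor(v[, 3] / cell))
  grp <- match(key, unique(key))
  cen <- rowsum(v, grp) / tabulate(grp)
  f2 <- matrix(grp[mesh$faces], ncol = 3L)
  deg <- f2[, 1] == f2[, 2] | f2[, 1] == f2[, 3] | f2[, 2] == f2[, 3]
  f2 <- f2[!deg, , drop = FALSE]
  if (nrow(f2) < 1L) stop("decimation removed all faces; cell too large")
  used <- sort(unique(as.vector(f2)))
  remap <- integer(nrow(cen)); remap[used] <- seq_along(used)
  tooth_mesh(cen[used, , drop = FALSE], matrix(remap[f2], ncol = 3L))
}

## ---- STL I/O --------------------------------------------------------------

#' Read an STL file
#'
#' Auto-detects the binary and ASCII dialects. Duplicate vertices shared by
#' neighbouring facets are welded at `tol`.
#'
#' @param path STL file path.
#' @param tol vertex welding tolerance in mm.
#' @return a [tooth_mesh()].
#' @export
read_stl <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  if (size < 15) stop("truncated STL file: ", path)
  head <- readBin(path, "raw", n = min(size, 512))
  printable <- head >= as.raw(32) & head <= as.raw(126) |
    head == as.raw(10) | head == as.raw(13) | head == as.raw(9)
  txt <- rawToChar(head[printable])
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE) && all(printable)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, size)
  if (nrow(tri) == 0L) stop("empty mesh: STL file has zero facets")
  nf <- nrow(tri) / 3L
  faces <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  weld_mesh(tooth_mesh(tri, faces, validate = FALSE), tol = tol)
}

read_stl_binary <- function(path, size) {
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (nf < 1L) stop("empty mesh: STL file has zero facets")
  if (size != 84 + 50 * as.numeric(nf))
    stop("truncated or corrupt binary STL: facet count does not match size")
  body <- readBin(con, "raw", n = 50L * nf)
  m <- matrix(body, nrow = 50L)
  floats <- readBin(as.raw(m[1:48, ]), "numeric", n = 12L * nf, size = 4L,
                    endian = "little")
  fm <- matrix(floats, nrow = 12L)  # rows 1:3 normal, 4:12 three vertices
  v <- rbind(t(fm[4:6, , drop = FALSE]),
             t(fm[7:9, , drop = FALSE]),
             t(fm[10:12, , drop = FALSE]))
  # interleave per facet: v1, v2, v3
  idx <- rep(seq_len(nf), each = 3L) + rep(c(0L, nf, 2L * nf), times = nf)
  v[idx, , drop = FALSE]
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L) stop("empty mesh: STL file has zero facets")
  if (length(vl) %% 3L != 0L) stop("corrupt ASCII STL: vertex count not x3")
  num <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  v <- do.call(rbind, num)
  if (anyNA(v)) stop("corrupt ASCII STL: unparsable vertex")
  v
}

#' Write an STL file
#'
#' @param mesh a [tooth_mesh()].
#' @param path output file path.
#' @param format `"binary"` (80-byte header, uint32 count, 50-byte facets,
#'   float32 coordinates) or `"ascii"` (full double precision).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  if (nrow(mesh$faces) < 1L) stop("empty mesh")
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  nf <- nrow(f)
  tri <- cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])  # nf x 12
  if (format == "binary") {
    con <- file(path, "wb"); on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "toothmatch binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    fb <- writeBin(as.numeric(t(tri)), raw(), size = 4L, endian = "little")
    m <- matrix(as.raw(0), nrow = 50L, ncol = nf)
    m[1:48, ] <- matrix(fb, nrow = 48L)
    writeBin(as.vector(m), con)
  } else {
    fmt <- paste0(" facet normal %.17g %.17g %.17g\n  outer loop\n",
                  "   vertex %.17g %.17g %.17g\n",
                  "   vertex %.17g %.17g %.17g\n",
                  "   vertex %.17g %.17g %.17g\n",
                  "  endloop\n endfacet")
    body <- sprintf(fmt, tri[, 1], tri[, 2], tri[, 3], tri[, 4], tri[, 5],
                    tri[, 6], tri[, 7], tri[, 8], tri[, 9], tri[, 10],
                    tri[, 11], tri[, 12])
    writeLines(c("solid toothmatch", body, "endsolid toothmatch"), path)
  }
  invisible(path)
}

## ---- misc geometry helpers ------------------------------------------------

# Face adjacency across shared undirected edges: m x 3 matrix of neighbour
# face ids (NA at boundary), column k = neighbour across edge opposite the
# ordering (v_k, v_{k+1}).
face_neighbors <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(m), times = 3L)
  slot <- rep(1:3, each = m)
  ord <- order(key)
  k <- key[ord]
  pos <- which(c(k[-length(k)] == k[-1], FALSE))
  nb <- matrix(NA_integer_, m, 3L)
  i1 <- ord[pos]; i2 <- ord[pos + 1L]
  nb[cbind(fid[i1], slot[i1])] <- fid[i2]
  nb[cbind(fid[i2], slot[i2])] <- fid[i1]
  nb
}

# Undirected edge list (unique) as a 2-column matrix of vertex indices.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

# Rotation by angle theta about unit direction d (Rodrigues).
rotation_about <- function(d, theta) {
  d <- unit3(d)
  K <- matrix(c(0, d[3], -d[2], -d[3], 0, d[1], d[2], -d[1], 0), 3L, 3L)
  diag(3) * cos(theta) + sin(theta) * K + (1 - cos(theta)) * (d %o% d)
}
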