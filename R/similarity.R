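#' Sample points from an element surface
#'
#' Returns all mesh vertices plus `ceiling(density * area)` uniform-random
#' points on the faces (area-weighted, reproducible under `seed`). The
#' Hausdorff distance is defined between two such point sets; the sampling
#' density bounds its discretisation error.
#'
#' @param element a `tooth_element`, [tooth_mesh()], or n x 3 point matrix.
#' @param density extra sample points per mm^2 (>= 0).
#' @param seed RNG seed for the face samples (the global RNG state is left
#'   untouched).
#' @param boundary_spacing optional spacing (mm) at which the open boundary
#'   edges of the element are additionally sampled. Element boundaries are
#'   cut polylines whose vertices fall at tessellation-dependent positions;
#'   densifying them makes the boundary representation (and hence Hausdorff
#'   distances between corresponding elements) tessellation-independent down
#'   to the given spacing.
#' @return object of class `sampled_surface` with `points` and `source_id`.
#' @export
sample_surface <- function(element, density = 10, seed = 1L,
                           boundary_spacing = NULL) {
  if (density < 0) stop("density must be >= 0")
  id <- NA_character_
  if (inherits(element, "tooth_element")) {
    id <- element$parent_id
    mesh <- element$mesh
  } else if (inherits(element, "tooth_mesh")) {
    mesh <- element
  } else {
    pts <- matrix(as.numeric(element), ncol = 3L)
    if (nrow(pts) < 1L) stop("empty element")
    return(structure(list(points = pts, source_id = id),
                     class = "sampled_surface"))
  }
  if (nrow(mesh$faces) < 1L) stop("empty element")
  pts <- mesh$vertices
  if (!is.null(boundary_spacing)) {
    stopifnot(boundary_spacing > 0)
    pts <- rbind(pts, densify_boundary(mesh, boundary_spacing))
  }
  ar <- face_areas(mesh)
  n_extra <- ceiling(density * sum(ar))
  if (n_extra > 0) {
    extra <- with_local_seed(seed, {
      fidx <- sample.int(length(ar), n_extra, replace = TRUE, prob = ar)
      r1 <- sqrt(stats::runif(n_extra))
      r2 <- stats::runif(n_extra)
      f <- mesh$faces[fidx, , drop = FALSE]
      a <- mesh$vertices[f[, 1], , drop = FALSE]
      b <- mesh$vertices[f[, 2], , drop = FALSE]
      cc <- mesh$vertices[f[, 3], , drop = FALSE]
      (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
    })
    pts <- rbind(pts, extra)
  }
  structure(list(points = pts, source_id = id), class = "sampled_surface")
}

# Interior points along the open (boundary) edges of a mesh, spaced at most
# `spacing` apart. Boundary edges belong to exactly one face.
densify_boundary <- function(mesh, spacing) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open_e <- e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  if (nrow(open_e) == 0L) return(matrix(numeric(0), 0L, 3L))
  a <- mesh$vertices[open_e[, 1], , drop = FALSE]
  b <- mesh$vertices[open_e[, 2], , drop = FALSE]
  len <- sqrt(rowSums((b - a)^2))
  out <- vector("list", nrow(open_e))
  for (i in seq_len(nrow(open_e))) {
    k <- ceiling(len[i] / spacing)
    if (k < 2L) next
    tt <- seq_len(k - 1L) / k
    out[[i]] <- (1 - tt) %o% a[i, ] + tt %o% b[i, ]
  }
  do.call(rbind, c(out, list(matrix(numeric(0), 0L, 3L))))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

as_point_matrix <- function(x) {
  if (inherits(x, "sampled_surface")) return(x$points)
  if (inherits(x, "tooth_mesh")) return(x$vertices)
  if (inherits(x, "tooth_element")) return(x$mesh$vertices)
  matrix(as.numeric(x), ncol = 3L)
}

#' Directed Hausdorff distance
#'
#' The longest distance from a point of `A` to its closest point in `B`
#' (mm). Not symmetric in its arguments.
#'
#' @param A,B `sampled_surface` objects or n x 3 point matrices.
#' @return numeric scalar (mm).
#' @export
directed_hausdorff <- function(A, B) {
  pa <- as_point_matrix(A); pb <- as_point_matrix(B)
  if (nrow(pa) < 1L || nrow(pb) < 1L) stop("empty point set")
  cpp_directed_hausdorff(pa, pb)$distance
}

#' Symmetric Hausdorff distance
#'
#' `max(directed_hausdorff(A, B), directed_hausdorff(B, A))` — the shape
#' similarity score between two registered element surfaces.
#'
#' @param A,B `sampled_surface` objects or n x 3 point matrices.
#' @return numeric scalar (mm).
#' @export
symmetric_hausdorff <- function(A, B) {
  max(directed_hausdorff(A, B), directed_hausdorff(B, A))
}
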