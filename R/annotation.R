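#' Surface curve
#'
#' An ordered polyline of points lying on a mesh surface, each tagged with
#' its containing face and barycentric coordinates. Closed curves repeat the
#' first point as the last.
#'
#' @param points n x 3 matrix of curve points (mm).
#' @param face integer vector of containing face indices (or `NULL`).
#' @param bary n x 3 matrix of barycentric coordinates in `face` (or `NULL`).
#' @param closed logical; closed curves must have first point == last point.
#' @return object of class `surface_curve`.
#' @export
surface_curve <- function(points, face = NULL, bary = NULL, closed = TRUE) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 2L) stop("a curve needs at least 2 points")
  if (closed && max(abs(points[1L, ] - points[nrow(points), ])) > 1e-9)
    stop("closed curve must have first point equal to last point")
  structure(list(points = points,
                 face = if (!is.null(face)) as.integer(face),
                 bary = if (!is.null(bary)) matrix(as.numeric(bary), ncol = 3L),
                 closed = isTRUE(closed)),
            class = "surface_curve")
}

#' @export
print.surface_curve <- function(x, ...) {
  cat(sprintf("surface_curve: %d points, %s\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Project points onto a mesh surface
#'
#' Closest point on any triangle, with containing face and barycentric
#' coordinates.
#'
#' @param mesh a [tooth_mesh()].
#' @param points n x 3 matrix.
#' @return list with `points` (projected), `face`, `bary`, `distance`.
#' @export
project_to_surface <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  cpp_closest_on_mesh(mesh$vertices, mesh$faces, points)
}

# Ensure a curve has face/bary tags on `mesh`.
curve_on_mesh <- function(mesh, curve) {
  if (!inherits(curve, "surface_curve")) {
    curve <- surface_curve(curve, closed = FALSE)
  }
  if (is.null(curve$face) || is.null(curve$bary)) {
    pr <- project_to_surface(mesh, curve$points)
    curve$points <- pr$point
    curve$face <- pr$face
    curve$bary <- pr$bary
  }
  curve
}

#' Closed periodic spline through annotated control points
#'
#' Interpolates a periodic cubic spline (chord-length parameterisation)
#' through ordered control points and, when a mesh is supplied, projects the
#' dense samples back onto the surface.
#'
#' @param control_points k x 3 matrix of ordered points, k >= 4; the curve is
#'   closed between the last and first point.
#' @param samples number of output samples around the closed curve.
#' @param mesh optional [tooth_mesh()] to project onto.
#' @return a closed [surface_curve()] (first sample repeated at the end).
#' @export
spline_closed_curve <- function(control_points, samples = 200, mesh = NULL) {
  cp <- matrix(as.numeric(control_points), ncol = 3L)
  n <- nrow(cp)
  if (n < 4L) stop("need at least 4 control points")
  if (max(abs(cp[1L, ] - cp[n, ])) < 1e-12) {
    cp <- cp[-n, , drop = FALSE]
    n <- n - 1L
    if (n < 4L) stop("need at least 4 distinct control points")
  }
  cpw <- rbind(cp, cp[1L, ])
  seg <- sqrt(rowSums(diff(cpw)^2))
  if (any(seg < 1e-12)) stop("coincident consecutive control points")
  s <- c(0, cumsum(seg))
  xout <- seq(0, s[length(s)], length.out = samples + 1L)
  pts <- vapply(1:3, function(k) {
    stats::spline(s, cpw[, k], method = "periodic", xout = xout)$y
  }, numeric(length(xout)))
  pts[nrow(pts), ] <- pts[1L, ]  # exact closure
  if (is.null(mesh)) {
    return(surface_curve(pts, closed = TRUE))
  }
  pr <- project_to_surface(mesh, pts)
  p <- pr$point
  p[nrow(p), ] <- p[1L, ]
  surface_curve(p, face = pr$face, bary = pr$bary, closed = TRUE)
}

## ---- geodesic machinery ---------------------------------------------------

#' Steiner-refined geodesic graph of a mesh
#'
#' Shortest paths over mesh edges plus `k` evenly spaced Steiner points per
#' edge, with every pair of boundary nodes of each face connected by its
#' Euclidean chord. Geodesic distances computed on this graph are accurate to
#' about 1-2% on smooth surfaces at the default `k`.
#'
#' @param mesh a [tooth_mesh()].
#' @param k Steiner points added per edge.
#' @return object of class `geodesic_graph` (reusable across queries).
#' @export
geodesic_graph <- function(mesh, k = 3) {
  v <- mesh$vertices
  nv <- nrow(v)
  ed <- mesh_edges(mesh)
  ne <- nrow(ed)
  # Steiner nodes: k per edge, fractions 1..k/(k+1) from endpoint 1.
  fr <- seq_len(k) / (k + 1)
  sx <- matrix(0, ne * k, 3L)
  for (i in seq_len(k)) {
    sx[seq.int(i, by = k, length.out = ne), ] <-
      v[ed[, 1], , drop = FALSE] * (1 - fr[i]) +
      v[ed[, 2], , drop = FALSE] * fr[i]
  }
  coords <- rbind(v, sx)
  # node ids of the k Steiner points of edge e: nv + (e-1)*k + 1:k
  edge_nodes <- function(e) nv + (e - 1L) * k + seq_len(k)
  # map face -> its three edges
  f <- mesh$faces
  ekey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  fe <- cbind(
    match(paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])), ekey),
    match(paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])), ekey),
    match(paste(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1])), ekey))
  nfc <- nrow(f)
  # boundary nodes per face: 3 vertices + 3k Steiner nodes
  bn <- matrix(0L, nfc, 3L + 3L * k)
  bn[, 1:3] <- f
  for (j in 1:3) {
    bn[, 3L + (j - 1L) * k + seq_len(k)] <-
      nv + (fe[, j] - 1L) * k + matrix(seq_len(k), nfc, k, byrow = TRUE)
  }
  nb <- ncol(bn)
  pr <- utils::combn(nb, 2L)
  from <- as.vector(bn[, pr[1L, ]])
  to <- as.vector(bn[, pr[2L, ]])
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(a * (nv + ne * k + 1) + b)
  a <- a[keep]; b <- b[keep]
  w <- sqrt(rowSums((coords[a, , drop = FALSE] -
                     coords[b, , drop = FALSE])^2))
  g <- igraph::make_empty_graph(n = nrow(coords), directed = FALSE)
  g <- igraph::add_edges(g, rbind(a, b), weight = w)
  structure(list(graph = g, coords = coords, n_vertices = nv, k = k,
                 face_nodes = bn),
            class = "geodesic_graph")
}

#' Geodesic distance field from a surface curve
#'
#' Multi-source shortest-path distance from every mesh vertex to the curve,
#' over the Steiner-refined edge graph.
#'
#' @param mesh a [tooth_mesh()].
#' @param curve a [surface_curve()] on the mesh (projected if untagged).
#' @param graph optional precomputed [geodesic_graph()].
#' @param k Steiner points per edge when `graph` is not supplied.
#' @return numeric vector of distances (mm), one per mesh vertex.
#' @export
geodesic_field <- function(mesh, curve, graph = NULL, k = 3) {
  curve <- curve_on_mesh(mesh, curve)
  if (is.null(graph)) graph <- geodesic_graph(mesh, k = k)
  pts <- curve$points
  fc <- curve$face
  if (curve$closed) {
    m <- nrow(pts)
    pts <- pts[-m, , drop = FALSE]
    fc <- fc[-m]
  }
  g <- graph$graph
  src <- igraph::vcount(g) + 1L
  g <- igraph::add_vertices(g, 1L)
  inc <- curve_incident_faces(mesh,
                              surface_curve(pts, face = fc,
                                            bary = curve$bary[seq_len(nrow(pts)), ,
                                                              drop = FALSE],
                                            closed = FALSE))
  reps <- lengths(inc)
  nodes <- graph$face_nodes[unlist(inc), , drop = FALSE]
  to <- as.vector(nodes)
  from <- rep(src, length(to))
  ppts <- pts[rep(rep(seq_len(nrow(pts)), times = reps),
                  times = ncol(nodes)), , drop = FALSE]
  w <- sqrt(rowSums((graph$coords[to, , drop = FALSE] - ppts)^2))
  g <- igraph::add_edges(g, rbind(from, to), weight = w)
  d <- igraph::distances(g, v = src, weights = igraph::E(g)$weight)
  as.vector(d)[seq_len(graph$n_vertices)]
}

# Insert projected midpoints until consecutive curve samples lie on
# identical or edge-adjacent faces, so that the chain of sample-containing
# faces covers every face the curve crosses (no corner-clip gaps).
densify_curve_on_mesh <- function(mesh, curve, max_rounds = 8L) {
  curve <- curve_on_mesh(mesh, curve)
  pts <- curve$points; fc <- curve$face; by <- curve$bary
  f <- mesh$faces
  for (r in seq_len(max_rounds)) {
    n <- nrow(pts)
    a <- fc[-n]; b <- fc[-1L]
    shared <- vapply(seq_len(n - 1L), function(i) {
      if (a[i] == b[i]) 3L else length(intersect(f[a[i], ], f[b[i], ]))
    }, integer(1))
    need <- which(shared < 2L)
    if (!length(need)) break
    mid <- (pts[need, , drop = FALSE] + pts[need + 1L, , drop = FALSE]) / 2
    pr <- project_to_surface(mesh, mid)
    ord <- order(c(seq_len(n), need + 0.5))
    pts <- rbind(pts, pr$point)[ord, , drop = FALSE]
    fc <- c(fc, pr$face)[ord]
    by <- rbind(by, pr$bary)[ord, , drop = FALSE]
  }
  surface_curve(pts, face = fc, bary = by, closed = curve$closed)
}

# All faces incident to each curve point: the containing face, plus — for
# points lying on an edge or vertex (within tol) — every face sharing that
# edge/vertex. Using the full incidence set keeps downstream computations
# independent of which face a projection tie-break assigned.
curve_incident_faces <- function(mesh, curve, tol = 1e-7) {
  f <- mesh$faces
  n <- nrow(curve$points)
  v2f <- split(rep(seq_len(nrow(f)), 3L), as.vector(f))
  lapply(seq_len(n), function(i) {
    fc <- curve$face[i]
    b <- curve$bary[i, ]
    low <- which(b < tol)
    if (length(low) == 0L) return(fc)
    if (length(low) >= 2L) {
      # on (or at) a vertex: all faces around it
      vtx <- f[fc, setdiff(1:3, low)[1L]]
      return(unique(c(fc, v2f[[as.character(vtx)]])))
    }
    # on an edge: both incident faces
    vv <- f[fc, setdiff(1:3, low)]
    cand <- intersect(v2f[[as.character(vv[1])]], v2f[[as.character(vv[2])]])
    unique(c(fc, cand))
  })
}

# Connected components of uncrossed faces (curve-containing faces blocked).
flood_components <- function(nb, blocked) {
  m <- nrow(nb)
  comp <- integer(m)
  comp[blocked] <- -1L
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      nxt <- nb[queue, , drop = FALSE]
      nxt <- nxt[!is.na(nxt)]
      nxt <- unique(nxt[comp[nxt] == 0L])
      comp[nxt] <- cur
      queue <- nxt
    }
  }
  comp[comp == -1L] <- 0L
  comp
}

#' Signed geodesic distance field relative to a separating curve
#'
#' Distance to the curve, positive on the side containing `side_point` and
#' negative on the other side. Sides are determined topologically: faces
#' containing curve samples block a flood fill over face adjacency.
#'
#' @param mesh a [tooth_mesh()].
#' @param curve a [surface_curve()] that separates the surface.
#' @param side_point 3D point identifying the positive side.
#' @param graph optional precomputed [geodesic_graph()].
#' @param k Steiner points per edge when `graph` is not supplied.
#' @return numeric vector (mm), one signed distance per vertex.
#' @export
signed_geodesic_field <- function(mesh, curve, side_point, graph = NULL,
                                  k = 3) {
  curve <- densify_curve_on_mesh(mesh, curve_on_mesh(mesh, curve))
  d <- geodesic_field(mesh, curve, graph = graph, k = k)
  nbm <- face_neighbors(mesh)
  crossed <- unique(unlist(curve_incident_faces(mesh, curve)))
  comp <- flood_components(nbm, crossed)
  if (max(comp) < 2L) {
    # curve grazes vertices/edges: widen the barrier by one face ring
    ring <- unique(c(crossed, nbm[crossed, ]))
    ring <- ring[!is.na(ring)]
    comp <- flood_components(nbm, ring)
    crossed <- ring
  }
  if (max(comp) < 2L)
    stop("curve does not separate the mesh into two regions")
  # component holding the positive side: nearest classified face centroid
  f <- mesh$faces; v <- mesh$vertices
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
          v[f[, 3], , drop = FALSE]) / 3
  sp <- as.numeric(side_point)
  dd <- colSums((t(cen) - sp)^2)
  dd[comp == 0L] <- Inf
  pos_comp <- comp[which.min(dd)]
  # vertex signs from incident classified faces
  nv <- nrow(v)
  vsign <- integer(nv)
  ok <- comp > 0L
  idx <- as.vector(f[ok, , drop = FALSE])
  sgn <- rep(ifelse(comp[ok] == pos_comp, 1L, -1L), times = 3L)
  vsign[idx] <- sgn  # last write wins; any incident classified face is fine
  if (any(vsign == 0L)) {
    # Vertices whose whole one-ring is blocked (the curve grazes them).
    # Classify them geometrically: side of the oriented curve in the
    # tangent plane, sign(dot(v - c, n x t)) with c the nearest curve
    # point, t the local curve tangent and n the local surface normal;
    # the global orientation is calibrated against the flood-fill
    # classification of the surrounding vertices.
    cpts <- curve$points
    m <- nrow(cpts)
    if (curve$closed) cpts <- cpts[-m, , drop = FALSE]
    nxt <- c(seq_len(nrow(cpts))[-1L], 1L)
    tang <- cpts[nxt, , drop = FALSE] - cpts
    fcn <- curve$face[seq_len(nrow(cpts))]
    fv <- mesh$faces[fcn, , drop = FALSE]
    e1 <- v[fv[, 2], , drop = FALSE] - v[fv[, 1], , drop = FALSE]
    e2 <- v[fv[, 3], , drop = FALSE] - v[fv[, 1], , drop = FALSE]
    nrmf <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                  e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                  e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    lat <- cbind(nrmf[, 2] * tang[, 3] - nrmf[, 3] * tang[, 2],
                 nrmf[, 3] * tang[, 1] - nrmf[, 1] * tang[, 3],
                 nrmf[, 1] * tang[, 2] - nrmf[, 2] * tang[, 1])
    geo_side <- function(idx) {
      nnc <- cpp_nn(cpts, v[idx, , drop = FALSE])
      k <- nnc$index
      sgn <- sign(rowSums((v[idx, , drop = FALSE] -
                             cpts[k, , drop = FALSE]) * lat[k, , drop = FALSE]))
      sgn
    }
    # calibrate orientation on classified vertices of blocked faces
    near <- setdiff(unique(as.vector(f[crossed, , drop = FALSE])),
                    which(vsign == 0L))
    flip <- 1
    if (length(near) >= 3L) {
      agree <- geo_side(near) * vsign[near]
      if (sum(agree) < 0) flip <- -1
    }
    un <- which(vsign == 0L)
    gs <- flip * geo_side(un)
    # a residual zero (vertex exactly on the curve) is harmless: d ~ 0 there
    gs[gs == 0] <- 1
    vsign[un] <- gs
  }
  vsign * d
}

# Marching-triangles extraction of the iso-contour psi == level, chained into
# polylines. Returns list of surface_curve loops (longest first).
level_set_curves <- function(mesh, psi, level) {
  p <- psi
  hit <- abs(p - level) < 1e-12
  p[hit] <- level + 1e-9
  f <- mesh$faces
  s <- matrix(p[f] - level, ncol = 3L)
  cr <- cbind(s[, 1] * s[, 2] < 0, s[, 2] * s[, 3] < 0, s[, 3] * s[, 1] < 0)
  nc <- rowSums(cr)
  cf <- which(nc == 2L)
  if (length(cf) == 0L) return(list())
  epair <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  # crossing point per unique crossed undirected edge
  keyof <- function(i, j) paste(pmin(i, j), pmax(i, j))
  rows <- list(); ks <- character(0)
  for (e in 1:3) {
    ff <- cf[cr[cf, e]]
    i <- f[ff, epair[[e]][1]]; j <- f[ff, epair[[e]][2]]
    tt <- s[cbind(ff, epair[[e]][1])] /
      (s[cbind(ff, epair[[e]][1])] - s[cbind(ff, epair[[e]][2])])
    pt <- mesh$vertices[i, , drop = FALSE] * (1 - tt) +
      mesh$vertices[j, , drop = FALSE] * tt
    rows[[e]] <- data.frame(face = ff, key = keyof(i, j),
                            x = pt[, 1], y = pt[, 2], z = pt[, 3],
                            stringsAsFactors = FALSE)
  }
  allcr <- do.call(rbind, rows)
  # face -> its two crossing rows; key -> incident rows (1 at open ends)
  byface <- split(seq_len(nrow(allcr)), allcr$face)
  key2rows <- split(seq_len(nrow(allcr)), allcr$key)
  visited <- rep(FALSE, length(byface))
  names(visited) <- names(byface)
  loops <- list()
  repeat {
    unv <- names(byface)[!visited]
    if (!length(unv)) break
    # start from an open chain end when one exists, else anywhere (a loop)
    startc <- unv[1L]
    entry <- NA_character_
    for (fc in unv) {
      kk <- allcr$key[byface[[fc]]]
      open_k <- kk[vapply(kk, function(kx) length(key2rows[[kx]]) == 1L,
                          logical(1))]
      if (length(open_k)) { startc <- fc; entry <- open_k[1L]; break }
    }
    cur <- startc
    prev_key <- entry
    chain <- if (is.na(entry)) character(0) else entry
    closed <- FALSE
    repeat {
      visited[[cur]] <- TRUE
      kk <- allcr$key[byface[[cur]]]
      nxt <- if (is.na(prev_key)) kk[1L] else setdiff(kk, prev_key)[1L]
      chain <- if (is.na(prev_key)) c(kk[2L], nxt) else c(chain, nxt)
      cand <- setdiff(as.character(allcr$face[key2rows[[nxt]]]), cur)
      if (!length(cand)) break
      if (visited[[cand[1L]]]) {
        closed <- cand[1L] == startc && is.na(entry)
        break
      }
      prev_key <- nxt
      cur <- cand[1L]
    }
    pts <- t(vapply(chain, function(kx) {
      r <- key2rows[[kx]][1L]
      c(allcr$x[r], allcr$y[r], allcr$z[r])
    }, numeric(3)))
    if (closed) pts[nrow(pts), ] <- pts[1L, ]
    if (nrow(pts) < 2L) next
    pr <- project_to_surface(mesh, pts)
    p2 <- pr$point
    if (closed) p2[nrow(p2), ] <- p2[1L, ]
    loops[[length(loops) + 1L]] <-
      surface_curve(p2, face = pr$face, bary = pr$bary, closed = closed)
  }
  loops[order(vapply(loops, function(cv) nrow(cv$points), numeric(1)),
              decreasing = TRUE)]
}

#' Geodesic offset curve
#'
#' The level set of points at a given geodesic (along-surface) distance from
#' a source curve, on the side identified by `side_point` — e.g. the line
#' 3 mm apical to the gingival margin.
#'
#' @param mesh a [tooth_mesh()].
#' @param curve source [surface_curve()].
#' @param distance offset distance in mm (>= 0).
#' @param side_point 3D point identifying the side to offset toward (for an
#'   apical offset, pass the root apex).
#' @param graph optional precomputed [geodesic_graph()].
#' @param k Steiner points per edge when `graph` is not supplied.
#' @return a [surface_curve()] at the requested offset.
#' @export
geodesic_offset_curve <- function(mesh, curve, distance, side_point,
                                  graph = NULL, k = 3) {
  if (distance < 0) stop("offset distance must be >= 0")
  curve <- curve_on_mesh(mesh, curve)
  if (distance == 0) return(curve)
  psi <- signed_geodesic_field(mesh, curve, side_point, graph = graph, k = k)
  loops <- level_set_curves(mesh, psi, distance)
  if (length(loops) == 0L)
    stop("offset exceeds available surface on that side")
  loops[[1L]]
}

## ---- element extraction ---------------------------------------------------

# Split faces crossed by the zero level of `fields[[1]]`, carrying all fields
# through by linear interpolation. Returns the refined mesh, per-face parent
# ids, and the interpolated fields.
split_by_zero <- function(mesh, fields) {
  psi <- fields[[1L]]
  p <- psi
  hit <- abs(p) < 1e-12
  p[hit] <- 1e-9
  f <- mesh$faces
  s <- matrix(p[f], ncol = 3L)
  cr <- cbind(s[, 1] * s[, 2] < 0, s[, 2] * s[, 3] < 0, s[, 3] * s[, 1] < 0)
  nc <- rowSums(cr)
  if (any(nc == 1L | nc == 3L)) stop("inconsistent level-set crossing")
  cf <- which(nc == 2L)
  v <- mesh$vertices
  nv <- nrow(v)
  # one new vertex per unique crossed edge
  edges <- list()
  for (e in 1:3) {
    ep <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))[[e]]
    ff <- cf[cr[cf, e]]
    edges[[e]] <- cbind(f[ff, ep[1]], f[ff, ep[2]])
  }
  alle <- do.call(rbind, edges)
  key <- paste(pmin(alle[, 1], alle[, 2]), pmax(alle[, 1], alle[, 2]))
  uk <- !duplicated(key)
  ue <- alle[uk, , drop = FALSE]
  ukey <- key[uk]
  tt <- p[ue[, 1]] / (p[ue[, 1]] - p[ue[, 2]])
  newv <- v[ue[, 1], , drop = FALSE] * (1 - tt) +
    v[ue[, 2], , drop = FALSE] * tt
  newid <- nv + seq_len(nrow(ue))
  lookup <- newid
  names(lookup) <- ukey
  fields2 <- lapply(fields, function(fd) {
    c(fd, fd[ue[, 1]] * (1 - tt) + fd[ue[, 2]] * tt)
  })
  fields2[[1L]][newid] <- 0  # exact on the cut
  v2 <- rbind(v, newv)
  keep <- setdiff(seq_len(nrow(f)), cf)
  out_f <- f[keep, , drop = FALSE]
  parent <- keep
  addf <- matrix(0L, 0L, 3L); addp <- integer(0)
  for (fc in cf) {
    tri <- f[fc, ]
    crs <- cr[fc, ]
    # rotate so crossings sit on edges (1,2) and (2,3): lone vertex is 2
    rot <- if (crs[1] && crs[2]) c(1L, 2L, 3L)
           else if (crs[2] && crs[3]) c(2L, 3L, 1L)
           else c(3L, 1L, 2L)
    A <- tri[rot[1]]; B <- tri[rot[2]]; C <- tri[rot[3]]
    P <- lookup[[paste(min(A, B), max(A, B))]]
    Q <- lookup[[paste(min(B, C), max(B, C))]]
    addf <- rbind(addf, c(P, B, Q), c(A, P, Q), c(A, Q, C))
    addp <- c(addp, fc, fc, fc)
  }
  out_f <- rbind(out_f, addf)
  parent <- c(parent, addp)
  list(mesh = tooth_mesh(v2, out_f, validate = FALSE),
       parent = parent, fields = fields2)
}

new_tooth_element <- function(kind, mesh, face_ids, parent_mesh, parent_id) {
  sub_f <- parent_mesh$faces[face_ids, , drop = FALSE]
  used <- sort(unique(as.vector(sub_f)))
  remap <- integer(nrow(parent_mesh$vertices))
  remap[used] <- seq_along(used)
  sm <- tooth_mesh(parent_mesh$vertices[used, , drop = FALSE],
                   matrix(remap[sub_f], ncol = 3L), validate = FALSE)
  structure(list(element_kind = kind, mesh = sm, face_ids = face_ids,
                 parent_id = parent_id),
            class = "tooth_element")
}

#' @export
print.tooth_element <- function(x, ...) {
  cat(sprintf("tooth_element <%s>: %d faces, area %.2f mm^2\n",
              x$element_kind, nrow(x$mesh$faces), mesh_area(x$mesh)))
  invisible(x)
}

#' Separate crown, emergence profile and root
#'
#' Partitions a tooth surface into the crown (coronal to the gingival margin
#' curve), the emergence profile (the band between the margin and its
#' offset curve) and the root remainder. Faces crossed by a region boundary
#' are split along the interpolated zero level of the signed geodesic field
#' of the corresponding curve, so the three regions partition the face set
#' exactly.
#'
#' @param mesh a [tooth_mesh()].
#' @param gingival closed gingival margin [surface_curve()].
#' @param offset closed offset [surface_curve()] apical to the margin (see
#'   [geodesic_offset_curve()]).
#' @param incisal_side_point 3D point on the coronal (crown) side.
#' @param graph optional precomputed [geodesic_graph()].
#' @param parent_id identifier stored in the returned elements.
#' @return list with `crown` and `emergence` ([new_tooth_element] objects),
#'   `root` (a `tooth_mesh`), and `mesh` (the refined parent mesh whose faces
#'   the three regions partition).
#' @export
extract_elements <- function(mesh, gingival, offset, incisal_side_point,
                             graph = NULL, parent_id = NA_character_) {
  gingival <- curve_on_mesh(mesh, gingival)
  offset <- curve_on_mesh(mesh, offset)
  if (!gingival$closed || !offset$closed)
    stop("gingival and offset curves must be closed")
  if (is.null(graph)) graph <- geodesic_graph(mesh)
  psi_g <- signed_geodesic_field(mesh, gingival, incisal_side_point,
                                 graph = graph)
  psi_o <- signed_geodesic_field(mesh, offset, incisal_side_point,
                                 graph = graph)
  # both boundaries inside one face means the curves (nearly) intersect
  f <- mesh$faces
  sg <- matrix(sign(psi_g)[f], ncol = 3L)
  so <- matrix(sign(psi_o)[f], ncol = 3L)
  both <- (apply(sg, 1L, function(r) any(r > 0) && any(r < 0))) &
          (apply(so, 1L, function(r) any(r > 0) && any(r < 0)))
  if (any(both))
    stop("annotation curves intersect or are closer than one face apart")
  s1 <- split_by_zero(mesh, list(psi_g, psi_o))
  s2 <- split_by_zero(s1$mesh, list(s1$fields[[2L]], s1$fields[[1L]]))
  m2 <- s2$mesh
  pg <- s2$fields[[2L]]  # signed gingival field on the refined mesh
  po <- s2$fields[[1L]]  # signed offset field
  fg <- rowSums(matrix(pg[m2$faces], ncol = 3L))
  fo <- rowSums(matrix(po[m2$faces], ncol = 3L))
  region <- ifelse(fg > 0, "crown", ifelse(fo > 0, "emergence", "root"))
  if (!all(c("crown", "emergence", "root") %in% region))
    stop("region extraction did not yield exactly 3 regions")
  nbm <- face_neighbors(m2)
  comp <- flood_components(nbm, blocked = integer(0))
  # regions must not be fragmented: flood fill restricted to each region
  for (rg in c("crown", "emergence", "root")) {
    idx <- which(region == rg)
    sub <- nbm[idx, , drop = FALSE]
    sub[!(sub %in% idx)] <- NA_integer_
    sub <- matrix(match(sub, idx), nrow = length(idx))
    cc <- flood_components(sub, blocked = integer(0))
    if (max(cc) != 1L)
      stop("region flood fill did not terminate in exactly 3 components")
  }
  list(crown = new_tooth_element("crown", m2, which(region == "crown"),
                                 m2, parent_id),
       emergence = new_tooth_element("emergence_profile", m2,
                                     which(region == "emergence"),
                                     m2, parent_id),
       root = new_tooth_element("root", m2, which(region == "root"),
                                m2, parent_id)$mesh,
       mesh = m2, psi_gingival = pg, psi_offset = po)
}

# Linear interpolation of a per-vertex field at curve points (via barycentric
# coordinates of the containing face).
field_at_curve <- function(mesh, curve, field) {
  curve <- curve_on_mesh(mesh, curve)
  f <- mesh$faces[curve$face, , drop = FALSE]
  vals <- matrix(field[f], ncol = 3L)
  rowSums(vals * curve$bary)
}
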