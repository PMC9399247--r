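#' Landmark triplet
#'
#' The three reference points used for superimposition: the most apical point
#' of the root and the most prominent incisal-edge points on the left and
#' right sides.
#'
#' @param apical,incisal_left,incisal_right 3D points (mm).
#' @return object of class `landmark_triplet`.
#' @export
landmark_triplet <- function(apical, incisal_left, incisal_right) {
  m <- rbind(as.numeric(apical), as.numeric(incisal_left),
             as.numeric(incisal_right))
  if (ncol(m) != 3L) stop("landmarks must be 3D points")
  a <- m[2L, ] - m[1L, ]; b <- m[3L, ] - m[1L, ]
  cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  if (0.5 * sqrt(sum(cr^2)) <= 1e-6)
    stop("landmark triplet is collinear")
  structure(list(apical = m[1L, ], incisal_left = m[2L, ],
                 incisal_right = m[3L, ]),
            class = "landmark_triplet")
}

as_landmark_matrix <- function(x) {
  if (inherits(x, "landmark_triplet"))
    return(rbind(x$apical, x$incisal_left, x$incisal_right))
  m <- matrix(as.numeric(x), ncol = 3L)
  if (nrow(m) != 3L) stop("expected 3 landmarks")
  m
}

#' Least-squares rigid superimposition of landmark triplets
#'
#' Closed-form (cross-covariance SVD) rotation + translation minimizing the
#' summed squared distance between corresponding landmarks; reflections are
#' excluded, no scaling.
#'
#' @param source,target [landmark_triplet()] objects (or 3 x 3 matrices of
#'   corresponding points, one per row).
#' @return a [rigid_transform()] mapping source onto target.
#' @export
landmark_align <- function(source, target) {
  S <- as_landmark_matrix(source)
  T_ <- as_landmark_matrix(target)
  for (m in list(S, T_)) {
    a <- m[2L, ] - m[1L, ]; b <- m[3L, ] - m[1L, ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    if (0.5 * sqrt(sum(cr^2)) <= 1e-6) stop("landmark triplet is collinear")
  }
  cs <- colMeans(S); ct <- colMeans(T_)
  H <- crossprod(sweep(S, 2L, cs), sweep(T_, 2L, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

#' Mirror a mesh along its long axis
#'
#' Reflects across the plane that contains the long axis and has the given
#' (axis-perpendicular) normal — the digital flip used to compare a tooth
#' with its contralateral.
#'
#' @param mesh a [tooth_mesh()] (or n x 3 point matrix).
#' @param axis the tooth [long_axis()].
#' @param mirror_normal plane normal; must be perpendicular to the axis
#'   direction within 1e-6. Default: the x axis (mesiodistal direction of
#'   the local tooth frame) projected off the axis.
#' @return the mirrored mesh (winding repaired) or points.
#' @export
mirror_along_long_axis <- function(mesh, axis, mirror_normal = NULL) {
  al <- long_axis_line(axis)
  if (is.null(mirror_normal)) {
    mirror_normal <- c(1, 0, 0) -
      sum(c(1, 0, 0) * al$direction) * al$direction
    if (sqrt(sum(mirror_normal^2)) < 1e-6)
      stop("axis is parallel to x; supply mirror_normal explicitly")
  }
  mirror_normal <- unit3(as.numeric(mirror_normal))
  if (abs(sum(mirror_normal * al$direction)) > 1e-6)
    stop("mirror_normal is not perpendicular to the long axis")
  reflect_mesh(mesh, reflection_plane(al$anchor, mirror_normal))
}

#' ICP configuration
#'
#' Free parameters of the constrained point-to-plane ICP step.
#'
#' @param max_iterations iteration cap.
#' @param convergence_tol stop when the point-to-plane RMS changes by less
#'   than this (mm).
#' @param correspondence_cap reject correspondences farther than this (mm).
#' @param sample_count number of source points used per iteration.
#' @return object of class `icp_config`.
#' @export
icp_config <- function(max_iterations = 100, convergence_tol = 1e-6,
                       correspondence_cap = 2.0, sample_count = 2000) {
  stopifnot(max_iterations >= 1, convergence_tol > 0,
            correspondence_cap > 0, sample_count >= 3)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 correspondence_cap = correspondence_cap,
                 sample_count = as.integer(sample_count)),
            class = "icp_config")
}

# Orthonormal basis (e1, e2) of the plane perpendicular to unit vector d.
perp_basis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(ref - sum(ref * d) * d)
  e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Rigid transform of the constrained family: rotation by theta about the
# axis line, plus translation (u, v) in the perpendicular plane.
axis_constrained_transform <- function(axis, theta, u, v) {
  al <- long_axis_line(axis)
  d <- al$direction; a <- al$anchor
  pb <- perp_basis(d)
  R <- rotation_about(d, theta)
  t <- a - as.vector(R %*% a) + u * pb$e1 + v * pb$e2
  rigid_transform(R, t)
}

#' Decompose a constrained transform into axis motion parameters
#'
#' For transforms in the constrained family (rotation about the long axis,
#' in-plane translation) returns the rotation angle and the two in-plane
#' translation components; also reports how far the transform departs from
#' that family.
#'
#' @param transform a [rigid_transform()].
#' @param axis the [long_axis()] defining the constraint.
#' @return list with `theta` (radians), `u`, `v` (mm), `axis_rotation_error`
#'   (|R d - d|) and `axial_translation` (displacement component along the
#'   axis, mm; 0 for in-family transforms).
#' @export
axis_motion_params <- function(transform, axis) {
  al <- long_axis_line(axis)
  d <- al$direction; a <- al$anchor
  pb <- perp_basis(d)
  R <- transform$rotation
  # angle about d from the action on e1
  r1 <- as.vector(R %*% pb$e1)
  theta <- atan2(sum(r1 * pb$e2), sum(r1 * pb$e1))
  disp <- as.vector(R %*% a) + transform$translation - a
  list(theta = theta,
       u = sum(disp * pb$e1),
       v = sum(disp * pb$e2),
       axis_rotation_error = sqrt(sum((as.vector(R %*% d) - d)^2)),
       axial_translation = sum(disp * d))
}

#' Constrained point-to-plane ICP
#'
#' Iterative closest point registration restricted to the 3-parameter family
#' of rotations about the tooth long axis plus translations in the plane
#' perpendicular to it. Each iteration samples source points, finds closest
#' target vertices (with area-weighted vertex normals), rejects
#' correspondences beyond the cap, and solves the linearised point-to-plane
#' least squares in (theta, u, v); the exact in-family update is composed so
#' the returned transform satisfies the constraints to machine precision.
#'
#' @param source,target [tooth_mesh()] objects; `source` is moved onto
#'   `target`.
#' @param axis the shared [long_axis()] (normally the target tooth's).
#' @param config an [icp_config()].
#' @param target_normals optional precomputed [vertex_normals()] of
#'   `target` (reused across many registrations against one target).
#' @param target_tree optional persistent nearest-neighbour tree of the
#'   target vertices (internal; built once per target when many sources are
#'   registered against it).
#' @param anchors optional landmark anchoring: a list with `source` and
#'   `target` (3 x 3 matrices of corresponding points, e.g. the landmark
#'   triplets) and `weight` (fraction of the total least-squares weight the
#'   anchors carry, default 0.1). Nearly rotation-symmetric teeth leave the
#'   spin about the long axis ill-determined by the surface alone; the
#'   incisal-edge landmarks then keep the rotation anatomically anchored.
#' @return list with `transform` (a [rigid_transform()] in the constrained
#'   family), `rms` (final point-to-plane RMS, mm), `iterations`,
#'   `converged`, and `trace` (per-iteration RMS before/after the inner
#'   solve and correspondence counts).
#' @export
constrained_icp <- function(source, target, axis, config = icp_config(),
                            target_normals = NULL, target_tree = NULL,
                            anchors = NULL) {
  if (nrow(source$faces) < 1L || nrow(target$faces) < 1L)
    stop("empty mesh")
  al <- long_axis_line(axis)
  d <- al$direction
  pb <- perp_basis(d)
  sv <- source$vertices
  ns <- nrow(sv)
  take <- unique(round(seq(1L, ns, length.out = min(config$sample_count, ns))))
  pts0 <- sv[take, , drop = FALSE]
  tv <- target$vertices
  tn <- if (is.null(target_normals)) vertex_normals(target) else target_normals
  tree <- if (is.null(target_tree)) cpp_kd_build(tv) else target_tree
  cum <- rigid_transform()
  rms_prev <- Inf
  trace <- list()
  converged <- FALSE
  iter <- 0L
  rms <- NA_real_
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    p <- apply_rigid(pts0, cum)
    nn <- cpp_kd_query(tree, p)
    keep <- nn$distance <= config$correspondence_cap
    if (!any(keep)) stop("no correspondences survive the distance cap")
    pk <- p[keep, , drop = FALSE]
    q <- tv[nn$index[keep], , drop = FALSE]
    nrm <- tn[nn$index[keep], , drop = FALSE]
    rel <- sweep(pk, 2L, al$anchor)
    # d x (p - a): rotational velocity field about the axis
    cxp <- cbind(d[2] * rel[, 3] - d[3] * rel[, 2],
                 d[3] * rel[, 1] - d[1] * rel[, 3],
                 d[1] * rel[, 2] - d[2] * rel[, 1])
    A <- cbind(rowSums(nrm * cxp),
               as.vector(nrm %*% pb$e1),
               as.vector(nrm %*% pb$e2))
    b <- rowSums(nrm * (q - pk))
    rms_before <- sqrt(mean(b^2))
    if (!is.null(anchors)) {
      as_ <- apply_rigid(anchors$source, cum)
      at <- anchors$target
      w <- if (is.null(anchors$weight)) 0.1 else anchors$weight
      mu <- sqrt(w * nrow(A) / (9 * max(1 - w, 1e-6)))
      rel_a <- sweep(as_, 2L, al$anchor)
      ca <- cbind(d[2] * rel_a[, 3] - d[3] * rel_a[, 2],
                  d[3] * rel_a[, 1] - d[1] * rel_a[, 3],
                  d[1] * rel_a[, 2] - d[2] * rel_a[, 1])
      Aa <- mu * rbind(cbind(ca[, 1], pb$e1[1], pb$e2[1]),
                       cbind(ca[, 2], pb$e1[2], pb$e2[2]),
                       cbind(ca[, 3], pb$e1[3], pb$e2[3]))
      ba <- mu * as.vector(at - as_)
      A <- rbind(A, Aa)
      b <- c(b, ba)
    }
    rms_solve_before <- sqrt(mean(b^2))  # incl. anchors when present
    AtA <- crossprod(A)
    sol <- tryCatch(solve(AtA + diag(1e-12, 3L), crossprod(A, b)),
                    error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol))) stop("non-finite ICP solve")
    rms_after_lin <- sqrt(mean((as.vector(A %*% sol) - b)^2))
    step <- axis_constrained_transform(axis, sol[1L], sol[2L], sol[3L])
    cum <- compose_rigid(step, cum)
    trace[[iter]] <- c(rms_before = rms_solve_before,
                       rms_after_linear = rms_after_lin,
                       n_corr = sum(keep))
    rms <- rms_before
    if (is.finite(rms_prev) &&
        abs(rms_prev - rms) < config$convergence_tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
  }
  # final residual with the final transform
  p <- apply_rigid(pts0, cum)
  nn <- cpp_kd_query(tree, p)
  keep <- nn$distance <= config$correspondence_cap
  b <- rowSums(tn[nn$index[keep], , drop = FALSE] *
                 (tv[nn$index[keep], , drop = FALSE] -
                    p[keep, , drop = FALSE]))
  list(transform = cum, rms = sqrt(mean(b^2)), iterations = iter,
       converged = converged,
       trace = do.call(rbind, trace))
}
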