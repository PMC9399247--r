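test_that("landmark alignment recovers known transforms exactly", {
  tri <- landmark_triplet(c(0, 0, 0), c(-4, 1, 20), c(4, -1, 21))
  # identity
  tf <- landmark_align(tri, tri)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-12)
  # forward-composed transform
  for (s in 1:5) {
    known <- random_rigid(100 + s)
    moved <- apply_rigid(as_mat <- rbind(tri$apical, tri$incisal_left,
                                         tri$incisal_right), known)
    rec <- landmark_align(as_mat, moved)
    expect_equal(rec$rotation, known$rotation, tolerance = 1e-9)
    expect_equal(rec$translation, known$translation, tolerance = 1e-9)
  }
  expect_error(landmark_triplet(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("landmark alignment matches brute-force minimisation", {
  for (s in 1:6) {
    set.seed(300 + s)
    S <- matrix(rnorm(9, 0, 5), 3, 3)
    T_ <- matrix(rnorm(9, 0, 5), 3, 3)
    # degenerate (collinear) draws are rejected by the constructor; skip them
    area <- function(m) {
      a <- m[2, ] - m[1, ]; b <- m[3, ] - m[1, ]
      cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
              a[1] * b[2] - a[2] * b[1])
      0.5 * sqrt(sum(cr^2))
    }
    if (area(S) < 0.5 || area(T_) < 0.5) next
    tf <- landmark_align(S, T_)
    sse_pkg <- sum((apply_rigid(S, tf) - T_)^2)
    sse_oracle <- brute_align_sse(S, T_)
    expect_lt(abs(sse_pkg - sse_oracle), 1e-6 * max(1, sse_oracle))
  }
})

test_that("mirroring along the long axis fixes the axis and involutes", {
  tooth <- make_test_tooth(21, c(24, 24))
  axis <- tooth$axis
  al <- long_axis_line(axis)
  # points on the axis are fixed
  axis_pts <- rbind(al$anchor, al$anchor + 5 * al$direction,
                    al$anchor + 15 * al$direction)
  expect_equal(mirror_along_long_axis(axis_pts, axis), axis_pts,
               tolerance = 1e-12)
  m1 <- mirror_along_long_axis(tooth$mesh, axis)
  m2 <- mirror_along_long_axis(m1, axis)
  expect_equal(m2$vertices, tooth$mesh$vertices, tolerance = 1e-12)
  expect_equal(m2$faces, tooth$mesh$faces)
  expect_error(mirror_along_long_axis(tooth$mesh, axis,
                                      mirror_normal = al$direction),
               "perpendicular")
})

test_that("a bilaterally symmetric tooth is invariant under mirroring", {
  sym <- generate_tooth(tooth_shape_params("central"), c(32, 32))
  mir <- mirror_along_long_axis(sym$mesh, sym$axis)
  expect_lt(symmetric_hausdorff(sym$mesh$vertices, mir$vertices), 1e-9)
})

test_that("constrained ICP is a no-op on identical meshes", {
  tooth <- make_test_tooth(22, c(24, 24))
  fit <- constrained_icp(tooth$mesh, tooth$mesh, tooth$axis)
  expect_lt(fit$rms, 1e-9)
  mp <- axis_motion_params(fit$transform, tooth$axis)
  expect_lt(abs(mp$theta), 1e-9)
  expect_lt(abs(mp$u) + abs(mp$v), 1e-9)
})

test_that("constrained ICP recovers in-constraint motions to 1e-3", {
  tooth <- make_test_tooth(23, c(40, 40))
  axis <- tooth$axis
  truth <- list(theta = 5 * pi / 180, u = 0.5, v = -0.3)
  tf <- toothmatch:::axis_constrained_transform(axis, truth$theta, truth$u,
                                                truth$v)
  target <- apply_rigid(tooth$mesh, tf)
  fit <- constrained_icp(tooth$mesh, target, axis,
                         icp_config(sample_count = 1200))
  mp <- axis_motion_params(fit$transform, axis)
  expect_equal(mp$theta, truth$theta, tolerance = 1e-3)
  expect_equal(mp$u, truth$u, tolerance = 1e-3)
  expect_equal(mp$v, truth$v, tolerance = 1e-3)
})

test_that("constrained ICP transforms stay in the constraint family", {
  tooth <- make_test_tooth(24, c(24, 24))
  axis <- tooth$axis
  for (s in 1:5) {
    set.seed(400 + s)
    tf <- toothmatch:::axis_constrained_transform(
      axis, runif(1, -0.2, 0.2), runif(1, -1, 1), runif(1, -1, 1))
    target <- apply_rigid(tooth$mesh, tf)
    fit <- constrained_icp(tooth$mesh, target, axis)
    mp <- axis_motion_params(fit$transform, axis)
    expect_lt(mp$axis_rotation_error, 1e-9)
    expect_lt(abs(mp$axial_translation), 1e-9)
  }
})

test_that("the ICP inner solve never increases the linearised residual", {
  tooth <- make_test_tooth(25, c(24, 24))
  axis <- tooth$axis
  tf <- toothmatch:::axis_constrained_transform(axis, 0.1, 0.8, -0.5)
  target <- apply_rigid(tooth$mesh, tf)
  fit <- constrained_icp(tooth$mesh, target, axis)
  tr <- fit$trace
  expect_true(all(tr[, "rms_after_linear"] <= tr[, "rms_before"] + 1e-12))
})

test_that("out-of-constraint motion leaves the grid-search-optimal residual", {
  # translation along the axis cannot be compensated; the ICP residual must
  # match the best achievable within the constraint family
  tooth <- make_test_tooth(26, c(16, 16))
  axis <- tooth$axis
  al <- long_axis_line(axis)
  target <- apply_rigid(tooth$mesh,
                        rigid_transform(diag(3), al$direction * 1.0))
  cfg <- icp_config(sample_count = 300)
  fit <- constrained_icp(tooth$mesh, target, axis, cfg)
  sv <- tooth$mesh$vertices
  take <- unique(round(seq(1, nrow(sv), length.out = 300)))
  pb <- toothmatch:::perp_basis(al$direction)
  objfn <- constrained_objective(sv[take, , drop = FALSE], target$vertices,
                                 vertex_normals(target), al$direction,
                                 al$anchor, pb$e1, pb$e2,
                                 cfg$correspondence_cap)
  gs <- grid_search_constrained(objfn)
  expect_lt(abs(fit$rms - gs$rms), 0.05 * gs$rms)
})
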