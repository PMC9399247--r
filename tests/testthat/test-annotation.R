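test_that("periodic spline interpolates control points and closes", {
  grid <- make_flat_grid(41, 41, 0.6)  # 24 x 24 mm plane
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  cp <- cbind(10 + 8 * cos(th), 10 + 8 * sin(th), 0)
  cv <- spline_closed_curve(cp, samples = 200, mesh = grid)
  expect_true(cv$closed)
  expect_equal(cv$points[1, ], cv$points[nrow(cv$points), ])
  # passes through every control point
  for (i in seq_len(nrow(cp))) {
    dmin <- min(sqrt(colSums((t(cv$points) - cp[i, ])^2)))
    expect_lt(dmin, 0.05)
  }
})

test_that("spline through points on a circle stays within 0.1 mm radially", {
  grid <- make_flat_grid(61, 61, 0.4)
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  cp <- cbind(12 + 10 * cos(th), 12 + 10 * sin(th), 0)
  cv <- spline_closed_curve(cp, samples = 400, mesh = grid)
  r <- sqrt((cv$points[, 1] - 12)^2 + (cv$points[, 2] - 12)^2)
  expect_lt(max(abs(r - 10)), 0.1)
})

test_that("spline input validation", {
  expect_error(spline_closed_curve(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))),
               "at least 4")
  cp <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_error(spline_closed_curve(cp), "coincident")
})

test_that("geodesic offset of a straight line on a plane is a parallel line", {
  grid <- make_flat_grid(41, 31, 0.5)  # 20 x 15 mm
  xs <- seq(0.25, 19.75, length.out = 120)
  src <- surface_curve(cbind(xs, 5.3, 0), closed = FALSE)
  off <- geodesic_offset_curve(grid, src, 3, side_point = c(10, 14, 0))
  # all offset points at y ~ 8.3, i.e. Euclidean distance 3 +/- 2%
  inner <- off$points[, 1] > 1 & off$points[, 1] < 19  # away from rim
  expect_gt(sum(inner), 10)
  expect_lt(max(abs(off$points[inner, 2] - 5.3 - 3)), 0.06)
})

test_that("geodesic offset on a cylinder lands at the expected height", {
  cyl <- make_cylinder(radius = 4, z0 = -6, z1 = 6, nt = 64, nz = 31)
  th <- seq(0, 2 * pi, length.out = 97)
  src <- surface_curve(cbind(4 * cos(th), 4 * sin(th), 0), closed = TRUE)
  off <- geodesic_offset_curve(cyl, src, 3, side_point = c(4, 0, -6))
  expect_true(off$closed)
  expect_lt(max(abs(off$points[, 3] + 3)), 0.06)  # z = -3 within 2%
})

test_that("offset distance zero returns the source curve", {
  cyl <- make_cylinder()
  th <- seq(0, 2 * pi, length.out = 49)
  src <- surface_curve(cbind(4 * cos(th), 4 * sin(th), 0), closed = TRUE)
  off <- geodesic_offset_curve(cyl, src, 0, side_point = c(4, 0, -6))
  expect_equal(off$points[, 3], src$points[, 3], tolerance = 1e-6)
})

test_that("offset beyond the surface errors", {
  cyl <- make_cylinder(radius = 4, z0 = -2, z1 = 2)
  th <- seq(0, 2 * pi, length.out = 49)
  src <- surface_curve(cbind(4 * cos(th), 4 * sin(th), 0), closed = TRUE)
  expect_error(geodesic_offset_curve(cyl, src, 10, side_point = c(4, 0, -2)),
               "exceeds")
})

test_that("offset distances are consistent when measured back to the source", {
  # offset by d, then evaluate the geodesic field of the source at the
  # offset curve: recovered distance within 2% for d in 1..5 mm
  tooth <- make_test_tooth(7, c(32, 32), sd = 0.2)
  mesh <- tooth$mesh
  graph <- geodesic_graph(mesh)
  fld <- geodesic_field(mesh, tooth$gingival, graph = graph)
  for (d in c(1, 3, 5)) {
    off <- geodesic_offset_curve(mesh, tooth$gingival, d,
                                 side_point = tooth$landmarks$apical,
                                 graph = graph)
    back <- toothmatch:::field_at_curve(mesh, off, fld)
    expect_lt(abs(mean(back) - d) / d, 0.02)
  }
})

test_that("element extraction partitions a near-cylindrical tooth exactly", {
  cyl <- make_capped_cylinder(radius = 4, height = 20, nt = 48, nz = 41)
  th <- seq(0, 2 * pi, length.out = 97)
  ging <- surface_curve(cbind(4 * cos(th), 4 * sin(th), 8), closed = TRUE)
  graph <- geodesic_graph(cyl)
  off <- geodesic_offset_curve(cyl, ging, 3, side_point = c(4, 0, 0.5),
                               graph = graph)
  expect_lt(max(abs(off$points[, 3] - 5)), 0.1)
  el <- extract_elements(cyl, ging, off, incisal_side_point = c(0, 0, 20),
                         graph = graph)
  # exact area partition after face splitting
  total <- mesh_area(el$crown$mesh) + mesh_area(el$emergence$mesh) +
    mesh_area(el$root)
  expect_equal(total, mesh_area(cyl), tolerance = 1e-6)
  expect_equal(mesh_area(el$mesh), mesh_area(cyl), tolerance = 1e-9)
  # emergence band face centroids lie between the two curve heights
  fc <- el$emergence$mesh
  cen <- (fc$vertices[fc$faces[, 1], 3] + fc$vertices[fc$faces[, 2], 3] +
            fc$vertices[fc$faces[, 3], 3]) / 3
  eps <- 1.1  # max face diameter of this discretisation
  expect_true(all(cen > 5 - eps & cen < 8 + eps))
  # crown is the top region, root the bottom
  expect_gt(min(el$crown$mesh$vertices[, 3]), 8 - eps)
  expect_lt(max(el$root$vertices[, 3]), 5 + eps)
})

test_that("element extraction rejects open curves", {
  cyl <- make_capped_cylinder()
  th <- seq(0, 2 * pi, length.out = 97)
  ging <- surface_curve(cbind(4 * cos(th), 4 * sin(th), 8), closed = TRUE)
  open_g <- surface_curve(cbind(4 * cos(th[1:50]), 4 * sin(th[1:50]), 8),
                          closed = FALSE)
  off <- surface_curve(cbind(4 * cos(th), 4 * sin(th), 5), closed = TRUE)
  expect_error(extract_elements(cyl, open_g, off, c(0, 0, 20)), "closed")
})

test_that("element areas on a synthetic tooth conserve the total", {
  tooth <- make_test_tooth(9, c(32, 32))
  graph <- geodesic_graph(tooth$mesh)
  off <- geodesic_offset_curve(tooth$mesh, tooth$gingival, 3,
                               side_point = tooth$landmarks$apical,
                               graph = graph)
  inc <- (tooth$landmarks$incisal_left + tooth$landmarks$incisal_right) / 2
  el <- extract_elements(tooth$mesh, tooth$gingival, off, inc, graph = graph)
  total <- mesh_area(el$crown$mesh) + mesh_area(el$emergence$mesh) +
    mesh_area(el$root)
  expect_equal(total, mesh_area(tooth$mesh), tolerance = 1e-6)
  # crown contains the incisal edge, root the apex
  expect_equal(max(el$crown$mesh$vertices[, 3]),
               max(tooth$mesh$vertices[, 3]), tolerance = 1e-9)
  expect_equal(min(el$root$vertices[, 3]), 0, tolerance = 1e-9)
})
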