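test_that("STL roundtrip preserves geometry in both dialects", {
  tet <- make_tetrahedron()
  for (fmt in c("binary", "ascii")) {
    f <- withr::local_tempfile(fileext = ".stl")
    write_stl(tet, f, format = fmt)
    m <- read_stl(f)
    expect_equal(nrow(m$vertices), 4L)
    expect_equal(nrow(m$faces), 4L)
    expect_equal(sort(apply(m$vertices, 1, paste, collapse = ",")),
                 sort(apply(tet$vertices, 1, paste, collapse = ",")))
    expect_equal(mesh_area(m), mesh_area(tet), tolerance = 1e-12)
    expect_equal(mesh_volume(m), mesh_volume(tet), tolerance = 1e-12)
  }
  # binary facet count field
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(tet, f, format = "binary")
  con <- file(f, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  expect_identical(readBin(con, "integer", 1, size = 4, endian = "little"), 4L)
})

test_that("binary STL of a cube welds to 8 vertices and 12 faces", {
  cube <- make_cube()
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, f, format = "binary")
  m <- read_stl(f)
  expect_equal(nrow(m$vertices), 8L)
  expect_equal(nrow(m$faces), 12L)
  expect_equal(mesh_area(m), 6, tolerance = 1e-12)
  expect_equal(mesh_volume(m), 1, tolerance = 1e-12)
})

test_that("ASCII STL roundtrip is exact for arbitrary double meshes", {
  tooth <- make_test_tooth(3, c(16, 16))
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(tooth$mesh, f, format = "ascii")
  m <- read_stl(f)
  expect_equal(mesh_area(m), mesh_area(tooth$mesh), tolerance = 1e-9)
  expect_equal(mesh_volume(m), mesh_volume(tooth$mesh), tolerance = 1e-9)
})

test_that("binary STL roundtrip is exact for float32-representable meshes", {
  tooth <- make_test_tooth(4, c(16, 16))
  # snap coordinates to float32 before writing; the dialect stores float32
  v32 <- matrix(readBin(writeBin(as.numeric(tooth$mesh$vertices), raw(),
                                 size = 4), "numeric", size = 4,
                        n = length(tooth$mesh$vertices)),
                ncol = 3)
  m0 <- tooth_mesh(v32, tooth$mesh$faces)
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(m0, f, format = "binary")
  m <- read_stl(f)
  expect_equal(mesh_area(m), mesh_area(m0), tolerance = 1e-9)
  expect_equal(mesh_volume(m), mesh_volume(m0), tolerance = 1e-9)
})

test_that("degenerate STL inputs error cleanly", {
  f <- withr::local_tempfile(fileext = ".stl")
  # zero-facet binary file
  con <- file(f, "wb")
  writeBin(charToRaw(sprintf("%-80s", "empty")), con)
  writeBin(0L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_stl(f), "empty mesh")
  # truncated binary file
  con <- file(f, "wb")
  writeBin(charToRaw(sprintf("%-80s", "trunc")), con)
  writeBin(5L, con, size = 4, endian = "little")
  writeBin(as.raw(rep(0, 60)), con)
  close(con)
  expect_error(read_stl(f), "truncated|corrupt")
  expect_error(read_stl(file.path(tempdir(), "nope.stl")), "not found")
})

test_that("apply_rigid matches hand calculations and preserves distances", {
  tet <- make_tetrahedron()
  expect_equal(apply_rigid(tet, rigid_transform())$vertices, tet$vertices)
  rz90 <- rigid_transform(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3))
  expect_equal(apply_rigid(rbind(c(1, 0, 0)), rz90), rbind(c(0, 1, 0)),
               tolerance = 1e-15)
  tf <- random_rigid(11)
  back <- apply_rigid(apply_rigid(tet, tf), invert_rigid(tf))
  expect_equal(back$vertices, tet$vertices, tolerance = 1e-12)
  moved <- apply_rigid(tet, tf)
  expect_equal(as.numeric(dist(moved$vertices)),
               as.numeric(dist(tet$vertices)), tolerance = 1e-9)
})

test_that("rigid_transform rejects reflections and non-orthonormal input", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_transform(matrix(rnorm(9), 3, 3)), "orthonormal")
})

test_that("reflect_mesh is an involution that preserves oriented volume", {
  tet <- make_tetrahedron()
  pl <- reflection_plane(c(0.3, 0, 0), c(1, 1, 0.5))
  twice <- reflect_mesh(reflect_mesh(tet, pl), pl)
  expect_equal(twice$vertices, tet$vertices, tolerance = 1e-12)
  expect_equal(twice$faces, tet$faces)
  # hand reflection across x = 0
  plx <- reflection_plane(c(0, 0, 0), c(1, 0, 0))
  expect_equal(reflect_mesh(rbind(c(1, 2, 3)), plx), rbind(c(-1, 2, 3)))
  # point on the plane is fixed
  expect_equal(reflect_mesh(rbind(c(0, 2, 3)), plx), rbind(c(0, 2, 3)))
  # winding repair keeps signed volume
  expect_equal(mesh_volume(reflect_mesh(tet, pl)), mesh_volume(tet),
               tolerance = 1e-12)
})

test_that("long_axis_line normalises the apical-to-coronal direction", {
  expect_equal(long_axis_line(long_axis(c(0, 0, 0), c(0, 0, 10)))$direction,
               c(0, 0, 1))
  al <- long_axis_line(long_axis(c(0, 0, 0), c(3, 0, 4)))
  expect_equal(al$direction, c(0.6, 0, 0.8))
  expect_equal(al$anchor, c(0, 0, 0))
  expect_error(long_axis(c(1, 1, 1), c(1, 1, 1)), "coincide")
})

test_that("grid decimation clusters by occupied cells and bounds error", {
  # vertices >= 2 mm apart survive 1 mm clustering untouched
  tet <- make_tetrahedron()
  big <- tooth_mesh(tet$vertices * 3, tet$faces)
  expect_equal(nrow(decimate_grid(big, 1)$vertices), 4L)
  # dense tooth: vertex count bounded by independent cell occupancy
  tooth <- make_test_tooth(5, c(48, 48))
  dec <- decimate_grid(tooth$mesh, 1)
  expect_lte(nrow(dec$vertices), occupied_cells(tooth$mesh$vertices, 1))
  expect_lte(nrow(dec$vertices), nrow(tooth$mesh$vertices))
  # Hausdorff bound cell * sqrt(3)
  hd <- symmetric_hausdorff(tooth$mesh$vertices, dec$vertices)
  expect_lte(hd, sqrt(3))
  expect_error(decimate_grid(tooth$mesh, 0), "positive")
})

test_that("weld_mesh collapses coincident vertices", {
  tet <- make_tetrahedron()
  v <- tet$vertices[as.vector(t(tet$faces)), ]
  soup <- tooth_mesh(v, matrix(seq_len(12), ncol = 3, byrow = TRUE))
  m <- weld_mesh(soup)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(mesh_area(m), mesh_area(tet), tolerance = 1e-12)
})

test_that("an STL written here is readable by an independent mesh library", {
  py <- Sys.which("python")
  cube <- make_cube()
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, f, format = "binary")
  out <- system2(py, c("-c", shQuote(paste0(
    "import trimesh; m = trimesh.load('", f,
    "'); print(len(m.vertices), len(m.faces), round(m.area, 9))"))),
    stdout = TRUE)
  expect_identical(out, "8 12 6.0")
})
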