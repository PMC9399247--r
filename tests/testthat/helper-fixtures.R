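# Geometric fixtures built in code.

make_tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  tooth_mesh(v, f)
}

make_cube <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side),
                             z = c(0, side)))
  dimnames(v) <- NULL
  # 12 outward-wound triangles
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 (down)
    c(5, 6, 7), c(6, 8, 7),   # z = side (up)
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = side
  tooth_mesh(v, f)
}

# Flat rectangular grid in the z = 0 plane.
make_flat_grid <- function(nx = 30, ny = 30, dx = 0.5) {
  g <- expand.grid(x = (seq_len(nx) - 1) * dx, y = (seq_len(ny) - 1) * dx)
  v <- cbind(g$x, g$y, 0)
  vid <- function(i, j) (j - 1L) * nx + i
  i <- seq_len(nx - 1L)
  f <- NULL
  for (j in seq_len(ny - 1L)) {
    f <- rbind(f,
               cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
               cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  }
  tooth_mesh(v, f)
}

# Open cylinder tube of given radius along z.
make_cylinder <- function(radius = 4, z0 = -6, z1 = 6, nt = 48, nz = 25) {
  th <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  zz <- seq(z0, z1, length.out = nz)
  v <- cbind(radius * cos(rep(th, nz)), radius * sin(rep(th, nz)),
             rep(zz, each = nt))
  vid <- function(i, j) (j - 1L) * nt + ((i - 1L) %% nt) + 1L
  i <- seq_len(nt)
  f <- NULL
  for (j in seq_len(nz - 1L)) {
    f <- rbind(f,
               cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
               cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  }
  tooth_mesh(v, f)
}

# Capped cylinder (watertight) used as a near-cylindrical tooth stand-in.
make_capped_cylinder <- function(radius = 4, height = 20, nt = 48, nz = 41) {
  tube <- make_cylinder(radius, 0, height, nt, nz)
  v <- tube$vertices
  nv <- nrow(v)
  v <- rbind(v, c(0, 0, 0), c(0, 0, height))
  bot <- nv + 1L; top <- nv + 2L
  vid <- function(i, j) (j - 1L) * nt + ((i - 1L) %% nt) + 1L
  i <- seq_len(nt)
  f <- rbind(tube$faces,
             cbind(bot, vid(i + 1L, 1L), vid(i, 1L)),
             cbind(top, vid(i, nz), vid(i + 1L, nz)))
  tooth_mesh(v, f)
}

# A deformed single tooth model, reproducible by seed.
make_test_tooth <- function(seed = 1, resolution = c(32, 32),
                            tooth_type = "central", sd = 0.3) {
  set.seed(seed)
  d <- matrix(rnorm(15, 0, sd), 5, 3)
  generate_tooth(tooth_shape_params(tooth_type, deform = d), resolution,
                 id = paste0("fix", seed))
}

random_rigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, -pi, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (ax %o% ax)
  rigid_transform(R, rnorm(3, 0, 5))
}
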