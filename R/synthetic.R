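#' Parametric tooth shape parameters
#'
#' Defaults emulate maxillary anterior tooth anatomy: a tapered single root
#' blending into a superellipse-section crown with a cervical bulge, an
#' incisally tapering (blade-like) faciolingual width for incisors and a
#' pointier, more tapered crown for canines, and a scalloped gingival margin
#' at the cervix. All lengths in mm. The local frame is +z = long axis with
#' the root apex at the origin, x = mesiodistal, y = faciolingual.
#'
#' @param tooth_type `"central"`, `"lateral"` or `"canine"`.
#' @param ... overrides for individual fields (`crown_height`, `root_height`,
#'   `md_radius`, `fl_radius`, `bulge`, `superellipse_n`, `scallop`,
#'   `taper_md`, `taper_fl`, `deform`).
#' @return object of class `tooth_shape_params`.
#' @export
tooth_shape_params <- function(tooth_type = c("central", "lateral", "canine"),
                               ...) {
  tooth_type <- match.arg(tooth_type)
  base <- switch(tooth_type,
    central = list(crown_height = 10.5, root_height = 13.0,
                   md_radius = 4.2, fl_radius = 3.5, bulge = 0.15,
                   superellipse_n = 3.0, scallop = 1.0,
                   taper_md = 0.15, taper_fl = 0.70),
    lateral = list(crown_height = 9.0, root_height = 13.0,
                   md_radius = 3.3, fl_radius = 3.0, bulge = 0.15,
                   superellipse_n = 2.8, scallop = 0.9,
                   taper_md = 0.20, taper_fl = 0.70),
    canine = list(crown_height = 10.0, root_height = 16.0,
                  md_radius = 3.8, fl_radius = 4.0, bulge = 0.20,
                  superellipse_n = 2.2, scallop = 1.1,
                  taper_md = 0.45, taper_fl = 0.55))
  base$tooth_type <- tooth_type
  base$deform <- matrix(0, 5L, 3L)  # angular basis x axial basis, mm
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(base)) stop("unknown parameter: ", nm)
    base[[nm]] <- dots[[nm]]
  }
  stopifnot(base$crown_height > 0, base$root_height > 0,
            base$md_radius > 0, base$fl_radius > 0)
  structure(base, class = "tooth_shape_params")
}

# Radius of the parametric tooth surface at (theta, t), t in [0,1] axial.
# Vectorised over equal-length theta and t.
tooth_radius <- function(par, theta, t) {
  H <- par$root_height + par$crown_height
  tr <- par$root_height / H
  s <- pmax(0, (t - tr) / (1 - tr))        # crown coordinate, 0 at cervix
  cerv <- 1 + par$bulge * exp(-((0 - 0.35) / 0.28)^2)
  crown <- 1 + par$bulge * exp(-((s - 0.35) / 0.28)^2)
  prof_root <- cerv * pmax(t / tr, 0)^0.65
  a <- par$md_radius * ifelse(t <= tr, prof_root, crown * (1 - par$taper_md * s^2))
  b <- par$fl_radius * ifelse(t <= tr, prof_root, crown * (1 - par$taper_fl * s^2))
  n <- par$superellipse_n
  rse <- (abs(cos(theta))^n / a^n + abs(sin(theta))^n / b^n)^(-1 / n)
  # smooth low-order deformation field, damped toward the apex
  D <- par$deform
  M <- cbind(1, cos(theta), sin(theta), cos(2 * theta), sin(2 * theta))
  Tm <- cbind(1, t, t^2)
  dr <- rowSums((M %*% D) * Tm)
  w <- pmin(1, t / 0.25)
  pmax(rse + w * dr, 0.15 * rse)
}

#' Generate one synthetic tooth
#'
#' Builds a watertight triangulated tooth surface from
#' [tooth_shape_params()]: an apex-fan at the origin, axial rings, and a top
#' cap; computes the landmarks (apex, two incisal-edge points at the
#' mesiodistal extremes of the top edge, crown midpoint), the long axis, and
#' the scalloped gingival margin curve at the root/crown junction.
#'
#' @param params a [tooth_shape_params()].
#' @param resolution `c(n_theta, n_z)` angular x axial sample counts.
#' @param id identifier stored on the model.
#' @return object of class `tooth_model` with elements `mesh`, `tooth_type`,
#'   `side`, `landmarks`, `axis`, `gingival`, `params`, `id`.
#' @export
generate_tooth <- function(params, resolution = c(64, 64), id = "tooth") {
  nt <- as.integer(resolution[1L]); nz <- as.integer(resolution[2L])
  if (nt < 8L || nz < 8L) stop("resolution must be at least 8 x 8")
  H <- params$root_height + params$crown_height
  tr <- params$root_height / H
  theta <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  tt <- seq(0.035, 1, length.out = nz)
  th_g <- rep(theta, times = nz)
  t_g <- rep(tt, each = nt)
  r <- tooth_radius(params, th_g, t_g)
  v <- cbind(r * cos(th_g), r * sin(th_g), t_g * H)
  apex_id <- nt * nz + 1L
  top_ring <- v[(nt * (nz - 1L) + 1L):(nt * nz), , drop = FALSE]
  top_center <- c(colMeans(top_ring[, 1:2, drop = FALSE]), H)
  v <- rbind(v, c(0, 0, 0), top_center)
  top_id <- apex_id + 1L
  vid <- function(i, j) (j - 1L) * nt + ((i - 1L) %% nt) + 1L
  i <- seq_len(nt)
  faces <- vector("list", nz + 1L)
  for (j in seq_len(nz - 1L)) {
    faces[[j]] <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                        cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  }
  faces[[nz]] <- cbind(apex_id, vid(i + 1L, 1L), vid(i, 1L))
  faces[[nz + 1L]] <- cbind(top_id, vid(i, nz), vid(i + 1L, nz))
  mesh <- tooth_mesh(v, do.call(rbind, faces))
  # landmarks
  apex <- v[apex_id, ]
  inc_r <- v[vid(1L, nz), ]                     # theta = 0, +x (mesial/right)
  inc_l <- v[vid(nt %/% 2L + 1L, nz), ]         # theta = pi, -x
  crown_rows <- which(t_g > tr)
  crown_mid <- colMeans(v[crown_rows, , drop = FALSE])
  landmarks <- list(apical = apex, incisal_left = inc_l,
                    incisal_right = inc_r, crown_mid = crown_mid)
  axis <- long_axis(apex, crown_mid)
  # scalloped gingival margin on the parametric surface, projected to mesh
  ncv <- max(96L, 3L * nt)
  thc <- seq(0, 2 * pi, length.out = ncv + 1L)[-(ncv + 1L)]
  zc <- tr * H + params$scallop * cos(2 * thc)
  tc <- zc / H
  rc <- tooth_radius(params, thc, tc)
  cpts <- cbind(rc * cos(thc), rc * sin(thc), zc)
  cpts <- rbind(cpts, cpts[1L, ])
  pr <- project_to_surface(mesh, cpts)
  p2 <- pr$point; p2[nrow(p2), ] <- p2[1L, ]
  gingival <- surface_curve(p2, face = pr$face, bary = pr$bary, closed = TRUE)
  structure(list(mesh = mesh, tooth_type = params$tooth_type, side = "right",
                 landmarks = landmarks, axis = axis, gingival = gingival,
                 params = params, id = id),
            class = "tooth_model")
}

#' @export
print.tooth_model <- function(x, ...) {
  cat(sprintf("tooth_model %s: %s (%s side), %d vertices\n", x$id,
              x$tooth_type, x$side, nrow(x$mesh$vertices)))
  invisible(x)
}

# Reflect a whole tooth model across the plane x = 0 through its long axis
# (used to place generated left-side teeth in left anatomy).
reflect_tooth_model <- function(model, side = "left") {
  pl <- reflection_plane(c(0, 0, 0), c(1, 0, 0))
  mesh <- reflect_mesh(model$mesh, pl)
  lm <- model$landmarks
  rf <- function(p) { p[1] <- -p[1]; p }
  landmarks <- list(apical = rf(lm$apical),
                    incisal_left = rf(lm$incisal_right),   # sides swap
                    incisal_right = rf(lm$incisal_left),
                    crown_mid = rf(lm$crown_mid))
  gpts <- model$gingival$points
  gpts[, 1] <- -gpts[, 1]
  pr <- project_to_surface(mesh, gpts)
  p2 <- pr$point; p2[nrow(p2), ] <- p2[1L, ]
  model$mesh <- mesh
  model$landmarks <- landmarks
  model$axis <- long_axis(landmarks$apical, landmarks$crown_mid)
  model$gingival <- surface_curve(p2, face = pr$face, bary = pr$bary,
                                  closed = TRUE)
  model$side <- side
  model
}

#' Population configuration
#'
#' Study conditions for the synthetic bilateral population: inter-individual
#' shape variation (`sigma_pop`, the SD of each smooth deformation
#' coefficient) must exceed the left/right asymmetry noise (`sigma_asym`,
#' extra deformation applied to left sides) for contralateral matching to be
#' possible.
#'
#' @param n_individuals number of individuals (>= 1).
#' @param sigma_pop SD (mm) of per-individual deformation coefficients.
#' @param sigma_asym SD (mm) of the additional left-side deformation.
#' @param resolution `c(n_theta, n_z)` mesh resolution per tooth.
#' @param seed base RNG seed; everything downstream derives from it.
#' @return object of class `population_config`.
#' @export
population_config <- function(n_individuals, sigma_pop = 0.5,
                              sigma_asym = 0.05, resolution = c(64, 64),
                              seed = 1L) {
  stopifnot(n_individuals >= 1, sigma_pop >= 0, sigma_asym >= 0,
            all(resolution >= 8))
  structure(list(n_individuals = as.integer(n_individuals),
                 sigma_pop = sigma_pop, sigma_asym = sigma_asym,
                 resolution = as.integer(resolution),
                 seed = as.integer(seed)),
            class = "population_config")
}

TOOTH_TYPES <- c("central", "lateral", "canine")

#' Generate the six anterior teeth of one individual
#'
#' Right-side teeth are the per-type base shapes plus an individual smooth
#' deformation drawn from `Normal(0, sigma_pop^2)` per coefficient; left
#' teeth are mirror images of the same individual geometry with additional
#' `Normal(0, sigma_asym^2)` deformation (the bilateral asymmetry). Fully
#' deterministic given the seed.
#'
#' @param cfg a [population_config()].
#' @param individual_id id string.
#' @param seed RNG seed for this individual.
#' @return list with `id` and `teeth`: `teeth[[side]][[tooth_type]]` are
#'   [generate_tooth()] models.
#' @export
generate_individual <- function(cfg, individual_id, seed) {
  draws <- with_local_seed(seed, {
    lapply(TOOTH_TYPES, function(tp) {
      list(pop = matrix(stats::rnorm(15, 0, cfg$sigma_pop), 5L, 3L),
           asym = matrix(stats::rnorm(15, 0, cfg$sigma_asym), 5L, 3L))
    })
  })
  names(draws) <- TOOTH_TYPES
  right <- list(); left <- list()
  for (tp in TOOTH_TYPES) {
    pr <- tooth_shape_params(tp, deform = draws[[tp]]$pop)
    right[[tp]] <- generate_tooth(pr, cfg$resolution,
                                  id = paste(individual_id, tp, "R",
                                             sep = "_"))
    pl <- tooth_shape_params(tp, deform = draws[[tp]]$pop +
                               draws[[tp]]$asym)
    left[[tp]] <- reflect_tooth_model(
      generate_tooth(pl, cfg$resolution,
                     id = paste(individual_id, tp, "L", sep = "_")))
  }
  list(id = individual_id, teeth = list(right = right, left = left))
}

#' Generate a synthetic bilateral tooth population
#'
#' @param cfg a [population_config()].
#' @param dir optional output directory; when given, STL meshes, landmark
#'   and gingival-curve annotations, and a JSON manifest are written there
#'   (see [write_population()]).
#' @return object of class `tooth_population`: list of individuals plus the
#'   config.
#' @export
generate_population <- function(cfg, dir = NULL) {
  inds <- lapply(seq_len(cfg$n_individuals), function(i) {
    generate_individual(cfg, sprintf("ind%03d", i),
                        seed = cfg$seed + 7919L * i)
  })
  pop <- structure(list(individuals = inds, config = cfg),
                   class = "tooth_population")
  if (!is.null(dir)) write_population(pop, dir)
  pop
}

#' @export
print.tooth_population <- function(x, ...) {
  cat(sprintf(paste0("tooth_population: %d individuals x 6 teeth ",
                     "(sigma_pop = %.3g, sigma_asym = %.3g, seed = %d)\n"),
              length(x$individuals), x$config$sigma_pop,
              x$config$sigma_asym, x$config$seed))
  invisible(x)
}

#' Write a population to disk
#'
#' One binary STL per tooth plus a JSON manifest holding ids, file paths,
#' landmarks and gingival margin curves; [read_population()] restores the
#' pipeline inputs without the generator.
#'
#' @param pop a [generate_population()] result.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_population <- function(pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  records <- list()
  for (ind in pop$individuals) {
    for (side in c("right", "left")) {
      for (tp in TOOTH_TYPES) {
        m <- ind$teeth[[side]][[tp]]
        fn <- paste0(m$id, ".stl")
        write_stl(m$mesh, file.path(dir, fn), format = "binary")
        records[[length(records) + 1L]] <- list(
          individual = ind$id, tooth_type = tp, side = side, file = fn,
          landmarks = lapply(m$landmarks, as.numeric),
          gingival = list(points = unname(as.matrix(m$gingival$points)),
                          closed = TRUE))
      }
    }
  }
  manifest <- list(
    config = unclass(pop$config),
    teeth = records)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a population from a manifest directory
#'
#' @param dir directory written by [write_population()].
#' @return a `tooth_population`.
#' @export
read_population <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- population_config(man$config$n_individuals, man$config$sigma_pop,
                           man$config$sigma_asym, man$config$resolution,
                           man$config$seed)
  rec <- man$teeth
  ids <- unique(rec$individual)
  inds <- lapply(ids, function(iid) {
    teeth <- list(right = list(), left = list())
    rows <- which(rec$individual == iid)
    for (r in rows) {
      mesh <- read_stl(file.path(dir, rec$file[r]))
      lm <- lapply(rec$landmarks[r, ], function(x) as.numeric(x[[1]]))
      names(lm) <- colnames(rec$landmarks)
      gp <- rec$gingival$points[[r]]
      pr <- project_to_surface(mesh, gp)
      p2 <- pr$point; p2[nrow(p2), ] <- p2[1L, ]
      model <- structure(list(
        mesh = mesh, tooth_type = rec$tooth_type[r], side = rec$side[r],
        landmarks = lm, axis = long_axis(lm$apical, lm$crown_mid),
        gingival = surface_curve(p2, face = pr$face, bary = pr$bary,
                                 closed = TRUE),
        params = NULL,
        id = sub("\\.stl$", "", rec$file[r])), class = "tooth_model")
      teeth[[rec$side[r]]][[rec$tooth_type[r]]] <- model
    }
    list(id = iid, teeth = teeth)
  })
  structure(list(individuals = inds, config = cfg),
            class = "tooth_population")
}
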