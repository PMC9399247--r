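#' Simulate a population to a directory
#'
#' Thin wrapper over [generate_population()] + [write_population()]; the
#' first stage of the simulate / match / report pipeline.
#'
#' @param cfg a [population_config()].
#' @param dir output directory.
#' @return the population, invisibly.
#' @export
run_simulate <- function(cfg, dir) {
  pop <- generate_population(cfg, dir = dir)
  invisible(pop)
}

# Per-tooth preparation: element extraction along the gingival margin and
# its geodesic offset, plus sampled element surfaces. Left teeth are first
# mirrored along their long axis (the digital flip).
prepare_tooth <- function(model, density, offset_mm, seed, mirror = FALSE,
                          boundary_spacing = 0.15) {
  if (mirror) model <- mirror_tooth_model(model)
  mesh <- model$mesh
  graph <- geodesic_graph(mesh)
  offset <- geodesic_offset_curve(mesh, model$gingival, offset_mm,
                                  side_point = model$landmarks$apical,
                                  graph = graph)
  inc_mid <- (model$landmarks$incisal_left + model$landmarks$incisal_right) / 2
  el <- extract_elements(mesh, model$gingival, offset, inc_mid,
                         graph = graph, parent_id = model$id)
  list(model = model,
       crown = sample_surface(el$crown, density, seed = seed,
                              boundary_spacing = boundary_spacing),
       emergence = sample_surface(el$emergence, density, seed = seed + 1L,
                                  boundary_spacing = boundary_spacing),
       normals = vertex_normals(mesh),
       triplet = landmark_triplet(model$landmarks$apical,
                                  model$landmarks$incisal_left,
                                  model$landmarks$incisal_right))
}

#' Mirror a tooth model along its long axis
#'
#' Applies [mirror_along_long_axis()] to the mesh, swaps the left/right
#' incisal landmarks, and re-projects the gingival margin curve.
#'
#' @param model a `tooth_model`.
#' @param mirror_normal optional plane normal (defaults to the mesiodistal
#'   x direction projected perpendicular to the axis).
#' @return the mirrored `tooth_model`.
#' @export
mirror_tooth_model <- function(model, mirror_normal = NULL) {
  axis <- model$axis
  mesh <- mirror_along_long_axis(model$mesh, axis, mirror_normal)
  al <- long_axis_line(axis)
  if (is.null(mirror_normal)) {
    mirror_normal <- c(1, 0, 0) - sum(c(1, 0, 0) * al$direction) * al$direction
  }
  mirror_normal <- unit3(as.numeric(mirror_normal))
  pl <- reflection_plane(al$anchor, mirror_normal)
  lm <- model$landmarks
  landmarks <- list(apical = as.vector(reflect_mesh(rbind(lm$apical), pl)),
                    incisal_left = as.vector(reflect_mesh(rbind(lm$incisal_right), pl)),
                    incisal_right = as.vector(reflect_mesh(rbind(lm$incisal_left), pl)),
                    crown_mid = as.vector(reflect_mesh(rbind(lm$crown_mid), pl)))
  gp <- reflect_mesh(model$gingival$points, pl)
  pr <- project_to_surface(mesh, gp)
  p2 <- pr$point; p2[nrow(p2), ] <- p2[1L, ]
  model$mesh <- mesh
  model$landmarks <- landmarks
  model$axis <- long_axis(landmarks$apical, landmarks$crown_mid)
  model$gingival <- surface_curve(p2, face = pr$face, bary = pr$bary,
                                  closed = TRUE)
  model$side <- if (model$side == "left") "left_mirrored" else "right_mirrored"
  model
}

#' Run the pair-matching measurements over a population
#'
#' For every enumerated (right of i, mirrored left of j) pair and tooth
#' type: mirror the left tooth along its long axis, superimpose by landmark
#' alignment followed by constrained point-to-plane ICP on the full tooth
#' surfaces, then score the crown and emergence-profile elements by the
#' symmetric Hausdorff distance between their sampled surfaces.
#'
#' @param pop a `tooth_population` (from [generate_population()] or
#'   [read_population()]) or a manifest directory path.
#' @param icp an [icp_config()]; the default trades a slightly looser
#'   convergence tolerance for speed over the thousands of pairs of a
#'   population run.
#' @param density extra random surface samples per mm^2. The default (0)
#'   scores the corresponding vertex sets of the equally-tessellated meshes
#'   plus densified element boundaries: independent random resamplings
#'   impose a Hausdorff floor equal to their covering radius (~0.4 mm at
#'   10 points/mm^2), which would mask sub-0.1 mm bilateral asymmetries.
#' @param boundary_spacing spacing (mm) of the densified element-boundary
#'   samples (see [sample_surface()]).
#' @param offset_mm geodesic offset of the emergence-profile boundary below
#'   the gingival margin.
#' @param anchor_weight landmark-anchor weight passed to
#'   [constrained_icp()]; anchoring keeps the spin about the long axis
#'   anatomically determined on nearly rotation-symmetric teeth.
#' @param seed seed for the surface samplers (default: the population's).
#' @param verbose print per-tooth-type progress.
#' @return data.frame of pair comparisons: `right_individual`,
#'   `left_individual`, `tooth_type`, `element_kind`, `hd` (mm),
#'   `is_symmetric`, `icp_rms` (mm).
#' @export
run_match <- function(pop, icp = icp_config(max_iterations = 50,
                                            convergence_tol = 1e-4,
                                            sample_count = 600),
                      density = 0, boundary_spacing = 0.15,
                      offset_mm = 3, anchor_weight = 0.6, seed = NULL,
                      verbose = FALSE) {
  if (is.character(pop)) pop <- read_population(pop)
  if (is.null(seed)) seed <- pop$config$seed
  inds <- pop$individuals
  n <- length(inds)
  ids <- vapply(inds, function(x) x$id, character(1))
  rows <- vector("list", 0L)
  for (tp in TOOTH_TYPES) {
    if (verbose) message("preparing ", tp, " teeth")
    targets <- lapply(seq_len(n), function(i) {
      tg <- prepare_tooth(inds[[i]]$teeth$right[[tp]], density, offset_mm,
                          seed = seed + 101L * i,
                          boundary_spacing = boundary_spacing)
      # persistent search trees, shared by every source registered here
      tg$mesh_tree <- cpp_kd_build(tg$model$mesh$vertices)
      tg$crown_tree <- cpp_kd_build(tg$crown$points)
      tg$emergence_tree <- cpp_kd_build(tg$emergence$points)
      tg
    })
    sources <- lapply(seq_len(n), function(j) {
      prepare_tooth(inds[[j]]$teeth$left[[tp]], density, offset_mm,
                    seed = seed + 101L * j + 50L, mirror = TRUE,
                    boundary_spacing = boundary_spacing)
    })
    if (verbose) message("matching ", tp, ": ", n * n, " pairs")
    for (i in seq_len(n)) {
      tgt <- targets[[i]]
      taxis <- tgt$model$axis
      for (j in seq_len(n)) {
        src <- sources[[j]]
        t0 <- landmark_align(src$triplet, tgt$triplet)
        moved <- apply_rigid(src$model$mesh, t0)
        fit <- constrained_icp(moved, tgt$model$mesh, taxis, icp,
                               target_normals = tgt$normals,
                               target_tree = tgt$mesh_tree,
                               anchors = list(
                                 source = apply_rigid(
                                   as_landmark_matrix(src$triplet), t0),
                                 target = as_landmark_matrix(tgt$triplet),
                                 weight = anchor_weight))
        total <- compose_rigid(fit$transform, t0)
        src_c <- apply_rigid(src$crown$points, total)
        src_e <- apply_rigid(src$emergence$points, total)
        hd_c <- max(cpp_kd_hausdorff(tgt$crown_tree, src_c)$distance,
                    cpp_directed_hausdorff(tgt$crown$points, src_c)$distance)
        hd_e <- max(cpp_kd_hausdorff(tgt$emergence_tree, src_e)$distance,
                    cpp_directed_hausdorff(tgt$emergence$points,
                                           src_e)$distance)
        rows[[length(rows) + 1L]] <- data.frame(
          right_individual = ids[i], left_individual = ids[j],
          tooth_type = tp,
          element_kind = c("crown", "emergence_profile"),
          hd = c(hd_c, hd_e), is_symmetric = i == j,
          icp_rms = fit$rms, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate thresholds and report pair-matching performance
#'
#' Per tooth type x element group: ROC curve over all pairs, the match
#' threshold at full specificity, the smallest full-sensitivity threshold,
#' classification counts and rates at the full-specificity threshold,
#' jitter-plot data, and a one-way ANOVA comparing TP / FN / TN HD groups.
#'
#' @param comparisons data.frame from [run_match()].
#' @param tn_cap true negatives exported per group in the jitter data.
#' @return object of class `match_report`: `table` (per-group performance),
#'   `thresholds`, `roc` (named list of [compute_roc()] objects), `jitter`,
#'   `anova` (named list).
#' @export
run_report <- function(comparisons, tn_cap = 100L) {
  groups <- unique(comparisons[, c("tooth_type", "element_kind")])
  rocs <- list(); thr <- list(); aov_l <- list()
  for (i in seq_len(nrow(groups))) {
    key <- paste(groups$tooth_type[i], groups$element_kind[i], sep = ".")
    gi <- comparisons$tooth_type == groups$tooth_type[i] &
      comparisons$element_kind == groups$element_kind[i]
    roc <- compute_roc(comparisons[gi, , drop = FALSE])
    rocs[[key]] <- roc
    thr[[i]] <- data.frame(tooth_type = groups$tooth_type[i],
                           element_kind = groups$element_kind[i],
                           threshold = as.numeric(threshold_full_specificity(roc)),
                           threshold_full_sensitivity =
                             threshold_full_sensitivity(roc),
                           auc = roc$auc, stringsAsFactors = FALSE)
  }
  thresholds <- do.call(rbind, thr)
  tab <- classify_pairs(comparisons,
                        thresholds[, c("tooth_type", "element_kind",
                                       "threshold")])
  jit <- jitter_export(comparisons,
                       thresholds[, c("tooth_type", "element_kind",
                                      "threshold")], tn_cap = tn_cap)
  for (i in seq_len(nrow(groups))) {
    key <- paste(groups$tooth_type[i], groups$element_kind[i], sep = ".")
    ji <- jit$tooth_type == groups$tooth_type[i] &
      jit$element_kind == groups$element_kind[i]
    gs <- split(jit$hd[ji], jit$label[ji])
    gs <- gs[lengths(gs) >= 2L]
    aov_l[[key]] <- if (length(gs) >= 2L) one_way_anova(gs) else NULL
  }
  structure(list(table = tab, thresholds = thresholds, roc = rocs,
                 jitter = jit, anova = aov_l),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("match_report (threshold = largest HD at 100% specificity)\n")
  tab <- x$table
  tab$threshold <- round(tab$threshold, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write report artifacts to a directory
#'
#' `report.json` (per-group table + thresholds), `table1.csv` (element by
#' sensitivity/accuracy), `roc_<group>.csv` point files and `jitter.csv`.
#'
#' @param report a [run_report()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(list(table = report$table,
                            thresholds = report$thresholds),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(report$table[, c("tooth_type", "element_kind",
                                    "sensitivity", "accuracy")],
                   file.path(dir, "table1.csv"), row.names = FALSE)
  utils::write.csv(report$jitter, file.path(dir, "jitter.csv"),
                   row.names = FALSE)
  for (key in names(report$roc)) {
    r <- report$roc[[key]]
    utils::write.csv(data.frame(threshold = r$thresholds,
                                sensitivity = r$sensitivity,
                                specificity = r$specificity),
                     file.path(dir, paste0("roc_", key, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' End-to-end study on a synthetic population
#'
#' Generate, match and report in one call.
#'
#' @param cfg a [population_config()].
#' @param ... passed to [run_match()].
#' @return list with `population`, `comparisons`, `report`.
#' @export
run_study <- function(cfg, ...) {
  pop <- generate_population(cfg)
  cmp <- run_match(pop, ...)
  list(population = pop, comparisons = cmp, report = run_report(cmp))
}
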