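# Independent oracles: brute-force or closed-form reference implementations
# kept deliberately separate from the package's accelerated code paths.

# Directed Hausdorff by the exhaustive double loop.
brute_directed_hausdorff <- function(A, B) {
  worst <- -Inf
  for (i in seq_len(nrow(A))) {
    d2 <- min(colSums((t(B) - A[i, ])^2))
    if (d2 > worst) worst <- d2
  }
  sqrt(worst)
}

# Sensitivity/specificity by explicit reclassification at a threshold.
brute_rates <- function(hd, pos, t) {
  call <- hd <= t
  c(sens = sum(call & pos) / sum(pos),
    spec = sum(!call & !pos) / sum(!pos))
}

# Exhaustive threshold sweep: largest threshold with specificity 1, and
# smallest threshold with sensitivity 1.
sweep_thresholds <- function(hd, pos) {
  cand <- sort(unique(hd))
  r <- t(vapply(cand, function(t) brute_rates(hd, pos, t), numeric(2)))
  list(full_spec = if (any(r[, "spec"] == 1)) max(cand[r[, "spec"] == 1]) else NA,
       full_sens = min(cand[r[, "sens"] == 1]))
}

# Best rigid landmark superimposition by direct numerical minimisation over
# an axis-angle + translation parameterisation (multi-start).
brute_align_sse <- function(S, T_) {
  obj <- function(par) {
    ax <- par[1:3]; nrmx <- sqrt(sum(ax^2))
    th <- nrmx
    if (th < 1e-12) R <- diag(3) else {
      u <- ax / nrmx
      K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
      R <- diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (u %o% u)
    }
    M <- S %*% t(R) + matrix(par[4:6], nrow(S), 3, byrow = TRUE)
    sum((M - T_)^2)
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(s * 17)
    st <- c(rnorm(3, 0, 1.5), rnorm(3, 0, 2))
    o <- optim(st, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    o <- optim(o$par, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# Point-to-plane RMS objective of the constrained registration family,
# assembled from first principles (Rodrigues rotation about the axis line,
# in-plane translation), with nearest-vertex correspondences under the cap.
constrained_objective <- function(pts0, tverts, tnorms, axis_dir, axis_anchor,
                                  e1, e2, cap) {
  force(pts0)
  function(theta, u, v) {
    d <- axis_dir
    K <- matrix(c(0, d[3], -d[2], -d[3], 0, d[1], d[2], -d[1], 0), 3, 3)
    R <- diag(3) * cos(theta) + sin(theta) * K + (1 - cos(theta)) * (d %o% d)
    tr <- axis_anchor - as.vector(R %*% axis_anchor) + u * e1 + v * e2
    p <- pts0 %*% t(R) + matrix(tr, nrow(pts0), 3, byrow = TRUE)
    nn <- toothmatch:::cpp_nn(tverts, p)
    keep <- nn$distance <= cap
    if (!any(keep)) return(Inf)
    q <- tverts[nn$index[keep], , drop = FALSE]
    nr <- tnorms[nn$index[keep], , drop = FALSE]
    sqrt(mean(rowSums(nr * (q - p[keep, , drop = FALSE]))^2))
  }
}

# Multi-level grid search of the constrained objective; independent of the
# ICP iteration path.
grid_search_constrained <- function(objfn, theta_range = 0.3, uv_range = 2,
                                    steps = 9L, levels = 4L) {
  ctr <- c(0, 0, 0)
  half <- c(theta_range, uv_range, uv_range)
  best <- c(Inf, 0, 0, 0)
  for (lv in seq_len(levels)) {
    gr <- expand.grid(
      th = seq(ctr[1] - half[1], ctr[1] + half[1], length.out = steps),
      u = seq(ctr[2] - half[2], ctr[2] + half[2], length.out = steps),
      v = seq(ctr[3] - half[3], ctr[3] + half[3], length.out = steps))
    vals <- mapply(objfn, gr$th, gr$u, gr$v)
    i <- which.min(vals)
    if (vals[i] < best[1]) best <- c(vals[i], gr$th[i], gr$u[i], gr$v[i])
    ctr <- best[2:4]
    half <- half * 2.2 / (steps - 1)
  }
  list(rms = best[1], theta = best[2], u = best[3], v = best[4])
}

# Numerical quadrature of the F density upper tail, as an independent
# p-value check (QUADPACK, not the distribution function).
f_pvalue_quadrature <- function(f, df1, df2) {
  stats::integrate(function(x) stats::df(x, df1, df2), lower = f,
                   upper = Inf, rel.tol = 1e-10)$value
}

# Independent per-face cell occupancy count for grid decimation.
occupied_cells <- function(v, cell) {
  length(unique(paste(floor(v[, 1] / cell), floor(v[, 2] / cell),
                      floor(v[, 3] / cell))))
}
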