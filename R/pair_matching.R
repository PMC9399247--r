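#' Enumerate contralateral pair comparisons
#'
#' One comparison per ordered (right of individual i, mirrored left of
#' individual j) combination: i == j gives the n symmetric (true-pair)
#' comparisons, i != j the n(n-1) nonsymmetric ones. Only the
#' right-versus-mirrored-left direction is enumerated, on the assumption that
#' it agrees with the left-versus-mirrored-right match.
#'
#' @param individuals character or integer vector of individual ids.
#' @param tooth_type one of `"central"`, `"lateral"`, `"canine"`.
#' @return data.frame of comparison stubs with columns `right_individual`,
#'   `left_individual`, `tooth_type`, `is_symmetric`.
#' @export
enumerate_pairs <- function(individuals, tooth_type = "central") {
  if (anyDuplicated(individuals)) stop("duplicate individual ids")
  n <- length(individuals)
  if (n < 1L) stop("need at least one individual")
  g <- expand.grid(right_individual = individuals,
                   left_individual = individuals,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$tooth_type <- tooth_type
  g$is_symmetric <- g$right_individual == g$left_individual
  g[order(!g$is_symmetric), , drop = FALSE]
}

#' ROC curve over pair comparisons
#'
#' Candidate thresholds are the sorted distinct observed HD values; a pair is
#' called positive (a match) when its HD is less than or equal to the
#' threshold. AUC is the trapezoid area over (1-specificity, sensitivity).
#'
#' @param comparisons data.frame with columns `hd` and `is_symmetric`.
#' @return object of class `roc_curve` with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `n_pos`, `n_neg`.
#' @export
compute_roc <- function(comparisons) {
  hd <- comparisons$hd
  pos <- comparisons$is_symmetric
  if (anyNA(hd) || any(hd < 0)) stop("hd values must be non-negative")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos < 1L || n_neg < 1L)
    stop("need at least one symmetric and one nonsymmetric comparison")
  th <- sort(unique(hd))
  tp <- vapply(th, function(t) sum(hd[pos] <= t), numeric(1))
  fp <- vapply(th, function(t) sum(hd[!pos] <= t), numeric(1))
  sens <- tp / n_pos
  spec <- (n_neg - fp) / n_neg
  fpr <- c(0, 1 - spec)
  tpr <- c(0, sens)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d positives, %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Match threshold at full specificity
#'
#' The largest candidate threshold retaining specificity 1 (no nonsymmetric
#' pair classified as a match) — the operating point that maximises
#' sensitivity subject to zero false positives. When even the smallest
#' symmetric HD exceeds some nonsymmetric HD, a degenerate threshold below
#' all observed values is returned with attribute `degenerate = TRUE`.
#'
#' @param roc a [compute_roc()] result.
#' @return threshold in mm (with attribute `degenerate` when applicable).
#' @export
threshold_full_specificity <- function(roc) {
  ok <- roc$specificity == 1
  if (!any(ok)) {
    out <- min(roc$thresholds) / 2
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  max(roc$thresholds[ok])
}

#' Smallest threshold at full sensitivity
#'
#' The smallest candidate threshold classifying every symmetric pair as a
#' match; identically the largest symmetric HD.
#'
#' @param roc a [compute_roc()] result.
#' @return threshold in mm.
#' @export
threshold_full_sensitivity <- function(roc) {
  min(roc$thresholds[roc$sensitivity == 1])
}

#' Classify pair comparisons at an HD threshold
#'
#' A pair is a predicted match when `hd <= threshold` (ties count as
#' matches). Counts and rates are reported per `tooth_type` x `element_kind`
#' group present in the input (one overall row when those columns are
#' absent).
#'
#' @param comparisons data.frame with `hd`, `is_symmetric` and optionally
#'   `tooth_type`, `element_kind`.
#' @param threshold scalar threshold (mm), or a data.frame with columns
#'   `tooth_type`, `element_kind`, `threshold` for per-group thresholds.
#' @return data.frame (one row per group): threshold, TP, FN, TN, FP,
#'   sensitivity (%), specificity (%), accuracy (%).
#' @export
classify_pairs <- function(comparisons, threshold) {
  df <- comparisons
  if (is.null(df$tooth_type)) df$tooth_type <- "all"
  if (is.null(df$element_kind)) df$element_kind <- "all"
  groups <- unique(df[, c("tooth_type", "element_kind")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    gi <- df$tooth_type == groups$tooth_type[i] &
      df$element_kind == groups$element_kind[i]
    thr <- if (is.data.frame(threshold)) {
      j <- which(threshold$tooth_type == groups$tooth_type[i] &
                   threshold$element_kind == groups$element_kind[i])
      if (length(j) != 1L) stop("no threshold for group ",
                                groups$tooth_type[i], "/",
                                groups$element_kind[i])
      threshold$threshold[j]
    } else as.numeric(threshold)
    if (thr < 0) stop("threshold must be >= 0")
    hd <- df$hd[gi]; pos <- df$is_symmetric[gi]
    call_match <- hd <= thr
    tp <- sum(call_match & pos); fn <- sum(!call_match & pos)
    fp <- sum(call_match & !pos); tn <- sum(!call_match & !pos)
    data.frame(tooth_type = groups$tooth_type[i],
               element_kind = groups$element_kind[i],
               threshold = thr, tp = tp, fn = fn, tn = tn, fp = fp,
               sensitivity = 100 * tp / (tp + fn),
               specificity = 100 * tn / (tn + fp),
               accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cohen's kappa with large-sample confidence interval
#'
#' Chance-corrected agreement between two raters from a square contingency
#' table: k = (p_o - p_e) / (1 - p_e).
#'
#' @param ratings square numeric matrix of cross-tabulated counts.
#' @param conf_level confidence level for the normal-approximation interval.
#' @return list with `kappa`, `p_observed`, `p_expected`, `se`, `ci_lower`,
#'   `ci_upper`.
#' @export
cohens_kappa <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (nrow(m) != ncol(m)) stop("ratings table must be square")
  n <- sum(m)
  if (n <= 0) stop("empty ratings table")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (1 - pe < 1e-12) stop("chance agreement is 1; kappa undefined")
  k <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(kappa = k, p_observed = po, p_expected = pe, se = se,
       ci_lower = k - z * se, ci_upper = k + z * se)
}

#' One-way analysis of variance over HD groups
#'
#' Standard between/within sum-of-squares decomposition with the p-value
#' from the F distribution; used to compare true-positive, false-negative
#' and true-negative HD distributions.
#'
#' @param groups list of (>= 2) numeric vectors.
#' @return list with `F`, `df1`, `df2`, `p_value`, and `degenerate` (TRUE
#'   when within-group variance is zero with nonzero between-group variance,
#'   in which case `p_value` is 0).
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 2L) stop("need at least 2 groups")
  ni <- lengths(groups)
  n <- sum(ni)
  kg <- length(groups)
  if (n - kg < 1L) stop("need at least 1 residual degree of freedom")
  gm <- mean(unlist(groups))
  mi <- vapply(groups, mean, numeric(1))
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- kg - 1L; df2 <- n - kg
  if (ssw < 1e-300) {
    if (ssb < 1e-300)
      return(list(F = 0, df1 = df1, df2 = df2, p_value = 1,
                  degenerate = FALSE))
    return(list(F = Inf, df1 = df1, df2 = df2, p_value = 0,
                degenerate = TRUE))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Export jitter-plot data
#'
#' Per group: every true-positive and false-negative HD, plus the smallest
#' `min(tn_cap, count)` true-negative HDs (the plotted subset of the many
#' nonsymmetric comparisons).
#'
#' @param comparisons data.frame with `hd`, `is_symmetric` and optionally
#'   `tooth_type`, `element_kind`.
#' @param threshold scalar or per-group threshold data.frame (see
#'   [classify_pairs()]).
#' @param tn_cap number of smallest true negatives exported per group.
#' @return data.frame with `tooth_type`, `element_kind`, `label` (TP, FN,
#'   TN), `hd`.
#' @export
jitter_export <- function(comparisons, threshold, tn_cap = 100L) {
  df <- comparisons
  if (is.null(df$tooth_type)) df$tooth_type <- "all"
  if (is.null(df$element_kind)) df$element_kind <- "all"
  groups <- unique(df[, c("tooth_type", "element_kind")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    gi <- df$tooth_type == groups$tooth_type[i] &
      df$element_kind == groups$element_kind[i]
    thr <- if (is.data.frame(threshold)) {
      j <- which(threshold$tooth_type == groups$tooth_type[i] &
                   threshold$element_kind == groups$element_kind[i])
      threshold$threshold[j]
    } else as.numeric(threshold)
    hd <- df$hd[gi]; pos <- df$is_symmetric[gi]
    tp <- hd[pos & hd <= thr]
    fn <- hd[pos & hd > thr]
    tnv <- sort(hd[!pos & hd > thr])
    tnv <- tnv[seq_len(min(tn_cap, length(tnv)))]
    data.frame(tooth_type = groups$tooth_type[i],
               element_kind = groups$element_kind[i],
               label = c(rep("TP", length(tp)), rep("FN", length(fn)),
                         rep("TN", length(tnv))),
               hd = c(tp, fn, tnv), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
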