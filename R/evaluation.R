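# Performance and reproducibility statistics: ROC/AUC with DeLong or
# bootstrap intervals, Hosmer-Lemeshow calibration, ICC(2,1), and the
# correlation-distance cluster map.

#' Mann-Whitney AUC
#'
#' The area under the ROC curve as the probability that a random positive
#' scores above a random negative, ties counted one half. Used internally
#' and handy as a fast rank-based AUC.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC with confidence interval
#'
#' AUC by the Mann-Whitney identity with a 95% confidence interval by the
#' DeLong method (default) or the stratified bootstrap (2000 replicates,
#' seeded). The curve itself (thresholds, sensitivity, specificity) comes
#' from the full empirical ROC.
#'
#' @param scores Numeric scores, higher indicating the positive class.
#' @param labels Binary labels.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap CI.
#' @return Object of class `roc_result`: `auc`, `ci` (length 2),
#'   `thresholds`, `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    boot_n = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  r <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  ci <- if (ci_method == "delong") {
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]
  } else {
    set.seed(seed)
    as.numeric(pROC::ci.auc(r, method = "bootstrap", boot.n = boot_n))[c(1, 3)]
  }
  ci <- pmin(pmax(ci, 0), 1)
  structure(
    list(auc = as.numeric(pROC::auc(r)), ci = ci,
         thresholds = r$thresholds, sensitivity = r$sensitivities,
         specificity = r$specificities,
         n_pos = sum(labels == 1), n_neg = sum(labels == 0)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI: %.3f-%.3f), n_pos=%d, n_neg=%d\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk calibration test: rows are binned by predicted
#' probability into `bins` equal-count groups (tied probabilities stay
#' together), and `sum((O - E)^2 / E)` over bins and both outcomes is
#' referred to a chi-square with `bins - 2` degrees of freedom. Bins whose
#' expected count vanishes are merged with a warning.
#'
#' @param probs Predicted probabilities in (0, 1).
#' @param labels Binary outcomes.
#' @param bins Number of bins (default 10).
#' @return Object of class `hl_result`: `statistic`, `df`, `p_value`,
#'   `table` (per-bin observed/expected).
#' @export
hosmer_lemeshow <- function(probs, labels, bins = 10L) {
  labels <- as.integer(as.logical(labels))
  if (any(probs <= 0 | probs >= 1)) stop("probabilities must lie strictly in (0,1)")
  n <- length(probs)
  if (n < 2L * bins) stop("need at least 2*bins observations")
  # rank-based equal-count bins; tied probabilities share a rank and stay
  # together, and the assignment is exactly mirror-symmetric under
  # probability complementation
  r <- rank(probs, ties.method = "average")
  grp <- factor(ceiling(r * bins / n - 1e-9))
  o1 <- tapply(labels, grp, sum)
  e1 <- tapply(probs, grp, sum)
  nn <- tapply(rep(1L, n), grp, sum)
  keep <- !is.na(nn)
  o1 <- o1[keep]; e1 <- e1[keep]; nn <- nn[keep]
  if (any(e1 < 1e-9 | (nn - e1) < 1e-9)) {
    warning("bin(s) with vanishing expected count merged into neighbors")
    ok <- e1 >= 1e-9 & (nn - e1) >= 1e-9
    o1 <- c(sum(o1[!ok]), o1[ok]); e1 <- c(sum(e1[!ok]), e1[ok])
    nn <- c(sum(nn[!ok]), nn[ok])
    if (e1[1] == 0) { o1 <- o1[-1]; e1 <- e1[-1]; nn <- nn[-1] }
  }
  stat <- sum((o1 - e1)^2 / e1 + ((nn - o1) - (nn - e1))^2 / (nn - e1))
  df <- max(length(o1) - 2L, 1L)
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         table = data.frame(n = as.integer(nn), observed = as.integer(o1),
                            expected = as.numeric(e1))),
    class = "hl_result"
  )
}

#' @export
print.hl_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f on %d df, p = %.4f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement — the
#' standard form for inter- and intra-observer reproducibility of feature
#' measurements. Computed from the two-way ANOVA mean squares:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Zero between-subject variance yields ICC 0 with `degenerate = TRUE`.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (complete, >= 3 subjects, >= 2 raters).
#' @return Object of class `icc_result`: `icc`, `model`, `n_subjects`,
#'   `n_raters`, `degenerate`.
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L || k < 2L) stop("ICC needs >= 3 subjects and >= 2 raters")
  if (any(!is.finite(ratings))) stop("ratings grid must be complete and finite")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  degenerate <- msr <= mse
  val <- if (degenerate) 0 else (msr - mse) / denom
  structure(
    list(icc = val,
         model = "ICC(2,1) two-way random, absolute agreement, single rater",
         n_subjects = n, n_raters = k, degenerate = degenerate),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s: %.3f (n=%d subjects, k=%d raters)%s\n", x$model, x$icc,
              x$n_subjects, x$n_raters,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Correlation-distance cluster map ordering
#'
#' Z-scores every feature (zero mean, unit SD), drops zero-variance
#' features with a warning, and hierarchically clusters both ROIs (rows)
#' and features (columns) with correlation distance `1 - Pearson r` and
#' average linkage. Returns the leaf orderings and the dendrograms; a
#' Newick export is available via [dendrogram_newick()].
#'
#' @param table Feature table.
#' @return Object of class `cluster_map`: `row_order`, `col_order`,
#'   `row_hclust`, `col_hclust`, `z` (the z-scored matrix).
#' @export
cluster_map <- function(table) {
  fm <- feature_matrix(table)
  x <- fm$x
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 ROIs and >= 2 features")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("all features have zero variance")
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance feature(s)")
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  d_col <- stats::as.dist(1 - stats::cor(z))
  d_row <- stats::as.dist(1 - stats::cor(t(z)))
  hc_col <- stats::hclust(d_col, method = "average")
  hc_row <- stats::hclust(d_row, method = "average")
  structure(
    list(row_order = hc_row$order, col_order = hc_col$order,
         row_hclust = hc_row, col_hclust = hc_col, z = z),
    class = "cluster_map"
  )
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An `hclust` object (e.g. `cluster_map(...)$row_hclust`).
#' @return A single Newick-format string.
#' @export
dendrogram_newick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("package 'ape' is required for Newick export")
  ape::write.tree(ape::as.phylo(hc))
}
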