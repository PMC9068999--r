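#' Canonical texture feature names
#'
#' The fixed, ordered name set of the default feature vector: 11 histogram
#' features, 11 co-occurrence features for each of 20 offsets (distances
#' 1..5 by directions `(d,0)`, `(0,d)`, `(d,d)`, `(d,-d)`), 5 gradient
#' features, 5 run-length features for each of 4 directions, and the 5
#' autoregressive features — 261 names in total. Every feature referenced
#' by the packaged printed discriminant functions and radiomics signatures
#' is in this set.
#'
#' @param distances Co-occurrence distances (default `1:5`).
#' @return Character vector of feature names in canonical order.
#' @export
canonical_feature_names <- function(distances = 1:5) {
  hist_names <- c("Mean", "Variance", "Skewness", "Kurtosis",
                  "Perc.01%", "Perc.10%", "Perc.50%", "Perc.90%", "Perc.99%",
                  "MinNorm", "MaxNorm")
  glcm_feats <- c("AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDfMom",
                  "SumAverg", "SumVarnc", "SumEntrp", "Entropy", "DifVarnc",
                  "DifEntrp")
  off <- glcm_offsets(distances)
  glcm_names <- unlist(lapply(seq_len(nrow(off)), function(k)
    sprintf("S(%d,%d)%s", off$dx[k], off$dy[k], glcm_feats)))
  grad_names <- c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis", "GrNonZeros")
  rlm_feats <- c("RLNonUni", "GLevNonU", "LngREmph", "ShrtREmp", "Fraction")
  rlm_names <- unlist(lapply(c("Horzl", "Vertl", "45dgr", "135dr"),
                             function(d) paste(d, rlm_feats, sep = "_")))
  ar_names <- c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma")
  c(hist_names, glcm_names, grad_names, rlm_names, ar_names)
}

#' Extract the full named feature vector from one ROI
#'
#' Concatenates all feature families in canonical order (see
#' [canonical_feature_names()]). All families are computed on the same
#' quantized level grid for internal consistency.
#'
#' @param roi A `quantized_roi`.
#' @param distances Co-occurrence distances (default `1:5`).
#' @param symmetric Symmetric co-occurrence accumulation (default `TRUE`).
#' @return Named numeric vector of length 261 (for the default config).
#' @export
extract_features <- function(roi, distances = 1:5, symmetric = TRUE) {
  off <- glcm_offsets(distances)
  glcm_vals <- unlist(lapply(seq_len(nrow(off)), function(k) {
    f <- glcm_features(compute_glcm(roi, off$dx[k], off$dy[k], symmetric))
    names(f) <- sprintf("S(%d,%d)%s", off$dx[k], off$dy[k], names(f))
    f
  }))
  rlm_vals <- unlist(lapply(c("Horzl", "Vertl", "45dgr", "135dr"), function(d) {
    f <- rlm_features(roi, d)
    names(f) <- paste(d, names(f), sep = "_")
    f
  }))
  fit <- ar_fit(roi)
  out <- c(histogram_features(roi), glcm_vals, gradient_features(roi),
           rlm_vals, c(fit$teta, Sigma = fit$sigma))
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature value(s): ", paste(names(out)[bad], collapse = ", "))
  out
}

#' Extract a feature table from images and an ROI table
#'
#' Applies [normalize_quantize()] then [extract_features()] to every row of
#' the ROI table. Images are supplied as a named list of [image2d()]
#' objects keyed by `"<rat_id>_<slice_id>"`.
#'
#' @param images Named list of [image2d()], keys `"<rat_id>_<slice_id>"`.
#' @param roi_table Data frame of ROI rows (see [read_roi_table()]).
#' @param k_bits,clip_mode Passed to [normalize_quantize()].
#' @param distances,symmetric Passed to [extract_features()].
#' @return A `data.frame` (class `feature_table`): metadata columns
#'   `rat_id`, `slice_id`, `side`, `group`, then the canonical features.
#' @export
extract_feature_table <- function(images, roi_table, k_bits = 6L,
                                  clip_mode = "mu3sd", distances = 1:5,
                                  symmetric = TRUE) {
  rows <- lapply(seq_len(nrow(roi_table)), function(r) {
    roi <- roi_table[r, ]
    key <- paste(roi$rat_id, roi$slice_id, sep = "_")
    img <- images[[key]]
    if (is.null(img)) stop("no image for ROI key: ", key)
    q <- normalize_quantize(img, roi, k_bits = k_bits, clip_mode = clip_mode)
    extract_features(q, distances = distances, symmetric = symmetric)
  })
  feat <- do.call(rbind, rows)
  meta <- roi_table[, c("rat_id", "slice_id", "side", "group"), drop = FALSE]
  out <- cbind(meta, as.data.frame(feat, check.names = FALSE))
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Split a feature table into its feature matrix and metadata
#' @param table A feature table (data frame with a `group` column).
#' @return List with `x` (numeric matrix, features), `group` (factor),
#'   `meta` (data.frame of non-feature columns).
#' @export
feature_matrix <- function(table) {
  meta_cols <- intersect(c("rat_id", "slice_id", "side", "group"), names(table))
  feat_cols <- setdiff(names(table), meta_cols)
  x <- as.matrix(table[, feat_cols, drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, group = factor(table$group, levels = unique(table$group)),
       meta = table[, meta_cols, drop = FALSE])
}

#' Write / read a feature table as CSV
#'
#' Metadata columns first, then features in canonical order; feature names
#' (which contain `%`, parentheses and commas) are preserved verbatim.
#'
#' @param table A feature table.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}
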