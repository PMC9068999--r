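# Stepwise discriminant analysis: Wilks-lambda feature selection, canonical
# discriminant functions, Fisher linear classification functions, and
# resubstitution / leave-one-out evaluation.

# within-group (W) and total (T) scatter matrices for all feature columns
.scatter <- function(x, group) {
  group <- droplevels(factor(group))
  xc_t <- scale(x, center = TRUE, scale = FALSE)
  t_mat <- crossprod(xc_t)
  w_mat <- matrix(0, ncol(x), ncol(x))
  for (g in levels(group)) {
    xg <- x[group == g, , drop = FALSE]
    w_mat <- w_mat + crossprod(scale(xg, center = TRUE, scale = FALSE))
  }
  dimnames(w_mat) <- dimnames(t_mat)
  list(W = w_mat, T = t_mat)
}

# log-determinant via Cholesky; NA when not positive definite
.logdet <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  2 * sum(log(diag(ch)))
}

# Wilks' Lambda = det(W)/det(T) for a column subset, from precomputed scatters
.wilks_subset <- function(sc, idx) {
  lw <- .logdet(sc$W[idx, idx, drop = FALSE])
  lt <- .logdet(sc$T[idx, idx, drop = FALSE])
  if (is.na(lw) || is.na(lt)) return(NA_real_)
  exp(lw - lt)
}

#' Stepwise feature selection by Wilks' lambda
#'
#' Classic stepwise discriminant selection: at each step the candidate
#' minimizing the partial Wilks' lambda enters if its partial F-to-enter
#' reaches `f_enter`; afterwards any included feature whose F-to-remove
#' falls below `f_remove` leaves. With `p` features already in,
#' `F = ((Lambda_p / Lambda_{p+1}) - 1) * (n - g - p) / (g - 1)`.
#' Candidates producing a numerically singular within-group scatter are
#' skipped with a warning.
#'
#' @param table A feature table (data frame with `group` plus feature
#'   columns), or a list as returned by [feature_matrix()].
#' @param f_enter,f_remove F thresholds (defaults 3.84 / 2.71, the common
#'   statistical-package defaults).
#' @param max_steps Maximum number of entry steps.
#' @return Character vector of selected feature names, in entry order.
#' @export
stepwise_select <- function(table, f_enter = 3.84, f_remove = 2.71,
                            max_steps = 50L) {
  fm <- if (is.list(table) && !is.data.frame(table)) table else feature_matrix(table)
  x <- fm$x; group <- droplevels(factor(fm$group))
  n <- nrow(x); g <- nlevels(group)
  if (g < 2L) stop("stepwise selection needs at least two groups")
  if (f_enter <= f_remove) stop("f_enter must exceed f_remove")
  sc <- .scatter(x, group)
  p_all <- ncol(x)
  sel <- integer(0)
  lambda_cur <- 1
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    # entry; candidates whose within-group scatter is (near-)singular with
    # the current set are skipped (tolerance guard against collinearity)
    cand <- setdiff(seq_len(p_all), sel)
    if (length(cand) && n - g - length(sel) > 1) {
      lam <- vapply(cand, function(kk) {
        idx <- c(sel, kk)
        if (rcond(sc$W[idx, idx, drop = FALSE]) < 1e-10) return(NA_real_)
        .wilks_subset(sc, idx)
      }, 0)
      ok <- is.finite(lam) & lam > 1e-12
      if (any(!is.finite(lam)))
        warning("skipped candidate(s) with singular within-group scatter")
      if (any(ok)) {
        best <- cand[ok][which.min(lam[ok])]
        lam_best <- min(lam[ok])
        f_stat <- (lambda_cur / lam_best - 1) * (n - g - length(sel)) / (g - 1)
        if (f_stat >= f_enter) {
          sel <- c(sel, best)
          lambda_cur <- lam_best
          changed <- TRUE
        }
      }
    }
    # removal
    if (length(sel) > 1L) {
      repeat {
        lam_wo <- vapply(seq_along(sel), function(ii)
          .wilks_subset(sc, sel[-ii]), 0)
        f_rm <- (lam_wo / lambda_cur - 1) * (n - g - length(sel) + 1) / (g - 1)
        worst <- which.min(f_rm)
        if (is.finite(f_rm[worst]) && f_rm[worst] < f_remove) {
          lambda_cur <- lam_wo[worst]
          sel <- sel[-worst]
          changed <- TRUE
        } else break
        if (length(sel) <= 1L) break
      }
    }
    if (!changed) break
  }
  colnames(x)[sel]
}

#' Wilks-lambda / Bartlett arithmetic from discriminant eigenvalues
#'
#' The dimensionality-test chain of canonical discriminant analysis,
#' computed purely from the eigenvalues and the design counts: percent
#' variance per function, residual Wilks' lambdas
#' `Lambda_k = prod_{i>=k} 1/(1+lambda_i)`, and Bartlett chi-square
#' statistics `chi2_k = -(n - 1 - (p+g)/2) * ln Lambda_k` on
#' `(p-k+1)(g-k)` degrees of freedom.
#'
#' @param eigenvalues Discriminant eigenvalues, descending.
#' @param n,p,g Sample size, number of features, number of groups.
#' @return Data frame with columns `eigenvalue`, `pct_variance`, `wilks`,
#'   `chisq`, `df`, `p_value`.
#' @export
canonical_chain <- function(eigenvalues, n, p, g) {
  m <- length(eigenvalues)
  wilks <- rev(cumprod(rev(1 / (1 + eigenvalues))))
  mult <- n - 1 - (p + g) / 2
  chisq <- -mult * log(wilks)
  df <- vapply(seq_len(m), function(k) (p - k + 1) * (g - k), 0)
  data.frame(eigenvalue = eigenvalues,
             pct_variance = 100 * eigenvalues / sum(eigenvalues),
             wilks = wilks, chisq = chisq, df = df,
             p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Fit canonical discriminant functions
#'
#' Eigen-decomposition of `W^{-1} B` on the selected features (`W` pooled
#' within-group scatter, `B` between-group scatter). Coefficients are
#' scaled so canonical scores have unit pooled within-group variance.
#'
#' @param table Feature table or [feature_matrix()] list.
#' @param features Character vector of feature names to use.
#' @return Object of class `canonical_model`: `features`, `eigenvalues`,
#'   `chain` (the [canonical_chain()] table), `coef` (p x m), `n`, `g`, `p`.
#' @export
fit_canonical <- function(table, features) {
  fm <- if (is.list(table) && !is.data.frame(table)) table else feature_matrix(table)
  x <- fm$x[, features, drop = FALSE]
  group <- droplevels(factor(fm$group))
  n <- nrow(x); g <- nlevels(group); p <- ncol(x)
  sc <- .scatter(x, group)
  b_mat <- sc$T - sc$W
  w_inv <- tryCatch(solve(sc$W), error = function(e)
    stop("singular within-group scatter (condition number too large): ",
         conditionMessage(e)))
  ei <- eigen(w_inv %*% b_mat)
  m <- min(p, g - 1)
  ord <- order(Re(ei$values), decreasing = TRUE)[seq_len(m)]
  lambda <- pmax(Re(ei$values[ord]), 0)
  vec <- Re(ei$vectors[, ord, drop = FALSE])
  # unit within-group variance scaling: v' (W/(n-g)) v = 1
  scale_f <- sqrt(diag(t(vec) %*% (sc$W / (n - g)) %*% vec))
  vec <- sweep(vec, 2, scale_f, "/")
  rownames(vec) <- features
  structure(
    list(features = features, eigenvalues = lambda,
         chain = canonical_chain(lambda, n, p, g),
         coef = vec, n = n, g = g, p = p, groups = levels(group)),
    class = "canonical_model"
  )
}

#' Fit Fisher linear classification functions
#'
#' One linear score per group:
#' `Y_g(x) = b_g0 + b_g' x` with `b_g = Wc^{-1} mu_g` and
#' `b_g0 = -mu_g' Wc^{-1} mu_g / 2 + ln(prior_g)`, where `Wc` is the pooled
#' within-group covariance. A sample is assigned to the group with the
#' highest score.
#'
#' @param table Feature table or [feature_matrix()] list.
#' @param features Feature names to use.
#' @param priors `"equal"` (default) or `"proportional"` to group sizes.
#' @return Object of class `fisher_classifier`: `features`, `groups`,
#'   `intercepts`, `coef` (p x g matrix), `priors`.
#' @export
fit_fisher <- function(table, features, priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  fm <- if (is.list(table) && !is.data.frame(table)) table else feature_matrix(table)
  x <- fm$x[, features, drop = FALSE]
  group <- droplevels(factor(fm$group))
  n <- nrow(x); g <- nlevels(group)
  sc <- .scatter(x, group)
  wc <- sc$W / (n - g)
  wc_inv <- tryCatch(solve(wc), error = function(e)
    stop("singular pooled within-group covariance: ", conditionMessage(e)))
  pri <- if (priors == "equal") rep(1 / g, g) else
    as.numeric(base::table(group)) / n
  mu <- matrix(vapply(levels(group), function(gl)
    colMeans(x[group == gl, , drop = FALSE]), numeric(ncol(x))),
    nrow = ncol(x))                              # p x g
  coef <- wc_inv %*% mu                          # p x g
  intercepts <- -0.5 * colSums(mu * coef) + log(pri)
  colnames(coef) <- levels(group)
  rownames(coef) <- features
  structure(
    list(features = features, groups = levels(group),
         intercepts = stats::setNames(intercepts, levels(group)),
         coef = coef, priors = stats::setNames(pri, levels(group))),
    class = "fisher_classifier"
  )
}

#' Classify feature vectors with Fisher functions
#'
#' Computes every group score `Y_g = b_g0 + sum_i b_gi x_i` and assigns the
#' argmax group; exact ties go to the earliest-declared group with a
#' warning.
#'
#' @param classifier A `fisher_classifier` (fitted or read from JSON).
#' @param x Named numeric vector, or a matrix / feature table with named
#'   columns covering every classifier feature.
#' @return List: `group` (character vector), `scores` (n x g matrix).
#' @export
classify <- function(classifier, x) {
  if (is.null(dim(x))) x <- t(as.matrix(x))
  if (is.data.frame(x)) x <- feature_matrix(x)$x
  missing <- setdiff(classifier$features, colnames(x))
  if (length(missing))
    stop("input is missing classifier feature(s): ",
         paste(missing, collapse = ", "))
  xm <- x[, classifier$features, drop = FALSE]
  scores <- sweep(xm %*% classifier$coef, 2, classifier$intercepts, "+")
  idx <- apply(scores, 1, function(s) {
    top <- which(s == max(s))
    if (length(top) > 1L) warning("tied classification scores; using first group")
    top[1L]
  })
  list(group = classifier$groups[idx], scores = scores)
}

#' Evaluate classification accuracy
#'
#' `"resubstitution"` fits once and classifies the training rows;
#' `"loo"` refits on `n - 1` rows for each held-out row (leave-one-out
#' cross-validation); `"logo"` leaves out one whole rat (grouped
#' cross-validation, for ROI rows correlated within a rat).
#'
#' @param table Feature table.
#' @param features Feature names to use.
#' @param mode `"resubstitution"`, `"loo"`, or `"logo"`.
#' @param priors Passed to [fit_fisher()].
#' @return Object of class `classification_report`: `confusion`,
#'   `per_group` (percent correct), `overall` (percent), `mode`.
#' @export
evaluate_classification <- function(table, features,
                                    mode = c("resubstitution", "loo", "logo"),
                                    priors = "equal") {
  mode <- match.arg(mode)
  fm <- feature_matrix(table)
  group <- droplevels(factor(fm$group))
  n <- length(group)
  pred <- character(n)
  if (mode == "resubstitution") {
    cls <- fit_fisher(table, features, priors)
    pred <- classify(cls, fm$x)$group
  } else {
    folds <- if (mode == "loo") as.list(seq_len(n)) else
      split(seq_len(n), table$rat_id)
    for (hold in folds) {
      train <- table[-hold, , drop = FALSE]
      if (any(base::table(droplevels(factor(train$group))) < 2L)) {
        warning("fold skipped: a group became (nearly) empty")
        pred[hold] <- NA_character_
        next
      }
      cls <- tryCatch(fit_fisher(train, features, priors),
                      error = function(e) NULL)
      if (is.null(cls)) {
        warning("fold skipped: singular within-group covariance on refit")
        pred[hold] <- NA_character_
        next
      }
      pred[hold] <- classify(cls, fm$x[hold, , drop = FALSE])$group
    }
  }
  keep <- !is.na(pred)
  confusion <- base::table(truth = group[keep],
                           predicted = factor(pred[keep], levels = levels(group)))
  per_group <- 100 * diag(confusion) / rowSums(confusion)
  overall <- 100 * sum(diag(confusion)) / sum(confusion)
  structure(
    list(confusion = confusion, per_group = per_group, overall = overall,
         mode = mode),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report (%s): overall %.1f%% correct\n",
              x$mode, x$overall))
  print(round(x$per_group, 1))
  invisible(x)
}

#' Serialize / deserialize Fisher classifiers as JSON
#'
#' The JSON schema (feature names, per-group intercepts and coefficients)
#' round-trips bit-exactly and also accepts externally published
#' discriminant functions for scoring without refitting.
#'
#' @param classifier A `fisher_classifier`.
#' @param path JSON file path.
#' @export
write_fisher_json <- function(classifier, path) {
  obj <- list(features = classifier$features, groups = classifier$groups,
              intercepts = as.list(classifier$intercepts),
              coefficients = stats::setNames(
                lapply(seq_along(classifier$groups),
                       function(k) as.list(stats::setNames(
                         classifier$coef[, k], classifier$features))),
                classifier$groups),
              priors = as.list(classifier$priors))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_fisher_json
#' @export
read_fisher_json <- function(path) {
  obj <- jsonlite::read_json(path)
  features <- unlist(obj$features)
  groups <- unlist(obj$groups)
  coef <- vapply(groups, function(g)
    unlist(obj$coefficients[[g]])[features], numeric(length(features)))
  coef <- matrix(coef, nrow = length(features),
                 dimnames = list(features, groups))
  pri <- if (!is.null(obj$priors)) unlist(obj$priors)[groups] else
    stats::setNames(rep(1 / length(groups), length(groups)), groups)
  structure(
    list(features = features, groups = groups,
         intercepts = unlist(obj$intercepts)[groups],
         coef = coef, priors = pri),
    class = "fisher_classifier"
  )
}
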