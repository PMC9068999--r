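#' Run-length matrix features
#'
#' Decomposes the ROI into maximal runs of identical gray level along one
#' of four directions and summarizes the run-length distribution. With
#' `N_r` the total number of runs and `R(g, l)` the count of runs of level
#' `g` and length `l`:
#' `ShrtREmp = sum(R / l^2) / N_r`, `LngREmph = sum(R * l^2) / N_r`,
#' `GLevNonU = sum_g (sum_l R)^2 / N_r`, `RLNonUni = sum_l (sum_g R)^2 / N_r`,
#' `Fraction = N_r / n_pixels`.
#'
#' @param roi A `quantized_roi`.
#' @param direction `"Horzl"` (rows), `"Vertl"` (columns), `"45dgr"`
#'   (up-right anti-diagonals) or `"135dr"` (down-right diagonals).
#' @return Named numeric vector `RLNonUni`, `GLevNonU`, `LngREmph`,
#'   `ShrtREmp`, `Fraction`.
#' @export
rlm_features <- function(roi, direction = c("Horzl", "Vertl", "45dgr", "135dr")) {
  direction <- match.arg(direction)
  lv <- roi$levels
  h <- nrow(lv); w <- ncol(lv)
  ridx <- matrix(seq_len(h), h, w)
  cidx <- matrix(seq_len(w), h, w, byrow = TRUE)
  lines <- switch(direction,
    Horzl = split(as.vector(t(lv)), rep(seq_len(h), each = w)),
    Vertl = split(as.vector(lv), rep(seq_len(w), each = h)),
    # anti-diagonals (up-right): constant row+col; walk left->right = bottom->top
    "45dgr" = split(as.vector(lv), as.vector(ridx + cidx)),
    # diagonals (down-right): constant col-row
    "135dr" = split(as.vector(lv), as.vector(cidx - ridx)))
  runs <- lapply(lines, function(s) stats::setNames(rle(s)[c("lengths", "values")],
                                                    c("l", "g")))
  l <- unlist(lapply(runs, `[[`, "l"), use.names = FALSE)
  g <- unlist(lapply(runs, `[[`, "g"), use.names = FALSE)
  n_r <- length(l)
  per_level <- tapply(rep(1L, n_r), g, sum)
  per_length <- tapply(rep(1L, n_r), l, sum)
  c(RLNonUni = sum(per_length^2) / n_r,
    GLevNonU = sum(per_level^2) / n_r,
    LngREmph = sum(l^2) / n_r,
    ShrtREmp = sum(1 / l^2) / n_r,
    Fraction = n_r / (h * w))
}

#' Absolute gradient features
#'
#' Gradient magnitude at each interior pixel from scaled central
#' differences,
#' `g(i,j) = sqrt((x(i+1,j) - x(i-1,j))^2 + (x(i,j+1) - x(i,j-1))^2) / 4`,
#' the 1-pixel border excluded. Returns moments of the gradient map and the
#' fraction of interior pixels with nonzero gradient. Skewness and kurtosis
#' (excess) of a constant gradient map are reported as 0 by convention.
#'
#' @param roi A `quantized_roi` with at least 3 rows and 3 columns.
#' @return Named numeric vector `GrMean`, `GrVariance`, `GrSkewness`,
#'   `GrKurtosis`, `GrNonZeros`.
#' @export
gradient_features <- function(roi) {
  x <- roi$levels
  h <- nrow(x); w <- ncol(x)
  if (h < 3L || w < 3L) stop("gradient features require an ROI of at least 3x3")
  i <- 2:(h - 1); j <- 2:(w - 1)
  dv <- x[i + 1, j, drop = FALSE] - x[i - 1, j, drop = FALSE]
  dh <- x[i, j + 1, drop = FALSE] - x[i, j - 1, drop = FALSE]
  g <- sqrt(dv^2 + dh^2) / 4
  mo <- .moments(as.vector(g))
  c(GrMean = mo[["mean"]], GrVariance = mo[["variance"]],
    GrSkewness = mo[["skewness"]], GrKurtosis = mo[["kurtosis"]],
    GrNonZeros = mean(g > 0))
}

#' Gray-level histogram features
#'
#' First-order statistics of the quantized levels: mean, (population)
#' variance, skewness, excess kurtosis, nearest-rank percentiles at
#' 1/10/50/90/99%, and the minimum / maximum observed level.
#'
#' @param roi A `quantized_roi`.
#' @return Named numeric vector `Mean`, `Variance`, `Skewness`, `Kurtosis`,
#'   `Perc.01%`, `Perc.10%`, `Perc.50%`, `Perc.90%`, `Perc.99%`, `MinNorm`,
#'   `MaxNorm`.
#' @export
histogram_features <- function(roi) {
  x <- as.vector(roi$levels)
  mo <- .moments(x)
  s <- sort(x)
  n <- length(s)
  pct <- function(p) s[max(1L, ceiling(p * n))]
  out <- c(Mean = mo[["mean"]], Variance = mo[["variance"]],
           Skewness = mo[["skewness"]], Kurtosis = mo[["kurtosis"]],
           pct(0.01), pct(0.10), pct(0.50), pct(0.90), pct(0.99),
           MinNorm = min(x), MaxNorm = max(x))
  names(out)[5:9] <- c("Perc.01%", "Perc.10%", "Perc.50%", "Perc.90%", "Perc.99%")
  out
}

# population moments; degenerate (zero-variance) skew/kurtosis -> 0
.moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n
  if (v > 0) {
    sk <- sum((x - m)^3) / n / v^1.5
    ku <- sum((x - m)^4) / n / v^2 - 3
  } else {
    sk <- 0; ku <- 0
  }
  c(mean = m, variance = v, skewness = sk, kurtosis = ku)
}

#' Fit the causal 2D autoregressive texture model
#'
#' Least-squares fit of the first-order causal neighborhood on
#' mean-centered levels:
#' `x(i,j) ~ Teta1*x(i,j-1) + Teta2*x(i-1,j-1) + Teta3*x(i-1,j) + Teta4*x(i-1,j+1)`
#' over all pixels whose four causal neighbors exist. `Sigma` is the
#' residual standard deviation. A rank-deficient system (e.g. a constant
#' ROI) returns all-zero coefficients with `degenerate = TRUE`.
#'
#' @param roi A `quantized_roi` with at least 2 rows and 3 columns.
#' @return List of class `ar_fit`: `teta` (named length-4), `sigma`,
#'   `degenerate`, `n_obs`.
#' @export
ar_fit <- function(roi) {
  x <- roi$levels
  h <- nrow(x); w <- ncol(x)
  if (h < 2L || w < 3L) stop("AR fit requires an ROI of at least 2 rows and 3 columns")
  xc <- x - mean(x)
  i <- 2:h; j <- 2:(w - 1)
  y  <- as.vector(xc[i, j, drop = FALSE])
  X <- cbind(as.vector(xc[i, j - 1, drop = FALSE]),
             as.vector(xc[i - 1, j - 1, drop = FALSE]),
             as.vector(xc[i - 1, j, drop = FALSE]),
             as.vector(xc[i - 1, j + 1, drop = FALSE]))
  qr_x <- qr(X)
  degenerate <- qr_x$rank < 4L
  if (degenerate) {
    teta <- rep(0, 4)
    sigma <- 0
  } else {
    teta <- qr.coef(qr_x, y)
    r <- y - X %*% teta
    sigma <- sqrt(sum(r^2) / length(y))
  }
  structure(
    list(teta = stats::setNames(as.numeric(teta),
                                c("Teta1", "Teta2", "Teta3", "Teta4")),
         sigma = sigma, degenerate = degenerate, n_obs = length(y)),
    class = "ar_fit"
  )
}
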