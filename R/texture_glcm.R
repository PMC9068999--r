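#' Gray-level co-occurrence matrix
#'
#' Counts pairs of gray levels separated by the pixel offset `(dx, dy)`
#' (columns right, rows down) inside the ROI and normalizes to a joint
#' probability matrix `P(i, j)`. With `symmetric = TRUE` (the MaZda
#' convention, and the default) each pair is also counted under the
#' reversed offset, so `P` is symmetric and features are independent of
#' scan direction. Offsets follow the `S(dx,dy)` naming: `S(d,0)`
#' horizontal, `S(0,d)` vertical, `S(d,d)` down-right diagonal,
#' `S(d,-d)` up-right (anti-)diagonal.
#'
#' @param roi A `quantized_roi`.
#' @param dx,dy Integer offset components.
#' @param symmetric Count both offset directions (default `TRUE`).
#' @return An object of class `glcm`: probability matrix `P` (`ng` x `ng`),
#'   `offset`, `n_pairs`.
#' @export
compute_glcm <- function(roi, dx, dy, symmetric = TRUE) {
  lv <- roi$levels
  ng <- roi$ng
  h <- nrow(lv); w <- ncol(lv)
  if (abs(dx) >= w || abs(dy) >= h)
    stop(sprintf("offset (%d,%d) leaves no pixel pairs in a %dx%d ROI",
                 dx, dy, h, w))
  rows <- seq_len(h); cols <- seq_len(w)
  r1 <- rows[rows + dy >= 1L & rows + dy <= h]
  c1 <- cols[cols + dx >= 1L & cols + dx <= w]
  a <- lv[r1, c1, drop = FALSE]
  b <- lv[r1 + dy, c1 + dx, drop = FALSE]
  counts <- matrix(tabulate((a - 1L) * ng + b, nbins = ng * ng),
                   nrow = ng, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  n_pairs <- sum(counts)
  if (n_pairs == 0L) stop("no pixel pairs for this offset")
  structure(
    list(P = counts / n_pairs, offset = c(dx = dx, dy = dy),
         n_pairs = n_pairs, ng = ng),
    class = "glcm"
  )
}

#' Haralick-style features of a co-occurrence matrix
#'
#' Computes the 11 MaZda GLCM features. Marginal indices use level values
#' `1..Ng`, so the sum index `i + j` runs over `2..2Ng`; entropies use the
#' natural logarithm with `0 * log 0 := 0`. When the ROI is constant the
#' marginal variances vanish and `Correlat` is reported as 0 by convention
#' (never `NaN`).
#'
#' @param m A `glcm` from [compute_glcm()].
#' @return Named numeric vector: `AngScMom`, `Contrast`, `Correlat`,
#'   `SumOfSqs`, `InvDfMom`, `SumAverg`, `SumVarnc`, `SumEntrp`, `Entropy`,
#'   `DifVarnc`, `DifEntrp`.
#' @export
glcm_features <- function(m) {
  P <- m$P
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)        # row index = first level
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  cov <- sum(i * j * P) - mux * muy
  correlat <- if (sx * sy > 0) cov / (sx * sy) else 0

  # i+j marginal on 2..2Ng and |i-j| marginal on 0..Ng-1
  psum <- as.vector(tapply(P, i + j, sum))
  ksum <- sort(unique(as.vector(i + j)))
  pdif <- as.vector(tapply(P, abs(i - j), sum))
  kdif <- sort(unique(as.vector(abs(i - j))))

  sum_avg <- sum(ksum * psum)
  dif_avg <- sum(kdif * pdif)

  c(AngScMom = sum(P^2),
    Contrast = sum((i - j)^2 * P),
    Correlat = correlat,
    SumOfSqs = sum((i - mux)^2 * P),
    InvDfMom = sum(P / (1 + (i - j)^2)),
    SumAverg = sum_avg,
    SumVarnc = sum((ksum - sum_avg)^2 * psum),
    SumEntrp = -sum(ifelse(psum > 0, psum * log(psum), 0)),
    Entropy  = -sum(ifelse(P > 0, P * log(P), 0)),
    DifVarnc = sum((kdif - dif_avg)^2 * pdif),
    DifEntrp = -sum(ifelse(pdif > 0, pdif * log(pdif), 0)))
}

#' Canonical co-occurrence offsets
#'
#' For each distance `d`, the four directions used in `S(dx,dy)` feature
#' names: `(d,0)`, `(0,d)`, `(d,d)`, `(d,-d)`.
#'
#' @param distances Integer distances (default `1:5`).
#' @return Data frame with columns `dx`, `dy`.
#' @export
glcm_offsets <- function(distances = 1:5) {
  do.call(rbind, lapply(distances, function(d)
    data.frame(dx = c(d, 0L, d, d), dy = c(0L, d, d, -d))))
}
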