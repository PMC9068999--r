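# Naive, loop-based oracle implementations, deliberately independent of the
# package's vectorized code paths, plus small fixture builders.

random_roi <- function(ng, h = 9L, w = 8L) {
  quantized_roi(matrix(sample.int(ng, h * w, replace = TRUE), h, w), ng = ng)
}

# pair-by-pair GLCM counting
oracle_glcm <- function(roi, dx, dy, symmetric = TRUE) {
  lv <- roi$levels
  ng <- roi$ng
  counts <- matrix(0, ng, ng)
  for (i in seq_len(nrow(lv))) {
    for (j in seq_len(ncol(lv))) {
      i2 <- i + dy; j2 <- j + dx
      if (i2 >= 1 && i2 <= nrow(lv) && j2 >= 1 && j2 <= ncol(lv)) {
        counts[lv[i, j], lv[i2, j2]] <- counts[lv[i, j], lv[i2, j2]] + 1
        if (symmetric)
          counts[lv[i2, j2], lv[i, j]] <- counts[lv[i2, j2], lv[i, j]] + 1
      }
    }
  }
  counts / sum(counts)
}

# literal term-by-term GLCM feature formulas
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  asm <- contrast <- idm <- ent <- ssq <- 0
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  cross <- 0
  psum <- numeric(2 * ng); pdif <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log(p)
    ssq <- ssq + (i - mux)^2 * p
    cross <- cross + i * j * p
    psum[i + j] <- psum[i + j] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
  }
  sa <- sum((2:(2 * ng)) * psum[2:(2 * ng)])
  sv <- sum(((2:(2 * ng)) - sa)^2 * psum[2:(2 * ng)])
  se <- -sum(ifelse(psum > 0, psum * log(psum), 0))
  da <- sum((0:(ng - 1)) * pdif)
  dv <- sum(((0:(ng - 1)) - da)^2 * pdif)
  de <- -sum(ifelse(pdif > 0, pdif * log(pdif), 0))
  c(AngScMom = asm, Contrast = contrast,
    Correlat = if (sx * sy > 0) (cross - mux * muy) / (sx * sy) else 0,
    SumOfSqs = ssq, InvDfMom = idm, SumAverg = sa, SumVarnc = sv,
    SumEntrp = se, Entropy = ent, DifVarnc = dv, DifEntrp = de)
}

# explicit run decomposition along a direction
oracle_rlm <- function(roi, direction) {
  lv <- roi$levels
  h <- nrow(lv); w <- ncol(lv)
  seqs <- list()
  if (direction == "Horzl") {
    for (i in 1:h) seqs[[length(seqs) + 1]] <- lv[i, ]
  } else if (direction == "Vertl") {
    for (j in 1:w) seqs[[length(seqs) + 1]] <- lv[, j]
  } else if (direction == "45dgr") {
    for (s in 2:(h + w)) {
      cells <- c()
      for (i in h:1) {
        j <- s - i
        if (j >= 1 && j <= w) cells <- c(cells, lv[i, j])
      }
      if (length(cells)) seqs[[length(seqs) + 1]] <- cells
    }
  } else {
    for (s in (1 - h):(w - 1)) {
      cells <- c()
      for (i in 1:h) {
        j <- s + i
        if (j >= 1 && j <= w) cells <- c(cells, lv[i, j])
      }
      if (length(cells)) seqs[[length(seqs) + 1]] <- cells
    }
  }
  lens <- c(); levs <- c()
  for (s in seqs) {
    k <- 1
    while (k <= length(s)) {
      m <- k
      while (m < length(s) && s[m + 1] == s[k]) m <- m + 1
      lens <- c(lens, m - k + 1); levs <- c(levs, s[k])
      k <- m + 1
    }
  }
  n_r <- length(lens)
  c(RLNonUni = sum(tapply(rep(1, n_r), lens, sum)^2) / n_r,
    GLevNonU = sum(tapply(rep(1, n_r), levs, sum)^2) / n_r,
    LngREmph = sum(lens^2) / n_r,
    ShrtREmp = sum(1 / lens^2) / n_r,
    Fraction = n_r / (h * w))
}

# per-pixel gradient loop
oracle_gradient <- function(roi) {
  x <- roi$levels
  h <- nrow(x); w <- ncol(x)
  g <- c()
  for (i in 2:(h - 1)) for (j in 2:(w - 1))
    g <- c(g, sqrt((x[i + 1, j] - x[i - 1, j])^2 +
                     (x[i, j + 1] - x[i, j - 1])^2) / 4)
  n <- length(g); m <- mean(g); v <- sum((g - m)^2) / n
  c(GrMean = m, GrVariance = v,
    GrSkewness = if (v > 0) sum((g - m)^3) / n / v^1.5 else 0,
    GrKurtosis = if (v > 0) sum((g - m)^4) / n / v^2 - 3 else 0,
    GrNonZeros = mean(g > 0))
}

# all-pairs AUC counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# proximal-gradient (ISTA) solver for L1-penalized logistic regression,
# glmnet objective: (1/n) * neg-loglik + lambda * ||beta||_1
oracle_lasso_logistic <- function(x, y, lambda, iters = 50000, step = NULL) {
  n <- nrow(x); p <- ncol(x)
  xb <- cbind(1, x)
  if (is.null(step)) step <- 4 * n / sum(xb^2)
  beta <- numeric(p + 1)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (it in seq_len(iters)) {
    eta <- xb %*% beta
    grad <- as.vector(crossprod(xb, stats::plogis(eta) - y)) / n
    beta_new <- beta - step * grad
    beta_new[-1] <- soft(beta_new[-1], step * lambda)
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(b), floor))
}

small_group_table <- function(n_per, means, sd = 1, p_noise = 3, seed = 1) {
  # simple multi-group table: one informative feature + noise features
  set.seed(seed)
  g <- length(means)
  rows <- do.call(rbind, lapply(seq_len(g), function(k) {
    a <- cbind(A = stats::rnorm(n_per, means[k], sd))
    if (p_noise == 0) return(a)
    cbind(a, matrix(stats::rnorm(n_per * p_noise), n_per,
                    dimnames = list(NULL, paste0("N", seq_len(p_noise)))))
  }))
  out <- data.frame(group = rep(paste0("g", seq_len(g)), each = n_per),
                    rows, check.names = FALSE)
  out
}
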