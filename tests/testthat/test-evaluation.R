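test_that("AUC matches exhaustive pair counting and is rank-invariant", {
  expect_equal(auc_mw(1:4, c(0, 0, 1, 1)), 1)
  expect_equal(auc_mw(1:4, c(0, 1, 0, 1)), 0.75)
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    sc <- round(rnorm(n), 1)  # force some ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc_mw(sc, y), oracle_auc(sc, y), tolerance = 1e-12)
    expect_equal(auc_mw(exp(sc), y), auc_mw(sc, y), tolerance = 1e-12)
    r <- roc_auc(sc, y)
    expect_equal(r$auc, oracle_auc(sc, y), tolerance = 1e-12)
  }
})

test_that("DeLong intervals contain the AUC and tighten with n", {
  make <- function(n, seed) {
    set.seed(seed)
    y <- rep(0:1, each = n / 2)
    list(s = rnorm(n) + y, y = y)
  }
  d50 <- make(50, 1); d500 <- make(500, 1)
  r50 <- roc_auc(d50$s, d50$y); r500 <- roc_auc(d500$s, d500$y)
  for (r in list(r50, r500)) {
    expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
    expect_true(all(diff(rev(r$sensitivity)) >= 0))
  }
  expect_lt(diff(r500$ci), diff(r50$ci))
  boot <- roc_auc(d50$s, d50$y, ci_method = "bootstrap", boot_n = 200, seed = 9)
  expect_true(boot$ci[1] <= boot$auc && boot$auc <= boot$ci[2])
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("Hosmer-Lemeshow is calibrated under the null and detects miscalibration", {
  n_seeds <- 300; n <- 3000
  rej <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    p <- runif(n, 0.05, 0.95)
    y <- rbinom(n, 1, p)
    if (hosmer_lemeshow(p, y)$p_value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_seeds, 0.02)
  expect_lte(rej / n_seeds, 0.09)

  power <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    p <- runif(n, 0.05, 0.95)
    y <- rbinom(n, 1, p)
    if (hosmer_lemeshow(p^2, y)$p_value < 0.05) power <- power + 1
  }
  expect_gte(power, 48)
})

test_that("Hosmer-Lemeshow degenerate and symmetry behavior", {
  set.seed(5)
  y <- rbinom(400, 1, 0.3)
  p_const <- rep(mean(y), 400)
  hl <- hosmer_lemeshow(p_const, y)
  expect_lt(hl$statistic, 1e-9)

  p <- runif(400, 0.1, 0.9)
  h1 <- hosmer_lemeshow(p, y)
  h2 <- hosmer_lemeshow(1 - p, 1 - y)
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-9)
  expect_equal(sum(h1$table$observed), sum(y))
})

test_that("ICC(2,1) recovers known variance components", {
  set.seed(11)
  subj <- rnorm(50, sd = 2)
  grid <- cbind(subj, subj)  # duplicated raters
  expect_equal(icc(grid)$icc, 1, tolerance = 1e-12)

  n <- 200
  subj <- rnorm(n, sd = 2)          # sigma2_subject = 4
  grid2 <- sapply(1:3, function(k) subj + rnorm(n, sd = 1))
  r <- icc(grid2)
  expect_equal(r$icc, 0.8, tolerance = 0.05)

  indep <- matrix(rnorm(3 * 300), 300, 3)
  expect_lt(abs(icc(indep)$icc), 0.12)

  flat <- matrix(rnorm(3 * 50, sd = 0.001), 50, 3) * 0 +
    matrix(rnorm(150), 50, 3)
  # zero between-subject variance: identical row means by construction
  degen <- matrix(rep(c(1, 2, 3), each = 50), 50, 3)
  rd <- icc(degen)
  expect_true(rd$degenerate)
  expect_equal(rd$icc, 0)
})

test_that("cluster map normalizes, orders duplicates together and splits groups", {
  set.seed(14)
  n <- 15
  shift <- rep(c(4, -4), 5)  # alternating so row-centering keeps the pattern
  base <- matrix(rnorm(2 * n * 10), 2 * n, 10)
  base[(n + 1):(2 * n), ] <- sweep(base[(n + 1):(2 * n), ], 2, shift, "+")
  colnames(base) <- paste0("f", 1:10)
  tab <- data.frame(group = rep(c("a", "b"), each = n), base, check.names = FALSE)
  tab2 <- rbind(tab, tab[1, ])  # duplicated ROI row
  cm <- cluster_map(tab2)
  expect_equal(colMeans(cm$z), rep(0, 10), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(cm$z, 2, sd), rep(1, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  dup_pos <- which(cm$row_order %in% c(1L, nrow(tab2)))
  expect_equal(abs(diff(dup_pos)), 1L)  # duplicates are adjacent leaves

  rand_index <- function(a, b) {
    tab_ab <- table(a, b)
    nc2 <- function(x) x * (x - 1) / 2
    agree <- sum(nc2(tab_ab))
    n <- length(a)
    expect_true(n > 1)
    (nc2(n) + 2 * agree - sum(nc2(rowSums(tab_ab))) - sum(nc2(colSums(tab_ab)))) /
      nc2(n)
  }
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    m <- matrix(rnorm(2 * n * 10), 2 * n, 10)
    m[(n + 1):(2 * n), ] <- sweep(m[(n + 1):(2 * n), ], 2, shift, "+")
    colnames(m) <- paste0("f", 1:10)
    d <- data.frame(group = rep(c("a", "b"), each = n), m, check.names = FALSE)
    cm_s <- cluster_map(d)
    cut2 <- cutree(cm_s$row_hclust, k = 2)
    if (rand_index(cut2, d$group) >= 0.95) hits <- hits + 1
  }
  expect_gte(hits, 19)

  nwk <- dendrogram_newick(cm$row_hclust)
  expect_true(is.character(nwk) && startsWith(nwk, "("))
})
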