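test_that("the eigenvalue-lambda-chisq chain satisfies its identities", {
  set.seed(8)
  for (rep in 1:5) {
    ev <- sort(rexp(4, 1), decreasing = TRUE)
    ch <- canonical_chain(ev, n = 200, p = 12, g = 5)
    # Lambda_k * prod_{i>=k}(1+lambda_i) = 1
    for (k in 1:4)
      expect_equal(ch$wilks[k] * prod(1 + ev[k:4]), 1, tolerance = 1e-10)
    expect_equal(sum(ch$pct_variance), 100, tolerance = 1e-9)
    expect_true(all(diff(ch$wilks) > 0))
    expect_true(all(ch$wilks > 0 & ch$wilks <= 1))
  }
})

test_that("stepwise selection finds the informative feature and resists noise", {
  hits <- 0; clean <- 0
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    tab <- small_group_table(n_per = 20, means = c(0, 2), p_noise = 5, seed = s)
    sel <- stepwise_select(tab, f_enter = 3.84, f_remove = 2.71)
    if (length(sel) >= 1 && sel[1] == "A") hits <- hits + 1
    if (all(sel == "A")) clean <- clean + 1
  }
  expect_gte(hits, 95)
  expect_gte(clean, 80)  # occasional spurious entries allowed at F = 3.84
})

test_that("collinear duplicates never co-enter and infinite threshold selects nothing", {
  tab <- small_group_table(n_per = 25, means = c(0, 3), p_noise = 2, seed = 11)
  tab$A_copy <- tab$A
  sel <- suppressWarnings(stepwise_select(tab))
  expect_lte(sum(sel %in% c("A", "A_copy")), 1L)
  expect_length(stepwise_select(tab, f_enter = Inf, f_remove = 1), 0L)
})

test_that("canonical fit reduces correctly for two separated groups", {
  tab <- small_group_table(n_per = 30, means = c(0, 4), p_noise = 1, seed = 2)
  cm <- fit_canonical(tab, c("A", "N1"))
  expect_length(cm$eigenvalues, 1L)
  expect_equal(cm$chain$pct_variance, 100)
  expect_true(cm$eigenvalues > 1)
})

test_that("Fisher classification agrees with an independent LDA implementation", {
  set.seed(77)
  tab <- small_group_table(n_per = 25, means = c(0, 1.5, 3, 4.5, 6),
                           p_noise = 3, seed = 77)
  feats <- c("A", "N1", "N2", "N3")
  cls <- fit_fisher(tab, feats, priors = "equal")
  pred <- classify(cls, tab)$group
  ref <- MASS::lda(feature_matrix(tab)$x[, feats], grouping = factor(tab$group),
                   prior = rep(0.2, 5))
  pred_ref <- as.character(predict(ref)$class)
  expect_identical(pred, pred_ref)
})

test_that("1-D two-group Fisher boundary is the closed-form midpoint", {
  tab <- small_group_table(n_per = 200, means = c(0, 2), p_noise = 1, seed = 5)
  cls <- fit_fisher(tab, "A", priors = "equal")
  # boundary where Y_1 = Y_2: x* = (b20 - b10) / (b11 - b21)
  xstar <- (cls$intercepts[1] - cls$intercepts[2]) /
    (cls$coef["A", 2] - cls$coef["A", 1])
  mu1 <- mean(tab$A[tab$group == "g1"]); mu2 <- mean(tab$A[tab$group == "g2"])
  expect_equal(unname(xstar), (mu1 + mu2) / 2, tolerance = 1e-10)
})

test_that("classify is a brute-force argmax, invariant to common intercept shifts", {
  tab <- small_group_table(n_per = 15, means = c(0, 1, 2), p_noise = 2, seed = 9)
  cls <- fit_fisher(tab, c("A", "N1"), priors = "equal")
  set.seed(10)
  x <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("A", "N1")))
  out <- classify(cls, x)
  for (i in 1:100) {
    manual <- vapply(seq_along(cls$groups), function(g)
      cls$intercepts[g] + sum(cls$coef[, g] * x[i, cls$features]), 0)
    expect_identical(out$group[i], cls$groups[which.max(manual)])
  }
  shifted <- cls
  shifted$intercepts <- cls$intercepts + 1234.5
  expect_identical(classify(shifted, x)$group, out$group)
})

test_that("tied classifiers fall back to declaration order with a warning", {
  tab <- small_group_table(n_per = 15, means = c(0, 1), p_noise = 1, seed = 3)
  cls <- fit_fisher(tab, "A")
  cls$coef[] <- 0
  cls$intercepts[] <- 0
  expect_warning(out <- classify(cls, c(A = 1)), "tied")
  expect_identical(out$group, cls$groups[1])
})

test_that("LOO is no more optimistic than resubstitution on average", {
  viol <- 0
  for (s in 1:8) {
    tab <- small_group_table(n_per = 12, means = c(0, 1, 2), p_noise = 2,
                             seed = 100 + s)
    rs <- evaluate_classification(tab, c("A", "N1"), "resubstitution")$overall
    lo <- evaluate_classification(tab, c("A", "N1"), "loo")$overall
    if (lo > rs) viol <- viol + 1
  }
  expect_lte(viol, 1)
})

test_that("perfect separation classifies perfectly in both modes", {
  tab <- small_group_table(n_per = 15, means = c(0, 50), sd = 0.5,
                           p_noise = 1, seed = 6)
  expect_equal(evaluate_classification(tab, "A", "resubstitution")$overall, 100)
  expect_equal(evaluate_classification(tab, "A", "loo")$overall, 100)
})

test_that("Fisher models round-trip through JSON bit-exactly", {
  tab <- small_group_table(n_per = 20, means = c(0, 1, 3), p_noise = 3, seed = 8)
  cls <- fit_fisher(tab, c("A", "N1", "N2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_fisher_json(cls, path)
  back <- read_fisher_json(path)
  expect_identical(back$features, cls$features)
  expect_equal(back$coef, cls$coef, tolerance = 0)
  expect_equal(back$intercepts, cls$intercepts, tolerance = 0)
})
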