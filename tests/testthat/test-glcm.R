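test_that("degenerate co-occurrence cases are exact", {
  cst <- quantized_roi(matrix(1L, 9, 8), ng = 4)
  g <- compute_glcm(cst, 1, 0)
  expect_equal(g$P[1, 1], 1)
  expect_equal(sum(g$P), 1)
  f <- glcm_features(g)
  expect_equal(f[["AngScMom"]], 1)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["InvDfMom"]], 1)
  expect_equal(f[["Entropy"]], 0)
  expect_equal(f[["Correlat"]], 0)  # degenerate marginals, by convention

  cb <- quantized_roi(outer(1:6, 1:6, function(i, j) 1L + (i + j) %% 2L), ng = 2)
  fcb <- glcm_features(compute_glcm(cb, 1, 0))
  expect_equal(fcb[["Contrast"]], 1)
  expect_equal(fcb[["AngScMom"]], 0.5)
  expect_equal(fcb[["InvDfMom"]], 0.5)
  expect_equal(fcb[["Correlat"]], -1)
  expect_equal(fcb[["DifVarnc"]], 0)
})

test_that("co-occurrence accumulation matches pair-by-pair counting", {
  set.seed(101)
  offsets <- glcm_offsets(1:5)
  for (rep in 1:10) {
    roi <- random_roi(sample(c(4L, 8L, 16L), 1))
    for (k in sample(nrow(offsets), 6)) {
      P <- compute_glcm(roi, offsets$dx[k], offsets$dy[k])$P
      expect_equal(P, oracle_glcm(roi, offsets$dx[k], offsets$dy[k]),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(P, t(P), tolerance = 1e-14)  # symmetric accumulation
    }
  }
  # explicit negative-dy offset on a small ROI
  roi6 <- random_roi(4L, 6L, 6L)
  expect_equal(compute_glcm(roi6, 2, -2)$P, oracle_glcm(roi6, 2, -2),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(compute_glcm(roi6, 6, 0), "offset")
})

test_that("co-occurrence features match the literal-formula oracle", {
  set.seed(55)
  for (rep in 1:10) {
    roi <- random_roi(8L)
    m <- compute_glcm(roi, sample(1:3, 1), sample(-2:2, 1))
    expect_equal(glcm_features(m), oracle_glcm_features(m$P), tolerance = 1e-10)
  }
  # random normalized probability grid, not tied to any ROI
  P <- matrix(runif(25), 5, 5); P <- P / sum(P)
  fake <- list(P = P)
  expect_equal(glcm_features(fake), oracle_glcm_features(P), tolerance = 1e-12)
})

test_that("level shifts leave difference-based features unchanged", {
  set.seed(9)
  roi <- random_roi(8L)
  shifted <- quantized_roi(roi$levels + 4L, ng = 12L)
  inv <- c("Contrast", "InvDfMom", "Entropy", "DifEntrp", "DifVarnc")
  f1 <- glcm_features(compute_glcm(roi, 1, 0))
  f2 <- glcm_features(compute_glcm(shifted, 1, 0))
  expect_equal(f1[inv], f2[inv], tolerance = 1e-12)
  expect_equal(gradient_features(roi)[["GrNonZeros"]],
               gradient_features(shifted)[["GrNonZeros"]])
  for (d in c("Horzl", "Vertl", "45dgr", "135dr"))
    expect_equal(rlm_features(roi, d), rlm_features(shifted, d),
                 tolerance = 1e-12)
})

test_that("90-degree rotation swaps horizontal and vertical features", {
  set.seed(77)
  roi <- random_roi(8L, 7L, 7L)
  rot <- quantized_roi(t(roi$levels)[ncol(roi$levels):1, ], ng = roi$ng)
  for (d in 1:3) {
    f_h <- glcm_features(compute_glcm(roi, d, 0))
    f_v <- glcm_features(compute_glcm(rot, 0, d))
    expect_equal(f_h, f_v, tolerance = 1e-12)
  }
  expect_equal(rlm_features(roi, "Horzl"), rlm_features(rot, "Vertl"),
               tolerance = 1e-12)
  expect_equal(rlm_features(roi, "Vertl"), rlm_features(rot, "Horzl"),
               tolerance = 1e-12)
})
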