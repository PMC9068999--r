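# two-group tables for signature tests: `p_signal` features shifted by
# `delta` between groups, the rest pure noise
two_group_table <- function(n_per = 30, p_signal = 3, p_noise = 17,
                            delta = 1.5, seed = 1) {
  set.seed(seed)
  p <- p_signal + p_noise
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  x[(n_per + 1):(2 * n_per), seq_len(p_signal)] <-
    x[(n_per + 1):(2 * n_per), seq_len(p_signal)] + delta
  colnames(x) <- c(paste0("sig", seq_len(p_signal)),
                   paste0("noise", seq_len(p_noise)))
  data.frame(group = rep(c("a", "b"), each = n_per), x, check.names = FALSE)
}

test_that("the null-model limit is exact at the top of the path", {
  tab <- two_group_table(n_per = 25, delta = 1, seed = 2)
  path <- fit_lasso_cv(tab, folds = 5, seed = 7)
  cf <- as.matrix(coef(path$cv, s = max(path$lambda)))[, 1]
  expect_true(all(cf[-1] == 0))
  phat <- mean(tab$group == "b")
  expect_equal(unname(cf[1]), qlogis(phat), tolerance = 1e-6)
})

test_that("signal features are recovered and noise stays sparse across seeds", {
  all_signal <- 0; low_noise <- 0
  n_rep <- 20
  for (s in seq_len(n_rep)) {
    tab <- two_group_table(n_per = 75, p_signal = 3, p_noise = 17,
                           delta = 1.5, seed = s)
    path <- fit_lasso_cv(tab, folds = 10, seed = s)
    # deviance-minimizing penalty: never misses true signal
    f_min <- names(build_signature(path, "lambda_min")$coefficients)
    if (all(paste0("sig", 1:3) %in% f_min)) all_signal <- all_signal + 1
    # 1-SE penalty: keeps the false-positive fraction low
    f_1se <- names(build_signature(path, "lambda_1se")$coefficients)
    if (sum(grepl("^noise", f_1se)) <= 0.2 * 17) low_noise <- low_noise + 1
  }
  expect_gte(all_signal, 18)
  expect_gte(low_noise, 15)
})

test_that("coefficients at a fixed lambda match a proximal-gradient oracle", {
  tab <- two_group_table(n_per = 20, p_signal = 2, p_noise = 1, delta = 2,
                         seed = 3)
  fm <- feature_matrix(tab)
  y <- as.integer(fm$group == "b")
  lam <- 0.05
  fit <- glmnet::glmnet(fm$x, y, family = "binomial", lambda = lam,
                        standardize = FALSE, thresh = 1e-12)
  ours <- as.matrix(coef(fit))[, 1]
  oracle <- oracle_lasso_logistic(fm$x, y, lam)
  expect_equal(unname(ours), unname(oracle), tolerance = 1e-5)
})

test_that("signatures are reproducible, consistent and JSON-stable", {
  tab <- two_group_table(seed = 4)
  p1 <- fit_lasso_cv(tab, folds = 10, seed = 42)
  p2 <- fit_lasso_cv(tab, folds = 10, seed = 42)
  expect_identical(p1$lambda_min, p2$lambda_min)
  s1 <- build_signature(p1); s2 <- build_signature(p2)
  expect_identical(s1$coefficients, s2$coefficients)

  # scoring equals the raw path coefficients at the same lambda
  cf <- as.matrix(coef(p1$cv, s = p1$lambda_min))[, 1]
  x <- feature_matrix(tab)$x
  direct <- unname(cf[1] + x[, names(cf[-1])] %*% cf[-1])
  expect_equal(score_signature(s1, tab)$score, as.vector(direct),
               tolerance = 1e-10)

  path_json <- withr::local_tempfile(fileext = ".json")
  write_signature_json(s1, path_json)
  back <- read_signature_json(path_json)
  expect_equal(back$intercept, s1$intercept, tolerance = 0)
  expect_equal(back$coefficients, s1$coefficients, tolerance = 0)

  # empty signature edge case
  null_sig <- structure(list(positive = "b", groups = c("a", "b"),
                             intercept = 0,
                             coefficients = setNames(numeric(0), character(0)),
                             lambda = NA, log_lambda = NA, n_features = 0L),
                        class = "radiomics_signature")
  out <- score_signature(null_sig, tab)
  expect_equal(out$probability, rep(0.5, nrow(tab)))
})

test_that("support size is (near-)monotone along the penalty path", {
  frac <- vapply(1:5, function(s) {
    tab <- two_group_table(n_per = 75, delta = 1.5, seed = s)
    path <- fit_lasso_cv(tab, folds = 5, seed = s)
    nz <- as.integer(path$cv$nzero)
    sum(diff(rev(nz)) > 0) / (length(nz) - 1)  # increasing lambda direction
  }, 0)
  expect_lte(mean(frac), 0.02)
})

test_that("scores agree with an explicit sum oracle on random vectors", {
  sig <- read_signature_json(mrtexture_fixture("signature_SPS1d_vs_SPS4d.json"))
  set.seed(12)
  x <- matrix(rnorm(100 * sig$n_features), 100, sig$n_features,
              dimnames = list(NULL, names(sig$coefficients)))
  got <- score_signature(sig, x)
  manual <- apply(x, 1, function(r) sig$intercept + sum(r * sig$coefficients))
  expect_equal(got$score, unname(manual), tolerance = 1e-12)
  expect_equal(got$probability, plogis(got$score))
  expect_error(score_signature(sig, x[, -1, drop = FALSE]), "missing")
})
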