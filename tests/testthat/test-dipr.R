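dipr_instance <- function(seed = 20, n = 14L, m1 = 5L, m2 = 8L) {
  set.seed(seed)
  list(X1 = scale(matrix(rnorm(n * m1), n, m1), center = TRUE, scale = FALSE),
       X2 = scale(matrix(rnorm(n * m2), n, m2), center = TRUE, scale = FALSE),
       y = {y <- rnorm(n); y - mean(y)})
}

test_that("block rescaling zeroes the unweighted block at the boundaries", {
  inst <- dipr_instance()
  s1 <- scale_blocks(inst$X1, inst$X2, 1)
  expect_equal(s1[, 6:13], matrix(0, 14L, 8L), ignore_attr = TRUE)
  s0 <- scale_blocks(inst$X1, inst$X2, 0)
  expect_equal(s0[, 1:5], matrix(0, 14L, 5L), ignore_attr = TRUE)
  expect_error(scale_blocks(inst$X1, inst$X2, 1.2), "WOutOfRange")
})

test_that("w = 0.5 maps to pooled ridge at 2*lambda (sqrt-w) / 4*lambda (linear-w)", {
  inst <- dipr_instance(21)
  pooled <- cbind(inst$X1, inst$X2)
  for (lambda in c(0.3, 2, 40)) {
    r_sqrt <- ridge_fit(scale_blocks(inst$X1, inst$X2, 0.5, "sqrt-w"),
                        inst$y, lambda)
    r2 <- ridge_fit(pooled, inst$y, 2 * lambda)
    expect_lt(max(abs(ridge_predict(r_sqrt, scale_blocks(inst$X1, inst$X2,
                                                         0.5, "sqrt-w")) -
                      ridge_predict(r2, pooled))), 1e-8)
    r_lin <- ridge_fit(scale_blocks(inst$X1, inst$X2, 0.5, "linear-w"),
                         inst$y, lambda)
    r4 <- ridge_fit(pooled, inst$y, 4 * lambda)
    expect_lt(max(abs(ridge_predict(r_lin, scale_blocks(inst$X1, inst$X2,
                                                          0.5, "linear-w")) -
                      ridge_predict(r4, pooled))), 1e-8)
  }
})

test_that("boundary fits reduce exactly to single-block ridge", {
  inst <- dipr_instance(22)
  for (lambda in c(0.5, 5)) {
    d1 <- dipr_fit(inst$X1, inst$X2, inst$y, 1, lambda)
    expect_equal(unname(d1$coefficients_block2), rep(0, 8L))
    expect_equal(predict(d1, inst$X1, inst$X2),
                 ridge_predict(ridge_fit(inst$X1, inst$y, lambda), inst$X1),
                 tolerance = 1e-10)
    d0 <- dipr_fit(inst$X1, inst$X2, inst$y, 0, lambda)
    expect_equal(unname(d0$coefficients_block1), rep(0, 5L))
    expect_equal(predict(d0, inst$X1, inst$X2),
                 ridge_predict(ridge_fit(inst$X2, inst$y, lambda), inst$X2),
                 tolerance = 1e-10)
  }
})

test_that("the fit minimizes the two-penalty objective at mapped penalties", {
  inst <- dipr_instance(23, n = 10L, m1 = 3L, m2 = 4L)
  for (conv in c("sqrt-w", "linear-w")) {
    for (w in c(0.25, 0.6)) {
      lambda <- 1.5
      d <- dipr_fit(inst$X1, inst$X2, inst$y, w, lambda, convention = conv)
      pen <- d$effective_penalties
      b_oracle <- numeric_dipr_oracle(inst$X1, inst$X2, inst$y,
                                      pen[1L], pen[2L])
      expect_lt(max(abs(c(d$coefficients_block1, d$coefficients_block2) -
                        b_oracle)), 1e-6)
    }
  }
})

test_that("conventions give identical predictions at matched penalty pairs", {
  inst <- dipr_instance(24)
  w <- 0.3; lambda <- 2
  d_sqrt <- dipr_fit(inst$X1, inst$X2, inst$y, w, lambda, "sqrt-w")
  pen <- d_sqrt$effective_penalties           # lambda/w, lambda/(1-w)
  # linear-w parameters hitting the same (lambda_a, lambda_b):
  # lp/wp^2 = lambda_a and lp/(1-wp)^2 = lambda_b
  wp <- 1 / (1 + sqrt(pen[1L] / pen[2L]))
  lp <- pen[1L] * wp^2
  d_lin <- dipr_fit(inst$X1, inst$X2, inst$y, wp, lp, "linear-w")
  expect_lt(max(abs(predict(d_sqrt, inst$X1, inst$X2) -
                    predict(d_lin, inst$X1, inst$X2))), 1e-8)
})

test_that("grid search equals a brute-force scan of explicit scaled fits", {
  inst <- dipr_instance(25, n = 16L, m1 = 6L, m2 = 5L)
  w_grid <- c(0, 0.25, 0.5, 0.75, 1)
  l_grid <- c(0.5, 2, 10)
  sr <- dipr_search(inst$X1, inst$X2, inst$y, w_grid, l_grid)
  brute <- outer(seq_along(w_grid), seq_along(l_grid),
                 Vectorize(function(iw, il) {
                   loo_evaluate(scale_blocks(inst$X1, inst$X2, w_grid[iw]),
                                inst$y, l_grid[il])$cvc
                 }))
  expect_equal(unname(sr$cvc_grid), brute, tolerance = 1e-10)
  expect_equal(sr$cvc, max(brute), tolerance = 1e-10)
})

test_that("a degenerate {0,1} grid returns the better single-block ridge", {
  inst <- dipr_instance(26)
  l0 <- 3
  sr <- dipr_search(inst$X1, inst$X2, inst$y, c(0, 1), l0)
  c1 <- loo_evaluate(inst$X1, inst$y, l0)$cvc
  c2 <- loo_evaluate(inst$X2, inst$y, l0)$cvc
  expect_equal(sr$cvc, max(c1, c2), tolerance = 1e-10)
  expect_equal(sr$w, if (c1 >= c2) 1 else 0)
})

test_that("the searched optimum dominates the three special cases", {
  for (seed in 27:31) {
    inst <- dipr_instance(seed, n = 18L, m1 = 10L, m2 = 12L)
    sr <- dipr_search(inst$X1, inst$X2, inst$y)
    special <- sr$cvc_grid[default_w_grid() %in% c(0, 0.5, 1), ]
    expect_gte(sr$cvc, max(special, na.rm = TRUE))
  }
})

test_that("a noise second block pushes the selected weight toward block one", {
  set.seed(32)
  hits <- 0L
  for (k in 1:5) {
    n <- 60L
    X1 <- scale(matrix(rnorm(n * 8L), n))
    X2 <- scale(matrix(rnorm(n * 8L), n))
    y <- drop(X1 %*% rnorm(8L, sd = 2)) + rnorm(n, sd = 0.5)
    if (dipr_search(X1, X2, y)$w > 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("search failure is an explicit status, not an error", {
  inst <- dipr_instance(33)
  sr <- dipr_search(inst$X1, inst$X2, rep(3, 14L), c(0, 0.5, 1), c(1, 10))
  expect_true(sr$failed)
  expect_true(is.na(sr$w) && is.na(sr$lambda))
})

test_that("nested CV recovers a noiseless block-one signal", {
  set.seed(34)
  n <- 40L
  X1 <- matrix(rnorm(n * 10L), n)
  X2 <- matrix(rnorm(n * 10L), n)
  y <- drop(scale(X1) %*% runif(10L, 0.5, 1.5))
  res <- nested_cv_evaluate(X1, X2, y, method = "dipr",
                            w_grid = default_w_grid(0.1),
                            lambda_grid = default_lambda_grid(20L, 10L))
  expect_equal(res$status, "ok")
  expect_gt(res$cvc, 0.95)
  expect_gt(res$mean_w, 0.8)
})

test_that("nested CV on pure noise gives correlations near zero", {
  set.seed(35)
  cvcs <- vapply(1:15, function(k) {
    X1 <- matrix(rnorm(20L * 5L), 20L)
    X2 <- matrix(rnorm(20L * 5L), 20L)
    y <- rnorm(20L)
    nested_cv_evaluate(X1, X2, y, method = "dipr",
                       w_grid = c(0, 0.5, 1),
                       lambda_grid = default_lambda_grid(10L, 5L))$cvc
  }, numeric(1))
  expect_lt(abs(mean(cvcs, na.rm = TRUE)), 0.2)
})

test_that("nested pooled equals nested DiPR restricted to w = 0.5", {
  res_pooled <- nested_cv_evaluate(
    tiny_fx$marker_table$values, tiny_fx$metabolite_table$values, tiny_std$y,
    method = "pooled", lambda_grid = c(1, 10, 100))
  res_dipr <- nested_cv_evaluate(
    tiny_fx$marker_table$values, tiny_fx$metabolite_table$values, tiny_std$y,
    method = "dipr", w_grid = 0.5, lambda_grid = c(1, 10, 100) / 2)
  expect_lt(max(abs(res_pooled$oof_predictions - res_dipr$oof_predictions)),
            1e-8)
  expect_equal(res_pooled$cvc, res_dipr$cvc, tolerance = 1e-8)
})

test_that("single-block nested CV with w_grid boundaries matches block runs", {
  lg <- c(2, 20)
  r_b1 <- nested_cv_evaluate(tiny_fx$marker_table$values, NULL, tiny_std$y,
                             method = "block1", lambda_grid = lg)
  r_w1 <- nested_cv_evaluate(tiny_fx$marker_table$values,
                             tiny_fx$metabolite_table$values, tiny_std$y,
                             method = "dipr", w_grid = 1, lambda_grid = lg)
  expect_lt(max(abs(r_b1$oof_predictions - r_w1$oof_predictions)), 1e-8)
  r_b2 <- nested_cv_evaluate(tiny_fx$metabolite_table$values, NULL,
                             tiny_std$y, method = "block1", lambda_grid = lg)
  r_w0 <- nested_cv_evaluate(tiny_fx$marker_table$values,
                             tiny_fx$metabolite_table$values, tiny_std$y,
                             method = "dipr", w_grid = 0, lambda_grid = lg)
  expect_lt(max(abs(r_b2$oof_predictions - r_w0$oof_predictions)), 1e-8)
})

test_that("full-data standardization mode runs and differs from fold mode", {
  r_fold <- nested_cv_evaluate(tiny_fx$marker_table$values, NULL, tiny_std$y,
                               method = "block1", lambda_grid = c(5, 50))
  r_full <- nested_cv_evaluate(tiny_fx$marker_table$values, NULL, tiny_std$y,
                               method = "block1", lambda_grid = c(5, 50),
                               standardization_mode = "full-data")
  expect_equal(r_full$status, "ok")
  expect_false(isTRUE(all.equal(r_fold$oof_predictions,
                                r_full$oof_predictions)))
})
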