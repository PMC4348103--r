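mk_table <- function(v) {
  sample_table(v, sprintf("s%d", seq_len(nrow(v))),
               sprintf("m%d", seq_len(ncol(v))), role = "marker")
}

test_that("MAF filter drops monomorphic and rare markers, keeps the rest", {
  v <- cbind(rep(1, 5), c(1, 1, 1, 1, 0))         # maf 0 and 0.2
  out <- filter_maf(mk_table(v), maf_min = 0.01)
  expect_equal(out$feature_names, "m2")
  expect_equal(attr(out, "dropped")$feature, "m1")
  expect_equal(attr(out, "dropped")$reason, "maf")
})

test_that("MAF is computed over non-missing calls only", {
  # 1 of 4 observed calls present -> maf 0.25
  v <- cbind(c(1, 0, 0, 0, NA), c(1, 1, 0, 1, 0))
  out <- filter_maf(mk_table(v), maf_min = 0.3)
  expect_equal(out$feature_names, "m2")
  expect_error(filter_maf(mk_table(cbind(c(0.5, 1, 0))), 0.01), "NotBinary")
})

test_that("MAF filter agrees with a brute-force per-column recount", {
  set.seed(42)
  v <- matrix(rbinom(50 * 20, 1L, runif(20, 0.0, 0.5)[rep(1:20, each = 50)]),
              50L, 20L) * 1.0
  v[sample(length(v), 30L)] <- NA
  for (thr in c(0.01, 0.05, 0.2)) {
    keep <- brute_maf_keep(v, thr)
    out <- filter_maf(mk_table(v), maf_min = thr)
    expect_equal(out$feature_names, sprintf("m%d", which(keep)))
  }
})

test_that("correlation dedup keeps the earlier of correlated pairs", {
  set.seed(1)
  a <- rbinom(30L, 1L, 0.5) * 1.0
  v <- cbind(a, a, 1 - a, rbinom(30L, 1L, 0.5))
  out <- dedup_correlated(mk_table(v), r2_max = 0.95)
  # m2 duplicates m1; m3 = 1 - m1 has r^2 = 1 as well
  expect_equal(out$feature_names, c("m1", "m4"))
  d <- attr(out, "dropped")
  expect_equal(d$feature, c("m2", "m3"))
  expect_equal(d$partner, c("m1", "m1"))
})

test_that("independent columns survive dedup; constants are left alone", {
  set.seed(2)
  v <- matrix(rbinom(100L * 6L, 1L, 0.5), 100L, 6L) * 1.0
  out <- dedup_correlated(mk_table(v), r2_max = 0.95)
  expect_equal(ncol(out$values), 6L)
  vc <- cbind(rep(1, 10), rbinom(10L, 1L, 0.5))
  out2 <- dedup_correlated(mk_table(vc), r2_max = 0.95)
  expect_equal(ncol(out2$values), 2L)    # constant col: r^2 undefined
})

test_that("QC pipeline is the identity on a clean table", {
  set.seed(3)
  v <- matrix(rbinom(60L * 8L, 1L, 0.4), 60L, 8L) * 1.0
  tab <- mk_table(v)
  stopifnot(all(brute_maf_keep(v, 0.01)))
  out <- qc_markers(tab, maf_min = 0.01, r2_max = 0.95)
  expect_identical(out$values, tab$values)
  expect_equal(nrow(attr(out, "dropped")), 0L)
})

test_that("standardization matches hand-computed values", {
  s <- standardize_fit(cbind(c(1, 2, 3)))
  expect_equal(s$matrix[, 1L], c(-1, 0, 1))
  # mean 6, sample sd sqrt(2); missing becomes 0 after rescaling
  s2 <- standardize_fit(cbind(c(5, NA, 7)))
  expect_equal(s2$matrix[, 1L], c(-1, 0, 1) / sqrt(2))
  expect_equal(s2$stats$column_means, 6)
  expect_equal(s2$stats$column_sds, sqrt(2))
  # constant column flagged and zeroed
  s3 <- standardize_fit(cbind(c(2, 2, 2)))
  expect_equal(s3$matrix[, 1L], c(0, 0, 0))
  expect_true(s3$stats$constant)
  expect_error(standardize_fit(matrix(1, 1L, 1L)), "TooFewRows")
})

test_that("population-SD denominator is available as an option", {
  s <- standardize_fit(cbind(c(1, 2, 3)), sd_denom = "n")
  expect_equal(s$stats$column_sds, sqrt(2 / 3))
  expect_equal(s$matrix[, 1L], c(-1, 0, 1) / sqrt(2 / 3))
})

test_that("applying fit statistics reproduces the fit and scales new data", {
  set.seed(4)
  M <- matrix(rnorm(20L * 6L), 20L, 6L)
  M[sample(length(M), 8L)] <- NA
  s <- standardize_fit(M)
  expect_identical(standardize_apply(M, s$stats), s$matrix)
  # held-out value 8 under {mean 6, sd sqrt(2)} -> sqrt(2)
  s2 <- standardize_fit(cbind(c(5, NA, 7)))
  expect_equal(drop(standardize_apply(cbind(8), s2$stats)), sqrt(2))
  # held-out missing value -> 0
  expect_equal(drop(standardize_apply(cbind(NA_real_), s2$stats)), 0)
  expect_error(standardize_apply(M[, 1:3], s$stats), "ShapeMismatch")
})

test_that("training columns are standardized to mean 0 and sd 1", {
  set.seed(5)
  M <- matrix(rnorm(30L * 5L, sd = 4), 30L, 5L)
  s <- standardize_fit(M)
  expect_lt(max(abs(colMeans(s$matrix))), 1e-10)
  expect_lt(max(abs(apply(s$matrix, 2L, sd) - 1)), 1e-10)
  # trait is centered only: its mean is stored, variance untouched
  y <- rnorm(30L, mean = 10)
  st <- standardize_fit(M, trait = y)
  expect_equal(st$stats$trait_mean, mean(y))
})
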