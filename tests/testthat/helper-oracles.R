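# Independent oracles and small generators shared across the test files.
# These deliberately avoid the code paths they are used to check.

# Penalized least-squares objective: |y - Xb|^2 + lambda |b|^2.
ridge_objective <- function(b, X, y, lambda) {
  r <- y - drop(X %*% b)
  sum(r^2) + lambda * sum(b^2)
}

# Generic numerical minimizer of the ridge objective (gradient BFGS from
# zero); independent of the closed-form solve.
numeric_ridge_oracle <- function(X, y, lambda) {
  fn <- function(b) ridge_objective(b, X, y, lambda)
  gr <- function(b) -2 * drop(crossprod(X, y - drop(X %*% b))) +
    2 * lambda * b
  stats::optim(rep(0, ncol(X)), fn, gr = gr, method = "BFGS",
               control = list(maxit = 2000L, reltol = 1e-15))$par
}

# Two-penalty objective for the two-block model.
dipr_objective <- function(b, X1, X2, y, lambda_a, lambda_b) {
  m1 <- ncol(X1)
  b1 <- b[seq_len(m1)]; b2 <- b[-seq_len(m1)]
  r <- y - drop(X1 %*% b1) - drop(X2 %*% b2)
  sum(r^2) + lambda_a * sum(b1^2) + lambda_b * sum(b2^2)
}

numeric_dipr_oracle <- function(X1, X2, y, lambda_a, lambda_b) {
  m1 <- ncol(X1)
  fn <- function(b) dipr_objective(b, X1, X2, y, lambda_a, lambda_b)
  gr <- function(b) {
    b1 <- b[seq_len(m1)]; b2 <- b[-seq_len(m1)]
    r <- y - drop(X1 %*% b1) - drop(X2 %*% b2)
    c(-2 * drop(crossprod(X1, r)) + 2 * lambda_a * b1,
      -2 * drop(crossprod(X2, r)) + 2 * lambda_b * b2)
  }
  stats::optim(rep(0, ncol(X1) + ncol(X2)), fn, gr = gr, method = "BFGS",
               control = list(maxit = 5000L, reltol = 1e-15))$par
}

# Explicit n-refit leave-one-out predictions (the slow path the fast
# hat-matrix shortcut must reproduce).
refit_loo_oracle <- function(X, y, lambda) {
  vapply(seq_len(nrow(X)), function(i) {
    m <- ridge_fit(X[-i, , drop = FALSE], y[-i], lambda)
    ridge_predict(m, X[i, , drop = FALSE])
  }, numeric(1))
}

# Random instance with centered columns and centered response (the scale on
# which the closed-form/oracle comparison is cleanest).
random_centered_instance <- function(seed, n, m) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * m), n, m), center = TRUE, scale = FALSE)
  y <- rnorm(n); y <- y - mean(y)
  list(X = X, y = y)
}

# Brute-force per-column minor-allele-frequency keep decision.
brute_maf_keep <- function(values, maf_min) {
  apply(values, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0L) return(FALSE)
    p <- sum(col == 1) / length(col)
    min(p, 1 - p) >= maf_min
  })
}

# Random sample_table for round-trip checks.
random_sample_table <- function(seed, n = 6L, m = 4L,
                                role = "metabolite", missing = TRUE) {
  set.seed(seed)
  v <- matrix(rnorm(n * m) * 10^sample(-3:3, 1L), n, m)
  if (role == "marker") v <- matrix(rbinom(n * m, 1L, 0.4), n, m) * 1.0
  if (missing) v[sample(length(v), max(1L, length(v) %/% 10L))] <- NA
  sample_table(v, sprintf("s%02d", seq_len(n)), sprintf("f%02d", seq_len(m)),
               role = role)
}

# Write the three standard input tables for command-level tests.
write_fixture_inputs <- function(dir, ds = tiny_fx) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(trait = file.path(dir, "traits.csv"),
                markers = file.path(dir, "markers.csv"),
                metabolites = file.path(dir, "metabolites.csv"))
  write_table(ds$trait_table, paths$trait)
  write_table(ds$marker_table, paths$markers)
  write_table(ds$metabolite_table, paths$metabolites)
  paths
}

# Reduced grids that keep command-level nested CV fast in tests.
small_model_cfg <- list(w_step = 0.25, lambda_points = 4L,
                        lambda_lo = 1e-2, lambda_hi = 1e2)

# One cached tiny fixture for tests that only need plausible shaped data.
tiny_fx <- make_fixture("tiny")
tiny_std <- list(
  X1 = standardize_fit(tiny_fx$marker_table$values)$matrix,
  X2 = standardize_fit(tiny_fx$metabolite_table$values)$matrix,
  y = tiny_fx$trait_table$values[, 1L])
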