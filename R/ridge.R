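# Ridge regression core.
#
# All models carry an unpenalized intercept, realized by centering the
# response and the columns of the design matrix before solving
#   b = (X'X + I lambda)^{-1} X' y          (primal)
#   b = X' (X X' + I lambda)^{-1} y         (dual, identical for lambda > 0)
# Column centering is absorbed by the intercept and leaves the penalized fit
# unchanged, so it is always safe; it also makes the all-ones vector a null
# eigenvector of the centered kernel K = Xc Xc', which is what makes the
# leave-one-out shortcut below exact (hat matrix H = 11'/n + Hc).

.center_cols <- function(X) {
  mu <- colMeans(X)
  list(X = sweep(X, 2L, mu, "-"), means = mu)
}

#' Default penalty grid
#'
#' Log-uniform ladder scaled by the number of covariates, so that pooled and
#' single-block searches cover comparable amounts of shrinkage per column.
#'
#' @param m number of covariate columns the model will see.
#' @param length.out grid size (default 25).
#' @param lo,hi grid endpoints as multiples of `m` (defaults 1e-3 and 1e3).
#' @return increasing numeric vector of penalties.
#' @export
default_lambda_grid <- function(m, length.out = 25L, lo = 1e-3, hi = 1e3) {
  exp(seq(log(lo * m), log(hi * m), length.out = length.out))
}

#' Fit a ridge regression model
#'
#' Closed-form ridge with an unpenalized intercept (handled by centering).
#' With `lambda = 0` the fit is ordinary least squares and requires more rows
#' than columns and full column rank.  The primal form is used when columns
#' do not outnumber rows, the dual (kernel) form otherwise; both give the
#' same coefficients for positive penalties.
#'
#' @param X numeric design matrix (n x m), no missing values; usually the
#'   standardized output of [standardize_fit()].
#' @param y numeric response of length n (original or centered scale).
#' @param lambda nonnegative penalty.
#' @param method `"auto"` (default), `"primal"` or `"dual"`.
#' @return object of class `ridge_model`: `coefficients`, `lambda`,
#'   `intercept`, `trait_mean` (mean of `y`) and `column_means` of `X`.
#' @export
ridge_fit <- function(X, y, lambda, method = c("auto", "primal", "dual")) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); m <- ncol(X)
  stopifnot(length(y) == n, n >= 2L, is.finite(lambda), lambda >= 0)
  cc <- .center_cols(X)
  yc <- y - mean(y)
  if (lambda == 0) {
    if (m >= n)
      stop("SingularSystem: lambda = 0 needs fewer columns than rows",
           call. = FALSE)
    qrX <- qr(cc$X)
    if (qrX$rank < m)
      stop("SingularSystem: design matrix is rank deficient at lambda = 0",
           call. = FALSE)
    b <- qr.coef(qrX, yc)
  } else if (method == "primal" || (method == "auto" && m <= n)) {
    b <- solve(crossprod(cc$X) + diag(lambda, m), crossprod(cc$X, yc))
  } else {
    b <- crossprod(cc$X, solve(tcrossprod(cc$X) + diag(lambda, n), yc))
  }
  b <- drop(b)
  names(b) <- colnames(X)
  structure(list(coefficients = b, lambda = lambda,
                 intercept = mean(y) - sum(cc$means * b),
                 trait_mean = mean(y), column_means = cc$means),
            class = "ridge_model")
}

#' Predict from a ridge model
#'
#' @param model a `ridge_model` from [ridge_fit()].
#' @param X_new matrix on the same covariate scale as the training `X`.
#' @return numeric vector of predictions on the original response scale.
#' @export
ridge_predict <- function(model, X_new) {
  stopifnot(inherits(model, "ridge_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$coefficients))
    stop("ShapeMismatch: model has ", length(model$coefficients),
         " coefficients, X_new has ", ncol(X_new), " columns", call. = FALSE)
  drop(X_new %*% model$coefficients) + model$intercept
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("ridge_model: %d coefficients, lambda = %.4g, |b|^2 = %.4g\n",
              length(x$coefficients), x$lambda, sum(x$coefficients^2)))
  invisible(x)
}

# Eigen "machine" reused across penalties (and, for DiPR, across weights).
# K must be the kernel of a column-centered design; eigenvalues are clamped
# at zero to absorb numerical negatives.
.kernel_machine <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  list(U = e$vectors, d = pmax(e$values, 0), Usq = e$vectors^2)
}

# Exact leave-one-out predictions for ridge-with-intercept from the machine:
# fitted = ybar + U diag(s) U' (y - ybar),  s = d/(d + lambda),
# h_ii = 1/n + sum_j U_ij^2 s_j,  loo_i = y_i - (y_i - fitted_i)/(1 - h_ii).
.loo_from_machine <- function(mach, y, lambda) {
  n <- length(y)
  s <- mach$d / (mach$d + lambda)
  ybar <- mean(y)
  a <- crossprod(mach$U, y - ybar)
  fitted <- ybar + drop(mach$U %*% (s * a))
  h <- 1 / n + drop(mach$Usq %*% s)
  y - (y - fitted) / (1 - h)
}

# Pearson correlation with an explicit undefined flag for zero variance.
.cvc <- function(obs, pred) {
  if (stats::sd(obs) < .SD_EPS || stats::sd(pred) < .SD_EPS)
    return(list(cvc = NA_real_, defined = FALSE))
  list(cvc = stats::cor(obs, pred), defined = TRUE)
}

#' Exact fast leave-one-out evaluation of a ridge model
#'
#' Computes the n leave-one-out predictions with the hat-matrix shortcut
#' `loo_i = y_i - e_i / (1 - h_ii)`, which is algebraically identical to
#' refitting the intercept-plus-ridge model n times on the fixed design
#' (column scaling is not redone per fold; recentering is absorbed by the
#' intercept and therefore exact).  The cross-validation correlation (CVC)
#' is the Pearson correlation between `y` and the leave-one-out predictions;
#' it is flagged undefined, not an error, when either side has zero variance.
#'
#' @inheritParams ridge_fit
#' @param lambda positive penalty.
#' @return object of class `loo_result`: `loo_predictions`, `cvc`,
#'   `defined`, `lambda`.
#' @export
loo_evaluate <- function(X, y, lambda) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 3L, lambda > 0)
  mach <- .kernel_machine(tcrossprod(.center_cols(X)$X))
  loo <- .loo_from_machine(mach, y, lambda)
  c1 <- .cvc(y, loo)
  structure(list(loo_predictions = loo, cvc = c1$cvc, defined = c1$defined,
                 lambda = lambda), class = "loo_result")
}

# Shared grid scan given a prebuilt machine; returns per-lambda cvcs and the
# selected index (max cvc, ties to the LARGER lambda = more shrinkage).
.select_lambda_machine <- function(mach, y, lambda_grid) {
  cvcs <- vapply(lambda_grid, function(l) {
    .cvc(y, .loo_from_machine(mach, y, l))$cvc
  }, numeric(1))
  if (all(is.na(cvcs)))
    return(list(cvcs = cvcs, best = NA_integer_, failed = TRUE))
  mx <- max(cvcs, na.rm = TRUE)
  best <- max(which(!is.na(cvcs) & cvcs >= mx - 0))
  list(cvcs = cvcs, best = best, failed = FALSE)
}

#' Choose the ridge penalty by leave-one-out cross-validation
#'
#' Evaluates every penalty in the grid with the exact fast LOO and returns
#' the one maximizing the CVC; ties are broken toward the larger penalty
#' (the more shrunken, simpler model).  If every grid point has an undefined
#' correlation the selection fails explicitly (`failed = TRUE`) rather than
#' raising an error -- this is how downstream reports surface "failed".
#'
#' @inheritParams ridge_fit
#' @param lambda_grid increasing vector of positive penalties.
#' @return list with `lambda` (selected, `NA` on failure), `loo` (the
#'   [loo_evaluate()] result at the selection), `cvcs` (per-grid-point) and
#'   `failed`.
#' @export
select_lambda <- function(X, y, lambda_grid = default_lambda_grid(ncol(X))) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(length(lambda_grid) >= 1L, all(lambda_grid > 0),
            !is.unsorted(lambda_grid))
  mach <- .kernel_machine(tcrossprod(.center_cols(X)$X))
  sel <- .select_lambda_machine(mach, y, lambda_grid)
  if (sel$failed)
    return(list(lambda = NA_real_, loo = NULL, cvcs = sel$cvcs,
                failed = TRUE))
  lam <- lambda_grid[sel$best]
  loo <- .loo_from_machine(mach, y, lam)
  cv <- .cvc(y, loo)
  list(lambda = lam,
       loo = structure(list(loo_predictions = loo, cvc = cv$cvc,
                            defined = cv$defined, lambda = lam),
                       class = "loo_result"),
       cvcs = sel$cvcs, failed = FALSE)
}
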