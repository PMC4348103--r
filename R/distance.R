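# Distance matrices among samples and the Mantel permutation test.

.distance_matrix <- function(D, sample_ids, metric, source_block) {
  dimnames(D) <- list(sample_ids, sample_ids)
  structure(list(sample_ids = sample_ids, D = D, metric = metric,
                 source_block = source_block),
            class = "distance_matrix")
}

#' Euclidean distances between samples
#'
#' @param X numeric matrix (samples x features), no missing values --
#'   typically a standardized covariate block.
#' @param sample_ids row identifiers; taken from `rownames(X)` by default.
#' @param source_block label recorded on the result.
#' @return object of class `distance_matrix`: `sample_ids`, symmetric
#'   nonnegative `D` with zero diagonal, `metric`, `source_block`.
#' @export
euclidean_distances <- function(X, sample_ids = rownames(X),
                                source_block = "") {
  X <- as.matrix(X)
  if (anyNA(X))
    stop("MissingValues: distance input must be complete", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(X)))
  .distance_matrix(as.matrix(stats::dist(X)), sample_ids, "euclidean",
                   source_block)
}

#' Cophenetic distances from average-linkage (UPGMA) clustering
#'
#' Clusters the samples by unweighted pair-group average linkage and returns
#' the merge height of every pair -- the ultrametric cophenetic distance,
#' the "distance through the tree" alternative to the raw metric.
#'
#' @param dm a `distance_matrix`.
#' @return a `distance_matrix` with metric `"upgma-cophenetic"`.
#' @export
upgma_cophenetic <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  hc <- stats::hclust(stats::as.dist(dm$D), method = "average")
  .distance_matrix(as.matrix(stats::cophenetic(hc)), dm$sample_ids,
                   "upgma-cophenetic", dm$source_block)
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the upper off-diagonal
#' triangles.  The null distribution is built by jointly permuting the rows
#' and columns of the second matrix; the one-sided ("greater") p-value uses
#' the add-one correction `p = (#\{r_perm >= r\} + 1) / (n_permutations + 1)`,
#' so the smallest attainable p is `1 / (n_permutations + 1)`.  The test is
#' seeded and therefore bit-reproducible.
#'
#' @param d1,d2 `distance_matrix` objects over the same samples in the same
#'   order.
#' @param n_permutations number of permutations (default 10000; 100000 gives
#'   finer p resolution at ten times the cost).
#' @param seed integer seed for the permutation stream.
#' @return object of class `mantel_result`: `r`, `p`, `n_permutations`,
#'   `seed`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 10000L, seed = 1L) {
  stopifnot(inherits(d1, "distance_matrix"), inherits(d2, "distance_matrix"),
            n_permutations >= 1L)
  if (!identical(d1$sample_ids, d2$sample_ids))
    stop("IdMismatch: distance matrices cover different samples or orders",
         call. = FALSE)
  n <- length(d1$sample_ids)
  stopifnot(n >= 4L)
  ut <- upper.tri(d1$D)
  v1 <- d1$D[ut]
  v2 <- d2$D[ut]
  if (stats::sd(v1) < .SD_EPS || stats::sd(v2) < .SD_EPS)
    stop("ZeroVariance: all off-diagonal distances equal; r undefined",
         call. = FALSE)
  r_obs <- stats::cor(v1, v2)
  set.seed(seed)
  r_perm <- vapply(seq_len(n_permutations), function(k) {
    idx <- sample.int(n)
    stats::cor(v1, d2$D[idx, idx][ut])
  }, numeric(1))
  p <- (sum(r_perm >= r_obs) + 1) / (n_permutations + 1)
  structure(list(r = r_obs, p = p, n_permutations = n_permutations,
                 seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.5g (%d permutations, seed %d)\n",
              x$r, x$p, x$n_permutations, x$seed))
  invisible(x)
}

#' Write a distance matrix as a square delimited table
#'
#' @param dm a `distance_matrix`.
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, delimiter = ",") {
  stopifnot(inherits(dm, "distance_matrix"))
  df <- data.frame(sample_id = dm$sample_ids, dm$D, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
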