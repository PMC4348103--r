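#' Filter markers by minor allele frequency
#'
#' Drops every marker whose minor-allele frequency, computed over non-missing
#' calls only, is below `maf_min`.  For dominant 1/0 markers the allele
#' frequency is the mean presence score, and the MAF is `min(p, 1 - p)`;
#' monomorphic markers therefore have MAF 0 and are always removed at any
#' positive threshold.
#'
#' @param markers marker-role [sample_table()] with entries in \{0, 1, NA\}.
#' @param maf_min minimum minor allele frequency retained (default 0.01).
#' @return A [sample_table()] with the surviving markers.  The attribute
#'   `"dropped"` holds a data frame (`feature`, `reason`, `partner`)
#'   describing removals (reason `"maf"`, no partner).
#' @export
filter_maf <- function(markers, maf_min = 0.01) {
  stopifnot(inherits(markers, "sample_table"))
  v <- markers$values
  ok <- v[!is.na(v)]
  if (length(ok) && !all(ok %in% c(0, 1)))
    stop("NotBinary: marker table contains values other than 0/1/missing",
         call. = FALSE)
  p <- colMeans(v, na.rm = TRUE)
  p[is.nan(p)] <- 0                       # all-missing column: maf 0, dropped
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min
  dropped <- data.frame(feature = markers$feature_names[!keep],
                        reason = rep("maf", sum(!keep)),
                        partner = rep(NA_character_, sum(!keep)),
                        stringsAsFactors = FALSE)
  if (!any(keep))
    stop("EmptyTable: all markers removed by MAF filter", call. = FALSE)
  out <- sample_table(v[, keep, drop = FALSE],
                      sample_ids = markers$sample_ids,
                      feature_names = markers$feature_names[keep],
                      role = "marker")
  attr(out, "dropped") <- dropped
  out
}

#' Remove near-duplicate markers by squared correlation
#'
#' Greedy left-to-right scan in column order: a marker is dropped when its
#' squared Pearson correlation (pairwise-complete over missing calls) with
#' any *retained* earlier marker exceeds `r2_max`; the earlier partner is
#' recorded.  Keeping the earlier column is an arbitrary but deterministic
#' tie-break.  Constant columns have undefined correlations and are never
#' dropped here (the MAF filter handles them).
#'
#' @param markers marker-role [sample_table()].
#' @param r2_max maximum tolerated squared correlation (default 0.95).
#' @return A [sample_table()] of retained markers, with a `"dropped"`
#'   attribute as in [filter_maf()] (reason `"r2"`, partner = retained twin).
#' @export
dedup_correlated <- function(markers, r2_max = 0.95) {
  stopifnot(inherits(markers, "sample_table"))
  v <- markers$values
  m <- ncol(v)
  r2 <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))^2
  r2[!is.finite(r2)] <- 0
  keep <- logical(m)
  partner <- rep(NA_character_, m)
  kept_idx <- integer(0)
  for (j in seq_len(m)) {
    hit <- kept_idx[r2[kept_idx, j] > r2_max]
    if (length(hit)) {
      partner[j] <- markers$feature_names[hit[1L]]
    } else {
      keep[j] <- TRUE
      kept_idx <- c(kept_idx, j)
    }
  }
  dropped <- data.frame(feature = markers$feature_names[!keep],
                        reason = rep("r2", sum(!keep)),
                        partner = partner[!keep], stringsAsFactors = FALSE)
  out <- sample_table(v[, keep, drop = FALSE],
                      sample_ids = markers$sample_ids,
                      feature_names = markers$feature_names[keep],
                      role = "marker")
  attr(out, "dropped") <- dropped
  out
}

#' Marker quality control: MAF filter then correlation deduplication
#'
#' Applies [filter_maf()] followed by [dedup_correlated()] (the fixed order
#' used throughout) and merges their drop reports.
#'
#' @inheritParams filter_maf
#' @inheritParams dedup_correlated
#' @return A [sample_table()]; attribute `"dropped"` combines both stages.
#' @export
qc_markers <- function(markers, maf_min = 0.01, r2_max = 0.95) {
  s1 <- filter_maf(markers, maf_min)
  s2 <- dedup_correlated(s1, r2_max)
  attr(s2, "dropped") <- rbind(attr(s1, "dropped"), attr(s2, "dropped"))
  s2
}

#' QC report as a data frame
#'
#' One row per original feature with its status after quality control.
#'
#' @param original the pre-QC marker [sample_table()].
#' @param filtered the post-QC table returned by [qc_markers()].
#' @return data frame with columns `feature`, `status`, `reason`, `partner`.
#' @export
qc_report <- function(original, filtered) {
  dropped <- attr(filtered, "dropped")
  rep <- data.frame(feature = original$feature_names,
                    status = "kept", reason = NA_character_,
                    partner = NA_character_, stringsAsFactors = FALSE)
  i <- match(dropped$feature, rep$feature)
  rep$status[i] <- "dropped"
  rep$reason[i] <- dropped$reason
  rep$partner[i] <- dropped$partner
  rep
}

.SD_EPS <- 1e-12

#' Fit standardization statistics and standardize a covariate matrix
#'
#' Each column is centered and scaled to unit sample standard deviation
#' (denominator n - 1 by default), with statistics computed over non-missing
#' entries.  After rescaling, missing entries are replaced by zero (the
#' column mean on the standardized scale) and constant columns are set to
#' zero and flagged.  The optional trait vector is centered only -- its mean
#' is stored so that predictions can be returned on the original scale.
#'
#' @param matrix numeric matrix, `NA` allowed.
#' @param trait optional numeric response vector (no `NA`).
#' @param sd_denom `"n-1"` (sample SD, default) or `"n"` (population SD).
#' @param source label recorded on the statistics (`"training-fold"` or
#'   `"full-data"`).
#' @return list with `matrix` (standardized, no missing) and `stats`, an
#'   object of class `standardization_stats` holding `column_means`,
#'   `column_sds`, `constant` flags, `trait_mean`, `sd_denom` and `source`.
#' @export
standardize_fit <- function(matrix, trait = NULL,
                            sd_denom = c("n-1", "n"),
                            source = "training-fold") {
  sd_denom <- match.arg(sd_denom)
  X <- as.matrix(matrix)
  n <- nrow(X)
  if (n < 2L) stop("TooFewRows: need at least 2 rows", call. = FALSE)
  nobs <- n - colSums(is.na(X))
  mu <- colMeans(X, na.rm = TRUE)
  mu[nobs == 0L] <- 0
  ss <- colSums(sweep(X, 2L, mu, "-")^2, na.rm = TRUE)
  denom <- if (sd_denom == "n-1") pmax(nobs - 1L, 1L) else pmax(nobs, 1L)
  sds <- sqrt(ss / denom)
  constant <- !is.finite(sds) | sds < .SD_EPS | nobs < 2L
  stats <- structure(list(column_means = mu, column_sds = sds,
                          constant = constant,
                          trait_mean = if (is.null(trait)) NA_real_
                                       else mean(trait),
                          sd_denom = sd_denom, source = source),
                     class = "standardization_stats")
  list(matrix = standardize_apply(X, stats), stats = stats)
}

#' Apply stored standardization statistics to a matrix
#'
#' Used to scale held-out samples with training-fold statistics so that no
#' information leaks from the test sample into the model.  Missing entries
#' and constant-flagged columns become zero.
#'
#' @param matrix numeric matrix with `ncol` matching the statistics.
#' @param stats a `standardization_stats` object from [standardize_fit()].
#' @return standardized numeric matrix without missing values.
#' @export
standardize_apply <- function(matrix, stats) {
  stopifnot(inherits(stats, "standardization_stats"))
  X <- as.matrix(matrix)
  if (ncol(X) != length(stats$column_means))
    stop("ShapeMismatch: matrix has ", ncol(X), " columns, stats expect ",
         length(stats$column_means), call. = FALSE)
  sds <- ifelse(stats$constant, 1, stats$column_sds)
  Z <- sweep(sweep(X, 2L, stats$column_means, "-"), 2L, sds, "/")
  Z[, stats$constant] <- 0
  Z[is.na(Z)] <- 0
  Z
}
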