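#' Construct a sample-by-feature table
#'
#' The basic rectangular container used throughout the package: a numeric
#' matrix with unique sample identifiers as rows and unique feature names as
#' columns, tagged with a role.  Missing entries are `NA`.  Marker-role tables
#' must contain only 0, 1 and `NA` (dominant presence/absence scores).
#'
#' @param values numeric matrix (samples x features); `NA` marks missing.
#' @param sample_ids character vector of unique row identifiers.
#' @param feature_names character vector of unique column names.
#' @param role one of `"trait"`, `"marker"`, `"metabolite"`.
#' @return An object of class `sample_table`: a list with elements
#'   `sample_ids`, `feature_names`, `values` (dimnamed matrix) and `role`.
#' @export
sample_table <- function(values, sample_ids = rownames(values),
                         feature_names = colnames(values),
                         role = c("trait", "marker", "metabolite")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(feature_names))
    stop("sample_ids and feature_names are required", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("EmptyTable: table has no rows or no columns", call. = FALSE)
  if (length(sample_ids) != nrow(values) ||
      length(feature_names) != ncol(values))
    stop("dimension mismatch between values and id/name vectors",
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("DuplicateId: duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(feature_names))
    stop("DuplicateId: duplicated feature name(s): ",
         paste(unique(feature_names[duplicated(feature_names)]),
               collapse = ", "), call. = FALSE)
  if (role == "marker") {
    v <- values[!is.na(values)]
    if (length(v) && !all(v %in% c(0, 1)))
      stop("NotBinary: marker table contains values other than 0/1/missing",
           call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(list(sample_ids = sample_ids, feature_names = feature_names,
                 values = values, role = role),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("sample_table [%s]: %d samples x %d features, %d missing\n",
              x$role, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Read a delimited sample-by-feature table
#'
#' Expects a header row and the sample identifier in the first column.  Cells
#' matching one of `missing_tokens` become `NA`; any other non-numeric cell is
#' an error naming the offending row and column.
#'
#' @param path file path.
#' @param role table role, see [sample_table()].
#' @param delimiter single-character field separator (default comma).
#' @param missing_tokens character vector of strings treated as missing.
#' @return A [sample_table()].
#' @export
read_table <- function(path, role = c("trait", "marker", "metabolite"),
                       delimiter = ",", missing_tokens = c("", "NA", "NaN")) {
  role <- match.arg(role)
  if (!file.exists(path))
    stop("FileMissing: no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("EmptyTable: ", path, " has no data rows or no feature columns",
         call. = FALSE)
  ids <- trimws(raw[[1L]])
  feats <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(feats))
  for (j in seq_along(feats)) {
    cell <- trimws(raw[[j + 1L]])
    miss <- cell %in% missing_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("NonNumericCell: '%s' at row '%s', column '%s' in %s",
                   cell[i], ids[i], feats[j], path), call. = FALSE)
    }
    num[miss] <- NA_real_
    vals[, j] <- num
  }
  sample_table(vals, sample_ids = ids, feature_names = feats, role = role)
}

#' Write a sample table to delimited text
#'
#' Inverse of [read_table()]: header row, sample id first column, missing
#' entries written as `missing_token`.  Values round-trip to at least 1e-12.
#'
#' @param x a [sample_table()].
#' @param path output file path.
#' @param delimiter field separator.
#' @param missing_token string written for `NA` entries.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, delimiter = ",", missing_token = "NA") {
  stopifnot(inherits(x, "sample_table"))
  df <- data.frame(sample_id = x$sample_ids,
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1L][is.na(x$values)] <- missing_token
  colnames(df) <- c("sample_id", x$feature_names)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Align a trait table and covariate blocks on shared samples
#'
#' Restricts all tables to the intersection of their sample identifiers, in
#' the order of the trait table (a fixed, canonical choice), and reports how
#' many samples each table lost.
#'
#' @param trait a trait-role [sample_table()].
#' @param blocks named list of covariate [sample_table()]s (at least one).
#' @param quiet suppress the per-table drop log.
#' @return An object of class `aligned_dataset`: list with `sample_ids`,
#'   `trait` and `blocks` (named list), all row-aligned.
#' @export
align_tables <- function(trait, blocks, quiet = FALSE) {
  stopifnot(inherits(trait, "sample_table"))
  if (!is.list(blocks) || length(blocks) == 0L)
    stop("at least one covariate block is required", call. = FALSE)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    names(blocks) <- paste0("block", seq_along(blocks))
  for (b in blocks) stopifnot(inherits(b, "sample_table"))
  ids <- trait$sample_ids
  for (b in blocks) ids <- ids[ids %in% b$sample_ids]
  if (length(ids) == 0L)
    stop("EmptyIntersection: no sample ids shared by all tables",
         call. = FALSE)
  take <- function(tab) {
    keep <- match(ids, tab$sample_ids)
    sample_table(tab$values[keep, , drop = FALSE], sample_ids = ids,
                 feature_names = tab$feature_names, role = tab$role)
  }
  if (!quiet) {
    message(sprintf("align: %d shared samples; dropped %d from trait table",
                    length(ids), nrow(trait$values) - length(ids)))
    for (nm in names(blocks))
      message(sprintf("align: dropped %d from block '%s'",
                      nrow(blocks[[nm]]$values) - length(ids), nm))
  }
  structure(list(sample_ids = ids, trait = take(trait),
                 blocks = lapply(blocks, take)),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("aligned_dataset: %d samples, %d trait(s), blocks: %s\n",
              length(x$sample_ids), ncol(x$trait$values),
              paste(sprintf("%s(%d)", names(x$blocks),
                            vapply(x$blocks, function(b) ncol(b$values), 1L)),
                    collapse = ", ")))
  invisible(x)
}
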