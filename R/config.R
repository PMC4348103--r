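# Run configuration: nested key-value settings with defaults, loadable from
# a YAML file.  Command-line flags (see exec/dipr) override file values,
# which override the defaults below.

#' Default run configuration
#'
#' QC thresholds follow the standard marker pipeline (MAF < 0.01 removed,
#' one of each pair with squared correlation > 0.95 removed); the weight
#' grid runs 0..1 in steps of 0.05; the penalty grid is log-uniform with 25
#' points scaled by the number of covariates.
#'
#' @return nested named list of settings.
#' @export
default_run_config <- function() {
  list(
    inputs = list(trait = NULL, markers = NULL, metabolites = NULL),
    delimiter = ",",
    missing_tokens = c("", "NA", "NaN"),
    qc = list(maf_min = 0.01, r2_max = 0.95),
    model = list(w_step = 0.05, lambda_points = 25L, lambda_lo = 1e-3,
                 lambda_hi = 1e3, convention = "sqrt-w",
                 standardization_mode = "training-fold"),
    mantel = list(n_permutations = 10000L, metric = "euclidean"),
    simulate = list(),
    seed = 1L,
    output_dir = "."
  )
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Values present in the file override the [default_run_config()] defaults;
#' missing keys keep their defaults.  A list may be passed instead of a path
#' (it is merged the same way), so programmatic callers and the CLI share
#' one code path.
#'
#' @param config path to a YAML file, a list of overrides, or `NULL` for
#'   pure defaults.
#' @return the merged configuration list.
#' @export
read_run_config <- function(config = NULL) {
  base <- default_run_config()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config))
      stop("FileMissing: no such config file: ", config, call. = FALSE)
    # YAML 1.1 would read the bare keys "n"/"y" (e.g. the sample-size field
    # of the simulate section) as booleans; keep them literal.
    config <- yaml::read_yaml(
      config,
      handlers = list(
        "bool#no" = function(x) if (tolower(x) %in% c("n")) x else FALSE,
        "bool#yes" = function(x) if (tolower(x) %in% c("y")) x else TRUE))
  }
  stopifnot(is.list(config))
  cfg <- .merge_config(base, config)
  stopifnot(cfg$qc$maf_min >= 0, cfg$qc$maf_min < 0.5,
            cfg$qc$r2_max > 0, cfg$qc$r2_max <= 1,
            cfg$model$w_step > 0, cfg$model$w_step <= 0.5,
            cfg$model$lambda_points >= 1)
  cfg
}

.config_w_grid <- function(cfg) default_w_grid(cfg$model$w_step)

.config_lambda_grid <- function(cfg, m) {
  default_lambda_grid(m, length.out = cfg$model$lambda_points,
                      lo = cfg$model$lambda_lo, hi = cfg$model$lambda_hi)
}
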