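#' Construct a table of paired transcription measurements
#'
#' The canonical data container: one row per promoter variant and
#' condition, holding the transcription rate measured with (`t_plus`) and
#' without (`t_minus`) the active transcription factor, in matched
#' arbitrary units. Architecture labels (e.g. a CRP site position such as
#' "-61.5") and condition labels (e.g. a cAMP concentration) are free
#' strings carried as metadata.
#'
#' @param promoter_id Character vector of promoter identifiers.
#' @param t_minus,t_plus Positive transcription rates (a.u.).
#' @param architecture,condition Optional grouping labels (recycled).
#' @param cAMP_uM Optional numeric effector concentration.
#' @param is_outlier Optional logical flag (default all FALSE).
#' @return A `data.frame` of class `"measurement_table"`.
#' @export
measurement_table <- function(promoter_id, t_minus, t_plus,
                              architecture = "default",
                              condition = "default",
                              cAMP_uM = NA_real_, is_outlier = FALSE) {
  df <- data.frame(promoter_id = as.character(promoter_id),
                   architecture = as.character(architecture),
                   condition = as.character(condition),
                   t_minus = as.numeric(t_minus),
                   t_plus = as.numeric(t_plus),
                   cAMP_uM = as.numeric(cAMP_uM),
                   is_outlier = as.logical(is_outlier),
                   stringsAsFactors = FALSE)
  validate_measurements(df)
}

validate_measurements <- function(df) {
  required <- c("promoter_id", "t_minus", "t_plus")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_allelic(paste("missing required column(s):",
                       paste(missing, collapse = ", ")), "parse_error")
  }
  if (is.null(df$architecture)) df$architecture <- "default"
  if (is.null(df$condition)) df$condition <- "default"
  df$promoter_id <- as.character(df$promoter_id)
  df$architecture <- as.character(df$architecture)
  df$condition <- as.character(df$condition)
  if (is.null(df$cAMP_uM)) df$cAMP_uM <- NA_real_
  df$cAMP_uM <- as.numeric(df$cAMP_uM)
  if (is.null(df$is_outlier)) df$is_outlier <- FALSE
  df$is_outlier[is.na(df$is_outlier)] <- FALSE
  for (col in c("t_minus", "t_plus")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad)) {
      stop_allelic(sprintf(
        "column '%s' must be numeric and > 0; offending row(s): %s",
        col, paste(utils::head(bad, 5), collapse = ", ")), "parse_error")
    }
    df[[col]] <- v
  }
  key <- paste(df$promoter_id, df$condition, sep = "\r")
  if (anyDuplicated(key)) {
    stop_allelic(sprintf(
      "duplicate (promoter_id, condition) key at row(s): %s",
      paste(which(duplicated(key)), collapse = ", ")), "parse_error")
  }
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Read / write measurement tables as CSV
#'
#' The canonical on-disk format is a UTF-8 comma-separated file with a
#' header row and columns `promoter_id, architecture, condition, t_minus,
#' t_plus` (plus optional `cAMP_uM`, `is_outlier`). A supplementary-style
#' export in which the paired channels are named differently (e.g. `tplus`
#' / `tminus` columns of a spreadsheet export) can be ingested by passing a
#' `col_map` renaming its columns onto the canonical schema.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(promoter_id = "name", t_minus = "tminus", t_plus = "tplus")`.
#' @return `read_measurements`: a validated [measurement_table()].
#' @export
read_measurements <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    stop_allelic(paste("no such file:", path), "parse_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df)) {
        stop_allelic(sprintf("mapped column '%s' (for '%s') not in file",
                             src, canon), "parse_error")
      }
      df[[canon]] <- df[[src]]
      if (!canon %in% col_map) df[[src]] <- NULL
    }
  }
  validate_measurements(df)
}

#' @rdname read_measurements
#' @param x A [measurement_table()].
#' @export
write_measurements <- function(x, path) {
  stopifnot(inherits(x, "measurement_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' A single human-readable YAML file configures a fitting run: mechanism,
#' fixed parameters, bootstrap settings, outlier threshold, regime
#' strictness and paths. Unknown keys are rejected to catch typos.
#'
#' @param path Path to a YAML file.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  defaults <- list(mechanism = "repression", F_tf = NULL,
                   fixed = list(), n_boot = 100L, seed = 1L,
                   n_starts = 10L, outlier_threshold = 0.5,
                   regime_strictness = 1,
                   select_concentrations = 4L,
                   input = NULL, output_dir = NULL)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop_allelic(paste("unknown config key(s):",
                       paste(unknown, collapse = ", ")), "config_error")
  }
  utils::modifyList(defaults, cfg)
}

#' Write a fit summary as versioned JSON
#'
#' Serializes point estimates, bootstrap confidence intervals, loss,
#' settings and seed to JSON (12 significant digits) so that a run is fully
#' regenerable from inputs + config + seed.
#'
#' @param fit A `manifold_fit` (and optionally its `manifold_boot`).
#' @param path Output path.
#' @param boot Optional bootstrap ensemble whose CIs to embed.
#' @export
write_fit_json <- function(fit, path, boot = NULL) {
  stopifnot(inherits(fit, "manifold_fit"))
  out <- list(schema_version = "1.0",
              package_version = as.character(utils::packageVersion("allelic")),
              mechanism = fit$mechanism,
              estimates = as.list(fit$estimates),
              dg = as.list(fit$dg),
              loss = fit$loss,
              n_used = fit$n_used,
              outliers_excluded = fit$outliers_excluded,
              settings = fit$settings,
              P_by_promoter = as.list(fit$P_by_promoter))
  if (!is.null(boot)) {
    out$bootstrap <- list(n_boot = boot$n_boot, n_failed = boot$n_failed,
                          seed = boot$seed, ci68 = boot$ci68,
                          ci95 = boot$ci95)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(12),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("<measurement_table> %d promoters, %d architecture(s), %d flagged outlier(s)\n",
              nrow(x), length(unique(x$architecture)), sum(x$is_outlier)))
  NextMethod()
}
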