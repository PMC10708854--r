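#' Construct a spectral TVC dataset
#'
#' A `spectral_dataset` is a data frame with one row per specimen and a
#' fixed column layout: `sample_id`, `temperature_C`, `storage_time_h`,
#' the 18 mean-reflectance features `Mean.01`..`Mean.18`, the 18
#' pixel-intensity standard-deviation features `StdDev.01`..`StdDev.18`,
#' and the (optional) regression target `tvc` in log10 cfu cm^-2.
#'
#' @param df data frame holding the columns above (`tvc` may be absent
#'   or `NA` for prediction-only samples).
#' @return The validated data frame with class `spectral_dataset`.
#' @seealso [read_dataset()], [write_dataset()], [feature_matrix()]
#' @export
spectral_dataset <- function(df) {
  required <- c("sample_id", "temperature_C", "storage_time_h",
                feature_cols("mean"), feature_cols("sd"))
  for (col in required) {
    if (!col %in% names(df)) {
      stop(sprintf("dataset is missing required column '%s'", col),
           call. = FALSE)
    }
  }
  if (anyDuplicated(names(df))) {
    stop(sprintf("duplicated column '%s'",
                 names(df)[duplicated(names(df))][1]), call. = FALSE)
  }
  if (!"tvc" %in% names(df)) df$tvc <- NA_real_
  df <- df[, c(required, "tvc")]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  num_cols <- setdiff(names(df), "sample_id")
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) &
                     !(is.na(v) | as.character(v) == ""))
      if (length(bad) && col != "tvc") {
        stop(sprintf("non-numeric value in column '%s', row %d", col, bad[1]),
             call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(as.character(v)))
    }
    df[[col]] <- v
  }
  feats <- c(feature_cols("mean"), feature_cols("sd"))
  if (nrow(df) > 0) {
    fm <- as.matrix(df[, feats])
    if (anyNA(fm)) {
      stop("reflectance features must not contain missing values",
           call. = FALSE)
    }
    if (any(!is.finite(df$tvc) & !is.na(df$tvc))) {
      stop("tvc must be finite when present", call. = FALSE)
    }
  }
  class(df) <- c("spectral_dataset", "data.frame")
  df
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("spectral_dataset: %d samples, 36 reflectance features (%d with tvc)\n",
              nrow(x), sum(!is.na(x$tvc))))
  if (nrow(x) > 0) {
    cat(sprintf("  temperatures (C): %s\n",
                paste(sort(unique(x$temperature_C)), collapse = ", ")))
    if (any(!is.na(x$tvc))) {
      cat(sprintf("  tvc range: %.3f - %.3f log10 cfu/cm^2\n",
                  min(x$tvc, na.rm = TRUE), max(x$tvc, na.rm = TRUE)))
    }
  }
  invisible(x)
}

#' Extract a feature block as a numeric matrix
#'
#' @param ds a [spectral_dataset()].
#' @param block `"mean"` for the mean-reflectance features or `"sd"` for
#'   the pixel-intensity standard deviations.
#' @param bands optional integer vector of waveband indices (1..18) to keep.
#' @return Numeric matrix (samples x bands) with the dataset's sample ids
#'   as row names.
#' @export
feature_matrix <- function(ds, block = c("mean", "sd"), bands = 1:18) {
  block <- match.arg(block)
  bands <- as.integer(bands)
  stopifnot(all(bands >= 1L), all(bands <= 18L))
  m <- as.matrix(as.data.frame(ds)[, feature_cols(block)[bands], drop = FALSE])
  rownames(m) <- ds$sample_id
  m
}

#' Read a spectral TVC dataset from delimited text
#'
#' @param path path to a delimited text file with the
#'   [spectral_dataset()] column layout; an empty `tvc` cell encodes a
#'   missing target.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(path, delim = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, na.strings = "")
  spectral_dataset(df)
}

#' Write a spectral TVC dataset to delimited text
#'
#' Missing `tvc` values are written as empty cells.  `read_dataset()`
#' recovers the dataset up to floating-point formatting (15 significant
#' digits are written).
#'
#' @param ds a [spectral_dataset()].
#' @param path output path.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, delim = ",") {
  ds <- spectral_dataset(as.data.frame(ds))
  out <- as.data.frame(ds)
  num_cols <- setdiff(names(out), "sample_id")
  for (col in num_cols) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 15, format = "g"))
  }
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Construct a feature-ranking table
#'
#' A ranking table records, for one or more feature-selection methods,
#' the importance rank each method assigned to the waveband indices it
#' retained.  Within a method, ranks must be the distinct integers
#' `1..m` with no gaps, where `m` is the number of bands the method kept.
#'
#' @param df data frame with columns `method` (character), `band_index`
#'   (integer, 1..18) and `rank` (positive integer).
#' @param statistic which feature block the ranking refers to.
#' @return The validated data frame with class `ranking_table` and the
#'   block stored in `attr(, "statistic")`.
#' @export
ranking_table <- function(df, statistic = c("mean", "sd")) {
  statistic <- match.arg(statistic)
  for (col in c("method", "band_index", "rank")) {
    if (!col %in% names(df)) {
      stop(sprintf("ranking table is missing column '%s'", col), call. = FALSE)
    }
  }
  df <- data.frame(method = as.character(df$method),
                   band_index = as.integer(df$band_index),
                   rank = as.integer(df$rank),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(df$band_index < 1L | df$band_index > 18L)) {
      stop("band_index must lie in 1..18", call. = FALSE)
    }
    if (any(df$rank < 1L)) stop("ranks must be positive", call. = FALSE)
    for (m in unique(df$method)) {
      r <- sort(df$rank[df$method == m])
      if (anyDuplicated(r)) {
        stop(sprintf("method '%s' assigns a duplicate rank", m), call. = FALSE)
      }
      if (!identical(r, seq_along(r))) {
        stop(sprintf("method '%s' has gaps in its rank sequence", m),
             call. = FALSE)
      }
      if (anyDuplicated(df$band_index[df$method == m])) {
        stop(sprintf("method '%s' ranks a band twice", m), call. = FALSE)
      }
    }
  }
  attr(df, "statistic") <- statistic
  class(df) <- c("ranking_table", "data.frame")
  df
}

#' Read a feature-ranking table from CSV
#'
#' @param path CSV file with columns `method,band_index,rank`.
#' @param statistic which feature block the ranking refers to.
#' @return A [ranking_table()].
#' @export
read_ranking_table <- function(path, statistic = c("mean", "sd")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ranking_table(df, statistic = statistic)
}

#' Write a feature-ranking table to CSV
#'
#' @param rt a [ranking_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking_table <- function(rt, path) {
  utils::write.csv(as.data.frame(rt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
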