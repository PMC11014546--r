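#' Construct a validated profile table
#'
#' A profile table couples per-sample metadata (perturbation id, plate, well,
#' control flag, ...) with a numeric feature matrix, one row per profile
#' (replicate, consensus, or single cell). Metadata columns are identified by
#' a name prefix (`"Metadata_"` by default, the convention used by profiling
#' pipelines) or by an explicit column list; every remaining column is treated
#' as a feature and must be numeric and finite.
#'
#' @param data A data frame with metadata and numeric feature columns.
#' @param metadata Character vector naming the metadata columns. If `NULL`,
#'   columns whose names start with `metadata_prefix` are used.
#' @param metadata_prefix Prefix identifying metadata columns when `metadata`
#'   is not given.
#' @param na_action What to do when a feature column contains non-finite
#'   values: `"error"` (default) rejects the table, `"drop_columns"` removes
#'   the offending columns with a warning.
#'
#' @return An object of class `profile_table`: a list with elements `data`
#'   (a tibble), `metadata` and `features` (character vectors of column
#'   names).
#' @export
#' @examples
#' df <- data.frame(
#'   Metadata_pert = c("a", "a", "b", "b"),
#'   f1 = rnorm(4), f2 = rnorm(4)
#' )
#' pt <- profile_table(df)
#' feature_matrix(pt)
profile_table <- function(data, metadata = NULL,
                          metadata_prefix = "Metadata_",
                          na_action = c("error", "drop_columns")) {
  na_action <- match.arg(na_action)
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (anyDuplicated(names(data)) > 0) {
    stop("duplicate column names: ",
         paste(unique(names(data)[duplicated(names(data))]), collapse = ", "))
  }
  if (is.null(metadata)) {
    metadata <- names(data)[startsWith(names(data), metadata_prefix)]
  } else {
    missing_cols <- setdiff(metadata, names(data))
    if (length(missing_cols) > 0) {
      stop("metadata columns not found: ", paste(missing_cols, collapse = ", "))
    }
  }
  features <- setdiff(names(data), metadata)
  if (length(features) == 0) {
    stop("no feature columns")
  }
  not_numeric <- features[!vapply(data[features], is.numeric, logical(1))]
  if (length(not_numeric) > 0) {
    stop("non-numeric feature columns (declare them as metadata?): ",
         paste(not_numeric, collapse = ", "))
  }
  bad <- features[vapply(data[features], function(v) any(!is.finite(v)), logical(1))]
  if (length(bad) > 0) {
    if (na_action == "error") {
      stop("non-finite values in feature columns: ",
           paste(bad, collapse = ", "))
    }
    warning("dropping ", length(bad),
            " feature column(s) with non-finite values: ",
            paste(bad, collapse = ", "))
    features <- setdiff(features, bad)
    data <- data[c(metadata, features)]
    if (length(features) == 0) stop("no feature columns")
  }
  if (nrow(data) < 2) stop("a profile table needs at least 2 profiles")
  structure(
    list(data = data, metadata = metadata, features = features),
    class = "profile_table"
  )
}

#' @export
print.profile_table <- function(x, ...) {
  cat(sprintf("<profile_table> %d profiles x %d features (%d metadata columns)\n",
              nrow(x$data), length(x$features), length(x$metadata)))
  print(utils::head(x$data, 5))
  invisible(x)
}

#' Accessors for profile tables
#'
#' @param x A `profile_table`.
#' @return `feature_matrix()` returns the numeric feature matrix (profiles in
#'   rows); `profile_metadata()` the metadata tibble; `feature_names()` and
#'   `metadata_names()` the respective column names; `n_profiles()` the row
#'   count.
#' @export
feature_matrix <- function(x) {
  stopifnot(inherits(x, "profile_table"))
  as.matrix(x$data[x$features])
}

#' @rdname feature_matrix
#' @export
profile_metadata <- function(x) {
  stopifnot(inherits(x, "profile_table"))
  x$data[x$metadata]
}

#' @rdname feature_matrix
#' @export
feature_names <- function(x) x$features

#' @rdname feature_matrix
#' @export
metadata_names <- function(x) x$metadata

#' @rdname feature_matrix
#' @export
n_profiles <- function(x) nrow(x$data)

#' Read a profile table from CSV or Parquet
#'
#' @param path Path to a `.csv` or `.parquet` file.
#' @inheritParams profile_table
#' @return A [profile_table].
#' @export
read_profiles <- function(path, metadata = NULL,
                          metadata_prefix = "Metadata_",
                          na_action = c("error", "drop_columns")) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  data <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    parquet = arrow::read_parquet(path),
    stop("unsupported file extension: .", ext, " (expected .csv or .parquet)")
  )
  profile_table(data, metadata = metadata, metadata_prefix = metadata_prefix,
                na_action = na_action)
}

#' Write a profile table to CSV or Parquet
#'
#' @param x A [profile_table].
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path) {
  stopifnot(inherits(x, "profile_table"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = readr::write_csv(x$data, path, progress = FALSE),
    parquet = arrow::write_parquet(x$data, path),
    stop("unsupported file extension: .", ext)
  )
  invisible(path)
}

#' Normalize profile features
#'
#' Two normalizations commonly applied to profiling data, optionally within
#' groups defined by a metadata column (typically the plate):
#'
#' * `standardize`: per feature, subtract the mean and divide by the standard
#'   deviation (z-score).
#' * `mad_robustize`: per feature, subtract the median and divide by the
#'   median absolute deviation scaled by the consistency constant 1.4826 (so
#'   the scale estimates the standard deviation under normality), plus
#'   `epsilon` to guard against zero scale.
#'
#' Features with zero scale within a group map to 0: a constant feature
#' carries no ranking information either way.
#'
#' @param x A [profile_table].
#' @param method `"standardize"` or `"mad_robustize"`.
#' @param by Optional metadata column; normalization is applied within each
#'   of its groups (e.g. per plate).
#' @param epsilon Small positive constant added to the scaled MAD.
#' @return A normalized [profile_table].
#' @export
normalize_profiles <- function(x, method = c("standardize", "mad_robustize"),
                               by = NULL, epsilon = 1e-6) {
  stopifnot(inherits(x, "profile_table"))
  method <- match.arg(method)
  stopifnot(epsilon > 0)
  if (!is.null(by)) {
    if (!by %in% x$metadata) stop("`by` is not a metadata column: ", by)
    groups <- split(seq_len(nrow(x$data)), x$data[[by]])
  } else {
    groups <- list(seq_len(nrow(x$data)))
  }
  small <- vapply(groups, length, integer(1)) < 2
  if (any(small)) {
    stop("normalization group(s) with a single profile: ",
         paste(names(groups)[small], collapse = ", "))
  }
  mat <- feature_matrix(x)
  for (idx in groups) {
    block <- mat[idx, , drop = FALSE]
    if (method == "standardize") {
      centre <- colMeans(block)
      scale <- apply(block, 2, stats::sd)
      scaled <- sweep(block, 2, centre, "-")
      zero <- scale == 0
      scale[zero] <- 1
      scaled <- sweep(scaled, 2, scale, "/")
      scaled[, zero] <- 0
    } else {
      centre <- apply(block, 2, stats::median)
      scale <- apply(block, 2, stats::mad) # constant 1.4826 is mad()'s default
      scaled <- sweep(block, 2, centre, "-")
      zero <- scale == 0
      scaled <- sweep(scaled, 2, scale + epsilon, "/")
      scaled[, zero] <- 0
    }
    mat[idx, ] <- scaled
  }
  out <- x
  out$data[x$features] <- tibble::as_tibble(mat)
  out
}

#' Aggregate replicates into consensus profiles
#'
#' Collapses each group of replicate profiles (distinct combination of the
#' `by` metadata columns) into one consensus profile by taking the per-feature
#' median. Metadata columns that are not constant within every group are
#' dropped, since they no longer describe the aggregated row.
#'
#' @param x A [profile_table].
#' @param by Metadata columns defining the groups (e.g. the perturbation id).
#' @return A [profile_table] with one row per distinct `by` combination.
#' @export
consensus_profiles <- function(x, by) {
  stopifnot(inherits(x, "profile_table"))
  missing_cols <- setdiff(by, x$metadata)
  if (length(missing_cols) > 0) {
    stop("`by` columns not in metadata: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(x$data) == 0) stop("empty table")
  other_meta <- setdiff(x$metadata, by)
  key <- interaction(x$data[by], drop = TRUE, lex.order = TRUE)
  constant <- vapply(other_meta, function(col) {
    all(tapply(x$data[[col]], key, function(v) length(unique(v))) == 1L)
  }, logical(1))
  keep_meta <- c(by, other_meta[constant])
  grouped <- dplyr::group_by(x$data, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    grouped,
    dplyr::across(dplyr::all_of(other_meta[constant]), dplyr::first),
    dplyr::across(dplyr::all_of(x$features), stats::median),
    .groups = "drop"
  )
  structure(
    list(data = out[c(keep_meta, x$features)],
         metadata = keep_meta, features = x$features),
    class = "profile_table"
  )
}
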