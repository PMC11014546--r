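#' Distance between two profiles
#'
#' Dissimilarities used to rank candidate profiles against a query:
#' * `cosine`: 1 - cosine similarity, in \[0, 2\]; invariant to positive
#'   rescaling of either profile. The default throughout the package, chosen
#'   for its ability to pick out related high-dimensional profiles.
#' * `euclidean`: the usual L2 distance.
#' * `correlation`: 1 - Pearson correlation, in \[0, 2\].
#'
#' @param x,y Numeric vectors of equal length.
#' @param metric One of `"cosine"`, `"euclidean"`, `"correlation"`.
#' @return A non-negative scalar; larger means less similar.
#' @export
#' @examples
#' profile_distance(c(1, 0), c(0, 1), "cosine") # orthogonal: 1
#' profile_distance(c(0, 0), c(3, 4), "euclidean") # 5
profile_distance <- function(x, y,
                             metric = c("cosine", "euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (length(x) != length(y)) stop("dimension mismatch")
  if (length(x) < 1) stop("profiles must have at least one feature")
  drop(query_distances(x, matrix(y, nrow = 1), metric))
}

# Distances from a query vector to each row of a candidate matrix.
# Vectorized core shared by all rank-list construction.
query_distances <- function(query, candidates, metric) {
  switch(metric,
    cosine = {
      qn <- sqrt(sum(query^2))
      cn <- sqrt(rowSums(candidates^2))
      if (qn == 0 || any(cn == 0)) {
        stop("cosine distance is undefined for an all-zero profile")
      }
      d <- 1 - drop(candidates %*% query) / (cn * qn)
      pmin(pmax(d, 0), 2)
    },
    euclidean = {
      sqrt(rowSums(sweep(candidates, 2, query, "-")^2))
    },
    correlation = {
      if (stats::sd(query) == 0 ||
          any(apply(candidates, 1, stats::sd) == 0)) {
        stop("correlation distance is undefined for a constant profile")
      }
      d <- 1 - drop(stats::cor(query, t(candidates)))
      pmin(pmax(d, 0), 2)
    },
    stop("unknown metric: ", metric)
  )
}

#' Binary rank list for one retrieval instance
#'
#' Ranks the instance's positives and references by increasing distance to
#' the query and marks positives with 1. Ties are broken deterministically by
#' original row index (stable order); ties have probability zero for
#' continuous features but must not introduce nondeterminism when they occur.
#'
#' @param instance A `retrieval_instance` from [build_instances()].
#' @param x The [profile_table] the instance indexes into.
#' @param metric Distance metric, see [profile_distance()].
#' @return Integer 0/1 vector of length `(M-1) + N` with `M-1` ones, carrying
#'   attributes `n_pos` and `n_total`.
#' @export
rank_list <- function(instance, x, metric = "cosine") {
  stopifnot(inherits(instance, "retrieval_instance"),
            inherits(x, "profile_table"))
  mat <- feature_matrix(x)
  candidates <- c(instance$positives, instance$references)
  d <- tryCatch(
    query_distances(mat[instance$query, ], mat[candidates, , drop = FALSE],
                    metric),
    error = function(e) {
      stop("group ", instance$group_id, ", query row ", instance$query, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  ord <- order(d, candidates) # stable: distance, then original row index
  relevance <- as.integer(candidates[ord] %in% instance$positives)
  structure(relevance,
            n_pos = length(instance$positives),
            n_total = length(candidates))
}

#' Non-interpolated average precision of a binary rank list
#'
#' AP is the mean of precision-at-k over the ranks k that hold a correct
#' match; equivalently the sum of precision times the increment in recall,
#' the non-interpolated area under the precision-recall curve. It equals 1
#' exactly when every positive precedes every negative, and is bounded below
#' by a positive quantity (the last positive contributes at least
#' n_pos / n_total).
#'
#' @param relevance Integer or logical 0/1 vector, positives marked 1, in
#'   rank order (nearest first).
#' @return AP in (0, 1].
#' @export
#' @examples
#' average_precision(c(1, 1, 0, 0)) # perfect retrieval: 1
#' average_precision(c(1, 0, 1)) # (1 + 2/3) / 2 = 5/6
average_precision <- function(relevance) {
  relevance <- as.integer(relevance)
  if (any(!relevance %in% c(0L, 1L))) stop("relevance must be binary")
  ranks <- which(relevance == 1L)
  if (length(ranks) == 0) stop("rank list contains no positives")
  mean(seq_along(ranks) / ranks)
}

#' Mean average precision of a query group
#'
#' @param ap Numeric vector of per-query AP values for one group.
#' @return The arithmetic mean of the AP values.
#' @export
mean_average_precision <- function(ap) {
  if (length(ap) == 0) stop("empty group")
  mean(ap)
}

#' Per-query AP scores for a set of retrieval instances
#'
#' Runs the ranking and AP computation for every instance and returns a tidy
#' table, one row per query, retaining the list-shape parameters needed for
#' significance testing.
#'
#' @param x A [profile_table].
#' @param instances Result of [build_instances()].
#' @param metric Distance metric, see [profile_distance()].
#' @return A tibble with columns `group_id`, `query` (row index), `query_id`
#'   (the group_by value combination of the query row), `ap`, `n_pos`
#'   (positives in the list, M-1), `n_total` (list length, M-1+N).
#' @export
compute_ap <- function(x, instances, metric = "cosine") {
  rows <- lapply(instances, function(inst) {
    rl <- rank_list(inst, x, metric)
    tibble::tibble(
      group_id = inst$group_id,
      query = inst$query,
      ap = average_precision(rl),
      n_pos = attr(rl, "n_pos"),
      n_total = attr(rl, "n_total")
    )
  })
  out <- if (length(rows) > 0) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(group_id = character(), query = integer(),
                   ap = double(), n_pos = integer(), n_total = integer())
  }
  attr(out, "skipped") <- attr(instances, "skipped")
  out
}
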