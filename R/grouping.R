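#' Declare a block design over profile metadata
#'
#' A grouping spec turns metadata into concrete retrieval tasks. Candidate
#' query profiles (selected by `query_filter`) are partitioned into query
#' groups by the distinct value combinations of `group_by`. Within a group,
#' each member is used once as the query; another profile counts as a correct
#' match (positive) when it agrees with the query on every `pos_same` column
#' and differs on every `pos_diff` column. Reference profiles (selected by
#' `reference_filter`, e.g. negative controls) enter the query's rank list
#' when they satisfy the analogous `ref_same` / `ref_diff` constraints.
#'
#' This same/different constraint language expresses the block designs used
#' to probe technical structure: e.g. `pos_same = c("pert", "well")`,
#' `pos_diff = "plate"` restricts correct matches to same-well replicates on
#' other plates, isolating plate effects from well-position effects.
#'
#' @param group_by Metadata columns whose combinations define query groups.
#' @param pos_same,pos_diff Columns that must match / differ between query
#'   and positive. `pos_same` defaults to `group_by`.
#' @param ref_same,ref_diff Columns that must match / differ between query
#'   and an admitted reference profile.
#' @param query_filter,reference_filter Profile filters: either a named list
#'   of allowed values per metadata column (conditions combined with AND,
#'   values combined with IN), a logical vector over rows, or `NULL`
#'   (all rows). `reference_filter = NULL` admits every profile that is not
#'   the query and not a positive.
#' @return A `grouping_spec` object.
#' @export
#' @examples
#' grouping_spec(
#'   group_by = "Metadata_pert",
#'   reference_filter = list(Metadata_control = "negcon")
#' )
grouping_spec <- function(group_by, pos_same = group_by, pos_diff = NULL,
                          ref_same = NULL, ref_diff = NULL,
                          query_filter = NULL, reference_filter = NULL) {
  if (length(group_by) == 0) stop("`group_by` must name at least one column")
  if (length(intersect(pos_same, pos_diff)) > 0) {
    stop("`pos_same` and `pos_diff` overlap")
  }
  if (length(intersect(ref_same, ref_diff)) > 0) {
    stop("`ref_same` and `ref_diff` overlap")
  }
  structure(
    list(group_by = group_by, pos_same = pos_same, pos_diff = pos_diff,
         ref_same = ref_same, ref_diff = ref_diff,
         query_filter = query_filter, reference_filter = reference_filter),
    class = "grouping_spec"
  )
}

# Evaluate a filter (named list / logical / NULL) into a logical row mask.
apply_filter <- function(meta, filter) {
  n <- nrow(meta)
  if (is.null(filter)) return(rep(TRUE, n))
  if (is.logical(filter)) {
    stopifnot(length(filter) == n)
    return(filter)
  }
  if (!is.list(filter) || is.null(names(filter)) || any(names(filter) == "")) {
    stop("a filter must be a named list, a logical vector, or NULL")
  }
  missing_cols <- setdiff(names(filter), names(meta))
  if (length(missing_cols) > 0) {
    stop("filter references missing metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  keep <- rep(TRUE, n)
  for (col in names(filter)) {
    keep <- keep & (meta[[col]] %in% filter[[col]])
  }
  keep
}

check_spec_columns <- function(meta, spec) {
  named <- unique(c(spec$group_by, spec$pos_same, spec$pos_diff,
                    spec$ref_same, spec$ref_diff))
  missing_cols <- setdiff(named, names(meta))
  if (length(missing_cols) > 0) {
    stop("grouping spec references missing metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  }
}

# Rows of `meta` (restricted to `candidates`) that agree with row `query` on
# all `same` columns and differ on all `diff` columns.
match_constraints <- function(meta, candidates, query, same, diff) {
  keep <- rep(TRUE, length(candidates))
  for (col in same) {
    keep <- keep & (meta[[col]][candidates] == meta[[col]][query])
  }
  for (col in diff) {
    keep <- keep & (meta[[col]][candidates] != meta[[col]][query])
  }
  candidates[keep]
}

#' Build retrieval instances from a profile table and a grouping spec
#'
#' Enumerates, for every query group and every member profile used as the
#' query, one retrieval instance: the query row, its positive rows
#' (count M-1) and its admitted reference rows (count N). Queries with no
#' positives or no references are skipped, not fatal; skipped queries are
#' reported in the `"skipped"` attribute with a reason code, so one
#' degenerate perturbation does not abort a screen-scale run.
#'
#' @param x A [profile_table].
#' @param spec A [grouping_spec].
#' @return A list of `retrieval_instance` objects (fields `group_id`,
#'   `query`, `positives`, `references`: integer row indices), with
#'   attribute `"skipped"`: a tibble of `(group_id, query, reason)`.
#' @export
build_instances <- function(x, spec) {
  stopifnot(inherits(x, "profile_table"), inherits(spec, "grouping_spec"))
  meta <- profile_metadata(x)
  check_spec_columns(meta, spec)
  q_mask <- apply_filter(meta, spec$query_filter)
  r_mask <- apply_filter(meta, spec$reference_filter)
  q_rows <- which(q_mask)
  r_rows <- which(r_mask)
  if (length(q_rows) == 0) stop("query filter selects no profiles")
  if (length(r_rows) == 0) stop("reference filter selects no profiles")

  group_key <- interaction(meta[spec$group_by], drop = TRUE, lex.order = TRUE,
                           sep = "|")
  groups <- split(q_rows, droplevels(group_key[q_rows]))

  instances <- list()
  skipped <- list()
  for (gid in names(groups)) {
    members <- groups[[gid]]
    for (q in members) {
      positives <- match_constraints(meta, setdiff(members, q), q,
                                     spec$pos_same, spec$pos_diff)
      references <- match_constraints(meta, setdiff(r_rows, q), q,
                                      spec$ref_same, spec$ref_diff)
      references <- setdiff(references, positives)
      if (length(positives) < 1) {
        skipped[[length(skipped) + 1]] <-
          tibble::tibble(group_id = gid, query = q, reason = "no_positives")
        next
      }
      if (length(references) < 1) {
        skipped[[length(skipped) + 1]] <-
          tibble::tibble(group_id = gid, query = q, reason = "no_references")
        next
      }
      instances[[length(instances) + 1]] <- structure(
        list(group_id = gid, query = q, positives = positives,
             references = references),
        class = "retrieval_instance"
      )
    }
  }
  skipped <- if (length(skipped) > 0) {
    dplyr::bind_rows(skipped)
  } else {
    tibble::tibble(group_id = character(), query = integer(),
                   reason = character())
  }
  structure(instances, skipped = skipped)
}

#' Skipped queries of an instance set or task result
#'
#' @param x The return value of [build_instances()] or of one of the
#'   assessment functions.
#' @return A tibble of skipped queries/groups with reason codes.
#' @export
skipped_groups <- function(x) {
  attr(x, "skipped") %||% tibble::tibble()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
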