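map_result <- function(ap_scores, results, task, params) {
  structure(
    list(ap_scores = ap_scores, results = results, task = task,
         params = params),
    skipped = attr(ap_scores, "skipped"),
    class = "map_result"
  )
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf("<map_result: %s> %d group(s), %d quer%s\n",
              x$task, nrow(x$results), nrow(x$ap_scores),
              if (nrow(x$ap_scores) == 1) "y" else "ies"))
  print(x$results)
  cat(sprintf("percent retrieved: %.1f%% (alpha = %g)\n",
              percent_retrieved(x$results), x$params$alpha))
  invisible(x)
}

run_map_task <- function(x, spec, task, metric, n_perm, alpha, seed,
                         max_exact = 10000) {
  instances <- build_instances(x, spec)
  if (length(instances) == 0) {
    stop("no usable retrieval instances (all groups skipped)")
  }
  ap <- compute_ap(x, instances, metric)
  res <- group_significance(ap, n_perm = n_perm, seed = seed, alpha = alpha,
                            max_exact = max_exact)
  map_result(ap, res, task,
             list(metric = metric, n_perm = n_perm, alpha = alpha,
                  seed = seed))
}

#' Phenotypic activity: replicate retrievability against controls
#'
#' For each perturbation, its replicate profiles form the query group and the
#' control profiles the reference group; the group's mAP measures how
#' reliably a replicate retrieves its siblings ahead of controls, and the
#' permutation p-value says whether that retrievability exceeds chance.
#' Perturbations with fewer than 2 replicates are skipped and reported.
#'
#' @param x A [profile_table] of replicate-level profiles.
#' @param pert_column Metadata column holding the perturbation identity.
#' @param control_filter Filter selecting control rows (named list of
#'   column = allowed values, or logical vector); these become the reference
#'   group and are excluded from the queries.
#' @param metric Distance metric, see [profile_distance()].
#' @param n_perm Permutations for the mAP null.
#' @param alpha Significance level on BH-corrected p-values.
#' @param seed Optional seed.
#' @return A `map_result`: `$ap_scores` (per-query AP tibble), `$results`
#'   (per-perturbation mAP, p, q, retrieved).
#' @export
#' @examples
#' pt <- make_fixture("toy_screen", seed = 1)
#' res <- phenotypic_activity(pt, "Metadata_pert",
#'                            list(Metadata_control = "negcon"),
#'                            n_perm = 1000, seed = 1)
#' res$results
phenotypic_activity <- function(x, pert_column, control_filter,
                                metric = "cosine", n_perm = 10000,
                                alpha = 0.05, seed = NULL) {
  is_control <- apply_filter(profile_metadata(x), control_filter)
  if (!any(is_control)) stop("no control profiles match the filter")
  spec <- grouping_spec(
    group_by = pert_column,
    pos_same = pert_column,
    query_filter = !is_control,
    reference_filter = is_control
  )
  run_map_task(x, spec, "phenotypic_activity", metric, n_perm, alpha, seed)
}

#' Phenotypic consistency: retrieving shared annotations
#'
#' Operates on consensus profiles (one per perturbation; see
#' [consensus_profiles()]). For each annotation label, the perturbations
#' carrying it form the query group, and perturbations carrying other labels
#' are the references; high mAP means the label's members are more similar
#' to one another than to the rest of the screen. Labels with a single
#' member are skipped and reported.
#'
#' @param x A [profile_table] of consensus profiles.
#' @param label_column Metadata column holding the annotation (e.g. mechanism
#'   of action, target gene).
#' @inheritParams phenotypic_activity
#' @return A `map_result` with one row per label group.
#' @export
phenotypic_consistency <- function(x, label_column, metric = "cosine",
                                   n_perm = 10000, alpha = 0.05,
                                   seed = NULL) {
  spec <- grouping_spec(
    group_by = label_column,
    pos_same = label_column,
    ref_diff = label_column
  )
  run_map_task(x, spec, "phenotypic_consistency", metric, n_perm, alpha, seed)
}

#' Phenotypic distinctiveness: retrieval against all other perturbations
#'
#' Measures how distinguishable a perturbation is from the other
#' perturbations in the experiment (rather than from negative controls):
#' positives are the perturbation's own replicates, references are the
#' replicates of every other perturbation. Controls are excluded by default.
#'
#' @param x A [profile_table] of replicate-level profiles.
#' @param pert_column Metadata column holding the perturbation identity.
#' @param control_filter Optional filter marking control rows to exclude.
#' @param include_controls If `TRUE`, control rows stay in the reference
#'   pool.
#' @inheritParams phenotypic_activity
#' @return A `map_result` with one row per perturbation.
#' @export
phenotypic_distinctiveness <- function(x, pert_column, control_filter = NULL,
                                       include_controls = FALSE,
                                       metric = "cosine", n_perm = 10000,
                                       alpha = 0.05, seed = NULL) {
  meta <- profile_metadata(x)
  is_control <- if (is.null(control_filter)) {
    rep(FALSE, nrow(meta))
  } else {
    apply_filter(meta, control_filter)
  }
  keep <- !is_control
  if (sum(keep) < 4) stop("need at least 2 perturbations with replicates")
  if (length(unique(meta[[pert_column]][keep])) < 2) {
    stop("fewer than 2 perturbations")
  }
  spec <- grouping_spec(
    group_by = pert_column,
    pos_same = pert_column,
    ref_diff = pert_column,
    query_filter = keep,
    reference_filter = if (include_controls) NULL else keep
  )
  run_map_task(x, spec, "phenotypic_distinctiveness", metric, n_perm, alpha,
               seed)
}

#' Per-label AP matrix for multiply-annotated perturbations
#'
#' A perturbation may carry several annotation labels (several targets,
#' several mechanisms). AP is computed one label at a time: for each label
#' and each annotated perturbation, positives are the label's other members
#' and references are all perturbations *not* annotated with that label
#' (perturbations sharing a different label with the query still count as
#' references). The result is a sparse matrix of AP values in long form,
#' whose sparsity pattern equals the annotation incidence; labels with one
#' member contribute no entries and are reported as skipped.
#'
#' @param x A [profile_table] of consensus profiles, one row per
#'   perturbation.
#' @param annotations Long-format data frame with columns `perturbation` and
#'   `label` (multiple rows per perturbation allowed).
#' @param pert_column Metadata column in `x` matching
#'   `annotations$perturbation`.
#' @param metric Distance metric, see [profile_distance()].
#' @return A tibble of class `multilabel_ap` with columns `perturbation`,
#'   `label`, `ap`, `n_pos`, `n_total`; attribute `"skipped"` lists omitted
#'   labels.
#' @export
multilabel_map <- function(x, annotations, pert_column, metric = "cosine") {
  stopifnot(inherits(x, "profile_table"),
            all(c("perturbation", "label") %in% names(annotations)))
  meta <- profile_metadata(x)
  perts <- meta[[pert_column]]
  if (anyDuplicated(perts) > 0) {
    stop("expected consensus profiles: one row per perturbation")
  }
  unknown <- setdiff(unique(annotations$perturbation), perts)
  if (length(unknown) > 0) {
    stop("annotated perturbation(s) without a profile: ",
         paste(unknown, collapse = ", "))
  }
  mat <- feature_matrix(x)
  rows <- list()
  skipped <- list()
  for (lab in sort(unique(annotations$label))) {
    members <- unique(annotations$perturbation[annotations$label == lab])
    member_rows <- match(members, perts)
    if (length(member_rows) < 2) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(group_id = lab, query = NA_integer_,
                       reason = "single_member_label")
      next
    }
    reference_rows <- which(!perts %in% members)
    if (length(reference_rows) < 1) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(group_id = lab, query = NA_integer_,
                       reason = "no_references")
      next
    }
    for (q in member_rows) {
      positives <- setdiff(member_rows, q)
      candidates <- c(positives, reference_rows)
      d <- query_distances(mat[q, ], mat[candidates, , drop = FALSE], metric)
      ord <- order(d, candidates)
      relevance <- as.integer(candidates[ord] %in% positives)
      rows[[length(rows) + 1]] <- tibble::tibble(
        perturbation = perts[q], label = lab,
        ap = average_precision(relevance),
        n_pos = length(positives),
        n_total = length(candidates)
      )
    }
  }
  if (length(rows) == 0) stop("no label has at least 2 annotated members")
  out <- dplyr::bind_rows(rows)
  skipped <- if (length(skipped) > 0) {
    dplyr::bind_rows(skipped)
  } else {
    tibble::tibble(group_id = character(), query = integer(),
                   reason = character())
  }
  structure(out, skipped = skipped,
            class = c("multilabel_ap", class(out)))
}

#' Aggregate a multi-label AP matrix
#'
#' Means are taken over the entries that are present; an absent
#' (perturbation, label) pair is missing, not zero, so unannotated pairs do
#' not drag the mean down.
#'
#' @param m A `multilabel_ap` tibble from [multilabel_map()].
#' @param axis `"per_label"` (consistency of each annotation group) or
#'   `"per_perturbation"`.
#' @return A tibble with the grouping column and `mAP`, plus `n_entries`.
#' @export
aggregate_multilabel <- function(m, axis = c("per_label",
                                             "per_perturbation")) {
  axis <- match.arg(axis)
  if (nrow(m) == 0) stop("empty AP matrix")
  key <- if (axis == "per_label") "label" else "perturbation"
  out <- dplyr::summarise(
    dplyr::group_by(m, dplyr::across(dplyr::all_of(key))),
    mAP = mean(ap), n_entries = dplyr::n(), .groups = "drop"
  )
  out[order(out[[key]]), ]
}
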