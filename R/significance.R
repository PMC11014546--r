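# Cache of exact AP null enumerations; these depend only on (n_pos, n_total),
# and a screen reuses the same handful of list shapes thousands of times.
.null_cache <- new.env(parent = emptyenv())

#' Clear the cached exact AP null distributions
#' @return Invisibly, the number of entries removed.
#' @export
clear_null_cache <- function() {
  n <- length(ls(.null_cache))
  rm(list = ls(.null_cache), envir = .null_cache)
  invisible(n)
}

# AP for each column of a matrix of sorted positive positions.
ap_from_positions <- function(pos) {
  if (!is.matrix(pos)) pos <- matrix(pos, ncol = 1)
  colMeans(seq_len(nrow(pos)) / pos)
}

#' Null distribution of AP under label exchangeability
#'
#' Under the null hypothesis that query and reference profiles are drawn from
#' one distribution, every arrangement of the `n_pos` positives among the
#' `n_total` ranks is equally likely, so the AP null depends only on
#' (`n_pos`, `n_total`) and has exact size `choose(n_total, n_pos)`. Mode
#' `"exact"` enumerates every arrangement; `"monte_carlo"` samples uniformly
#' random binary lists; `"auto"` (default) enumerates when
#' `choose(n_total, n_pos) <= max_exact` and samples otherwise.
#'
#' @param n_pos Number of positives in the list (M-1).
#' @param n_total List length (M-1+N).
#' @param mode `"auto"`, `"exact"`, or `"monte_carlo"`.
#' @param n_samples Monte-Carlo sample size.
#' @param seed Optional seed for Monte-Carlo sampling.
#' @param max_exact Enumeration cap on `choose(n_total, n_pos)`.
#' @return A `map_null` object: list with `n_pos`, `n_total`, `mode`,
#'   `values` (AP support or samples), and, for exact mode, `probs`.
#' @export
#' @examples
#' null_ap(1, 3, mode = "exact") # support {1, 1/2, 1/3}, uniform
null_ap <- function(n_pos, n_total, mode = c("auto", "exact", "monte_carlo"),
                    n_samples = 10000, seed = NULL, max_exact = 10000) {
  mode <- match.arg(mode)
  stopifnot(n_pos >= 1, n_total >= 2)
  if (n_pos >= n_total) {
    stop("need at least one negative: n_pos < n_total required")
  }
  n_config <- choose(n_total, n_pos)
  if (mode == "auto") {
    mode <- if (n_config <= max_exact) "exact" else "monte_carlo"
  }
  if (mode == "exact") {
    if (n_config > max_exact) {
      stop(sprintf("exact enumeration of %g configurations exceeds cap %g",
                   n_config, max_exact))
    }
    key <- paste0("e", n_pos, "_", n_total)
    if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
    pos <- utils::combn(n_total, n_pos) # columns already sorted ascending
    ap <- ap_from_positions(pos)
    support <- sort(unique(ap))
    probs <- tabulate(match(ap, support), nbins = length(support)) / length(ap)
    out <- structure(
      list(n_pos = n_pos, n_total = n_total, mode = "exact",
           values = support, probs = probs, n_config = n_config),
      class = "map_null"
    )
    .null_cache[[key]] <- out
    return(out)
  }
  draw <- function() {
    ap <- vapply(seq_len(n_samples), function(i) {
      mean(seq_len(n_pos) / sort.int(sample.int(n_total, n_pos)))
    }, double(1))
    structure(
      list(n_pos = n_pos, n_total = n_total, mode = "monte_carlo",
           values = ap, n_samples = n_samples, seed = seed),
      class = "map_null"
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.map_null <- function(x, ...) {
  cat(sprintf("<map_null> n_pos=%d n_total=%d mode=%s (%s)\n",
              x$n_pos, x$n_total, x$mode,
              if (x$mode == "exact") {
                sprintf("support %d of %g configs", length(x$values),
                        x$n_config)
              } else {
                sprintf("%d samples", x$n_samples)
              }))
  invisible(x)
}

#' Draw AP values from a null distribution
#'
#' @param null A `map_null` object.
#' @param n Number of draws.
#' @return Numeric vector of `n` AP values. Exact nulls are sampled from
#'   their enumerated support with the enumerated probabilities; Monte-Carlo
#'   nulls are resampled with replacement.
#' @export
sample_null_ap <- function(null, n) {
  stopifnot(inherits(null, "map_null"))
  if (null$mode == "exact") {
    sample(null$values, n, replace = TRUE, prob = null$probs)
  } else {
    sample(null$values, n, replace = TRUE)
  }
}

#' Mean of an AP null distribution
#' @param null A `map_null` object.
#' @return The null expectation of AP.
#' @export
null_ap_mean <- function(null) {
  stopifnot(inherits(null, "map_null"))
  if (null$mode == "exact") sum(null$values * null$probs) else mean(null$values)
}

#' Permutation p-value for an observed mAP
#'
#' The null for a group mAP is built by drawing, per permutation, one AP per
#' query from that query's rank-list null and averaging, mirroring the
#' rank-list-reshuffling construction. With a single query and an exact null,
#' the p-value is the exact tail probability P(AP >= observed); otherwise it
#' is the add-one smoothed permutation estimate
#' (1 + #\{null mAP >= observed\}) / (1 + n_perm), which is never zero and is
#' a valid permutation p-value.
#'
#' @param observed Observed mAP.
#' @param nulls A single `map_null` or a list of them, one per query in the
#'   group (queries may have different list shapes).
#' @param n_perm Number of permutations for the Monte-Carlo construction.
#' @param seed Optional seed.
#' @return p-value in (0, 1].
#' @export
map_p_value <- function(observed, nulls, n_perm = 10000, seed = NULL) {
  if (inherits(nulls, "map_null")) nulls <- list(nulls)
  stopifnot(length(nulls) >= 1,
            all(vapply(nulls, inherits, logical(1), "map_null")))
  if (length(nulls) == 1 && nulls[[1]]$mode == "exact") {
    null <- nulls[[1]]
    return(sum(null$probs[null$values >= observed - 1e-12]))
  }
  compute <- function() {
    null_map <- rowMeans(
      vapply(nulls, sample_null_ap, double(n_perm), n = n_perm)
    )
    (1 + sum(null_map >= observed - 1e-12)) / (1 + n_perm)
  }
  if (is.null(seed)) compute() else withr::with_seed(seed, compute())
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control across the groups of a screen.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as `p`; elementwise `q >= p`.
#' @export
#' @examples
#' bh_fdr(c(0.005, 0.01, 0.03, 0.04)) # 0.02 0.02 0.04 0.04
bh_fdr <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Percent retrieved
#'
#' The percentage of groups whose FDR-corrected mAP p-value falls below
#' `alpha` — the screen-level summary of how many perturbations (or
#' annotation groups) are confidently retrievable.
#'
#' @param results A tibble with a logical `retrieved` column (as returned by
#'   the assessment functions) or a `q_value` column, or a bare logical /
#'   p-value-like numeric vector.
#' @param alpha Significance level applied to corrected p-values when
#'   `retrieved` is not already present.
#' @return Percentage in \[0, 100\].
#' @export
percent_retrieved <- function(results, alpha = 0.05) {
  retrieved <- if (is.data.frame(results)) {
    if ("retrieved" %in% names(results)) {
      results$retrieved
    } else if ("q_value" %in% names(results)) {
      results$q_value < alpha
    } else {
      stop("results need a `retrieved` or `q_value` column")
    }
  } else if (is.logical(results)) {
    results
  } else {
    results < alpha
  }
  if (length(retrieved) == 0) stop("empty results")
  100 * mean(retrieved)
}

#' Group-level significance from per-query AP scores
#'
#' Aggregates a per-query AP table (from [compute_ap()]) into one row per
#' group: mAP, permutation p-value, BH q-value across groups, and the
#' retrieved flag at `alpha`. Groups sharing an identical multiset of
#' per-query list shapes reuse one seeded null-mAP sample, which is what
#' makes screen-scale runs cheap.
#'
#' @param ap_scores Tibble with columns `group_id`, `ap`, `n_pos`, `n_total`.
#' @param n_perm Permutations for the mAP null.
#' @param seed Optional seed controlling all Monte-Carlo draws.
#' @param alpha Significance level for the retrieved call.
#' @param max_exact Enumeration cap passed to [null_ap()].
#' @return A tibble with columns `group_id`, `mAP`, `p_value`, `q_value`,
#'   `retrieved`, `n_queries`, `n_pos`, `n_total`.
#' @export
group_significance <- function(ap_scores, n_perm = 10000, seed = NULL,
                               alpha = 0.05, max_exact = 10000) {
  stopifnot(all(c("group_id", "ap", "n_pos", "n_total") %in% names(ap_scores)))
  if (nrow(ap_scores) == 0) stop("no AP scores")
  run <- function() {
    groups <- split(ap_scores, ap_scores$group_id)
    groups <- groups[order(names(groups))]
    null_map_samples <- list() # keyed by the group's multiset of shapes
    rows <- lapply(names(groups), function(gid) {
      g <- groups[[gid]]
      obs <- mean(g$ap)
      shapes <- sprintf("%d/%d", g$n_pos, g$n_total)
      if (nrow(g) == 1 && choose(g$n_total, g$n_pos) <= max_exact) {
        null <- null_ap(g$n_pos, g$n_total, mode = "exact",
                        max_exact = max_exact)
        p <- sum(null$probs[null$values >= obs - 1e-12])
      } else {
        key <- paste(sort(shapes), collapse = ";")
        if (is.null(null_map_samples[[key]])) {
          nulls <- lapply(seq_len(nrow(g)), function(i) {
            null_ap(g$n_pos[i], g$n_total[i], mode = "auto",
                    n_samples = n_perm, max_exact = max_exact)
          })
          null_map_samples[[key]] <<- rowMeans(
            vapply(nulls, sample_null_ap, double(n_perm), n = n_perm)
          )
        }
        nm <- null_map_samples[[key]]
        p <- (1 + sum(nm >= obs - 1e-12)) / (1 + n_perm)
      }
      tibble::tibble(
        group_id = gid, mAP = obs, p_value = p,
        n_queries = nrow(g),
        n_pos = g$n_pos[1], n_total = g$n_total[1]
      )
    })
    out <- dplyr::bind_rows(rows)
    out$q_value <- bh_fdr(out$p_value)
    out$retrieved <- out$q_value < alpha
    out[c("group_id", "mAP", "p_value", "q_value", "retrieved",
          "n_queries", "n_pos", "n_total")]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
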