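#' Configuration for one simulated screening condition
#'
#' The generator emulates the simplest screening situation: control profiles
#' whose features are i.i.d. draws from the null family (standard normal by
#' default), and perturbation replicates in which a fraction
#' `frac_perturbed` of the features is location-shifted by `shift` (default
#' 1, i.e. N(1, 1) against N(0, 1)) while the rest stay null. The perturbed
#' features are the first `round(frac_perturbed * n_features)` columns;
#' features are i.i.d., so the choice of indices is immaterial and a
#' deterministic choice aids debugging. A heavy-tailed variant draws from a
#' location-shifted Cauchy instead.
#'
#' @param n_features Number of features d.
#' @param frac_perturbed Fraction f of features that are shifted in
#'   perturbation replicates (0 gives a pure-null condition).
#' @param n_replicates Replicates per perturbation (M, at least 2).
#' @param n_controls Control replicates per perturbation (N).
#' @param n_perturbations Independent perturbation instances per condition.
#' @param null_family `"normal"` or `"cauchy"`.
#' @param shift Location shift of perturbed features.
#' @param scale Scale of both families.
#' @param share_controls If `TRUE`, one control matrix is drawn per condition
#'   and shared across perturbations (screen-realistic correlation); by
#'   default fresh controls are drawn per perturbation.
#' @param seed Optional seed making the condition fully reproducible.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_features = 100, frac_perturbed = 0,
                              n_replicates = 2, n_controls = 12,
                              n_perturbations = 100,
                              null_family = c("normal", "cauchy"),
                              shift = 1, scale = 1,
                              share_controls = FALSE, seed = NULL) {
  null_family <- match.arg(null_family)
  stopifnot(n_features >= 1, frac_perturbed >= 0, frac_perturbed <= 1,
            n_replicates >= 2, n_controls >= 1, n_perturbations >= 1,
            scale > 0)
  structure(
    list(n_features = as.integer(n_features),
         frac_perturbed = frac_perturbed,
         n_replicates = as.integer(n_replicates),
         n_controls = as.integer(n_controls),
         n_perturbations = as.integer(n_perturbations),
         null_family = null_family, shift = shift, scale = scale,
         share_controls = share_controls, seed = seed),
    class = "simulation_config"
  )
}

rand_null <- function(n, family, scale) {
  switch(family,
    normal = stats::rnorm(n, 0, scale),
    cauchy = stats::rcauchy(n, 0, scale)
  )
}

#' Simulate perturbation and control profiles for one condition
#'
#' @param config A [simulation_config].
#' @return A list of `n_perturbations` elements, each a list with
#'   `perturbation` (M x d matrix) and `controls` (N x d matrix). The number
#'   of shifted features is `round(frac_perturbed * n_features)`.
#' @export
simulate_condition <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  d <- config$n_features
  n_shift <- round(config$frac_perturbed * d)
  run <- function() {
    shared <- if (config$share_controls) {
      matrix(rand_null(config$n_controls * d, config$null_family,
                       config$scale),
             config$n_controls, d)
    }
    lapply(seq_len(config$n_perturbations), function(i) {
      pert <- matrix(rand_null(config$n_replicates * d, config$null_family,
                               config$scale),
                     config$n_replicates, d)
      if (n_shift > 0) {
        pert[, seq_len(n_shift)] <- pert[, seq_len(n_shift)] + config$shift
      }
      ctrl <- if (config$share_controls) {
        shared
      } else {
        matrix(rand_null(config$n_controls * d, config$null_family,
                         config$scale),
               config$n_controls, d)
      }
      list(perturbation = pert, controls = ctrl)
    })
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

# mAP and per-perturbation permutation p-values for a simulated condition.
# All perturbations in a condition share the rank-list shape
# (n_pos = M - 1, n_total = M - 1 + N), so one seeded null-mAP sample serves
# the whole condition. Assumes the RNG state is already set by the caller.
map_condition_pvalues <- function(instances, metric = "cosine",
                                  n_perm = 10000) {
  m <- nrow(instances[[1]]$perturbation)
  n <- nrow(instances[[1]]$controls)
  nulls <- lapply(seq_len(m), function(i) {
    null_ap(m - 1, m - 1 + n, mode = "auto", n_samples = n_perm)
  })
  null_map <- rowMeans(vapply(nulls, sample_null_ap, double(n_perm),
                              n = n_perm))
  res <- vapply(instances, function(inst) {
    ap <- instance_ap_scores(inst$perturbation, inst$controls, metric)
    obs <- mean(ap)
    p <- (1 + sum(null_map >= obs - 1e-12)) / (1 + n_perm)
    c(obs, p)
  }, double(2))
  tibble::tibble(mAP = res[1, ], p_value = res[2, ])
}

# Per-replicate AP for one perturbation (rows of `reps` as queries) against
# `ctrls`, using fast matrix products for the cosine metric.
instance_ap_scores <- function(reps, ctrls, metric = "cosine") {
  m <- nrow(reps)
  n <- nrow(ctrls)
  if (metric == "cosine") {
    rn <- reps / sqrt(rowSums(reps^2))
    cn <- ctrls / sqrt(rowSums(ctrls^2))
    s_rr <- tcrossprod(rn)
    s_rc <- tcrossprod(rn, cn)
    vapply(seq_len(m), function(i) {
      d <- c(1 - s_rr[i, -i], 1 - s_rc[i, ])
      idx <- c(seq_len(m)[-i], m + seq_len(n))
      ord <- order(d, idx)
      relevance <- as.integer(ord <= m - 1)
      average_precision(relevance)
    }, double(1))
  } else {
    vapply(seq_len(m), function(i) {
      candidates <- rbind(reps[-i, , drop = FALSE], ctrls)
      d <- query_distances(reps[i, ], candidates, metric)
      ord <- order(d, seq_len(m - 1 + n))
      relevance <- as.integer(ord <= m - 1)
      average_precision(relevance)
    }, double(1))
  }
}

#' Build the simulation grid
#'
#' Expands the factor levels into one [simulation_config] per cell. The
#' defaults reproduce the benchmark design: features in
#' \{100, 200, 500, 1000, 2500, 5000\}, perturbed fraction on a binary
#' exponential scale from 1% to 64%, 2-4 replicates, and 12/24/36 controls
#' (378 cells).
#'
#' @param n_features,frac_perturbed,n_replicates,n_controls Factor levels.
#' @param ... Passed to [simulation_config()] (e.g. `null_family`, `shift`,
#'   `n_perturbations`).
#' @return A list of `simulation_config` objects.
#' @export
benchmark_grid <- function(n_features = c(100, 200, 500, 1000, 2500, 5000),
                           frac_perturbed = c(0.01, 0.02, 0.04, 0.08, 0.16,
                                              0.32, 0.64),
                           n_replicates = c(2, 3, 4),
                           n_controls = c(12, 24, 36), ...) {
  cells <- expand.grid(n_features = n_features,
                       frac_perturbed = frac_perturbed,
                       n_replicates = n_replicates,
                       n_controls = n_controls,
                       KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cells)), function(i) {
    simulation_config(n_features = cells$n_features[i],
                      frac_perturbed = cells$frac_perturbed[i],
                      n_replicates = cells$n_replicates[i],
                      n_controls = cells$n_controls[i], ...)
  })
}

#' Benchmark retrieval methods on simulated conditions
#'
#' For every grid cell, generates `n_perturbations` independent
#' perturbation/control instances and applies each requested method to the
#' same data. Recall is the fraction of perturbations with raw p-value below
#' `alpha` (for k-means, the fraction with exact cluster separation);
#' `corrected = TRUE` switches to BH-corrected p-values within each cell.
#' A method failing on a cell is logged as a warning and its row omitted.
#'
#' @param grid A list of [simulation_config] objects (see
#'   [benchmark_grid()]).
#' @param methods Subset of `"map"`, `"mp_value"`, `"mmd"`, `"kmeans"`.
#' @param seed Seed; each cell derives a child seed from it, so adding cells
#'   or methods never perturbs other cells' draws.
#' @param n_perm_map Permutations for the mAP null.
#' @param n_perm_baseline Permutations for mp-value and MMD.
#' @param alpha Detection threshold on (raw) p-values.
#' @param corrected Use BH-corrected p-values for recall.
#' @param metric Distance metric for the mAP method.
#' @return A tibble, one row per (cell, method), with the condition
#'   parameters and `recall`.
#' @export
run_benchmark <- function(grid, methods = c("map", "mp_value", "mmd",
                                            "kmeans"),
                          seed = 1, n_perm_map = 10000,
                          n_perm_baseline = 1000, alpha = 0.05,
                          corrected = FALSE, metric = "cosine") {
  if (length(grid) == 0) stop("empty grid")
  if (inherits(grid, "simulation_config")) grid <- list(grid)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (i in seq_along(grid)) {
    config <- grid[[i]]
    cell_seed <- (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
    config$seed <- NULL
    cell <- withr::with_seed(cell_seed, {
      instances <- simulate_condition(config)
      lapply(methods, function(method) {
        recall <- tryCatch({
          if (method == "map") {
            pv <- map_condition_pvalues(instances, metric, n_perm_map)
            p <- pv$p_value
            mean((if (corrected) bh_fdr(p) else p) < alpha)
          } else if (method == "kmeans") {
            mean(vapply(instances, function(inst) {
              kmeans_separation(inst$perturbation, inst$controls)$detected
            }, logical(1)))
          } else {
            fn <- if (method == "mp_value") mp_value else mmd_test
            p <- vapply(instances, function(inst) {
              fn(inst$perturbation, inst$controls,
                 n_perm = n_perm_baseline)$p_value
            }, double(1))
            mean((if (corrected) bh_fdr(p) else p) < alpha)
          }
        }, error = function(e) {
          warning(sprintf("method %s failed on cell %d: %s", method, i,
                          conditionMessage(e)), call. = FALSE)
          NA_real_
        })
        if (is.na(recall)) return(NULL)
        tibble::tibble(
          n_features = config$n_features,
          frac_perturbed = config$frac_perturbed,
          n_replicates = config$n_replicates,
          n_controls = config$n_controls,
          null_family = config$null_family,
          shift = config$shift, scale = config$scale,
          method = method, recall = recall,
          n_perturbations = config$n_perturbations,
          seed = cell_seed
        )
      })
    })
    rows <- c(rows, cell)
  }
  dplyr::bind_rows(rows)
}

#' Tidy recall table keyed by condition and method
#'
#' Validates that each (condition, method) key appears once and returns the
#' long-format table ready for plotting recall curves.
#'
#' @param rows Output of [run_benchmark()].
#' @return The validated tibble, sorted by condition and method.
#' @export
recall_table <- function(rows) {
  if (nrow(rows) == 0) stop("empty benchmark result")
  keys <- c("n_features", "frac_perturbed", "n_replicates", "n_controls",
            "null_family", "shift", "scale", "method")
  stopifnot(all(keys %in% names(rows)))
  key <- do.call(paste, c(rows[keys], sep = "\r"))
  if (anyDuplicated(key) > 0) stop("duplicate (condition, method) keys")
  rows[order(key), ]
}
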