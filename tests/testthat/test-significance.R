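test_that("exact null for one positive among three is uniform on {1, 1/2, 1/3}", {
  null <- null_ap(1, 3, mode = "exact")
  expect_equal(sort(null$values), c(1 / 3, 1 / 2, 1))
  expect_equal(null$probs, rep(1 / 3, 3))
  expect_equal(null$n_config, choose(3, 1))
  expect_equal(sum(null$probs), 1, tolerance = 1e-12)
})

test_that("exact enumeration respects its preconditions and cap", {
  expect_error(null_ap(2, 2), "negative")
  expect_error(null_ap(10, 30, mode = "exact", max_exact = 1000), "cap")
  # probabilities always sum to one and the support stays in (0, 1]
  for (shape in list(c(2, 6), c(3, 9), c(4, 10))) {
    null <- null_ap(shape[1], shape[2], mode = "exact")
    expect_equal(sum(null$probs), 1, tolerance = 1e-12)
    expect_true(all(null$values > 0 & null$values <= 1))
  }
})

test_that("monte-carlo null matches the enumerated distribution", {
  null_e <- null_ap(2, 4, mode = "exact")
  null_mc <- null_ap(2, 4, mode = "monte_carlo", n_samples = 1e5, seed = 7)
  se <- sd(null_mc$values) / sqrt(1e5)
  expect_lt(abs(mean(null_mc$values) - null_ap_mean(null_e)), 3 * se)
  # KS distance between the empirical and enumerated CDFs
  cdf <- cumsum(null_e$probs)
  ecdf_at <- vapply(null_e$values,
                    function(v) mean(null_mc$values <= v + 1e-12), double(1))
  expect_lt(max(abs(ecdf_at - cdf)), 0.01)
})

test_that("single-query p-values are exact tail probabilities", {
  null <- null_ap(1, 3, mode = "exact")
  expect_equal(map_p_value(1, null), 1 / 3)
  expect_equal(map_p_value(1 / 2, null), 2 / 3)
  expect_equal(map_p_value(0.1, null), 1)
})

test_that("monte-carlo p-values are smoothed and bounded by the resolution", {
  nulls <- replicate(2, null_ap(1, 3, mode = "exact"), simplify = FALSE)
  # observed below the entire null: maximal p = 1
  expect_equal(map_p_value(0.01, nulls, n_perm = 500, seed = 1), 1)
  # observed above the entire null: p equals the resolution bound
  expect_equal(map_p_value(1.5, nulls, n_perm = 500, seed = 1), 1 / 501)
  p <- map_p_value(0.9, nulls, n_perm = 500, seed = 1)
  expect_gte(p, 1 / 501)
  expect_lte(p, 1)
})

test_that("mAP p-values are calibrated when rank lists are truly exchangeable", {
  # 500 groups of 3 queries; each query's list drawn uniformly at random,
  # exactly the exchangeability model the null construction assumes
  n_pos <- 2
  n_total <- 14
  null <- null_ap(n_pos, n_total, mode = "exact")
  p <- withr::with_seed(13, {
    vapply(1:500, function(i) {
      ap <- vapply(1:3, function(q) {
        mean(seq_len(n_pos) / sort(sample.int(n_total, n_pos)))
      }, double(1))
      map_p_value(mean(ap), replicate(3, null, simplify = FALSE),
                  n_perm = 2000)
    }, double(1))
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 2.576 * sqrt(0.05 * 0.95 / 500) + 0.005)
})

test_that("p-values are invariant to monotone transforms of the distance", {
  pt <- toy_table(n_pert = 3, n_rep = 3, n_ctrl = 8, d = 6, seed = 21)
  spec <- grouping_spec(group_by = "Metadata_pert",
                        query_filter = list(Metadata_control = "trt"),
                        reference_filter = list(Metadata_control = "negcon"))
  inst <- build_instances(pt, spec)
  ap1 <- compute_ap(pt, inst, "cosine")
  # squared half-cosine-distance is strictly monotone in cosine distance,
  # so every rank list, AP, and p-value must be unchanged
  rl_ap <- vapply(inst, function(i) {
    mat <- feature_matrix(pt)
    cand <- c(i$positives, i$references)
    d <- mapeval:::query_distances(mat[i$query, ],
                                   mat[cand, , drop = FALSE], "cosine")
    d2 <- (d / 2)^2
    ord <- order(d2, cand)
    average_precision(as.integer(cand[ord] %in% i$positives))
  }, double(1))
  expect_equal(ap1$ap, rl_ap, tolerance = 1e-12)
  r1 <- group_significance(ap1, n_perm = 1000, seed = 5)
  ap2 <- ap1
  ap2$ap <- rl_ap
  r2 <- group_significance(ap2, n_perm = 1000, seed = 5)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("BH q-values match the hand-computed step-up and reference", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  withr::with_seed(31, {
    for (i in 1:100) {
      p <- runif(sample(1:40, 1))
      q <- bh_fdr(p)
      expect_equal(q, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(q >= p))
    }
  })
})

test_that("percent retrieved summarizes corrected significance", {
  res <- tibble::tibble(q_value = c(0.01, 0.2, 0.03, 0.04))
  expect_equal(percent_retrieved(res), 75)
  expect_equal(percent_retrieved(tibble::tibble(retrieved = rep(FALSE, 3))),
               0)
  expect_equal(percent_retrieved(tibble::tibble(retrieved = rep(TRUE, 4))),
               100)
  expect_error(percent_retrieved(tibble::tibble(q_value = double(0))),
               "empty")
})

test_that("group significance aggregates, corrects, and flags retrieval", {
  pt <- toy_table(n_pert = 4, n_rep = 3, n_ctrl = 10, d = 40,
                  active = 1:2, shift = 8, seed = 17)
  spec <- grouping_spec(group_by = "Metadata_pert",
                        query_filter = list(Metadata_control = "trt"),
                        reference_filter = list(Metadata_control = "negcon"))
  ap <- compute_ap(pt, build_instances(pt, spec))
  res <- group_significance(ap, n_perm = 2000, seed = 3)
  expect_equal(nrow(res), 4)
  expect_true(all(res$q_value >= res$p_value))
  expect_identical(res$retrieved, res$q_value < 0.05)
  expect_equal(res$mAP,
               vapply(split(ap$ap, ap$group_id), mean, double(1))[res$group_id],
               ignore_attr = TRUE)
  expect_true(all(res$retrieved[1:2]))
  # identical call is deterministic under the same seed
  res2 <- group_significance(ap, n_perm = 2000, seed = 3)
  expect_identical(res, res2)
})
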