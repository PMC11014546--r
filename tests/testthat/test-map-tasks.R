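test_that("identical replicates orthogonal to controls give activity mAP 1", {
  d <- 14
  reps <- rbind(diag(d)[1, ], diag(d)[1, ])
  ctrl <- diag(d)[2:13, ]
  pt <- table_from_matrix(
    rbind(reps, ctrl), c("g1", "g1", rep("control", 12)),
    extra = data.frame(Metadata_control = c("trt", "trt", rep("negcon", 12)))
  )
  res <- phenotypic_activity(pt, "Metadata_pert",
                             list(Metadata_control = "negcon"),
                             n_perm = 1000, seed = 1)
  expect_equal(res$results$mAP, 1)
  expect_equal(res$results$n_pos, 1L)
  expect_equal(res$results$n_total, 13L)
})

test_that("a toy screen separates active from inactive perturbations", {
  pt <- make_fixture("toy_screen", seed = 1)
  res <- phenotypic_activity(pt, "Metadata_pert",
                             list(Metadata_control = "negcon"),
                             n_perm = 5000, seed = 2)
  got <- res$results
  expect_equal(nrow(got), 10)
  active <- sprintf("pert%02d", 1:5)
  expect_true(all(got$retrieved[got$group_id %in% active]))
  expect_false(any(got$retrieved[!got$group_id %in% active]))
  expect_equal(percent_retrieved(got), 50)
  # single-replicate perturbations are skipped with a reason, not fatal
  pt2 <- pt
  pt2$data <- pt$data[-(2:3), ] # pert01 left with one replicate
  res2 <- phenotypic_activity(pt2, "Metadata_pert",
                              list(Metadata_control = "negcon"),
                              n_perm = 200, seed = 1)
  expect_equal(nrow(res2$results), 9)
  expect_true("no_positives" %in% skipped_groups(res2)$reason)
})

test_that("consistency retrieves coherent labels against other labels", {
  mat <- rbind(c(1, 0, 0), c(2, 0, 0),   # label A: collinear
               c(0, 1, 0), c(0, 0, 1))   # label B: orthogonal to A
  pt <- table_from_matrix(mat, sprintf("p%d", 1:4),
                          extra = data.frame(Metadata_label =
                                               c("A", "A", "B", "B")))
  res <- phenotypic_consistency(pt, "Metadata_label", n_perm = 500, seed = 1)
  got <- res$results
  expect_equal(got$mAP[got$group_id == "A"], 1)
  expect_equal(got$n_pos[got$group_id == "A"], 1L)
  expect_equal(got$n_total[got$group_id == "A"], 3L)
})

test_that("consistency references depend on label inequality, not identity", {
  withr::with_seed(5, {
    mat <- rbind(matrix(rnorm(2 * 6, mean = 3), 2, 6),
                 matrix(rnorm(4 * 6), 4, 6))
  })
  labels1 <- c("A", "A", "B", "B", "B", "B")
  labels2 <- c("A", "A", "B1", "B2", "B1", "B2") # same rows, split names
  pt1 <- table_from_matrix(mat, sprintf("p%d", 1:6),
                           extra = data.frame(Metadata_label = labels1))
  pt2 <- table_from_matrix(mat, sprintf("p%d", 1:6),
                           extra = data.frame(Metadata_label = labels2))
  r1 <- phenotypic_consistency(pt1, "Metadata_label", n_perm = 500, seed = 9)
  r2 <- phenotypic_consistency(pt2, "Metadata_label", n_perm = 500, seed = 9)
  a1 <- r1$results[r1$results$group_id == "A", ]
  a2 <- r2$results[r2$results$group_id == "A", ]
  expect_equal(a1$mAP, a2$mAP)
  expect_equal(a1$n_total, a2$n_total)
})

test_that("distinctiveness penalizes perturbations that mimic each other", {
  v1 <- c(1, 0, 0, 0)
  v2 <- c(0.9, 0.1, 0, 0)
  mat <- rbind(v1, v2,            # pert A
               v1, v2,            # pert B: exact copy of A
               c(0, 0, 1, 0), c(0, 0, 0.9, 0.1)) # pert C: orthogonal
  pt <- table_from_matrix(mat, rep(c("A", "B", "C"), each = 2))
  res <- phenotypic_distinctiveness(pt, "Metadata_pert", n_perm = 500,
                                    seed = 1)
  got <- res$results
  expect_lt(got$mAP[got$group_id == "A"], 1)
  expect_lt(got$mAP[got$group_id == "B"], 1)
  expect_equal(got$mAP[got$group_id == "C"], 1)
})

test_that("distinctiveness excludes controls unless asked to include them", {
  pt <- toy_table(n_pert = 3, n_rep = 2, n_ctrl = 5, d = 8, active = 1:3,
                  shift = 4, seed = 8)
  res <- phenotypic_distinctiveness(pt, "Metadata_pert",
                                    control_filter =
                                      list(Metadata_control = "negcon"),
                                    n_perm = 300, seed = 2)
  expect_true(all(res$results$n_total == 5)) # 1 positive + 4 other replicates
  res_inc <- phenotypic_distinctiveness(pt, "Metadata_pert",
                                        control_filter =
                                          list(Metadata_control = "negcon"),
                                        include_controls = TRUE,
                                        n_perm = 300, seed = 2)
  expect_true(all(res_inc$results$n_total == 10)) # + 5 controls
})

test_that("multilabel AP matrix has the annotation sparsity pattern", {
  pt <- make_fixture("multilabel_toy", seed = 3)
  ann <- attr(pt, "annotations")
  m <- multilabel_map(pt, ann, "Metadata_pert")
  expect_equal(nrow(m), nrow(ann)) # one entry per annotation pair
  expect_equal(sum(m$perturbation == "p1"), 2) # p1 carries two labels
  expect_true(all(m$ap > 0 & m$ap <= 1))
})

test_that("orthogonal disjoint label groups score AP 1 everywhere", {
  mat <- rbind(c(5, 0, 0, 0), c(6, 0, 0, 0), c(7, 0, 0, 0),
               c(0, 5, 0, 0), c(0, 6, 0, 0), c(0, 0, 7, 1e-3))
  pt <- table_from_matrix(mat, sprintf("p%d", 1:6))
  ann <- data.frame(perturbation = sprintf("p%d", 1:6),
                    label = c("X", "X", "X", "Y", "Y", "Z"))
  # label Z has a single member: omitted and logged, others all perfect
  m <- multilabel_map(pt, ann, "Metadata_pert")
  expect_equal(nrow(m), 5)
  expect_true(all(m$ap == 1))
  expect_equal(skipped_groups(m)$reason, "single_member_label")
})

test_that("single-label column means reproduce phenotypic consistency", {
  withr::with_seed(11, {
    mat <- rbind(matrix(rnorm(3 * 8, 2), 3, 8),
                 matrix(rnorm(3 * 8, -2), 3, 8),
                 matrix(rnorm(2 * 8), 2, 8))
  })
  labels <- c("A", "A", "A", "B", "B", "B", "C", "C")
  perts <- sprintf("p%d", 1:8)
  pt <- table_from_matrix(mat, perts,
                          extra = data.frame(Metadata_label = labels))
  m <- multilabel_map(pt, data.frame(perturbation = perts, label = labels),
                      "Metadata_pert")
  agg <- aggregate_multilabel(m, "per_label")
  cons <- phenotypic_consistency(pt, "Metadata_label", n_perm = 200,
                                 seed = 1)
  want <- cons$results[order(cons$results$group_id), ]
  expect_equal(agg$mAP, want$mAP, tolerance = 1e-12)
})

test_that("multilabel aggregation averages present entries only", {
  m <- tibble::tibble(
    perturbation = c("p1", "p2", "p1", "p3"),
    label = c("L1", "L1", "L2", "L2"),
    ap = c(1, 0.5, 1 / 3, 1 / 3),
    n_pos = 1L, n_total = 3L
  )
  class(m) <- c("multilabel_ap", class(m))
  per_label <- aggregate_multilabel(m, "per_label")
  expect_equal(per_label$mAP, c(0.75, 1 / 3))
  per_pert <- aggregate_multilabel(m, "per_perturbation")
  expect_equal(per_pert$mAP[per_pert$perturbation == "p3"], 1 / 3)
  expect_equal(per_pert$mAP[per_pert$perturbation == "p1"], mean(c(1, 1 / 3)))
})
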