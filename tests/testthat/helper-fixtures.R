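# Small tables built in code, shared across test files.

# n_pert perturbations x n_rep replicates plus n_ctrl controls, i.i.d. N(0,1)
# unless `shift` moves all features of the perturbations listed in `active`.
toy_table <- function(n_pert = 2, n_rep = 3, n_ctrl = 6, d = 5,
                      active = integer(0), shift = 0, seed = 1) {
  withr::with_seed(seed, {
    pert <- sprintf("pert%02d", rep(seq_len(n_pert), each = n_rep))
    trt <- matrix(rnorm(n_pert * n_rep * d), ncol = d)
    rows_active <- rep(seq_len(n_pert), each = n_rep) %in% active
    trt[rows_active, ] <- trt[rows_active, ] + shift
    ctrl <- matrix(rnorm(n_ctrl * d), ncol = d)
    df <- data.frame(
      Metadata_pert = c(pert, rep("control", n_ctrl)),
      Metadata_control = c(rep("trt", n_pert * n_rep),
                           rep("negcon", n_ctrl))
    )
    feats <- as.data.frame(rbind(trt, ctrl))
    names(feats) <- paste0("f", seq_len(d))
    profile_table(cbind(df, feats))
  })
}

# One perturbation on a 3-plate x 2-well layout (6 replicates, one per
# plate/well combination) plus controls.
plate_layout_table <- function(n_ctrl = 4, d = 4, seed = 2) {
  withr::with_seed(seed, {
    layout <- expand.grid(plate = c("p1", "p2", "p3"), well = c("A1", "B1"),
                          stringsAsFactors = FALSE)
    df <- data.frame(
      Metadata_pert = c(rep("g1", nrow(layout)), rep("control", n_ctrl)),
      Metadata_plate = c(layout$plate, rep("p1", n_ctrl)),
      Metadata_well = c(layout$well, rep("Z1", n_ctrl)),
      Metadata_control = c(rep("trt", nrow(layout)), rep("negcon", n_ctrl))
    )
    feats <- as.data.frame(matrix(rnorm((nrow(layout) + n_ctrl) * d),
                                  ncol = d))
    names(feats) <- paste0("f", seq_len(d))
    profile_table(cbind(df, feats))
  })
}

# Profile table from a bare feature matrix and a perturbation label vector.
table_from_matrix <- function(mat, pert, extra = NULL) {
  df <- data.frame(Metadata_pert = pert)
  if (!is.null(extra)) df <- cbind(df, extra)
  feats <- as.data.frame(mat)
  names(feats) <- paste0("f", seq_len(ncol(mat)))
  profile_table(cbind(df, feats))
}

# Hand-buildable retrieval instance (same structure build_instances emits).
manual_instance <- function(query, positives, references, group_id = "g") {
  structure(
    list(group_id = group_id, query = query, positives = positives,
         references = references),
    class = "retrieval_instance"
  )
}

# Independent AP oracle: precision at every rank via cumulative sums, then
# averaged over the ranks holding positives.
ap_oracle <- function(relevance) {
  precision <- cumsum(relevance) / seq_along(relevance)
  mean(precision[relevance == 1])
}

# Independent BH step-up reference.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# All binary 0/1 lists of length len with at least one 1 and one 0.
all_binary_lists <- function(len) {
  grid <- as.matrix(expand.grid(rep(list(0:1), len)))
  grid[rowSums(grid) > 0 & rowSums(grid) < len, , drop = FALSE]
}
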