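# Small deterministic problem generators used across the test files.

make_tiny_problem <- function(seed = 1, n_per = 10, p = 4, m = 3, n_tissues = 2,
                              missing_rate = 0) {
  set.seed(seed)
  n <- n_per * n_tissues
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  labels <- rep(paste0("g", seq_len(n_tissues)), each = n_per)
  B <- lapply(seq_len(n_tissues), function(t) {
    Bt <- matrix(0, p, m)
    Bt[1, ] <- ifelse(t == 1, 0.8, -0.8)
    Bt[2, 1] <- 0.5
    Bt
  })
  Y <- matrix(NA_real_, n, m, dimnames = list(NULL, paste0("d", seq_len(m))))
  for (t in seq_len(n_tissues)) {
    idx <- which(labels == paste0("g", t))
    Y[idx, ] <- X[idx, , drop = FALSE] %*% B[[t]] +
      matrix(rnorm(length(idx) * m, sd = 0.5), length(idx), m)
  }
  if (missing_rate > 0) {
    Y[matrix(runif(n * m) < missing_rate, n, m)] <- NA
  }
  tree <- build_drug_tree(if (anyNA(Y)) Y else Y,
                          use = if (anyNA(Y)) "pairwise.complete.obs"
                          else "everything")
  list(Y = Y, X = X, labels = labels, tree = tree, B_true = B,
       n = n, p = p, m = m, n_tissues = n_tissues)
}

# A fixed hand-specified drug tree over m drugs: chain or from merge matrix.
manual_tree <- function(merge, height, m, labels = paste0("d", seq_len(m))) {
  mixlasso:::new_drug_tree(m = m, labels = labels, merge = merge,
                           height = height)
}

# Two-drug tree: one root at (normalized) height 1, weight `omega_root`.
two_drug_tree <- function(omega_root = 1) {
  tr <- manual_tree(matrix(c(-1L, -2L), 1, 2), height = 1, m = 2)
  tr$omega <- omega_root
  tr
}
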