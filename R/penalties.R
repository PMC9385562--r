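# Coefficient sets are handled as a list of p x m matrices, one per tissue.
as_coef_list <- function(B) {
  if (is.list(B)) return(lapply(B, as.matrix))
  if (is.array(B) && length(dim(B)) == 3L) {
    return(lapply(seq_len(dim(B)[3L]), function(t) B[, , t, drop = TRUE]))
  }
  if (is.matrix(B)) return(list(B))
  stop("B must be a matrix, a list of matrices, or a p x m x T array",
       call. = FALSE)
}

#' Euclidean-ball shrinkage operator
#'
#' Projects a vector onto the unit Euclidean ball: `v / max(1, ||v||_2)`.
#' This is the closed-form maximizer of the Nesterov-smoothed dual of a group
#' L2 norm; it is the identity whenever `||v||_2 <= 1`.
#'
#' @param v Numeric vector.
#' @return Vector of the same length with Euclidean norm at most 1.
#' @export
#' @examples
#' group_shrink(c(3, 4))   # (0.6, 0.8)
group_shrink <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  v / max(1, sqrt(sum(v^2)))
}

# Effective per-feature penalty weights lambda_j = lambda * factor_{s(j)}.
effective_lambda <- function(p, lambda, source_blocks = NULL,
                             lambda_factors = NULL) {
  lambda * source_factor_vector(p, source_blocks, lambda_factors)
}

#' Tree-guided group penalty value
#'
#' Exact value of the dendrogram penalty: for every tissue t, feature j and
#' tree node v, the Euclidean norm of the coefficient block across the drugs
#' in group G_v, weighted by the node weight (normalized merge height for
#' internal nodes, 1 for leaves) and by the per-source penalty factor:
#' \deqn{\sum_t \sum_j \lambda_j \sum_v \omega_v \|\beta^{(t)}_{j, G_v}\|_2.}
#'
#' @param B Coefficient set: p x m matrix, list of per-tissue matrices, or a
#'   p x m x T array.
#' @param tree A [build_drug_tree()] object over the m drugs.
#' @param lambda Positive overall penalty level.
#' @param source_blocks Optional named block sizes per omics source (as set by
#'   [stack_omics()]).
#' @param lambda_factors Optional named per-source multipliers (integrative
#'   penalty factors); effective weight for a feature in source s is
#'   `lambda * lambda_factors[s]`.
#' @param include Which node layers to sum: `"both"` (default), `"internal"`,
#'   or `"leaf"`.
#' @return Nonnegative scalar.
#' @export
tree_penalty <- function(B, tree, lambda, source_blocks = NULL,
                         lambda_factors = NULL,
                         include = c("both", "internal", "leaf")) {
  include <- match.arg(include)
  Bl <- as_coef_list(B)
  p <- nrow(Bl[[1L]])
  m <- ncol(Bl[[1L]])
  if (m != tree$m) stop("drug dimension of B does not match the tree", call. = FALSE)
  pre <- tree_precompute(tree)
  lam_j <- effective_lambda(p, lambda, source_blocks, lambda_factors)
  total <- 0
  for (Bt in Bl) {
    if (!all(dim(Bt) == c(p, m))) stop("per-tissue matrices differ in shape",
                                       call. = FALSE)
    if (include != "leaf" && pre$n_groups > 0L) {
      rn <- sqrt(pmax((Bt^2) %*% pre$Mv, 0))        # p x n_int block norms
      total <- total + sum(lam_j * (rn %*% pre$omega))
    }
    if (include != "internal") {
      total <- total + sum(lam_j * (abs(Bt) %*% pre$leaf_weight))
    }
  }
  total
}

#' Tissue sparse-group penalty value
#'
#' Ties the T tissue-specific effects of each (feature, drug) pair together:
#' a group-L2 term over the cross-tissue coefficient vector plus an L1 term,
#' \deqn{(1-\alpha)\,\gamma\, T^{e} \sum_{j,k} \|\beta^{(1:T)}_{jk}\|_2
#'       + \alpha\,\gamma\, \|B\|_1,}
#' with group-size exponent e = 1/2 by default (the sparse-group-lasso
#' convention, making gamma scale-free in T).
#'
#' @inheritParams tree_penalty
#' @param gamma Nonnegative tissue-penalty level.
#' @param alpha Mixing weight in \[0, 1\] between L1 (`alpha = 1`) and group L2
#'   (`alpha = 0`).
#' @param t_exponent Group-size exponent e, `0.5` or `1`.
#' @return Nonnegative scalar.
#' @export
tissue_penalty <- function(B, gamma, alpha = 0.5, t_exponent = 0.5) {
  stopifnot(gamma >= 0, alpha >= 0, alpha <= 1, t_exponent %in% c(0.5, 1))
  Bl <- as_coef_list(B)
  Tn <- length(Bl)
  N2 <- Reduce(`+`, lapply(Bl, function(Bt) Bt^2))
  l1 <- sum(vapply(Bl, function(Bt) sum(abs(Bt)), 1))
  (1 - alpha) * gamma * Tn^t_exponent * sum(sqrt(N2)) + alpha * gamma * l1
}

# Smoothed internal-tree + tissue-group penalty and its gradient.
#
# Each group term w * ||x||_2 is replaced by its Nesterov envelope
# max_{||a|| <= 1} <a, w x> - (mu/2) ||a||^2, whose value is the Huber
# function (w||x|| - mu/2 if w||x|| >= mu, else (w||x||)^2 / (2 mu)) and whose
# gradient is w * S(w x / mu) with S the unit-ball shrinkage.
#
# Blocks: for every tissue, feature and internal tree node, the coefficient
# slice across the node's drugs (weight lambda_j * omega_v); and for every
# (feature, drug), the cross-tissue slice (weight g = (1-alpha) gamma T^e),
# whose optimal dual is shared across tissues.
smoothed_penalty_core <- function(Bl, pre, lam_j, g, mu) {
  if (mu <= 0) stop("smoothing parameter mu must be positive", call. = FALSE)
  Tn <- length(Bl)
  p <- nrow(Bl[[1L]])
  m <- ncol(Bl[[1L]])
  grad <- lapply(Bl, function(Bt) matrix(0, p, m))
  value <- 0
  if (pre$n_groups > 0L && any(lam_j > 0)) {
    W <- outer(lam_j, pre$omega)                     # p x n_int weights
    for (t in seq_len(Tn)) {
      rn <- sqrt(pmax((Bl[[t]]^2) %*% pre$Mv, 0))    # p x n_int
      wr <- W * rn
      value <- value + sum(ifelse(wr >= mu, wr - mu / 2, wr^2 / (2 * mu)))
      inv_rn <- ifelse(rn > 0, 1 / rn, Inf)
      S <- W * pmin(W / mu, inv_rn)                  # scale on each block
      grad[[t]] <- grad[[t]] + Bl[[t]] * (S %*% t(pre$Mv))
    }
  }
  if (g > 0 && Tn >= 1L) {
    N <- sqrt(Reduce(`+`, lapply(Bl, function(Bt) Bt^2)))
    gN <- g * N
    value <- value + sum(ifelse(gN >= mu, gN - mu / 2, gN^2 / (2 * mu)))
    sg <- g * pmin(g / mu, ifelse(N > 0, 1 / N, Inf))
    for (t in seq_len(Tn)) grad[[t]] <- grad[[t]] + Bl[[t]] * sg
  }
  list(value = value, grad = grad)
}

#' Nesterov-smoothed penalty and gradient
#'
#' Evaluates the smooth surrogate f_mu of the nonsmooth penalty terms that the
#' optimizer smooths — the internal-node tree groups and the cross-tissue
#' group-L2 term — together with its gradient per tissue. Leaf-node terms and
#' the L1 term are not smoothed (they are handled exactly by the proximal
#' step) and are not included here.
#'
#' The surrogate satisfies the sandwich bound
#' `f_mu(B) <= Omega(B) <= f_mu(B) + mu * D`, where `Omega` is the exact sum
#' of the smoothed group terms and `D = blocks / 2` is the maximum of the
#' prox function over the feasible duals (each dual block has norm at most 1).
#'
#' @inheritParams tree_penalty
#' @inheritParams tissue_penalty
#' @param mu Positive smoothing parameter.
#' @return A list: `value` (f_mu), `grad` (list of p x m gradient matrices,
#'   one per tissue), `n_blocks` (number of dual blocks), and `D`
#'   (= `n_blocks / 2`, the smoothing gap constant).
#' @export
smoothed_penalty <- function(B, tree, lambda, gamma = 0, alpha = 0.5, mu,
                             t_exponent = 0.5, source_blocks = NULL,
                             lambda_factors = NULL) {
  Bl <- as_coef_list(B)
  p <- nrow(Bl[[1L]])
  Tn <- length(Bl)
  pre <- tree_precompute(tree)
  lam_j <- effective_lambda(p, lambda, source_blocks, lambda_factors)
  g <- if (gamma > 0) (1 - alpha) * gamma * Tn^t_exponent else 0
  out <- smoothed_penalty_core(Bl, pre, lam_j, g, mu)
  n_blocks <- Tn * p * pre$n_groups + if (g > 0) p * tree$m else 0L
  out$n_blocks <- n_blocks
  out$D <- n_blocks / 2
  out
}

#' Smoothing parameter from a desired accuracy
#'
#' The smoothing-proximal-gradient convention `mu = epsilon / (2 D)`, where D
#' is the maximum of the dual prox function: one half times the number of dual
#' blocks (each block is constrained to the unit ball).
#'
#' @param epsilon Desired accuracy of the smooth approximation.
#' @param n_blocks Number of smoothed dual blocks.
#' @return Positive smoothing parameter.
#' @export
mu_from_accuracy <- function(epsilon, n_blocks) {
  stopifnot(epsilon > 0, n_blocks >= 1)
  epsilon / (2 * (n_blocks / 2))
}
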