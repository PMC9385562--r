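# Proxy covariance: per tissue V(t) = I + c J (compound symmetric), the fixed
# plug-in for the unknown random-intercept covariance. Its inverse and log
# determinant are closed form:
#   V^{-1} = I - (c / (1 + c n_t)) J,   log|V| = log(1 + c n_t).

#' Closed-form inverse of the compound-symmetric proxy covariance
#'
#' Returns the exact inverse of `I + c J` (J the all-ones matrix), i.e.
#' `I - (c / (1 + c n_t)) J`.
#'
#' @param n_t Block size (samples in the tissue).
#' @param c Nonnegative proxy constant (the model default is `log(n)` with n
#'   the total sample count; `c = 0` gives the identity).
#' @return An `n_t` x `n_t` matrix.
#' @export
#' @examples
#' proxy_inverse(2, 1)   #  [[2/3, -1/3], [-1/3, 2/3]]
proxy_inverse <- function(n_t, c) {
  stopifnot(n_t >= 1, c >= 0)
  diag(n_t) - (c / (1 + c * n_t)) * matrix(1, n_t, n_t)
}

# Resolve the proxy constant: "logn" -> log(n), "none" -> 0, or a number.
resolve_proxy_c <- function(proxy_c, n) {
  if (is.character(proxy_c)) {
    switch(proxy_c,
           logn = {
             if (n < 2) stop("proxy c = log(n) needs n >= 2", call. = FALSE)
             log(n)
           },
           none = 0,
           stop("unknown proxy_c: ", proxy_c, call. = FALSE))
  } else {
    stopifnot(is.numeric(proxy_c), length(proxy_c) == 1L, proxy_c >= 0)
    as.numeric(proxy_c)
  }
}

#' Project residuals onto the observed entries
#'
#' The missing-response projection: unobserved entries are set to zero so that
#' no loss, gradient, or metric ever uses them; observed entries pass through
#' unchanged. `NA` residuals at unobserved positions are also zeroed.
#'
#' @param R Numeric matrix of residuals.
#' @param observed Logical (or 0/1) matrix of the same shape; `NULL` means
#'   `!is.na(R)`.
#' @return Matrix of the same shape with unobserved entries equal to 0.
#' @export
project_missing <- function(R, observed = NULL) {
  if (is.null(observed)) observed <- !is.na(R)
  stopifnot(all(dim(R) == dim(observed)))
  R[!observed | is.na(R)] <- 0
  R * (observed * 1)
}

# Observed mask from Y and an optional explicit mask.
resolve_observed <- function(Y, observed = NULL) {
  if (is.null(observed)) return(!is.na(Y))
  observed <- observed & !is.na(Y)
  storage.mode(observed) <- "logical"
  observed
}

#' Negative log likelihood under the proxy covariance
#'
#' Sum over tissues and drugs of the Gaussian negative log likelihood with the
#' compound-symmetric proxy covariance `V(t) = I + c J`, with residuals at
#' unobserved response entries projected to zero before the quadratic form:
#' \deqn{\sum_{t,k} \tfrac{n_t}{2}\log 2\pi + \tfrac12 \log(1 + c\,n_t)
#'   + \tfrac12 r_{tk}^\top V(t)^{-1} r_{tk},\quad
#'   r_{tk} = \Pi(y^{(t)}_k - \beta^{(t)}_{0k} - X^{(t)} \beta^{(t)}_k).}
#'
#' @param Y Response matrix (n x m); `NA` marks unobserved entries.
#' @param X Predictor matrix (n x p), same row order as `Y`.
#' @param tissues A [tissue_design()] or a label vector of length n.
#' @param intercepts T x m matrix (or length-m vector recycled per tissue) of
#'   per-drug intercepts.
#' @param B Coefficient set (list of p x m matrices per tissue, p x m x T
#'   array, or one matrix shared by all tissues).
#' @param proxy_c `"logn"` (default), `"none"`, or a nonnegative number.
#' @param observed Optional logical mask overriding `!is.na(Y)`.
#' @return Scalar negative log likelihood.
#' @export
mixlasso_nll <- function(Y, X, tissues, intercepts, B, proxy_c = "logn",
                         observed = NULL) {
  design <- if (inherits(tissues, "tissue_design")) tissues else tissue_design(tissues)
  Bl <- as_coef_list(B)
  if (length(Bl) == 1L && design$n_groups > 1L) {
    Bl <- rep(Bl, design$n_groups)
  }
  stopifnot(length(Bl) == design$n_groups)
  m <- ncol(Y)
  if (is.null(dim(intercepts))) {
    intercepts <- matrix(intercepts, design$n_groups, m, byrow = TRUE)
  }
  if (!all(is.finite(X)) ||
      !all(is.finite(vapply(Bl, function(b) sum(b), 1)))) {
    stop("non-finite inputs", call. = FALSE)
  }
  cc <- resolve_proxy_c(proxy_c, design$n)
  obs <- resolve_observed(Y, observed)
  total <- 0
  for (t in seq_len(design$n_groups)) {
    idx <- which(as.integer(design$labels) == t)
    n_t <- length(idx)
    d_t <- cc / (1 + cc * n_t)
    Rt <- Y[idx, , drop = FALSE] -
      matrix(intercepts[t, ], n_t, m, byrow = TRUE) -
      X[idx, , drop = FALSE] %*% Bl[[t]]
    Rt <- project_missing(Rt, obs[idx, , drop = FALSE])
    quad <- 0.5 * (sum(Rt^2) - d_t * sum(colSums(Rt)^2))
    total <- total + m * (n_t / 2 * log(2 * pi) + 0.5 * log(1 + cc * n_t)) + quad
  }
  total
}

#' Predict per-tissue random intercepts
#'
#' Maximum a posteriori prediction of the tissue random effect from the
#' fitted-model residuals:
#' \deqn{\hat u_t = \big(m\,n_t + 1/c\big)^{-1}
#'   \mathbf 1^\top \sum_k \Pi\big(y^{(t)}_k - \beta^{(t)}_{0k}
#'   - X^{(t)}\beta^{(t)}_k\big),}
#' with `c = log(n)` under the default proxy. Unobserved entries contribute
#' zero. With `c = 0` (no random effect) all predictions are zero.
#'
#' @inheritParams mixlasso_nll
#' @return Named numeric vector of length T.
#' @export
predict_random_effects <- function(Y, X, tissues, intercepts, B,
                                   proxy_c = "logn", observed = NULL) {
  design <- if (inherits(tissues, "tissue_design")) tissues else tissue_design(tissues)
  if (design$n < 2) stop("random-effect prediction needs n >= 2", call. = FALSE)
  Bl <- as_coef_list(B)
  if (length(Bl) == 1L && design$n_groups > 1L) Bl <- rep(Bl, design$n_groups)
  m <- ncol(Y)
  if (is.null(dim(intercepts))) {
    intercepts <- matrix(intercepts, design$n_groups, m, byrow = TRUE)
  }
  cc <- resolve_proxy_c(proxy_c, design$n)
  obs <- resolve_observed(Y, observed)
  u <- setNames(numeric(design$n_groups), levels(design$labels))
  if (cc <= 0) return(u)
  for (t in seq_len(design$n_groups)) {
    idx <- which(as.integer(design$labels) == t)
    n_t <- length(idx)
    Rt <- Y[idx, , drop = FALSE] -
      matrix(intercepts[t, ], n_t, m, byrow = TRUE) -
      X[idx, , drop = FALSE] %*% Bl[[t]]
    Rt <- project_missing(Rt, obs[idx, , drop = FALSE])
    u[t] <- sum(Rt) / (m * n_t + 1 / cc)
  }
  u
}

#' Exact mix-lasso objective value
#'
#' The full nonsmooth objective: proxy-covariance negative log likelihood plus
#' the tree penalty (internal and leaf nodes) plus the tissue sparse-group
#' penalty. Used for reporting and for cross-checking the optimizer against
#' independent solvers.
#'
#' @inheritParams mixlasso_nll
#' @inheritParams tree_penalty
#' @inheritParams tissue_penalty
#' @param tree A [build_drug_tree()] object.
#' @param lambda,gamma,alpha Penalty parameters.
#' @return Scalar objective value.
#' @export
mixlasso_objective <- function(Y, X, tissues, intercepts, B, tree, lambda,
                               gamma = 0, alpha = 0.5, proxy_c = "logn",
                               t_exponent = 0.5, source_blocks = NULL,
                               lambda_factors = NULL, observed = NULL) {
  design <- if (inherits(tissues, "tissue_design")) tissues else tissue_design(tissues)
  Bl <- as_coef_list(B)
  if (length(Bl) == 1L && design$n_groups > 1L) Bl <- rep(Bl, design$n_groups)
  mixlasso_nll(Y, X, design, intercepts, Bl, proxy_c, observed) +
    tree_penalty(Bl, tree, lambda, source_blocks, lambda_factors) +
    tissue_penalty(Bl, gamma, alpha, t_exponent)
}
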