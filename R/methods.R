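#' Predict drug responses from a fitted model
#'
#' Row i of tissue t is predicted as
#' `intercept(t) + x_i' B(t) + u_t`: the tissue-specific linear predictor plus
#' the predicted random intercept (the same `u_t` for all drugs). Prediction
#' for a tissue the model was not fitted on is an error — there is no
#' pan-tissue fallback.
#'
#' @param object A `mix_lasso_fit`.
#' @param X Predictor matrix for the new samples (same columns as training).
#' @param tissues Tissue labels for the new samples. For a tree-lasso fit
#'   (single group) this may be omitted.
#' @param random_effects Include the predicted random intercepts (default
#'   `TRUE`; tree-lasso fits have none).
#' @param ... Unused.
#' @return Numeric matrix (rows of `X` x drugs).
#' @export
predict.mix_lasso_fit <- function(object, X, tissues = NULL,
                                  random_effects = TRUE, ...) {
  stopifnot(is.matrix(X))
  if (is.null(tissues)) {
    if (length(object$tissue_levels) != 1L) {
      stop("tissue labels are required for a multi-group fit", call. = FALSE)
    }
    tissues <- rep(object$tissue_levels, nrow(X))
  }
  labs <- as.character(tissues)
  unknown <- setdiff(unique(labs), object$tissue_levels)
  if (length(unknown)) {
    stop("unknown tissue label(s) at prediction time: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- ncol(object$intercepts)
  out <- matrix(NA_real_, nrow(X), m,
                dimnames = list(rownames(X), colnames(object$intercepts)))
  for (t in seq_along(object$tissue_levels)) {
    lev <- object$tissue_levels[t]
    idx <- which(labs == lev)
    if (!length(idx)) next
    pred <- X[idx, , drop = FALSE] %*% object$coefficients[[t]]
    pred <- sweep(pred, 2L, object$intercepts[t, ], "+")
    if (random_effects) pred <- pred + object$u[t]
    out[idx, ] <- pred
  }
  out
}

#' Extract coefficients as an array
#'
#' @param object A `mix_lasso_fit`.
#' @param ... Unused.
#' @return A p x m x T array of tissue-specific coefficients (original
#'   predictor scale).
#' @export
coef.mix_lasso_fit <- function(object, ...) {
  Bl <- object$coefficients
  arr <- array(unlist(Bl), dim = c(nrow(Bl[[1L]]), ncol(Bl[[1L]]), length(Bl)),
               dimnames = c(dimnames(Bl[[1L]]), list(names(Bl))))
  arr
}

#' Cross-tissue coefficient slice
#'
#' The vector `(beta^(1)_jk, ..., beta^(T)_jk)` of one feature-drug pair
#' across all tissues — the group the tissue penalty acts on.
#'
#' @param fit A `mix_lasso_fit`.
#' @param feature Feature index or name.
#' @param drug Drug index or name.
#' @return Named numeric vector of length T.
#' @export
cross_tissue_slice <- function(fit, feature, drug) {
  vapply(fit$coefficients, function(Bt) Bt[feature, drug], 1)
}

#' @export
print.mix_lasso_fit <- function(x, ...) {
  nz <- sum(vapply(x$coefficients, function(Bt) sum(Bt != 0), 1))
  tot <- length(x$coefficients) * length(x$coefficients[[1L]])
  cat("<", class(x)[1L], "> ", length(x$tissue_levels), " tissue(s), ",
      ncol(x$intercepts), " drugs, ", nrow(x$coefficients[[1L]]),
      " features\n", sep = "")
  cat("lambda = ", x$lambda, ", gamma = ", x$gamma, ", alpha = ", x$alpha,
      ", proxy c = ", signif(x$proxy_c, 4), "\n", sep = "")
  cat("nonzero coefficients: ", nz, " / ", tot,
      "  (objective ", signif(utils::tail(x$objective, 1), 8),
      if (x$converged) ", converged" else ", NOT converged",
      " in ", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Tidy a mix-lasso fit into a coefficient tibble
#'
#' @param x A `mix_lasso_fit`.
#' @param nonzero_only Keep only nonzero coefficients (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `tissue`, `feature`, `drug`, `estimate`.
#' @exportS3Method generics::tidy
tidy.mix_lasso_fit <- function(x, nonzero_only = TRUE, ...) {
  rows <- purrr::imap(x$coefficients, function(Bt, lev) {
    idx <- if (nonzero_only) which(Bt != 0, arr.ind = TRUE) else
      as.matrix(expand.grid(row = seq_len(nrow(Bt)), col = seq_len(ncol(Bt))))
    if (nrow(idx) == 0L) return(NULL)
    tibble::tibble(
      tissue = lev,
      feature = rownames(Bt)[idx[, 1L]],
      drug = colnames(Bt)[idx[, 2L]],
      estimate = Bt[idx]
    )
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a mix-lasso fit
#'
#' @param x A `mix_lasso_fit`.
#' @param ... Unused.
#' @return A one-row tibble: penalty parameters, objective, convergence,
#'   iteration count, and the number of nonzero coefficients.
#' @exportS3Method generics::glance
glance.mix_lasso_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, gamma = x$gamma, alpha = x$alpha,
    proxy_c = x$proxy_c, mu = x$mu,
    objective = utils::tail(x$objective, 1),
    converged = x$converged, iterations = x$iterations,
    n_nonzero = sum(vapply(x$coefficients, function(Bt) sum(Bt != 0), 1)),
    n_tissues = length(x$tissue_levels),
    n_drugs = ncol(x$intercepts),
    n_features = nrow(x$coefficients[[1L]])
  )
}

#' Active (selected) feature sets per tissue and drug
#'
#' @param fit A `mix_lasso_fit`.
#' @return A tibble with columns `tissue`, `drug`, `feature` listing exact
#'   nonzeros of the coefficient set.
#' @export
active_set <- function(fit) {
  tidy(fit, nonzero_only = TRUE)[, c("tissue", "drug", "feature")]
}
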