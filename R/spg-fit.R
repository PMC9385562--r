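#' Control parameters for the smoothing proximal gradient optimizer
#'
#' @param mu Smoothing parameter for the Nesterov envelope of the nonsmooth
#'   group terms (default `1e-3`). Ignored when `epsilon` is supplied, in
#'   which case `mu = epsilon / (2 D)` with D the smoothing gap constant of
#'   the problem (see [mu_from_accuracy()]).
#' @param epsilon Optional desired accuracy of the smooth approximation.
#' @param max_iter Maximum number of proximal-gradient iterations per
#'   smoothing stage.
#' @param tol Relative-objective convergence tolerance.
#' @param accelerate Use Nesterov momentum `(b - 1) / (b + 2)` with
#'   function-value restart (default `TRUE`).
#' @param monotone Enforce a nonincreasing objective trace: an iterate that
#'   increases the objective triggers a momentum restart and a plain proximal
#'   step (default `TRUE`).
#' @param mu_stages Optional decreasing vector of smoothing parameters for
#'   continuation: the problem is solved at each stage, warm-starting the
#'   next; the last stage defines the reported fit.
#' @param verbose Print per-stage progress.
#' @return A list of class `spg_control`.
#' @export
spg_control <- function(mu = 1e-3, epsilon = NULL, max_iter = 1000,
                        tol = 1e-6, accelerate = TRUE, monotone = TRUE,
                        mu_stages = NULL, verbose = FALSE) {
  stopifnot(mu > 0, max_iter >= 1, tol > 0)
  if (!is.null(mu_stages)) stopifnot(all(diff(mu_stages) < 0), all(mu_stages > 0))
  structure(list(mu = mu, epsilon = epsilon, max_iter = max_iter, tol = tol,
                 accelerate = accelerate, monotone = monotone,
                 mu_stages = mu_stages, verbose = verbose),
            class = "spg_control")
}

# Largest eigenvalue of a symmetric PSD matrix by deterministic power
# iteration (no RNG so fits are reproducible bit for bit).
power_lmax <- function(A, iters = 200, tol = 1e-9) {
  d <- nrow(A)
  if (d == 1L) return(abs(A[1, 1]))
  v <- seq_len(d) / sqrt(sum(seq_len(d)^2))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- A %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v_new <- as.vector(w / nw)
    lam_new <- nw
    if (abs(lam_new - lam) <= tol * max(1, lam_new) && i > 5) {
      return(lam_new)
    }
    v <- v_new
    lam <- lam_new
  }
  lam
}

#' Per-tissue Lipschitz constant of the smoothed gradient
#'
#' `L(t) = lambda_max(X*' V(t)^-1 X*) + U / mu`, where `X*` augments a ones
#' column for the intercept and
#' `U = max_s(lambda_s)^2 max_k sum_{v internal, k in G_v} omega_v^2 + g^2`
#' (with `g = (1 - alpha) gamma T^e`) is the squared spectral norm of the
#' stacked smoothed-penalty map — exact when all penalty factors are equal.
#' When the tissue has unobserved responses, the quadratic part is bounded by
#' `lambda_max(X*' X*)`, which dominates the masked curvature for every drug.
#'
#' @param Xt Predictor matrix of the tissue (n_t x p), without the intercept
#'   column.
#' @param c Proxy-covariance constant (numeric; 0 for the identity).
#' @param tree Drug tree.
#' @param lambda,gamma,alpha Penalty parameters.
#' @param mu Smoothing parameter.
#' @param n_tissues Number of sample groups T (enters through g).
#' @param t_exponent Group-size exponent of the tissue penalty.
#' @param source_blocks,lambda_factors Integrative penalty factor structure.
#' @param complete Whether all responses of this tissue are observed.
#' @return Positive scalar L(t).
#' @export
lipschitz_constant <- function(Xt, c, tree, lambda, gamma = 0, alpha = 0.5,
                               mu, n_tissues = 1, t_exponent = 0.5,
                               source_blocks = NULL, lambda_factors = NULL,
                               complete = TRUE) {
  stopifnot(mu > 0)
  n_t <- nrow(Xt)
  Xi <- cbind(1, Xt)
  A <- crossprod(Xi)
  if (complete && c > 0) {
    d_t <- c / (1 + c * n_t)
    cs <- colSums(Xi)
    A <- A - d_t * tcrossprod(cs)
  }
  quad <- power_lmax(A) * 1.02
  pre <- tree_precompute(tree)
  lam_j <- effective_lambda(ncol(Xt), lambda, source_blocks, lambda_factors)
  g <- if (gamma > 0) (1 - alpha) * gamma * n_tissues^t_exponent else 0
  U <- max(lam_j)^2 * max(c(pre$anc_w2, 0)) + g^2
  quad + U / mu
}

#' Proximal update: gradient step plus soft-thresholding
#'
#' One closed-form proximal step of the optimizer: a gradient step
#' `W - grad / L` followed by entrywise soft-thresholding at
#' `threshold / L`. Entries with threshold 0 (the intercept row) get a plain
#' gradient step. Thresholding produces exact zeros, which is how the model
#' performs feature selection.
#'
#' @param W Current (momentum) iterate.
#' @param grad Gradient of the smooth part at `W`, same shape.
#' @param L Positive Lipschitz constant.
#' @param threshold Nonnegative matrix (or scalar) of penalty weights; the
#'   applied threshold is `threshold / L`.
#' @return Updated matrix with exact zeros where the threshold fires.
#' @export
#' @examples
#' prox_update(matrix(1), matrix(0), 1, 0.3)  # 0.7
prox_update <- function(W, grad, L, threshold) {
  stopifnot(L > 0)
  V <- W - grad / L
  sign(V) * pmax(abs(V) - threshold / L, 0)
}

# Shared fitting engine. Y may contain NA; `observed` additionally masks.
# Returns the internal (standardized-X) solution plus bookkeeping.
spg_engine <- function(Y, X, design, tree, lambda, gamma, alpha, cc,
                       t_exponent, source_blocks, lambda_factors,
                       observed, control, init = NULL) {
  n <- nrow(Y); m <- ncol(Y); p <- ncol(X)
  Tn <- design$n_groups
  obs <- resolve_observed(Y, observed)
  pre <- tree_precompute(tree)
  lam_j <- effective_lambda(p, lambda, source_blocks, lambda_factors)
  g <- if (gamma > 0) (1 - alpha) * gamma * Tn^t_exponent else 0
  n_blocks <- Tn * p * pre$n_groups + if (g > 0) p * m else 0L

  # per-tissue data
  tiss <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    idx <- which(as.integer(design$labels) == t)
    n_t <- length(idx)
    Mt <- obs[idx, , drop = FALSE] * 1
    Yt <- Y[idx, , drop = FALSE]
    Yt[Mt == 0 | is.na(Yt)] <- 0
    d_t <- cc / (1 + cc * n_t)
    const_t <- m * (n_t / 2 * log(2 * pi) + 0.5 * log(1 + cc * n_t))
    tiss[[t]] <- list(idx = idx, n_t = n_t, Xi = cbind(1, X[idx, , drop = FALSE]),
                      Y = Yt, M = Mt, d = d_t, const = const_t,
                      complete = all(Mt == 1))
  }

  # exact (unsmoothed) leaf + l1 penalty weights per coefficient entry
  thr_mat <- outer(lam_j, pre$leaf_weight) + alpha * gamma

  mu_stages <- control$mu_stages
  if (is.null(mu_stages)) {
    mu_final <- if (!is.null(control$epsilon)) {
      mu_from_accuracy(control$epsilon, max(n_blocks, 1))
    } else {
      control$mu
    }
    mu_stages <- mu_final
  }

  # initialization: B = 0, intercepts = per-tissue observed drug means
  Bc <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Bt <- matrix(0, p + 1, m)
    ns <- colSums(tiss[[t]]$M)
    mean_t <- ifelse(ns > 0, colSums(tiss[[t]]$Y) / pmax(ns, 1), 0)
    Bt[1, ] <- mean_t
    Bc[[t]] <- Bt
  }
  if (!is.null(init)) Bc <- init

  quad_value <- function(Bl) {
    tot <- 0
    for (t in seq_len(Tn)) {
      z <- tiss[[t]]
      R <- z$M * (z$Y - z$Xi %*% Bl[[t]])
      tot <- tot + z$const +
        0.5 * (sum(R^2) - z$d * sum(colSums(R)^2))
    }
    tot
  }
  quad_grad <- function(Bl) {
    lapply(seq_len(Tn), function(t) {
      z <- tiss[[t]]
      R <- z$M * (z$Y - z$Xi %*% Bl[[t]])
      cs <- colSums(R)
      Q <- R - matrix(z$d * cs, z$n_t, m, byrow = TRUE)
      -crossprod(z$Xi, z$M * Q)
    })
  }
  coef_rows <- function(Bl) lapply(Bl, function(Bt) Bt[-1, , drop = FALSE])
  exact_l1 <- function(Bl) {
    sum(vapply(Bl, function(Bt) sum(thr_mat * abs(Bt[-1, , drop = FALSE])), 1))
  }

  trace <- numeric(0)
  iterations <- 0L
  converged <- FALSE
  L <- NULL

  for (mu in mu_stages) {
    L <- vapply(seq_len(Tn), function(t) {
      z <- tiss[[t]]
      A <- crossprod(z$Xi)
      if (z$complete && cc > 0) A <- A - z$d * tcrossprod(colSums(z$Xi))
      power_lmax(A) * 1.02 +
        (max(lam_j)^2 * max(c(pre$anc_w2, 0)) + g^2) / mu
    }, 1)

    objective <- function(Bl) {
      sp <- smoothed_penalty_core(coef_rows(Bl), pre, lam_j, g, mu)
      quad_value(Bl) + sp$value + exact_l1(Bl)
    }
    full_grad <- function(Bl) {
      gq <- quad_grad(Bl)
      sp <- smoothed_penalty_core(coef_rows(Bl), pre, lam_j, g, mu)
      for (t in seq_len(Tn)) {
        gq[[t]][-1, ] <- gq[[t]][-1, , drop = FALSE] + sp$grad[[t]]
      }
      gq
    }
    take_step <- function(Wl) {
      gr <- full_grad(Wl)
      lapply(seq_len(Tn), function(t) {
        V <- Wl[[t]] - gr[[t]] / L[t]
        V[-1, ] <- sign(V[-1, , drop = FALSE]) *
          pmax(abs(V[-1, , drop = FALSE]) - thr_mat / L[t], 0)
        V
      })
    }

    Bp <- Bc
    h_cur <- objective(Bc)
    trace <- c(trace, h_cur)
    b <- 1
    stage_converged <- FALSE
    for (it in seq_len(control$max_iter)) {
      mom <- if (control$accelerate) (b - 1) / (b + 2) else 0
      Wl <- lapply(seq_len(Tn), function(t) {
        Bc[[t]] + mom * (Bc[[t]] - Bp[[t]])
      })
      Bn <- take_step(Wl)
      h_new <- objective(Bn)
      if (control$monotone && h_new > h_cur + 1e-10 * max(1, abs(h_cur))) {
        # momentum overshoot: restart and take a plain proximal step
        b <- 1
        Bn <- take_step(Bc)
        h_new <- objective(Bn)
        if (h_new > h_cur + 1e-7 * max(1, abs(h_cur))) {
          if (h_new > h_cur + 0.1 * abs(h_cur) + 1) {
            stop("SPG divergence: objective increased from ", h_cur, " to ",
                 h_new, call. = FALSE)
          }
          # numerically stalled; keep the current iterate
          Bn <- Bc
          h_new <- h_cur
        }
      }
      rel <- abs(h_cur - h_new) / max(1, abs(h_cur))
      Bp <- Bc
      Bc <- Bn
      h_cur <- h_new
      trace <- c(trace, h_cur)
      b <- b + 1
      iterations <- iterations + 1L
      if (rel < control$tol) {
        stage_converged <- TRUE
        break
      }
    }
    converged <- stage_converged
    if (control$verbose) {
      message(sprintf("mu = %.3g: objective %.6f after %d iterations%s",
                      mu, h_cur, iterations,
                      if (stage_converged) " (converged)" else ""))
    }
  }

  list(B = Bc, objective = trace, converged = converged,
       iterations = iterations, mu = mu_stages[length(mu_stages)],
       L = L, n_blocks = n_blocks, g = g, lam_j = lam_j)
}

#' Fit the mix-lasso model
#'
#' Minimizes the mix-lasso objective — proxy-covariance negative log
#' likelihood plus the tree-guided group penalty over the drug dendrogram and
#' the tissue sparse-group penalty — by the smoothing proximal gradient
#' method with Nesterov acceleration. Internal-node tree terms and the
#' cross-tissue group term are smoothed; leaf terms and the L1 term are
#' handled exactly by the proximal step, so selected-out coefficients are
#' exact zeros. Responses may contain `NA` (missing at random); unobserved
#' entries never enter the loss or gradient. Per-tissue random intercepts are
#' predicted after convergence by their posterior mean.
#'
#' @param Y Response matrix (n samples x m drugs), `NA` for unobserved.
#' @param X Predictor matrix (n x p); an attribute `source_blocks` (as set by
#'   [stack_omics()]) activates integrative penalty factors.
#' @param tissues A [tissue_design()] or a label vector of length n.
#' @param tree A [build_drug_tree()] over the m drugs (built from training
#'   responses or supplied externally).
#' @param lambda Positive tree-penalty level.
#' @param gamma Nonnegative tissue-penalty level (0 disables the term).
#' @param alpha Sparse-group mixing weight in \[0, 1\].
#' @param proxy_c `"logn"` (default; the selection-consistent proxy),
#'   `"none"`, or a nonnegative number — the constant c of the per-tissue
#'   proxy covariance `I + c J`.
#' @param t_exponent Group-size exponent of the tissue penalty (0.5 or 1).
#' @param lambda_factors Optional named per-source penalty multipliers.
#' @param observed Optional logical mask overriding `!is.na(Y)`.
#' @param standardize Center and unit-scale predictor columns before fitting
#'   (binary 0/1 columns are centered only); coefficients are reported on the
#'   original scale.
#' @param control An [spg_control()] list.
#' @param init Optional warm start: list of (p + 1) x m matrices per tissue
#'   (first row = intercepts) on the standardized scale, as stored in
#'   `$B_internal` of a previous fit on the same data.
#' @return An object of class `mix_lasso_fit`: per-tissue coefficient
#'   matrices (`coefficients`, original scale), `intercepts` (T x m),
#'   random effects `u`, the `objective` trace, `converged`, `iterations`,
#'   the penalty parameters, and the tree.
#' @seealso [fit_tree_lasso()], [cv_mix_lasso()], [predict.mix_lasso_fit()]
#' @export
fit_mix_lasso <- function(Y, X, tissues, tree, lambda, gamma = 0, alpha = 0.5,
                          proxy_c = "logn", t_exponent = 0.5,
                          lambda_factors = NULL, observed = NULL,
                          standardize = TRUE, control = spg_control(),
                          init = NULL) {
  stopifnot(is.matrix(Y), is.matrix(X), nrow(Y) == nrow(X), lambda > 0,
            gamma >= 0, alpha >= 0, alpha <= 1)
  if (ncol(Y) != tree$m) stop("tree has ", tree$m, " leaves but Y has ",
                              ncol(Y), " drugs", call. = FALSE)
  if (anyNA(X)) stop("missing predictor values are not supported", call. = FALSE)
  design <- if (inherits(tissues, "tissue_design")) tissues else tissue_design(tissues)
  stopifnot(design$n == nrow(Y))
  source_blocks <- attr(X, "source_blocks")
  cc <- resolve_proxy_c(proxy_c, design$n)
  obs <- resolve_observed(Y, observed)
  if (any(colSums(obs) == 0)) {
    stop("a drug column has no observed responses", call. = FALSE)
  }

  std <- if (standardize) standardize_predictors(X) else
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))

  eng <- spg_engine(Y, std$X, design, tree, lambda, gamma, alpha, cc,
                    t_exponent, source_blocks, lambda_factors, obs, control,
                    init = init)

  feat <- colnames(X); if (is.null(feat)) feat <- paste0("x", seq_len(ncol(X)))
  drugs <- colnames(Y); if (is.null(drugs)) drugs <- paste0("y", seq_len(ncol(Y)))
  Tn <- design$n_groups
  coefs <- vector("list", Tn)
  intercepts <- matrix(0, Tn, ncol(Y),
                       dimnames = list(levels(design$labels), drugs))
  for (t in seq_len(Tn)) {
    Bt <- eng$B[[t]]
    Bo <- Bt[-1, , drop = FALSE] / std$scale
    intercepts[t, ] <- Bt[1, ] - colSums(Bo * std$center)
    dimnames(Bo) <- list(feat, drugs)
    coefs[[t]] <- Bo
  }
  names(coefs) <- levels(design$labels)

  u <- predict_random_effects(Y, X, design, intercepts, coefs,
                              proxy_c = cc, observed = obs)

  structure(
    list(coefficients = coefs, intercepts = intercepts, u = u,
         B_internal = eng$B, objective = eng$objective,
         converged = eng$converged, iterations = eng$iterations,
         lambda = lambda, gamma = gamma, alpha = alpha,
         t_exponent = t_exponent, proxy_c = cc, mu = eng$mu,
         L = eng$L, n_blocks = eng$n_blocks, tree = tree,
         tissue_levels = levels(design$labels),
         source_blocks = source_blocks, lambda_factors = lambda_factors,
         standardize = standardize,
         x_center = std$center, x_scale = std$scale,
         n = design$n, sizes = design$sizes),
    class = "mix_lasso_fit"
  )
}

#' Fit the tree lasso reference model
#'
#' The tree-guided group lasso baseline: all samples form a single group, no
#' tissue penalty, identity covariance. Equivalent to [fit_mix_lasso()] with
#' `T = 1`, `gamma = 0`, `proxy_c = 0`. The classical model requires complete
#' responses; set `allow_missing = TRUE` to apply the missing-entry
#' projection instead (used for internal comparisons on masked data).
#'
#' @inheritParams fit_mix_lasso
#' @param allow_missing Permit `NA` responses via the projection operator.
#' @return A `tree_lasso_fit` (inherits `mix_lasso_fit`).
#' @export
fit_tree_lasso <- function(Y, X, tree, lambda, lambda_factors = NULL,
                           observed = NULL, allow_missing = FALSE,
                           standardize = TRUE, control = spg_control(),
                           init = NULL) {
  obs <- resolve_observed(Y, observed)
  if (!allow_missing && !all(obs)) {
    stop("tree lasso requires complete responses; ",
         "use allow_missing = TRUE to apply the missing-entry projection",
         call. = FALSE)
  }
  fit <- fit_mix_lasso(Y, X, tissues = rep("all", nrow(Y)), tree = tree,
                       lambda = lambda, gamma = 0, alpha = 0,
                       proxy_c = 0, lambda_factors = lambda_factors,
                       observed = obs, standardize = standardize,
                       control = control, init = init)
  class(fit) <- c("tree_lasso_fit", class(fit))
  fit
}
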