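# Independent oracles. Everything here is deliberately written with plain
# dense linear algebra and explicit loops, sharing no code path with the
# package internals it checks.

# Dense-covariance negative log likelihood: explicit V = I + cJ, solve() and
# determinant(), one drug at a time.
dense_nll_oracle <- function(Y, X, labels, intercepts, Bl, cc,
                             observed = NULL) {
  if (is.null(observed)) observed <- !is.na(Y)
  levs <- unique(labels)
  m <- ncol(Y)
  total <- 0
  for (t in seq_along(levs)) {
    idx <- which(labels == levs[t])
    n_t <- length(idx)
    V <- diag(n_t) + cc * matrix(1, n_t, n_t)
    Vinv <- solve(V)
    ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
    for (k in seq_len(m)) {
      r <- Y[idx, k] - intercepts[t, k] - X[idx, , drop = FALSE] %*% Bl[[t]][, k]
      r[!observed[idx, k]] <- 0
      r[is.na(r)] <- 0
      total <- total + n_t / 2 * log(2 * pi) + 0.5 * ld +
        0.5 * as.numeric(t(r) %*% Vinv %*% r)
    }
  }
  total
}

# Exact mix-lasso objective by explicit loops over all penalty groups.
oracle_objective <- function(Y, X, labels, intercepts, Bl, tree, lambda,
                             gamma, alpha, cc, observed = NULL) {
  nll <- dense_nll_oracle(Y, X, labels, intercepts, Bl, cc, observed)
  p <- ncol(X); m <- ncol(Y); Tn <- length(Bl)
  pen <- 0
  for (t in seq_len(Tn)) {
    for (j in seq_len(p)) {
      for (v in seq_along(tree$groups)) {
        pen <- pen + lambda * tree$omega[v] *
          sqrt(sum(Bl[[t]][j, tree$groups[[v]]]^2))
      }
      for (k in seq_len(m)) {
        pen <- pen + lambda * tree$leaf_weight[k] * abs(Bl[[t]][j, k])
      }
    }
  }
  for (j in seq_len(p)) {
    for (k in seq_len(m)) {
      slice <- vapply(Bl, function(B) B[j, k], 1)
      pen <- pen + (1 - alpha) * gamma * sqrt(Tn) * sqrt(sum(slice^2)) +
        alpha * gamma * sum(abs(slice))
    }
  }
  nll + pen
}

# Consensus ADMM for the exact nonsmooth objective (complete responses).
# Variable duplication per overlapping group; quadratic theta-update via
# Cholesky solves; block soft-threshold z-updates. Returns the best exact
# objective value seen and the final coefficients.
admm_oracle <- function(Y, X, labels, tree, lambda, gamma, alpha, cc,
                        rho = 5, iters = 4000) {
  levs <- unique(labels)
  Tn <- length(levs)
  n <- nrow(Y); p <- ncol(X); m <- ncol(Y)
  Xi_list <- list(); A_list <- list(); rhs_list <- list()
  for (t in seq_len(Tn)) {
    idx <- which(labels == levs[t])
    n_t <- length(idx)
    V <- diag(n_t) + cc * matrix(1, n_t, n_t)
    Vinv <- solve(V)
    Xi <- cbind(1, X[idx, , drop = FALSE])
    Xi_list[[t]] <- Xi
    A_list[[t]] <- t(Xi) %*% Vinv %*% Xi
    rhs_list[[t]] <- t(Xi) %*% Vinv %*% Y[idx, , drop = FALSE]
  }

  # group catalogue: list(type, t, j, k(s), weight)
  groups <- list()
  for (t in seq_len(Tn)) {
    for (j in seq_len(p)) {
      for (v in seq_along(tree$groups)) {
        groups[[length(groups) + 1L]] <-
          list(t = t, j = j, ks = tree$groups[[v]], ts = t,
               w = lambda * tree$omega[v])
      }
      for (k in seq_len(m)) {
        groups[[length(groups) + 1L]] <-
          list(t = t, j = j, ks = k, ts = t,
               w = lambda * tree$leaf_weight[k] + alpha * gamma)
      }
    }
  }
  if (gamma > 0) {
    for (j in seq_len(p)) {
      for (k in seq_len(m)) {
        groups[[length(groups) + 1L]] <-
          list(t = NA, j = j, ks = k, ts = seq_len(Tn),
               w = (1 - alpha) * gamma * sqrt(Tn))
      }
    }
  }

  # membership count per (t, j, k) -> same for all j; compute per (t, k)
  count <- array(0, dim = c(Tn, p, m))
  for (g in groups) {
    for (tt in g$ts) count[tt, g$j, g$ks] <- count[tt, g$j, g$ks] + 1
  }

  # Cholesky per (t, distinct count value)
  chol_cache <- list()
  get_chol <- function(t, ck) {
    key <- paste(t, ck)
    if (is.null(chol_cache[[key]])) {
      D <- diag(c(0, rep(1, p)))
      chol_cache[[key]] <<- chol(A_list[[t]] + rho * ck * D)
    }
    chol_cache[[key]]
  }

  B <- lapply(seq_len(Tn), function(t) matrix(0, p + 1, m))
  z <- lapply(groups, function(g) numeric(length(g$ks) * length(g$ts)))
  u <- lapply(groups, function(g) numeric(length(g$ks) * length(g$ts)))

  get_block <- function(B, g) {
    as.numeric(vapply(g$ts, function(tt) B[[tt]][g$j + 1, g$ks],
                      numeric(length(g$ks))))
  }
  block_soft <- function(v, kappa) {
    nv <- sqrt(sum(v^2))
    if (nv <= kappa) return(v * 0)
    (1 - kappa / nv) * v
  }

  best <- Inf
  best_B <- B
  for (it in seq_len(iters)) {
    # theta-update
    S <- lapply(seq_len(Tn), function(t) matrix(0, p + 1, m))
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      val <- z[[gi]] - u[[gi]]
      pos <- 0
      for (tt in g$ts) {
        S[[tt]][g$j + 1, g$ks] <- S[[tt]][g$j + 1, g$ks] +
          val[pos + seq_along(g$ks)]
        pos <- pos + length(g$ks)
      }
    }
    for (t in seq_len(Tn)) {
      for (k in seq_len(m)) {
        ck <- count[t, 1, k]
        R <- get_chol(t, ck)
        rhs <- rhs_list[[t]][, k] + rho * S[[t]][, k]
        B[[t]][, k] <- backsolve(R, forwardsolve(t(R), rhs))
      }
    }
    # z- and u-updates
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      bg <- get_block(B, g)
      z[[gi]] <- block_soft(bg + u[[gi]], g$w / rho)
      u[[gi]] <- u[[gi]] + bg - z[[gi]]
    }
    if (it %% 25 == 0 || it == iters) {
      intercepts <- t(vapply(B, function(Bt) Bt[1, ], numeric(m)))
      if (m == 1) intercepts <- matrix(intercepts, Tn, 1)
      Bl <- lapply(B, function(Bt) Bt[-1, , drop = FALSE])
      f <- oracle_objective(Y, X, labels, intercepts, Bl, tree, lambda,
                            gamma, alpha, cc)
      if (f < best) {
        best <- f
        best_B <- B
      }
    }
  }
  intercepts <- t(vapply(best_B, function(Bt) Bt[1, ], numeric(m)))
  if (m == 1) intercepts <- matrix(intercepts, Tn, 1)
  list(objective = best,
       intercepts = intercepts,
       B = lapply(best_B, function(Bt) Bt[-1, , drop = FALSE]))
}

# Numerical gradient of a scalar function of a list of matrices.
numeric_grad <- function(f, Bl, h = 1e-6) {
  lapply(seq_along(Bl), function(t) {
    G <- Bl[[t]] * 0
    for (i in seq_along(G)) {
      Bp <- Bl; Bm <- Bl
      Bp[[t]][i] <- Bp[[t]][i] + h
      Bm[[t]][i] <- Bm[[t]][i] - h
      G[i] <- (f(Bp) - f(Bm)) / (2 * h)
    }
    G
  })
}
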