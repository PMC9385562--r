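test_that("Lipschitz constant dominates the quadratic curvature", {
  # no penalty smoothing terms: L = lambda_max([1 X]' [1 X]) (c = 0)
  X <- diag(2)
  tr <- two_drug_tree()
  tr$omega <- 0                                   # disable internal weight
  L <- lipschitz_constant(X, c = 0, tr, lambda = 1e-12, gamma = 0, mu = 1)
  Xi <- cbind(1, X)
  expect_equal(L, max(eigen(crossprod(Xi))$values), tolerance = 0.03)

  # quadrupling of the penalty part under doubled lambda
  set.seed(61)
  X2 <- matrix(rnorm(24), 6, 4)
  prob <- make_tiny_problem(seed = 61, p = 4, m = 3)
  pen_part <- function(lam) {
    lipschitz_constant(X2, c = 0, prob$tree, lambda = lam, gamma = 0,
                       mu = 0.1) -
      lipschitz_constant(X2, c = 0, prob$tree, lambda = 1e-14, gamma = 0,
                         mu = 0.1)
  }
  expect_equal(pen_part(2) / pen_part(1), 4, tolerance = 1e-6)

  # dominates the true curvature measured by dense eigendecomposition
  for (cc in c(0, 1, log(50))) {
    Xi2 <- cbind(1, X2)
    Vinv <- proxy_inverse(6, cc)
    true_quad <- max(eigen(t(Xi2) %*% Vinv %*% Xi2)$values)
    L2 <- lipschitz_constant(X2, c = cc, prob$tree, lambda = 0.5,
                             gamma = 0.3, mu = 0.1, n_tissues = 2)
    expect_gte(L2, true_quad)
  }
})

test_that("proximal update soft-thresholds with exact zeros", {
  expect_equal(prox_update(matrix(0), matrix(0), 1, 0.3), matrix(0))
  expect_equal(prox_update(matrix(1), matrix(0), 1, 0.3), matrix(0.7))
  expect_equal(prox_update(matrix(-1), matrix(0), 1, 0.3), matrix(-0.7))
  # threshold at least |w| gives an exact zero
  expect_identical(prox_update(matrix(0.2), matrix(0), 1, 0.5), matrix(0))
  # gradient step happens before thresholding; L rescales both
  expect_equal(prox_update(matrix(2), matrix(1), 2, 1), matrix(1))
})

test_that("huge penalties shrink everything to the null model", {
  prob <- make_tiny_problem(seed = 71, n_per = 8, p = 4, m = 3,
                            missing_rate = 0.1)
  fit <- fit_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree, lambda = 1e5,
                       gamma = 1e5, control = spg_control(max_iter = 200))
  for (t in 1:2) {
    expect_equal(fit$coefficients[[t]], fit$coefficients[[t]] * 0,
                 ignore_attr = TRUE)
    idx <- prob$labels == paste0("g", t)
    means <- colMeans(prob$Y[idx, , drop = FALSE], na.rm = TRUE)
    expect_equal(fit$intercepts[t, ], means, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # objective equals the null NLL plus zero penalty
  expect_equal(utils::tail(fit$objective, 1),
               mixlasso_nll(prob$Y, prob$X, prob$labels, fit$intercepts,
                            fit$coefficients),
               tolerance = 1e-8)
})

test_that("objective trace is nonincreasing under the monotone safeguard", {
  prob <- make_tiny_problem(seed = 81, n_per = 12, p = 5, m = 3,
                            missing_rate = 0.15)
  fit <- fit_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree, lambda = 0.8,
                       gamma = 0.5, control = spg_control(max_iter = 300))
  expect_true(all(diff(fit$objective) <= 1e-8 * pmax(1, abs(fit$objective[-1]))))
  expect_true(fit$converged)
})

test_that("tree lasso equals the single-group special case of mix-lasso", {
  prob <- make_tiny_problem(seed = 91, n_per = 20, p = 4, m = 3,
                            n_tissues = 1)
  ctl <- spg_control(max_iter = 2000, tol = 1e-10)
  ft <- fit_tree_lasso(prob$Y, prob$X, prob$tree, lambda = 1.2, control = ctl)
  fm <- fit_mix_lasso(prob$Y, prob$X, rep("one", prob$n), prob$tree,
                      lambda = 1.2, gamma = 0, alpha = 0, proxy_c = 0,
                      control = ctl)
  expect_equal(utils::tail(ft$objective, 1), utils::tail(fm$objective, 1),
               tolerance = 1e-6)
  expect_equal(ft$coefficients[[1]], fm$coefficients[[1]], tolerance = 1e-4)
  expect_equal(unname(ft$u), 0)
  # missing responses are rejected unless explicitly allowed
  Yna <- prob$Y; Yna[1, 1] <- NA
  expect_error(fit_tree_lasso(Yna, prob$X, prob$tree, lambda = 1),
               "complete responses")
  expect_s3_class(fit_tree_lasso(Yna, prob$X, prob$tree, lambda = 1,
                                 allow_missing = TRUE,
                                 control = spg_control(max_iter = 50)),
                  "tree_lasso_fit")
})

test_that("SPG reaches the convex-solver optimum on a tiny instance", {
  # the bulk of the oracle-equivalence checking lives in the acceptance
  # suite; this is one guard-rail instance
  prob <- make_tiny_problem(seed = 95, n_per = 8, p = 3, m = 2)
  cc <- log(prob$n)
  lam <- 2; gam <- 1.5; al <- 0.4
  ctl <- spg_control(mu_stages = c(1e-2, 1e-4, 1e-6), max_iter = 3000,
                     tol = 1e-12)
  fit <- fit_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree, lambda = lam,
                       gamma = gam, alpha = al, standardize = FALSE,
                       control = ctl)
  f_spg <- oracle_objective(prob$Y, prob$X, prob$labels, fit$intercepts,
                            fit$coefficients, prob$tree, lam, gam, al, cc)
  orc <- admm_oracle(prob$Y, prob$X, prob$labels, prob$tree, lam, gam, al,
                     cc, rho = 5, iters = 3000)
  expect_equal(f_spg, orc$objective, tolerance = 1e-4)
})

test_that("without the tissue penalty the model separates per tissue", {
  # gamma = 0 and c = 0 decouple the tissues: the joint fit equals
  # independent tree-lasso fits stacked
  prob <- make_tiny_problem(seed = 96, n_per = 15, p = 3, m = 2,
                            n_tissues = 2)
  ctl <- spg_control(max_iter = 3000, tol = 1e-11)
  fm <- fit_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree, lambda = 1,
                      gamma = 0, alpha = 0, proxy_c = 0,
                      standardize = FALSE, control = ctl)
  for (t in 1:2) {
    idx <- prob$labels == paste0("g", t)
    ft <- fit_tree_lasso(prob$Y[idx, ], prob$X[idx, ], prob$tree, lambda = 1,
                         standardize = FALSE, control = ctl)
    expect_equal(fm$coefficients[[t]], ft$coefficients[[1]],
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("fits are deterministic and respect penalty continuity", {
  prob <- make_tiny_problem(seed = 99, n_per = 10, p = 4, m = 3,
                            missing_rate = 0.1)
  ctl <- spg_control(max_iter = 200)
  f1 <- fit_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree, lambda = 1,
                      gamma = 0.5, control = ctl)
  f2 <- fit_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree, lambda = 1,
                      gamma = 0.5, control = ctl)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$objective, f2$objective)
  # small lambda perturbation changes the objective continuously
  f3 <- fit_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree,
                      lambda = 1 + 1e-4, gamma = 0.5, control = ctl)
  expect_lt(abs(utils::tail(f3$objective, 1) - utils::tail(f1$objective, 1)),
            0.05)
})
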