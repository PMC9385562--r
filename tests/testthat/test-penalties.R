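test_that("group_shrink projects onto the unit ball", {
  expect_equal(group_shrink(c(0, 0)), c(0, 0))
  expect_equal(group_shrink(c(3, 4)), c(0.6, 0.8))
  expect_equal(group_shrink(c(0.3, 0.4)), c(0.3, 0.4))   # inside: identity
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(sample(1:6, 1), sd = 3)
    expect_lte(sqrt(sum(group_shrink(v)^2)), 1 + 1e-12)
  }
})

test_that("tree penalty matches hand computation and is homogeneous", {
  # one tissue, one feature, two drugs beta = (3, 4); leaves weight 1,
  # root weight 0.5; lambda = 1: leaves 3 + 4 = 7, root 0.5 * 5, total 9.5
  tr <- two_drug_tree(omega_root = 0.5)
  B <- matrix(c(3, 4), 1, 2)
  expect_equal(tree_penalty(B, tr, lambda = 1), 9.5)
  expect_equal(tree_penalty(B, tr, lambda = 2), 19)       # homogeneity
  expect_equal(tree_penalty(B * 0, tr, lambda = 1), 0)
  expect_equal(tree_penalty(B, tr, lambda = 1, include = "internal"), 2.5)
  expect_equal(tree_penalty(B, tr, lambda = 1, include = "leaf"), 7)
})

test_that("tree penalty agrees with the explicit group-loop oracle", {
  prob <- make_tiny_problem(seed = 21, p = 3, m = 4)
  set.seed(22)
  Bl <- lapply(1:2, function(t) matrix(rnorm(12), 3, 4))
  got <- tree_penalty(Bl, prob$tree, lambda = 0.7)
  want <- 0
  for (t in 1:2) for (j in 1:3) {
    for (v in seq_along(prob$tree$groups)) {
      want <- want + 0.7 * prob$tree$omega[v] *
        sqrt(sum(Bl[[t]][j, prob$tree$groups[[v]]]^2))
    }
    want <- want + 0.7 * sum(abs(Bl[[t]][j, ]))
  }
  expect_equal(got, want)
})

test_that("tissue penalty matches hand computations", {
  # T = 2, single (j, k), beta = (3, 4), gamma = 1:
  # alpha = 0 -> sqrt(2) * 5; alpha = 1 -> 7
  Bl <- list(matrix(3, 1, 1), matrix(4, 1, 1))
  expect_equal(tissue_penalty(Bl, gamma = 1, alpha = 0), 5 * sqrt(2))
  expect_equal(tissue_penalty(Bl, gamma = 1, alpha = 1), 7)
  expect_equal(tissue_penalty(Bl, gamma = 1, alpha = 0.5),
               0.5 * sqrt(2) * 5 + 0.5 * 7)
  expect_equal(tissue_penalty(lapply(Bl, function(B) B * 0), 1, 0.5), 0)
  # exponent 1 uses T instead of sqrt(T)
  expect_equal(tissue_penalty(Bl, gamma = 1, alpha = 0, t_exponent = 1), 10)
})

test_that("smoothed single-group values follow the Huber envelope", {
  # single root group (weight 1) over two drugs, one tissue, one feature
  tr <- two_drug_tree(omega_root = 1)
  # block norm 5 >= mu = 1: value = 5 - 0.5 = 4.5 (leaf terms not smoothed)
  sp <- smoothed_penalty(matrix(c(3, 4), 1, 2), tr, lambda = 1, mu = 1)
  expect_equal(sp$value, 4.5)
  # block norm 0.3 < mu = 1: quadratic branch 0.3^2 / 2 = 0.045
  sp2 <- smoothed_penalty(matrix(c(0.3, 0), 1, 2), tr, lambda = 1, mu = 1)
  expect_equal(sp2$value, 0.045)
  # B = 0 -> value 0, gradient 0
  sp0 <- smoothed_penalty(matrix(0, 1, 2), tr, lambda = 1, gamma = 0.5,
                          mu = 1)
  expect_equal(sp0$value, 0)
  expect_equal(sp0$grad[[1]], matrix(0, 1, 2))
  expect_error(smoothed_penalty(matrix(1, 1, 2), tr, lambda = 1, mu = 0),
               "mu")
})

test_that("sandwich bound f_mu <= Omega <= f_mu + mu * D holds", {
  prob <- make_tiny_problem(seed = 31, p = 4, m = 5)
  set.seed(32)
  for (mu in c(1, 0.1, 0.01)) {
    Bl <- lapply(1:2, function(t) matrix(rnorm(20, sd = 0.5), 4, 5))
    sp <- smoothed_penalty(Bl, prob$tree, lambda = 0.8, gamma = 0.6,
                           alpha = 0.3, mu = mu)
    omega_exact <- tree_penalty(Bl, prob$tree, 0.8, include = "internal") +
      (1 - 0.3) * 0.6 * sqrt(2) *
        sum(sqrt(Bl[[1]]^2 + Bl[[2]]^2))
    expect_lte(sp$value, omega_exact + 1e-10)
    expect_lte(omega_exact, sp$value + mu * sp$D + 1e-10)
  }
  # gap vanishes as mu -> 0
  Bl <- lapply(1:2, function(t) matrix(rnorm(20), 4, 5))
  gap <- function(mu) {
    sp <- smoothed_penalty(Bl, prob$tree, lambda = 0.8, gamma = 0.6,
                           alpha = 0.3, mu = mu)
    tree_penalty(Bl, prob$tree, 0.8, include = "internal") +
      0.7 * 0.6 * sqrt(2) * sum(sqrt(Bl[[1]]^2 + Bl[[2]]^2)) - sp$value
  }
  expect_lt(gap(1e-4), gap(1e-2))
  expect_lt(gap(1e-2), gap(1))
})

test_that("smoothed-penalty gradient matches central finite differences", {
  prob <- make_tiny_problem(seed = 41, p = 3, m = 4)
  set.seed(42)
  Bl <- lapply(1:2, function(t) matrix(rnorm(12, sd = 0.7), 3, 4))
  mu <- 0.05
  sp <- smoothed_penalty(Bl, prob$tree, lambda = 0.9, gamma = 0.4,
                         alpha = 0.3, mu = mu)
  fd <- numeric_grad(function(B) {
    smoothed_penalty(B, prob$tree, lambda = 0.9, gamma = 0.4, alpha = 0.3,
                     mu = mu)$value
  }, Bl)
  for (t in 1:2) {
    expect_equal(sp$grad[[t]], fd[[t]], tolerance = 1e-5)
  }
})

test_that("with one tissue and gamma 0 the smoothing reduces to tree lasso", {
  prob <- make_tiny_problem(seed = 51, p = 4, m = 3, n_tissues = 1)
  set.seed(52)
  B <- matrix(rnorm(12), 4, 3)
  sp_mix <- smoothed_penalty(list(B), prob$tree, lambda = 1.1, gamma = 0,
                             alpha = 0.5, mu = 0.02)
  sp_tree <- smoothed_penalty(B, prob$tree, lambda = 1.1, gamma = 0,
                              alpha = 0, mu = 0.02)
  expect_equal(sp_mix$value, sp_tree$value)
  expect_equal(sp_mix$grad[[1]], sp_tree$grad[[1]])
  expect_equal(sp_mix$n_blocks, 4 * length(prob$tree$groups))
})
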