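test_that("cross-validation is deterministic and honors the grid", {
  prob <- make_tiny_problem(seed = 131, n_per = 12, p = 4, m = 3,
                            missing_rate = 0.1)
  ctl <- spg_control(max_iter = 80)
  cv1 <- cv_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree,
                      lambda = 0.8, gamma = 0.4, nfolds = 3, seed = 5,
                      control = ctl)
  # single grid point: that point is returned
  expect_equal(cv1$best$lambda, 0.8)
  expect_equal(cv1$best$gamma, 0.4)
  expect_equal(nrow(cv1$summary), 1)
  # identical seed reproduces folds and scores exactly
  cv2 <- cv_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree,
                      lambda = 0.8, gamma = 0.4, nfolds = 3, seed = 5,
                      control = ctl)
  expect_identical(cv1$table, cv2$table)
  # duplicate grid points give identical scores
  cv3 <- cv_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree,
                      lambda = c(0.8, 0.8), gamma = 0.4, nfolds = 3, seed = 5,
                      control = ctl, warm_start = FALSE)
  expect_equal(cv3$summary$rmse, cv1$summary$rmse, tolerance = 1e-10)
})

test_that("cross-validation refuses folds that lose a tissue", {
  prob <- make_tiny_problem(seed = 132, n_per = 2, p = 3, m = 2)
  expect_error(
    cv_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree, lambda = 1,
                 nfolds = 3, control = spg_control(max_iter = 20)),
    "smaller than the number of folds")
})

test_that("CV on sparse data selects a positive penalty", {
  des <- simulation_design(scenario = 1, scale = "reduced", m = 8, p = 50,
                           n = 60, n_tissues = 2, n_blocks = 5)
  dat <- simulate_dataset(des, seed = 13)
  tree <- build_drug_tree(dat$Y, use = "pairwise.complete.obs")
  cv <- cv_mix_lasso(dat$Y, dat$X, dat$tissues, tree,
                     lambda = c(5, 1, 0.2), gamma = 0.5, seed = 2,
                     control = spg_control(max_iter = 80, mu = 1e-2))
  expect_gt(cv$best$lambda, 0)
  expect_equal(nrow(cv$summary), 3)
})

test_that("repeated hold-out evaluates per tissue-drug cell and records supports", {
  prob <- make_tiny_problem(seed = 141, n_per = 16, p = 4, m = 3,
                            missing_rate = 0.1)
  ho <- repeated_holdout_evaluate(prob$Y, prob$X, prob$labels, prob$tree,
                                  model = "mix", lambda = 0.6, gamma = 0.3,
                                  repeats = 3, seed = 9,
                                  control = spg_control(max_iter = 60))
  expect_equal(sort(unique(ho$metrics$repeat_id)), 1:3)
  expect_equal(nrow(ho$metrics), 3 * 2 * 3)       # repeats x tissues x drugs
  # identical seed reproduces everything
  ho2 <- repeated_holdout_evaluate(prob$Y, prob$X, prob$labels, prob$tree,
                                   model = "mix", lambda = 0.6, gamma = 0.3,
                                   repeats = 3, seed = 9,
                                   control = spg_control(max_iter = 60))
  expect_identical(ho$metrics, ho2$metrics)
  # train_frac = 1 with one repeat equals in-sample evaluation
  ho3 <- repeated_holdout_evaluate(prob$Y, prob$X, prob$labels, prob$tree,
                                   model = "mix", lambda = 0.6, gamma = 0.3,
                                   train_frac = 1, repeats = 1, seed = 9,
                                   control = spg_control(max_iter = 60))
  fit <- fit_mix_lasso(prob$Y, prob$X, prob$labels, prob$tree, lambda = 0.6,
                       gamma = 0.3, control = spg_control(max_iter = 60))
  pred <- predict(fit, prob$X, tissues = prob$labels)
  insample <- mixlasso:::evaluate_predictions(prob$Y, pred, prob$labels)
  expect_equal(ho3$metrics$rmse, insample$rmse, tolerance = 1e-10)
})

test_that("perfect predictions give rmse 0 and spearman 1", {
  Y <- matrix(rnorm(30), 10, 3)
  ev <- mixlasso:::evaluate_predictions(Y, Y, rep("a", 10))
  expect_equal(ev$rmse, rep(0, 3))
  expect_equal(ev$spearman, rep(1, 3))
  # fewer than 3 observed points: spearman undefined
  Y2 <- Y; Y2[3:10, 1] <- NA
  ev2 <- mixlasso:::evaluate_predictions(Y2, Y2, rep("a", 10))
  expect_true(is.na(ev2$spearman[1]))
})

test_that("selection frequency thresholds and is monotone in r", {
  sel <- tibble::tibble(
    repeat_id = c(1, 2, 1, 1, 2, 3, 4, 5),
    tissue = "t1",
    drug = c("d1", "d1", "d2", "d3", "d3", "d3", "d3", "d3"),
    feature = c("f1", "f1", "f2", "f3", "f3", "f3", "f3", "f3")
  )
  s2 <- selection_frequency(sel, r = 2)
  expect_setequal(s2$selected$feature, c("f1", "f3"))
  s5 <- selection_frequency(sel, r = 5)
  expect_equal(s5$selected$feature, "f3")
  s1 <- selection_frequency(sel, r = 1)
  expect_equal(nrow(s1$selected), 3)              # union of supports
  # raising r never adds triples
  expect_true(all(s5$selected$feature %in% s2$selected$feature))
  # empty input
  s0 <- selection_frequency(sel[0, ], r = 2)
  expect_equal(nrow(s0$selected), 0)
})

test_that("Lance-Williams distance follows the per-element ratio form", {
  expect_equal(lance_williams_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(lance_williams_distance(c(1, 0), c(0, 1)), 2)
  expect_equal(lance_williams_distance(c(2, 2), c(1, 1)), 2 / 3)
  # 0/0 summands contribute zero
  expect_equal(lance_williams_distance(c(0, 2), c(0, 1)), 1 / 3)
  # symmetry and the per-element bound
  set.seed(151)
  for (i in 1:10) {
    x <- rpois(20, 5); y <- rpois(20, 5)
    d <- lance_williams_distance(x, y)
    expect_equal(d, lance_williams_distance(y, x))
    expect_lte(d, 20)
    # agreement with base dist(canberra) on nonnegative vectors
    expect_equal(d, as.numeric(dist(rbind(x, y), method = "canberra")))
  }
  expect_error(lance_williams_distance(c(-1, 1), c(1, 1)), "nonnegative")
})

test_that("Wilcoxon comparison handles ties, direction, and symmetry", {
  a <- seq(0.1, 0.9, length.out = 10)
  # identical tables: all zero differences -> p = 1
  res0 <- compare_models_wilcoxon(a, a)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$direction, 0)
  # uniform shift: all positive differences (tied magnitudes force the
  # normal approximation); matches the rank-test oracle and is tiny
  res1 <- compare_models_wilcoxon(a, a + 1)
  expect_equal(res1$p_value,
               suppressWarnings(wilcox.test(a + 1, a, paired = TRUE,
                                            correct = TRUE)$p.value))
  expect_lt(res1$p_value, 0.01)
  expect_equal(res1$direction, 1)
  # swapping inputs flips the direction, same p
  res2 <- compare_models_wilcoxon(a + 1, a)
  expect_equal(res2$p_value, res1$p_value)
  expect_equal(res2$direction, -1)
  # agreement with stats::wilcox.test on a random untied instance
  set.seed(161)
  b <- a + rnorm(10, 0.2, 0.3)
  expect_equal(compare_models_wilcoxon(a, b)$p_value,
               wilcox.test(b, a, paired = TRUE, exact = TRUE)$p.value)
  # too few pairs
  expect_error(compare_models_wilcoxon(a[1:4], a[1:4] + 1), "6 valid pairs")
  # NA pairs are dropped before testing
  a2 <- a; a2[1] <- NA
  expect_equal(compare_models_wilcoxon(a2, a2 + 1)$n_pairs, 9)
})

test_that("feature-selection AUC follows the rank formula", {
  expect_equal(feature_selection_auc(c(1, 0.5, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(feature_selection_auc(c(0, 0, 1, 2), c(1, 1, 0, 0)), 0)
  # truth recovered exactly scores 1 even with magnitude variation
  truth <- matrix(c(0.5, 0, -0.7, 0), 2, 2)
  expect_equal(feature_selection_auc(truth, truth != 0), 1)
  # chance level for randomly permuted scores
  set.seed(171)
  y <- rep(c(0, 1), each = 500)
  aucs <- replicate(20, feature_selection_auc(sample(seq_len(1000)), y))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  expect_error(feature_selection_auc(c(1, 2), c(1, 1)), "both zero and nonzero")
})
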