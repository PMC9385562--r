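# Data-adaptive anchor for the penalty grid: the largest absolute gradient
# entry of the quadratic loss at the null model (B = 0, intercepts = observed
# drug means), on standardized predictors — the analogue of glmnet's
# lambda_max for this loss.
lambda_anchor <- function(Y, X, design, cc, observed = NULL) {
  obs <- resolve_observed(Y, observed)
  Xs <- standardize_predictors(X)$X
  g_max <- 0
  for (t in seq_len(design$n_groups)) {
    idx <- which(as.integer(design$labels) == t)
    n_t <- length(idx)
    Mt <- obs[idx, , drop = FALSE] * 1
    Yt <- Y[idx, , drop = FALSE]
    Yt[Mt == 0 | is.na(Yt)] <- 0
    mean_t <- ifelse(colSums(Mt) > 0, colSums(Yt) / pmax(colSums(Mt), 1), 0)
    R <- Mt * (Yt - matrix(mean_t, n_t, ncol(Y), byrow = TRUE))
    d_t <- cc / (1 + cc * n_t)
    Q <- R - matrix(d_t * colSums(R), n_t, ncol(Y), byrow = TRUE)
    G <- crossprod(Xs[idx, , drop = FALSE], Mt * Q)
    g_max <- max(g_max, max(abs(G)))
  }
  g_max
}

#' Run the mix-lasso versus tree-lasso simulation benchmark
#'
#' For each scenario: repeatedly simulate a dataset, estimate the drug tree
#' from the (incomplete) training responses with pairwise-complete
#' correlations, tune each model by stratified 3-fold cross-validation over a
#' data-adaptive penalty grid, fit on the full training set, predict the
#' fresh validation set, and score per-(group, drug) Spearman correlation and
#' RMSE plus feature-selection ROC AUC against the true support. Per-cell
#' correlations are averaged over the simulations and the two models are
#' compared by a paired two-sided Wilcoxon signed-rank test.
#'
#' @param design A [simulation_design()]; its scenario is replaced by each
#'   element of `scenarios` in turn (group values re-derived per scenario).
#' @param scenarios Integer vector of scenario ids to run.
#' @param seed Master seed; per-simulation seeds are derived as
#'   `seed + 1000 * scenario + sim`.
#' @param lambda_frac Fractions of the data-adaptive anchor forming the
#'   lambda grid (default `c(0.08, 0.03, 0.01)`).
#' @param gamma_ratio Tissue-penalty level as a multiple of lambda for the
#'   mix-lasso grid (default 1; the grid ties gamma to lambda).
#' @param alpha Sparse-group mixing weight for mix-lasso (default 0.5).
#' @param nfolds Cross-validation folds (default 3).
#' @param cv_control,fit_control [spg_control()] settings for the
#'   cross-validation fits and the final fits.
#' @param verbose Print per-simulation progress.
#' @return A list of class `mixlasso_benchmark`: `metrics` (per sim x model
#'   x tissue x drug), `summary` (per-cell means over sims), `tests` (paired
#'   Wilcoxon per scenario, on Spearman and on RMSE), `auc` (per sim and
#'   model), `auc_summary`, and the settings.
#' @export
run_benchmark <- function(design = simulation_design(scale = "reduced"),
                          scenarios = design$scenario, seed = 1,
                          lambda_frac = c(0.08, 0.03, 0.01), gamma_ratio = 1,
                          alpha = 0.5, nfolds = 3,
                          cv_control = spg_control(mu = 1e-2, max_iter = 150,
                                                   tol = 1e-5),
                          fit_control = spg_control(mu = 1e-2, max_iter = 400,
                                                    tol = 1e-6),
                          verbose = FALSE) {
  metrics <- list(); aucs <- list(); failures <- list()
  for (s in scenarios) {
    des <- simulation_design(
      scenario = s, scale = design$scale, m = design$m, n = design$n,
      n_tissues = design$n_tissues, p = design$p, n_val = design$n_val,
      n_blocks = design$n_blocks, block_cor = design$block_cor,
      v_cor = design$v_cor, missing_rate = design$missing_rate,
      n_sims = design$n_sims
    )
    truth <- make_true_coefficients(des)
    for (i in seq_len(des$n_sims)) {
      sim_seed <- seed + 1000L * s + i
      res <- tryCatch(
        benchmark_one(des, truth, sim_seed, lambda_frac, gamma_ratio, alpha,
                      nfolds, cv_control, fit_control),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- tibble::tibble(
          scenario = s, sim = i, message = conditionMessage(res))
        next
      }
      res$metrics$scenario <- s; res$metrics$sim <- i
      res$auc$scenario <- s; res$auc$sim <- i
      metrics[[length(metrics) + 1L]] <- res$metrics
      aucs[[length(aucs) + 1L]] <- res$auc
      if (verbose) {
        message(sprintf("scenario %d sim %d done (seed %d)", s, i, sim_seed))
      }
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  aucs <- dplyr::bind_rows(aucs)
  summary <- metrics |>
    dplyr::group_by(.data$scenario, .data$model, .data$tissue, .data$drug) |>
    dplyr::summarise(spearman = mean(.data$spearman, na.rm = TRUE),
                     rmse = mean(.data$rmse, na.rm = TRUE), .groups = "drop")
  tests <- summary |>
    dplyr::group_by(.data$scenario) |>
    dplyr::group_modify(function(df, key) {
      mix <- dplyr::filter(df, .data$model == "mix")
      tre <- dplyr::filter(df, .data$model == "tree")
      dplyr::bind_rows(
        dplyr::mutate(compare_models_wilcoxon(tre, mix, "spearman"),
                      metric = "spearman"),
        dplyr::mutate(compare_models_wilcoxon(tre, mix, "rmse"),
                      metric = "rmse")
      )
    }) |>
    dplyr::ungroup()
  auc_summary <- aucs |>
    dplyr::group_by(.data$scenario, .data$model) |>
    dplyr::summarise(auc = mean(.data$auc), .groups = "drop")
  structure(
    list(metrics = metrics, summary = summary, tests = tests, auc = aucs,
         auc_summary = auc_summary,
         failures = dplyr::bind_rows(failures),
         design = design, scenarios = scenarios, seed = seed,
         lambda_frac = lambda_frac, gamma_ratio = gamma_ratio, alpha = alpha),
    class = "mixlasso_benchmark"
  )
}

# One simulation repeat: simulate, tune by CV, fit, evaluate.
benchmark_one <- function(des, truth, sim_seed, lambda_frac, gamma_ratio,
                          alpha, nfolds, cv_control, fit_control) {
  dat <- simulate_dataset(des, truth, seed = sim_seed)
  design <- tissue_design(dat$tissues)
  tree <- build_drug_tree(dat$Y, use = "pairwise.complete.obs")
  cc <- log(des$n)

  lam0_mix <- lambda_anchor(dat$Y, dat$X, design, cc)
  grid_mix <- data.frame(lambda = lam0_mix * sort(lambda_frac, decreasing = TRUE))
  grid_mix$gamma <- gamma_ratio * grid_mix$lambda
  grid_mix$alpha <- alpha
  cv_mix <- cv_engine(dat$Y, dat$X, design, tree, grid_mix, "mix", nfolds,
                      sim_seed, "rmse", "logn", 0.5, NULL, cv_control)

  d_all <- tissue_design(rep("all", des$n))
  lam0_tree <- lambda_anchor(dat$Y, dat$X, d_all, 0)
  grid_tree <- data.frame(lambda = lam0_tree * sort(lambda_frac,
                                                    decreasing = TRUE),
                          gamma = 0, alpha = 0)
  cv_tree <- cv_engine(dat$Y, dat$X, d_all, tree, grid_tree, "tree", nfolds,
                       sim_seed, "rmse", "none", 0.5, NULL, cv_control,
                       allow_missing = TRUE)

  fit_mix <- fit_mix_lasso(dat$Y, dat$X, design, tree,
                           lambda = cv_mix$best$lambda,
                           gamma = cv_mix$best$gamma, alpha = alpha,
                           control = fit_control)
  fit_tree <- fit_tree_lasso(dat$Y, dat$X, tree,
                             lambda = cv_tree$best$lambda,
                             allow_missing = TRUE, control = fit_control)

  pred_mix <- predict(fit_mix, dat$X_val, tissues = dat$tissues_val)
  pred_tree <- predict(fit_tree, dat$X_val)
  ev_mix <- evaluate_predictions(dat$Y_val, pred_mix, dat$tissues_val)
  ev_tree <- evaluate_predictions(dat$Y_val, pred_tree, dat$tissues_val)
  ev_mix$model <- "mix"; ev_tree$model <- "tree"

  support <- dat$truth$support
  auc <- tibble::tibble(
    model = c("mix", "tree"),
    auc = c(
      feature_selection_auc(fit_mix$coefficients,
                            rep(list(support), length(fit_mix$coefficients))),
      feature_selection_auc(fit_tree$coefficients[[1L]], support)
    )
  )
  list(metrics = dplyr::bind_rows(ev_mix, ev_tree), auc = auc)
}

#' @export
print.mixlasso_benchmark <- function(x, ...) {
  cat("<mixlasso_benchmark> scenarios ", paste(x$scenarios, collapse = ", "),
      ", ", x$design$n_sims, " sims each, seed ", x$seed, "\n", sep = "")
  print(x$tests)
  print(x$auc_summary)
  if (nrow(x$failures)) {
    cat(nrow(x$failures), "simulation(s) failed\n")
  }
  invisible(x)
}
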