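# Stratified fold assignment: within every tissue the samples are spread
# evenly over the k folds, so no fold can lose an entire tissue.
stratified_folds <- function(design, k, seed) {
  if (any(design$sizes < k)) {
    stop("tissue(s) smaller than the number of folds: ",
         paste(names(design$sizes)[design$sizes < k], collapse = ", "),
         call. = FALSE)
  }
  folds <- integer(design$n)
  set.seed(seed)
  for (t in seq_len(design$n_groups)) {
    idx <- which(as.integer(design$labels) == t)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

cv_engine <- function(Y, X, design, tree, grid, model, nfolds, seed, metric,
                      proxy_c, t_exponent, lambda_factors, control,
                      allow_missing = TRUE, warm_start = TRUE) {
  folds <- stratified_folds(design, nfolds, seed)
  rows <- list()
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    va <- !tr
    d_tr <- tissue_design(as.character(design$labels)[tr],
                          levels = levels(design$labels))
    init <- NULL
    for (gi in seq_len(nrow(grid))) {
      gpt <- grid[gi, ]
      fit <- if (model == "mix") {
        fit_mix_lasso(Y[tr, , drop = FALSE], X[tr, , drop = FALSE], d_tr,
                      tree, lambda = gpt$lambda, gamma = gpt$gamma,
                      alpha = gpt$alpha, proxy_c = proxy_c,
                      t_exponent = t_exponent,
                      lambda_factors = lambda_factors,
                      control = control, init = init)
      } else {
        fit_tree_lasso(Y[tr, , drop = FALSE], X[tr, , drop = FALSE], tree,
                       lambda = gpt$lambda, lambda_factors = lambda_factors,
                       allow_missing = allow_missing, control = control,
                       init = init)
      }
      if (warm_start) init <- fit$B_internal
      pred <- predict(fit, X[va, , drop = FALSE],
                      tissues = if (model == "mix")
                        as.character(design$labels)[va] else NULL)
      obs <- Y[va, , drop = FALSE]
      ok <- !is.na(obs)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lambda = gpt$lambda, gamma = gpt$gamma, alpha = gpt$alpha, fold = f,
        rmse = sqrt(mean((obs[ok] - pred[ok])^2)),
        spearman = suppressWarnings(cor(obs[ok], pred[ok],
                                        method = "spearman")),
        n_obs = sum(ok)
      )
    }
  }
  table <- dplyr::bind_rows(rows)
  summary <- table |>
    dplyr::group_by(.data$lambda, .data$gamma, .data$alpha) |>
    dplyr::summarise(rmse = mean(.data$rmse),
                     spearman = mean(.data$spearman), .groups = "drop")
  best <- if (metric == "rmse") {
    summary[which.min(summary$rmse), ]
  } else {
    summary[which.max(summary$spearman), ]
  }
  structure(
    list(table = table, summary = summary,
         best = list(lambda = best$lambda, gamma = best$gamma,
                     alpha = best$alpha),
         metric = metric, model = model, nfolds = nfolds, seed = seed),
    class = "mixlasso_cv"
  )
}

#' @export
print.mixlasso_cv <- function(x, ...) {
  cat("<mixlasso_cv> ", x$model, "-lasso, ", x$nfolds, "-fold, metric ",
      x$metric, "\n", sep = "")
  cat("best: lambda = ", x$best$lambda, ", gamma = ", x$best$gamma,
      ", alpha = ", x$best$alpha, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Cross-validate mix-lasso penalty parameters
#'
#' k-fold cross-validation (folds stratified by tissue, deterministic given
#' `seed`) over a grid of penalty parameters; the selected point minimizes
#' mean held-out RMSE over observed validation entries (or maximizes mean
#' Spearman correlation with `metric = "spearman"`).
#'
#' @inheritParams fit_mix_lasso
#' @param lambda,gamma,alpha Grid values; the grid is their cross product.
#' @param nfolds Number of folds (default 3).
#' @param seed Integer seed controlling the fold assignment.
#' @param metric `"rmse"` (default) or `"spearman"`.
#' @param warm_start Warm-start successive grid points within a fold.
#' @return A `mixlasso_cv` object: per-fold `table`, per-point `summary`,
#'   and `best` parameters.
#' @export
cv_mix_lasso <- function(Y, X, tissues, tree, lambda, gamma = 0, alpha = 0.5,
                         nfolds = 3, seed = 1, metric = c("rmse", "spearman"),
                         proxy_c = "logn", t_exponent = 0.5,
                         lambda_factors = NULL, control = spg_control(),
                         warm_start = TRUE) {
  metric <- match.arg(metric)
  design <- if (inherits(tissues, "tissue_design")) tissues else tissue_design(tissues)
  grid <- expand.grid(lambda = sort(lambda, decreasing = TRUE), gamma = gamma,
                      alpha = alpha, KEEP.OUT.ATTRS = FALSE)
  cv_engine(Y, X, design, tree, grid, "mix", nfolds, seed, metric, proxy_c,
            t_exponent, lambda_factors, control, warm_start = warm_start)
}

#' Cross-validate the tree-lasso penalty
#'
#' @inheritParams cv_mix_lasso
#' @inheritParams fit_tree_lasso
#' @return A `mixlasso_cv` object.
#' @export
cv_tree_lasso <- function(Y, X, tree, lambda, nfolds = 3, seed = 1,
                          metric = c("rmse", "spearman"),
                          lambda_factors = NULL, allow_missing = FALSE,
                          control = spg_control(), warm_start = TRUE) {
  metric <- match.arg(metric)
  if (!allow_missing && anyNA(Y)) {
    stop("tree lasso requires complete responses; ",
         "use allow_missing = TRUE", call. = FALSE)
  }
  design <- tissue_design(rep("all", nrow(Y)))
  grid <- expand.grid(lambda = sort(lambda, decreasing = TRUE), gamma = 0,
                      alpha = 0, KEEP.OUT.ATTRS = FALSE)
  cv_engine(Y, X, design, tree, grid, "tree", nfolds, seed, metric, "none",
            0.5, lambda_factors, control, allow_missing = allow_missing,
            warm_start = warm_start)
}

#' Repeated stratified hold-out evaluation
#'
#' Splits the samples into training and validation fractions (75% / 25% by
#' convention), stratified within each tissue, fits the model on the training
#' part and evaluates per-(tissue, drug) Spearman correlation and RMSE on the
#' observed validation entries; repeated `repeats` times. The nonzero
#' coefficient pattern of every repeat is retained for selection-frequency
#' stability analysis. Tissues too small to split are dropped with a warning.
#'
#' @inheritParams cv_mix_lasso
#' @param model `"mix"` or `"tree"`.
#' @param train_frac Training fraction (default 0.75).
#' @param repeats Number of repeated splits (default 10).
#' @return A `mixlasso_holdout` object: `metrics` (tibble: repeat, tissue,
#'   drug, spearman, rmse, n_obs), `selected` (tibble: repeat, tissue, drug,
#'   feature), and the settings.
#' @export
repeated_holdout_evaluate <- function(Y, X, tissues, tree,
                                      model = c("mix", "tree"),
                                      lambda, gamma = 0, alpha = 0.5,
                                      train_frac = 0.75, repeats = 10,
                                      seed = 1, proxy_c = "logn",
                                      t_exponent = 0.5, lambda_factors = NULL,
                                      control = spg_control()) {
  model <- match.arg(model)
  design <- if (inherits(tissues, "tissue_design")) tissues else tissue_design(tissues)
  n_train <- floor(train_frac * design$sizes)
  splittable <- n_train >= 1 & (design$sizes - n_train) >= ifelse(train_frac < 1, 1, 0)
  if (!all(splittable)) {
    warning("tissue(s) too small to split, excluded: ",
            paste(names(design$sizes)[!splittable], collapse = ", "))
  }
  keep <- as.character(design$labels) %in% names(design$sizes)[splittable]
  Yk <- Y[keep, , drop = FALSE]; Xk <- X[keep, , drop = FALSE]
  dk <- tissue_design(as.character(design$labels)[keep],
                      levels = names(design$sizes)[splittable])
  metrics <- list(); selected <- list()
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    tr <- logical(dk$n)
    for (t in seq_len(dk$n_groups)) {
      idx <- which(as.integer(dk$labels) == t)
      tr[sample(idx, floor(train_frac * length(idx)))] <- TRUE
    }
    if (train_frac >= 1) tr[] <- TRUE
    labs_tr <- as.character(dk$labels)[tr]
    fit <- if (model == "mix") {
      fit_mix_lasso(Yk[tr, , drop = FALSE], Xk[tr, , drop = FALSE],
                    tissue_design(labs_tr, levels = levels(dk$labels)), tree,
                    lambda = lambda, gamma = gamma, alpha = alpha,
                    proxy_c = proxy_c, t_exponent = t_exponent,
                    lambda_factors = lambda_factors, control = control)
    } else {
      fit_tree_lasso(Yk[tr, , drop = FALSE], Xk[tr, , drop = FALSE], tree,
                     lambda = lambda, lambda_factors = lambda_factors,
                     allow_missing = TRUE, control = control)
    }
    va <- if (train_frac >= 1) rep(TRUE, dk$n) else !tr
    pred <- predict(fit, Xk[va, , drop = FALSE],
                    tissues = if (model == "mix")
                      as.character(dk$labels)[va] else NULL)
    ev <- evaluate_predictions(Yk[va, , drop = FALSE], pred,
                               as.character(dk$labels)[va])
    ev$repeat_id <- r
    metrics[[r]] <- ev
    sel <- active_set(fit)
    if (nrow(sel)) sel$repeat_id <- r
    selected[[r]] <- sel
  }
  structure(
    list(metrics = dplyr::bind_rows(metrics),
         selected = dplyr::bind_rows(selected),
         model = model, lambda = lambda, gamma = gamma, alpha = alpha,
         train_frac = train_frac, repeats = repeats, seed = seed),
    class = "mixlasso_holdout"
  )
}

#' @export
print.mixlasso_holdout <- function(x, ...) {
  cat("<mixlasso_holdout> ", x$model, "-lasso, ", x$repeats, " repeats, ",
      round(100 * x$train_frac), "% training\n", sep = "")
  print(dplyr::summarise(x$metrics,
                         mean_spearman = mean(.data$spearman, na.rm = TRUE),
                         mean_rmse = mean(.data$rmse, na.rm = TRUE)))
  invisible(x)
}

#' Selection frequency over repeated splits
#'
#' A (tissue, feature, drug) triple counts as selected when its coefficient
#' is nonzero in at least `r` of the repeats (the conventions are r = 2 and
#' r = 5 out of 10). A feature is counted once per drug it predicts, so
#' per-tissue counts can exceed the number of distinct features.
#'
#' @param x A `mixlasso_holdout` object, or a tibble with columns
#'   `repeat_id`, `tissue`, `drug`, `feature`.
#' @param r Minimum number of repeats (inclusive).
#' @param source_of Optional named vector mapping feature names to omics
#'   sources, for per-source counts.
#' @return A list of class `selection_frequency`: `selected` (tibble:
#'   tissue, feature, drug, count), `by_tissue`, optionally `by_source`,
#'   and `r`.
#' @export
selection_frequency <- function(x, r, source_of = NULL) {
  sel <- if (inherits(x, "mixlasso_holdout")) x$selected else x
  stopifnot(r >= 1)
  if (nrow(sel) == 0L) {
    counts <- tibble::tibble(tissue = character(), feature = character(),
                             drug = character(), count = integer())
  } else {
    counts <- sel |>
      dplyr::count(.data$tissue, .data$feature, .data$drug, name = "count") |>
      dplyr::filter(.data$count >= r)
  }
  out <- list(
    selected = counts,
    by_tissue = dplyr::count(counts, .data$tissue, name = "n_selected"),
    r = r
  )
  if (!is.null(source_of) && nrow(counts)) {
    counts$source <- unname(source_of[counts$feature])
    out$by_source <- dplyr::count(counts, .data$tissue, .data$source,
                                  name = "n_selected")
    out$selected <- counts
  }
  class(out) <- "selection_frequency"
  out
}

#' @export
print.selection_frequency <- function(x, ...) {
  cat("<selection_frequency> r >= ", x$r, ": ", nrow(x$selected),
      " (tissue, feature, drug) triples\n", sep = "")
  print(x$by_tissue)
  invisible(x)
}
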