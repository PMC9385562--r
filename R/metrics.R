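# Held-out metric helpers. All metrics use observed entries only.

spearman_safe <- function(obs, pred) {
  ok <- !is.na(obs) & !is.na(pred)
  if (sum(ok) < 3L) return(NA_real_)
  if (sd(obs[ok]) == 0 || sd(pred[ok]) == 0) return(NA_real_)
  cor(obs[ok], pred[ok], method = "spearman")
}

rmse_observed <- function(obs, pred) {
  ok <- !is.na(obs) & !is.na(pred)
  if (!any(ok)) return(NA_real_)
  sqrt(mean((obs[ok] - pred[ok])^2))
}

# Per-(tissue, drug) Spearman and RMSE between an observed and a predicted
# response matrix.
evaluate_predictions <- function(Y, pred, tissues) {
  design <- if (inherits(tissues, "tissue_design")) tissues else tissue_design(tissues)
  drugs <- colnames(Y); if (is.null(drugs)) drugs <- paste0("y", seq_len(ncol(Y)))
  rows <- list()
  for (t in seq_len(design$n_groups)) {
    idx <- which(as.integer(design$labels) == t)
    for (k in seq_len(ncol(Y))) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tissue = levels(design$labels)[t],
        drug = drugs[k],
        spearman = spearman_safe(Y[idx, k], pred[idx, k]),
        rmse = rmse_observed(Y[idx, k], pred[idx, k]),
        n_obs = sum(!is.na(Y[idx, k]))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Feature-selection ROC AUC against a known support
#'
#' Scores every coefficient by its magnitude and asks how well magnitude
#' ranks truly nonzero coefficients above truly zero ones: the area under the
#' ROC curve by the rank (Mann-Whitney) formula with midranks for ties.
#'
#' @param estimate Estimated coefficients (matrix, list of per-tissue
#'   matrices, or array) — magnitudes are used as scores.
#' @param truth Ground-truth support of the same shape (nonzero = relevant),
#'   logical or numeric.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' feature_selection_auc(c(0.9, 0.5, 0, 0.1), c(1, 1, 0, 0))
feature_selection_auc <- function(estimate, truth) {
  s <- abs(unlist(estimate, use.names = FALSE))
  y <- unlist(truth, use.names = FALSE) != 0
  if (length(s) != length(y)) stop("shape mismatch", call. = FALSE)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop("truth must contain both zero and nonzero coefficients", call. = FALSE)
  }
  r <- rank(s, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired Wilcoxon comparison of two accuracy tables
#'
#' Two-sided Wilcoxon signed-rank test over paired per-(tissue, drug)
#' accuracy values (e.g., validation Spearman correlations averaged over
#' simulation repeats) of two models. Pairs with an undefined value are
#' dropped; zero differences follow the signed-rank zero-discard convention
#' (all-zero differences give p = 1). The exact distribution is used for at
#' most 25 untied pairs, the normal approximation otherwise.
#'
#' @param a,b Numeric vectors of paired accuracy values (same length and
#'   order), or data frames with columns `tissue`, `drug`, and a metric
#'   column named by `metric` which are joined on (tissue, drug).
#' @param metric Metric column when `a` and `b` are data frames.
#' @return A one-row tibble: `p_value`, `direction` (+1 if `b` tends larger,
#'   -1 if `a`, 0 for a tie), `median_diff` (median of `b - a`), `n_pairs`.
#' @export
compare_models_wilcoxon <- function(a, b, metric = "spearman") {
  if (is.data.frame(a)) {
    j <- dplyr::inner_join(
      dplyr::select(a, "tissue", "drug", a_val = dplyr::all_of(metric)),
      dplyr::select(b, "tissue", "drug", b_val = dplyr::all_of(metric)),
      by = c("tissue", "drug")
    )
    a <- j$a_val; b <- j$b_val
  }
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 6L) {
    stop("fewer than 6 valid pairs; the signed-rank test is not meaningful",
         call. = FALSE)
  }
  d <- b - a
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    return(tibble::tibble(p_value = 1, direction = 0, median_diff = 0,
                          n_pairs = length(d)))
  }
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  p <- suppressWarnings(
    wilcox.test(nz, alternative = "two.sided", mu = 0, exact = exact,
                correct = TRUE)$p.value
  )
  tibble::tibble(p_value = p,
                 direction = sign(median(d)),
                 median_diff = median(d),
                 n_pairs = length(d))
}

#' Lance-Williams distance between selected-feature count vectors
#'
#' Per-element ratio form \eqn{\sum_i |x_i - y_i| / (|x_i| + |y_i|)} with the
#' convention that 0/0 summands contribute 0. Each summand lies in \[0, 1\],
#' so the statistic is bounded by the vector length; it quantifies how stable
#' per-tissue selected-feature counts are between two selection criteria
#' (smaller = more similar).
#'
#' @param x,y Nonnegative numeric vectors of equal length.
#' @return Nonnegative scalar, at most `length(x)`.
#' @export
#' @examples
#' lance_williams_distance(c(2, 2), c(1, 1))  # 2/3
lance_williams_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) {
    stop("Lance-Williams distance requires nonnegative entries", call. = FALSE)
  }
  den <- abs(x) + abs(y)
  num <- abs(x - y)
  sum(ifelse(den > 0, num / den, 0))
}
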