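#' Tissue design: group labels, indicator matrix and group sizes
#'
#' Encodes the assignment of the n samples to T sample groups (cancer tissue
#' types). The indicator matrix Z has one column per group with exactly one 1
#' per row; group order is the order of first appearance unless `levels` is
#' given.
#'
#' @param labels Vector (character/factor/integer) of length n with one group
#'   label per sample.
#' @param levels Optional explicit group order.
#' @return An object of class `tissue_design` with elements `labels` (factor),
#'   `Z` (n x T indicator matrix), `sizes` (named integer vector n_t),
#'   `n_groups` (T) and `n` (number of samples).
#' @export
tissue_design <- function(labels, levels = NULL) {
  if (length(labels) < 1L) stop("empty label vector", call. = FALSE)
  if (anyNA(labels)) stop("missing tissue labels are not allowed", call. = FALSE)
  if (is.null(levels)) levels <- unique(as.character(labels))
  f <- factor(as.character(labels), levels = levels)
  if (anyNA(f)) stop("labels outside the supplied levels", call. = FALSE)
  if (any(table(f) == 0L)) stop("every group must be nonempty", call. = FALSE)
  Z <- matrix(0L, length(f), nlevels(f),
              dimnames = list(names(labels), levels(f)))
  Z[cbind(seq_along(f), as.integer(f))] <- 1L
  structure(
    list(labels = f, Z = Z,
         sizes = setNames(as.integer(table(f)), levels(f)),
         n_groups = nlevels(f), n = length(f)),
    class = "tissue_design"
  )
}

#' @export
print.tissue_design <- function(x, ...) {
  cat("<tissue_design> ", x$n, " samples in ", x$n_groups, " groups\n", sep = "")
  print(x$sizes)
  invisible(x)
}

#' Drop sample groups below a minimum size
#'
#' Tissue-specific modeling needs a minimum number of samples per group; groups
#' with fewer than `min_size` members (the convention is 15 cell lines) are
#' removed together with their rows. The operation is idempotent.
#'
#' @param labels Group label vector (length n).
#' @param min_size Inclusive minimum group size (default 15).
#' @return A list with `keep` (logical row mask), `design` (a [tissue_design()]
#'   on the retained rows), and `groups` (a tibble with one row per input
#'   group: `tissue`, `n`, `kept`).
#' @export
#' @examples
#' filter_min_group_size(rep(c("a", "b", "c"), c(20, 14, 3)), min_size = 15)$groups
filter_min_group_size <- function(labels, min_size = 15) {
  stopifnot(min_size >= 1)
  tab <- table(factor(as.character(labels), levels = unique(as.character(labels))))
  kept_groups <- names(tab)[tab >= min_size]
  groups <- tibble::tibble(
    tissue = names(tab),
    n = as.integer(tab),
    kept = names(tab) %in% kept_groups
  )
  if (length(kept_groups) == 0L) {
    stop("no group reaches min_size = ", min_size, "; empty dataset", call. = FALSE)
  }
  keep <- as.character(labels) %in% kept_groups
  list(keep = keep,
       design = tissue_design(labels[keep], levels = kept_groups),
       groups = groups)
}

#' Select features by cumulative variance
#'
#' Orders features (columns) by descending variance and keeps the smallest
#' prefix whose summed variance reaches `fraction` of the total — the standard
#' "most variable features covering >= 50% of the cumulative variance" filter.
#' Variance uses the unbiased (n - 1) denominator; ties keep the original
#' column order, so the result is deterministic and invariant to column
#' permutation up to the tie rule.
#'
#' @param X Numeric matrix, samples in rows. Missing predictor values are not
#'   supported.
#' @param fraction Target fraction of total variance in (0, 1].
#' @return Integer vector of retained column indices, ordered by descending
#'   variance.
#' @export
#' @examples
#' X <- sapply(c(2, 1.5, 1, 0.5), function(s) rnorm(50, sd = s))
#' select_by_cumulative_variance(X, 0.5)
select_by_cumulative_variance <- function(X, fraction = 0.5) {
  stopifnot(is.matrix(X), fraction > 0, fraction <= 1)
  if (anyNA(X)) stop("missing predictor values are not supported", call. = FALSE)
  v <- apply(X, 2L, var)
  total <- sum(v)
  if (total <= 0) stop("all features are constant; total variance is zero",
                       call. = FALSE)
  ord <- order(v, decreasing = TRUE)  # ties keep original order
  k <- which(cumsum(v[ord]) >= fraction * total)[1L]
  ord[seq_len(k)]
}

#' Combine predictor matrices from several omics sources
#'
#' Column-binds per-source predictor matrices (rows = samples, identically
#' ordered across sources) and records the source block structure, so that
#' integrative penalty factors can penalize each source differently.
#'
#' @param ... Named numeric matrices, or a single named list of them.
#' @return A numeric matrix with attribute `source_blocks`, a named integer
#'   vector of block sizes p_s in column order.
#' @export
#' @examples
#' gex <- matrix(rnorm(20), 5, 4); mut <- matrix(rbinom(10, 1, .3), 5, 2)
#' X <- stack_omics(gex = gex, mut = mut)
#' attr(X, "source_blocks")
stack_omics <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !is.matrix(mats[[1L]])) {
    mats <- mats[[1L]]
  }
  if (is.null(names(mats)) || any(names(mats) == "")) {
    names(mats) <- paste0("source", seq_along(mats))
  }
  n <- unique(vapply(mats, nrow, 1L))
  if (length(n) != 1L) stop("sources have differing sample counts", call. = FALSE)
  for (nm in names(mats)) {
    if (anyNA(mats[[nm]])) {
      stop("missing predictor values are not supported (source ", nm, ")",
           call. = FALSE)
    }
  }
  X <- do.call(cbind, mats)
  attr(X, "source_blocks") <- vapply(mats, ncol, 1L)
  X
}

# Per-feature penalty multipliers from the source block structure.
# lambda_factors: named per-source multipliers (default all 1).
source_factor_vector <- function(p, source_blocks = NULL, lambda_factors = NULL) {
  if (is.null(source_blocks)) source_blocks <- c(all = p)
  stopifnot(sum(source_blocks) == p)
  if (is.null(lambda_factors)) {
    lambda_factors <- setNames(rep(1, length(source_blocks)), names(source_blocks))
  }
  if (is.null(names(lambda_factors)) && length(lambda_factors) == length(source_blocks)) {
    names(lambda_factors) <- names(source_blocks)
  }
  missing_src <- setdiff(names(source_blocks), names(lambda_factors))
  if (length(missing_src)) {
    stop("no penalty factor for source(s): ", paste(missing_src, collapse = ", "),
         call. = FALSE)
  }
  rep(as.numeric(lambda_factors[names(source_blocks)]), times = source_blocks)
}

# Center/scale predictors; binary (0/1) columns are centered only.
standardize_predictors <- function(X) {
  ctr <- colMeans(X)
  is_bin <- apply(X, 2L, function(col) all(col %in% c(0, 1)))
  scl <- apply(X, 2L, sd)
  scl[is_bin | scl <= 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  list(X = Xs, center = ctr, scale = scl)
}
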