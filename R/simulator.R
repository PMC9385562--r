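#' Simulation design for the benchmark study
#'
#' Describes the generator for the benchmark: m response variables (drugs),
#' n training samples from T equally sized groups (tissues), p features whose
#' covariance has equal diagonal blocks with constant within-block
#' correlation, compound-symmetric response noise within each tissue
#' (independent across drugs), a fraction of training responses missing at
#' random, and a fresh complete validation set. Four scenarios set the
#' per-group values of the nonzero coefficients:
#'
#' * scenario 1 — all groups 0.5 (homogeneous effects);
#' * scenario 2 — groups 1-2 at -0.5, the rest at 0.5 (opposite signs);
#' * scenario 3 — pairs of groups at 0.4, 0.6, 0.8, 1.0, 1.2 (varying scale);
#' * scenario 4 — signed values of varying scale per group (for T = 10:
#'   -0.7, -0.5, -0.3, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4; for T = 4:
#'   -0.7, -0.3, 0.6, 1.4).
#'
#' The full-scale defaults are m = 120, n = 300, T = 10, p = 1000, 10 blocks
#' at correlation 0.4, noise correlation 0.5, 5% missing, 50 simulations;
#' `scale = "reduced"` gives the down-scaled design m = 24, p = 200, T = 4,
#' n = 120, 10 simulations with the same correlations and missing rate.
#'
#' @param scenario Scenario id in 1..4.
#' @param scale `"full"` (default) or `"reduced"`.
#' @param m,n,n_tissues,p,n_val Dimensions (defaults from `scale`).
#' @param n_blocks Number of feature-covariance blocks (default 10).
#' @param block_cor Within-block feature correlation (default 0.4).
#' @param v_cor Within-tissue response-noise correlation (default 0.5).
#' @param missing_rate Fraction of training responses missing (default 0.05).
#' @param n_sims Number of simulation repeats.
#' @param group_values Optional explicit per-group nonzero coefficient values
#'   (length T), overriding the scenario preset (e.g. all zero for a
#'   no-signal control).
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(scenario = 1, scale = c("full", "reduced"),
                              m = NULL, n = NULL, n_tissues = NULL, p = NULL,
                              n_val = NULL, n_blocks = 10, block_cor = 0.4,
                              v_cor = 0.5, missing_rate = 0.05, n_sims = NULL,
                              group_values = NULL) {
  scale <- match.arg(scale)
  def <- if (scale == "full") {
    list(m = 120, n = 300, n_tissues = 10, p = 1000, n_sims = 50)
  } else {
    list(m = 24, n = 120, n_tissues = 4, p = 200, n_sims = 10)
  }
  m <- m %||% def$m; n <- n %||% def$n
  n_tissues <- n_tissues %||% def$n_tissues; p <- p %||% def$p
  n_sims <- n_sims %||% def$n_sims; n_val <- n_val %||% n
  if (!scenario %in% 1:4) stop("scenario must be 1, 2, 3, or 4", call. = FALSE)
  if (is.null(group_values)) {
    group_values <- scenario_values(scenario, n_tissues)
  }
  stopifnot(length(group_values) == n_tissues,
            n %% n_tissues == 0, block_cor >= 0, block_cor < 1,
            v_cor >= 0, v_cor < 1, missing_rate >= 0, missing_rate < 1)
  structure(
    list(scenario = scenario, scale = scale, m = m, n = n,
         n_tissues = n_tissues, p = p, n_val = n_val, n_blocks = n_blocks,
         block_cor = block_cor, v_cor = v_cor, missing_rate = missing_rate,
         n_sims = n_sims, group_values = group_values),
    class = "simulation_design"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-group nonzero coefficient values for each scenario.
scenario_values <- function(scenario, n_tissues) {
  Tn <- n_tissues
  switch(scenario,
    rep(0.5, Tn),
    {
      if (Tn < 3) stop("scenario 2 needs at least 3 groups", call. = FALSE)
      c(-0.5, -0.5, rep(0.5, Tn - 2))
    },
    0.4 + 0.2 * (ceiling(seq_len(Tn) / 2) - 1),
    {
      v10 <- c(-0.7, -0.5, -0.3, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4)
      if (Tn == 10) v10
      else if (Tn == 4) c(-0.7, -0.3, 0.6, 1.4)
      else v10[round(seq(1, 10, length.out = Tn))]
    }
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("<simulation_design> scenario ", x$scenario, " (", x$scale, "): m = ",
      x$m, ", n = ", x$n, ", T = ", x$n_tissues, ", p = ", x$p,
      ", missing ", 100 * x$missing_rate, "%, ", x$n_sims, " sims\n", sep = "")
  cat("group values: ", paste(x$group_values, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ground-truth coefficients with tree-structured support
#'
#' The support is shared by all groups and nested along the drug axis so it
#' is consistent with a drug dendrogram: features 1-5 affect all m drugs,
#' features 6-15 affect drugs 1..m/2, and features 16-35 affect drugs
#' 1..m/4 — 15 m nonzero coefficients per group (1800 at the full-scale
#' defaults). Values on the support are the design's per-group scenario
#' values.
#'
#' @param design A [simulation_design()].
#' @return A list of class `mixlasso_true_model`: `B` (list of p x m
#'   matrices per group), `support` (p x m logical, common to all groups),
#'   and `values` (per-group value vector).
#' @export
make_true_coefficients <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  m <- design$m; p <- design$p
  if (m %% 4 != 0) stop("m must be divisible by 4", call. = FALSE)
  if (p < 35) stop("p must be at least 35 for the default support layout",
                   call. = FALSE)
  support <- matrix(FALSE, p, m)
  support[1:5, seq_len(m)] <- TRUE
  support[6:15, seq_len(m / 2)] <- TRUE
  support[16:35, seq_len(m / 4)] <- TRUE
  B <- lapply(design$group_values, function(v) {
    Bt <- matrix(0, p, m)
    Bt[support] <- v
    Bt
  })
  names(B) <- paste0("g", seq_along(B))
  structure(list(B = B, support = support, values = design$group_values),
            class = "mixlasso_true_model")
}

# Draw n rows from N(0, Sigma_X) with equal compound-symmetric blocks.
draw_block_features <- function(n, p, n_blocks, rho) {
  sizes <- rep(p %/% n_blocks, n_blocks)
  extra <- p %% n_blocks
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  cols <- lapply(sizes, function(pb) {
    Z <- matrix(rnorm(n * pb), n, pb)
    shared <- rnorm(n)
    sqrt(1 - rho) * Z + sqrt(rho) * shared
  })
  X <- do.call(cbind, cols)
  colnames(X) <- paste0("x", seq_len(p))
  X
}

# Compound-symmetric noise per tissue: unit variance, correlation v across
# samples within the tissue, independent across drugs.
draw_cs_noise <- function(n_t, m, v) {
  Z <- matrix(rnorm(n_t * m), n_t, m)
  shared <- rnorm(m)
  sqrt(1 - v) * Z + sqrt(v) * matrix(shared, n_t, m, byrow = TRUE)
}

#' Simulate one benchmark dataset
#'
#' Generates training features, responses with compound-symmetric
#' within-tissue noise, a missing-at-random training mask, and a fresh
#' complete validation set, all per the design. All randomness flows from
#' `seed` through a fixed draw order, so datasets are reproducible.
#'
#' @param design A [simulation_design()].
#' @param true_model Optional [make_true_coefficients()] output (built from
#'   the design when omitted).
#' @param seed Integer seed.
#' @return A list of class `mixlasso_sim_data`: training `Y` (with `NA` for
#'   masked entries), `Y_complete`, `X`, `tissues`, validation `X_val`,
#'   `Y_val`, `tissues_val`, the `truth`, the `design`, and `seed`.
#' @export
simulate_dataset <- function(design, true_model = NULL, seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  if (is.null(true_model)) true_model <- make_true_coefficients(design)
  Tn <- design$n_tissues
  m <- design$m; p <- design$p
  set.seed(seed)

  gen_split <- function(n_total) {
    n_t <- n_total %/% Tn
    sizes <- rep(n_t, Tn)
    sizes[seq_len(n_total - sum(sizes))] <- n_t + 1L
    labels <- rep(paste0("g", seq_len(Tn)), times = sizes)
    X <- draw_block_features(n_total, p, design$n_blocks, design$block_cor)
    Y <- matrix(NA_real_, n_total, m,
                dimnames = list(NULL, paste0("d", seq_len(m))))
    start <- 1L
    for (t in seq_len(Tn)) {
      idx <- start:(start + sizes[t] - 1L)
      start <- start + sizes[t]
      Y[idx, ] <- X[idx, , drop = FALSE] %*% true_model$B[[t]] +
        draw_cs_noise(length(idx), m, design$v_cor)
    }
    list(X = X, Y = Y, labels = labels)
  }

  train <- gen_split(design$n)
  mask <- matrix(runif(design$n * m) < design$missing_rate, design$n, m)
  Y_missing <- train$Y
  Y_missing[mask] <- NA
  val <- gen_split(design$n_val)

  structure(
    list(Y = Y_missing, Y_complete = train$Y, X = train$X,
         tissues = train$labels,
         X_val = val$X, Y_val = val$Y, tissues_val = val$labels,
         truth = true_model, design = design, seed = seed),
    class = "mixlasso_sim_data"
  )
}

#' @export
print.mixlasso_sim_data <- function(x, ...) {
  cat("<mixlasso_sim_data> scenario ", x$design$scenario, ": ",
      nrow(x$Y), " x ", ncol(x$Y), " training responses (",
      round(100 * mean(is.na(x$Y)), 1), "% missing), ",
      nrow(x$Y_val), " validation samples, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
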