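#' Build the drug-response dendrogram that parameterizes the tree penalty
#'
#' Drugs with correlated response profiles should share selected features; the
#' tree penalty encodes this through overlapping groups read off a dendrogram
#' over the drugs. The tree is built by hierarchical agglomerative
#' complete-linkage clustering with the Pearson-correlation distance
#' d(k, l) = 1 - cor(y_k, y_l); merge heights are divided by the maximum
#' height so the root sits at height 1. Leaf groups carry weight 1; an
#' internal node's weight is its normalized merge height, so tight clusters
#' are penalized jointly at low cost.
#'
#' @param Y Numeric matrix (samples x drugs). Pairwise-complete correlations
#'   can be requested through `use` when `Y` contains missing entries.
#' @param use Passed to [stats::cor()] (default `"everything"`, which requires
#'   complete responses).
#' @return An object of class `drug_tree`: `m`, `labels`, `merge` and `height`
#'   in [stats::hclust()] convention, normalized heights `h_norm`, internal
#'   node groups `groups` (list of drug index vectors), internal weights
#'   `omega`, and leaf weights `leaf_weight` (all 1).
#' @export
#' @examples
#' Y <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("d1", "d2", "d3")))
#' tr <- build_drug_tree(Y)
#' enumerate_groups(tr)
build_drug_tree <- function(Y, use = "everything") {
  stopifnot(is.matrix(Y))
  m <- ncol(Y)
  labels <- colnames(Y)
  if (is.null(labels)) labels <- paste0("drug", seq_len(m))
  if (m < 2L) {
    return(new_drug_tree(m = m, labels = labels,
                         merge = matrix(integer(0), 0, 2),
                         height = numeric(0)))
  }
  if (nrow(Y) < 3L) stop("need at least 3 rows to estimate drug correlations",
                         call. = FALSE)
  cc <- suppressWarnings(cor(Y, use = use))
  if (anyNA(cc)) {
    stop("undefined drug-drug correlation (constant column or too few ",
         "complete pairs)", call. = FALSE)
  }
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "complete")
  new_drug_tree(m = m, labels = labels, merge = hc$merge, height = hc$height)
}

# Internal constructor shared by build and newick import.
new_drug_tree <- function(m, labels, merge, height) {
  n_int <- nrow(merge)
  hmax <- if (n_int > 0L) max(height) else 0
  h_norm <- if (hmax > 0) height / hmax else height
  groups <- vector("list", n_int)
  if (n_int > 0L) {
    for (i in seq_len(n_int)) {
      kids <- merge[i, ]
      groups[[i]] <- sort(unlist(lapply(kids, function(k) {
        if (k < 0) -k else groups[[k]]
      })))
    }
  }
  structure(
    list(m = m, labels = labels, merge = merge, height = height,
         h_norm = h_norm, groups = groups, omega = h_norm,
         leaf_weight = rep(1, m)),
    class = "drug_tree"
  )
}

#' @export
print.drug_tree <- function(x, ...) {
  cat("<drug_tree> ", x$m, " drugs, ", length(x$groups),
      " internal nodes, root height ",
      if (length(x$h_norm)) max(x$h_norm) else 0, "\n", sep = "")
  invisible(x)
}

#' Enumerate all penalty groups of a drug tree
#'
#' Materializes the groups G_v that the tree penalty sums over: one singleton
#' group per leaf (weight 1) and one group per internal node (weight = its
#' normalized height), in post-order traversal from the root, leaves before
#' their parent. Every drug appears in exactly one leaf group and in each of
#' its ancestors' groups.
#'
#' @param tree A [build_drug_tree()] object.
#' @return A tibble with columns `node` (id; leaves `1..m`, internal `m + i`),
#'   `label`, `is_internal`, `height` (normalized), `weight`, `size`, and
#'   `drugs` (list column of member drug indices).
#' @export
enumerate_groups <- function(tree) {
  stopifnot(inherits(tree, "drug_tree"))
  m <- tree$m
  n_int <- length(tree$groups)
  if (n_int == 0L) {
    ord <- seq_len(m)
  } else {
    # iterative post-order over nodes; internal node i has id m + i
    ord <- integer(0)
    stack <- list(list(id = m + n_int, seen = FALSE))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (top$id <= m) {
        ord <- c(ord, top$id)
      } else if (top$seen) {
        ord <- c(ord, top$id)
      } else {
        kids <- tree$merge[top$id - m, ]
        ids <- ifelse(kids < 0, -kids, kids + m)
        stack <- c(stack, list(list(id = top$id, seen = TRUE)),
                   list(list(id = ids[2L], seen = FALSE)),
                   list(list(id = ids[1L], seen = FALSE)))
      }
    }
  }
  rows <- lapply(ord, function(id) {
    if (id <= m) {
      tibble::tibble(node = id, label = tree$labels[id], is_internal = FALSE,
                     height = 0, weight = tree$leaf_weight[id], size = 1L,
                     drugs = list(id))
    } else {
      i <- id - m
      g <- tree$groups[[i]]
      tibble::tibble(node = id, label = paste0("node", id), is_internal = TRUE,
                     height = tree$h_norm[i], weight = tree$omega[i],
                     size = length(g), drugs = list(g))
    }
  })
  dplyr::bind_rows(rows)
}

#' Export a drug tree to Newick format
#'
#' Branch lengths encode the normalized merge heights, so the tree round-trips
#' through [read_tree_newick()].
#'
#' @param tree A `drug_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "drug_tree"))
  if (tree$m < 2L) {
    writeLines(paste0("(", tree$labels, ":0);"), path)
    return(invisible(path))
  }
  leaf_order <- function(i) {  # leaves under merge row i, left to right
    unlist(lapply(tree$merge[i, ], function(k) {
      if (k < 0) -k else leaf_order(k)
    }))
  }
  hc <- structure(
    list(merge = tree$merge, height = tree$h_norm,
         order = leaf_order(nrow(tree$merge)), labels = tree$labels),
    class = "hclust"
  )
  ph <- ape::as.phylo(hc)
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Import a drug tree from Newick format
#'
#' Expects an ultrametric tree such as written by [write_tree_newick()];
#' heights are (re-)normalized so the root sits at height 1.
#'
#' @param path Newick file path.
#' @return A `drug_tree`.
#' @export
read_tree_newick <- function(path) {
  ph <- ape::read.tree(path)
  if (is.null(ph)) stop("could not parse newick file: ", path, call. = FALSE)
  if (ape::Ntip(ph) < 2L) {
    return(new_drug_tree(m = ape::Ntip(ph), labels = ph$tip.label,
                         merge = matrix(integer(0), 0, 2), height = numeric(0)))
  }
  hc <- ape::as.hclust.phylo(stats::reorder(ph))
  new_drug_tree(m = length(hc$labels), labels = hc$labels,
                merge = hc$merge, height = hc$height)
}

# Fit-time view of the tree: indicator matrix over internal groups plus
# per-drug ancestor weight sums used by the Lipschitz bound.
tree_precompute <- function(tree) {
  m <- tree$m
  n_int <- length(tree$groups)
  Mv <- matrix(0, m, n_int)
  for (i in seq_len(n_int)) Mv[tree$groups[[i]], i] <- 1
  keep <- tree$omega > 0
  list(
    Mv = Mv[, keep, drop = FALSE],
    omega = tree$omega[keep],
    anc_w2 = if (n_int) as.vector(Mv %*% (tree$omega^2)) else rep(0, m),
    leaf_weight = tree$leaf_weight,
    n_groups = sum(keep)
  )
}
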