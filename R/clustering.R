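# Agglomerative clustering of standardized feature vectors: Euclidean
# distances, Ward linkage (merge heights reported as within-cluster
# SSE increases), the Calinski-Harabasz variance ratio criterion, and
# cluster-number selection with a reference-null "no sub-structure" check.

#' Pairwise Euclidean distance matrix
#'
#' @param X n x p numeric matrix (rows = subjects).
#' @return n x n symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite rows in feature matrix")
  if (nrow(X) < 2) stop("need at least 2 subjects")
  as.matrix(stats::dist(X))
}

#' Ward minimum-variance linkage
#'
#' Agglomerative merging that at each step joins the pair of clusters whose
#' union minimally increases the total within-cluster sum of squares
#' (Lance-Williams `ward.D2` recurrence on Euclidean distances). Merge
#' heights are reported in SSE-increase units (`h^2 / 2` of the `ward.D2`
#' height), which makes them directly comparable to an exhaustive greedy
#' SSE search.
#'
#' @param X n x p feature matrix, or a `dist`/square distance matrix.
#' @param labels optional leaf labels (subject ids).
#' @return A `merge_tree`: list with `hclust` (the underlying tree),
#'   `merges` (data frame `step, node_a, node_b, height_sse, new_size`,
#'   negative node ids = leaves) and `labels`.
#' @export
ward_linkage <- function(X, labels = NULL) {
  if (inherits(X, "dist")) {
    d <- X
  } else {
    X <- as.matrix(X)
    if (nrow(X) == ncol(X) && isSymmetric(unname(X)) &&
        all(abs(diag(X)) < 1e-12)) {
      d <- stats::as.dist(X)
    } else {
      if (!all(is.finite(X))) stop("non-finite rows in feature matrix")
      d <- stats::dist(X)
    }
  }
  hc <- stats::hclust(d, method = "ward.D2")
  if (!is.null(labels)) hc$labels <- labels
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sz <- function(v) if (v < 0) 1L else sizes[v]
    sizes[i] <- sz(hc$merge[i, 1]) + sz(hc$merge[i, 2])
  }
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       node_a = hc$merge[, 1], node_b = hc$merge[, 2],
                       height_sse = hc$height^2 / 2, new_size = sizes)
  structure(list(hclust = hc, merges = merges,
                 labels = hc$labels %||% as.character(seq_len(attr(d, "Size")))),
            class = "merge_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.merge_tree <- function(x, ...) {
  cat("<merge_tree> ", length(x$labels), " leaves, ", nrow(x$merges),
      " merges\n", sep = "")
  invisible(x)
}

#' Cut a merge tree into k clusters
#'
#' @param tree a `merge_tree`.
#' @param k number of clusters.
#' @return Integer cluster labels named by leaf label.
#' @export
cut_tree <- function(tree, k) {
  stats::cutree(tree$hclust, k = k)
}

#' Variance ratio (Calinski-Harabasz) criterion
#'
#' `[tr(B)/(k-1)] / [tr(W)/(n-k)]` where `B` and `W` are the between- and
#' within-group scatter matrices of the partition. Zero within-cluster
#' scatter yields `Inf` (perfect separation).
#'
#' @param X n x p feature matrix.
#' @param labels cluster assignment with `2 <= k < n` non-empty clusters.
#' @return Criterion value.
#' @export
variance_ratio <- function(X, labels) {
  X <- as.matrix(X)
  labels <- factor(labels)
  k <- nlevels(labels)
  n <- nrow(X)
  if (any(table(labels) == 0)) stop("empty cluster")
  if (k < 2 || k >= n) stop("need 2 <= k < n clusters")
  grand <- colMeans(X)
  trW <- 0; trB <- 0
  for (g in levels(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    m <- colMeans(Xg)
    trW <- trW + sum(sweep(Xg, 2, m)^2)
    trB <- trB + nrow(Xg) * sum((m - grand)^2)
  }
  if (trW == 0) return(Inf)
  (trB / (k - 1)) / (trW / (n - k))
}

#' Select the number of clusters by the variance ratio criterion
#'
#' Cuts the Ward tree at every `k` in `k_range`, scores each partition with
#' [variance_ratio()] and selects the maximizer (ties broken toward the
#' smallest `k`). Optionally performs a reference-null check for the
#' absence of sub-structure: the observed maximum criterion value is
#' compared to the 95th percentile of maxima obtained from `n_null`
#' datasets drawn uniformly on the data's PCA bounding box; if the observed
#' maximum does not exceed that reference, `no_substructure` is flagged.
#' This operationalizes "no sub-groups could be identified" and is an
#' extension of the plain criterion.
#'
#' @param X n x p standardized feature matrix.
#' @param tree optional precomputed [ward_linkage()] tree.
#' @param k_range cluster counts to score (clipped to `n - 1`).
#' @param labels leaf labels (subject ids).
#' @param null_check perform the reference-null check?
#' @param n_null number of null datasets (default 99).
#' @param null_quantile reference percentile (default 0.95).
#' @param seed RNG seed for the null draw.
#' @return A `cluster_solution`: list with `labels` (named cluster ids at
#'   `k_selected`), `k_selected`, `vrc_by_k`, `tree`, `no_substructure`,
#'   `null_max` (the null maxima, when checked) and `k_range`.
#' @export
select_k <- function(X, tree = NULL, k_range = 2:10, labels = NULL,
                     null_check = TRUE, n_null = 99, null_quantile = 0.95,
                     seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range empty after clipping to [2, n-1]")
  if (is.null(tree)) tree <- ward_linkage(X, labels = labels)
  vrc_by_k <- vapply(k_range, function(k)
    variance_ratio(X, cut_tree(tree, k)), 0)
  names(vrc_by_k) <- k_range
  k_selected <- k_range[which.max(vrc_by_k)]  # which.max: first = smallest k
  obs_max <- max(vrc_by_k)

  no_substructure <- NA
  null_max <- NULL
  if (null_check) {
    pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    r <- sum(pr$sdev > 1e-10 * pr$sdev[1])
    S <- pr$x[, seq_len(r), drop = FALSE]
    lo <- apply(S, 2, min); hi <- apply(S, 2, max)
    draw_null <- function() {
      S0 <- matrix(stats::runif(n * r, rep(lo, each = n), rep(hi, each = n)),
                   n, r)
      X0 <- S0 %*% t(pr$rotation[, seq_len(r), drop = FALSE])
      X0 <- sweep(X0, 2, pr$center, `+`)
      t0 <- ward_linkage(X0)
      max(vapply(k_range, function(k)
        variance_ratio(X0, cut_tree(t0, k)), 0))
    }
    null_max <- with_seed(seed %||% 1L, replicate(n_null, draw_null()))
    no_substructure <- obs_max <= stats::quantile(null_max, null_quantile)
  }
  structure(list(labels = cut_tree(tree, k_selected),
                 k_selected = k_selected, vrc_by_k = vrc_by_k, tree = tree,
                 no_substructure = unname(no_substructure),
                 null_max = null_max, k_range = k_range),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k = ", x$k_selected, " (VRC ",
      sprintf("%.1f", max(x$vrc_by_k)), ")",
      if (isTRUE(x$no_substructure)) " [no sub-structure vs null]", "\n",
      sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Export a merge tree as Newick
#'
#' @param tree a `merge_tree`.
#' @return Newick string with SSE-increase branch heights.
#' @export
tree_newick <- function(tree) {
  hc <- tree$hclust
  h <- tree$merges$height_sse
  node_h <- function(v) if (v < 0) 0 else h[v]
  build <- function(i) {
    part <- function(v) {
      lab <- if (v < 0) tree$labels[-v] else build(v)
      sprintf("%s:%g", lab, h[i] - node_h(v))
    }
    sprintf("(%s,%s)", part(hc$merge[i, 1]), part(hc$merge[i, 2]))
  }
  paste0(build(nrow(hc$merge)), ";")
}
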