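# PCA of the standardized feature matrix, per-PC group effect sizes,
# per-axis relative loadings (squared correlations), and waveform
# reconstruction in raw units.

#' Principal component analysis of the standardized feature matrix
#'
#' Singular value decomposition of the column-centered standardized matrix,
#' retaining all `p = min(n - 1, ncol)` components. Sign indeterminacy is
#' fixed by making each loading column's largest-magnitude element
#' positive, so reports are reproducible across platforms.
#'
#' @param x a `feature_matrix` from [build_feature_matrix()], or a plain
#'   numeric matrix that is treated as already standardized.
#' @return A `pca_model`: list with `loadings` (ncol x p, orthonormal
#'   columns), `scores` (n x p), `explained_pct`, `center` (column means of
#'   the standardized matrix), `col_means`/`col_sds` of the raw matrix,
#'   `column_map` and `sign_convention_applied`.
#' @export
fit_pca <- function(x) {
  if (inherits(x, "feature_matrix")) {
    X <- x$X_std
    col_means <- x$col_means
    col_sds <- ifelse(x$zero_variance, 1, x$col_sds)
    column_map <- x$column_map
  } else {
    X <- as.matrix(x)
    col_means <- rep(0, ncol(X))
    col_sds <- rep(1, ncol(X))
    column_map <- data.frame(column = seq_len(ncol(X)),
                             axis = NA_character_,
                             point = seq_len(ncol(X)))
  }
  n <- nrow(X)
  if (n < 3) stop("need at least 3 subjects for PCA")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (max(pr$sdev) < 1e-12) stop("rank-0 matrix: no variance to decompose")
  p <- min(n - 1L, ncol(X))
  loadings <- pr$rotation[, seq_len(p), drop = FALSE]
  scores <- pr$x[, seq_len(p), drop = FALSE]
  for (j in seq_len(p)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vars <- pr$sdev^2
  explained_pct <- 100 * vars[seq_len(p)] / sum(vars)
  structure(list(loadings = loadings, scores = scores,
                 explained_pct = explained_pct, center = pr$center,
                 col_means = col_means, col_sds = col_sds,
                 column_map = column_map, sign_convention_applied = TRUE),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", nrow(x$scores), " subjects, ", ncol(x$scores),
      " components; PC1-3 explain ",
      paste(sprintf("%.1f%%", x$explained_pct[1:min(3, length(x$explained_pct))]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-component group effect sizes
#'
#' Eta-squared (between-group over total sum of squares) of each principal
#' component's scores across the supplied groups, flagging components whose
#' effect exceeds the large-effect threshold.
#'
#' @param scores n x p score matrix (or a `pca_model`).
#' @param labels group assignment of length n (>= 2 groups, each with >= 2
#'   members).
#' @param threshold large-effect flag threshold (default 0.14).
#' @return Data frame `pc, eta_squared, large_effect`.
#' @export
pc_effect_sizes <- function(scores, labels, threshold = 0.14) {
  if (inherits(scores, "pca_model")) scores <- scores$scores
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2)) stop("every group needs >= 2 members")
  es <- apply(scores, 2, eta_squared, labels = labels)
  data.frame(pc = seq_len(ncol(scores)), eta_squared = unname(es),
             large_effect = unname(es) > threshold)
}

#' Relative per-axis loading of a principal component
#'
#' Squared Pearson correlations between one PC's scores and each raw
#' (un-standardized) feature column, summed within the VT, AP and ML column
#' blocks and expressed as percentages of the grand sum. Zero-variance
#' columns contribute 0.
#'
#' @param model a `pca_model`.
#' @param fm the `feature_matrix` the model was fitted on.
#' @param pc_index which component.
#' @return Named numeric vector `c(VT =, AP =, ML =)` summing to 100.
#' @export
relative_loading <- function(model, fm, pc_index) {
  stopifnot(pc_index >= 1, pc_index <= ncol(model$scores))
  s <- model$scores[, pc_index]
  r2 <- squared_loadings(s, fm)
  ax <- fm$column_map$axis
  sums <- vapply(c("VT", "AP", "ML"), function(a) sum(r2[ax == a]), 0)
  100 * sums / sum(sums)
}

# squared correlations of one score vector with every raw column;
# zero-variance columns are treated as correlation 0
squared_loadings <- function(score, fm) {
  sdv <- fm$col_sds
  ok <- !fm$zero_variance
  r2 <- numeric(ncol(fm$X_raw))
  r2[ok] <- as.numeric(stats::cor(score, fm$X_raw[, ok, drop = FALSE]))^2
  r2
}

#' Reconstruct acceleration waveforms from principal components
#'
#' Returns the raw-unit waveform at given component scores:
#' `col_means + col_sds * (center + sum_j score_j * loading_j)`, reshaped
#' to the 3 x points layout. With `score_value = 0` this is the grand-mean
#' waveform; with all components at a subject's scores it reproduces that
#' subject's raw row exactly.
#'
#' @param model a `pca_model` fitted on a `feature_matrix`.
#' @param pc_index component index (scalar or vector).
#' @param score_value score at which to reconstruct (same length as
#'   `pc_index`; e.g. a cluster's mean score).
#' @return 3 x points matrix (rows VT/AP/ML) in m/s^2.
#' @export
reconstruct <- function(model, pc_index, score_value) {
  stopifnot(length(pc_index) == length(score_value),
            all(pc_index >= 1), all(pc_index <= ncol(model$loadings)))
  std_row <- model$center
  for (j in seq_along(pc_index))
    std_row <- std_row + score_value[j] * model$loadings[, pc_index[j]]
  raw <- model$col_means + model$col_sds * std_row
  cm <- model$column_map
  n_pts <- max(cm$point)
  out <- matrix(NA_real_, 3, n_pts, dimnames = list(c("VT", "AP", "ML"), NULL))
  if (all(is.na(cm$axis))) return(matrix(raw, nrow = 1))
  for (a in c("VT", "AP", "ML"))
    out[a, cm$point[cm$axis == a]] <- raw[cm$axis == a]
  out
}
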