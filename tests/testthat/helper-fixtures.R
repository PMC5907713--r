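# Shared fixtures and independent oracles for the test suite.

# small trajectory table: `markers` named list of length-3 offsets (mm),
# positions constant over frames unless `drift` supplied per frame
toy_trajectory <- function(n_frames = 10, markers = list(M1 = c(0, 0, 0),
                                                         M2 = c(10, 0, 0),
                                                         M3 = c(0, 10, 0),
                                                         M4 = c(10, 10, 10)),
                           fs = 200, drift = NULL) {
  do.call(rbind, lapply(names(markers), function(m) {
    base <- matrix(markers[[m]], n_frames, 3, byrow = TRUE)
    if (!is.null(drift)) base <- base + drift
    data.frame(frame = 0:(n_frames - 1), time = (0:(n_frames - 1)) / fs,
               marker_id = m, x = base[, 1], y = base[, 2], z = base[, 3],
               stringsAsFactors = FALSE)
  }))
}

# down-scaled archetype library for pipeline-level tests
micro_archetypes <- function(n_male = 5, n_c1 = 4, n_c2 = 5) {
  sp <- default_archetypes()
  sp$male$n_subjects <- n_male
  sp$female_C1$n_subjects <- n_c1
  sp$female_C2$n_subjects <- n_c2
  sp
}

# one cached noise-free marker subject + its kinematic chain (built once;
# several kinematics/waveform tests share it)
cached_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- run_config()
      tr <- make_subject(default_archetypes()$female_C1, seed = 42,
                         cfg = cfg, noise_sd_mm = 0)
      centroid <- pelvic_centroid(tr$dynamic)
      acc_g <- double_differentiate(centroid, cfg)
      acc_l <- global_to_local(acc_g, tr$dynamic, tr$static)
      cache <<- list(cfg = cfg, trial = tr, centroid = centroid,
                     acc_g = acc_g, acc_l = acc_l)
    }
    cache
  }
})

# independent eta-squared: explicit loops, no shared code with the package
brute_eta_squared <- function(values, labels) {
  labels <- as.character(labels)
  grand <- sum(values) / length(values)
  sst <- 0
  for (v in values) sst <- sst + (v - grand)^2
  ssb <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    m <- sum(values[idx]) / sum(idx)
    ssb <- ssb + sum(idx) * (m - grand)^2
  }
  ssb / sst
}

# independent Cramer's V from first principles
brute_cramers_v <- function(tab) {
  N <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / N
  chi2 <- sum((tab - expected)^2 / expected)
  list(chi2 = chi2, v = sqrt(chi2 / (N * (min(dim(tab)) - 1))))
}

# exhaustive greedy minimum-SSE-increase agglomeration (Ward oracle)
brute_ward <- function(X) {
  sse <- function(idx) {
    Xi <- X[idx, , drop = FALSE]
    sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  merges <- list()
  while (length(clusters) > 1) {
    bestd <- Inf
    best <- NULL
    for (i in 1:(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- sse(c(clusters[[i]], clusters[[j]])) -
          sse(clusters[[i]]) - sse(clusters[[j]])
        if (d < bestd) {
          bestd <- d
          best <- c(i, j)
        }
      }
    }
    merges[[length(merges) + 1]] <-
      list(members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
           delta_sse = bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# leaf membership of each merge step of a merge_tree
tree_members <- function(tree) {
  hc <- tree$hclust
  members <- list()
  for (s in seq_len(nrow(hc$merge))) {
    mem <- function(v) if (v < 0) -v else members[[v]]
    members[[s]] <- sort(c(mem(hc$merge[s, 1]), mem(hc$merge[s, 2])))
  }
  members
}

# independent Calinski-Harabasz with explicit scatter loops
brute_vrc <- function(X, labels) {
  labels <- as.character(labels)
  n <- nrow(X)
  k <- length(unique(labels))
  grand <- colMeans(X)
  trW <- 0
  trB <- 0
  for (g in unique(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    m <- colMeans(Xg)
    for (r in seq_len(nrow(Xg))) trW <- trW + sum((Xg[r, ] - m)^2)
    trB <- trB + nrow(Xg) * sum((m - grand)^2)
  }
  (trB / (k - 1)) / (trW / (n - k))
}
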