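test_that("distance matrix matches brute force", {
  X <- rbind(c(0, 0, 0), c(3, 4, 0))
  D <- distance_matrix(X)
  expect_equal(D[1, 2], 5)
  expect_equal(unname(diag(D)), c(0, 0))
  X2 <- rbind(X, X[1, ])
  expect_equal(distance_matrix(X2)[1, 3], 0)

  set.seed(3)
  X <- matrix(rnorm(10 * 7), 10, 7)
  D <- distance_matrix(X)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(D[i, j], sqrt(sum((X[i, ] - X[j, ])^2)),
                   tolerance = 1e-12)
      expect_equal(D[i, j], D[j, i])
    }
  }
  expect_error(distance_matrix(rbind(c(1, NA), c(0, 0))), "finite")
})

test_that("Ward linkage reproduces exhaustive greedy SSE agglomeration", {
  X2 <- rbind(c(0, 0), c(3, 4))
  t2 <- ward_linkage(X2)
  expect_equal(nrow(t2$merges), 1)
  expect_equal(t2$merges$height_sse, 25 / 2)  # SSE increase of the pair

  t3 <- ward_linkage(cbind(c(0, 1, 10)))
  expect_equal(tree_members(t3)[[1]], c(1, 2))

  set.seed(12)
  for (rep in 1:4) {
    X <- matrix(rnorm(8 * 5), 8, 5)
    tree <- ward_linkage(X)
    oracle <- brute_ward(X)
    members <- tree_members(tree)
    for (s in 1:7) {
      expect_identical(members[[s]], oracle[[s]]$members)
      expect_equal(tree$merges$height_sse[s], oracle[[s]]$delta_sse,
                   tolerance = 1e-8)
    }
    expect_true(all(diff(tree$merges$height_sse) >= -1e-12))
  }
  # feature matrix and distance inputs give the same tree
  X <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(ward_linkage(X)$merges,
               ward_linkage(distance_matrix(X))$merges)
})

test_that("variance ratio equals hand-computed scatter traces", {
  set.seed(5)
  X <- matrix(rnorm(12 * 6), 12, 6)
  labels <- rep(c("a", "b", "c"), each = 4)
  expect_equal(variance_ratio(X, labels), brute_vrc(X, labels),
               tolerance = 1e-10)

  blobs <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
                 matrix(rnorm(12, 8, 0.1), 6, 2))
  true_split <- rep(1:2, each = 6)
  rand_split <- rep(1:2, 6)
  expect_gt(variance_ratio(blobs, true_split),
            variance_ratio(blobs, rand_split))

  dup <- rbind(matrix(1, 3, 2), matrix(5, 3, 2))
  expect_equal(variance_ratio(dup, rep(1:2, each = 3)), Inf)
  expect_error(variance_ratio(X, factor(rep("a", 12), levels = c("a", "b"))),
               "empty|2 <= k")
})

test_that("k selection finds planted structure and ties break small", {
  set.seed(6)
  blobs3 <- do.call(rbind, lapply(c(0, 10, 20), function(m)
    matrix(rnorm(16, m, 0.5), 8, 2)))
  sol <- select_k(blobs3, k_range = 2:6, null_check = FALSE)
  expect_equal(sol$k_selected, 3)
  expect_equal(length(unique(sol$labels)), 3)
  for (k in 2:6) expect_equal(length(unique(cut_tree(sol$tree, k))), k)

  co <- make_waveform_cohort(default_archetypes()[c("female_C1", "female_C2")],
                             seed = 31)
  fm <- build_feature_matrix(co$waveforms)
  sol <- select_k(fm$X_std, k_range = 2:10, labels = fm$subjects,
                  null_check = FALSE)
  expect_equal(sol$k_selected, 2)
  expect_gte(mclust::adjustedRandIndex(sol$labels, co$archetype), 0.9)
})

test_that("cluster labels are invariant to subject input order", {
  co <- make_waveform_cohort(default_archetypes()[c("female_C1", "female_C2")],
                             seed = 17)
  fm <- build_feature_matrix(co$waveforms)
  sol <- select_k(fm$X_std, labels = fm$subjects, null_check = FALSE)
  set.seed(1)
  perm <- sample(length(co$waveforms))
  fm2 <- build_feature_matrix(co$waveforms[perm])
  sol2 <- select_k(fm2$X_std, labels = fm2$subjects, null_check = FALSE)
  expect_equal(sol2$k_selected, sol$k_selected)
  # same partition by subject id (cluster numbering may differ)
  ids <- fm$subjects
  expect_equal(mclust::adjustedRandIndex(sol$labels[ids], sol2$labels[ids]), 1)
})

test_that("a single Gaussian cloud raises the no-sub-structure flag", {
  flags <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(30 * 20), 30, 20)
    select_k(X, k_range = 2:6, n_null = 99, seed = s)$no_substructure
  }, TRUE)
  expect_gte(mean(flags), 0.8)
  # well-separated structure must not be flagged
  co <- make_waveform_cohort(default_archetypes()[c("female_C1", "female_C2")],
                             seed = 23)
  fm <- build_feature_matrix(co$waveforms)
  sol <- select_k(fm$X_std, labels = fm$subjects, n_null = 99, seed = 4)
  expect_false(sol$no_substructure)
})

test_that("merge trees export to Newick with all leaves", {
  X <- matrix(rnorm(5 * 3), 5, 3)
  tree <- ward_linkage(X, labels = paste0("s", 1:5))
  nw <- tree_newick(tree)
  expect_match(nw, ";$")
  for (l in paste0("s", 1:5)) expect_match(nw, l, fixed = TRUE)
  ph <- ape::read.tree(text = nw)
  expect_equal(sort(ph$tip.label), paste0("s", 1:5))
})
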