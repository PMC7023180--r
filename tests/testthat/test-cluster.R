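sq_euclid <- function(points) {
  d <- as.matrix(dist(points))^2
  rownames(d) <- colnames(d) <- paste0("p", seq_len(nrow(d)))
  d
}

test_that("two objects merge once at their distance under every linkage", {
  d <- matrix(c(0, 3.5, 3.5, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  for (lk in c("ward_d", "ward_d2", "single", "complete", "average")) {
    tree <- hierarchical_cluster(d, lk)
    expect_equal(nrow(tree$merges), 1)
    expect_equal(tree$merges$height, 3.5)
    expect_equal(tree$merges$size, 2L)
    expect_equal(sort(c(tree$merges$left, tree$merges$right)), c(0L, 1L))
  }
})

test_that("ward_d on 1-D points {0, 1, 10} reproduces the hand-computed ESS path", {
  pts <- matrix(c(0, 1, 10), 3, 1)
  tree <- hierarchical_cluster(sq_euclid(pts), "ward_d")
  # frozen from oracle_ward_ess: increments 0.5 and 180.5/3, heights = 2x
  expect_equal(tree$merges$left, c(0L, 2L))
  expect_equal(tree$merges$right, c(1L, 3L))
  expect_equal(tree$merges$height, c(1, 361 / 3), tolerance = 1e-12)
  oracle <- oracle_ward_ess(pts)
  expect_equal(tree$merges$height, 2 * oracle$increment, tolerance = 1e-12)
})

test_that("Lance-Williams ward_d matches the from-scratch ESS oracle on random point sets", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(3:8, 1); dims <- sample(1:3, 1)
    pts <- matrix(rnorm(n * dims, sd = 2), n, dims)
    tree <- hierarchical_cluster(sq_euclid(pts), "ward_d")
    oracle <- oracle_ward_ess(pts)
    expect_equal(tree$merges$left, oracle$left)
    expect_equal(tree$merges$right, oracle$right)
    expect_equal(tree$merges$height, 2 * oracle$increment,
                 tolerance = 1e-9)
    # independent cross-check against the reference implementation
    hc <- stats::hclust(as.dist(sq_euclid(pts)), method = "ward.D")
    expect_equal(tree$merges$height, hc$height, tolerance = 1e-9)
    expect_true(all(diff(tree$merges$height) >= -1e-9))
  }
})

test_that("single linkage matches the exhaustive minimum-leaf-distance oracle", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    m <- matrix(runif(n * n), n, n); m <- m + t(m); diag(m) <- 0
    rownames(m) <- colnames(m) <- letters[seq_len(n)]
    tree <- hierarchical_cluster(m, "single")
    expect_equal(tree$merges$height, oracle_single_linkage(m),
                 tolerance = 1e-12)
  }
})

test_that("invalid distance matrices are rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(hierarchical_cluster(bad), class = "invalid_input")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(hierarchical_cluster(neg), class = "invalid_input")
})

test_that("relabeling leaves permutes the tree but preserves heights", {
  set.seed(23)
  pts <- matrix(rnorm(12), 6, 2)
  d <- sq_euclid(pts)
  perm <- sample(6)
  t1 <- hierarchical_cluster(d, "ward_d")
  t2 <- hierarchical_cluster(d[perm, perm], "ward_d")
  expect_equal(sort(t1$merges$height), sort(t2$merges$height),
               tolerance = 1e-9)
  c1 <- cophenetic_matrix(t1)$values
  c2 <- cophenetic_matrix(t2)$values
  expect_equal(c2[t1$labels, t1$labels], c1, tolerance = 1e-9)
})

test_that("cut_tree honours k bounds and matches stats::cutree partitions", {
  set.seed(41)
  pts <- matrix(rnorm(16), 8, 2)
  tree <- hierarchical_cluster(sq_euclid(pts), "ward_d")
  expect_equal(unname(cut_tree(tree, 1)), rep(0L, 8))
  expect_equal(sort(unname(cut_tree(tree, 8))), 0:7)
  expect_error(cut_tree(tree, 0), class = "parameter_error")
  expect_error(cut_tree(tree, 9), class = "parameter_error")
  for (k in 2:7) {
    ours <- cut_tree(tree, k)
    ref <- stats::cutree(as.hclust(tree), k)
    # same partition up to label renaming
    expect_equal(mclust::adjustedRandIndex(ours, ref), 1)
  }
})

test_that("cophenetic matrices agree with the LCA oracle and are ultrametric", {
  set.seed(53)
  for (rep in 1:15) {
    pts <- matrix(rnorm(12), 6, 2)
    tree <- hierarchical_cluster(sq_euclid(pts), "ward_d")
    cm <- cophenetic_matrix(tree)$values
    expect_equal(unname(cm), oracle_cophenetic(tree), tolerance = 1e-12)
    expect_true(isSymmetric(cm))
    expect_equal(unname(diag(cm)), rep(0, 6))
    for (i in 1:4) for (j in (i + 1):5) for (l in (j + 1):6) {
      trip <- sort(c(cm[i, j], cm[i, l], cm[j, l]), decreasing = TRUE)
      expect_equal(trip[1], trip[2], tolerance = 1e-9)
    }
  }
})

test_that("nearest-pattern classification recovers classes and reports distances", {
  ref <- data.frame(analyte_id = c("E2", "TET"),
                    rbind(c(10, 0, 0, 5, 0, 0), c(0, 0, 12, 0, 0, 9)))
  classes <- c("estrogen", "antibiotic")
  hit <- classify_unknown(c(10, 0, 0, 5, 0, 0), ref, classes)
  expect_equal(hit$class, "estrogen")
  expect_equal(hit$nearest, "E2")
  expect_equal(hit$distance, 0)
  # single reference always wins
  one <- classify_unknown(c(1, 1, 1, 1, 1, 1), ref[1, ], classes[1])
  expect_equal(one$class, "estrogen")
  # ties break by reference order
  tie <- classify_unknown(c(5, 0, 6, 2.5, 0, 4.5), ref, classes)
  expect_equal(tie$nearest, "E2")
  expect_error(classify_unknown(c(1, 2), ref, classes),
               class = "incompatible_pattern")
})

test_that("held-out noisy replicates are classified correctly at low noise", {
  sc <- synthetic_scenario(noise_sd = 1, seed = 303)
  # reference: exact (noise-free) patterns; queries: cell-mean noise applied
  ref_rows <- lapply(sc$analyte_ids, function(a) {
    bins <- do.call(rbind, lapply(sc$temperatures_c, function(t) {
      r <- simulate_response(sc, a, t)
      r$post - r$pre
    }))
    as.data.frame(t(as.vector(t(bins))))
  })
  ref <- cbind(data.frame(analyte_id = sc$analyte_ids),
               do.call(rbind, ref_rows))
  refm <- as.matrix(ref[, -1])
  mean_sd <- sc$noise_sd / sqrt(sc$layout$roi_side^2) * sqrt(2)  # post - pre
  set.seed(99)
  correct <- 0L
  for (q in 1:100) {
    i <- sample(nrow(ref), 1)
    query <- refm[i, ] + rnorm(ncol(refm), 0, mean_sd)
    hit <- classify_unknown(query, ref, sc$class_labels)
    correct <- correct + (hit$class == sc$class_labels[[i]])
  }
  expect_gte(correct, 90)
})

test_that("Newick export round-trips through an independent parser", {
  d <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("A", "B"),
                                                   c("A", "B")))
  tree2 <- hierarchical_cluster(d, "single")
  expect_equal(dendrogram_to_newick(tree2), "(A:2,B:2);")

  # labels with reserved characters are single-quoted
  dq <- matrix(c(0, 1, 1, 0), 2, 2,
               dimnames = list(c("leaf 1", "a:b"), c("leaf 1", "a:b")))
  expect_equal(dendrogram_to_newick(hierarchical_cluster(dq, "single")),
               "('leaf 1':1,'a:b':1);")

  set.seed(61)
  pts <- matrix(rnorm(8), 8, 1)
  rownames(pts) <- paste0("leaf", 1:8)
  d8 <- sq_euclid(pts); rownames(d8) <- colnames(d8) <- rownames(pts)
  tree <- hierarchical_cluster(d8, "ward_d")
  nwk <- dendrogram_to_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(phy), 8)
  expect_true(ape::is.rooted(phy))
  # path distance between leaves in the phylo = 2 x cophenetic height
  cp <- ape::cophenetic.phylo(phy)
  ours <- cophenetic_matrix(tree)$values
  expect_equal(cp[rownames(ours), colnames(ours)], 2 * ours,
               tolerance = 1e-6)
})
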