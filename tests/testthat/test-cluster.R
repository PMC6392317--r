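test_that("squared Euclidean distances match the definition and a brute-force loop", {
  d <- dist_squared_euclidean(rbind(a = c(0, 0), b = c(3, 4)))
  expect_equal(d["a", "b"], 25)
  expect_equal(diag(d), c(a = 0, b = 0))

  same <- dist_squared_euclidean(rbind(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same["x", "y"], 0)

  withr::with_seed(10, {
    m <- matrix(rnorm(18), 6, 3)
    d6 <- dist_squared_euclidean(m)
    for (i in 1:6) for (j in 1:6) {
      expect_equal(d6[i, j], sum((m[i, ] - m[j, ])^2))
    }
  })

  m_na <- rbind(a = c(1, NA), b = c(0, 0))
  colnames(m_na) <- c("f1", "f2")
  expect_error(dist_squared_euclidean(m_na), "a.*f2")
  expect_error(dist_squared_euclidean(m_na[1, , drop = FALSE]), "2 items")
})

test_that("two items merge once at their distance", {
  d <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- ward_cluster(d)
  expect_equal(length(tr$height), 1)
  expect_equal(tr$height, 5)
  expect_equal(sort(tr$merge[1, ]), c(-2, -1))
})

test_that("well-separated planar pairs merge before anything else", {
  pts <- rbind(p1 = c(0, 0), p2 = c(0, 0.5), q1 = c(100, 0),
               q2 = c(100, 0.4))
  tr <- ward_cluster(dist_squared_euclidean(pts))
  first_two <- list(sort(-tr$merge[1, ]), sort(-tr$merge[2, ]))
  expect_setequal(lapply(first_two, paste, collapse = ","),
                  list("1,2", "3,4"))
})

test_that("Ward agglomeration equals the exhaustive greedy oracle on small instances", {
  withr::with_seed(99, {
    for (trial in 1:60) {
      n <- sample(3:7, 1)
      f <- sample(2:3, 1)
      x <- matrix(rnorm(n * f), n, f)
      tr <- ward_cluster(dist_squared_euclidean(x))
      oracle <- ward_oracle(x)
      expect_equal(tr$height, oracle$heights, tolerance = 1e-10)
      expect_equal(tree_partitions(tr), oracle$partitions)
    }
  })
})

test_that("merge heights admit no inversions and match hclust ward.D", {
  withr::with_seed(7, {
    for (trial in 1:20) {
      n <- sample(4:12, 1)
      x <- matrix(rnorm(n * 3), n, 3)
      rownames(x) <- sprintf("it%02d", seq_len(n))
      d <- dist_squared_euclidean(x)
      tr <- ward_cluster(d)
      expect_false(is.unsorted(tr$height))
      hc <- stats::hclust(stats::as.dist(d), method = "ward.D")
      expect_equal(sort(tr$height), sort(hc$height), tolerance = 1e-10)
      for (k in 2:(n - 1)) {
        ours <- cut_tree(tr, k = k)$cluster
        theirs <- unname(stats::cutree(hc, k = k))
        expect_equal(canonical_partition(ours),
                     canonical_partition(theirs))
      }
    }
  })
})

test_that("cophenetic distances and correlation match independent computations", {
  withr::with_seed(21, {
    x <- matrix(rnorm(24), 8, 3)
    rownames(x) <- letters[1:8]
    d <- dist_squared_euclidean(x)
    tr <- ward_cluster(d)
    cm <- cophenetic_distances(tr)
    ref <- as.matrix(stats::cophenetic(as.hclust(tr)))
    expect_equal(cm[letters[1:8], letters[1:8]],
                 ref[letters[1:8], letters[1:8]], tolerance = 1e-12)

    cc <- cophenetic_correlation(d, tr)
    lower <- lower.tri(d)
    expect_equal(cc, stats::cor(d[lower], cm[lower]))
    expect_true(cc >= -1 && cc <= 1)
  })
})

test_that("a tree correlates perfectly with its own ultrametric", {
  withr::with_seed(33, {
    x <- matrix(rnorm(21), 7, 3)
    tr <- ward_cluster(dist_squared_euclidean(x))
    cm <- cophenetic_distances(tr)
    expect_equal(cophenetic_correlation(cm, tr), 1)
  })
  const <- matrix(1, 3, 3) - diag(3)
  tr_const <- ward_cluster(const)
  expect_message(cc <- cophenetic_correlation(const, tr_const), "constant")
  expect_true(is.na(cc))
})

test_that("tree cuts behave at the extremes and recover planted groups", {
  withr::with_seed(12, {
    centers <- rbind(c(0, 0), c(50, 0), c(0, 50))
    x <- centers[rep(1:3, each = 4), ] + matrix(rnorm(24, sd = 0.5), 12, 2)
    rownames(x) <- sprintf("g%d_%d", rep(1:3, each = 4), rep(1:4, 3))
    tr <- ward_cluster(dist_squared_euclidean(x))

    expect_equal(cut_tree(tr, height = 0)$cluster, 1:12)
    expect_equal(unique(cut_tree(tr, height = max(tr$height) + 1)$cluster), 1)

    mid <- cut_tree(tr, k = 3)
    planted <- rep(1:3, each = 4)
    expect_equal(canonical_partition(mid$cluster),
                 canonical_partition(planted))
    gap_cut <- cut_tree(tr, height = (tr$height[9] + tr$height[10]) / 2)
    expect_equal(dplyr::n_distinct(gap_cut$cluster), 3)
  })
  expect_error(cut_tree(ward_cluster(diag(0, 2) + 1 - diag(2))), "exactly one")
})

test_that("cluster assignments are invariant to row permutation", {
  withr::with_seed(8, {
    x <- matrix(rnorm(30), 10, 3)
    rownames(x) <- sprintf("it%02d", 1:10)
    perm <- sample(10)
    t1 <- cut_tree(ward_cluster(dist_squared_euclidean(x)), k = 3)
    t2 <- cut_tree(ward_cluster(dist_squared_euclidean(x[perm, ])), k = 3)
    m1 <- setNames(t1$cluster, t1$item)
    m2 <- setNames(t2$cluster, t2$item)
    expect_equal(rand_index(m1[sort(t1$item)], m2[sort(t1$item)]), 1)
  })
})

test_that("excluding an analyte equals clustering with that column deleted", {
  gen <- generate_panel(generator_config(seed = 17))
  a <- assess_risk(gen$panel)
  via_exclude <- cluster_thq(a, exclude = c("Cu", "ethanol"))
  wide <- tidyr::pivot_wider(
    dplyr::filter(a$thq_rowpct, analyte != "ethanol"),
    names_from = analyte, values_from = thq
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$brand
  manual <- ward_cluster(dist_squared_euclidean(m[, colnames(m) != "Cu"]))
  expect_equal(via_exclude$tree$height, manual$height)
  expect_equal(via_exclude$tree$merge, manual$merge)
})

test_that("split-half stability is deterministic and saturates on duplicated structure", {
  base <- rbind(matrix(0, 4, 3), matrix(10, 4, 3))
  x <- base + withr::with_seed(2, matrix(rnorm(24, sd = 0.01), 8, 3))
  rownames(x) <- sprintf("it%d", 1:8)
  s1 <- split_half_stability(x, n_splits = 5, seed = 123)
  s2 <- split_half_stability(x, n_splits = 5, seed = 123)
  expect_identical(s1, s2)
  expect_equal(attr(s1, "mean_agreement"), 1)
  expect_error(split_half_stability(x, n_splits = 0, seed = 1), "n_splits")
  expect_error(split_half_stability(x[1:3, ], 2, seed = 1), "4 items")
})

test_that("trees export to hclust and Newick", {
  withr::with_seed(4, {
    x <- matrix(rnorm(15), 5, 3)
    rownames(x) <- sprintf("leaf%d", 1:5)
    tr <- ward_cluster(dist_squared_euclidean(x))
    hc <- as.hclust(tr)
    expect_s3_class(hc, "hclust")
    expect_setequal(hc$order, 1:5)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_tree_newick(tr, path)
    phy <- ape::read.tree(path)
    expect_setequal(phy$tip.label, sprintf("leaf%d", 1:5))
    expect_s3_class(autoplot(tr), "ggplot")
    expect_equal(glance(tr)$n_leaves, 5)
    expect_equal(nrow(tidy(tr)), 4)
  })
})
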