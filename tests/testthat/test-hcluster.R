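table1_dendrogram <- function() agglomerate(to_distance(table1_proximity()))

test_that("two items merge once at their distance", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  dend <- agglomerate(d)
  expect_length(dend$height, 1)
  expect_equal(dend$height, 0.3)
  expect_equal(dend$members[[1]], list(left = "a", right = "b"))
})

test_that("input validation rejects bad distance matrices", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(agglomerate(d), "symmetric")
  d2 <- matrix(c(0, -1, -1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(agglomerate(d2), "non-negative")
  expect_error(agglomerate(matrix(0, 1, 1, dimnames = list("a", "a"))),
               "at least 2")
})

test_that("published distances merge ALS with PSII inhibitors first", {
  dend <- table1_dendrogram()
  expect_equal(sort(c(dend$members[[1]]$left, dend$members[[1]]$right)),
               c("2", "5"))
  expect_equal(dend$height[1], 1 - 0.526)
  expect_equal(sort(c(dend$members[[2]]$left, dend$members[[2]]$right)),
               sort(c("12+13+27", "15")))
  expect_equal(dend$height[2], 1 - 0.438)
})

test_that("agglomerate matches the brute-force oracle on random matrices", {
  set.seed(2024)
  for (trial in 1:100) {
    n <- sample(3:7, 1)
    d <- random_distance(n)
    dend <- agglomerate(d)
    oracle <- brute_complete_linkage(d)
    expect_equal(dend$height, vapply(oracle, `[[`, numeric(1), "height"))
    expect_identical(dend_signature(dend), merge_signature(oracle))
    # heights are monotone (complete linkage)
    expect_true(all(diff(dend$height) >= 0))
    # cross-check heights against the stats::hclust implementation
    h <- hclust(as.dist(d), method = "complete")
    expect_equal(dend$height, h$height)
  }
})

test_that("merge height equals the diameter of the newly formed cluster", {
  set.seed(88)
  for (trial in 1:20) {
    d <- random_distance(sample(4:8, 1))
    dend <- agglomerate(d)
    for (s in seq_along(dend$height)) {
      members <- c(dend$members[[s]]$left, dend$members[[s]]$right)
      expect_equal(dend$height[s],
                   max(d[dend$members[[s]]$left, dend$members[[s]]$right]))
      expect_equal(dend$height[s], max(d[members, members]))
    }
  }
})

test_that("agglomerate is invariant to label permutation up to relabeling", {
  set.seed(99)
  for (trial in 1:20) {
    d <- random_distance(6)
    perm <- sample(6)
    d2 <- d[perm, perm]
    expect_identical(dend_signature(agglomerate(d)),
                     dend_signature(agglomerate(d2)))
  }
})

test_that("cut_dendrogram returns nested, deterministic partitions", {
  dend <- table1_dendrogram()
  M <- length(dend$leaves)
  expect_equal(unname(cut_dendrogram(dend, 1)), rep(1L, M))
  expect_equal(sort(unname(cut_dendrogram(dend, M))), 1:M)
  prev <- cut_dendrogram(dend, 1)
  for (k in 2:M) {
    cur <- cut_dendrogram(dend, k)
    # refinement: members of one cluster at k share their cluster at k-1
    for (cl in unique(cur)) {
      expect_length(unique(prev[names(cur)[cur == cl]]), 1)
    }
    prev <- cur
  }
  expect_error(cut_dendrogram(dend, 0), "between")
  expect_error(cut_dendrogram(dend, M + 1), "between")
})

test_that("cutting the published tree at k = 3 gives the published clusters", {
  part <- cut_dendrogram(table1_dendrogram(), 3)
  clusters <- unname(lapply(split(names(part), part), sort))
  has_cluster <- function(members)
    any(vapply(clusters, identical, logical(1), sort(members)))
  expect_true(has_cluster(c("2", "4", "5", "9")))
  expect_true(has_cluster(c("12+13+27", "14", "15")))
  expect_true(has_cluster(c("1", "3", "22")))
})

test_that("agglomeration schedule tracks merge heights by cluster count", {
  d <- matrix(c(0, .2, .2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  sched2 <- agglomeration_schedule(agglomerate(d))
  expect_equal(sched2, data.frame(k = 1, coefficient = 0.2))

  dend <- table1_dendrogram()
  sched <- agglomeration_schedule(dend)
  expect_equal(nrow(sched), 9)
  expect_equal(sched$k, 9:1)
  expect_equal(sched$coefficient[1], 1 - 0.526)
  # coefficient is non-decreasing as k decreases
  expect_true(all(diff(sched$coefficient) >= 0))
})

test_that("select_k picks the planted split on a 2-block matrix", {
  labs <- sprintf("x%d", 1:6)
  d <- matrix(0.9, 6, 6, dimnames = list(labs, labs))
  block <- list(1:3, 4:6)
  for (b in block) d[b, b] <- 0.1
  diag(d) <- 0
  dend <- agglomerate(d)
  expect_equal(select_k(dend, selection_rule("max_gap"))$k, 2L)
  expect_equal(select_k(dend, selection_rule("balanced_no_singleton"))$k, 2L)
})

test_that("ties resolve to the smallest k, with singleton fallback warning", {
  labs <- c("a", "b", "c")
  d <- matrix(0.5, 3, 3, dimnames = list(labs, labs)); diag(d) <- 0
  dend <- agglomerate(d)
  # every 2-cluster cut of 3 equidistant items has a singleton
  expect_warning(sel <- select_k(dend, selection_rule(k_range = 2)),
                 "singleton")
  expect_equal(sel$k, 2L)
  expect_equal(sel$method, "max_gap")
})

test_that("balance rule selects three clusters on the published tree", {
  dend <- table1_dendrogram()
  sel <- select_k(dend, selection_rule("balanced_no_singleton", 2:5))
  expect_equal(sel$k, 3L)
  bal <- sel$diagnostics$balance
  expect_true(all(bal$has_singleton[bal$k %in% 4:5]))
  # the raw elbow on the 1 - Jaccard coefficient prefers k = 2; the
  # diagnostics keep both views visible
  gap <- sel$diagnostics$gap
  expect_equal(gap$k[which.max(gap$gap)], 2L)
})

test_that("newick export is a valid ultrametric tree", {
  skip_if_not_installed("ape")
  dend <- table1_dendrogram()
  nwk <- as_newick(dend)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, gsub("[,;:() \t]", "_", dend$leaves))
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  expect_equal(depths, rep(max(dend$height), length(depths)),
               tolerance = 1e-8)
})

test_that("as.hclust conversion agrees with cut_dendrogram", {
  dend <- table1_dendrogram()
  h <- as.hclust(dend)
  expect_equal(h$height, dend$height)
  for (k in c(2, 3, 5)) {
    ct <- cutree(h, k)
    part <- cut_dendrogram(dend, k)
    # same partition up to relabeling
    expect_equal(length(unique(ct)), length(unique(part)))
    tab <- table(ct[names(part)], part)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})
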