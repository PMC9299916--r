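two_moa_matrix <- function() {
  cells <- matrix(c(1L, 1L, 1L, 0L,
                    0L, 1L, 1L, 1L), 2, 4, byrow = TRUE,
                  dimnames = list(c("a", "b"),
                                  c("s1", "s2", "s3", "s4")))
  incidence_matrix(cells)
}

test_that("prevalence network counts shared species", {
  net <- build_prevalence_network(two_moa_matrix())
  expect_equal(net$edges$weight, 2L)            # s2, s3 shared
  expect_equal(net$nodes$prevalence, c(3L, 3L)) # row sums
  expect_equal(net$flavour, "prevalence")
})

test_that("disjoint MoAs yield no edge but a recorded zero pair", {
  cells <- matrix(c(1L, 1L, 0L, 0L,
                    0L, 0L, 1L, 1L), 2, 4, byrow = TRUE,
                  dimnames = list(c("a", "b"), sprintf("s%d", 1:4)))
  net <- build_prevalence_network(incidence_matrix(cells))
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(net$pairs), 1L)
  expect_equal(net$pairs$weight, 0L)
})

test_that("total prevalence weight equals sum over species of C(m_s, 2)", {
  set.seed(42)
  for (rep in 1:10) {
    m <- incidence_matrix(random_incidence(6, 30))
    net <- build_prevalence_network(m)
    expect_equal(sum(net$pairs$weight),
                 sum(choose(colSums(m), 2)))
  }
})

test_that("proximity network is the complete weighted graph of similarities", {
  prox <- table1_proximity()
  net <- build_proximity_network(prox)
  expect_equal(nrow(net$edges), choose(10, 2))
  heaviest <- net$edges[which.max(net$edges$weight), ]
  expect_setequal(c(heaviest$moa_a, heaviest$moa_b), c("2", "5"))
  expect_equal(heaviest$weight, 0.526)
  for (i in seq_len(nrow(net$edges))) {
    expect_equal(net$edges$weight[i],
                 unclass(prox)[net$edges$moa_a[i], net$edges$moa_b[i]])
  }
})

test_that("network builds are permutation-invariant in node labels", {
  set.seed(17)
  m <- random_incidence(5, 20)
  n1 <- build_prevalence_network(incidence_matrix(m))
  n2 <- build_prevalence_network(incidence_matrix(m[sample(5), ]))
  key <- function(net) {
    p <- net$pairs
    setNames(p$weight, paste(pmin(p$moa_a, p$moa_b),
                             pmax(p$moa_a, p$moa_b)))
  }
  k1 <- key(n1); k2 <- key(n2)
  expect_mapequal(as.list(k1), as.list(k2))
})

test_that("correlate_networks uses all pairs and the t transform", {
  m <- suppressMessages(generate_incidence(synthetic_config(seed = 3)))$matrix
  f <- filter_matrix(merge_moa_groups(m), filter_policy())
  prev <- build_prevalence_network(f)
  prox <- build_proximity_network(proximity_matrix(f))
  res <- correlate_networks(prev, prox)
  expect_equal(res$n, choose(nrow(f), 2))
  expect_equal(res$df, res$n - 2L)
  expect_equal(res$r_squared, res$estimate^2)
  # with 10 nodes the df must be 43
  if (nrow(f) == 10L) expect_equal(res$df, 43L)
})

test_that("an affine increasing transform of weights gives r = 1", {
  net <- build_prevalence_network(two_moa_matrix())
  # need >2 pairs for a meaningful test: use a 4-MoA matrix
  set.seed(5)
  m <- incidence_matrix(random_incidence(4, 15))
  a <- build_prevalence_network(m)
  b <- a
  b$pairs$weight <- 3 * a$pairs$weight + 2
  b$flavour <- "proximity"
  expect_equal(correlate_networks(a, b)$estimate, 1)
})

test_that("constant weight vectors raise an undefined-correlation error", {
  cells <- matrix(1L, 3, 4, dimnames = list(letters[1:3], sprintf("s%d", 1:4)))
  a <- build_prevalence_network(incidence_matrix(cells))
  expect_error(correlate_networks(a, a), "constant")
})

test_that("hand-computed Pearson r on a 4-node toy matches", {
  labs <- c("a", "b", "c", "d")
  w1 <- c(3, 1, 0, 2, 5, 4)          # six pair weights
  w2 <- c(2, 1, 1, 3, 4, 5)
  # direct formula evaluation (the oracle)
  r_direct <- sum((w1 - mean(w1)) * (w2 - mean(w2))) /
    sqrt(sum((w1 - mean(w1))^2) * sum((w2 - mean(w2))^2))
  pairs <- data.frame(moa_a = c("a", "a", "a", "b", "b", "c"),
                      moa_b = c("b", "c", "d", "c", "d", "d"))
  nodes <- data.frame(moa = labs, prevalence = NA_integer_,
                      cluster = NA_integer_)
  mk <- function(w, fl) {
    p <- cbind(pairs, weight = w)
    structure(list(nodes = nodes, edges = p[p$weight > 0, ], pairs = p,
                   flavour = fl), class = "moa_network")
  }
  res <- correlate_networks(mk(w1, "prevalence"), mk(w2, "proximity"))
  expect_equal(res$estimate, r_direct)
  expect_equal(res$df, 4L)
})

test_that("graph exports round-trip weights and attributes", {
  part <- cut_dendrogram(agglomerate(to_distance(table1_proximity())), 3)
  net <- build_proximity_network(table1_proximity(), partition = part)
  g1 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, g1)
  back <- igraph::read_graph(g1, format = "graphml")
  expect_equal(igraph::ecount(back), 45)
  expect_setequal(igraph::V(back)$name, net$nodes$moa)
  expect_equal(sort(igraph::E(back)$weight), sort(net$edges$weight))
  expect_setequal(igraph::V(back)$cluster, 1:3)

  skip_if_not_installed("xml2")
  g2 <- withr::local_tempfile(fileext = ".gexf")
  write_network_gexf(net, g2)
  doc <- xml2::read_xml(g2)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:node", ns), 10)
  expect_length(xml2::xml_find_all(doc, "//d1:edge", ns), 45)

  g3 <- withr::local_tempfile(fileext = ".csv")
  write_network_edgelist(net, g3)
  el <- read.csv(g3)
  expect_named(el, c("moa_a", "moa_b", "weight"))
  expect_equal(nrow(el), 45)
})
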