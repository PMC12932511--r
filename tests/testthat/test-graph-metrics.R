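# Nodal metrics against closed-form cases, brute-force oracles and igraph.

path3 <- matrix(c(0, 1, 0,
                  1, 0, 1,
                  0, 1, 0), 3, 3)

test_that("metrics reproduce closed-form values on canonical graphs", {
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(unname(node_degree(k4)), rep(3L, 4))
  expect_equal(unname(clustering_coefficient(k4)), rep(1, 4))
  expect_equal(unname(local_efficiency(k4)), rep(1, 4))
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))

  expect_equal(unname(node_degree(path3)), c(1L, 2L, 1L))
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))

  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(unname(clustering_coefficient(star))[1], 0)
  expect_equal(unname(local_efficiency(star))[1], 0)

  # 4-cycle: the opposite pair has two geodesics, one through each node
  c4 <- matrix(0, 4, 4)
  c4[cbind(1:4, c(2, 3, 4, 1))] <- 1; c4 <- c4 + t(c4)
  expect_equal(unname(betweenness_centrality(c4)), rep(0.5, 4))

  # isolated node contributes zeros everywhere
  iso <- rbind(cbind(path3, 0), 0)
  m <- nodal_metrics(iso)
  expect_equal(unlist(m[4, c("bc", "c", "le", "nd")], use.names = FALSE),
               c(0, 0, 0, 0))
})

test_that("all four metrics match brute-force oracles on random graphs", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    a <- rand_adjacency(n, runif(1, 0.15, 0.7))
    expect_equal(unname(node_degree(a)), as.integer(rowSums(a)))
    expect_equal(unname(clustering_coefficient(a)), oracle_clustering(a),
                 tolerance = 1e-12)
    expect_equal(unname(betweenness_centrality(a)), oracle_betweenness(a),
                 tolerance = 1e-9)
    expect_equal(unname(local_efficiency(a)), oracle_local_efficiency(a),
                 tolerance = 1e-12)
  }
})

test_that("betweenness and clustering agree with igraph", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:10) {
    a <- rand_adjacency(10, 0.4)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(unname(betweenness_centrality(a)),
                 unname(igraph::betweenness(g)), tolerance = 1e-9)
    ig_c <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    expect_equal(unname(clustering_coefficient(a)), unname(ig_c),
                 tolerance = 1e-12)
  }
})

test_that("degree sum identity and density partition identity hold", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(6:14, 1)
    a <- rand_adjacency(n, 0.5)
    expect_equal(sum(node_degree(a)), sum(a))
    mask <- rep(FALSE, n); mask[sample(n, sample(2:(n - 2), 1))] <- TRUE
    net <- structure(list(adjacency = a, ez_mask = mask), class = "ez_network")
    d <- subnetwork_densities(net)
    expect_equal(d$e_ez + d$e_nez + d$e_cross, sum(a) / 2)
    # direct edge-count oracle
    expect_equal(d$e_ez, sum(a[mask, mask]) / 2)
    expect_equal(d$e_cross, sum(a[mask, !mask]))
    expect_equal(d$d_ez, d$e_ez / choose(sum(mask), 2))
    expect_equal(d$d_cross, d$e_cross / (sum(mask) * sum(!mask)))
  }
})

test_that("sub-network densities handle canonical and degenerate cases", {
  # EZ block of 3 nodes with 2 internal edges -> d_ez = 2/3
  a <- matrix(0, 5, 5)
  a[1, 2] <- a[2, 3] <- a[4, 5] <- 1
  a <- a + t(a)
  net <- structure(list(adjacency = a,
                        ez_mask = c(TRUE, TRUE, TRUE, FALSE, FALSE)),
                   class = "ez_network")
  expect_equal(subnetwork_densities(net)$d_ez, 2 / 3)
  # complete graph: every density is 1
  k6 <- matrix(1, 6, 6) - diag(6)
  net6 <- structure(list(adjacency = k6,
                         ez_mask = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)),
                    class = "ez_network")
  d6 <- subnetwork_densities(net6)
  expect_equal(c(d6$d_ez, d6$d_nez, d6$d_cross), c(1, 1, 1))
  # single-node module: internal density undefined, not zero
  net1 <- structure(list(adjacency = k6,
                         ez_mask = c(TRUE, rep(FALSE, 5))),
                    class = "ez_network")
  expect_true(is.na(subnetwork_densities(net1)$d_ez))
})

test_that("feature table has band x metric columns in schema order", {
  set.seed(3)
  rec <- new_recording("P1", "seeg", "interictal",
                       matrix(rnorm(6 * 1500), 6), 500,
                       ez_mask = c(TRUE, TRUE, rep(FALSE, 4)))
  nets <- lapply(decompose_bands(rec), function(b) binarize(pcc_matrix(b), 0.7))
  ft <- nodal_feature_table(nets)
  feat_cols <- setdiff(names(ft), c("patient_id", "node", "state",
                                    "modality", "ez_label"))
  expect_length(feat_cols, 28L)
  expect_true(all(grepl("^(full|delta|theta|alpha|beta|gamma|hf)_(bc|c|le|nd)$",
                        feat_cols)))
  expect_equal(ft$ez_label, c("EZ", "EZ", rep("NEZ", 4)))
  # definitional: full_nd equals the degree of the full-band network
  expect_equal(ft$full_nd, unname(node_degree(nets$full)))
  # two bands x four metrics -> eight feature columns
  ft2 <- nodal_feature_table(nets[c("alpha", "beta")])
  expect_length(setdiff(names(ft2), c("patient_id", "node", "state",
                                      "modality", "ez_label")), 8L)
  bad <- nets
  bad$full$labels <- rev(bad$full$labels)
  expect_error(nodal_feature_table(bad), "labels")
})
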