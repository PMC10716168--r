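test_that("distances use reciprocal weights with Dijkstra additivity", {
  d <- shortest_paths_matrix(p3(c(2, 2)))
  expect_equal(d[1, 2], 0.5)
  expect_equal(d[1, 3], 1.0)
  # disconnected dyads
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  expect_equal(shortest_paths_matrix(W)[1, 3], Inf)
})

test_that("hand-derived efficiencies, path length and strength on K3/P3", {
  K <- k3()
  expect_equal(global_efficiency(K), 1)
  expect_equal(nodal_efficiency(K), c(1, 1, 1))
  expect_equal(characteristic_path_length(K), 1)
  expect_equal(local_efficiency(K), 1)

  P <- p3()
  expect_equal(global_efficiency(P), 5 / 6)
  expect_equal(nodal_efficiency(P), c(0.75, 1, 0.75))
  expect_equal(as.numeric(characteristic_path_length(P)), 4 / 3)
  expect_equal(nodal_local_efficiency(P), c(0, 0, 0))

  P2 <- p3(c(2, 2))
  expect_equal(degree_strength(P2), c(2, 4, 2))
  expect_equal(network_strength(P2), 8 / 3)

  # star: leaves have singleton neighbourhoods, hub's neighbour graph is edgeless
  expect_equal(nodal_local_efficiency(star5()), rep(0, 5))
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
})

test_that("Onnela clustering scales by max weight and zeroes isolated nodes", {
  expect_equal(clustering_coefficient(k3())$nodal, c(1, 1, 1))
  cw <- clustering_coefficient(k3(c(4, 1, 1)))
  expect_equal(cw$nodal, rep((1 * 0.25 * 0.25)^(1 / 3), 3), tolerance = 1e-12)
  # isolated node has zero clustering
  W <- rbind(cbind(k3(), 0), 0)
  expect_equal(clustering_coefficient(W)$nodal[4], 0)
  # max-weight scaling makes clustering invariant to global rescaling
  expect_equal(clustering_coefficient(5 * k3(c(4, 1, 1)))$nodal, cw$nodal)
})

test_that("betweenness splits credit over tied shortest paths, normalised to [0,1]", {
  expect_equal(betweenness_centrality(p3()), c(0, 1, 0))
  expect_equal(betweenness_centrality(k3()), c(0, 0, 0))
  cyc <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; cyc[i, j] <- cyc[j, i] <- 1 }
  expect_equal(betweenness_centrality(cyc), rep(1 / 6, 4))
  expect_error(betweenness_centrality(k3()[1:2, 1:2]), "3 regions")
})

test_that("metrics agree with the brute-force oracle on random small graphs", {
  set.seed(7)
  for (i in 1:40) {
    W <- random_weighted_graph(sample(4:7, 1), density = stats::runif(1, 0.3, 0.8))
    o <- brute_metrics(W)
    expect_equal(global_efficiency(W), o$e_glob, tolerance = 1e-9)
    expect_equal(nodal_local_efficiency(W), o$n_eloc, tolerance = 1e-9)
    expect_equal(clustering_coefficient(W)$nodal, o$c_nodal, tolerance = 1e-9)
    expect_equal(betweenness_centrality(W), o$betweenness, tolerance = 1e-9)
  }
})

test_that("weight rescaling acts on metrics as the definitions dictate", {
  set.seed(3)
  W <- random_weighted_graph(6, 0.6)
  c <- 3.7
  expect_equal(global_efficiency(c * W), c * global_efficiency(W))
  expect_equal(degree_strength(c * W), c * degree_strength(W))
  expect_equal(as.numeric(characteristic_path_length(c * W)),
               as.numeric(characteristic_path_length(W)) / c)
  expect_equal(clustering_coefficient(c * W)$nodal, clustering_coefficient(W)$nodal)
  expect_equal(order(betweenness_centrality(c * W)), order(betweenness_centrality(W)))
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(5)
  for (i in 1:10) {
    W <- random_weighted_graph(6, 0.4)
    e0 <- global_efficiency(W)
    off <- which(W == 0 & upper.tri(W))
    if (!length(off)) next
    pick <- sample(off, 1)
    ij <- arrayInd(pick, dim(W))
    W[ij[1, 1], ij[1, 2]] <- 1; W[ij[1, 2], ij[1, 1]] <- 1
    expect_gte(global_efficiency(W), e0 - 1e-12)
  }
})

test_that("matched random networks preserve degrees and weights, reproducibly", {
  set.seed(2)
  W <- random_weighted_graph(12, 0.3)
  ens <- random_ensemble(W, n = 5, seed = 11)
  deg0 <- sort(rowSums(W > 0))
  w0 <- sort(W[upper.tri(W) & W > 0])
  for (e in ens) {
    expect_equal(sort(rowSums(e$weights > 0)), deg0)
    expect_equal(sort(e$weights[upper.tri(e$weights) & e$weights > 0]), w0)
  }
  ens2 <- random_ensemble(W, n = 5, seed = 11)
  expect_identical(lapply(ens, `[[`, "weights"), lapply(ens2, `[[`, "weights"))
  expect_error(random_ensemble(p3(c(1, 0))), "2 edges")
})

test_that("small-world ratios are 1 against the network itself and sigma = gamma/lambda", {
  W <- random_weighted_graph(10, 0.4)
  sw <- small_worldness(W, list(connectome(W)))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
  set.seed(4)
  ens <- random_ensemble(W, n = 20, seed = 9)
  sw2 <- small_worldness(W, ens)
  expect_equal(sw2$sigma, sw2$gamma / sw2$lambda)
})
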