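test_that("connectivity reproduces hand-computed Pearson coefficients", {
  net <- connectivity_matrix(rbind(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(net$w[1, 2], 1.0)
  net2 <- connectivity_matrix(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(net2$w[1, 2], -1.0)
  # direct evaluation of the double-sum definition gives 0.8
  expect_equal(pearson_oracle(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  net3 <- connectivity_matrix(rbind(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  expect_equal(net3$w[1, 2], 0.8)
})

test_that("connectivity matches the brute-force double-sum oracle to 1e-12", {
  for (s in 1:5) {
    set.seed(s)
    traces <- matrix(rnorm(10 * 50), 10, 50)
    net <- connectivity_matrix(traces)
    expect_lt(max(abs(net$w - connectivity_oracle(traces))), 1e-12)
    expect_identical(net$w, t(net$w))
    expect_equal(diag(net$w), rep(0, 10), ignore_attr = TRUE)
  }
})

test_that("zero-variance series are rejected by name", {
  traces <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(connectivity_matrix(traces), "b")
})

test_that("mean connectivity averages raw signed upper-triangle weights", {
  A <- matrix(0, 3, 3)
  A[upper.tri(A)] <- c(0.5, 0.7, 0.9)
  A <- A + t(A)
  expect_equal(mean_connectivity(as_network(A)), 0.7)
  expect_equal(mean_connectivity(as_network(matrix(0, 3, 3))), 0)
  # signed weights cancel: pairs {-0.5, +0.5, -0.5, +0.5, ...} average to 0
  S <- matrix(0, 4, 4)
  S[upper.tri(S)] <- c(-0.5, 0.5, -0.5, 0.5, -0.5, 0.5)
  S <- S + t(S)
  expect_equal(mean_connectivity(as_network(S)), 0)
})

test_that("strong ratio uses strict inequality at the threshold", {
  A <- matrix(0, 3, 3)
  A[upper.tri(A)] <- c(0.5, 0.7, 0.9)
  A <- A + t(A)
  expect_equal(strong_ratio(as_network(A)), 1 / 3)
  tie <- matrix(0.8, 3, 3); diag(tie) <- 0
  expect_equal(strong_ratio(as_network(tie)), 0)
  hi <- matrix(0.95, 3, 3); diag(hi) <- 0
  expect_equal(strong_ratio(as_network(hi)), 1)
})

test_that("region networks average within regions and drop empty ones", {
  p <- tiny_params(n_neurons = 12, response_amplitude = 0,
                   within_amplitude = 0, between_amplitude = 0)
  ds <- simulate_session(p, build_schedule(p, seed = 1), make_atlas(3),
                         seed = 1)
  # identical trace everywhere -> region correlation must be 1
  ds$traces <- matrix(rep(sin(seq_len(ncol(ds$traces)) / 7), each = 12), 12)
  ds$traces <- ds$traces + matrix(rnorm(length(ds$traces), 0, 1e-8), 12)
  net <- region_network(ds)
  expect_equal(net$w[upper.tri(net$w)],
               rep(1, sum(upper.tri(net$w))), tolerance = 1e-6)

  # force one region empty
  ds$region <- rep(c(0L, 1L), each = 6)
  net2 <- region_network(ds)
  expect_equal(nrow(net2$w), 2)
  expect_equal(attr(net2, "dropped_regions"), "R03")
})

test_that("regions carrying independent noise correlate near zero", {
  r <- c()
  for (s in 1:10) {
    p <- session_params(n_neurons = 20, n_sets = 1, reps_per_set = 1,
                        response_amplitude = 0, within_amplitude = 0,
                        between_amplitude = 0, noise_sd = 0.5)
    ds <- simulate_session(p, build_schedule(p, seed = s), make_atlas(4),
                           seed = s + 100)
    net <- region_network(ds)
    r <- c(r, net$w[upper.tri(net$w)])
  }
  expect_lt(abs(mean(r)), 0.05)
  expect_lt(max(abs(r)), 0.3)
})

test_that("spectral partitioning recovers a planted two-block structure", {
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 0.9; A[6:10, 6:10] <- 0.9
  diag(A) <- 0
  part <- spectral_partition(as_network(A), k = 2, seed = 1)
  expect_equal(length(unique(part$membership[1:5])), 1)
  expect_equal(length(unique(part$membership[6:10])), 1)
  expect_false(part$membership[1] == part$membership[6])
})

test_that("k = n gives singletons and node order does not change the partition", {
  A <- random_graph(6, seed = 2)
  net <- as_network(A)
  singles <- spectral_partition(net, k = 6, seed = 1)
  expect_equal(sort(unique(singles$membership)), 0:5)

  A2 <- matrix(0, 9, 9)
  A2[1:3, 1:3] <- 0.9; A2[4:6, 4:6] <- 0.9; A2[7:9, 7:9] <- 0.9
  A2[1:3, 4:6] <- A2[4:6, 1:3] <- 0.1
  diag(A2) <- 0
  perm <- c(4, 8, 1, 6, 2, 9, 3, 7, 5)
  p1 <- spectral_partition(as_network(A2), k = 3, seed = 1)$membership
  p2 <- spectral_partition(as_network(A2[perm, perm]), k = 3, seed = 1)$membership
  # same partition up to relabeling
  expect_equal(length(unique(paste(p1[perm], p2))), 3)
})

test_that("modularity matches the worked two-triangle case", {
  # two disjoint unit-weight triangles
  tri <- matrix(0, 6, 6)
  tri[1:3, 1:3] <- 1; tri[4:6, 4:6] <- 1
  diag(tri) <- 0
  net <- as_network(tri)
  part <- list(membership = c(0, 0, 0, 1, 1, 1))
  # oracle first: the literal double loop gives 0.5 at gamma 1, 0 at gamma 2
  expect_equal(modularity_oracle(tri, part$membership, 1), 0.5)
  expect_equal(modularity_oracle(tri, part$membership, 2), 0)
  expect_equal(network_modularity(net, part), 0.5)
  expect_equal(network_modularity(net, part, modularity_params(gamma = 2)), 0)
})

test_that("single-community modularity is exactly zero at gamma 1", {
  for (s in 1:10) {
    A <- random_graph(sample(3:10, 1), seed = s)
    net <- as_network(A)
    one <- list(membership = rep(0L, nrow(A)))
    expect_equal(network_modularity(net, one), 0, tolerance = 1e-14)
  }
})

test_that("modularity agrees with the brute-force oracle on random graphs", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(3:10, 1)
    A <- random_graph(n, seed = s + 1000)
    memb <- sample(0:2, n, replace = TRUE)
    g <- runif(1, 0.5, 2)
    q1 <- network_modularity(as_network(A), list(membership = memb),
                             modularity_params(gamma = g))
    expect_lt(abs(q1 - modularity_oracle(A, memb, g)), 1e-12)
  }
})

test_that("modularity agrees with igraph as an independent cross-check", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    A <- random_graph(8, seed = s)
    memb <- sample(0:1, 8, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    q_ig <- igraph::modularity(g, memb + 1,
                               weights = igraph::E(g)$weight)
    q <- network_modularity(as_network(A), list(membership = memb))
    expect_equal(q, q_ig, tolerance = 1e-12)
  }
})

test_that("negative-weight policies transform the matrix as declared", {
  A <- matrix(c(0, -0.4, -0.4, 0), 2, 2)
  net <- as_network(A)
  expect_error(network_modularity(net, list(membership = c(0, 1))),
               "zero")   # clip leaves no weight
  expect_equal(degree_centrality(net, modularity_params(negative = "abs")),
               c(V1 = 0.4, V2 = 0.4))
  expect_error(degree_centrality(net, modularity_params(negative = "error")),
               "negative")
})

test_that("degree centrality is the row sum of incident weights", {
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(unname(degree_centrality(as_network(path))), c(1, 2, 1))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(unname(degree_centrality(as_network(star))), c(4, 1, 1, 1, 1))
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2; w[1, 3] <- w[3, 1] <- 0.3
  expect_equal(unname(degree_centrality(as_network(w))[1]), 0.5)
  # binary mode counts strict exceedances
  expect_equal(unname(degree_centrality(as_network(star), binary = TRUE,
                                        threshold = 0.8)), c(4, 1, 1, 1, 1))
})

test_that("network metrics are invariant under simultaneous node permutation", {
  A <- random_graph(7, seed = 9)
  memb <- c(0, 0, 1, 1, 1, 2, 2)
  perm <- sample(7)
  net <- as_network(A)
  netp <- as_network(A[perm, perm])
  expect_equal(mean_connectivity(net), mean_connectivity(netp))
  expect_equal(strong_ratio(net, 0.5), strong_ratio(netp, 0.5))
  expect_equal(network_modularity(net, list(membership = memb)),
               network_modularity(netp, list(membership = memb[perm])))
  expect_equal(unname(degree_centrality(net)[perm]),
               unname(degree_centrality(netp)))
})

test_that("greedy partitioning finds the planted communities of a clean block graph", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1
  diag(A) <- 0
  part <- greedy_partition(as_network(A))
  expect_equal(part$k, 2)
  expect_equal(network_modularity(as_network(A), part), 0.5)
})
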