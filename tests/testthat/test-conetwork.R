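test_that("Spearman correlations match the mid-rank Pearson oracle", {
  x <- 1:5; y <- c(5, 6, 7, 8, 7)
  sp <- spearman_matrix(cbind(x = x, y = y))
  expect_equal(sp$rho["x", "y"], 8 / sqrt(95), tolerance = 1e-12)
  expect_equal(sp$rho["x", "y"], oracle_spearman(x, y), tolerance = 1e-12)
  # monotone pair and its mirror image
  z <- exp(1:5)
  sp2 <- spearman_matrix(cbind(x = x, z = z, nz = -z))
  expect_equal(sp2$rho["x", "z"], 1)
  expect_equal(sp2$rho["x", "nz"], -1)
  expect_equal(sp2$p["x", "z"], 0)
})

test_that("Spearman handles constant columns and random ties vs oracle", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 2, 2, 2, 2),
             c = c(1, 1, 2, 3, 3))
  sp <- spearman_matrix(m)
  expect_identical(sp$constant, "b")
  expect_true(all(is.na(sp$rho["b", ])))
  expect_equal(sp$rho["a", "c"], oracle_spearman(m[, "a"], m[, "c"]),
               tolerance = 1e-12)
  set.seed(10)
  for (i in 1:20) {
    x <- sample(1:4, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(spearman_matrix(cbind(x, y))$rho["x", "y"],
                 oracle_spearman(x, y), tolerance = 1e-12)
  }
  expect_error(spearman_matrix(m[1:3, ]), ">= 4 samples")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_adjust(0.123), 0.123)
  set.seed(11)
  for (i in 1:20) {
    p <- runif(15)
    expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("network edges are monotone in both retention thresholds", {
  cfg <- simulation_config(n_sites = 20, habitats = "sediment", n_taxa = 60,
                           n_guilds = 3, guild_correlation = 0.9, seed = 12)
  sim <- simulate_abundances(cfg)
  rhos <- c(0.5, 0.65, 0.8, 0.9)
  counts <- vapply(rhos, function(r) {
    nrow(build_network(sim$abundance, rho_threshold = r)$edges)
  }, 0)
  expect_true(all(diff(counts) <= 0))
  qs <- c(0.05, 0.01, 0.001)
  countsq <- vapply(qs, function(q) {
    nrow(build_network(sim$abundance, q_threshold = q)$edges)
  }, 0)
  expect_true(all(diff(countsq) <= 0))
})

test_that("the abundance pre-filter removes rare taxa before correlation", {
  set.seed(13)
  m <- matrix(rpois(20 * 10, 50), 20, 10)
  m[, 10] <- rep(c(0, 1), 10)   # rare taxon, well under 0.01% summed
  colnames(m) <- paste0("t", 1:10)
  net <- build_network(abundance_matrix(m), min_rel_abund = 0.05)
  expect_false("t10" %in% igraph::V(net$graph)$name)
  net_all <- build_network(abundance_matrix(m), min_rel_abund = 0)
  expect_true("t10" %in% igraph::V(net_all$graph)$name)
  expect_error(build_network(abundance_matrix(m[1:3, ])), ">= 4 samples")
})

test_that("planted guilds are recovered with few spurious edges", {
  cfg <- simulation_config(n_sites = 40, habitats = "sediment",
                           n_taxa = 100, n_guilds = 3, guild_size = 10,
                           guild_correlation = 0.95, seed = 14)
  sim <- simulate_abundances(cfg)
  net <- build_network(sim$abundance)
  g <- sim$truth$guild
  ga <- g[net$edges$taxon_a]; gb <- g[net$edges$taxon_b]
  within <- sum(ga > 0 & ga == gb)
  cross <- sum(ga > 0 & gb > 0 & ga != gb)
  expect_gte(within / (3 * choose(10, 2)), 0.8)
  expect_lte(cross / (choose(30, 2) - 3 * choose(10, 2)), 0.05)
})

test_that("textbook graphs give their known topological values", {
  k3 <- topological_metrics(igraph::make_full_graph(3))
  expect_equal(k3$connectance, 1)
  expect_equal(k3$clustering_coefficient, 1)
  expect_equal(k3$diameter, 1)
  expect_equal(k3$average_path_length, 1)
  expect_equal(k3$edge_connectivity, 2)

  p3 <- topological_metrics(igraph::make_graph(~ a - b, b - c))
  expect_equal(p3$average_path_length, 4 / 3)
  expect_equal(p3$diameter, 2)
  expect_equal(p3$clustering_coefficient, 0)
  expect_equal(p3$connectance, 2 / 3)

  star <- topological_metrics(igraph::make_star(4, mode = "undirected"))
  expect_equal(star$degree_centralization, 1)
  expect_equal(star$betweenness_centralization, 1)
  expect_equal(star$edge_connectivity, 1)

  k4 <- topological_metrics(igraph::make_full_graph(4))
  expect_equal(k4$degree_centralization, 0)
  expect_equal(k4$mean_degree, 3)
})

test_that("degenerate graphs return the declared conventions", {
  empty1 <- topological_metrics(igraph::make_empty_graph(1, directed = FALSE))
  expect_equal(empty1$node_number, 1)
  expect_equal(empty1$edge_number, 0)
  expect_equal(empty1$average_path_length, 0)
  expect_equal(empty1$diameter, 0)
  expect_equal(empty1$connectance, 0)
  expect_equal(empty1$clustering_coefficient, 0)
  # disconnected: path metrics from the largest component, connectivity 0
  two <- igraph::graph_from_literal(a - b, b - c, d - e)
  m <- topological_metrics(two)
  expect_equal(m$n_components, 2)
  expect_equal(m$average_path_length, 4 / 3)
  expect_equal(m$diameter, 2)
  expect_equal(m$edge_connectivity, 0)
})

test_that("all ten metrics agree with exhaustive oracles on random graphs", {
  set.seed(15)
  for (i in 1:40) {
    n <- sample(2:10, 1)
    A <- random_adjacency(n, runif(1, 0.15, 0.7))
    got <- topological_metrics(graph_from_adjacency01(A))
    want <- oracle_graph_metrics(A)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("subnetworks are induced on the taxa present in a sample", {
  cfg <- simulation_config(n_sites = 15, habitats = "sediment", n_taxa = 50,
                           n_guilds = 2, guild_correlation = 0.95, seed = 16)
  sim <- simulate_abundances(cfg)
  net <- build_network(sim$abundance)
  ab <- sim$abundance
  # a sample containing every network taxon reproduces whole-network metrics
  full <- ab$values[1, , drop = FALSE] + 1
  afull <- abundance_matrix(full, metadata = ab$metadata[1, , drop = FALSE])
  m_full <- sample_subnetwork(net, afull)
  whole <- topological_metrics(net$graph)
  expect_equal(m_full[, names(whole)], whole)
  # a sample with a single present taxon hits the degenerate contract
  one <- ab$values[1, , drop = FALSE] * 0
  one[1, igraph::V(net$graph)$name[1]] <- 5
  aone <- abundance_matrix(one)
  m_one <- sample_subnetwork(net, aone, rownames(one)[1])
  expect_equal(m_one$node_number, 1)
  expect_equal(m_one$edge_number, 0)
  expect_equal(m_one$average_path_length, 0)
  expect_error(sample_subnetwork(net, ab, "nope"), "unknown sample")
  # per-sample extraction equals the brute-force induced-subgraph oracle
  metr <- sample_subnetwork(net, ab)
  s3 <- rownames(ab$values)[3]
  present <- colnames(ab$values)[ab$values[s3, ] > 0]
  verts <- intersect(igraph::V(net$graph)$name, present)
  A <- as.matrix(igraph::as_adjacency_matrix(
    igraph::induced_subgraph(net$graph, verts)))
  expect_equal(metr[metr$sample == s3, -1],
               oracle_graph_metrics(A), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("modularity detection matches the direct Q formula", {
  g2 <- igraph::graph_from_literal(a - b, b - c, a - c, d - e, e - f, d - f)
  res <- network_modularity(g2)
  expect_equal(res$Q, 0.5)
  expect_equal(length(unique(res$membership)), 2)
  A <- as.matrix(igraph::as_adjacency_matrix(g2))
  expect_equal(oracle_modularity_q(A, res$membership[rownames(A)]), 0.5)
  # complete graph: no structure, detected Q not below the trivial partition
  k5 <- igraph::make_full_graph(5)
  expect_equal(network_modularity(k5)$Q, 0, tolerance = 1e-12)
  expect_error(network_modularity(igraph::make_empty_graph(3,
                                                           directed = FALSE)),
               "edgeless")
})

test_that("complexity index is PC1 of the flipped, z-scored metric table", {
  set.seed(17)
  # rank-1 table: every column a multiple of one latent vector
  base <- rnorm(10)
  m <- data.frame(edge_number = 3 * base + 5, mean_degree = -2 * base,
                  clustering_coefficient = 0.5 * base)
  cx <- complexity_index(m)
  expect_equal(cx$variance_explained, 1)
  expect_gte(cx$loadings["edge_number"], 0)
  expect_equal(mean(cx$scores), 0, tolerance = 1e-10)
  # scores match an independent eigendecomposition of the correlation matrix
  m2 <- as.data.frame(matrix(rnorm(8 * 4), 8, 4,
    dimnames = list(NULL, c("edge_number", "node_number",
                            "average_path_length", "diameter"))))
  cx2 <- complexity_index(m2)
  flipped <- m2
  flipped$average_path_length <- -flipped$average_path_length
  flipped$diameter <- -flipped$diameter
  z <- scale(as.matrix(flipped))
  ev <- eigen(cor(as.matrix(flipped)))
  sc <- z %*% ev$vectors[, 1]
  if (sum(sc * cx2$scores) < 0) sc <- -sc
  expect_equal(unname(cx2$scores), drop(sc), tolerance = 1e-8)
  expect_equal(cx2$variance_explained, ev$values[1] / 4, tolerance = 1e-8)
})

test_that("the sparsity flip is applied exactly once", {
  set.seed(18)
  m <- as.data.frame(matrix(rnorm(9 * 3), 9, 3,
    dimnames = list(NULL, c("edge_number", "mean_degree",
                            "average_path_length"))))
  cx <- complexity_index(m)
  pre <- m
  pre$average_path_length <- -pre$average_path_length  # user pre-flip
  cx_pre <- complexity_index(pre)
  # the internal flip acts once in each call, so the two runs see opposite
  # path-length columns: identical scores, opposite loading on that metric
  expect_equal(abs(cx$scores), abs(cx_pre$scores), tolerance = 1e-10)
  expect_equal(cx$loadings["average_path_length"],
               -cx_pre$loadings["average_path_length"], tolerance = 1e-10)
  expect_error(complexity_index(data.frame(edge_number = rep(1, 5),
                                           mean_degree = rep(2, 5))),
               "nonzero variance")
})
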