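# Brute-force oracles, implemented independently of the package internals
# (explicit enumeration, Floyd-Warshall-style BFS, direct formulas) so that
# implementation and check never share code paths.

# mid-ranks without rank()
oracle_midrank <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (1 + sum(x == xi)) / 2, 0)
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- p[ord] * m / seq_len(m)
  # step-up: cumulative min from the largest rank down
  for (i in rev(seq_len(m))) {
    adj[i] <- min(adj[i:m], 1)
  }
  q[ord] <- adj
  q
}

# --- graph oracles on a 0/1 adjacency matrix ------------------------------

oracle_bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(A[u, ] == 1)) {
        if (is.infinite(d[v])) { d[v] <- d[u] + 1; nxt <- c(nxt, v) }
      }
    }
    frontier <- unique(nxt)
  }
  d
}

oracle_components <- function(A) {
  n <- nrow(A)
  memb <- rep(0L, n); cid <- 0L
  for (s in seq_len(n)) {
    if (memb[s] == 0L) {
      cid <- cid + 1L
      memb[is.finite(oracle_bfs_dist(A, s))] <- cid
    }
  }
  memb
}

# enumerate all shortest s-t paths by walking the BFS distance field backwards
oracle_all_shortest_paths <- function(A, s, t, d) {
  if (!is.finite(d[t]) || s == t) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- which(A[v, ] == 1 & d == d[v] - 1)
    out <- list()
    for (u in preds) {
      for (pp in walk(u)) out[[length(out) + 1]] <- c(pp, v)
    }
    out
  }
  walk(t)
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  btw <- rep(0, n)
  for (s in seq_len(n - 1)) {
    d <- oracle_bfs_dist(A, s)
    for (t in (s + 1):n) {
      paths <- oracle_all_shortest_paths(A, s, t, d)
      if (!length(paths)) next
      through <- rep(0, n)
      for (pp in paths) {
        interior <- setdiff(pp, c(s, t))
        through[interior] <- through[interior] + 1
      }
      btw <- btw + through / length(paths)
    }
  }
  btw
}

oracle_min_cut <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {   # vertex 1 always on side 0
    side <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1)])
    cross <- sum(A[side == 0, side == 1, drop = FALSE])
    best <- min(best, cross)
  }
  best
}

oracle_graph_metrics <- function(A) {
  n <- nrow(A)
  e <- sum(A) / 2
  deg <- rowSums(A)
  memb <- if (n) oracle_components(A) else integer(0)
  n_comp <- length(unique(memb))
  # largest component, ties to the one containing the lowest vertex index
  lcc <- if (n) {
    sizes <- table(memb)
    big <- as.integer(names(sizes)[sizes == max(sizes)])
    pick <- big[which.min(vapply(big, function(b) min(which(memb == b)), 0L))]
    which(memb == pick)
  } else integer(0)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) D[s, ] <- oracle_bfs_dist(A, s)
  if (e == 0 || n < 2) {
    apl <- 0; diam <- 0; econn <- 0
  } else {
    dl <- D[lcc, lcc, drop = FALSE]
    pairs <- dl[upper.tri(dl)]
    apl <- if (length(pairs)) mean(pairs) else 0
    diam <- if (length(pairs)) max(pairs) else 0
    econn <- if (n_comp > 1) 0 else oracle_min_cut(A)
  }
  tri <- 0
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      tri <- tri + A[i, j] * A[j, k] * A[i, k]
    }
  }
  triplets <- sum(choose(deg, 2))
  btw <- oracle_betweenness(A)
  data.frame(
    node_number = n, edge_number = e,
    betweenness_centralization = if (n >= 3) {
      sum(max(btw) - btw) / ((n - 1)^2 * (n - 2) / 2)
    } else 0,
    mean_degree = if (n) 2 * e / n else 0,
    average_path_length = apl,
    connectance = if (n >= 2) 2 * e / (n * (n - 1)) else 0,
    diameter = diam, edge_connectivity = econn,
    degree_centralization = if (n >= 3) {
      sum(max(deg) - deg) / ((n - 1) * (n - 2))
    } else 0,
    clustering_coefficient = if (triplets > 0) 3 * tri / triplets else 0,
    n_components = n_comp
  )
}

oracle_modularity_q <- function(A, membership) {
  m <- sum(A) / 2
  deg <- rowSums(A)
  q <- 0
  for (cc in unique(membership)) {
    idx <- membership == cc
    e_in <- sum(A[idx, idx]) / 2
    q <- q + e_in / m - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

# ANOSIM R by the direct rank formula (vegan convention: divisor n(n-1)/4)
oracle_anosim_R <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  lower <- which(lower.tri(d))
  vals <- d[lower]
  rk <- oracle_midrank(vals)
  same <- outer(groups, groups, "==")[lower]
  (mean(rk[!same]) - mean(rk[same])) / (n * (n - 1) / 4)
}

random_adjacency <- function(n, p_edge = 0.4) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(runif(length(up)) < p_edge)
  A + t(A)
}

graph_from_adjacency01 <- function(A) {
  dimnames(A) <- list(paste0("v", seq_len(nrow(A))),
                      paste0("v", seq_len(nrow(A))))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# small simulated configs shared by several tests
tiny_function_table <- function(values, categories = NULL, directions = NULL) {
  p <- ncol(values)
  schema <- data.frame(
    function_id = colnames(values),
    category = categories %||% rep("nutrient_pool", p),
    direction = directions %||% rep(1L, p)
  )
  meta <- data.frame(
    site_id = paste0("s", seq_len(nrow(values))),
    habitat = "sediment",
    latitude = seq(25, 40, length.out = nrow(values))
  )
  function_table(values, meta, schema)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
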