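#' Pairwise Spearman correlation matrix with p-values
#'
#' Spearman rank correlation (mid-ranks for ties) between all pairs of taxa,
#' with two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (p = 0 at |rho| = 1). Constant taxa have undefined correlations: their
#' rows/columns are `NA` and they are reported in the `constant` attribute.
#'
#' @param a An [abundance_matrix()] or a numeric samples-by-variables matrix.
#' @return List with `rho` and `p` (symmetric matrices, unit/NA diagonal),
#'   `n` (number of samples) and `constant` (names of constant columns).
#' @export
spearman_matrix <- function(a) {
  m <- if (inherits(a, "abundance_matrix")) a$values else as.matrix(a)
  n <- nrow(m)
  if (n < 4) stop("need >= 4 samples for correlation inference", call. = FALSE)
  const <- apply(m, 2, function(x) length(unique(x)) == 1)
  r <- apply(m, 2, rank)               # mid-ranks; Spearman = Pearson of ranks
  rho <- suppressWarnings(cor(r))
  rho[const, ] <- NA
  rho[, const] <- NA
  p <- spearman_p(rho, n)
  diag(p) <- NA
  list(rho = rho, p = p, n = n, constant = colnames(m)[const])
}

spearman_p <- function(rho, n) {
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-15] <- 0
  p[is.na(rho)] <- NA
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `min_k>=rank (p_k * m / k)`, monotone in the
#' original p-values and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   preserved).
#' @return Vector of q-values, same length and names as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Build a co-occurrence network from an abundance matrix
#'
#' Taxa whose summed relative abundance across the input samples falls below
#' `min_rel_abund` (default 1e-4, i.e. 0.01%) are removed first. Spearman
#' correlations are then computed between all remaining taxon pairs, p-values
#' are Benjamini-Hochberg adjusted over that whole family, and an edge is
#' retained when `|rho| > rho_threshold` and `q < q_threshold` (defaults 0.65
#' and 0.01). Set `positive_only = TRUE` to keep co-presence edges only.
#'
#' @param a An [abundance_matrix()] of counts or relative abundances.
#' @param rho_threshold Absolute-correlation threshold (strict `>`).
#' @param q_threshold FDR threshold (strict `<`).
#' @param min_rel_abund Minimum summed relative abundance for a taxon to
#'   enter the correlation step.
#' @param positive_only Drop negative-correlation edges.
#' @return Object of class `cooccurrence_network`: list with `graph` (an
#'   [igraph::graph] whose vertices are the retained taxa, edge attributes
#'   `rho` and `q`), `edges` (data.frame `taxon_a`, `taxon_b`, `rho`, `q`),
#'   `params` and `n_samples`.
#' @export
#' @examples
#' sim <- simulate_abundances(simulation_config(n_sites = 15, n_taxa = 40,
#'                                              n_guilds = 2, seed = 2,
#'                                              guild_correlation = 0.95))
#' net <- build_network(sim$abundance)
#' net
build_network <- function(a, rho_threshold = 0.65, q_threshold = 0.01,
                          min_rel_abund = 1e-4, positive_only = FALSE) {
  stopifnot(inherits(a, "abundance_matrix"))
  if (nrow(a$values) < 4) {
    stop("need >= 4 samples to build a co-occurrence network", call. = FALSE)
  }
  rel <- to_relative(a)
  keep <- colSums(rel$values) >= min_rel_abund
  m <- a$values[, keep, drop = FALSE]
  if (ncol(m) < 2) stop("fewer than 2 taxa pass the abundance filter",
                        call. = FALSE)
  sp <- spearman_matrix(m)
  ut <- upper.tri(sp$rho)
  q <- matrix(NA_real_, nrow(sp$p), ncol(sp$p), dimnames = dimnames(sp$p))
  q[ut] <- fdr_adjust(sp$p[ut])
  sel <- which(ut & !is.na(sp$rho) & abs(sp$rho) > rho_threshold &
                 !is.na(q) & q < q_threshold, arr.ind = TRUE)
  if (positive_only && nrow(sel)) {
    sel <- sel[sp$rho[sel] > 0, , drop = FALSE]
  }
  edges <- data.frame(
    taxon_a = colnames(m)[sel[, 1]],
    taxon_b = colnames(m)[sel[, 2]],
    rho = sp$rho[sel],
    q = q[sel],
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = colnames(m), stringsAsFactors = FALSE)
  )
  structure(
    list(graph = g, edges = edges,
         params = list(rho_threshold = rho_threshold,
                       q_threshold = q_threshold,
                       min_rel_abund = min_rel_abund,
                       positive_only = positive_only),
         n_samples = nrow(m), constant_taxa = sp$constant),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network: ", igraph::vcount(x$graph), " taxa, ",
      nrow(x$edges), " edges (|rho| > ", x$params$rho_threshold,
      ", q < ", x$params$q_threshold, ", ", x$n_samples, " samples)\n",
      sep = "")
  if (nrow(x$edges)) {
    cat(sprintf("  positive edges: %d, negative edges: %d\n",
                sum(x$edges$rho > 0), sum(x$edges$rho < 0)))
  }
  invisible(x)
}

largest_component <- function(g) {
  comp <- igraph::components(g)
  if (comp$no <= 1) return(g)
  big <- which(comp$csize == max(comp$csize))
  # ties broken by the component containing the lowest-index vertex
  pick <- big[which.min(vapply(big, function(b) min(which(comp$membership == b)),
                               0L))]
  igraph::induced_subgraph(g, which(comp$membership == pick))
}

#' Ten topological metrics of an undirected graph
#'
#' Computes node number, edge number, mean degree, connectance (realized
#' fraction of possible edges), average path length, diameter, edge
#' connectivity, degree centralization, betweenness centralization and the
#' global clustering coefficient (transitivity), plus the number of connected
#' components. Centralizations use Freeman normalization against the
#' star-graph maximum (betweenness over unordered pairs, endpoints excluded).
#' When the graph is disconnected, average path length and diameter are
#' computed on the largest connected component (ties broken by lowest vertex
#' index) and edge connectivity is 0. Degenerate graphs (fewer than 2 nodes
#' or no edges) return 0 for path metrics, clustering and connectance.
#'
#' @param g An [igraph::graph] (undirected, simple).
#' @return One-row data.frame with columns `node_number`, `edge_number`,
#'   `betweenness_centralization`, `mean_degree`, `average_path_length`,
#'   `connectance`, `diameter`, `edge_connectivity`,
#'   `degree_centralization`, `clustering_coefficient`, `n_components`.
#' @export
#' @examples
#' topological_metrics(igraph::make_full_graph(3))
topological_metrics <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) stop("graph must be undirected", call. = FALSE)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) {
    comp_no <- 0L
  } else {
    comp_no <- igraph::components(g)$no
  }
  deg <- if (n) igraph::degree(g) else numeric(0)
  mean_degree <- if (n) 2 * e / n else 0
  connectance <- if (n >= 2) 2 * e / (n * (n - 1)) else 0
  # Freeman centralizations (0 when the star maximum is 0, i.e. n < 3)
  degree_centralization <- if (n >= 3) {
    sum(max(deg) - deg) / ((n - 1) * (n - 2))
  } else 0
  btw <- if (n) igraph::betweenness(g, directed = FALSE) else numeric(0)
  betweenness_centralization <- if (n >= 3) {
    sum(max(btw) - btw) / ((n - 1)^2 * (n - 2) / 2)
  } else 0
  if (e == 0 || n < 2) {
    apl <- 0; diam <- 0; econn <- 0
  } else {
    lcc <- largest_component(g)
    apl <- if (igraph::vcount(lcc) >= 2) {
      igraph::mean_distance(lcc, directed = FALSE)
    } else 0
    diam <- igraph::diameter(lcc, directed = FALSE, unconnected = FALSE)
    econn <- if (comp_no > 1) 0 else igraph::edge_connectivity(g)
  }
  cc <- igraph::transitivity(g, type = "global")
  if (is.nan(cc) || is.na(cc)) cc <- 0
  data.frame(
    node_number = n, edge_number = e,
    betweenness_centralization = betweenness_centralization,
    mean_degree = mean_degree, average_path_length = apl,
    connectance = connectance, diameter = as.numeric(diam),
    edge_connectivity = econn,
    degree_centralization = degree_centralization,
    clustering_coefficient = cc, n_components = comp_no
  )
}

#' Per-sample subnetwork metrics
#'
#' Extracts the subgraph of a co-occurrence network induced by the taxa
#' present (abundance > 0) in one sample and computes its topological
#' metrics, so network complexity can be attributed to individual samples.
#'
#' @param net A [build_network()] result.
#' @param a The [abundance_matrix()] holding the sample (taxa matched by
#'   name to the network's vertices).
#' @param sample Sample id (row name of `a`), or omit to compute metrics for
#'   every sample.
#' @return One-row data.frame per requested sample (column `sample` first),
#'   as in [topological_metrics()].
#' @export
sample_subnetwork <- function(net, a, sample = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"),
            inherits(a, "abundance_matrix"))
  samples <- sample %||% rownames(a$values)
  missing <- setdiff(samples, rownames(a$values))
  if (length(missing)) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(samples, function(s) {
    present <- colnames(a$values)[a$values[s, ] > 0]
    verts <- intersect(igraph::V(net$graph)$name, present)
    sub <- igraph::induced_subgraph(net$graph, verts)
    cbind(data.frame(sample = s, stringsAsFactors = FALSE),
          topological_metrics(sub))
  })
  do.call(rbind, out)
}

#' Modularity of a co-occurrence network
#'
#' Greedy agglomerative maximization of Newman-Girvan modularity
#' (deterministic; [igraph::cluster_fast_greedy()]). Values above 0.4 are
#' conventionally read as modular structure.
#'
#' @param g An [igraph::graph] or a [build_network()] result.
#' @return List with `Q` (modularity of the detected partition) and
#'   `membership` (named integer vector of community ids).
#' @export
network_modularity <- function(g) {
  if (inherits(g, "cooccurrence_network")) g <- g$graph
  stopifnot(igraph::is_igraph(g))
  if (igraph::ecount(g) == 0) {
    stop("modularity undefined for an edgeless graph", call. = FALSE)
  }
  cl <- igraph::cluster_fast_greedy(g)
  list(Q = igraph::modularity(cl),
       membership = setNames(igraph::membership(cl),
                             igraph::V(g)$name))
}

#' Composite network-complexity index
#'
#' Principal-component summary of a table of per-sample subnetwork metrics.
#' Average path length and diameter are negated first (they measure network
#' sparsity, not complexity), each metric is z-scored, and the first
#' principal axis is returned as the complexity score. The axis is oriented
#' so that its loading on `edge_number` is non-negative (falling back to the
#' largest-magnitude loading if `edge_number` is absent or constant), making
#' higher scores mean more complex networks.
#'
#' @param m data.frame of per-sample metrics (e.g. from
#'   [sample_subnetwork()]); non-numeric columns and `n_components` are
#'   ignored; zero-variance metrics are dropped with a message.
#' @return Object of class `complexity_index`: list with `scores` (named,
#'   zero-mean), `loadings`, `variance_explained` (share of variance on
#'   axis 1) and `metrics_used`.
#' @export
complexity_index <- function(m) {
  m <- as.data.frame(m)
  rn <- if ("sample" %in% names(m)) m$sample else rownames(m)
  num <- m[, setdiff(names(m)[vapply(m, is.numeric, TRUE)], "n_components"),
           drop = FALSE]
  if (nrow(num) < 3) stop("need >= 3 samples for the complexity index",
                          call. = FALSE)
  for (col in intersect(c("average_path_length", "diameter"), names(num))) {
    num[[col]] <- -num[[col]]  # sparsity measures enter negated
  }
  keep <- vapply(num, function(x) sd(x) > 0, TRUE)
  if (sum(keep) < 2) {
    stop("need >= 2 metrics with nonzero variance", call. = FALSE)
  }
  if (any(!keep)) {
    message("dropping constant metric(s): ",
            paste(names(num)[!keep], collapse = ", "))
  }
  num <- num[, keep, drop = FALSE]
  z <- scale(as.matrix(num))
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  ref <- if ("edge_number" %in% names(loadings)) {
    loadings["edge_number"]
  } else 0
  if (ref == 0) ref <- loadings[which.max(abs(loadings))]
  if (ref < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  structure(
    list(scores = setNames(unname(scores), rn),
         loadings = loadings,
         variance_explained = unname(pc$sdev[1]^2 / sum(pc$sdev^2)),
         metrics_used = colnames(num)),
    class = "complexity_index"
  )
}

#' @export
print.complexity_index <- function(x, ...) {
  cat("Network-complexity index (PC1 of ", length(x$metrics_used),
      " metrics): ", sprintf("%.1f%%", 100 * x$variance_explained),
      " of variance\n", sep = "")
  cat("Loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}
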