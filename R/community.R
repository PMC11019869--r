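#' Alpha diversity: observed richness and Shannon index
#'
#' Observed richness is the number of taxa with non-zero abundance in a
#' sample; the Shannon index is `H = -sum(p_i * log(p_i))` over the non-zero
#' relative abundances, in nats (natural log, the prevailing ecology
#' convention). `H <= log(richness)` always, with equality for a perfectly
#' even sample.
#'
#' @param a An [abundance_matrix()].
#' @return data.frame with columns `sample`, `observed_richness`, `shannon`.
#' @export
#' @examples
#' a <- abundance_matrix(rbind(S1 = c(5, 5, 5, 5), S2 = c(10, 0, 0, 0)))
#' alpha_diversity(a)
alpha_diversity <- function(a) {
  stopifnot(inherits(a, "abundance_matrix"))
  m <- a$values
  if (any(rowSums(m) == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "), call. = FALSE)
  }
  data.frame(
    sample = rownames(m),
    observed_richness = unname(rowSums(m > 0)),
    shannon = unname(vegan::diversity(m, index = "shannon")),
    stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`: 0 for identical samples,
#' 1 for samples with disjoint taxon sets.
#'
#' @param a An [abundance_matrix()].
#' @return A square symmetric matrix with zero diagonal and values in
#'   `[0, 1]`, of class `dist_matrix` (plain matrix with sample dimnames).
#' @export
bray_curtis <- function(a) {
  stopifnot(inherits(a, "abundance_matrix"))
  if (any(rowSums(a$values) == 0)) {
    stop("Bray-Curtis undefined for all-zero sample(s): ",
         paste(rownames(a$values)[rowSums(a$values) == 0], collapse = ", "),
         call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(a$values, method = "bray"))
  stopifnot(isSymmetric(d), all(diag(d) == 0))
  d
}

#' NMDS ordination of a dissimilarity matrix
#'
#' Non-metric multidimensional scaling (monotone-regression stress
#' minimization over random restarts, via [vegan::metaMDS()]) of a
#' Bray-Curtis matrix. Ties in the monotone regression receive equal fitted
#' values (primary tie treatment). The run is deterministic given `seed`.
#'
#' @param d Square dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param k Number of ordination dimensions (default 2).
#' @param n_restarts Random restarts for the stress minimization.
#' @param seed Integer RNG seed.
#' @return An object of class `nmds_ordination`: list with `points`
#'   (samples x k matrix of coordinates, centered at the origin; columns
#'   `NMDS1`, `NMDS2`, ...), `stress`, `converged`, `n_restarts`, `seed`.
#' @export
nmds_ordination <- function(d, k = 2, n_restarts = 20, seed = 1) {
  d <- as.matrix(d)
  if (nrow(d) < k + 2) stop("need at least k + 2 samples for NMDS",
                            call. = FALSE)
  set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(d), k = k, try = n_restarts,
                        trymax = n_restarts, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  pts <- sweep(fit$points, 2, colMeans(fit$points))
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(
    list(points = pts, stress = fit$stress, converged = fit$converged > 0,
         n_restarts = n_restarts, seed = seed),
    class = "nmds_ordination"
  )
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat("NMDS ordination: ", nrow(x$points), " samples, ", ncol(x$points),
      " dimensions, stress = ", signif(x$stress, 4),
      if (x$converged) " (converged)" else " (not converged)", "\n", sep = "")
  invisible(x)
}

#' ANOSIM test of group differences
#'
#' Analysis of similarities: `R = (rb - rw) / (M / 4)`, where `rb` and `rw`
#' are the mean ranks of between- and within-group dissimilarities and
#' `M = n(n-1)/2`. Significance is assessed by permuting group labels; the
#' reported p-value includes the observed statistic in numerator and
#' denominator (`p = (1 + #{R* >= R}) / (1 + n_perm)`).
#'
#' @param d Square dissimilarity matrix.
#' @param groups Group labels, one per sample (>= 2 groups, each of size
#'   >= 2).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer RNG seed.
#' @return List of class `anosim_result` with `R`, `p`, `n_perm`, `groups`.
#' @export
anosim_groups <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) stop("one group label per sample required",
                                      call. = FALSE)
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2)) {
    stop("ANOSIM needs >= 2 groups with >= 2 members each", call. = FALSE)
  }
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(d), groups, permutations = n_perm)
  structure(
    list(R = unname(fit$statistic), p = fit$signif, n_perm = n_perm,
         groups = groups, seed = seed),
    class = "anosim_result"
  )
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations, %d groups)\n",
              x$R, x$p, x$n_perm, nlevels(x$groups)))
  invisible(x)
}
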