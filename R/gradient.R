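#' Ordinary least-squares regression of a response on latitude
#'
#' Fits `y ~ latitude` by OLS and reports the slope (response units per
#' degree latitude) with its 95% confidence interval from the t-distribution
#' on `n - 2` degrees of freedom, the intercept, R-squared and the two-sided
#' slope p-value. Optionally restricted to one habitat.
#'
#' @param y Named or positional numeric vector of per-sample responses
#'   (e.g. `emf_average`).
#' @param metadata data.frame with a `latitude` column (and `habitat` when
#'   `habitat` is given), aligned with `y`.
#' @param habitat Optional habitat to restrict the fit to.
#' @param conf_level Confidence level for the slope interval.
#' @return Object of class `emf_latfit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `ci` (length 2), `n`, `habitat`.
#' @export
#' @examples
#' sim <- simulate_functions(simulation_config(n_sites = 20, seed = 5))
#' res <- emf(sim$table)
#' fit_latitude_regression(res$scores$emf_average, res$metadata)
fit_latitude_regression <- function(y, metadata, habitat = NULL,
                                    conf_level = 0.95) {
  lat <- metadata$latitude
  if (is.null(lat)) stop("metadata lacks a latitude column", call. = FALSE)
  if (length(y) != length(lat)) stop("y and metadata are not aligned",
                                     call. = FALSE)
  if (!is.null(habitat)) {
    keep <- metadata$habitat == habitat
    y <- y[keep]; lat <- lat[keep]
  }
  ok <- complete.cases(y, lat)
  y <- y[ok]; lat <- lat[ok]
  if (length(y) < 3) stop("need >= 3 observations", call. = FALSE)
  if (sd(lat) == 0) stop("latitude is constant; slope undefined",
                         call. = FALSE)
  fit <- lm(y ~ lat)
  sm <- summary(fit)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = unname(sm$coefficients[2, 4]),
         ci = unname(confint(fit, "lat", level = conf_level)[1, ]),
         n = length(y), habitat = habitat %||% "all",
         conf_level = conf_level),
    class = "emf_latfit"
  )
}

#' @export
print.emf_latfit <- function(x, ...) {
  cat(sprintf(
    "Latitude regression (%s habitats, n = %d):\n  slope = %.4g per degree [%.4g, %.4g], R^2 = %.3f, p = %.3g\n",
    x$habitat, x$n, x$slope, x$ci[1], x$ci[2], x$r_squared, x$p_value))
  invisible(x)
}

#' Slope of threshold function counts against latitude
#'
#' For each threshold of the multiple-threshold index, regresses the number
#' of functions exceeding the threshold on latitude and records the OLS
#' slope with its 95% confidence interval — the threshold-slope curve whose
#' shape summarizes how the gradient effect depends on how strictly
#' "functioning" is defined. Thresholds whose counts do not vary get slope 0
#' and `NA` limits, flagged in `degenerate`.
#'
#' @param emf_res An [emf()] result (or a matrix like its
#'   `threshold_counts`).
#' @param metadata data.frame with `latitude`, aligned with the count rows;
#'   defaults to the metadata stored in `emf_res`.
#' @return data.frame with one row per threshold: `threshold`, `slope`,
#'   `ci_lower`, `ci_upper`, `n`, `degenerate`.
#' @export
threshold_slope_curve <- function(emf_res, metadata = NULL) {
  counts <- if (inherits(emf_res, "emf_result")) {
    emf_res$threshold_counts
  } else as.matrix(emf_res)
  if (is.null(metadata) && inherits(emf_res, "emf_result")) {
    metadata <- emf_res$metadata
  }
  lat <- metadata$latitude
  if (length(lat) != nrow(counts)) stop("metadata not aligned with counts",
                                        call. = FALSE)
  out <- lapply(colnames(counts), function(tc) {
    yy <- counts[, tc]
    if (sd(yy) == 0) {
      data.frame(threshold = as.numeric(tc), slope = 0,
                 ci_lower = NA_real_, ci_upper = NA_real_,
                 n = length(yy), degenerate = TRUE)
    } else {
      fit <- lm(yy ~ lat)
      ci <- confint(fit, "lat")
      data.frame(threshold = as.numeric(tc),
                 slope = unname(coef(fit)[2]),
                 ci_lower = ci[1, 1], ci_upper = ci[1, 2],
                 n = length(yy), degenerate = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Mann-Whitney U contrast between two groups
#'
#' Rank-sum test of a location difference. The U statistic is computed from
#' rank sums with mid-rank ties; the p-value is exact for small untied
#' samples (both groups <= 8, no ties) and uses the normal approximation
#' with tie correction and continuity correction otherwise. Two-sided.
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_max Largest per-group size for which the exact distribution
#'   is used (in the absence of ties).
#' @return List with `U`, `p`, `median_x`, `median_y`, `n_x`, `n_y`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty",
                                     call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  p <- wt$p.value
  # every observation tied: the rank distribution is a point mass
  if (is.nan(p) && length(unique(c(x, y))) == 1) p <- 1
  list(U = unname(wt$statistic), p = p,
       median_x = median(x), median_y = median(y),
       n_x = length(x), n_y = length(y))
}

#' Group contrasts for a table of variables
#'
#' Applies [mann_whitney()] to every column of a numeric table, split by a
#' two-level grouping factor (e.g. low vs high latitude).
#'
#' @param tab data.frame or matrix of per-sample variables.
#' @param groups Two-level factor aligned with the rows of `tab`.
#' @return data.frame with one row per variable: `variable`, `U`, `p`,
#'   medians and group sizes.
#' @export
group_contrasts <- function(tab, groups) {
  tab <- as.data.frame(tab)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) {
    stop("groups must have exactly 2 levels", call. = FALSE)
  }
  lv <- levels(droplevels(groups))
  out <- lapply(names(tab), function(v) {
    mw <- mann_whitney(tab[[v]][groups == lv[1]], tab[[v]][groups == lv[2]])
    data.frame(variable = v, U = mw$U, p = mw$p,
               median_1 = mw$median_x, median_2 = mw$median_y,
               n_1 = mw$n_x, n_2 = mw$n_y, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "group_levels") <- lv
  res
}

#' Spearman correlation screen between targets and drivers
#'
#' Pairwise Spearman correlations between every target column (EMF indices,
#' diversity, network complexity, ...) and every driver column (geographic,
#' climatic, edaphic factors), with Benjamini-Hochberg FDR adjustment over
#' all pairs of the screen. Pairs with fewer than 4 complete observations
#' are reported with `NA` correlation.
#'
#' @param targets,drivers Numeric data.frames/matrices with aligned rows.
#' @return Long-format data.frame: `target`, `driver`, `rho`, `p`, `q`, `n`.
#' @export
correlation_screen <- function(targets, drivers) {
  targets <- as.data.frame(targets)
  drivers <- as.data.frame(drivers)
  if (nrow(targets) != nrow(drivers)) {
    stop("targets and drivers must have aligned samples", call. = FALSE)
  }
  grid <- expand.grid(target = names(targets), driver = names(drivers),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- targets[[grid$target[i]]]
    y <- drivers[[grid$driver[i]]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      data.frame(grid[i, ], rho = NA_real_, p = NA_real_, n = n)
    } else {
      rho <- cor(rank(x[ok]), rank(y[ok]))
      data.frame(grid[i, ], rho = rho, p = spearman_p(rho, n), n = n)
    }
  })
  res <- do.call(rbind, res)
  res$q <- fdr_adjust(res$p)
  rownames(res) <- NULL
  res[, c("target", "driver", "rho", "p", "q", "n")]
}
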