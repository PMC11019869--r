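#' Apply directional adjustment to a function table
#'
#' Variables whose raw increase is environmentally undesirable (the water
#' nutrient-load and chlorophyll variables in the default schema) carry
#' `direction = -1` and are multiplied by -1 so that "more" always means
#' "better functioning" before standardization. The schema's direction flags
#' are reset to +1 afterwards, so applying the operation a second time is the
#' identity (no accidental double flip).
#'
#' @param t A [function_table()].
#' @return A `function_table` with adjusted values and all directions +1.
#' @export
apply_direction <- function(t) {
  stopifnot(inherits(t, "function_table"))
  flip <- t$schema$direction == -1L
  t$values[, flip] <- -t$values[, flip, drop = FALSE]
  t$schema$direction <- rep(1L, nrow(t$schema))
  t
}

#' Min-max standardize a function table
#'
#' Rescales each function to `STD = (X - X_min) / (X_max - X_min)` over its
#' non-missing samples, where the minimum and maximum are taken across all
#' samples, so every function lies on a common 0-1 scale. Directional
#' adjustment ([apply_direction()]) must be applied first; note that the
#' standardized flipped variable equals `1 - STD` of the unflipped one. A
#' zero-range (constant) function carries no ranking information: its values
#' are set to 0.5 with a warning so downstream indices stay defined.
#'
#' @param t A [function_table()] (directions already applied; a remaining
#'   -1 direction is an error).
#' @return A `standardized_table`: a `function_table` whose `values` lie in
#'   `[0, 1]`, with a `provenance` element recording `x_min` and `x_max`
#'   per function.
#' @export
#' @examples
#' sim <- simulate_functions(simulation_config(n_sites = 6, seed = 1))
#' std <- standardize_functions(apply_direction(sim$table))
#' range(std$values, na.rm = TRUE)
standardize_functions <- function(t) {
  stopifnot(inherits(t, "function_table"))
  if (any(t$schema$direction == -1L)) {
    stop("apply_direction() must be called before standardization",
         call. = FALSE)
  }
  x_min <- apply(t$values, 2, min, na.rm = TRUE)
  x_max <- apply(t$values, 2, max, na.rm = TRUE)
  rng <- x_max - x_min
  std <- t$values
  for (j in seq_len(ncol(std))) {
    if (rng[j] == 0) {
      warning("function '", colnames(std)[j],
              "' has zero range; standardized to 0.5", call. = FALSE)
      std[!is.na(std[, j]), j] <- 0.5
    } else {
      std[, j] <- (std[, j] - x_min[j]) / rng[j]
    }
  }
  t$values <- std
  t$provenance <- data.frame(function_id = colnames(std),
                             x_min = unname(x_min), x_max = unname(x_max))
  class(t) <- c("standardized_table", "function_table")
  t
}

#' Average multifunctionality index
#'
#' The arithmetic mean of the standardized function values of each sample,
#' taken over its non-missing functions. A sample with no observed function
#' is an error.
#'
#' @param s A `standardized_table` from [standardize_functions()].
#' @return Named numeric vector of per-sample EMF_average values in `[0, 1]`.
#' @export
emf_average <- function(s) {
  stopifnot(inherits(s, "standardized_table"))
  n_used <- rowSums(!is.na(s$values))
  if (any(n_used == 0)) {
    stop("sample(s) with all functions missing: ",
         paste(rownames(s$values)[n_used == 0], collapse = ", "),
         call. = FALSE)
  }
  rowMeans(s$values, na.rm = TRUE)
}

#' Category-weighted multifunctionality index
#'
#' Functions within the same category (nitrogen cycling, nutrient pool,
#' plant productivity, water quality) are first averaged, then the
#' category means are averaged, giving each category equal weight regardless
#' of how many proxies represent it. Categories whose functions are all
#' missing for a sample are dropped for that sample. With equally sized
#' categories (or one function per category) the index equals
#' [emf_average()].
#'
#' @param s A `standardized_table`.
#' @return Named numeric vector of per-sample EMF_weighted values in `[0, 1]`.
#' @export
emf_weighted <- function(s) {
  stopifnot(inherits(s, "standardized_table"))
  cats <- unique(s$schema$category)
  cat_means <- sapply(cats, function(cc) {
    cols <- s$schema$function_id[s$schema$category == cc]
    rowMeans(s$values[, cols, drop = FALSE], na.rm = TRUE)  # NaN if all NA
  })
  if (is.null(dim(cat_means))) cat_means <- matrix(cat_means, nrow = 1)
  res <- rowMeans(cat_means, na.rm = TRUE)
  if (any(is.nan(res))) {
    stop("sample(s) with all functions missing: ",
         paste(rownames(s$values)[is.nan(res)], collapse = ", "),
         call. = FALSE)
  }
  setNames(res, rownames(s$values))
}

#' Multiple-threshold function counts
#'
#' For each threshold `t` on a percent grid (default 5..95% in 1% steps),
#' counts per sample the number of functions whose standardized value is at
#' least `t`% of that function's reference maximum. The reference maximum is
#' the mean of the top `robust_max_k` standardized values per function
#' (default `k = 1`, i.e. the observed maximum, which is 1 by construction
#' after min-max standardization). "Exceeds" is read inclusively (`>=`) by
#' default; set `inclusive = FALSE` for a strict comparison.
#'
#' @param s A `standardized_table`.
#' @param thresholds Integer percent grid (default `5:95`).
#' @param robust_max_k Top-k values averaged to define each function's
#'   reference maximum.
#' @param inclusive Count ties at exactly the threshold (default `TRUE`).
#' @return Integer matrix, samples x thresholds, with the threshold percents
#'   as column names. Counts are non-increasing along each row.
#' @export
multi_threshold <- function(s, thresholds = 5:95, robust_max_k = 1,
                            inclusive = TRUE) {
  stopifnot(inherits(s, "standardized_table"))
  if (!length(thresholds)) stop("empty threshold grid", call. = FALSE)
  if (any(thresholds < 0 | thresholds > 100)) {
    stop("thresholds must be percentages in [0, 100]", call. = FALSE)
  }
  maxref <- apply(s$values, 2, function(x) {
    x <- sort(x[!is.na(x)], decreasing = TRUE)
    mean(x[seq_len(min(robust_max_k, length(x)))])
  })
  cmp <- if (inclusive) `>=` else `>`
  counts <- sapply(thresholds, function(t) {
    cut <- matrix(maxref * t / 100, nrow(s$values), ncol(s$values),
                  byrow = TRUE)
    rowSums(cmp(s$values, cut), na.rm = TRUE)
  })
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  dimnames(counts) <- list(rownames(s$values), thresholds)
  counts
}

#' Compute all ecosystem multifunctionality indices
#'
#' Convenience wrapper: applies the directional flip and min-max
#' standardization to a raw function table, then computes the average index,
#' the category-weighted index and the multiple-threshold counts.
#'
#' @param t A raw [function_table()].
#' @param thresholds,robust_max_k,inclusive Passed to [multi_threshold()].
#' @return An object of class `emf_result`: a list with `scores` (data.frame
#'   with `emf_average`, `emf_weighted`, `n_functions_used` per sample),
#'   `threshold_counts` (matrix), `metadata`, `schema` and the standardized
#'   table in `standardized`.
#' @export
#' @examples
#' sim <- simulate_functions(simulation_config(n_sites = 8, seed = 3))
#' res <- emf(sim$table)
#' res
emf <- function(t, thresholds = 5:95, robust_max_k = 1, inclusive = TRUE) {
  std <- standardize_functions(apply_direction(t))
  scores <- data.frame(
    sample = rownames(std$values),
    emf_average = unname(emf_average(std)),
    emf_weighted = unname(emf_weighted(std)),
    n_functions_used = unname(rowSums(!is.na(std$values))),
    stringsAsFactors = FALSE
  )
  structure(
    list(scores = scores,
         threshold_counts = multi_threshold(std, thresholds, robust_max_k,
                                            inclusive),
         metadata = std$metadata, schema = std$schema, standardized = std),
    class = "emf_result"
  )
}

#' @export
print.emf_result <- function(x, ...) {
  cat("EMF indices for", nrow(x$scores), "samples,",
      nrow(x$schema), "functions\n")
  cat(sprintf("  EMF_average : mean %.3f, range %.3f-%.3f\n",
              mean(x$scores$emf_average), min(x$scores$emf_average),
              max(x$scores$emf_average)))
  cat(sprintf("  EMF_weighted: mean %.3f, range %.3f-%.3f\n",
              mean(x$scores$emf_weighted), min(x$scores$emf_weighted),
              max(x$scores$emf_weighted)))
  tc <- colnames(x$threshold_counts)
  cat("  Threshold grid: ", tc[1], "-", tc[length(tc)], "% (",
      length(tc), " thresholds)\n", sep = "")
  invisible(x)
}

#' @export
summary.emf_result <- function(object, ...) {
  print(object)
  cat("\nPer-sample scores:\n")
  print(utils::head(object$scores, 10))
  invisible(object)
}
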