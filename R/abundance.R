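#' Construct an abundance matrix
#'
#' A samples-by-taxa matrix of non-negative counts or relative abundances with
#' a level tag (`"genus"`, `"species"` or `"KO"` for KEGG-Orthology functional
#' genes) and optional per-sample metadata (site, habitat, latitude group).
#'
#' @param values Numeric matrix or data.frame, samples in rows.
#' @param level One of `"genus"`, `"species"`, `"KO"`.
#' @param metadata Optional data.frame, one row per sample.
#' @param normalized Logical; `TRUE` marks rows as relative abundances and
#'   enforces row sums of 1 (within 1e-9).
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, level = c("genus", "species", "KO"),
                             metadata = NULL, normalized = FALSE) {
  level <- match.arg(level)
  m <- as.matrix(values)
  if (!is.numeric(m)) stop("abundance values must be numeric", call. = FALSE)
  if (anyNA(m)) stop("abundance values must not be missing", call. = FALSE)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at sample ", rownames(m)[bad[1]] %||% bad[1],
         ", taxon ", colnames(m)[bad[2]] %||% bad[2], call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  if (normalized && any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("normalized abundance rows must sum to 1", call. = FALSE)
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != nrow(m)) {
      stop("metadata rows != abundance rows", call. = FALSE)
    }
    rownames(metadata) <- rownames(m)
  }
  structure(
    list(values = m, level = level, metadata = metadata,
         normalized = normalized),
    class = "abundance_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("Abundance matrix (", x$level, " level): ", nrow(x$values),
      " samples x ", ncol(x$values), " taxa",
      if (x$normalized) ", relative" else ", counts", "\n", sep = "")
  invisible(x)
}

#' Read / write an abundance matrix
#'
#' TSV (or CSV by extension) with a header row; the first column holds sample
#' ids when `orientation = "samples"` (rows are samples) or taxon ids when
#' `orientation = "taxa"` (rows are taxa, the common deposition layout, which
#' is transposed on read).
#'
#' @param path File path.
#' @param level Taxon level tag, see [abundance_matrix()].
#' @param orientation `"samples"` or `"taxa"`: what the file's rows are.
#' @return `read_abundance()` returns an [abundance_matrix()];
#'   `write_abundance()` returns `path` invisibly.
#' @export
read_abundance <- function(path, level = c("genus", "species", "KO"),
                           orientation = c("samples", "taxa")) {
  level <- match.arg(level)
  orientation <- match.arg(orientation)
  df <- read_table_file(path)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path,
                           call. = FALSE)
  rownames(m) <- ids
  if (orientation == "taxa") m <- t(m)
  abundance_matrix(m, level = level)
}

#' @rdname read_abundance
#' @param a An `abundance_matrix`.
#' @export
write_abundance <- function(a, path, orientation = c("samples", "taxa")) {
  stopifnot(inherits(a, "abundance_matrix"))
  orientation <- match.arg(orientation)
  m <- a$values
  if (orientation == "taxa") m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (orientation == "taxa") "taxon" else "sample"
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total so rows sum to 1. Needed, e.g., for
#' the low-abundance taxon pre-filter applied before network construction
#' (taxa with summed relative abundance below 0.01%). Idempotent: applying it
#' to an already-normalized matrix returns the same values.
#'
#' @param a An [abundance_matrix()].
#' @return An `abundance_matrix` with `normalized = TRUE`.
#' @export
to_relative <- function(a) {
  stopifnot(inherits(a, "abundance_matrix"))
  rs <- rowSums(a$values)
  if (any(rs == 0)) {
    stop("all-zero abundance row for sample(s): ",
         paste(rownames(a$values)[rs == 0], collapse = ", "), call. = FALSE)
  }
  abundance_matrix(a$values / rs, level = a$level, metadata = a$metadata,
                   normalized = TRUE)
}
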