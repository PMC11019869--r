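#' Construct a function table
#'
#' A `function_table` couples a numeric samples-by-functions matrix with
#' per-sample site metadata and a per-function schema. Rows are keyed by the
#' pair (site, habitat); habitats are metadata, not part of the sample name,
#' because the three habitats (rhizosphere soil, bulk soil, channel sediment)
#' are analysed both jointly and separately. Missing measurements stay `NA`
#' and are never silently replaced by zero; downstream EMF indices are
#' computed over the observed subset and report how many functions were used.
#'
#' @param values Numeric data.frame or matrix, samples in rows, function
#'   variables in columns.
#' @param metadata data.frame with one row per sample: `site_id`, `habitat`
#'   (one of `"rhizosphere"`, `"bulk"`, `"sediment"`), `latitude` (decimal
#'   degrees N), optionally `longitude`, `elevation` and `lat_group`
#'   (`"low"`/`"high"`). A missing `lat_group` is derived from `latitude`
#'   and `split_latitude`.
#' @param schema Schema data.frame (default [default_function_schema()]
#'   restricted to the supplied columns must cover every column).
#' @param split_latitude Latitude (degrees N) separating the low- and
#'   high-latitude groups when `lat_group` is not supplied. The default
#'   33 degrees N approximates the Qinling-Huaihe Line, the climatic boundary
#'   between southern and northern China.
#' @return An object of class `function_table`: a list with elements
#'   `values` (numeric matrix), `metadata`, `schema` and `split_latitude`.
#' @export
#' @examples
#' ft <- simulate_functions(simulation_config(n_sites = 6, seed = 1))$table
#' ft
function_table <- function(values, metadata, schema = default_function_schema(),
                           split_latitude = 33) {
  values <- as.data.frame(values)
  if (!nrow(values)) stop("function table has no rows", call. = FALSE)
  for (j in names(values)) {
    if (!is.numeric(values[[j]])) {
      stop("non-numeric function column: ", j, call. = FALSE)
    }
  }
  schema <- validate_schema(schema)
  unknown <- setdiff(names(values), schema$function_id)
  if (length(unknown)) {
    stop("function column(s) absent from schema: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  schema <- schema[match(names(values), schema$function_id), , drop = FALSE]
  rownames(schema) <- NULL

  metadata <- as.data.frame(metadata)
  if (nrow(metadata) != nrow(values)) {
    stop("metadata rows (", nrow(metadata), ") != value rows (",
         nrow(values), ")", call. = FALSE)
  }
  for (f in c("site_id", "habitat", "latitude")) {
    if (!f %in% names(metadata)) stop("metadata lacks column: ", f, call. = FALSE)
  }
  if (!all(is.finite(metadata$latitude))) {
    stop("non-finite latitude in metadata", call. = FALSE)
  }
  bad <- setdiff(unique(metadata$habitat), c("rhizosphere", "bulk", "sediment"))
  if (length(bad)) {
    stop("unknown habitat value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(metadata$site_id, metadata$habitat, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicated (site_id, habitat) sample key: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(metadata$lat_group)) {
    metadata$lat_group <- ifelse(metadata$latitude < split_latitude,
                                 "low", "high")
  }
  if (!all(metadata$lat_group %in% c("low", "high"))) {
    stop("lat_group must be 'low' or 'high'", call. = FALSE)
  }
  m <- as.matrix(values)
  rownames(m) <- key
  rownames(metadata) <- key
  structure(
    list(values = m, metadata = metadata, schema = schema,
         split_latitude = split_latitude),
    class = "function_table"
  )
}

#' @export
print.function_table <- function(x, ...) {
  cat("Function table: ", nrow(x$values), " samples (",
      length(unique(x$metadata$site_id)), " sites x ",
      length(unique(x$metadata$habitat)), " habitats), ",
      ncol(x$values), " functions\n", sep = "")
  cat("Categories:",
      paste(sprintf("%s (%d)", names(table(x$schema$category)),
                    table(x$schema$category)), collapse = ", "), "\n")
  cat("Latitude range: ",
      sprintf("%.2f-%.2f degrees N", min(x$metadata$latitude),
              max(x$metadata$latitude)),
      "; groups: low n=", sum(x$metadata$lat_group == "low"),
      ", high n=", sum(x$metadata$lat_group == "high"), "\n", sep = "")
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat("Missing cells:", nmiss, "\n")
  invisible(x)
}

read_table_file <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, check.names = FALSE, na.strings = "NA",
             stringsAsFactors = FALSE)
}

metadata_cols <- c("site_id", "habitat", "latitude", "longitude",
                   "elevation", "lat_group")

#' Read / write a function table
#'
#' Function tables are stored as TSV (or CSV, by file extension) with one row
#' per sample, metadata columns (`site_id`, `habitat`, `latitude`, optionally
#' `longitude`, `elevation`, `lat_group`) followed by one column per function
#' variable; missing values are written as `NA`. The schema travels in a
#' separate YAML file (see [read_schema()]). Any function column not present
#' in the schema is an error; any non-numeric cell in a function column is an
#' error naming the row and column.
#'
#' @param path Path to the table file.
#' @param schema_path Path to the YAML schema.
#' @param split_latitude See [function_table()].
#' @return `read_function_table()` returns a [function_table()];
#'   `write_function_table()` returns `path` invisibly.
#' @export
read_function_table <- function(path, schema_path, split_latitude = 33) {
  schema <- read_schema(schema_path)
  df <- read_table_file(path)
  meta <- df[, intersect(metadata_cols, names(df)), drop = FALSE]
  vals <- df[, setdiff(names(df), metadata_cols), drop = FALSE]
  for (j in names(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad_row <- which(!is.na(vals[[j]]) &
                         is.na(suppressWarnings(as.numeric(vals[[j]]))))
      stop("non-numeric value in function column '", j, "', row ",
           if (length(bad_row)) bad_row[1] else "?", call. = FALSE)
    }
  }
  function_table(vals, meta, schema, split_latitude = split_latitude)
}

#' @rdname read_function_table
#' @param x A `function_table`.
#' @export
write_function_table <- function(x, path, schema_path = NULL) {
  stopifnot(inherits(x, "function_table"))
  df <- cbind(
    x$metadata[, intersect(metadata_cols, names(x$metadata)), drop = FALSE],
    as.data.frame(x$values)
  )
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA")
  if (!is.null(schema_path)) write_schema(x$schema, schema_path)
  invisible(path)
}
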