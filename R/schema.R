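#' Default ecosystem-function schema
#'
#' The standard set of 18 river ecosystem-function variables grouped into four
#' categories: nitrogen cycling (potential nitrification `PN`, denitrification
#' `DN`, anammox `AN` rates of soil/sediment), nutrient pools (soil/sediment
#' `TC`, `TOC`, `TN`, `NO3`, `NH4`, `TP`), plant productivity (`biomass`) and
#' water quality (`W_DO`, `W_TDS`, `W_TOC`, `W_TN`, `W_NH4`, `W_NO3`, `W_TP`,
#' `W_Chla`). Water variables whose increase degrades water quality (all but
#' dissolved oxygen) carry `direction = -1` and are negated by
#' [apply_direction()] before standardization.
#'
#' @return A data.frame with columns `function_id`, `category` (one of
#'   `"nitrogen_cycling"`, `"nutrient_pool"`, `"plant_productivity"`,
#'   `"water_quality"`) and `direction` (+1 or -1).
#' @export
#' @examples
#' sch <- default_function_schema()
#' table(sch$category)
default_function_schema <- function() {
  data.frame(
    function_id = c(
      "PN", "DN", "AN",
      "TC", "TOC", "TN", "NO3", "NH4", "TP",
      "biomass",
      "W_DO", "W_TDS", "W_TOC", "W_TN", "W_NH4", "W_NO3", "W_TP", "W_Chla"
    ),
    category = c(
      rep("nitrogen_cycling", 3),
      rep("nutrient_pool", 6),
      "plant_productivity",
      rep("water_quality", 8)
    ),
    direction = c(rep(1L, 11), rep(-1L, 7)),
    stringsAsFactors = FALSE
  )
}

emf_categories <- c(
  "nitrogen_cycling", "nutrient_pool", "plant_productivity", "water_quality"
)

validate_schema <- function(schema) {
  req <- c("function_id", "category", "direction")
  if (!is.data.frame(schema) || !all(req %in% names(schema))) {
    stop("schema must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(schema$function_id)) {
    stop("duplicated function_id in schema: ",
         paste(unique(schema$function_id[duplicated(schema$function_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(schema$category), emf_categories)
  if (length(bad)) {
    stop("unknown function category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(schema$direction %in% c(-1L, 1L))) {
    stop("schema direction must be +1 or -1", call. = FALSE)
  }
  schema$direction <- as.integer(schema$direction)
  schema[, req]
}

#' Read or write a function schema file
#'
#' Schemas are stored as YAML mapping each function id to its `category` and
#' `direction`, e.g. `PN: {category: nitrogen_cycling, direction: 1}`.
#'
#' @param path File path.
#' @param schema A schema data.frame (see [default_function_schema()]).
#' @return `read_schema()` returns a validated schema data.frame;
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("empty schema file: ", path, call. = FALSE)
  schema <- data.frame(
    function_id = names(raw),
    category = vapply(raw, function(x) as.character(x$category), ""),
    direction = vapply(raw, function(x) as.integer(x$direction), 1L),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  validate_schema(schema)
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  schema <- validate_schema(schema)
  out <- lapply(seq_len(nrow(schema)), function(i) {
    list(category = schema$category[i], direction = schema$direction[i])
  })
  names(out) <- schema$function_id
  yaml::write_yaml(out, path)
  invisible(path)
}
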