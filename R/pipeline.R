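#' Run the full analysis pipeline
#'
#' Executes the stages simulate -> EMF -> community -> network -> gradient in
#' dependency order from a single configuration, writing every result as TSV
#' plus a JSON run manifest recording the package version, seeds, parameters
#' and an MD5 hash of every output file, so a run is reproducible and
#' auditable. Stages can be toggled; the gradient stage silently adapts when
#' the network stage (and hence the complexity index) is disabled.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognized entries:
#'   \describe{
#'     \item{out_dir}{Output directory (created if absent). Required.}
#'     \item{seed}{Integer master seed (default 1); stage seeds derive from
#'       it.}
#'     \item{simulate}{List of [simulation_config()] arguments (optional).}
#'     \item{functions,schema,abundance}{Input file paths, used when the
#'       simulate stage is disabled.}
#'     \item{stages}{Character subset of
#'       `c("simulate", "emf", "community", "network", "gradient")`
#'       (default all).}
#'     \item{thresholds}{Integer percent grid for [multi_threshold()].}
#'     \item{network}{List of [build_network()] arguments
#'       (`rho_threshold`, `q_threshold`, `min_rel_abund`).}
#'   }
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "emfrun")
#' run_pipeline(list(out_dir = out, seed = 1,
#'                   simulate = list(n_sites = 10, n_taxa = 60)))
#' }
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||%
    c("simulate", "emf", "community", "network", "gradient")
  thresholds <- config$thresholds %||% (5:95)
  net_par <- config$network %||% list()
  manifest <- list(package = "riveremf",
                   version = as.character(packageVersion("riveremf")),
                   seed = seed, stages = stages,
                   parameters = list(thresholds = range(thresholds),
                                     network = net_par))
  paths <- character(0)
  note <- function(p) paths[[length(paths) + 1]] <<- p

  ## ---- inputs: simulate or read -------------------------------------
  if ("simulate" %in% stages) {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(simulation_config, sim_args)
    fun_sim <- simulate_functions(cfg)
    ab_sim <- simulate_abundances(cfg)
    ft <- fun_sim$table
    ab <- ab_sim$abundance
    write_function_table(ft, file.path(out_dir, "functions.tsv"),
                         file.path(out_dir, "schema.yaml"))
    note("functions.tsv"); note("schema.yaml")
    write_abundance(ab, file.path(out_dir, "abundance.tsv"))
    note("abundance.tsv")
    truth <- list(functions = fun_sim$truth[
                    c("emf_slope_true", "per_function_std_slope")],
                  guild = as.list(ab_sim$truth$guild),
                  guild_correlation = as.list(ab_sim$truth$guild_correlation))
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    note("ground_truth.json")
    manifest$parameters$simulate <- sim_args
  } else {
    ft <- read_function_table(config$functions, config$schema)
    ab <- if (!is.null(config$abundance)) {
      read_abundance(config$abundance)
    } else NULL
  }
  meta <- ft$metadata

  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    note(name)
  }

  ## ---- EMF ----------------------------------------------------------
  emf_res <- NULL
  if ("emf" %in% stages) {
    emf_res <- emf(ft, thresholds = thresholds)
    tsv(cbind(emf_res$scores,
              as.data.frame(emf_res$threshold_counts, check.names = FALSE)),
        "emf.tsv")
  }

  ## ---- community ----------------------------------------------------
  div <- ord <- ano <- NULL
  if ("community" %in% stages && !is.null(ab)) {
    div <- alpha_diversity(ab)
    tsv(div, "diversity.tsv")
    bc <- bray_curtis(ab)
    tsv(data.frame(sample = rownames(bc), bc, check.names = FALSE),
        "bray_curtis.tsv")
    ord <- nmds_ordination(bc, seed = seed)
    tsv(data.frame(sample = rownames(ord$points), ord$points,
                   stress = ord$stress), "nmds.tsv")
    if (!is.null(ab$metadata$lat_group)) {
      ano <- anosim_groups(bc, ab$metadata$lat_group, seed = seed)
      tsv(data.frame(test = "anosim_lat_group", R = ano$R, p = ano$p,
                     n_perm = ano$n_perm), "anosim.tsv")
    }
  }

  ## ---- network ------------------------------------------------------
  submetrics <- cx <- NULL
  group_nets <- list()
  if ("network" %in% stages && !is.null(ab)) {
    groups <- ab$metadata$lat_group %||% rep("all", nrow(ab$values))
    edges_all <- list()
    metrics_rows <- list()
    for (gname in unique(groups)) {
      rows <- which(groups == gname)
      sub <- abundance_matrix(ab$values[rows, , drop = FALSE],
                              level = ab$level,
                              metadata = ab$metadata[rows, , drop = FALSE])
      net <- do.call(build_network, c(list(a = sub), net_par))
      group_nets[[gname]] <- net
      if (nrow(net$edges)) {
        edges_all[[gname]] <- cbind(group = gname, net$edges)
      }
      metrics_rows[[gname]] <- cbind(group = gname,
                                     sample_subnetwork(net, sub))
    }
    tsv(do.call(rbind, c(edges_all,
                         list(data.frame(group = character(0),
                                         taxon_a = character(0),
                                         taxon_b = character(0),
                                         rho = numeric(0),
                                         q = numeric(0))))),
        "edges.tsv")
    submetrics <- do.call(rbind, metrics_rows)
    rownames(submetrics) <- NULL
    tsv(submetrics, "subnetwork_metrics.tsv")
    cx <- tryCatch(complexity_index(submetrics), error = function(e) NULL)
    if (!is.null(cx)) {
      tsv(data.frame(sample = names(cx$scores), complexity = cx$scores),
          "complexity.tsv")
      tsv(data.frame(metric = names(cx$loadings), loading = cx$loadings,
                     variance_explained = cx$variance_explained),
          "complexity_loadings.tsv")
    }
  } else if ("gradient" %in% stages) {
    message("network stage disabled; gradient stage will omit complexity")
  }

  ## ---- gradient -----------------------------------------------------
  if ("gradient" %in% stages && !is.null(emf_res)) {
    fit <- fit_latitude_regression(emf_res$scores$emf_average, meta)
    tsv(data.frame(response = "emf_average", slope = fit$slope,
                   ci_lower = fit$ci[1], ci_upper = fit$ci[2],
                   r_squared = fit$r_squared, p = fit$p_value, n = fit$n),
        "latitude_regression.tsv")
    tsv(threshold_slope_curve(emf_res), "threshold_slopes.tsv")
    tsv(group_contrasts(
          emf_res$scores[, c("emf_average", "emf_weighted")],
          meta$lat_group), "group_contrasts.tsv")
    targets <- emf_res$scores[, c("emf_average", "emf_weighted"),
                              drop = FALSE]
    if (!is.null(div)) targets$shannon <- div$shannon
    if (!is.null(cx) && all(emf_res$scores$sample %in% names(cx$scores))) {
      targets$complexity <- unname(cx$scores[emf_res$scores$sample])
    }
    drivers <- meta[, "latitude", drop = FALSE]
    if (!is.null(meta$elevation)) drivers$elevation <- meta$elevation
    tsv(correlation_screen(targets, drivers), "driver_screen.tsv")
  }

  ## ---- manifest -----------------------------------------------------
  files <- file.path(out_dir, unlist(paths))
  manifest$outputs <- lapply(seq_along(files), function(i) {
    list(file = unlist(paths)[i],
         md5 = unname(tools::md5sum(files[i])))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
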