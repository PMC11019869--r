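#' Configuration for the synthetic river-gradient generator
#'
#' Bundles every knob of the two generators ([simulate_functions()] and
#' [simulate_abundances()]) together with the RNG seed, so a configuration
#' fully determines a dataset. The defaults emulate a survey of 30 river
#' sites spanning 21.76-45.09 degrees N, each sampled in three habitats
#' (riparian rhizosphere soil, riparian bulk soil, channel sediment), with 18
#' ecosystem-function variables that decline with latitude after directional
#' adjustment, and a genus table of 200 taxa containing 6 correlated
#' "guilds" of 10 taxa each so that co-occurrence networks have recoverable
#' planted structure.
#'
#' @param n_sites Number of river sites (>= 4). Latitudes are drawn
#'   stratified-uniform: the latitude range is cut into `n_sites` equal bands
#'   with one uniform draw per band, so the gradient is evenly covered.
#' @param lat_range Numeric length-2, degrees N.
#' @param habitats Character subset of `c("rhizosphere", "bulk", "sediment")`;
#'   each site contributes one sample per habitat.
#' @param split_latitude Low/high latitude group boundary (degrees N).
#' @param survey_split If `TRUE`, reproduce an 11 low / 19 high site design
#'   (11 latitudes stratified below `split_latitude`, 19 above) instead of
#'   stratifying the full range.
#' @param function_effects data.frame with columns `function_id`, `alpha`
#'   (raw-scale intercept), `beta` (raw units per degree latitude) and
#'   `sigma` (> 0, residual SD). Default: every function has `alpha = 1`,
#'   `sigma = 0.05` and `beta = -0.01 * direction`, i.e. after the
#'   directional flip every function declines by 0.01 raw units per degree.
#' @param habitat_effects Named numeric vector of additive per-habitat
#'   offsets applied to every function (default all 0).
#' @param schema Function schema, see [default_function_schema()].
#' @param n_taxa,n_guilds,guild_size Genus-table dimensions; the first
#'   `n_guilds * guild_size` taxa form the guild blocks
#'   (`n_guilds * guild_size <= n_taxa`).
#' @param guild_correlation Within-guild latent correlation in `[0, 1)`;
#'   either a scalar or a named vector `c(low = ..., high = ...)` giving a
#'   different correlation per latitude group (how the generator plants a
#'   network-complexity contrast between groups).
#' @param turnover_scale Niche breadth in degrees latitude of the Gaussian
#'   taxon responses; small values mean fast compositional turnover along the
#'   gradient, `Inf` switches the gradient off. Guild members share their
#'   guild's niche optimum (a guild being a set of taxa with a common
#'   environmental response); free taxa draw individual optima.
#' @param base_meanlog,base_sdlog Log-normal parameters of per-taxon baseline
#'   abundance.
#' @param depth_sdlog SD of the log-normal per-sample depth factor.
#' @param factor_scale SD (log scale) of the per-sample stochastic component
#'   that the guild latent factor and taxon-specific noise share.
#' @param overdispersion `NULL` for Poisson counts (default) or a positive
#'   negative-binomial size parameter for overdispersed counts.
#' @param seed Integer RNG seed. The two generators draw site latitudes
#'   first with identical code, so the same config yields the same site
#'   layout for functions and abundances.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 30,
                              lat_range = c(21.76, 45.09),
                              habitats = c("rhizosphere", "bulk", "sediment"),
                              split_latitude = 33,
                              survey_split = FALSE,
                              function_effects = NULL,
                              habitat_effects = NULL,
                              schema = default_function_schema(),
                              n_taxa = 200,
                              n_guilds = 6,
                              guild_size = 10,
                              guild_correlation = 0.8,
                              turnover_scale = 8,
                              base_meanlog = log(50),
                              base_sdlog = 0.8,
                              depth_sdlog = 0.2,
                              factor_scale = 1.5,
                              overdispersion = NULL,
                              seed = 1L) {
  schema <- validate_schema(schema)
  if (n_sites < 4) stop("n_sites must be >= 4", call. = FALSE)
  if (length(lat_range) != 2 || diff(lat_range) <= 0) {
    stop("lat_range must span a positive latitude interval", call. = FALSE)
  }
  habitats <- match.arg(habitats, c("rhizosphere", "bulk", "sediment"),
                        several.ok = TRUE)
  if (is.null(function_effects)) {
    function_effects <- data.frame(
      function_id = schema$function_id,
      alpha = 1,
      beta = -0.01 * schema$direction,
      sigma = 0.05,
      stringsAsFactors = FALSE
    )
  }
  if (!all(schema$function_id %in% function_effects$function_id)) {
    stop("function_effects must cover every schema function", call. = FALSE)
  }
  function_effects <- function_effects[
    match(schema$function_id, function_effects$function_id), , drop = FALSE]
  if (any(function_effects$sigma <= 0)) {
    stop("all function noise SDs (sigma) must be > 0", call. = FALSE)
  }
  if (is.null(habitat_effects)) {
    habitat_effects <- setNames(rep(0, length(habitats)), habitats)
  }
  if (!all(habitats %in% names(habitat_effects))) {
    stop("habitat_effects must name every habitat", call. = FALSE)
  }
  r <- guild_correlation
  if (length(r) == 1 && is.null(names(r))) r <- c(low = unname(r), high = unname(r))
  if (!all(c("low", "high") %in% names(r))) {
    stop("guild_correlation must be a scalar or named c(low=, high=)",
         call. = FALSE)
  }
  if (any(r < 0 | r >= 1)) {
    stop("guild_correlation must lie in [0, 1)", call. = FALSE)
  }
  if (n_guilds * guild_size > n_taxa) {
    stop("n_guilds * guild_size exceeds n_taxa", call. = FALSE)
  }
  if (!is.null(overdispersion) && overdispersion <= 0) {
    stop("overdispersion (NB size) must be positive", call. = FALSE)
  }
  structure(
    list(n_sites = as.integer(n_sites), lat_range = lat_range,
         habitats = habitats, split_latitude = split_latitude,
         survey_split = isTRUE(survey_split),
         function_effects = function_effects,
         habitat_effects = habitat_effects, schema = schema,
         n_taxa = as.integer(n_taxa), n_guilds = as.integer(n_guilds),
         guild_size = as.integer(guild_size), guild_correlation = r,
         turnover_scale = turnover_scale, base_meanlog = base_meanlog,
         base_sdlog = base_sdlog, depth_sdlog = depth_sdlog,
         factor_scale = factor_scale, overdispersion = overdispersion,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Stratified-uniform site latitudes; called first by both generators so a
# shared config yields a shared site layout.
draw_latitudes <- function(cfg) {
  if (cfg$survey_split) {
    lo <- strat_unif(11, c(cfg$lat_range[1], cfg$split_latitude))
    hi <- strat_unif(19, c(cfg$split_latitude, cfg$lat_range[2]))
    c(lo, hi)
  } else {
    strat_unif(cfg$n_sites, cfg$lat_range)
  }
}

strat_unif <- function(n, range) {
  brk <- seq(range[1], range[2], length.out = n + 1)
  brk[-(n + 1)] + runif(n) * diff(brk)
}

site_layout <- function(cfg) {
  lat <- draw_latitudes(cfg)
  n_sites <- length(lat)
  sites <- sprintf("R%02d", seq_len(n_sites))
  data.frame(
    site_id = rep(sites, each = length(cfg$habitats)),
    habitat = rep(cfg$habitats, times = n_sites),
    latitude = rep(lat, each = length(cfg$habitats)),
    lat_group = rep(ifelse(lat < cfg$split_latitude, "low", "high"),
                    each = length(cfg$habitats)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a function table with a planted latitude gradient
#'
#' Each raw function variable is generated as
#' `X = alpha_f + beta_f * latitude + habitat offset + Normal(0, sigma_f^2)`.
#' The returned ground truth records the generating coefficients and the
#' latitude slope of the average multifunctionality index implied by them:
#' since min-max standardization rescales function `f` by its realized range,
#' the implied EMF_average slope is the mean over functions of
#' `direction_f * beta_f / range_f`, with `range_f` the realized range of the
#' direction-adjusted raw values.
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `table` (a [function_table()]) and `truth`
#'   (generating coefficients, per-site latitudes and `emf_slope_true`).
#' @export
#' @examples
#' sim <- simulate_functions(simulation_config(n_sites = 8, seed = 42))
#' sim$truth$emf_slope_true
simulate_functions <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  layout <- site_layout(cfg)
  n <- nrow(layout)
  fe <- cfg$function_effects
  hoff <- cfg$habitat_effects[layout$habitat]
  vals <- sapply(seq_len(nrow(fe)), function(j) {
    fe$alpha[j] + fe$beta[j] * layout$latitude + hoff +
      rnorm(n, sd = fe$sigma[j])
  })
  colnames(vals) <- fe$function_id
  tab <- function_table(vals, layout, cfg$schema,
                        split_latitude = cfg$split_latitude)
  dirv <- cfg$schema$direction
  ranges <- apply(vals, 2, function(x) diff(range(x)))
  truth <- list(
    function_effects = fe,
    direction = setNames(dirv, fe$function_id),
    latitudes = unique(layout[, c("site_id", "latitude")]),
    emf_slope_true = mean(dirv * fe$beta / ranges),
    per_function_std_slope = setNames(dirv * fe$beta / ranges,
                                      fe$function_id),
    seed = cfg$seed
  )
  list(table = tab, truth = truth)
}

#' Simulate a genus abundance matrix with guilds and latitudinal turnover
#'
#' Taxa respond to latitude through Gaussian niches (random optima over the
#' latitude range, common breadth `turnover_scale`); per-taxon log-normal
#' baselines and a per-sample log-normal depth factor set overall abundance;
#' guild members additionally share a per-sample latent factor with
#' within-guild correlation `guild_correlation` (possibly different between
#' latitude groups), and counts are drawn Poisson (or negative-binomial)
#' around the expected abundance. The guild structure is what a co-occurrence
#' network built from the output should recover.
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `abundance` (an [abundance_matrix()] with
#'   site metadata attached) and `truth` (guild membership map, per-group
#'   guild correlations, niche optima).
#' @export
#' @examples
#' sim <- simulate_abundances(simulation_config(n_sites = 10, n_taxa = 50,
#'                                              n_guilds = 2, seed = 7))
#' table(sim$truth$guild)
simulate_abundances <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  layout <- site_layout(cfg)
  n <- nrow(layout)
  p <- cfg$n_taxa
  guild <- rep(0L, p)
  if (cfg$n_guilds > 0) {
    guild[seq_len(cfg$n_guilds * cfg$guild_size)] <-
      rep(seq_len(cfg$n_guilds), each = cfg$guild_size)
  }
  logbase <- rnorm(p, cfg$base_meanlog, cfg$base_sdlog)
  optima <- runif(p, cfg$lat_range[1], cfg$lat_range[2])
  if (cfg$n_guilds > 0) {
    # guild members share their guild's niche optimum: a guild is a set of
    # taxa with a common environmental response plus a shared latent factor
    guild_opt <- runif(cfg$n_guilds, cfg$lat_range[1], cfg$lat_range[2])
    optima[guild > 0] <- guild_opt[guild[guild > 0]]
  }
  depth <- rnorm(n, 0, cfg$depth_sdlog)
  niche <- if (is.finite(cfg$turnover_scale)) {
    -outer(layout$latitude, optima, "-")^2 / (2 * cfg$turnover_scale^2)
  } else {
    matrix(0, n, p)
  }
  r_i <- cfg$guild_correlation[layout$lat_group]
  z <- matrix(rnorm(n * max(cfg$n_guilds, 1)), n)  # shared guild factors
  e <- matrix(rnorm(n * p), n, p)                  # taxon-specific noise
  stoch <- e
  if (cfg$n_guilds > 0) {
    for (g in seq_len(cfg$n_guilds)) {
      idx <- which(guild == g)
      stoch[, idx] <- sqrt(r_i) * z[, g] + sqrt(1 - r_i) * e[, idx]
    }
  }
  logmu <- sweep(niche, 2, logbase, "+") + depth + cfg$factor_scale * stoch
  mu <- exp(logmu)
  counts <- if (is.null(cfg$overdispersion)) {
    rpois(n * p, mu)
  } else {
    rnbinom(n * p, mu = mu, size = cfg$overdispersion)
  }
  m <- matrix(counts, n, p,
              dimnames = list(paste(layout$site_id, layout$habitat, sep = ":"),
                              sprintf("g%03d", seq_len(p))))
  ab <- abundance_matrix(m, level = "genus", metadata = layout)
  truth <- list(
    guild = setNames(guild, colnames(m)),
    guild_correlation = cfg$guild_correlation,
    optima = setNames(optima, colnames(m)),
    turnover_scale = cfg$turnover_scale,
    seed = cfg$seed
  )
  list(abundance = ab, truth = truth)
}
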