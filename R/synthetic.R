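# Synthetic FIA-style remeasurement data with known ground truth.

# Default 6x6 correlation structure among plot effects, ordered as
# effect_component_names(). Anchors: cross-size mortality 0.47, growth
# persistence 0.70, mortality persistence 0.25 (small) / 0.45 (large),
# growth-mortality near zero.
default_effect_correlation <- function() {
  r <- diag(6)
  set <- function(i, j, v) {
    r[i, j] <<- v
    r[j, i] <<- v
  }
  set(1, 2, 0.04); set(1, 3, 0.10); set(1, 4, 0.70)
  set(1, 5, 0.05); set(1, 6, 0.13)
  set(2, 3, 0.47); set(2, 4, 0.05); set(2, 5, 0.25); set(2, 6, 0.15)
  set(3, 4, 0.13); set(3, 5, 0.15); set(3, 6, 0.45)
  set(4, 5, 0.04); set(4, 6, 0.10)
  set(5, 6, 0.47)
  dimnames(r) <- list(effect_component_names(), effect_component_names())
  r
}

#' Generate ground-truth effect distributions for synthetic regions
#'
#' Builds one [region_effect_distribution()] per synthetic forest region. All
#' regions share the default effect correlation structure (cross-size
#' mortality correlation 0.47, growth persistence 0.70, mortality persistence
#' 0.25 for small and 0.45 for large trees, growth-mortality correlations
#' near zero) and the growth-effect sd; the mortality-effect sd increases
#' along the region index from `sd_mort[1]` to `sd_mort[2]`, spanning
#' fourfold-disturbance probabilities of roughly 1-5% per census interval.
#' Mortality-effect means are set to `-sd^2/2` so each region's mean
#' mortality multiplier `E[exp(E_M)]` is exactly 1 (plot effects redistribute
#' mortality without changing its regional mean).
#'
#' @param n_regions Number of synthetic regions (>= 1).
#' @param seed Integer seed (stored; the construction itself is
#'   deterministic).
#' @param sd_growth Growth-effect sd (log scale). Default 0.3.
#' @param sd_mort Length-2 range of mortality-effect sds across regions.
#' @param params Demography parameters; default
#'   [default_demography_params()].
#' @param correlation Optional 6x6 correlation matrix overriding the default.
#' @return An object of class `synthetic_truth`: list with `params`,
#'   `regions` (named list of `region_effect_distribution`), `region_climate`
#'   (data frame of region MAT/MAP centres) and `seed`.
#' @export
generate_truth <- function(n_regions, seed, sd_growth = 0.3,
                           sd_mort = c(0.6, 0.85),
                           params = default_demography_params(),
                           correlation = NULL) {
  if (n_regions < 1) stopf("n_regions must be >= 1")
  r <- if (is.null(correlation)) default_effect_correlation() else correlation
  if (!is_pd(r)) stopf("effect correlation matrix is not positive definite")
  sdm <- if (n_regions == 1) mean(sd_mort) else
    seq(sd_mort[1], sd_mort[2], length.out = n_regions)
  mats <- if (n_regions == 1) 12 else seq(5, 20, length.out = n_regions)
  maps <- if (n_regions == 1) 1100 else seq(800, 1400, length.out = n_regions)
  regions <- list()
  for (i in seq_len(n_regions)) {
    sds <- c(sd_growth, sdm[i], sdm[i], sd_growth, sdm[i], sdm[i])
    sigma <- diag(sds) %*% r %*% diag(sds)
    mu <- c(0, -sdm[i]^2 / 2, -sdm[i]^2 / 2, 0, -sdm[i]^2 / 2, -sdm[i]^2 / 2)
    regions[[sprintf("region_%02d", i)]] <-
      region_effect_distribution(mu, sigma, params$global$sigma_growth)
  }
  structure(list(
    params = params,
    regions = regions,
    region_climate = data.frame(
      region = names(regions), mat = mats, map = maps
    ),
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

# Truncated draws of stem diameters for the two size classes. Small trees
# come from the 2.1 m microplots (2.54-12.7 cm), large trees from the 7.3 m
# subplots (>= 12.7 cm).
draw_dbh <- function(n, size_class) {
  ifelse(size_class == "small",
         exp(stats::runif(n, log(2.6), log(12.6))),
         12.7 + stats::rgamma(n, shape = 2, scale = 6))
}

#' Generate a synthetic tree remeasurement inventory
#'
#' Simulates FIA-style paired-census tree tables under the stored truth: each
#' plot draws a six-component effect vector from its region's multivariate
#' normal, each tree then survives the census interval with probability
#' `(1 - m')^interval` where `m'` is the logit-shifted background mortality,
#' and surviving trees grow by a normal increment with mean
#' `exp(E_G) * G * interval` and sd `sigma_growth * sqrt(interval)`.
#'
#' Census intervals are 3-8 yr (mode 5); plots whose first measurement year
#' precedes 2003 belong to the "earlier" period, the rest to "recent"; a
#' fraction `frac_both` of plots is measured in both periods (the others in
#' one period only, chosen at random, but their latent effect vector always
#' has all six components). Small trees (< 12.7 cm DBH, sampled on the
#' microplot) are rarer per plot than large ones. Fractions of plots can be
#' flagged non-forestland / harvested / condition-boundary to exercise the
#' data filters.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param n_plots Total number of plots (>= 1), spread evenly over regions.
#' @param mean_trees_per_plot Mean Poisson tree count per measured
#'   plot-period (> 0). Default 20.
#' @param seed Integer seed.
#' @param prop_small Probability a tree is in the small size class.
#' @param frac_both Fraction of plots measured in both census periods.
#' @param frac_nonforest,frac_harvested,frac_boundary Fractions of plots
#'   flagged for removal by [apply_plot_filters()].
#' @return An object of class `inventory_tables`: list with data frames
#'   `trees` (plot_id, subplot, period, size_class, pft, dbh_t0, dbh_t1,
#'   status_t1, shading), `plots` (plot_id, period, region, mat, map,
#'   meas_year_start, interval, forestland, harvested, cond_boundary) and
#'   `truth_effects` (the per-plot effect draws actually used, one row per
#'   plot with the six components).
#' @export
generate_inventory <- function(truth, n_plots, mean_trees_per_plot = 20, seed,
                               prop_small = 0.3, frac_both = 0.2,
                               frac_nonforest = 0, frac_harvested = 0,
                               frac_boundary = 0) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_plots < 1) stopf("n_plots must be >= 1")
  if (mean_trees_per_plot <= 0) stopf("mean_trees_per_plot must be > 0")
  set.seed(as.integer(seed))
  params <- truth$params
  region_names <- names(truth$regions)
  comp <- effect_component_names()

  plot_rows <- list()
  tree_rows <- list()
  effect_rows <- list()
  plot_region <- rep(region_names, length.out = n_plots)

  for (i in seq_len(n_plots)) {
    pid <- sprintf("P%05d", i)
    region <- plot_region[i]
    dist <- truth$regions[[region]]
    rc <- truth$region_climate[truth$region_climate$region == region, ]
    mat <- stats::rnorm(1, rc$mat, 1)
    map <- max(stats::rnorm(1, rc$map, 100), 0)
    clim <- climate_conditions(mat, map)
    v <- drop(rmvn(1, dist$mu, dist$sigma_mat))
    effect_rows[[i]] <- c(list(plot_id = pid, region = region),
                          as.list(stats::setNames(v, comp)))

    periods <- if (stats::runif(1) < frac_both) c("earlier", "recent")
               else sample(c("earlier", "recent"), 1)
    for (period in periods) {
      year <- if (period == "earlier") sample(1998:2002, 1) else sample(2003:2008, 1)
      interval <- sample(c(3, 4, 5, 5, 5, 6, 7, 8), 1)
      plot_rows[[length(plot_rows) + 1]] <- data.frame(
        plot_id = pid, period = period, region = region, mat = mat, map = map,
        meas_year_start = year, interval = interval,
        forestland = stats::runif(1) >= frac_nonforest,
        harvested = stats::runif(1) < frac_harvested,
        cond_boundary = stats::runif(1) < frac_boundary
      )
      n_tree <- max(1L, stats::rpois(1, mean_trees_per_plot))
      size_class <- ifelse(stats::runif(n_tree) < prop_small, "small", "large")
      dbh0 <- draw_dbh(n_tree, size_class)
      shading <- stats::runif(n_tree, 0, 3)
      # PFT composition follows climate suitability, as it would in a real
      # inventory: poorly suited PFTs are rare rather than common-but-dying.
      suit <- vapply(pft_names(params), function(p) {
        climate_term(clim, params$pft[[p]]$growth$t_opt,
                     params$pft[[p]]$growth$t_width,
                     params$pft[[p]]$growth$p_opt,
                     params$pft[[p]]$growth$p_width)
      }, numeric(1))
      pft <- sample(pft_names(params), n_tree, replace = TRUE, prob = suit)
      e_m <- v[effect_index("mortality", size_class, period)]
      e_g <- v[effect_index("growth", size_class, period)]
      m0 <- background_mortality(dbh0, shading, clim, pft, params)
      m1 <- apply_mortality_effect(m0, e_m)
      died <- stats::runif(n_tree) < interval_death_prob(m1, interval)
      g0 <- background_growth(dbh0, shading, clim, pft, params)
      inc <- stats::rnorm(n_tree,
                          mean = apply_growth_effect(g0, e_g) * interval,
                          sd = dist$sigma_growth * sqrt(interval))
      tree_rows[[length(tree_rows) + 1]] <- data.frame(
        plot_id = pid, subplot = sample(1:4, n_tree, replace = TRUE),
        period = period, size_class = size_class, pft = pft,
        dbh_t0 = dbh0,
        dbh_t1 = ifelse(died, NA_real_, dbh0 + inc),
        status_t1 = ifelse(died, "dead", "live"),
        shading = shading
      )
    }
  }
  structure(list(
    trees = do.call(rbind, tree_rows),
    plots = do.call(rbind, plot_rows),
    truth_effects = do.call(rbind, lapply(effect_rows, as.data.frame))
  ), class = "inventory_tables")
}

#' Generate an initial stand state
#'
#' `bare_ground` yields an empty cohort list (biomass 0), matching the
#' initialization of the long stand simulations; `random` yields a small
#' random stand with positive stem density, useful for property tests.
#'
#' @param kind `"bare_ground"` or `"random"`.
#' @param params A `demography_params` object.
#' @param seed Integer seed (used for `kind = "random"`).
#' @param climate A [climate_conditions()] object for the stand.
#' @return A `stand_state`; see [stand_state()].
#' @export
generate_initial_stand <- function(kind = c("bare_ground", "random"), params,
                                   seed = 1,
                                   climate = climate_conditions(9, 1000)) {
  kind <- match.arg(kind)
  if (kind == "bare_ground") {
    cohorts <- data.frame(pft = character(), dbh = numeric(), density = numeric())
  } else {
    set.seed(as.integer(seed))
    n <- sample(3:6, 1)
    cohorts <- data.frame(
      pft = sample(pft_names(params), n, replace = TRUE),
      dbh = exp(stats::runif(n, log(3), log(40))),
      density = stats::rexp(n, rate = 1 / 100)
    )
  }
  stand_state(cohorts = cohorts, effects = c(0, 0, 0), time = 0,
              climate = climate)
}
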