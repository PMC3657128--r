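# Shared fixtures (built once per test run) and independent oracles.

fv_params <- default_demography_params()
fv_climate <- climate_conditions(9, 1000)

fv_truth <- generate_truth(3, seed = 11)
fv_inv <- generate_inventory(fv_truth, n_plots = 45, mean_trees_per_plot = 12,
                             seed = 12, frac_both = 0.5)

# A single-region truth used by the heavier fit tests.
fv_truth1 <- generate_truth(1, seed = 21)

# Zero-innovation effect process: effects stay at mu exactly.
fv_null_process <- function(mu = c(0, 0, 0)) {
  effect_process(mu, matrix(0, 3, 3), matrix(0, 3, 3), mode = "variable")
}

# Naive per-tree loop implementation of the joint log-likelihood; the
# independent oracle for the vectorized log_likelihood().
naive_log_likelihood <- function(tables, effects, dist, params) {
  comp <- effect_component_names()
  ll <- 0
  for (i in seq_len(nrow(tables$trees))) {
    tr <- tables$trees[i, ]
    pl <- tables$plots[tables$plots$plot_id == tr$plot_id &
                         tables$plots$period == tr$period, ]
    clim <- climate_conditions(pl$mat, pl$map)
    m <- background_mortality(tr$dbh_t0, tr$shading, clim, tr$pft, params)
    g <- background_growth(tr$dbh_t0, tr$shading, clim, tr$pft, params)
    v <- effects[effects$plot_id == tr$plot_id, comp]
    j_m <- effect_index("mortality", tr$size_class, tr$period)
    j_g <- effect_index("growth", tr$size_class, tr$period)
    m_adj <- apply_mortality_effect(m, as.numeric(v[j_m]))
    p_die <- 1 - (1 - m_adj)^pl$interval
    ll <- ll + if (tr$status_t1 == "dead") log(p_die) else log(1 - p_die)
    if (tr$status_t1 == "live" && !is.na(tr$dbh_t1)) {
      mu_inc <- exp(as.numeric(v[j_g])) * g * pl$interval
      ll <- ll + dnorm(tr$dbh_t1 - tr$dbh_t0, mu_inc,
                       dist$sigma_growth * sqrt(pl$interval), log = TRUE)
    }
  }
  for (p in unique(effects$plot_id)) {
    x <- as.numeric(effects[effects$plot_id == p, comp])
    d <- x - dist$mu
    s_inv <- solve(dist$sigma_mat)
    ll <- ll + as.numeric(-0.5 * t(d) %*% s_inv %*% d) -
      0.5 * as.numeric(determinant(dist$sigma_mat)$modulus) - 3 * log(2 * pi)
  }
  ll
}

# Truth effects of an inventory in the plot_id/component layout that
# log_likelihood() expects.
truth_effects_frame <- function(inv) {
  inv$truth_effects[, c("plot_id", effect_component_names())]
}

# Subset inventory tables to one region.
region_tables <- function(inv, region) {
  keep <- inv$plots$region == region
  ids <- inv$plots$plot_id[keep]
  structure(list(trees = inv$trees[inv$trees$plot_id %in% ids, , drop = FALSE],
                 plots = inv$plots[keep, , drop = FALSE],
                 truth_effects =
                   inv$truth_effects[inv$truth_effects$region == region, ,
                                     drop = FALSE]),
            class = "inventory_tables")
}

# Minimal effect_posterior stand-in holding given per-plot "posterior mean"
# effects; used to unit-test correlation summaries without running MCMC.
fake_fit <- function(v, region = "region_01") {
  comp <- effect_component_names()
  plot_ids <- sprintf("P%05d", seq_len(nrow(v)))
  pe <- expand.grid(plot_id = plot_ids, component = comp,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pe$mean <- as.vector(v)
  pe$sd <- 0.1
  structure(list(region = region, plot_ids = plot_ids, plot_effects = pe),
            class = "effect_posterior")
}
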