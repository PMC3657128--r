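# Tree-level likelihood of the plot-effect model.

# Flatten inventory tables into the per-tree quantities the likelihood needs:
# background rates, observed outcomes, interval lengths, and the indices of
# the effect components each tree informs. Validates that every tree row
# references an existing plot row.
prep_tree_data <- function(tables, params) {
  trees <- tables$trees
  plots <- tables$plots
  key_t <- paste(trees$plot_id, trees$period)
  key_p <- paste(plots$plot_id, plots$period)
  m <- match(key_t, key_p)
  if (anyNA(m)) {
    stopf("tree rows reference %d (plot, period) pairs absent from the plot table",
          sum(is.na(m)))
  }
  clim <- list(mat = plots$mat[m], map = plots$map[m])
  m_bg <- background_mortality(trees$dbh_t0, trees$shading, clim, trees$pft, params)
  g_bg <- background_growth(trees$dbh_t0, trees$shading, clim, trees$pft, params)
  data.frame(
    plot_id = trees$plot_id,
    comp_m = effect_index("mortality", trees$size_class, trees$period),
    comp_g = effect_index("growth", trees$size_class, trees$period),
    died = trees$status_t1 == "dead",
    interval = plots$interval[m],
    logit_m = logit(m_bg),
    g_bg = g_bg,
    inc = trees$dbh_t1 - trees$dbh_t0
  )
}

# Tree-level log-likelihood terms given per-tree effect values.
mortality_loglik <- function(logit_m, e_m, interval, died) {
  m_adj <- inv_logit(logit_m + e_m)
  log_surv <- interval * log1p(-m_adj)
  ifelse(died, log1p(-exp(log_surv)), log_surv)
}

growth_loglik <- function(inc, g_bg, e_g, interval, sigma_growth) {
  stats::dnorm(inc, mean = exp(e_g) * g_bg * interval,
               sd = sigma_growth * sqrt(interval), log = TRUE)
}

mvn_logdens <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * ncol(x) * log(2 * pi)
}

#' Joint log-likelihood of inventory observations and plot effects
#'
#' Sums, over all tree rows of one region's tables, the Bernoulli log-mass of
#' each tree's survival outcome (death probability compounded over the census
#' interval from the logit-shifted annual mortality) and, for surviving trees
#' with a remeasured diameter, the normal log-density of the observed
#' increment around `exp(E_G) * G * interval`; adds the multivariate normal
#' log-density of each plot's six-component effect vector under the region
#' distribution.
#'
#' @param tables An `inventory_tables` object (one region).
#' @param effects Data frame with column `plot_id` plus the six effect
#'   columns named as `effect_component_names()`; one row per plot.
#' @param dist A [region_effect_distribution()].
#' @param params A `demography_params` object.
#' @return A single numeric log-likelihood.
#' @export
log_likelihood <- function(tables, effects, dist, params) {
  td <- prep_tree_data(tables, params)
  comp <- effect_component_names()
  if (!all(comp %in% names(effects))) stopf("effects must contain columns %s",
                                            paste(comp, collapse = ", "))
  row <- match(td$plot_id, effects$plot_id)
  if (anyNA(row)) stopf("tree rows reference plot ids absent from effects")
  v <- as.matrix(effects[, comp])
  e_m <- v[cbind(row, td$comp_m)]
  ll <- sum(mortality_loglik(td$logit_m, e_m, td$interval, td$died))
  live <- !is.na(td$inc)
  if (any(live)) {
    e_g <- v[cbind(row, td$comp_g)][live]
    ll <- ll + sum(growth_loglik(td$inc[live], td$g_bg[live], e_g,
                                 td$interval[live], dist$sigma_growth))
  }
  ll + sum(mvn_logdens(v, dist$mu, dist$sigma_mat))
}
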