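# Disturbance statistics derived from estimated plot-effect distributions.

#' Observed vs simulated plot-mortality cumulative distributions
#'
#' For every measured plot-period, the observed statistic is the fraction of
#' its trees that died between censuses. The simulated counterpart replaces
#' each tree's outcome with a Bernoulli draw from its background-model death
#' probability (compounded over the census interval) and re-aggregates to the
#' plot level. If real plot mortality contains disturbance events, the
#' observed distribution has an upper tail that the purely tree-level
#' simulation cannot reproduce.
#'
#' @param tables An `inventory_tables` object.
#' @param params A `demography_params` object.
#' @param seed Integer seed for the Bernoulli draws.
#' @return A list of class `mortality_cdf` with data frames `observed` and
#'   `simulated` (columns `x` = plot mortality fraction, `f` = cumulative
#'   frequency), and `n_units`, the number of plot-periods.
#' @export
simulate_plot_mortality_cdf <- function(tables, params, seed = 1) {
  td <- prep_tree_data(tables, params)
  if (nrow(td) == 0) stopf("tables contain no trees")
  set.seed(as.integer(seed))
  unit <- paste(td$plot_id, ifelse(td$comp_m <= 3, "earlier", "recent"))
  obs <- tapply(td$died, unit, mean)
  p_die <- interval_death_prob(inv_logit(td$logit_m), td$interval)
  sim_died <- stats::runif(nrow(td)) < p_die
  sim <- tapply(sim_died, unit, mean)
  as_cdf <- function(x) {
    f <- stats::ecdf(x)
    xs <- sort(unique(as.numeric(x)))
    data.frame(x = xs, f = f(xs))
  }
  structure(list(observed = as_cdf(obs), simulated = as_cdf(sim),
                 n_units = length(obs)), class = "mortality_cdf")
}

#' Probability of a threshold-fold mortality elevation
#'
#' With mortality effects E normal on the log-multiplier scale (so that
#' `exp(E)` is log-normal), the probability that a plot experiences at least
#' a `threshold_fold`-fold elevation of expected mortality above the mean
#' effect is the normal tail `1 - pnorm(log(threshold_fold) / effect_sd)`.
#'
#' @param effect_sd Marginal sd of the mortality-effect component (>= 0).
#'   Vectorized.
#' @param threshold_fold Fold-elevation threshold (>= 1). Default 4.
#' @return Probability in \[0, 1\].
#' @examples
#' disturbance_probability(log(4))  # 1 - pnorm(1) = 0.1587
#' @export
disturbance_probability <- function(effect_sd, threshold_fold = 4) {
  if (any(effect_sd < 0)) stopf("effect_sd must be >= 0")
  if (any(threshold_fold < 1)) stopf("threshold_fold must be >= 1")
  lt <- log(threshold_fold)
  ifelse(effect_sd == 0, as.numeric(lt <= 0),
         1 - stats::pnorm(lt / effect_sd))
}

#' Disturbance probabilities per size class and period for a region
#'
#' Evaluates [disturbance_probability()] for each mortality-effect component
#' of a region distribution. With `baseline = "region"` the elevation is
#' measured against the region's mean effect, using the component's marginal
#' sd. With `baseline = "plot"` it is measured against the plot's own
#' long-term (two-period) mean effect, whose deviation in one period is
#' `(E_t - E_t') / 2` with variance `(var - cross_cov) / 2`, so persistent
#' between-plot differences do not count as disturbance.
#'
#' @param dist A [region_effect_distribution()].
#' @param threshold_fold Fold-elevation threshold (>= 1).
#' @param baseline `"region"` or `"plot"`.
#' @return Data frame with columns `size_class`, `period`, `effect_sd`,
#'   `probability`.
#' @export
disturbance_summary <- function(dist, threshold_fold = 4,
                                baseline = c("region", "plot")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(dist, "region_effect_distribution"))
  s <- dist$sigma_mat
  idx <- data.frame(size_class = c("small", "large", "small", "large"),
                    period = c("earlier", "earlier", "recent", "recent"),
                    i = c(2L, 3L, 5L, 6L))
  sd_out <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx$i[r]
    j <- if (i <= 3) i + 3L else i - 3L  # same component, other period
    sd_out[r] <- if (baseline == "region") sqrt(s[i, i])
                 else sqrt(max(s[i, i] - s[i, j], 0) / 2)
  }
  data.frame(size_class = idx$size_class, period = idx$period,
             effect_sd = sd_out,
             probability = disturbance_probability(sd_out, threshold_fold))
}

#' Correlations among posterior-mean plot effects
#'
#' Pearson correlations among the six posterior-mean effects across plots:
#' the full 6x6 matrix plus named headline pairs (growth vs small/large
#' mortality within each period, small vs large mortality within each
#' period, and the between-period persistence of each effect). With a list
#' of fits, per-region matrices and pooled overall correlations are both
#' returned.
#'
#' @param fits An `effect_posterior` from [fit_region()], or a list of them
#'   (one per region).
#' @return A list of class `effect_correlations` with elements `overall`
#'   (6x6 correlation matrix), `by_region` (named list of 6x6 matrices) and
#'   `pairs` (data frame `pair`, `r`).
#' @export
effect_correlations <- function(fits) {
  if (inherits(fits, "effect_posterior")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "effect_posterior")))
  mats <- lapply(fits, effect_means)
  for (m in mats) if (nrow(m) < 3) stopf("need >= 3 plots per region to correlate effects")
  pooled <- do.call(rbind, mats)
  overall <- stats::cor(pooled)
  by_region <- stats::setNames(lapply(mats, stats::cor),
                               vapply(fits, function(f) f$region, character(1)))
  pair_def <- list(
    growth_mort_small_earlier = c(1, 2), growth_mort_large_earlier = c(1, 3),
    growth_mort_small_recent = c(4, 5), growth_mort_large_recent = c(4, 6),
    small_large_earlier = c(2, 3), small_large_recent = c(5, 6),
    growth_persistence = c(1, 4), mort_small_persistence = c(2, 5),
    mort_large_persistence = c(3, 6)
  )
  pairs <- data.frame(
    pair = names(pair_def),
    r = vapply(pair_def, function(ij) overall[ij[1], ij[2]], numeric(1))
  )
  rownames(pairs) <- NULL
  structure(list(overall = overall, by_region = by_region, pairs = pairs),
            class = "effect_correlations")
}

#' @export
print.effect_correlations <- function(x, ...) {
  cat("Correlations among posterior-mean plot effects\n")
  print(transform(x$pairs, r = round(r, 3)))
  invisible(x)
}
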