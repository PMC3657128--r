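#' Plot effects on demographic rates
#'
#' A plot's mortality effect `e_m` shifts the logit of the background annual
#' mortality probability: `m' = logit^-1(logit(m) + e_m)`. Because annual
#' mortality is small, `m'` is approximately `exp(e_m) * m`, so `exp(e_m)`
#' can be read as a mortality multiplier; [approx_mortality_effect()] computes
#' that approximation directly (clipped at 1). A plot's growth effect `e_g` is
#' a log-scale multiplier on the background growth rate:
#' `g' = exp(e_g) * g`.
#'
#' @param m Background annual mortality probability, strictly inside (0, 1).
#'   Vectorized.
#' @param e_m Mortality effect on the logit scale (dimensionless). Vectorized.
#' @return Adjusted annual mortality probability.
#' @examples
#' apply_mortality_effect(0.1, log(4))   # 4/13
#' approx_mortality_effect(0.015, 1)     # exp(1) * 0.015
#' apply_growth_effect(1, log(2))        # 2
#' @export
apply_mortality_effect <- function(m, e_m) {
  if (any(m <= 0 | m >= 1)) stopf("m must be strictly inside (0, 1)")
  inv_logit(logit(m) + e_m)
}

#' @rdname apply_mortality_effect
#' @export
approx_mortality_effect <- function(m, e_m) {
  if (any(m <= 0 | m >= 1)) stopf("m must be strictly inside (0, 1)")
  pmin(exp(e_m) * m, 1)
}

#' @rdname apply_mortality_effect
#' @param g Background growth rate, cm/yr (>= 0). Vectorized.
#' @param e_g Growth effect: log-scale multiplier. Vectorized.
#' @export
apply_growth_effect <- function(g, e_g) {
  if (any(g < 0)) stopf("g must be >= 0")
  exp(e_g) * g
}

#' Fixed ordering of the six per-plot effect components
#'
#' Growth, small-tree mortality and large-tree mortality effects for the
#' earlier census period, then the same three for the recent period. All
#' vectors, matrices and tables of plot effects use this order.
#'
#' @return Character vector of length 6.
#' @export
effect_component_names <- function() {
  c("growth_earlier", "mort_small_earlier", "mort_large_earlier",
    "growth_recent", "mort_small_recent", "mort_large_recent")
}

# Component index for a (size_class, period, variable) combination.
# Vectorized over any combination of argument lengths.
effect_index <- function(variable, size_class, period) {
  lens <- c(length(variable), length(size_class), length(period))
  n <- if (any(lens == 0)) 0L else max(lens)
  variable <- rep_len(variable, n)
  size_class <- rep_len(size_class, n)
  period <- rep_len(period, n)
  base <- ifelse(period == "earlier", 0L, 3L)
  off <- ifelse(variable == "growth", 1L,
                ifelse(size_class == "small", 2L, 3L))
  as.integer(base + off)
}

#' Region-level distribution of plot effects
#'
#' The six effects per plot (growth, small-tree mortality, large-tree
#' mortality; each for the earlier and the recent census period) are modelled
#' as one draw from a region-specific multivariate normal with mean `mu` and
#' covariance `sigma_mat`. `sigma_growth` is the residual sd of observed
#' diameter increments (cm per sqrt(yr)).
#'
#' @param mu Numeric 6-vector, ordered as `effect_component_names()`.
#' @param sigma_mat Symmetric positive-definite 6x6 covariance matrix.
#' @param sigma_growth Growth residual sd (> 0).
#' @return An object of class `region_effect_distribution`.
#' @seealso [derive_blocks()], [generate_truth()]
#' @export
region_effect_distribution <- function(mu, sigma_mat, sigma_growth) {
  mu <- as.numeric(mu)
  sigma_mat <- as.matrix(sigma_mat)
  if (length(mu) != 6 || !all(dim(sigma_mat) == c(6, 6))) {
    stopf("mu must have length 6 and sigma_mat be 6x6")
  }
  if (max(abs(sigma_mat - t(sigma_mat))) > 1e-8) stopf("sigma_mat must be symmetric")
  if (!is_pd(sigma_mat)) stopf("sigma_mat must be positive definite")
  if (sigma_growth <= 0) stopf("sigma_growth must be > 0")
  names(mu) <- effect_component_names()
  dimnames(sigma_mat) <- list(effect_component_names(), effect_component_names())
  structure(list(mu = mu, sigma_mat = symmetrize(sigma_mat),
                 sigma_growth = sigma_growth),
            class = "region_effect_distribution")
}

#' Within- and cross-period covariance blocks
#'
#' Splits the 6x6 effect covariance into the 3x3 within-period block `c0`
#' (the average of the earlier and recent diagonal blocks, symmetrized) and
#' the 3x3 cross-period block `c1` (the earlier-by-recent off-diagonal block,
#' symmetrized as `(B + t(B)) / 2`). These are the stationary covariance and
#' lag-one cross-covariance handed to [var1_from_blocks()].
#'
#' @param dist A [region_effect_distribution()].
#' @return A list with 3x3 matrices `c0` and `c1`.
#' @export
derive_blocks <- function(dist) {
  s <- dist$sigma_mat
  c0 <- symmetrize((s[1:3, 1:3] + s[4:6, 4:6]) / 2)
  c1 <- symmetrize(s[1:3, 4:6])
  if (!is_pd(c0)) stopf("within-period covariance block c0 is not positive definite")
  comp <- c("growth", "mort_small", "mort_large")
  dimnames(c0) <- dimnames(c1) <- list(comp, comp)
  list(c0 = c0, c1 = c1)
}
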