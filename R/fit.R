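# Hierarchical Bayesian estimation of plot effects for one forest region.
#
# Sampler: Metropolis-within-Gibbs. Each of the six effect components is
# updated for all plots at once by a random-walk Metropolis step whose prior
# is the exact univariate conditional of the region MVN given the plot's
# other five components; (mu, Sigma) are then refreshed from their conjugate
# Normal-Inverse-Wishart full conditional and sigma_growth^2 from its
# conjugate Inverse-Gamma full conditional. Proposal scales adapt toward a
# 35% acceptance rate during burn-in only.

#' Sampler configuration for [fit_region()]
#'
#' @param n_iter Number of post-burn-in sweeps.
#' @param burnin Number of adaptation/burn-in sweeps discarded.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer RNG seed; every sampler run is reproducible given it.
#' @param mu0,kappa0 Normal prior on `mu` given `Sigma`: mean `mu0`,
#'   precision scale `kappa0` (small `kappa0` = broad prior).
#' @param nu0,s0 Inverse-Wishart prior on `Sigma`: degrees of freedom `nu0`
#'   (default dimension + 2) and scale matrix `s0`.
#' @param sigma_a0,sigma_b0 Inverse-Gamma prior on `sigma_growth^2`.
#' @param fix_hyper Optional [region_effect_distribution()]; if supplied,
#'   `mu`, `Sigma` and `sigma_growth` are held fixed at its values and only
#'   the plot effects are sampled (used for oracle checks and single-plot
#'   posteriors).
#' @param step_init Initial random-walk proposal sd per component.
#' @param rhat_threshold Split-chain convergence statistic above which the
#'   fit is flagged as not converged (with a warning).
#' @param init Optional named list of starting values (any of `v`, a plots
#'   x 6 matrix; `mu`; `sigma`; `sigma_growth`); defaults are diffuse.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_iter = 1000, burnin = 500, thin = 1, seed = 1,
                       mu0 = rep(0, 6), kappa0 = 0.01, nu0 = 8, s0 = diag(6),
                       sigma_a0 = 0.01, sigma_b0 = 0.01, fix_hyper = NULL,
                       step_init = 0.4, rhat_threshold = 1.1, init = list()) {
  if (!is.null(fix_hyper)) stopifnot(inherits(fix_hyper, "region_effect_distribution"))
  structure(list(n_iter = n_iter, burnin = burnin, thin = thin,
                 seed = as.integer(seed), mu0 = mu0, kappa0 = kappa0,
                 nu0 = nu0, s0 = s0, sigma_a0 = sigma_a0, sigma_b0 = sigma_b0,
                 fix_hyper = fix_hyper, step_init = step_init,
                 rhat_threshold = rhat_threshold, init = init),
            class = "fit_config")
}

riwish <- function(nu, s) {
  chol2inv(chol(stats::rWishart(1, nu, chol2inv(chol(s)))[, , 1]))
}

#' Fit the hierarchical plot-effect model for one region
#'
#' Estimates, by MCMC, the posterior distribution of every plot's
#' six-component effect vector (growth, small-tree mortality, large-tree
#' mortality in the earlier and recent census periods), the region-level
#' multivariate normal hyperparameters (`mu`, `Sigma`), and the growth
#' residual sd `sigma_growth`, from tree-level survival and growth
#' observations. Plots with few or no trees informing a component receive
#' posteriors pulled toward the multivariate normal conditional given their
#' other components, so every plot gets all six effects.
#'
#' @param tables An `inventory_tables` object.
#' @param region Region label present in `tables$plots$region`.
#' @param config A [fit_config()].
#' @param params A `demography_params` object used for the background rates.
#' @return An object of class `effect_posterior`: per-plot posterior means
#'   and sds with effective sample sizes and split-chain convergence
#'   statistics (`$plot_effects`), hyperparameter summaries (`$hyper`),
#'   retained draws (`$draws`, thinned; plot-effect draws as an
#'   iterations x plots x 6 array), and `$diagnostics`.
#' @seealso [effect_means()], [as_region_distribution()],
#'   [effect_correlations()]
#' @export
fit_region <- function(tables, region, config = fit_config(),
                       params = default_demography_params()) {
  stopifnot(inherits(config, "fit_config"))
  plots_all <- tables$plots
  keep <- plots_all$region == region
  if (!any(keep)) stopf("region '%s' not present in tables", region)
  sub <- list(trees = tables$trees[tables$trees$plot_id %in%
                                     plots_all$plot_id[keep], , drop = FALSE],
              plots = plots_all[keep, , drop = FALSE])
  plot_ids <- sort(unique(sub$plots$plot_id))
  n_plots <- length(plot_ids)
  fixed <- !is.null(config$fix_hyper)
  if (!fixed && n_plots < 2) {
    stopf("region '%s' has %d plot(s); >= 2 required to estimate (mu, Sigma)",
          region, n_plots)
  }

  td <- prep_tree_data(sub, params)
  td$g <- match(td$plot_id, plot_ids)
  live <- !is.na(td$inc)

  # Per-component tree groupings. Components 1 and 4 are growth, the rest
  # mortality (see effect_component_names()).
  comp_trees <- lapply(1:6, function(j) {
    if (j %in% c(1L, 4L)) which(live & td$comp_g == j) else which(td$comp_m == j)
  })

  set.seed(config$seed)
  v <- matrix(0, n_plots, 6)
  if (fixed) {
    mu <- config$fix_hyper$mu
    sigma <- config$fix_hyper$sigma_mat
    sigma_g <- config$fix_hyper$sigma_growth
  } else {
    mu <- rep(0, 6)
    sigma <- diag(0.3, 6)
    sigma_g <- if (any(live)) {
      stats::sd((td$inc[live] - td$g_bg[live] * td$interval[live]) /
                  sqrt(td$interval[live]))
    } else 0.1
    if (!is.finite(sigma_g) || sigma_g <= 0) sigma_g <- 0.1
  }
  if (!is.null(config$init$v)) v <- config$init$v
  if (!fixed) {
    if (!is.null(config$init$mu)) mu <- config$init$mu
    if (!is.null(config$init$sigma)) sigma <- config$init$sigma
    if (!is.null(config$init$sigma_growth)) sigma_g <- config$init$sigma_growth
  }

  step <- rep(config$step_init, 6)
  acc <- att <- rep(0, 6)
  n_sweeps <- config$burnin + config$n_iter
  keep_iter <- seq(config$burnin + 1, n_sweeps, by = config$thin)
  n_keep <- length(keep_iter)
  v_draws <- array(NA_real_, c(n_keep, n_plots, 6))
  mu_draws <- matrix(NA_real_, n_keep, 6)
  sigma_draws <- array(NA_real_, c(n_keep, 6, 6))
  sigma_g_draws <- numeric(n_keep)
  k <- 0L

  comp_loglik <- function(j, e) {
    idx <- comp_trees[[j]]
    if (length(idx) == 0) return(numeric(n_plots))
    et <- e[td$g[idx]]
    ll <- if (j %in% c(1L, 4L)) {
      growth_loglik(td$inc[idx], td$g_bg[idx], et, td$interval[idx], sigma_g)
    } else {
      mortality_loglik(td$logit_m[idx], et, td$interval[idx], td$died[idx])
    }
    out <- numeric(n_plots)
    sums <- rowsum(ll, td$g[idx])
    out[as.integer(rownames(sums))] <- sums
    out
  }

  for (it in seq_len(n_sweeps)) {
    omega <- chol2inv(chol(sigma))
    vc <- sweep(v, 2, mu)
    for (j in 1:6) {
      cond_sd <- sqrt(1 / omega[j, j])
      cond_mean <- mu[j] + vc[, j] - drop(vc %*% omega[, j]) / omega[j, j]
      # random-walk proposal (mixes well-informed effects locally) ...
      cur <- v[, j]
      prop <- cur + stats::rnorm(n_plots, 0, step[j])
      log_acc <- comp_loglik(j, prop) - comp_loglik(j, cur) +
        stats::dnorm(prop, cond_mean, cond_sd, log = TRUE) -
        stats::dnorm(cur, cond_mean, cond_sd, log = TRUE)
      take <- log(stats::runif(n_plots)) < log_acc
      v[take, j] <- prop[take]
      acc[j] <- acc[j] + mean(take)
      att[j] <- att[j] + 1
      # ... then a Metropolized independence proposal from the conditional
      # prior, which regenerates weakly-informed effects wholesale (the
      # prior cancels, leaving only the likelihood ratio).
      cur <- v[, j]
      prop <- stats::rnorm(n_plots, cond_mean, cond_sd)
      take <- log(stats::runif(n_plots)) < comp_loglik(j, prop) - comp_loglik(j, cur)
      v[take, j] <- prop[take]
      vc[, j] <- v[, j] - mu[j]
    }
    if (it <= config$burnin && it %% 50 == 0) {
      rate <- acc / att
      step <- step * exp(pmin(pmax(rate - 0.35, -0.5), 0.5))
      acc[] <- att[] <- 0
    }

    if (!fixed) {
      vbar <- colMeans(v)
      s_mat <- crossprod(sweep(v, 2, vbar))
      kappa_n <- config$kappa0 + n_plots
      m_n <- (config$kappa0 * config$mu0 + n_plots * vbar) / kappa_n
      nu_n <- config$nu0 + n_plots
      d0 <- vbar - config$mu0
      s_n <- config$s0 + s_mat +
        (config$kappa0 * n_plots / kappa_n) * tcrossprod(d0)
      sigma <- symmetrize(riwish(nu_n, s_n))
      mu <- drop(rmvn(1, m_n, sigma / kappa_n))

      gidx <- which(live)
      if (length(gidx) > 0) {
        e_g <- v[cbind(td$g[gidx], td$comp_g[gidx])]
        res <- td$inc[gidx] - exp(e_g) * td$g_bg[gidx] * td$interval[gidx]
        a_n <- config$sigma_a0 + length(gidx) / 2
        b_n <- config$sigma_b0 + 0.5 * sum(res^2 / td$interval[gidx])
        sigma_g <- sqrt(1 / stats::rgamma(1, a_n, rate = b_n))
      }
    }

    if (it %in% keep_iter) {
      k <- k + 1L
      v_draws[k, , ] <- v
      mu_draws[k, ] <- mu
      sigma_draws[k, , ] <- sigma
      sigma_g_draws[k] <- sigma_g
    }
  }

  summarize_fit(region, plot_ids, v_draws, mu_draws, sigma_draws,
                sigma_g_draws, config, fixed)
}

summarize_fit <- function(region, plot_ids, v_draws, mu_draws, sigma_draws,
                          sigma_g_draws, config, fixed) {
  comp <- effect_component_names()
  n_plots <- length(plot_ids)
  pe <- expand.grid(plot_id = plot_ids, component = comp,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pe$mean <- as.vector(apply(v_draws, c(2, 3), mean))
  pe$sd <- as.vector(apply(v_draws, c(2, 3), stats::sd))
  pe$ess <- as.vector(apply(v_draws, c(2, 3), ess))
  pe$rhat <- as.vector(apply(v_draws, c(2, 3), split_rhat))

  q <- function(x, p) unname(stats::quantile(x, p))
  hyper_mu <- data.frame(
    component = comp,
    mean = colMeans(mu_draws),
    sd = apply(mu_draws, 2, stats::sd),
    q05 = apply(mu_draws, 2, q, 0.05),
    q95 = apply(mu_draws, 2, q, 0.95),
    ess = apply(mu_draws, 2, ess),
    rhat = apply(mu_draws, 2, split_rhat)
  )
  sigma_mean <- apply(sigma_draws, c(2, 3), mean)
  dimnames(sigma_mean) <- list(comp, comp)
  corr_mean <- stats::cov2cor(sigma_mean)
  sg <- c(mean = mean(sigma_g_draws), sd = stats::sd(sigma_g_draws),
          q05 = q(sigma_g_draws, 0.05), q95 = q(sigma_g_draws, 0.95))

  rhats <- c(hyper_mu$rhat, split_rhat(sigma_g_draws), pe$rhat)
  max_rhat <- max(rhats, na.rm = TRUE)
  converged <- fixed || is.na(max_rhat) || max_rhat < config$rhat_threshold
  if (!converged) {
    warning(sprintf(
      "fit_region('%s'): split-chain convergence statistic %.3f exceeds %.2f; increase n_iter/burnin",
      region, max_rhat, config$rhat_threshold), call. = FALSE)
  }

  structure(list(
    region = region,
    plot_ids = plot_ids,
    plot_effects = pe,
    hyper = list(mu = hyper_mu, sigma_mat_mean = sigma_mean,
                 correlation_mean = corr_mean, sigma_growth = sg),
    draws = list(v = v_draws, mu = mu_draws, sigma = sigma_draws,
                 sigma_growth = sigma_g_draws),
    diagnostics = list(converged = converged, max_rhat = max_rhat,
                       n_plots = n_plots, n_draws = nrow(mu_draws),
                       hyper_fixed = fixed),
    config = config
  ), class = "effect_posterior")
}

#' Posterior-mean effects as a plots x 6 matrix
#'
#' @param fit An `effect_posterior` from [fit_region()].
#' @return Numeric matrix, rows named by plot id, columns by
#'   `effect_component_names()`.
#' @export
effect_means <- function(fit) {
  stopifnot(inherits(fit, "effect_posterior"))
  comp <- effect_component_names()
  m <- matrix(fit$plot_effects$mean, nrow = length(fit$plot_ids),
              dimnames = list(fit$plot_ids, comp))
  m
}

#' Posterior-mean region distribution
#'
#' Collapses a fit into the [region_effect_distribution()] used by the
#' disturbance summaries and the stand simulator.
#'
#' @param fit An `effect_posterior` from [fit_region()].
#' @return A `region_effect_distribution`.
#' @export
as_region_distribution <- function(fit) {
  stopifnot(inherits(fit, "effect_posterior"))
  region_effect_distribution(fit$hyper$mu$mean, fit$hyper$sigma_mat_mean,
                             unname(fit$hyper$sigma_growth["mean"]))
}

#' @export
print.effect_posterior <- function(x, ...) {
  cat(sprintf("Hierarchical plot-effect fit: region '%s'\n", x$region))
  cat(sprintf("  plots: %d, retained draws: %d, hyperparameters %s\n",
              x$diagnostics$n_plots, x$diagnostics$n_draws,
              if (x$diagnostics$hyper_fixed) "fixed" else "estimated"))
  cat(sprintf("  converged: %s (max split-Rhat %.3f)\n",
              x$diagnostics$converged, x$diagnostics$max_rhat))
  cat("  posterior mean mu:\n")
  print(stats::setNames(round(x$hyper$mu$mean, 3), x$hyper$mu$component))
  invisible(x)
}
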