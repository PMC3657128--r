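# Construct a one-region inventory with a given number of large earlier-period
# trees per plot (plus optional growth observations), for targeted fit checks.
make_mortality_tables <- function(n_plots, trees_per_plot, seed,
                                  with_growth = FALSE) {
  set.seed(seed)
  plots <- data.frame(plot_id = sprintf("P%03d", seq_len(n_plots)),
                      period = "earlier", region = "reg",
                      mat = 9, map = 1000, meas_year_start = 2000,
                      interval = 5, forestland = TRUE, harvested = FALSE,
                      cond_boundary = FALSE)
  trees <- do.call(rbind, lapply(seq_len(n_plots), function(i) {
    dbh <- runif(trees_per_plot, 15, 35)
    data.frame(plot_id = plots$plot_id[i], subplot = 1, period = "earlier",
               size_class = "large", pft = "northern_hardwood",
               dbh_t0 = dbh,
               dbh_t1 = ifelse(rep(with_growth, trees_per_plot),
                               dbh + rnorm(trees_per_plot, 1, 0.2), NA_real_),
               status_t1 = sample(c("live", "dead"), trees_per_plot, TRUE,
                                  prob = c(0.9, 0.1)),
               shading = runif(trees_per_plot, 0, 2))
  }))
  trees$dbh_t1[trees$status_t1 == "dead"] <- NA_real_
  structure(list(trees = trees, plots = plots), class = "inventory_tables")
}

fixed_dist <- region_effect_distribution(rep(0, 6), diag(0.5, 6), 0.08)

test_that("fits are reproducible and validate their inputs", {
  tables <- make_mortality_tables(3, 8, seed = 1)
  cfg <- fit_config(n_iter = 100, burnin = 50, seed = 4, fix_hyper = fixed_dist)
  f1 <- fit_region(tables, "reg", cfg)
  f2 <- fit_region(tables, "reg", cfg)
  expect_identical(f1$plot_effects, f2$plot_effects)
  expect_error(fit_region(tables, "elsewhere", cfg), "not present")
  # estimating hyperparameters requires at least two plots ...
  one <- make_mortality_tables(1, 8, seed = 2)
  expect_error(fit_region(one, "reg", fit_config(n_iter = 50, burnin = 20)),
               "2 required")
  # ... but a single-plot fit with fixed hyperparameters is allowed
  expect_s3_class(fit_region(one, "reg", cfg), "effect_posterior")
})

test_that("non-convergence is flagged with a warning, never silently", {
  tables <- make_mortality_tables(4, 6, seed = 3)
  cfg <- fit_config(n_iter = 60, burnin = 10, seed = 5,
                    rhat_threshold = 1.000001)
  expect_warning(fit <- fit_region(tables, "reg", cfg), "convergence")
  expect_false(fit$diagnostics$converged)
})

test_that("per-plot posterior sd shrinks as trees per plot grow", {
  sds <- vapply(c(4, 16, 64), function(n) {
    tables <- make_mortality_tables(1, n, seed = 100 + n)
    fit <- fit_region(tables, "reg",
                      fit_config(n_iter = 1500, burnin = 500, seed = 6,
                                 fix_hyper = fixed_dist))
    pe <- fit$plot_effects
    pe$sd[pe$component == "mort_large_earlier"]
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("a component with no trees reverts to its conditional prior", {
  # plots have only large earlier trees: the small-tree effect posterior must
  # track the MVN conditional expectation given the sampled other effects
  sigma <- fv_truth1$regions$region_01$sigma_mat
  dist <- region_effect_distribution(fv_truth1$regions$region_01$mu, sigma, 0.08)
  tables <- make_mortality_tables(12, 25, seed = 7)
  fit <- fit_region(tables, "reg",
                    fit_config(n_iter = 3000, burnin = 500, seed = 8,
                               fix_hyper = dist))
  v <- fit$draws$v
  j <- 2L  # mort_small_earlier: no data anywhere in these tables
  others <- setdiff(1:6, j)
  s_oo_inv <- solve(sigma[others, others])
  w <- drop(sigma[j, others] %*% s_oo_inv)
  for (p in c(1, 5, 12)) {
    cond <- dist$mu[j] +
      as.matrix(sweep(v[, p, others], 2, dist$mu[others])) %*% w
    direct <- mean(v[, p, j])
    mc_se <- sd(v[, p, j]) / sqrt(forestvar:::ess(v[, p, j]))
    expect_lt(abs(direct - mean(cond)), 4 * mc_se + 0.02)
  }
})

test_that("nominal 90% intervals for mu cover the truth across replicates", {
  # reduced-scale simulation-based calibration: 20 refits of small synthetic
  # regions; coverage of the 90% posterior intervals should be near nominal
  n_rep <- 20
  covered <- 0L
  total <- 0L
  for (r in seq_len(n_rep)) {
    truth <- generate_truth(1, seed = 500 + r)
    inv <- generate_inventory(truth, n_plots = 60, mean_trees_per_plot = 8,
                              seed = 700 + r, frac_both = 0.5)
    fit <- suppressWarnings(fit_region(
      inv, "region_01", fit_config(n_iter = 300, burnin = 250, seed = 900 + r)))
    hm <- fit$hyper$mu
    mu_true <- truth$regions$region_01$mu
    covered <- covered + sum(hm$q05 <= mu_true & mu_true <= hm$q95)
    total <- total + length(mu_true)
  }
  coverage <- covered / total
  expect_gte(coverage, 0.75)
})

test_that("posterior summaries expose diagnostics and downstream objects", {
  inv <- region_tables(fv_inv, "region_02")
  fit <- suppressWarnings(fit_region(inv, "region_02",
                                     fit_config(n_iter = 200, burnin = 150,
                                                seed = 10)))
  pe <- fit$plot_effects
  expect_setequal(unique(pe$component), effect_component_names())
  expect_true(all(is.finite(pe$mean) & pe$sd > 0 & pe$ess > 0))
  em <- effect_means(fit)
  expect_equal(dim(em), c(length(fit$plot_ids), 6))
  rd <- as_region_distribution(fit)
  expect_s3_class(rd, "region_effect_distribution")
  expect_output(print(fit), "Hierarchical plot-effect fit")
})
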