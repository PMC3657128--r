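test_that("VAR(1) construction satisfies the stationarity identities", {
  c0 <- diag(c(0.09, 0.5, 0.5))
  # white noise when the cross-period block vanishes
  w <- var1_from_blocks(c0, matrix(0, 3, 3))
  expect_equal(w$a_mat, matrix(0, 3, 3))
  expect_equal(w$q_mat, c0)
  # scalar AR(1) identities embedded in the first coordinate
  s <- var1_from_blocks(diag(3), diag(c(0.5, 0, 0)))
  expect_equal(s$a_mat[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(s$q_mat[1, 1], 0.75, tolerance = 1e-12)
  # perfect persistence degenerates to zero innovation, flagged
  expect_warning(pp <- var1_from_blocks(c0, c0), "persistent")
  expect_lt(max(abs(pp$q_mat)), 1e-10)
  # impossible cross-covariance raises an error with a remedy hint
  expect_error(var1_from_blocks(c0, 1.2 * c0), "shrink c1")
  expect_error(var1_from_blocks(matrix(0, 3, 3), matrix(0, 3, 3)),
               "positive definite")
})

test_that("effect stepping honors fixed and variable modes", {
  mu <- c(0.1, -0.2, -0.3)
  still <- effect_process(mu, matrix(0, 3, 3), matrix(0, 3, 3))
  set.seed(1)
  expect_equal(step_effects(c(5, 5, 5), still), mu)

  blocks <- derive_blocks(fv_truth$regions$region_01)
  vq <- var1_from_blocks(blocks$c0, blocks$c1)
  fixed <- effect_process(mu, vq$a_mat, vq$q_mat, mode = "fixed")
  # pinned at the log-normal multiplier mean of the stationary law
  expect_equal(fixed$pin[2:3], mu[2:3] + diag(blocks$c0)[2:3] / 2,
               tolerance = 1e-8, ignore_attr = TRUE)
  set.seed(2)
  e <- mu
  growth_vals <- numeric(50)
  for (i in 1:50) {
    e <- step_effects(e, fixed)
    expect_equal(e[2:3], fixed$pin[2:3], ignore_attr = TRUE)
    growth_vals[i] <- e[1]
  }
  expect_gt(sd(growth_vals), 0)  # growth still varies
  expect_error(effect_process(mu, diag(1.5, 3), diag(3)), "spectral radius")
})

test_that("the VAR trajectory reproduces its stationary moments", {
  blocks <- derive_blocks(fv_truth$regions$region_02)
  vq <- var1_from_blocks(blocks$c0, blocks$c1)
  mu <- c(0, -0.25, -0.25)
  proc <- effect_process(mu, vq$a_mat, vq$q_mat)
  set.seed(3)
  n <- 2e4
  traj <- matrix(NA_real_, n, 3)
  e <- mu
  for (i in seq_len(n)) {
    e <- step_effects(e, proc)
    traj[i, ] <- e
  }
  # empirical mean within 3 SE of mu (SE inflated by autocorrelation ~ (1+a)/(1-a))
  for (j in 1:3) {
    rho <- vq$a_mat[j, j]
    se <- sd(traj[, j]) / sqrt(n) * sqrt((1 + rho) / (1 - rho))
    expect_lt(abs(mean(traj[, j]) - mu[j]), 3 * se)
  }
  c0_hat <- cov(traj)
  expect_lt(norm(c0_hat - blocks$c0, "F") / norm(blocks$c0, "F"), 0.1)
})

test_that("stand stepping: mortality thins, growth advances, recruits enter", {
  cohorts <- data.frame(pft = c("northern_hardwood", "southern_conifer"),
                        dbh = c(10, 25), density = c(300, 120))
  st <- stand_state(cohorts, climate = fv_climate)
  nxt <- step_stand(st, fv_params, fv_null_process())
  # surviving originals: density strictly reduced, dbh strictly increased
  orig <- nxt$cohorts[nxt$cohorts$dbh > 3, ]
  expect_equal(nrow(orig), 2)
  expect_true(all(orig$density < cohorts$density))
  expect_true(all(orig$dbh > cohorts$dbh))
  expect_equal(nxt$time, 5)
  # zero-effect step equals the background update exactly
  heights <- forestvar:::tree_height(cohorts$dbh, cohorts$pft, fv_params)
  shading <- forestvar:::cai_at_height(cohorts, heights, fv_params)
  g <- background_growth(cohorts$dbh, shading, fv_climate, cohorts$pft, fv_params)
  m <- background_mortality(cohorts$dbh, shading, fv_climate, cohorts$pft,
                            fv_params)
  expect_equal(sort(orig$dbh), sort(cohorts$dbh + 5 * g), tolerance = 1e-10)
  expect_equal(sort(orig$density), sort(cohorts$density * (1 - m)^5),
               tolerance = 1e-10)
})

test_that("an extreme mortality effect clears the stand down to recruits", {
  cohorts <- data.frame(pft = c("northern_hardwood", "boreal_conifer"),
                        dbh = c(8, 30), density = c(200, 100))
  st <- stand_state(cohorts, climate = fv_climate)
  lethal <- fv_null_process(mu = c(0, 25, 25))
  nxt <- step_stand(st, fv_params, lethal)
  expect_true(all(nxt$cohorts$dbh == fv_params$global$recruit_dbh))
})

test_that("stand simulation is reproducible with the right shape", {
  proc <- forestvar:::effect_process_from_distribution(fv_truth$regions$region_01)
  init <- generate_initial_stand("bare_ground", fv_params, climate = fv_climate)
  tr0 <- simulate_stand(init, 0, "fixed", fv_params, proc, seed = 4)
  expect_equal(unique(tr0$time), 0)
  expect_equal(tr0$biomass[tr0$pft == "total"], 0)
  tr1 <- simulate_stand(init, 200, "variable", fv_params, proc, seed = 5)
  tr2 <- simulate_stand(init, 200, "variable", fv_params, proc, seed = 5)
  expect_identical(tr1, tr2)
  expect_equal(length(unique(tr1$time)), 41)
  expect_setequal(unique(tr1$pft), c("total", names(fv_params$pft)))
  expect_true(all(is.finite(tr1$biomass)))
  tot <- tr1$biomass[tr1$pft == "total"]
  per_pft <- tapply(tr1$biomass[tr1$pft != "total"], tr1$time[tr1$pft != "total"],
                    sum)
  expect_equal(as.numeric(per_pft), tot, tolerance = 1e-9)
  expect_error(simulate_stand(init, 7, "fixed", fv_params, proc), "multiple of 5")
})

test_that("deterministic bare-ground succession rises to a stable plateau", {
  proc <- fv_null_process()  # no effect variation at all
  init <- generate_initial_stand("bare_ground", fv_params, climate = fv_climate)
  tr <- simulate_stand(init, 1500, "fixed", fv_params, proc, seed = 6)
  tot <- tr$biomass[tr$pft == "total"]
  # monotone rise through establishment and a bounded quasi-equilibrium after
  expect_true(all(diff(tot[1:30]) > 0))
  plateau <- tot[tr$time[tr$pft == "total"] >= 750]
  expect_lt((max(plateau) - min(plateau)) / mean(plateau), 0.35)
  expect_gt(mean(plateau), 100)
  expect_lt(mean(plateau), 500)
})
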