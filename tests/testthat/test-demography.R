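test_that("canopy profile is zero for an empty stand and additive over cohorts", {
  empty <- data.frame(pft = character(), dbh = numeric(), density = numeric())
  prof <- canopy_profile(empty, fv_params)
  expect_true(all(prof$cai == 0))

  one <- data.frame(pft = "northern_hardwood", dbh = 20, density = 150)
  two <- rbind(one, one)
  p1 <- canopy_profile(one, fv_params)
  p2 <- canopy_profile(two, fv_params)
  expect_equal(p2$cai, 2 * p1$cai)
})

test_that("canopy profile matches hand-computed crown area stacking", {
  # construct a PFT whose 10 cm tree has crown area exactly 10 m2 and crown
  # top exactly 20 m: CAI below 20 m must be 100 * 10 / 10000 = 0.1
  p <- fv_params
  p$pft$northern_hardwood$allometry$h_max <- 40
  p$pft$northern_hardwood$allometry$a_h <- log(2) / 10
  p$pft$northern_hardwood$allometry$crown_a <- 10 / 10^1.1
  one <- data.frame(pft = "northern_hardwood", dbh = 10, density = 100)
  prof <- canopy_profile(one, p, heights = c(0, 10, 19.9, 20, 25))
  expect_equal(prof$cai, c(0.1, 0.1, 0.1, 0, 0), tolerance = 1e-12)
})

test_that("canopy profile is non-increasing in height for random stands", {
  set.seed(42)
  for (rep in 1:10) {
    st <- generate_initial_stand("random", fv_params, seed = rep)
    prof <- canopy_profile(st$cohorts, fv_params)
    expect_true(all(diff(prof$cai) <= 1e-12))
    expect_true(all(prof$cai >= 0))
  }
  expect_error(canopy_profile(data.frame(pft = "northern_hardwood", dbh = 5,
                                         density = -1), fv_params),
               "density")
})

test_that("background growth has the stated product structure and limits", {
  g0 <- background_growth(20, 0, fv_climate, "northern_hardwood", fv_params)
  # no shading: product of size and climate terms only
  pp <- fv_params$pft$northern_hardwood$growth
  size_term <- pp$g1 * 20^pp$alpha * exp(-pp$beta * 20)
  clim_term <- exp(-((9 - pp$t_opt) / pp$t_width)^2 -
                     ((1000 - pp$p_opt) / pp$p_width)^2)
  expect_equal(g0, size_term * clim_term, tolerance = 1e-12)

  shade <- seq(0, 8, by = 0.5)
  g <- background_growth(20, shade, fv_climate, "northern_hardwood", fv_params)
  expect_true(all(diff(g) < 0))
  expect_lt(background_growth(20, 1e3, fv_climate, "northern_hardwood",
                              fv_params), 1e-12)
  expect_error(background_growth(20, 0, fv_climate, "no_such_pft", fv_params),
               "unknown PFT")
})

test_that("mortality is 1/(1+L) with longevity additive offset psi", {
  p <- fv_params
  p$pft$northern_hardwood$longevity$l1 <- 0
  p$global$psi <- 0
  expect_equal(background_mortality(20, 0, fv_climate, "northern_hardwood", p), 1)
  p$global$psi <- 99
  expect_equal(background_mortality(20, 0, fv_climate, "northern_hardwood", p),
               0.01, tolerance = 1e-12)
  p$global$psi <- 65.667
  expect_equal(background_mortality(20, 0, fv_climate, "northern_hardwood", p),
               0.015, tolerance = 1e-4)
  p$global$psi <- -1
  expect_error(background_mortality(20, 0, fv_climate, "northern_hardwood", p),
               "negative longevity")
})

test_that("mortality is bounded in (0,1] and increases with shading", {
  set.seed(7)
  for (pft in names(fv_params$pft)) {
    dbh <- exp(runif(20, log(3), log(80)))
    shade <- runif(20, 0, 6)
    m <- background_mortality(dbh, shade, fv_climate, pft, fv_params)
    g <- background_growth(dbh, shade, fv_climate, pft, fv_params)
    expect_true(all(m > 0 & m <= 1))
    expect_true(all(g >= 0))
    ms <- background_mortality(20, seq(0, 6, 0.5), fv_climate, pft, fv_params)
    expect_true(all(diff(ms) > 0))
  }
})

test_that("interval death probability compounds the annual rate", {
  expect_equal(interval_death_prob(0, 5), 0)
  expect_equal(interval_death_prob(1, 3), 1)
  expect_equal(interval_death_prob(0.015, 5), 1 - 0.985^5, tolerance = 1e-12)
  expect_equal(interval_death_prob(0.015, 5), 0.07278, tolerance = 1e-4)
  m <- runif(20)
  expect_equal(interval_death_prob(m, 1), m)
  expect_error(interval_death_prob(-0.1, 5), "m_annual")
  expect_error(interval_death_prob(0.5, 0), "interval")
})

test_that("recruitment saturates at r_max in the open and shuts out in shade", {
  pft <- "southern_conifer"  # shade-intolerant
  opt <- climate_conditions(fv_params$pft[[pft]]$growth$t_opt,
                            fv_params$pft[[pft]]$growth$p_opt)
  expect_equal(recruitment(pft, 0, opt, fv_params),
               fv_params$pft[[pft]]$recruitment$r_max)
  expect_lt(recruitment(pft, 50, opt, fv_params), 1e-10)
  # climate where suitability is exactly 0.5 halves open-canopy recruitment
  half <- climate_conditions(fv_params$pft[[pft]]$growth$t_opt +
                               fv_params$pft[[pft]]$growth$t_width * sqrt(log(2)),
                             fv_params$pft[[pft]]$growth$p_opt)
  expect_equal(recruitment(pft, 0, half, fv_params),
               0.5 * fv_params$pft[[pft]]$recruitment$r_max, tolerance = 1e-12)
})

test_that("biomass allometry is the documented power law", {
  expect_equal(aboveground_biomass(0, "boreal_conifer", fv_params), 0)
  expect_equal(aboveground_biomass(10, "boreal_conifer", fv_params),
               0.1 * 10^2.4, tolerance = 1e-12)
  expect_equal(aboveground_biomass(10, "boreal_conifer", fv_params), 25.12,
               tolerance = 1e-3)
  b <- aboveground_biomass(c(15, 30), "southern_hardwood", fv_params)
  expect_equal(b[2] / b[1], 2^2.4, tolerance = 1e-12)
})

test_that("demography parameters survive a JSON round trip", {
  path <- tempfile(fileext = ".json")
  write_demography_params(fv_params, path)
  back <- read_demography_params(path)
  expect_equal(back$global$sigma_growth, fv_params$global$sigma_growth)
  expect_equal(back$pft$northern_hardwood$longevity$l1,
               fv_params$pft$northern_hardwood$longevity$l1)
  expect_equal(
    background_mortality(17, 1.3, fv_climate, "southern_hydric", back),
    background_mortality(17, 1.3, fv_climate, "southern_hydric", fv_params))
  expect_error(read_demography_params({
    bad <- tempfile(fileext = ".json")
    jsonlite::write_json(list(schema = "other"), bad, auto_unbox = TRUE)
    bad
  }), "schema")
})
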