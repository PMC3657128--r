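# Cohort-based stand dynamics with stochastically varying plot effects.

#' Stand state
#'
#' The simulator's state: a cohort table (`pft`, `dbh` in cm, `density` in
#' stems/ha), the current three-component effect vector (growth, small-tree
#' mortality, large-tree mortality; log/logit scale), simulation time (yr,
#' multiple of 5) and the stand's climate.
#'
#' @param cohorts Data frame with columns `pft`, `dbh`, `density`.
#' @param effects Numeric 3-vector.
#' @param time Simulation time, yr (multiple of 5).
#' @param climate A [climate_conditions()] object.
#' @return An object of class `stand_state`.
#' @export
stand_state <- function(cohorts, effects = c(0, 0, 0), time = 0,
                        climate = climate_conditions(9, 1000)) {
  stopifnot(is.data.frame(cohorts),
            all(c("pft", "dbh", "density") %in% names(cohorts)))
  if (nrow(cohorts) > 0 && any(cohorts$density < 0)) stopf("density must be >= 0")
  if (nrow(cohorts) > 0 && any(cohorts$dbh < 0)) stopf("dbh must be >= 0")
  if (time %% 5 != 0) stopf("time must be a multiple of 5")
  structure(list(cohorts = cohorts, effects = as.numeric(effects),
                 time = time, climate = climate),
            class = "stand_state")
}

#' Stationary VAR(1) process for the demographic effects
#'
#' Constructs the first-order vector autoregression
#' `e[t+1] = mu + A (e[t] - mu) + eta`, `eta ~ MVN(0, Q)`, whose stationary
#' covariance equals the estimated within-period block `c0` and whose
#' lag-one cross-covariance equals the estimated between-period block `c1`:
#' `A = t(c1) c0^-1`, `Q = c0 - A c0 t(A)`. One VAR step corresponds to one
#' 5-yr simulator timestep.
#'
#' @param c0 3x3 positive-definite stationary covariance.
#' @param c1 3x3 lag-one cross-covariance.
#' @return A list `(a_mat, q_mat)`.
#' @seealso [derive_blocks()], [effect_process()]
#' @export
var1_from_blocks <- function(c0, c1) {
  c0 <- as.matrix(c0); c1 <- as.matrix(c1)
  if (!is_pd(c0)) stopf("c0 must be positive definite")
  a_mat <- t(c1) %*% chol2inv(chol(c0))
  q_mat <- symmetrize(c0 - a_mat %*% c0 %*% t(a_mat))
  if (!is_psd(q_mat)) {
    stopf(paste("implied innovation covariance is not positive semidefinite;",
                "the cross-period block is too strong relative to c0 -",
                "shrink c1 toward zero (e.g. c1 * 0.9) and retry"))
  }
  ev <- max(abs(eigen(q_mat, symmetric = TRUE, only.values = TRUE)$values))
  if (ev < 1e-12) warning("innovation covariance is numerically zero: perfectly persistent effects",
                          call. = FALSE)
  list(a_mat = a_mat, q_mat = q_mat)
}

#' Effect process specification
#'
#' @param mu Stationary mean 3-vector (growth, small-mortality,
#'   large-mortality effects).
#' @param a_mat,q_mat VAR(1) transition and innovation covariance (see
#'   [var1_from_blocks()]).
#' @param mode `"variable"` (all effects evolve) or `"fixed"` (mortality
#'   components pinned; the growth component still evolves). Pinning is at
#'   the mean of each mortality effect's log-normal multiplier distribution,
#'   `mu + var/2` on the log scale, so the fixed scenario carries the same
#'   time-averaged expected mortality as the variable one and the two differ
#'   only in variability.
#' @return A list of class `effect_process`.
#' @export
effect_process <- function(mu, a_mat, q_mat, mode = c("variable", "fixed")) {
  mode <- match.arg(mode)
  mu <- as.numeric(mu)
  stopifnot(length(mu) == 3, all(dim(a_mat) == c(3, 3)),
            all(dim(q_mat) == c(3, 3)))
  if (max(abs(eigen(a_mat, only.values = TRUE)$values)) >= 1) {
    stopf("VAR transition matrix must have spectral radius < 1")
  }
  if (!is_psd(q_mat)) stopf("q_mat must be positive semidefinite")
  proc <- structure(list(mu = mu, a_mat = a_mat, q_mat = symmetrize(q_mat),
                         mode = mode), class = "effect_process")
  sc <- stationary_cov(proc)
  pin <- mu
  pin[2:3] <- mu[2:3] + diag(sc)[2:3] / 2
  proc$pin <- pin
  proc
}

#' Build an effect process from a fitted region distribution
#'
#' Collapses a six-dimensional [region_effect_distribution()] to the
#' three-component VAR(1) driving the simulator: the process mean averages
#' the earlier- and recent-period block means, and the transition/innovation
#' matrices come from [derive_blocks()] + [var1_from_blocks()].
#'
#' @param dist A [region_effect_distribution()].
#' @param mode `"variable"` or `"fixed"`; see [effect_process()].
#' @return An [effect_process()].
#' @export
effect_process_from_distribution <- function(dist, mode = "variable") {
  blocks <- derive_blocks(dist)
  var1 <- var1_from_blocks(blocks$c0, blocks$c1)
  mu <- (dist$mu[1:3] + dist$mu[4:6]) / 2
  effect_process(mu, var1$a_mat, var1$q_mat, mode = mode)
}

#' Advance the effect vector one 5-yr step
#'
#' In `"variable"` mode the full VAR(1) update is applied. In `"fixed"` mode
#' the same innovation is drawn (so growth noise is matched between
#' scenarios run from the same seed) but the mortality components are pinned
#' at the log-scale mean of their stationary multiplier distribution
#' (`proc$pin`); only the growth effect evolves.
#'
#' @param e Current effect 3-vector.
#' @param proc An [effect_process()].
#' @return The next effect 3-vector.
#' @export
step_effects <- function(e, proc) {
  stopifnot(inherits(proc, "effect_process"))
  eta <- drop(rmvn(1, rep(0, 3), proc$q_mat))
  out <- proc$mu + drop(proc$a_mat %*% (e - proc$mu)) + eta
  if (proc$mode == "fixed") out[2:3] <- proc$pin[2:3]
  out
}

# Merge cohorts of the same PFT whose diameters round to the same 1 cm bin
# (density-weighted mean DBH) and drop cohorts below the density floor.
# Keeps the cohort list bounded during millennial runs.
consolidate_cohorts <- function(cohorts, floor) {
  if (nrow(cohorts) == 0) return(cohorts)
  cohorts <- cohorts[cohorts$density >= floor, , drop = FALSE]
  if (nrow(cohorts) == 0) return(cohorts)
  key <- paste(cohorts$pft, round(cohorts$dbh))
  dens <- tapply(cohorts$density, key, sum)
  dbh <- tapply(cohorts$density * cohorts$dbh, key, sum) / dens
  pft <- tapply(cohorts$pft, key, `[`, 1)
  out <- data.frame(pft = as.character(pft), dbh = as.numeric(dbh),
                    density = as.numeric(dens))
  rownames(out) <- NULL
  out
}

#' Advance a stand one 5-yr timestep
#'
#' In order: (1) the effect vector advances via [step_effects()]; (2) each
#' cohort grows by five times its effect-adjusted annual diameter growth,
#' with shading taken as the crown area index at the cohort's height at the
#' start of the step; (3) each cohort's density is thinned deterministically
#' by the 5-yr survival fraction implied by its effect-adjusted annual
#' mortality, routed to the small- or large-tree effect by its starting DBH
#' against the 12.7 cm threshold; (4) deterministic recruitment adds one new
#' cohort per PFT at the entry diameter; (5) cohorts below the density floor
#' are dropped and same-PFT cohorts in the same 1 cm diameter bin merged.
#'
#' @param stand A [stand_state()].
#' @param params A `demography_params` object.
#' @param proc An [effect_process()].
#' @return The next `stand_state`.
#' @export
step_stand <- function(stand, params, proc) {
  stopifnot(inherits(stand, "stand_state"))
  e <- step_effects(stand$effects, proc)
  cohorts <- stand$cohorts
  clim <- stand$climate
  thr <- params$global$size_threshold
  if (nrow(cohorts) > 0) {
    heights <- tree_height(cohorts$dbh, cohorts$pft, params)
    shading <- cai_at_height(cohorts, heights, params)
    g <- background_growth(cohorts$dbh, shading, clim, cohorts$pft, params)
    m <- background_mortality(cohorts$dbh, shading, clim, cohorts$pft, params)
    e_m <- ifelse(cohorts$dbh < thr, e[2], e[3])
    m_adj <- apply_mortality_effect(m, e_m)
    grown <- cohorts$dbh + 5 * apply_growth_effect(g, e[1])
    cohorts$dbh <- pmax(grown, cohorts$dbh)  # no shrinking cohorts
    cohorts$density <- cohorts$density * (1 - m_adj)^5
  }
  floor_cai <- cai_at_height(cohorts, 0, params)
  recruits <- recruitment(pft_names(params), floor_cai, clim, params)
  new_cohorts <- data.frame(pft = pft_names(params),
                            dbh = params$global$recruit_dbh,
                            density = recruits)
  cohorts <- rbind(cohorts, new_cohorts[new_cohorts$density > 0, , drop = FALSE])
  cohorts <- consolidate_cohorts(cohorts, params$global$density_floor)
  stand_state(cohorts = cohorts, effects = e, time = stand$time + 5,
              climate = clim)
}

stand_biomass <- function(stand, params) {
  cohorts <- stand$cohorts
  if (nrow(cohorts) == 0) {
    total <- 0
    per_pft <- stats::setNames(rep(0, length(pft_names(params))),
                               pft_names(params))
  } else {
    b <- aboveground_biomass(cohorts$dbh, cohorts$pft, params) *
      cohorts$density / 1000  # kg/ha -> Mg/ha
    per_pft <- vapply(pft_names(params),
                      function(p) sum(b[cohorts$pft == p]), numeric(1))
    total <- sum(b)
  }
  c(total = total, per_pft)
}

#' Simulate stand biomass dynamics
#'
#' Runs [step_stand()] for `years / 5` timesteps from an initial stand and
#' records total and per-PFT aboveground biomass (Mg/ha) every 5 years.
#' Under `scenario = "fixed"` the mortality effects are pinned at their
#' stationary mean while growth effects still vary; under `"variable"` all
#' effects follow the VAR(1) process. The same seed yields matched growth
#' innovations in both scenarios.
#'
#' @param init A [stand_state()].
#' @param years Simulation horizon, yr (non-negative multiple of 5).
#' @param scenario `"variable"` or `"fixed"`.
#' @param params A `demography_params` object.
#' @param proc An [effect_process()] (its `mode` is overridden by
#'   `scenario`).
#' @param seed Integer seed.
#' @param init_effects If `TRUE` (default), draw the initial effect vector
#'   from the stationary distribution (mean in fixed mode for mortality).
#' @return A long data frame of class `biomass_trajectory` with columns
#'   `time`, `pft` (including `"total"`), `biomass` (Mg/ha); `years/5 + 1`
#'   time points.
#' @export
simulate_stand <- function(init, years, scenario = c("variable", "fixed"),
                           params, proc, seed = 1, init_effects = TRUE) {
  scenario <- match.arg(scenario)
  if (years %% 5 != 0 || years < 0) stopf("years must be a non-negative multiple of 5")
  proc <- effect_process(proc$mu, proc$a_mat, proc$q_mat, mode = scenario)
  set.seed(as.integer(seed))
  stand <- init
  if (init_effects) {
    e0 <- drop(rmvn(1, rep(0, 3), stationary_cov(proc))) + proc$mu
    if (scenario == "fixed") e0[2:3] <- proc$pin[2:3]
    stand$effects <- e0
  }
  n_steps <- years / 5
  rec <- matrix(NA_real_, n_steps + 1, 1 + length(pft_names(params)))
  rec[1, ] <- stand_biomass(stand, params)
  for (s in seq_len(n_steps)) {
    stand <- step_stand(stand, params, proc)
    rec[s + 1, ] <- stand_biomass(stand, params)
  }
  labels <- c("total", pft_names(params))
  out <- data.frame(
    time = rep(seq(0, years, by = 5), times = length(labels)),
    pft = rep(labels, each = n_steps + 1),
    biomass = as.vector(rec)
  )
  structure(out, class = c("biomass_trajectory", "data.frame"),
            final_stand = stand)
}

# Stationary covariance of the VAR(1) by fixed-point iteration.
stationary_cov <- function(proc) {
  c0 <- proc$q_mat
  for (i in 1:500) {
    c0_new <- proc$a_mat %*% c0 %*% t(proc$a_mat) + proc$q_mat
    if (max(abs(c0_new - c0)) < 1e-12) break
    c0 <- c0_new
  }
  symmetrize(c0)
}
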