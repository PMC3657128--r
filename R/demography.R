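#' Climate conditions
#'
#' Bundle of the two climate covariates used by the background demographic
#' model: mean annual temperature (MAT) and mean annual precipitation (MAP).
#'
#' @param mat Mean annual temperature, degrees C.
#' @param map Mean annual precipitation, mm/yr. Must be non-negative.
#' @return An object of class `climate_conditions`.
#' @examples
#' climate_conditions(mat = 9, map = 1000)
#' @export
climate_conditions <- function(mat, map) {
  if (!is.finite(mat) || !is.finite(map)) stopf("mat and map must be finite")
  if (map < 0) stopf("map must be >= 0 (got %g)", map)
  structure(list(mat = mat, map = map), class = "climate_conditions")
}

#' Default background demography parameters
#'
#' Returns the full parameter set of the background demographic model: per-PFT
#' blocks for growth (size, competition and climate terms), longevity (whose
#' reciprocal, after adding one, is the annual mortality probability),
#' allometry (height, crown area, aboveground biomass) and recruitment, plus
#' global constants (growth residual sd `sigma_growth`, the reserved additive
#' offsets `delta` and `psi`, the small/large size threshold, the recruit
#' entry diameter and the cohort density floor).
#'
#' Seven plant functional types (PFTs) are parameterized, defined by
#' latitudinal range (boreal, northern temperate, southern temperate) and leaf
#' habit (hardwood, conifer), plus a southern hydric type. Defaults are chosen
#' so that a mid-sized canopy tree in its climatic optimum grows about
#' 0.2-0.4 cm/yr and dies with annual probability near 0.015, and so that a
#' closed-canopy temperate stand equilibrates at roughly 150-300 Mg/ha
#' aboveground biomass.
#'
#' @return A nested list of class `demography_params` with elements
#'   `schema`, `global`, and `pft`.
#' @seealso [background_growth()], [background_mortality()],
#'   [write_demography_params()]
#' @export
default_demography_params <- function() {
  # succession: early / mid / late shade tolerance syndrome
  mk_pft <- function(t_opt, p_opt, succession) {
    g1 <- switch(succession, early = 0.065, mid = 0.055, late = 0.045)
    gg <- switch(succession, early = 0.50, mid = 0.35, late = 0.25)
    l1 <- switch(succession, early = 22, mid = 32, late = 42)
    rmax <- switch(succession, early = 200, mid = 100, late = 60)
    rg <- switch(succession, early = 1.2, mid = 0.6, late = 0.25)
    list(
      succession = succession,
      growth = list(
        g1 = g1, alpha = 0.8, beta = 0.03, gamma = gg,
        t_opt = t_opt, t_width = 10, p_opt = p_opt, p_width = 1500
      ),
      longevity = list(
        l1 = l1, alpha = 0.8, beta = 0.05, gamma = 0.25,
        t_opt = t_opt, t_width = 12, p_opt = p_opt, p_width = 2000
      ),
      allometry = list(
        h_max = 30, a_h = 0.06, crown_a = 0.8, crown_b = 1.1,
        biomass_a = 0.1, biomass_b = 2.4
      ),
      recruitment = list(r_max = rmax, gamma = rg)
    )
  }
  structure(list(
    schema = "forestvar-demography-1",
    global = list(
      delta = 0, psi = 0, sigma_growth = 0.08,
      size_threshold = 12.7, recruit_dbh = 2.54, density_floor = 0.001
    ),
    pft = list(
      boreal_hardwood    = mk_pft(5,  800,  "early"),
      boreal_conifer     = mk_pft(4,  800,  "mid"),
      northern_hardwood  = mk_pft(9,  1000, "late"),
      northern_conifer   = mk_pft(8,  1100, "late"),
      southern_hardwood  = mk_pft(17, 1200, "mid"),
      southern_conifer   = mk_pft(18, 1300, "early"),
      southern_hydric    = mk_pft(19, 1400, "mid")
    )
  ), class = "demography_params")
}

pft_names <- function(params) names(params$pft)

# Look up one numeric parameter for a vector of pft labels; errors on
# unknown labels so typos never silently recycle another PFT's constants.
pft_param <- function(params, pft, block, field) {
  unknown <- setdiff(unique(pft), names(params$pft))
  if (length(unknown) > 0) stopf("unknown PFT label(s): %s", paste(unknown, collapse = ", "))
  tab <- vapply(params$pft, function(p) p[[block]][[field]], numeric(1))
  unname(tab[pft])
}

climate_term <- function(climate, t_opt, t_width, p_opt, p_width) {
  exp(-((climate$mat - t_opt) / t_width)^2 - ((climate$map - p_opt) / p_width)^2)
}

#' Background annual diameter growth
#'
#' Expected annual diameter growth of a tree as the product of a hump-shaped
#' size term `g1 * dbh^alpha * exp(-beta * dbh)`, an exponential shading decay
#' `exp(-gamma * shading_cai)` (normalized to 1 at zero shading), and a
#' Gaussian climate suitability term centred on the PFT's (MAT, MAP) optimum,
#' plus the reserved additive constant `delta` (0 by default).
#'
#' @param dbh Stem diameter at breast height, cm (> 0). Vectorized.
#' @param shading_cai Crown area index overtopping the tree (dimensionless,
#'   >= 0). Vectorized.
#' @param climate A [climate_conditions()] object.
#' @param pft PFT label(s); recycled against `dbh`.
#' @param params A `demography_params` object.
#' @return Expected growth, cm/yr (>= 0).
#' @examples
#' p <- default_demography_params()
#' background_growth(20, 0, climate_conditions(9, 1000), "northern_hardwood", p)
#' @export
background_growth <- function(dbh, shading_cai, climate, pft, params) {
  if (any(dbh <= 0)) stopf("dbh must be > 0")
  if (any(shading_cai < 0)) stopf("shading_cai must be >= 0")
  g1 <- pft_param(params, pft, "growth", "g1")
  alpha <- pft_param(params, pft, "growth", "alpha")
  beta <- pft_param(params, pft, "growth", "beta")
  gamma <- pft_param(params, pft, "growth", "gamma")
  ge <- climate_term(climate,
                     pft_param(params, pft, "growth", "t_opt"),
                     pft_param(params, pft, "growth", "t_width"),
                     pft_param(params, pft, "growth", "p_opt"),
                     pft_param(params, pft, "growth", "p_width"))
  g <- g1 * dbh^alpha * exp(-beta * dbh) * exp(-gamma * shading_cai) * ge +
    params$global$delta
  pmax(g, 0)
}

#' Background annual mortality probability
#'
#' Expected longevity L is the product of a size term (increasing up to a
#' senescence decline), a shading term `exp(-gamma * shading_cai)` (crowded
#' trees are shorter-lived), a Gaussian climate term, and the reserved
#' additive constant `psi`. The annual mortality probability is `1 / (1 + L)`,
#' which is always in (0, 1].
#'
#' @inheritParams background_growth
#' @return Annual mortality probability, in (0, 1].
#' @examples
#' p <- default_demography_params()
#' background_mortality(20, 1, climate_conditions(9, 1000), "northern_hardwood", p)
#' @export
background_mortality <- function(dbh, shading_cai, climate, pft, params) {
  if (any(dbh <= 0)) stopf("dbh must be > 0")
  if (any(shading_cai < 0)) stopf("shading_cai must be >= 0")
  l1 <- pft_param(params, pft, "longevity", "l1")
  alpha <- pft_param(params, pft, "longevity", "alpha")
  beta <- pft_param(params, pft, "longevity", "beta")
  gamma <- pft_param(params, pft, "longevity", "gamma")
  le <- climate_term(climate,
                     pft_param(params, pft, "longevity", "t_opt"),
                     pft_param(params, pft, "longevity", "t_width"),
                     pft_param(params, pft, "longevity", "p_opt"),
                     pft_param(params, pft, "longevity", "p_width"))
  l <- l1 * dbh^alpha * exp(-beta * dbh) * exp(-gamma * shading_cai) * le +
    params$global$psi
  if (any(l < 0)) stopf("negative longevity; check params")
  1 / (1 + l)
}

#' Death probability over a census interval
#'
#' Compounds an annual mortality probability over an interval of `interval`
#' years: `1 - (1 - m_annual)^interval`.
#'
#' @param m_annual Annual mortality probability in \[0, 1\]. Vectorized.
#' @param interval Interval length, yr (> 0). Vectorized.
#' @return Death probability over the interval.
#' @examples
#' interval_death_prob(0.015, 5)  # 0.07278
#' @export
interval_death_prob <- function(m_annual, interval) {
  if (any(m_annual < 0 | m_annual > 1)) stopf("m_annual must be in [0, 1]")
  if (any(interval <= 0)) stopf("interval must be > 0")
  1 - (1 - m_annual)^interval
}

#' Expected recruitment into a stand
#'
#' Deterministic expected number of new recruits per hectare over one 5-year
#' timestep: the PFT's maximum rate, damped exponentially by crown area index
#' at the forest floor (strongly so for shade-intolerant PFTs) and scaled by
#' the PFT's climate suitability in \[0, 1\].
#'
#' @param pft PFT label(s).
#' @param floor_cai Crown area index at the forest floor (>= 0).
#' @param climate A [climate_conditions()] object.
#' @param params A `demography_params` object.
#' @return Expected recruits per ha per 5-yr step.
#' @export
recruitment <- function(pft, floor_cai, climate, params) {
  if (any(floor_cai < 0)) stopf("floor_cai must be >= 0")
  r_max <- pft_param(params, pft, "recruitment", "r_max")
  gamma <- pft_param(params, pft, "recruitment", "gamma")
  suit <- climate_term(climate,
                       pft_param(params, pft, "growth", "t_opt"),
                       pft_param(params, pft, "growth", "t_width"),
                       pft_param(params, pft, "growth", "p_opt"),
                       pft_param(params, pft, "growth", "p_width"))
  r_max * exp(-gamma * floor_cai) * suit
}

#' Aboveground biomass of a tree
#'
#' Power-law allometry `a * dbh^b` with per-PFT constants (defaults a = 0.1,
#' b = 2.4).
#'
#' @param dbh Diameter at breast height, cm (>= 0). Vectorized.
#' @param pft PFT label(s).
#' @param params A `demography_params` object.
#' @return Biomass, kg per tree.
#' @examples
#' aboveground_biomass(10, "northern_hardwood", default_demography_params())
#' @export
aboveground_biomass <- function(dbh, pft, params) {
  if (any(dbh < 0)) stopf("dbh must be >= 0")
  a <- pft_param(params, pft, "allometry", "biomass_a")
  b <- pft_param(params, pft, "allometry", "biomass_b")
  a * dbh^b
}

tree_height <- function(dbh, pft, params) {
  h_max <- pft_param(params, pft, "allometry", "h_max")
  a_h <- pft_param(params, pft, "allometry", "a_h")
  h_max * (1 - exp(-a_h * dbh))
}

crown_area <- function(dbh, pft, params) {
  a <- pft_param(params, pft, "allometry", "crown_a")
  b <- pft_param(params, pft, "allometry", "crown_b")
  a * dbh^b
}

# Crown area index (m2 crown area per m2 ground, i.e. /10000 per ha) summed
# over all cohorts whose crown top lies strictly above height h. Vectorized
# over h.
cai_at_height <- function(cohorts, h, params) {
  if (nrow(cohorts) == 0) return(rep(0, length(h)))
  if (any(cohorts$density < 0)) stopf("cohort density must be >= 0")
  tops <- tree_height(cohorts$dbh, cohorts$pft, params)
  areas <- crown_area(cohorts$dbh, cohorts$pft, params) * cohorts$density / 1e4
  vapply(h, function(hh) sum(areas[tops > hh]), numeric(1))
}

#' Vertical crown area index profile of a stand
#'
#' Crown area index (CAI) at a ladder of evaluation heights: at height h, the
#' summed crown area per unit ground area of all cohorts whose crown top lies
#' above h. The profile is non-increasing with height; the value at h = 0 is
#' the stand's total CAI.
#'
#' @param cohorts A data frame of cohorts with columns `pft`, `dbh` (cm) and
#'   `density` (stems/ha); see [generate_initial_stand()].
#' @param params A `demography_params` object.
#' @param heights Evaluation heights, m, ascending. Default: 0 to just above
#'   the tallest possible crown in 0.5 m steps.
#' @return A data frame of class `canopy_profile` with columns `height` and
#'   `cai`.
#' @export
canopy_profile <- function(cohorts, params, heights = NULL) {
  stopifnot(is.data.frame(cohorts))
  if (is.null(heights)) {
    h_top <- max(vapply(params$pft, function(p) p$allometry$h_max, numeric(1)))
    heights <- seq(0, h_top + 1, by = 0.5)
  }
  if (is.unsorted(heights)) stopf("heights must be ascending")
  structure(
    data.frame(height = heights, cai = cai_at_height(cohorts, heights, params)),
    class = c("canopy_profile", "data.frame")
  )
}

#' Write / read demography parameters as JSON
#'
#' Serializes the nested per-PFT parameter list with its `schema` key so that
#' parameter sets can be versioned and shared between pipeline stages.
#'
#' @param params A `demography_params` object.
#' @param path File path.
#' @return `write_demography_params()` returns `path` invisibly;
#'   `read_demography_params()` returns a `demography_params` object.
#' @export
write_demography_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_demography_params
#' @export
read_demography_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "forestvar-demography-1")) {
    stopf("unrecognized demography params schema: %s", obj$schema)
  }
  structure(obj, class = "demography_params")
}
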