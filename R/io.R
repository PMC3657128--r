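# CSV/JSON readers and writers, FIA-style plot filters, and a staged
# pipeline runner. CSV dialect: UTF-8, comma separators, header row, "."
# decimal mark, empty string for missing values.

tree_columns <- c("plot_id", "subplot", "period", "size_class", "pft",
                  "dbh_t0", "dbh_t1", "status_t1", "shading")
plot_columns <- c("plot_id", "period", "region", "mat", "map",
                  "meas_year_start", "interval", "forestland", "harvested",
                  "cond_boundary")

#' Write inventory tables to CSV
#'
#' Writes `trees.csv` and `plots.csv` (and `truth_effects.csv` when ground
#' truth is attached) under `dir` using the documented column dictionary.
#'
#' @param tables An `inventory_tables` object.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_inventory <- function(tables, dir) {
  stopifnot(inherits(tables, "inventory_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tables$trees, file.path(dir, "trees.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(tables$plots, file.path(dir, "plots.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(tables$truth_effects)) {
    utils::write.csv(tables$truth_effects, file.path(dir, "truth_effects.csv"),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' Read inventory tables from CSV
#'
#' Reads and validates the tree and plot tables. A missing column raises a
#' schema error naming it. Tree rows with a malformed (non-numeric,
#' non-finite or non-positive) starting diameter are rejected; dead trees
#' have their end diameter forced to missing. The numbers of rows kept and
#' dropped per rule are attached as the `"validation"` attribute.
#'
#' @param tree_path,plot_path Paths to `trees.csv` and `plots.csv`.
#' @return An `inventory_tables` object.
#' @export
read_inventory <- function(tree_path, plot_path) {
  trees <- utils::read.csv(tree_path, na.strings = "",
                           colClasses = "character")
  plots <- utils::read.csv(plot_path, na.strings = "",
                           colClasses = "character")
  for (col in tree_columns) {
    if (!col %in% names(trees)) stopf("tree table is missing column '%s'", col)
  }
  for (col in plot_columns) {
    if (!col %in% names(plots)) stopf("plot table is missing column '%s'", col)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  trees$subplot <- as.integer(trees$subplot)
  trees$dbh_t0 <- num(trees$dbh_t0)
  trees$dbh_t1 <- num(trees$dbh_t1)
  trees$shading <- num(trees$shading)
  plots$mat <- num(plots$mat)
  plots$map <- num(plots$map)
  plots$meas_year_start <- as.integer(plots$meas_year_start)
  plots$interval <- num(plots$interval)
  for (col in c("forestland", "harvested", "cond_boundary")) {
    plots[[col]] <- as.logical(plots[[col]])
  }
  bad_dbh <- !is.finite(trees$dbh_t0) | trees$dbh_t0 <= 0
  n_bad <- sum(bad_dbh)
  trees <- trees[!bad_dbh, , drop = FALSE]
  trees$dbh_t1[trees$status_t1 == "dead"] <- NA_real_
  out <- structure(list(trees = trees, plots = plots, truth_effects = NULL),
                   class = "inventory_tables")
  attr(out, "validation") <- list(
    trees_kept = nrow(trees), trees_dropped_malformed_dbh = n_bad,
    plots_kept = nrow(plots)
  )
  out
}

#' Apply FIA-style plot filters
#'
#' Drops plot rows (and their trees) that are not on forestland, were
#' harvested between measurements, or intersect a forest-type condition
#' boundary. Counts removed per rule are attached as the `"filter_report"`
#' attribute. The operation is idempotent.
#'
#' @param tables An `inventory_tables` object.
#' @return The filtered `inventory_tables`.
#' @export
apply_plot_filters <- function(tables) {
  stopifnot(inherits(tables, "inventory_tables"))
  p <- tables$plots
  drop_nonforest <- !p$forestland
  drop_harvest <- p$harvested
  drop_boundary <- p$cond_boundary
  keep <- !(drop_nonforest | drop_harvest | drop_boundary)
  kept_plots <- p[keep, , drop = FALSE]
  key_keep <- paste(kept_plots$plot_id, kept_plots$period)
  trees <- tables$trees
  trees <- trees[paste(trees$plot_id, trees$period) %in% key_keep, , drop = FALSE]
  out <- structure(list(trees = trees, plots = kept_plots,
                        truth_effects = tables$truth_effects),
                   class = "inventory_tables")
  attr(out, "filter_report") <- list(
    dropped_nonforestland = sum(drop_nonforest),
    dropped_harvested = sum(drop_harvest & !drop_nonforest),
    dropped_condition_boundary = sum(drop_boundary & !drop_nonforest & !drop_harvest),
    plots_kept = nrow(kept_plots), trees_kept = nrow(trees)
  )
  out
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

check_config_keys <- function(config, allowed, stage) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stopf("unknown config key(s) for stage '%s': %s", stage,
          paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) stopf("config must carry an explicit seed")
}

write_stage_log <- function(stage, config, out_dir, outputs) {
  log <- list(stage = stage, seed = config$seed,
              config_hash = config_hash(config), outputs = outputs,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(log, file.path(out_dir, paste0(stage, "_log.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Thin orchestration over the package's functions, communicating through
#' CSV/JSON files so stages can be chained: `generate` writes a synthetic
#' inventory plus ground truth; `fit` estimates plot effects for one region
#' from a written inventory; `summarize` turns a fitted hyperparameter file
#' into disturbance probabilities and effect correlations; `simulate` runs
#' one stand trajectory; `experiment` runs the mortality-increase
#' experiment. Every stage writes a `<stage>_log.json` with the seed and a
#' hash of the configuration that produced its outputs. Unknown stages or
#' config keys raise errors.
#'
#' @param stage One of `"generate"`, `"fit"`, `"summarize"`, `"simulate"`,
#'   `"experiment"`.
#' @param config Named list; must contain `seed` and `out_dir`, plus
#'   stage-specific keys (see Details in the source).
#' @return The primary output of the stage, invisibly.
#' @export
run_stage <- function(stage, config) {
  stages <- c("generate", "fit", "summarize", "simulate", "experiment")
  if (!is.character(stage) || length(stage) != 1 || !stage %in% stages) {
    stopf("unknown stage '%s'; expected one of %s", paste(stage, collapse = ","),
          paste(stages, collapse = ", "))
  }
  if (is.null(config$out_dir)) stopf("config must set out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (stage == "generate") {
    check_config_keys(config, c("seed", "out_dir", "n_regions", "n_plots",
                                "mean_trees_per_plot"), stage)
    truth <- generate_truth(config$n_regions %||% 3, seed = config$seed)
    inv <- generate_inventory(truth, n_plots = config$n_plots %||% 100,
                              mean_trees_per_plot = config$mean_trees_per_plot %||% 20,
                              seed = config$seed)
    write_inventory(inv, config$out_dir)
    truth_json <- lapply(truth$regions, function(d) {
      list(mu = d$mu, sigma_mat = d$sigma_mat, sigma_growth = d$sigma_growth)
    })
    jsonlite::write_json(truth_json, file.path(config$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_stage_log(stage, config, config$out_dir,
                    c("trees.csv", "plots.csv", "truth_effects.csv", "truth.json"))
    return(invisible(inv))
  }

  if (stage == "fit") {
    check_config_keys(config, c("seed", "out_dir", "in_dir", "region",
                                "n_iter", "burnin", "thin"), stage)
    inv <- apply_plot_filters(read_inventory(
      file.path(config$in_dir, "trees.csv"),
      file.path(config$in_dir, "plots.csv")))
    cfg <- fit_config(n_iter = config$n_iter %||% 1000,
                      burnin = config$burnin %||% 500,
                      thin = config$thin %||% 1, seed = config$seed)
    fit <- fit_region(inv, config$region, cfg)
    utils::write.csv(fit$plot_effects,
                     file.path(config$out_dir, "plot_effects.csv"),
                     row.names = FALSE)
    dist <- as_region_distribution(fit)
    jsonlite::write_json(
      list(region = fit$region, mu = dist$mu, sigma_mat = dist$sigma_mat,
           sigma_growth = dist$sigma_growth,
           converged = fit$diagnostics$converged,
           max_rhat = fit$diagnostics$max_rhat,
           seed = config$seed, config_hash = config_hash(config)),
      file.path(config$out_dir, "hyper.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, matrix = "rowmajor")
    write_stage_log(stage, config, config$out_dir,
                    c("plot_effects.csv", "hyper.json"))
    return(invisible(fit))
  }

  read_hyper <- function(path) {
    h <- jsonlite::read_json(path, simplifyVector = TRUE)
    region_effect_distribution(h$mu, matrix(unlist(h$sigma_mat), 6, 6,
                                            byrow = TRUE),
                               h$sigma_growth)
  }

  if (stage == "summarize") {
    check_config_keys(config, c("seed", "out_dir", "hyper_path",
                                "effects_path", "threshold_fold"), stage)
    dist <- read_hyper(config$hyper_path)
    ds <- disturbance_summary(dist, config$threshold_fold %||% 4)
    utils::write.csv(ds, file.path(config$out_dir, "disturbance_summary.csv"),
                     row.names = FALSE)
    outputs <- "disturbance_summary.csv"
    if (!is.null(config$effects_path)) {
      pe <- utils::read.csv(config$effects_path)
      wide <- stats::reshape(pe[, c("plot_id", "component", "mean")],
                             idvar = "plot_id", timevar = "component",
                             direction = "wide")
      cors <- stats::cor(as.matrix(wide[, -1]))
      utils::write.csv(cors, file.path(config$out_dir, "effect_correlations.csv"))
      outputs <- c(outputs, "effect_correlations.csv")
    }
    write_stage_log(stage, config, config$out_dir, outputs)
    return(invisible(ds))
  }

  if (stage == "simulate") {
    check_config_keys(config, c("seed", "out_dir", "hyper_path", "years",
                                "scenario", "mat", "map"), stage)
    dist <- read_hyper(config$hyper_path)
    params <- default_demography_params()
    proc <- effect_process_from_distribution(dist)
    clim <- climate_conditions(config$mat %||% 9, config$map %||% 1000)
    init <- generate_initial_stand("bare_ground", params, climate = clim)
    tr <- simulate_stand(init, config$years %||% 500,
                         config$scenario %||% "variable", params, proc,
                         seed = config$seed)
    utils::write.csv(tr, file.path(config$out_dir, "trajectory.csv"),
                     row.names = FALSE)
    write_stage_log(stage, config, config$out_dir, "trajectory.csv")
    return(invisible(tr))
  }

  # stage == "experiment"
  check_config_keys(config, c("seed", "out_dir", "hyper_path", "n_stands",
                              "ks", "years", "mat", "map"), stage)
  dist <- read_hyper(config$hyper_path)
  clim <- climate_conditions(config$mat %||% 9, config$map %||% 1000)
  stands <- replicate(config$n_stands %||% 10,
                      list(dist = dist, climate = clim), simplify = FALSE)
  res <- mortality_increase_experiment(
    stands, ks = config$ks %||% c(1, 1.5, 2), seed = config$seed,
    years = config$years %||% 500)
  utils::write.csv(res, file.path(config$out_dir, "experiment.csv"),
                   row.names = FALSE)
  write_stage_log(stage, config, config$out_dir, "experiment.csv")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
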