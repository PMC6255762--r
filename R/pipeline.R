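#' Configure a full study run
#'
#' Bundles every stage's settings: the synthetic landscape and ground-truth
#' parameters (simulate mode) or paths to previously written inputs (ingest
#' mode), the friction speeds, the priors and MCMC schedule, the holdout
#' fraction and the reporting thresholds. Exactly one of the two modes is
#' active: `inputs = NULL` selects simulate mode.
#'
#' @param landscape a [landscape_config()].
#' @param true_params a [true_parameters()] (simulate mode).
#' @param n_clusters number of survey clusters.
#' @param urban_threshold people-per-cell defining urban cells.
#' @param speed_table,road_speed friction settings (see [build_friction()]).
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_config()]; its seed is replaced by a substream of
#'   the master `seed`.
#' @param validation_fraction holdout share in (0, 1).
#' @param thresholds reporting travel times in minutes.
#' @param inputs `NULL`, or a named list of paths written by a previous
#'   simulate run: `children`, `clusters`, `facilities`, `land_class`,
#'   `elevation`, `roads`, `population`, `admin`.
#' @param seed master integer seed; every stage derives its own substream.
#' @return A list of class `run_config`.
#' @export
run_config <- function(landscape = landscape_config(),
                       true_params = true_parameters(),
                       n_clusters = 120, urban_threshold = 100,
                       speed_table = default_speed_table(), road_speed = 60,
                       priors = prior_spec(), mcmc = mcmc_config(),
                       validation_fraction = 0.10,
                       thresholds = c(10, 30, 60, 120),
                       inputs = NULL, seed = 1L) {
  if (!is.null(inputs)) {
    needed <- c("children", "clusters", "facilities", "land_class",
                "elevation", "roads", "population", "admin")
    if (!all(needed %in% names(inputs)))
      stop("ingest mode needs input paths: ",
           paste(setdiff(needed, names(inputs)), collapse = ", "), call. = FALSE)
  }
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(landscape = landscape, true_params = true_params,
                 n_clusters = n_clusters, urban_threshold = urban_threshold,
                 speed_table = speed_table, road_speed = road_speed,
                 priors = priors, mcmc = mcmc,
                 validation_fraction = validation_fraction,
                 thresholds = thresholds, inputs = inputs,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

read_csv_plain <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Run the complete pipeline
#'
#' Executes the stages in order — simulate (or ingest) the survey world,
#' build the friction surface and travel-time raster, extract covariates,
#' split off the holdout set, fit the item-response model, back-calculate
#' treatment curves and maps, validate on the holdout, aggregate by admin
#' unit — writing every artefact into `out_dir` together with a manifest
#' recording the master seed and a hash of the configuration. A failed
#' stage leaves a `FAILED` marker naming the stage and rethrows.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with all in-memory stage results
#'   (`landscape`-style input list, `clusters`, `children`, `split`,
#'   `fit`, `curves`, `threshold_table`, `floor`, `validation`,
#'   `aggregates`, `national_rate`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  artefacts <- character(0)
  add <- function(p) artefacts <<- c(artefacts, basename(p))
  stage <- "start"
  on_fail <- function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    master <- config$seed

    stage <- "simulate"
    if (is.null(config$inputs)) {
      say("simulating landscape and survey ...")
      lc <- config$landscape
      lc$seed <- substream_seed(master, "landscape")
      world <- generate_landscape(lc)
      clusters <- sample_clusters(world$population, config$n_clusters,
                                  config$urban_threshold,
                                  seed = substream_seed(master, "clusters"))
      clusters <- displace_clusters(clusters,
                                    seed = substream_seed(master, "displace"),
                                    extent = world$land_class)
      for (nm in c("land_class", "elevation", "roads", "population", "admin"))
        add(write_ascii_grid(world[[nm]], file.path(out_dir, paste0(nm, ".asc"))))
      add(write_csv_plain(world$facilities, file.path(out_dir, "facilities.csv")))
      add(write_csv_plain(clusters, file.path(out_dir, "clusters.csv")))
    } else {
      say("ingesting inputs ...")
      world <- list(
        land_class = read_ascii_grid(config$inputs$land_class, "land_class"),
        elevation = read_ascii_grid(config$inputs$elevation, "elevation_m"),
        roads = read_ascii_grid(config$inputs$roads, "road_mask"),
        population = read_ascii_grid(config$inputs$population, "u5_population"),
        admin = read_ascii_grid(config$inputs$admin, "admin_unit"),
        facilities = read_csv_plain(config$inputs$facilities),
        class_names = names(config$speed_table))
      clusters <- read_csv_plain(config$inputs$clusters)
    }

    stage <- "traveltime"
    say("computing travel time ...")
    friction <- build_friction(world$land_class, world$roads, world$elevation,
                               config$speed_table, config$road_speed,
                               class_names = world$class_names %||%
                                 names(config$speed_table))
    tt <- cost_distance(friction, world$facilities, tier = "any_public")
    add(write_ascii_grid(friction, file.path(out_dir, "friction.asc")))
    add(write_ascii_grid(tt, file.path(out_dir, "travel_time.asc")))

    stage <- "responses"
    if (is.null(config$inputs)) {
      children <- simulate_responses(clusters, tt, config$true_params,
                                     seed = substream_seed(master, "responses"))
      add(write_csv_plain(children, file.path(out_dir, "children.csv")))
    } else {
      children <- read_csv_plain(config$inputs$children)
    }

    stage <- "covariates"
    # re-extract covariates from the raster so simulate and ingest runs
    # follow an identical path
    cl_tt <- extract_travel_time(tt, clusters$x_pub, clusters$y_pub)
    cov <- tibble::tibble(cluster_id = clusters$cluster_id,
                          travel_time_min = cl_tt,
                          urban = as.integer(clusters$residence == "urban"))
    children <- children |>
      dplyr::select(-dplyr::any_of(c("travel_time_min", "urban"))) |>
      dplyr::left_join(cov, by = "cluster_id")

    stage <- "holdout"
    split <- holdout_split(children, config$validation_fraction,
                           seed = substream_seed(master, "holdout"))

    stage <- "fit"
    say("fitting the item-response model ...")
    mc <- config$mcmc
    mc$seed <- substream_seed(master, "fit")
    fit <- fit_treatment_irt(split$train, config$priors, mc)
    add(write_csv_plain(as_tibble(fit$draws), file.path(out_dir, "posterior_draws.csv")))
    conv <- convergence_report(fit)
    jsonlite::write_json(conv, file.path(out_dir, "convergence.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    add("convergence.json")

    stage <- "summarise"
    say("back-calculating treatment curves ...")
    grid <- seq(0, max(config$thresholds, 240), by = 5)
    curves <- dplyr::bind_rows(
      treatment_curve(fit, grid, "rural"),
      treatment_curve(fit, grid, "urban"))
    thr_tab <- summarize_at_thresholds(
      treatment_curve(fit, grid, "rural"), config$thresholds)
    floor_sum <- threshold_floor(fit)
    urban_raster <- fever_raster(
      (world$population$values >= config$urban_threshold) * 1,
      world$population$cell_size, world$population$xll, world$population$yll,
      layer = "urban")
    p_map <- probability_raster(fit, tt, urban_raster)
    add(write_csv_plain(curves, file.path(out_dir, "treatment_curves.csv")))
    add(write_csv_plain(thr_tab, file.path(out_dir, "threshold_table.csv")))
    add(write_csv_plain(floor_sum, file.path(out_dir, "threshold_floor.csv")))
    add(write_ascii_grid(p_map, file.path(out_dir, "probability_map.asc")))

    stage <- "validate"
    val <- validate_holdout(fit, split$test)
    jsonlite::write_json(list(n_test = val$n_test,
                              misclassification = val$misclassification,
                              cutoff = val$cutoff, auc = val$roc$auc),
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
    add("validation.json")
    add(write_csv_plain(val$roc$points, file.path(out_dir, "roc_points.csv")))

    stage <- "aggregate"
    agg <- admin_rates(children, clusters, world$admin, world$population)
    add(write_csv_plain(agg, file.path(out_dir, "admin_rates.csv")))
    nat <- national_summary(agg)

    stage <- "manifest"
    manifest <- list(seed = master,
                     config_hash = rlang::hash(config),
                     mode = if (is.null(config$inputs)) "simulate" else "ingest",
                     national_rate_per_1000 = nat,
                     artefacts = sort(unique(artefacts)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    invisible(list(world = world, clusters = clusters, children = children,
                   split = split, fit = fit, curves = curves,
                   threshold_table = thr_tab, floor = floor_sum,
                   validation = val, aggregates = agg, national_rate = nat,
                   manifest = manifest))
  }, error = on_fail)
}
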