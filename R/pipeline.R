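#' Build a run configuration
#'
#' Bundles everything an end-to-end screen run needs; fully serialisable to
#' JSON so a run is reproducible from its config plus seed.
#'
#' @param layout A [plate_layout()].
#' @param sim_params A [clone_sim_params()].
#' @param n_days Number of daily imaging rounds.
#' @param wells Well ids to simulate/process.
#' @param statistic,thresholds Passed to [classify_growth()].
#' @param pick_class Growth class to put on the pick-list (default `"low"`).
#' @param seed Integer RNG seed.
#' @param image_dir Optional directory for simulated images (`NULL` keeps
#'   them in memory).
#' @param store Optional CSV count-store path.
#' @param report_path Optional JSON report path.
#' @return An object of class `run_config`.
#' @export
run_config <- function(layout = plate_layout(), sim_params = clone_sim_params(),
                       n_days = 4L, wells = 1L,
                       statistic = "final_count", thresholds = NULL,
                       pick_class = "low", seed = 1L,
                       image_dir = NULL, store = NULL, report_path = NULL) {
  structure(
    list(layout = layout, sim_params = sim_params, n_days = as.integer(n_days),
         wells = as.integer(wells), statistic = statistic,
         thresholds = thresholds, pick_class = pick_class,
         seed = as.integer(seed), image_dir = image_dir, store = store,
         report_path = report_path),
    class = "run_config"
  )
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ser <- config
  ser$layout <- unclass(ser$layout)
  ser$sim_params <- unclass(ser$sim_params)
  jsonlite::write_json(unclass(ser), path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    layout = do.call(plate_layout, raw$layout),
    sim_params = do.call(clone_sim_params, raw$sim_params),
    n_days = raw$n_days, wells = raw$wells,
    statistic = raw$statistic, thresholds = raw$thresholds,
    pick_class = raw$pick_class, seed = raw$seed,
    image_dir = raw$image_dir, store = raw$store,
    report_path = raw$report_path
  )
}

#' Run the arrayed-editing imaging workflow end to end
#'
#' Executes simulate -> count -> join -> fit -> classify -> pick under one
#' seed and returns a structured report: per-stage record counts, the
#' resolved configuration, and the pick-list. Any stage failure aborts with
#' the stage name; artifacts produced by earlier stages (image files, the
#' count store) are retained.
#'
#' @param config A [run_config()].
#' @return An object of class `screen_run`: a list with `config`, `records`,
#'   `fits`, `classified`, `pick_list`, `truth`, and `report`.
#' @examples
#' cfg <- run_config(layout = plate_layout(grid_rows = 3, grid_cols = 3),
#'                   n_days = 3, seed = 7)
#' run <- run_end_to_end(cfg)
#' glance(run)
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  sim <- stage("simulate", generate_plate_timelapse(
    config$layout, config$sim_params, config$n_days,
    wells = config$wells, dir = config$image_dir))
  records <- stage("count", process_plate(
    sim$images, layout = config$layout, store = config$store,
    nucleus_radius_px = config$sim_params$nucleus_radius_px))
  series <- stage("join", join_timepoints(records))
  fits <- stage("fit", fit_growth(series))
  seeded <- sum(dplyr::filter(sim$truth, .data$day == 1L)$true_count > 0L)
  classified <- if (seeded == 0L) {
    dplyr::mutate(fits, statistic_value = NA_real_,
                  growth_class = factor(
                    rep(NA_character_, nrow(fits)),
                    levels = c("low", "intermediate", "high"), ordered = TRUE))
  } else {
    stage("classify", classify_growth(fits, statistic = config$statistic,
                                      thresholds = config$thresholds))
  }
  pick <- if (seeded == 0L) {
    tibble(well = integer(), grid_row = integer(), grid_col = integer())
  } else {
    stage("pick", pick_features(classified, class = config$pick_class))
  }

  report <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("gridedit")),
    n_images = nrow(sim$images),
    n_records = nrow(records),
    n_features = nrow(series),
    n_seeded_features = seeded,
    class_counts = as.list(table(classified$growth_class)),
    n_picked = nrow(pick)
  )
  if (seeded == 0L) report$note <- "zero seeded features"
  if (!is.null(config$report_path)) {
    jsonlite::write_json(report, config$report_path, auto_unbox = TRUE,
                         digits = NA)
  }
  structure(
    list(config = config, records = records, fits = fits,
         classified = classified, pick_list = pick, truth = sim$truth,
         report = report),
    class = "screen_run"
  )
}

#' @export
print.screen_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<screen_run> %d images -> %d records, %d features (%d seeded), %d picked\n",
    r$n_images, r$n_records, r$n_features, r$n_seeded_features, r$n_picked))
  invisible(x)
}

#' @rdname run_end_to_end
#' @param x A `screen_run`.
#' @param ... Unused.
#' @export
glance.screen_run <- function(x, ...) {
  r <- x$report
  tibble(
    n_images = r$n_images, n_records = r$n_records,
    n_features = r$n_features, n_seeded_features = r$n_seeded_features,
    n_low = r$class_counts$low %||% 0L,
    n_intermediate = r$class_counts$intermediate %||% 0L,
    n_high = r$class_counts$high %||% 0L,
    n_picked = r$n_picked, seed = r$seed
  )
}

#' @rdname run_end_to_end
#' @export
tidy.screen_run <- function(x, ...) {
  x$classified |>
    dplyr::select("well", "grid_row", "grid_col", "rate", "doubling_time",
                  "r_squared", "statistic_value", "growth_class")
}
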