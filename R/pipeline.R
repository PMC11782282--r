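#' Read a pipeline configuration
#'
#' One YAML (or JSON) file drives the end-to-end run. Every analysis
#' parameter is surfaced with its conventional default (0.1 deg
#' dispersion, 100 ms minimum fixation, 30 deg/s and 8000 deg/s^2 saccade
#' thresholds, 20% out-of-image margin, 3 cpd spectrum threshold): they
#' are defaults, not constants.
#'
#' Expected keys: `geometry` (width_px, height_px, width_cm, height_cm,
#' distance_cm), `sample_rate_hz`, optional `detection` (any
#' [detection_params()] field), optional `scoring` (`margin_frac`,
#' `denoise`), `participants_csv` (columns
#' `participant_id,group_label,gaze_csv,trials_csv`), `maps_manifest_csv`,
#' optional `scores_csv` and `feature_item_map_csv`, `output_dir`, `seed`.
#' Relative paths are resolved against the config file's directory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg$.base_dir <- normalizePath(dirname(path))
  as_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg A named list with the keys above (paths resolved against
#'   `cfg$.base_dir` if present, else the working directory).
#' @export
as_pipeline_config <- function(cfg) {
  g <- cfg$geometry
  if (is.null(g)) stop("config must contain a `geometry` block", call. = FALSE)
  cfg$geometry <- screen_geometry(g$width_px, g$height_px, g$width_cm,
                                  g$height_cm, g$distance_cm)
  cfg$sample_rate_hz <- cfg$sample_rate_hz %||% 500
  det <- cfg$detection %||% list()
  cfg$detection <- do.call(detection_params, det)
  sc <- cfg$scoring %||% list()
  cfg$scoring <- list(margin_frac = sc$margin_frac %||% 0.20,
                      denoise = isTRUE(sc$denoise %||% TRUE))
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "pipeline_config")
}

resolve_path <- function(p, cfg) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) return(p)
  if (!is.null(cfg$.base_dir)) file.path(cfg$.base_dir, p) else p
}

#' Run the full analysis pipeline
#'
#' Executes the stage order maps -> fixation detection -> fixation
#' saliency values -> group comparisons (-> item correlations), writing
#' per-stage CSV artifacts and a JSON run manifest (parameters, seed,
#' per-stage row counts) into the configured output directory. Reruns with
#' the same config and inputs are byte-identical. A stage failure aborts
#' with the stage name; artifacts written so far are retained alongside a
#' `FAILED` marker file.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]) or a
#'   named list accepted by [as_pipeline_config()].
#' @return Invisibly, a list with `events`, `records`, `summaries`,
#'   `comparisons`, `correlations` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- as_pipeline_config(config)
  out_dir <- config$output_dir %||% "gazesal_results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  counts <- list()
  fail_marker <- file.path(out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)

  result <- tryCatch({
    stage <- "maps"
    manifest <- read_map_manifest(resolve_path(config$maps_manifest_csv, config))
    counts$maps <- nrow(manifest)

    stage <- "participants"
    parts <- readr::read_csv(resolve_path(config$participants_csv, config),
                             show_col_types = FALSE, progress = FALSE)
    need <- c("participant_id", "group_label", "gaze_csv", "trials_csv")
    miss <- setdiff(need, names(parts))
    if (length(miss)) stop("participants CSV missing column(s): ",
                           paste(miss, collapse = ", "))
    counts$participants <- nrow(parts)

    stage <- "detect"
    recs <- purrr::pmap(parts[need], function(participant_id, group_label,
                                              gaze_csv, trials_csv) {
      trials <- read_trials_csv(resolve_path(trials_csv, config))
      read_gaze_csv(resolve_path(gaze_csv, config), config$geometry,
                    config$sample_rate_hz, trials = trials,
                    participant_id = participant_id, group_label = group_label)
    })
    scored <- score_cohort(recs, manifest, config$detection,
                           margin_frac = config$scoring$margin_frac,
                           denoise = config$scoring$denoise)
    ev_dir <- file.path(out_dir, "events")
    dir.create(ev_dir, showWarnings = FALSE)
    purrr::walk2(scored$events, parts$participant_id, function(ev, id) {
      write_events_csv(ev, file.path(ev_dir, paste0(id, "_events.csv")))
    })
    counts$events <- sum(vapply(scored$events, nrow, integer(1)))

    stage <- "score"
    write_scores_csv(scored, out_dir)
    counts$records <- nrow(scored$records)
    counts$summaries <- nrow(scored$summaries)

    stage <- "compare"
    comparisons <- NULL
    if (dplyr::n_distinct(scored$summaries$group_label) == 2L) {
      comparisons <- compare_groups(scored$summaries)
      readr::write_csv(comparisons, file.path(out_dir, "group_comparisons.csv"),
                       progress = FALSE)
      counts$comparisons <- nrow(comparisons)
    }

    stage <- "correlate"
    correlations <- NULL
    scores_path <- resolve_path(config$scores_csv, config)
    if (!is.null(scores_path)) {
      cr <- readr::read_csv(scores_path, show_col_types = FALSE, progress = FALSE)
      mapping <- if (!is.null(config$feature_item_map_csv)) {
        readr::read_csv(resolve_path(config$feature_item_map_csv, config),
                        show_col_types = FALSE, progress = FALSE)
      } else {
        default_feature_item_map()
      }
      correlations <- correlate_items(scored$summaries, cr, mapping)
      readr::write_csv(correlations, file.path(out_dir, "item_correlations.csv"),
                       progress = FALSE)
      counts$correlations <- nrow(correlations)
    }

    stage <- "manifest"
    run_manifest <- list(
      package_version = as.character(utils::packageVersion("gazesal")),
      seed = config$seed,
      geometry = unclass(config$geometry),
      detection = unclass(config$detection),
      scoring = config$scoring,
      row_counts = counts)
    jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    list(events = scored$events, records = scored$records,
         summaries = scored$summaries, comparisons = comparisons,
         correlations = correlations, manifest = run_manifest)
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               fail_marker)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
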