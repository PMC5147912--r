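#' Default run configuration
#'
#' Every numeric constant the pipeline uses lives here: the N/C
#' classification threshold (1.8), the hit-calling threshold (60\% of the
#' positive control), the positive-control identity (4 nM LMB), the
#' segmentation and ring-mask parameters, the minimum cell count per
#' well, the dose-response fit options, and the simulator settings.
#'
#' @param ... named overrides merged into the defaults (nested lists are
#'   merged recursively); unknown keys are rejected.
#' @return a validated configuration list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    threshold = 1.8,
    hit_threshold = 60,
    positive_control = list(compound = "LMB", conc = 4, conc_unit = "nM"),
    segmentation = list(block_size = 51, offset = NULL,
                        min_area = 40, max_area = 1200),
    ring = list(gap = 1, width = 4),
    min_cells = 50,
    intensity_stat = "mean",
    zprime_variant = "zhang",
    fit = list(direction = "increasing", hill_range = c(0.2, 10)),
    simulate = list(n_cells = 100, image_shape = c(360, 360),
                    background_level = 200, read_noise_sd = 30,
                    shot_noise = TRUE,
                    state_meanlog_resting = 0,
                    state_meanlog_translocated = log(3),
                    state_sdlog = 0.2,
                    model_bottom = 0.05, model_top = 0.90,
                    model_ec50_uM = 1.5, model_hill = 1)
  )
  over <- list(...)
  if (length(over) > 0) cfg <- .merge_config(cfg, over, path = "")
  structure(cfg, class = "run_config")
}

# recursive merge that rejects keys absent from the defaults
.merge_config <- function(base, over, path) {
  if (is.null(names(over)) || any(names(over) == "")) {
    stop("config overrides must be named (at '", path, "')")
  }
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (k in names(over)) {
    if (is.list(base[[k]]) && is.list(over[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- .merge_config(base[[k]], over[[k]], paste0(path, ".", k))
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' Build simulator objects from a run configuration
#'
#' @param config a `run_config`.
#' @return list with `spec` ([well_spec()] template), `states`
#'   ([state_distributions()]) and `model` ([dose_model()]).
#' @export
config_simulator <- function(config) {
  s <- config$simulate
  list(
    spec = well_spec(n_cells = s$n_cells, image_shape = s$image_shape,
                     noise = noise_spec(s$background_level, s$read_noise_sd,
                                        s$shot_noise),
                     seed = config$seed),
    states = state_distributions(s$state_meanlog_resting,
                                 s$state_meanlog_translocated,
                                 s$state_sdlog),
    model = dose_model(s$model_bottom, s$model_top, s$model_ec50_uM,
                       s$model_hill)
  )
}

#' Write the resolved configuration as JSON next to the run outputs
#'
#' @param config a `run_config`.
#' @param path output JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
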