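#' Analyze a plate of two-channel images
#'
#' Runs segmentation and quantification on every well, aggregates well
#' summaries, computes control statistics and Z', normalizes compound
#' activities, calls hits, and fits dose-response curves for every
#' compound with at least five distinct concentrations on the plate.
#'
#' @param images named list of `list(dapi, gfp)` matrices (one per well).
#' @param layout plate layout data frame.
#' @param config a `run_config` from [default_config()].
#' @param plate plate id used in messages and outputs.
#' @return list of class `hcs_plate_result`: `cells` (per-cell records
#'   across wells), `wells` (per-well summaries), `controls`, `zprime`,
#'   `activities`, `hits`, `fits` (named list of `hcs_4pl`, possibly
#'   empty), `log` (character).
#' @export
analyze_plate <- function(images, layout, config = default_config(),
                          plate = "plate") {
  log_lines <- character(0)
  cells_list <- list()
  wells_list <- list()
  for (wname in names(images)) {
    cells <- analyze_field(images[[wname]]$dapi, images[[wname]]$gfp, config)
    excl <- attr(cells, "excluded")
    if (!is.null(excl) && nrow(excl) > 0) {
      log_lines <- c(log_lines, sprintf("%s %s: excluded cell %d (%s)",
                                        plate, wname, excl$label, excl$reason))
    }
    ws <- summarize_well(cells, well = wname, min_cells = config$min_cells)
    if (nzchar(ws$qc_flags)) {
      log_lines <- c(log_lines, sprintf("%s %s: qc flag %s", plate, wname,
                                        ws$qc_flags))
    }
    if (nrow(cells) > 0) cells_list[[wname]] <- cbind(well = wname, cells)
    wells_list[[wname]] <- ws
  }
  cells <- if (length(cells_list) > 0) {
    do.call(rbind, c(cells_list, make.row.names = FALSE))
  } else {
    data.frame(well = character(0))
  }
  wells <- do.call(rbind, c(wells_list, make.row.names = FALSE))

  m <- merge(layout, wells, by = "well")
  controls <- control_stats(m$pct_translocated[m$role == "positive"],
                            m$pct_translocated[m$role == "negative"])
  zp <- if (controls$n_pos >= 2 && controls$n_neg >= 2) {
    zprime(controls, variant = config$zprime_variant)
  } else {
    NA_real_
  }

  cw <- m[m$role == "compound" & is.finite(m$pct_translocated), , drop = FALSE]
  activities <- data.frame(well = cw$well, compound = cw$compound,
                           conc = cw$conc, conc_unit = cw$conc_unit,
                           pct_translocated = cw$pct_translocated,
                           activity_pct = normalize_activity(
                             cw$pct_translocated, controls, plate = plate),
                           stringsAsFactors = FALSE)
  hits <- call_hits(activities[, c("well", "compound", "activity_pct")],
                    hit_threshold = config$hit_threshold)

  fits <- list()
  for (cmp in unique(activities$compound)) {
    d <- activities[activities$compound == cmp, , drop = FALSE]
    if (length(unique(d$conc[!is.na(d$conc)])) >= 5) {
      fits[[cmp]] <- fit_4pl(conc_to_uM(d$conc, d$conc_unit), d$activity_pct,
                             direction = config$fit$direction,
                             hill_range = config$fit$hill_range)
    }
  }
  structure(list(cells = cells, wells = wells, controls = controls,
                 zprime = zp, activities = activities, hits = hits,
                 fits = fits, log = log_lines),
            class = "hcs_plate_result")
}

#' Run the full simulate-or-read analysis pipeline and write artifacts
#'
#' Either renders a synthetic plate from the configuration's simulator
#' settings (`simulate = TRUE`) or reads TIFF pairs from `image_dir`,
#' then analyzes the plate and writes all artifacts to `out_dir`:
#' `cells.csv`, `wells.csv`, `hits.csv`, `qc.json`, `fits.json`,
#' `config.json` (the resolved configuration) and `log.txt`.  The run is
#' deterministic given the configuration and seed.
#'
#' @param config a `run_config`.
#' @param out_dir artifact directory (created).
#' @param layout plate layout data frame (required when simulating).
#' @param image_dir directory of TIFF pairs; when `NULL` the plate is
#'   simulated.
#' @param write_images also write the simulated TIFF pairs under
#'   `out_dir/images`?
#' @return invisibly, the `hcs_plate_result` (with `layout` attached).
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         layout = NULL, image_dir = NULL,
                         write_images = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  if (is.null(image_dir)) {
    if (is.null(layout)) stop("simulation requires a plate layout")
    sim <- config_simulator(config)
    plate <- render_plate(layout, sim$model, sim$spec, seed = config$seed,
                          states = sim$states)
    images <- lapply(plate$wells, function(f) list(dapi = f$dapi, gfp = f$gfp))
    if (write_images) write_plate_images(plate, file.path(out_dir, "images"))
    log_lines <- c(log_lines, sprintf("simulated %d wells (seed %d)",
                                      length(images), config$seed))
  } else {
    if (is.null(layout)) layout <- read_plate_map(file.path(image_dir, "layout.csv"))
    rd <- read_well_images(image_dir, layout)
    images <- rd$images
    if (nrow(rd$flags) > 0) {
      log_lines <- c(log_lines, sprintf("%s: %s", rd$flags$well, rd$flags$flag))
    }
  }

  res <- analyze_plate(images, layout, config)
  res$log <- c(log_lines, res$log)
  attr(res, "layout") <- layout

  write.csv(res$cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  write.csv(res$wells, file.path(out_dir, "wells.csv"), row.names = FALSE)
  write.csv(res$hits, file.path(out_dir, "hits.csv"), row.names = FALSE)
  qc <- list(zprime = res$zprime,
             controls = unclass(res$controls),
             n_wells = nrow(res$wells),
             flagged_wells = res$wells$well[nzchar(res$wells$qc_flags)])
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  fits_out <- lapply(res$fits, function(f) {
    f[c("bottom", "top", "midpoint", "hill", "rss", "converged", "reason",
        "absolute_midpoint", "direction")]
  })
  jsonlite::write_json(fits_out, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write_config(config, file.path(out_dir, "config.json"))
  writeLines(res$log, file.path(out_dir, "log.txt"))
  invisible(res)
}
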