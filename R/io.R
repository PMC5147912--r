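# Images are stored as 16-bit grayscale TIFF with intensities in
# 16-bit counts; the tiff package works on the [0,1] scale, so values are
# divided by 65535 on write and multiplied back on read.

#' Write a rendered field's channel images as 16-bit TIFF pair
#'
#' Files are named `<well>_dapi.tif` and `<well>_gfp.tif`.
#'
#' @param field an `hcs_field` from [render_well()].
#' @param dir output directory (created if needed).
#' @param well well id used in the file names.
#' @return invisibly, the two file paths.
#' @export
write_field_images <- function(field, dir, well) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(well, c("_dapi.tif", "_gfp.tif")))
  tiff::writeTIFF(pmin(field$dapi, 65535) / 65535, paths[1], bits.per.sample = 16)
  tiff::writeTIFF(pmin(field$gfp, 65535) / 65535, paths[2], bits.per.sample = 16)
  invisible(paths)
}

#' Write all images of a rendered plate plus ground truth and layout
#'
#' Alongside the per-well TIFF pairs, writes `ground_truth.csv` (one row
#' per planted cell) and `layout.csv` (plate map dialect
#' `well,role,compound,conc,conc_unit`).
#'
#' @param plate an `hcs_plate` from [render_plate()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_plate_images <- function(plate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (wname in names(plate$wells)) {
    write_field_images(plate$wells[[wname]], dir, wname)
  }
  write.csv(plate$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  write_plate_map(plate$layout, file.path(dir, "layout.csv"))
  invisible(dir)
}

#' Read per-well DAPI/GFP image pairs from a directory
#'
#' Expects `<well>_dapi.tif` and `<well>_gfp.tif` for every non-empty,
#' non-blank well of the layout.  Wells with missing files are skipped
#' and flagged (the run continues); a shape mismatch between the two
#' channels of a well is an error naming that well.  8- and 16-bit
#' inputs are both converted to numeric matrices on the 16-bit count
#' scale; per-well ratios are invariant to that per-well scaling.
#'
#' @param dir directory holding the TIFF pairs.
#' @param layout plate layout data frame.
#' @return list with `images` (named list of `list(dapi, gfp)`) and
#'   `flags` (data frame well/flag for wells with missing files).
#' @export
read_well_images <- function(dir, layout) {
  active <- layout[!layout$role %in% c("empty", "blank"), , drop = FALSE]
  images <- list()
  flags <- data.frame(well = character(0), flag = character(0))
  for (wname in active$well) {
    fd <- file.path(dir, paste0(wname, "_dapi.tif"))
    fg <- file.path(dir, paste0(wname, "_gfp.tif"))
    missing <- c("missing_dapi"[!file.exists(fd)], "missing_gfp"[!file.exists(fg)])
    if (length(missing) > 0) {
      flags <- rbind(flags, data.frame(well = wname,
                                       flag = paste(missing, collapse = ";")))
      next
    }
    dapi <- tiff::readTIFF(fd) * 65535
    gfp <- tiff::readTIFF(fg) * 65535
    if (!all(dim(dapi) == dim(gfp))) {
      stop("well ", wname, ": DAPI shape ", paste(dim(dapi), collapse = "x"),
           " does not match GFP shape ", paste(dim(gfp), collapse = "x"))
    }
    images[[wname]] <- list(dapi = dapi, gfp = gfp)
  }
  list(images = images, flags = flags)
}
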