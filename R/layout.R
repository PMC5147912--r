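#' Construct a plate layout table
#'
#' A layout is a plain data frame with one row per well and columns
#' `well`, `row`, `col`, `role`, `compound`, `conc`, `conc_unit`.  Roles
#' are `negative`, `positive`, `compound`, `blank` or `empty`;
#' concentrations are carried only on compound wells.
#'
#' @param rows,cols plate dimensions (default 96-well, 8 x 12).
#' @return an all-`empty` layout to be filled by the helpers below.
#' @export
plate_layout <- function(rows = 8, cols = 12) {
  wells <- well_names(rows, cols)
  data.frame(well = wells,
             row = rep(seq_len(rows), each = cols),
             col = rep(seq_len(cols), times = rows),
             role = "empty", compound = NA_character_,
             conc = NA_real_, conc_unit = NA_character_,
             stringsAsFactors = FALSE)
}

#' Single-dose screening plate layout
#'
#' Mirrors the conventional screening plate design: controls occupy the
#' first and last columns (negatives = vehicle in column 1, positives =
#' the reference export inhibitor in the last column), and each interior
#' well carries one compound at a fixed screening concentration.
#'
#' @param compounds character vector of compound ids (at most
#'   `rows * (cols - 2)`).
#' @param conc,conc_unit screening concentration (default 10 uM).
#' @param rows,cols plate dimensions.
#' @return a layout data frame.
#' @export
layout_screen_plate <- function(compounds, conc = 10, conc_unit = "uM",
                                rows = 8, cols = 12) {
  lay <- plate_layout(rows, cols)
  lay$role[lay$col == 1] <- "negative"
  lay$role[lay$col == cols] <- "positive"
  interior <- which(lay$col > 1 & lay$col < cols)
  if (length(compounds) > length(interior)) {
    stop("too many compounds (", length(compounds), ") for ",
         length(interior), " interior wells")
  }
  sel <- interior[seq_along(compounds)]
  lay$role[sel] <- "compound"
  lay$compound[sel] <- compounds
  lay$conc[sel] <- conc
  lay$conc_unit[sel] <- conc_unit
  lay
}

#' Dose-response plate layout for one compound
#'
#' Places a serial-dilution series in the interior wells (row-major,
#' `replicates` consecutive wells per concentration) with negative
#' controls in column 1 and positive controls in the last column.
#'
#' @param compound compound id.
#' @param series a [dilution_series()].
#' @param replicates wells per concentration.
#' @param rows,cols plate dimensions.
#' @return a layout data frame.
#' @export
layout_dose_plate <- function(compound, series, replicates = 1,
                              rows = 8, cols = 12) {
  stopifnot(inherits(series, "dilution_series"))
  lay <- plate_layout(rows, cols)
  lay$role[lay$col == 1] <- "negative"
  lay$role[lay$col == cols] <- "positive"
  interior <- which(lay$col > 1 & lay$col < cols)
  need <- length(series$concentrations) * replicates
  if (need > length(interior)) stop("series does not fit on the plate")
  sel <- interior[seq_len(need)]
  lay$role[sel] <- "compound"
  lay$compound[sel] <- compound
  lay$conc[sel] <- rep(series$concentrations, each = replicates)
  lay$conc_unit[sel] <- series$unit
  lay
}

#' Read / write a plate map CSV
#'
#' Interchange dialect: header `well,role,compound,conc,conc_unit`, wells
#' named "A01".."H12".
#'
#' @param path CSV file path.
#' @return `read_plate_map` returns a layout data frame.
#' @export
read_plate_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "role", "compound", "conc", "conc_unit")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("plate map ", path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$row <- match(substr(df$well, 1, 1), LETTERS)
  df$col <- as.integer(substr(df$well, 2, 3))
  df[, c("well", "row", "col", "role", "compound", "conc", "conc_unit")]
}

#' @rdname read_plate_map
#' @param layout a layout data frame.
#' @export
write_plate_map <- function(layout, path) {
  write.csv(layout[, c("well", "role", "compound", "conc", "conc_unit")],
            path, row.names = FALSE, na = "")
  invisible(path)
}
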