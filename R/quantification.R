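#' Classify nuclear accumulation from an N/C ratio
#'
#' A cell is called translocated when its nuclear/cytoplasmic mean GFP
#' ratio strictly exceeds the threshold (default 1.8); a ratio exactly at
#' the threshold is not translocated.
#'
#' @param ratio numeric N/C ratio(s), >= 0.
#' @param threshold classification cutoff.
#' @return logical vector.
#' @export
classify_translocated <- function(ratio, threshold = 1.8) {
  stopifnot(all(ratio >= 0, na.rm = TRUE))
  ratio > threshold
}

#' Measure per-cell compartment GFP and N/C ratios
#'
#' For every nucleus with a retained cytoplasmic ring, computes the mean
#' (or integrated) GFP over the nucleus mask and over the ring mask, the
#' nucleocytoplasmic ratio, the nuclear-vertex count, and the
#' translocation call.  Cells whose cytoplasmic signal is zero are
#' excluded with a recorded reason rather than producing a division error.
#'
#' @param gfp GFP channel matrix, same shape as the masks.
#' @param nuclei a `label_mask` from [segment_nuclei()].
#' @param rings a `ring_mask_set` from [make_cytoplasm_rings()].
#' @param threshold N/C ratio cutoff for the translocation call.
#' @param intensity_stat `"mean"` (per-pixel mean, area-fair default) or
#'   `"integrated"` (summed intensity per compartment).
#' @return data frame with one row per retained cell: `label`, `nuc_area`,
#'   `ring_area`, `nuc_mean_gfp`, `cyt_mean_gfp`, `nc_ratio`,
#'   `nuclear_vertices`, `translocated`.  Excluded cells are listed in
#'   attribute `excluded` (label + reason).
#' @export
measure_cells <- function(gfp, nuclei, rings, threshold = 1.8,
                          intensity_stat = c("mean", "integrated")) {
  intensity_stat <- match.arg(intensity_stat)
  stopifnot(is.matrix(gfp), all(dim(gfp) == dim(nuclei)),
            inherits(rings, "ring_mask_set"),
            all(dim(rings$rings) == dim(nuclei)))
  K <- max(nuclei)
  excluded <- data.frame(label = integer(0), reason = character(0))
  if (length(rings$dropped) > 0) {
    excluded <- rbind(excluded, data.frame(label = rings$dropped,
                                           reason = "empty_ring"))
  }
  labs <- rings$labels
  if (length(labs) == 0) {
    out <- data.frame(label = integer(0), nuc_area = integer(0),
                      ring_area = integer(0), nuc_mean_gfp = numeric(0),
                      cyt_mean_gfp = numeric(0), nc_ratio = numeric(0),
                      nuclear_vertices = integer(0), translocated = logical(0))
    attr(out, "excluded") <- excluded
    return(out)
  }
  nuc_sum <- tapply(gfp[nuclei > 0], nuclei[nuclei > 0], sum)
  nuc_n <- tabulate(nuclei, nbins = K)
  ring_sum <- tapply(gfp[rings$rings > 0], rings$rings[rings$rings > 0], sum)
  ring_n <- tabulate(rings$rings, nbins = K)
  verts <- count_nuclear_vertices(nuclei)

  nuc_stat <- unname(nuc_sum[as.character(labs)])
  cyt_stat <- unname(ring_sum[as.character(labs)])
  if (intensity_stat == "mean") {
    nuc_stat <- nuc_stat / nuc_n[labs]
    cyt_stat <- cyt_stat / ring_n[labs]
  }
  zero <- cyt_stat <= 0
  if (any(zero)) {
    excluded <- rbind(excluded, data.frame(label = labs[zero],
                                           reason = "zero_cytoplasmic_signal"))
  }
  keep <- !zero
  ratio <- nuc_stat[keep] / cyt_stat[keep]
  out <- data.frame(label = labs[keep],
                    nuc_area = nuc_n[labs][keep],
                    ring_area = ring_n[labs][keep],
                    nuc_mean_gfp = nuc_stat[keep],
                    cyt_mean_gfp = cyt_stat[keep],
                    nc_ratio = ratio,
                    nuclear_vertices = as.integer(verts[as.character(labs[keep])]),
                    translocated = classify_translocated(ratio, threshold))
  attr(out, "excluded") <- excluded[order(excluded$label), , drop = FALSE]
  out
}

#' Aggregate per-cell records to a well summary
#'
#' @param cells data frame of per-cell records (from [measure_cells()]),
#'   with columns `translocated` and `nuclear_vertices`.
#' @param well well id.
#' @param min_cells wells with fewer cells are flagged `low_count`.
#' @return one-row data frame: `well`, `n_cells`, `pct_translocated`
#'   (NA for empty wells), `mean_vertices`, `qc_flags`
#'   (semicolon-separated, "" when clean).
#' @export
summarize_well <- function(cells, well = NA_character_, min_cells = 50) {
  n <- nrow(cells)
  flags <- character(0)
  if (n == 0) {
    flags <- c(flags, "empty")
    pct <- NA_real_; mv <- NA_real_
  } else {
    pct <- 100 * sum(cells$translocated) / n
    mv <- mean(cells$nuclear_vertices)
    if (n < min_cells) flags <- c(flags, "low_count")
  }
  data.frame(well = well, n_cells = n, pct_translocated = pct,
             mean_vertices = mv, qc_flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Run segmentation and quantification on one two-channel field
#'
#' Convenience wrapper: segments nuclei on the DAPI channel, builds ring
#' masks, and measures per-cell GFP ratios.
#'
#' @param dapi,gfp channel matrices of equal shape.
#' @param config a run configuration (see [default_config()]).
#' @return the per-cell data frame of [measure_cells()].
#' @export
analyze_field <- function(dapi, gfp, config = default_config()) {
  seg <- config$segmentation
  nuclei <- segment_nuclei(dapi, block_size = seg$block_size,
                           offset = seg$offset,
                           min_area = seg$min_area, max_area = seg$max_area)
  rings <- make_cytoplasm_rings(nuclei, ring_gap = config$ring$gap,
                                ring_width = config$ring$width)
  measure_cells(gfp, nuclei, rings, threshold = config$threshold,
                intensity_stat = config$intensity_stat)
}
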