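#' Camera noise model for the synthetic plate simulator
#'
#' Standard fluorescence camera model: Poisson shot noise on the expected
#' signal, then additive Gaussian read noise, then clipping at zero and
#' quantization to 16-bit counts.
#'
#' @param background_level constant background, 16-bit counts (a.u.).
#' @param read_noise_sd standard deviation of additive Gaussian read noise.
#' @param shot_noise apply Poisson shot noise to the expected intensity?
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(background_level = 200, read_noise_sd = 30, shot_noise = TRUE) {
  stopifnot(background_level >= 0, read_noise_sd >= 0)
  structure(list(background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise)),
            class = "noise_spec")
}

#' Per-state N/C ratio distributions for simulated cells
#'
#' Cells are in one of two states: "resting" (reporter mostly cytoplasmic)
#' or "translocated" (reporter accumulated in the nucleus).  Within each
#' state the true per-cell N/C ratio is drawn log-normally.  Defaults put
#' the resting median at 1.0 and the translocated median at 3.0 with
#' sdlog 0.2, straddling the 1.8 classification cutoff with realistic
#' within-population overlap.
#'
#' @param meanlog_resting,meanlog_translocated log-scale medians.
#' @param sdlog log-scale standard deviation (shared by both states).
#' @return an object of class `state_distributions`.
#' @export
state_distributions <- function(meanlog_resting = log(1.0),
                                meanlog_translocated = log(3.0),
                                sdlog = 0.2) {
  stopifnot(sdlog >= 0, meanlog_translocated > meanlog_resting)
  structure(list(meanlog_resting = meanlog_resting,
                 meanlog_translocated = meanlog_translocated,
                 sdlog = sdlog),
            class = "state_distributions")
}

#' Specification of one simulated field of cells
#'
#' @param n_cells number of cells to place (>= 0).
#' @param image_shape `c(height, width)` in pixels.
#' @param translocation_fraction probability that a cell is in the
#'   translocated state.
#' @param noise a [noise_spec()].
#' @param seed integer seed; identical spec + seed gives bit-identical images.
#' @param nucleus_axes_range range of nucleus semi-axes in pixels (>= 3).
#' @param cyto_thickness thickness of the rendered cytoplasmic annulus (px).
#' @param dapi_level mean nuclear DAPI intensity (a.u.).
#' @param gfp_total_meanlog,gfp_total_sdlog log-normal parameters of the
#'   per-cell total GFP signal (summed over nucleus + cytoplasm pixels).
#' @return an object of class `well_spec`.
#' @export
well_spec <- function(n_cells = 100,
                      image_shape = c(360, 360),
                      translocation_fraction = 0.05,
                      noise = noise_spec(),
                      seed = 1L,
                      nucleus_axes_range = c(5, 9),
                      cyto_thickness = 6,
                      dapi_level = 3000,
                      gfp_total_meanlog = log(3.2e5),
                      gfp_total_sdlog = 0.15) {
  stopifnot(n_cells >= 0,
            length(image_shape) == 2, all(image_shape >= 16),
            translocation_fraction >= 0, translocation_fraction <= 1,
            inherits(noise, "noise_spec"),
            length(nucleus_axes_range) == 2, nucleus_axes_range[1] >= 3,
            nucleus_axes_range[2] >= nucleus_axes_range[1],
            cyto_thickness >= 1, dapi_level > 0)
  structure(list(n_cells = as.integer(n_cells),
                 image_shape = as.integer(image_shape),
                 translocation_fraction = translocation_fraction,
                 noise = noise, seed = as.integer(seed),
                 nucleus_axes_range = nucleus_axes_range,
                 cyto_thickness = cyto_thickness,
                 dapi_level = dapi_level,
                 gfp_total_meanlog = gfp_total_meanlog,
                 gfp_total_sdlog = gfp_total_sdlog),
            class = "well_spec")
}

#' Dose-dependent translocation model (generative four-parameter logistic)
#'
#' Describes how the fraction of translocated cells in a well depends on
#' compound concentration: a 4PL rising from `bottom` (vehicle) to `top`
#' (full response) with midpoint `ec50_uM` and Hill slope `hill`.
#' Positive-control wells are simulated at `top`, negative controls at
#' `bottom`.
#'
#' @param bottom,top translocated fractions in [0, 1], `bottom < top`.
#' @param ec50_uM midpoint concentration in micromolar.
#' @param hill Hill slope (> 0).
#' @return an object of class `dose_model`.
#' @export
dose_model <- function(bottom = 0.05, top = 0.90, ec50_uM = 1.5, hill = 1) {
  stopifnot(bottom >= 0, top <= 1, bottom < top, ec50_uM > 0, hill > 0)
  structure(list(bottom = bottom, top = top, ec50_uM = ec50_uM, hill = hill),
            class = "dose_model")
}

#' Translocated fraction predicted at a concentration
#'
#' Evaluates `bottom + (top - bottom) / (1 + (ec50/conc)^hill)`; at
#' concentration zero the limit `bottom` is returned.
#'
#' @param model a [dose_model()].
#' @param conc_uM concentration(s) in micromolar, >= 0.
#' @return translocated fraction(s) in [0, 1].
#' @export
translocation_fraction_at <- function(model, conc_uM) {
  stopifnot(inherits(model, "dose_model"), all(conc_uM >= 0))
  out <- ifelse(conc_uM == 0,
                model$bottom,
                model$bottom + (model$top - model$bottom) /
                  (1 + (model$ec50_uM / conc_uM)^model$hill))
  unname(out)
}

# Rasterize one elliptical nucleus and its cytoplasmic annulus on a local
# crop; returns linear pixel indices into the full image.
.rasterize_cell <- function(center, axes, theta, shape, cyto_thickness) {
  r_out <- ceiling(max(axes) + cyto_thickness) + 1L
  rows <- max(1L, floor(center[1]) - r_out):min(shape[1], ceiling(center[1]) + r_out)
  cols <- max(1L, floor(center[2]) - r_out):min(shape[2], ceiling(center[2]) + r_out)
  dy <- rep(rows - center[1], times = length(cols))
  dx <- rep(cols - center[2], each = length(rows))
  u <- (dx * cos(theta) + dy * sin(theta)) / axes[1]
  v <- (-dx * sin(theta) + dy * cos(theta)) / axes[2]
  nuc_local <- (u * u + v * v) <= 1
  # cytoplasm = points within euclidean distance cyto_thickness of the
  # nucleus pixel set (exact distance map on the local crop)
  m <- matrix(as.numeric(nuc_local), nrow = length(rows))
  d <- EBImage::distmap(1 - m, metric = "euclidean")
  cyto_local <- !nuc_local & d <= cyto_thickness
  idx <- function(sel) {
    rr <- rep(rows, times = length(cols))[sel]
    cc <- rep(cols, each = length(rows))[sel]
    (cc - 1L) * shape[1] + rr
  }
  list(nucleus = idx(nuc_local), cytoplasm = idx(cyto_local))
}

#' Render one synthetic two-channel well image with ground truth
#'
#' Places `n_cells` non-overlapping cells (elliptical nuclei with a
#' surrounding cytoplasmic annulus) by hard-core rejection sampling, draws
#' each cell's translocation state from `spec$translocation_fraction` and
#' its true N/C ratio from the corresponding state distribution, renders
#' the DAPI channel (nucleus at `dapi_level` over background) and the GFP
#' channel (each cell's total GFP split between nucleus and cytoplasm so
#' that the planted mean-intensity ratio equals the drawn true ratio
#' exactly before noise), then applies the camera noise model.
#'
#' @param spec a [well_spec()].
#' @param states a [state_distributions()].
#' @param max_tries placement attempts per cell before giving up.
#' @return a list of class `hcs_field` with elements `dapi` and `gfp`
#'   (numeric matrices, 16-bit count scale), `truth` (one row per rendered
#'   cell: center, axes, orientation, state, true ratio, compartment values
#'   and areas), and planted `nucleus_map` / `cyto_map` label images.
#' @export
render_well <- function(spec, states = state_distributions(), max_tries = 2000L) {
  stopifnot(inherits(spec, "well_spec"), inherits(states, "state_distributions"))
  set.seed(spec$seed)
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  n <- spec$n_cells
  ax_rng <- spec$nucleus_axes_range
  thick <- spec$cyto_thickness

  axes_a <- runif(n, ax_rng[1], ax_rng[2])
  axes_b <- runif(n, ax_rng[1], ax_rng[2])
  theta <- runif(n, 0, pi)
  reach <- pmax(axes_a, axes_b) + thick          # cell footprint radius

  margin <- ceiling(max(c(reach, 0))) + 2
  if (n > 0 && (H - 2 * margin < 1 || W - 2 * margin < 1)) {
    stop("image_shape ", H, "x", W, " too small for cells of footprint radius ",
         round(max(reach), 1))
  }
  centers <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
      if (nrow(centers) == 0) { ok <- TRUE } else {
        dmin <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
        ok <- all(dmin >= reach[i] + reach[seq_len(nrow(centers))] + 1)
      }
      if (ok) { centers <- rbind(centers, cand); placed <- TRUE; break }
    }
    if (!placed) {
      stop("could not place cell ", i, " of ", n, " in a ", H, "x", W,
           " field after ", max_tries, " tries: requested density too high")
    }
  }

  translocated <- if (n > 0) rbinom(n, 1, spec$translocation_fraction) == 1 else logical(0)
  meanlog <- ifelse(translocated, states$meanlog_translocated, states$meanlog_resting)
  nc_ratio_true <- if (n > 0) rlnorm(n, meanlog, states$sdlog) else numeric(0)
  dapi_level <- if (n > 0) spec$dapi_level * rlnorm(n, 0, 0.1) else numeric(0)
  gfp_total <- if (n > 0) rlnorm(n, spec$gfp_total_meanlog, spec$gfp_total_sdlog) else numeric(0)

  bg <- spec$noise$background_level
  dapi <- matrix(bg, H, W)
  gfp <- matrix(bg, H, W)
  nucleus_map <- matrix(0L, H, W)
  cyto_map <- matrix(0L, H, W)
  nuc_area <- integer(n); cyt_area <- integer(n)
  nuc_value <- numeric(n); cyt_value <- numeric(n)

  for (i in seq_len(n)) {
    px <- .rasterize_cell(centers[i, ], c(axes_a[i], axes_b[i]), theta[i],
                          c(H, W), thick)
    An <- length(px$nucleus); Ac <- length(px$cytoplasm)
    nuc_area[i] <- An; cyt_area[i] <- Ac
    cyt_value[i] <- gfp_total[i] / (nc_ratio_true[i] * An + Ac)
    nuc_value[i] <- nc_ratio_true[i] * cyt_value[i]
    dapi[px$nucleus] <- dapi_level[i]
    gfp[px$nucleus] <- nuc_value[i]
    gfp[px$cytoplasm] <- cyt_value[i]
    nucleus_map[px$nucleus] <- i
    cyto_map[px$cytoplasm] <- i
  }
  if (any(c(dapi, gfp) < 0)) stop("negative intensities in rendered field")

  apply_noise <- function(img) {
    if (spec$noise$shot_noise) img <- matrix(rpois(length(img), img), H, W)
    if (spec$noise$read_noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$noise$read_noise_sd), H, W)
    }
    pmin(pmax(round(img), 0), 65535)
  }
  dapi <- apply_noise(dapi)
  gfp <- apply_noise(gfp)

  truth <- data.frame(
    cell = seq_len(n),
    center_row = if (n > 0) centers[, 1] else numeric(0),
    center_col = if (n > 0) centers[, 2] else numeric(0),
    axis_a = axes_a, axis_b = axes_b, orientation = theta,
    dapi_level = dapi_level, gfp_total = gfp_total,
    nc_ratio_true = nc_ratio_true, translocated = translocated,
    nuc_area = nuc_area, cyt_area = cyt_area,
    nuc_value = nuc_value, cyt_value = cyt_value
  )
  structure(list(dapi = dapi, gfp = gfp, truth = truth,
                 nucleus_map = nucleus_map, cyto_map = cyto_map,
                 spec = spec),
            class = "hcs_field")
}

#' Render a full plate of synthetic wells from a layout and a dose model
#'
#' Negative-control wells are simulated at the model's `bottom` fraction,
#' positive controls at `top`, and compound wells at
#' [translocation_fraction_at()] evaluated at the well's concentration.
#' Each well's seed is derived deterministically from the plate seed and
#' the well id, so results do not depend on rendering order.
#'
#' @param layout a plate layout data frame (see [plate_layout()]).
#' @param model a [dose_model()].
#' @param base_spec a [well_spec()] providing field size, cell count, noise
#'   and geometry; its `translocation_fraction` and `seed` are overridden
#'   per well.
#' @param seed integer plate seed.
#' @param states a [state_distributions()].
#' @return a list of class `hcs_plate`: `wells` (named list of `hcs_field`),
#'   `truth` (row-bound per-cell ground truth with a `well` column),
#'   `layout`, `model`.
#' @export
render_plate <- function(layout, model, base_spec, seed,
                         states = state_distributions()) {
  stopifnot(is.data.frame(layout), inherits(model, "dose_model"),
            inherits(base_spec, "well_spec"))
  active <- layout[!layout$role %in% c("empty", "blank"), , drop = FALSE]
  bad <- setdiff(active$role, c("negative", "positive", "compound"))
  if (length(bad) > 0) stop("unknown well role(s): ", paste(unique(bad), collapse = ", "))
  wells <- list()
  truths <- list()
  for (k in seq_len(nrow(active))) {
    row <- active[k, ]
    frac <- switch(row$role,
                   negative = model$bottom,
                   positive = model$top,
                   compound = translocation_fraction_at(
                     model, conc_to_uM(row$conc, row$conc_unit)))
    spec_k <- base_spec
    spec_k$translocation_fraction <- frac
    spec_k$seed <- derive_seed(seed, row$well)
    fld <- render_well(spec_k, states)
    wells[[row$well]] <- fld
    if (nrow(fld$truth) > 0) {
      truths[[row$well]] <- cbind(well = row$well, fld$truth)
    }
  }
  truth <- if (length(truths) > 0) do.call(rbind, c(truths, make.row.names = FALSE)) else
    data.frame(well = character(0))
  structure(list(wells = wells, truth = truth, layout = layout, model = model),
            class = "hcs_plate")
}
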