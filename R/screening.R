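#' Control-well statistics for a plate
#'
#' @param pos_pct,neg_pct per-well translocation percentages of the
#'   positive (reference export inhibitor) and negative (vehicle) control
#'   wells.
#' @return an object of class `control_stats` with means, standard
#'   deviations and counts.
#' @export
control_stats <- function(pos_pct, neg_pct) {
  pos_pct <- pos_pct[is.finite(pos_pct)]
  neg_pct <- neg_pct[is.finite(neg_pct)]
  structure(list(mean_pos = mean(pos_pct), sd_pos = sd(pos_pct),
                 mean_neg = mean(neg_pct), sd_neg = sd(neg_pct),
                 n_pos = length(pos_pct), n_neg = length(neg_pct)),
            class = "control_stats")
}

#' Normalize well activity to plate controls
#'
#' The positive-control mean defines 100\% activity and the vehicle mean
#' 0\%; activity is the affine rescaling
#' `100 * (well_pct - mean_neg) / (mean_pos - mean_neg)` and may fall
#' outside [0, 100].
#'
#' @param well_pct per-well translocation percentage(s).
#' @param controls a [control_stats()].
#' @param plate plate id used in the degenerate-controls error message.
#' @return normalized activity in percent of the positive control.
#' @export
normalize_activity <- function(well_pct, controls, plate = "plate") {
  stopifnot(inherits(controls, "control_stats"))
  if (!is.finite(controls$mean_pos) || !is.finite(controls$mean_neg) ||
      controls$mean_pos == controls$mean_neg) {
    stop("degenerate controls on ", plate,
         ": positive and negative control means are equal (",
         controls$mean_pos, ")")
  }
  100 * (well_pct - controls$mean_neg) / (controls$mean_pos - controls$mean_neg)
}

#' Call screening hits from normalized activities
#'
#' A compound is a hit when its activity strictly exceeds the threshold
#' (default 60\% of the positive control).  Output is sorted by activity
#' descending, ties broken by well id.
#'
#' @param activities data frame with columns `well`, `compound`,
#'   `activity_pct`.
#' @param hit_threshold activity cutoff in percent.
#' @return the input with an `is_hit` column, sorted.
#' @export
call_hits <- function(activities, hit_threshold = 60) {
  stopifnot(all(c("well", "compound", "activity_pct") %in% names(activities)),
            all(is.finite(activities$activity_pct)))
  out <- activities
  out$is_hit <- out$activity_pct > hit_threshold
  out[order(-out$activity_pct, out$well), , drop = FALSE]
}

#' Z'-factor plate quality statistic
#'
#' The standard screening-window statistic
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`; values near 1
#' indicate a robust assay window, values below 0 a failed plate.  The
#' `"as-printed"` variant divides only the negative-control term by the
#' mean separation (a bracketing sometimes seen in print); it is provided
#' for comparison only and is not recommended.
#'
#' @param controls a [control_stats()] with at least two wells per arm.
#' @param variant `"zhang"` (default) or `"as-printed"`.
#' @return Z' (dimensionless, <= 1).
#' @export
zprime <- function(controls, variant = c("zhang", "as-printed")) {
  variant <- match.arg(variant)
  stopifnot(inherits(controls, "control_stats"))
  if (controls$n_pos < 2 || controls$n_neg < 2) {
    stop("Z' needs at least 2 positive and 2 negative control wells")
  }
  sep <- controls$mean_pos - controls$mean_neg
  if (sep == 0) stop("Z' undefined: control means are equal")
  if (variant == "zhang") {
    1 - 3 * (controls$sd_pos + controls$sd_neg) / abs(sep)
  } else {
    1 - (3 * controls$sd_pos + 3 * controls$sd_neg / sep)
  }
}
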