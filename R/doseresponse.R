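#' Serial-dilution concentration series
#'
#' Exact geometric series `top_conc / fold^(i-1)`, i = 1..n_points,
#' carrying its unit.  The conventional cytotoxicity design is eight
#' 2-fold dilutions from 50 uM (down to 0.39 uM); extended 20-point series
#' from 50 uM reach 95 pM.
#'
#' @param top_conc highest concentration (> 0).
#' @param fold dilution factor (> 1).
#' @param n_points number of concentrations (>= 1).
#' @param unit concentration unit ("M", "mM", "uM", "nM", "pM").
#' @return object of class `dilution_series` with `concentrations`
#'   (strictly decreasing), `unit`, `top_conc`, `fold`, `n_points`.
#' @export
dilution_series <- function(top_conc, fold = 2, n_points = 8, unit = "uM") {
  if (!(is.numeric(top_conc) && top_conc > 0)) stop("top_conc must be > 0")
  if (!(is.numeric(fold) && fold > 1)) stop("fold must be > 1")
  if (!(n_points >= 1)) stop("n_points must be >= 1")
  conc_to_uM(1, unit)  # validates the unit
  structure(list(concentrations = top_conc / fold^(seq_len(n_points) - 1),
                 unit = unit, top_conc = top_conc, fold = fold,
                 n_points = as.integer(n_points)),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("%d-point %g-fold dilution series: %g down to %g %s\n",
              x$n_points, x$fold, x$top_conc,
              x$concentrations[x$n_points], x$unit))
  invisible(x)
}

# 4PL response evaluated with signed hill on log10 concentration:
# bottom + (top - bottom) / (1 + 10^(hill * (lmid - lconc)))
# hill > 0 rises with concentration; hill < 0 falls (top = low-dose asymptote).
.fourpl <- function(lconc, bottom, top, lmid, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (lmid - lconc)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `r(c) = bottom + (top - bottom) / (1 + (midpoint/c)^hill)` on
#' log10-concentration via Levenberg-Marquardt with multi-start
#' initialization (midpoint starts at the 25th/50th/75th concentration
#' quantiles).  The Hill slope's sign is constrained by the assay
#' direction: `"increasing"` for activation readouts (response rises with
#' dose), `"decreasing"` for inhibition readouts such as viability.
#'
#' The `converged` flag is honest: it is `FALSE` when every start fails
#' (`rss = Inf`), when the fitted curve does not beat a flat (constant)
#' model (F-test, alpha 0.001), or when the midpoint runs to the edge of
#' the searched concentration window - the behaviour expected of an
#' inactive compound.
#'
#' @param conc concentrations (> 0; zero-concentration points are dropped).
#' @param response responses, same length.
#' @param direction `"increasing"` or `"decreasing"`.
#' @param weights optional least-squares weights.
#' @param hill_range allowed Hill slope magnitude range.
#' @return object of class `hcs_4pl`: `bottom`, `top`, `midpoint`, `hill`
#'   (signed), `rss`, `converged`, `reason`, `n`, `residual_se`,
#'   `midpoint_se` (delta-method from the residual covariance),
#'   `absolute_midpoint` (concentration where the curve crosses response
#'   50, `NA` unless bottom/top bracket 50), `direction`.
#' @export
fit_4pl <- function(conc, response, direction = c("increasing", "decreasing"),
                    weights = NULL, hill_range = c(0.2, 10)) {
  direction <- match.arg(direction)
  stopifnot(length(conc) == length(response), all(is.finite(response)))
  pos <- conc > 0
  conc <- conc[pos]; response <- response[pos]
  if (!is.null(weights)) weights <- weights[pos]
  if (length(unique(conc)) < 5) {
    stop("fit_4pl needs at least 5 distinct positive concentrations")
  }
  lconc <- log10(conc)
  n <- length(response)
  span <- diff(range(response))
  sgn <- if (direction == "increasing") 1 else -1
  w <- if (is.null(weights)) rep(1, n) else weights

  lower <- c(bottom = min(response) - 2 * max(span, 1),
             top = min(response) - 2 * max(span, 1),
             lmid = min(lconc) - 2,
             hill = if (sgn > 0) hill_range[1] else -hill_range[2])
  upper <- c(bottom = max(response) + 2 * max(span, 1),
             top = max(response) + 2 * max(span, 1),
             lmid = max(lconc) + 2,
             hill = if (sgn > 0) hill_range[2] else -hill_range[1])

  dat <- data.frame(lconc = lconc, response = response)
  best <- NULL
  for (lmid0 in unname(quantile(lconc, c(0.25, 0.5, 0.75)))) {
    for (h0 in sgn * c(0.5, 1, 2)) {
      start <- list(bottom = min(response), top = max(response),
                    lmid = lmid0, hill = h0)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          response ~ .fourpl(lconc, bottom, top, lmid, hill),
          data = dat, start = start, weights = w,
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 300,
                                               ftol = 1e-12, ptol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(w * residuals(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
  }

  out <- list(bottom = NA_real_, top = NA_real_, midpoint = NA_real_,
              hill = NA_real_, rss = Inf, converged = FALSE,
              reason = "no_start_converged", n = n,
              residual_se = NA_real_, midpoint_se = NA_real_,
              absolute_midpoint = NA_real_, direction = direction)
  class(out) <- "hcs_4pl"
  if (is.null(best)) return(out)

  p <- coef(best$fit)
  out$bottom <- unname(p["bottom"]); out$top <- unname(p["top"])
  out$midpoint <- 10^unname(p["lmid"]); out$hill <- unname(p["hill"])
  out$rss <- best$rss
  out$residual_se <- sqrt(best$rss / max(n - 4, 1))
  se <- tryCatch(sqrt(diag(vcov(best$fit)))["lmid"], error = function(e) NA_real_)
  out$midpoint_se <- unname(out$midpoint * log(10) * se)

  # honest convergence: must beat a flat model and keep the midpoint
  # inside the searched window
  rss0 <- sum(w * (response - sum(w * response) / sum(w))^2)
  df2 <- n - 4
  if (df2 > 0 && out$rss < rss0) {
    fstat <- ((rss0 - out$rss) / 3) / (out$rss / df2)
    pval <- pf(fstat, 3, df2, lower.tail = FALSE)
  } else {
    pval <- 1
  }
  lmid_hat <- unname(p["lmid"])
  at_edge <- lmid_hat <= lower["lmid"] + 1e-6 || lmid_hat >= upper["lmid"] - 1e-6
  if (pval > 0.001) {
    out$converged <- FALSE; out$reason <- "flat_response"
    out$midpoint <- NA_real_; out$midpoint_se <- NA_real_
  } else if (at_edge) {
    out$converged <- FALSE; out$reason <- "midpoint_at_boundary"
  } else {
    out$converged <- TRUE; out$reason <- "ok"
  }
  lo <- min(out$bottom, out$top); hi <- max(out$bottom, out$top)
  if (out$converged && lo < 50 && hi > 50) {
    ratio <- (out$top - 50) / (50 - out$bottom)
    out$absolute_midpoint <- out$midpoint / ratio^(1 / out$hill)
  }
  out
}

#' @export
print.hcs_4pl <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "4PL fit (%s): midpoint %.4g (se %.2g), hill %.3g, bottom %.3g, top %.3g, rss %.4g\n",
      x$direction, x$midpoint, x$midpoint_se, x$hill, x$bottom, x$top, x$rss))
  } else {
    cat(sprintf("4PL fit: not converged (%s) - compound inactive or data degenerate\n",
                x$reason))
  }
  invisible(x)
}

#' Normalize MTT absorbance readings to percent viability
#'
#' `viability = 100 * (A_treated - mean(A_blank)) / (mean(A_vehicle) - mean(A_blank))`;
#' replicate treated wells at the same concentration are averaged with a
#' standard deviation.  Vehicle wells average 100\% by construction.
#'
#' @param table data frame with columns `role` (`treated` / `vehicle` /
#'   `blank`), `conc_uM` (treated wells) and `absorbance` (570 nm, a.u.).
#' @return data frame per concentration: `conc_uM`, `viability_pct`,
#'   `sd`, `n`; per-well viabilities in attribute `per_well`.
#' @export
viability_from_absorbance <- function(table) {
  stopifnot(all(c("role", "conc_uM", "absorbance") %in% names(table)))
  a_veh <- mean(table$absorbance[table$role == "vehicle"])
  a_blk <- mean(table$absorbance[table$role == "blank"])
  if (!is.finite(a_veh) || !is.finite(a_blk)) {
    stop("viability normalization needs at least one vehicle and one blank well")
  }
  if (a_veh == a_blk) stop("vehicle and blank absorbance are equal: no signal window")
  tr <- table[table$role == "treated", , drop = FALSE]
  tr$viability_pct <- 100 * (tr$absorbance - a_blk) / (a_veh - a_blk)
  agg <- aggregate(viability_pct ~ conc_uM, data = tr,
                   FUN = function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- data.frame(conc_uM = agg$conc_uM,
                    viability_pct = agg$viability_pct[, "mean"],
                    sd = agg$viability_pct[, "sd"],
                    n = as.integer(agg$viability_pct[, "n"]))
  out <- out[order(-out$conc_uM), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_well") <- tr
  out
}

#' Simulate an MTT absorbance table with a known IC50
#'
#' Generates triplicate (by default) treated wells over a dilution series
#' from a decreasing 4PL viability curve (100\% at zero dose, 0\% at
#' saturating dose, midpoint `ic50_uM`), plus vehicle and blank control
#' wells, with Gaussian absorbance noise expressed as a fraction of the
#' vehicle signal.
#'
#' @param ic50_uM true midpoint in micromolar.
#' @param series a [dilution_series()].
#' @param hill Hill slope magnitude (> 0).
#' @param n_rep treated replicates per concentration.
#' @param n_vehicle,n_blank numbers of control wells.
#' @param a_vehicle,a_blank expected absorbances of vehicle and blank wells.
#' @param noise_sd_frac Gaussian noise sd as a fraction of `a_vehicle`.
#' @param seed integer seed.
#' @return absorbance table suitable for [viability_from_absorbance()],
#'   with attribute `truth` recording the generator parameters.
#' @export
simulate_viability_table <- function(ic50_uM, series = dilution_series(50, 2, 20),
                                     hill = 1, n_rep = 3,
                                     n_vehicle = 8, n_blank = 4,
                                     a_vehicle = 1.2, a_blank = 0.08,
                                     noise_sd_frac = 0.05, seed = 1L) {
  stopifnot(ic50_uM > 0, hill > 0, inherits(series, "dilution_series"),
            a_vehicle > a_blank)
  set.seed(seed)
  conc <- conc_to_uM(series$concentrations, series$unit)
  v_frac <- 1 / (1 + (conc / ic50_uM)^hill)
  tab <- rbind(
    data.frame(role = "treated",
               conc_uM = rep(conc, each = n_rep),
               expected = a_blank + (a_vehicle - a_blank) * rep(v_frac, each = n_rep)),
    data.frame(role = "vehicle", conc_uM = NA_real_,
               expected = rep(a_vehicle, n_vehicle)),
    data.frame(role = "blank", conc_uM = NA_real_,
               expected = rep(a_blank, n_blank)))
  tab$absorbance <- tab$expected + rnorm(nrow(tab), 0, noise_sd_frac * a_vehicle)
  tab$expected <- NULL
  attr(tab, "truth") <- list(ic50_uM = ic50_uM, hill = hill,
                             a_vehicle = a_vehicle, a_blank = a_blank,
                             noise_sd_frac = noise_sd_frac, seed = seed)
  tab
}

#' Fit an IC50 from a viability table
#'
#' @param viability output of [viability_from_absorbance()] (or any data
#'   frame with `conc_uM` and `viability_pct`).
#' @param ... passed to [fit_4pl()].
#' @return an `hcs_4pl` fit with `midpoint` = IC50 in micromolar.
#' @export
fit_ic50 <- function(viability, ...) {
  fit_4pl(viability$conc_uM, viability$viability_pct,
          direction = "decreasing", ...)
}

#' EC50 estimation from per-well summaries and a plate layout
#'
#' Normalizes compound-well translocation percentages to the plate
#' controls and fits one 4PL per compound; the fitted midpoint is the
#' EC50 in micromolar (concentrations are converted from the layout
#' unit).  With balanced replicate wells per dose the fit is identical to
#' fitting dose means.
#'
#' @param wells per-well summary data frame (columns `well`,
#'   `pct_translocated`).
#' @param layout plate layout data frame.
#' @param controls optional [control_stats()]; computed from the layout's
#'   control wells when `NULL`.
#' @param direction assay direction passed to [fit_4pl()].
#' @return named list of `hcs_4pl` fits, one per compound; each carries
#'   the fitted `data` (conc_uM, activity_pct) as an attribute.
#' @export
ec50_from_plate <- function(wells, layout, controls = NULL,
                            direction = "increasing") {
  m <- merge(layout, wells[, c("well", "pct_translocated")], by = "well")
  if (is.null(controls)) {
    controls <- control_stats(m$pct_translocated[m$role == "positive"],
                              m$pct_translocated[m$role == "negative"])
  }
  cw <- m[m$role == "compound" & is.finite(m$pct_translocated), , drop = FALSE]
  cw$activity_pct <- normalize_activity(cw$pct_translocated, controls)
  cw$conc_uM <- conc_to_uM(cw$conc, cw$conc_unit)
  fits <- list()
  for (cmp in unique(cw$compound)) {
    d <- cw[cw$compound == cmp, , drop = FALSE]
    fit <- fit_4pl(d$conc_uM, d$activity_pct, direction = direction)
    attr(fit, "data") <- d[, c("well", "conc_uM", "activity_pct")]
    fits[[cmp]] <- fit
  }
  fits
}
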