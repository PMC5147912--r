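# Independent oracles used by the property tests.  These deliberately use
# naive algorithms (pairwise pixel distances, exhaustive grid search) so
# they share no code with the implementation under test.

# Brute-force ring construction: for every background pixel compute its
# exact Euclidean distance to every nucleus pixel set; a pixel belongs to
# the ring of label l iff gap < d(p, l) <= gap + width, and contested
# pixels go to the nearest claiming nucleus (ties: nearest centroid, then
# lower label).
brute_force_rings <- function(nuclei, gap, width) {
  H <- nrow(nuclei); W <- ncol(nuclei)
  coords <- which(nuclei > 0, arr.ind = TRUE)
  labs <- nuclei[nuclei > 0]
  ulabs <- sort(unique(labs))
  cents <- t(vapply(ulabs, function(l) colMeans(coords[labs == l, , drop = FALSE]),
                    numeric(2)))
  ring <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      if (nuclei[r, cc] > 0) next
      d_all <- sqrt((coords[, 1] - r)^2 + (coords[, 2] - cc)^2)
      d_lab <- vapply(ulabs, function(l) min(d_all[labs == l]), numeric(1))
      claim <- which(d_lab > gap & d_lab <= gap + width)
      if (length(claim) == 0) next
      cd <- sqrt((cents[claim, 1] - r)^2 + (cents[claim, 2] - cc)^2)
      o <- order(d_lab[claim], cd, ulabs[claim])
      ring[r, cc] <- ulabs[claim][o[1]]
    }
  }
  ring
}

# Exhaustive grid search for the 4PL least-squares problem: bottom and
# span are profiled out by closed-form linear regression at every
# (log10 midpoint, hill) grid node; a second, finer pass zooms in around
# the coarse optimum.
grid_fit_4pl <- function(conc, resp, direction = "increasing") {
  lc <- log10(conc)
  sgn <- if (direction == "increasing") 1 else -1
  eval_node <- function(lmid, hill) {
    f <- 1 / (1 + 10^(hill * (lmid - lc)))
    vf <- f - mean(f)
    if (sum(vf^2) < 1e-12) return(list(rss = Inf))
    slope <- sum(vf * (resp - mean(resp))) / sum(vf^2)
    bottom <- mean(resp) - slope * mean(f)
    list(rss = sum((resp - bottom - slope * f)^2),
         lmid = lmid, hill = hill, bottom = bottom, top = bottom + slope)
  }
  search <- function(lmids, hills) {
    best <- list(rss = Inf)
    for (lm0 in lmids) for (h in hills) {
      cand <- eval_node(lm0, h)
      if (cand$rss < best$rss) best <- cand
    }
    best
  }
  lmids <- seq(min(lc) - 1, max(lc) + 1, length.out = 80)
  hills <- sgn * seq(0.2, 6, by = 0.1)
  best <- search(lmids, hills)
  dl <- diff(lmids[1:2]); dh <- 0.1
  best <- search(seq(best$lmid - dl, best$lmid + dl, length.out = 41),
                 sgn * seq(max(0.2, abs(best$hill) - dh),
                           abs(best$hill) + dh, length.out = 41))
  best$midpoint <- 10^best$lmid
  best
}

# Small noise-free field used across tests: well-separated cells, no
# camera noise, so planted and measured quantities agree tightly.
clean_field <- function(n_cells = 12, shape = c(256, 256), frac = 0,
                        seed = 42, ratio_sdlog = 0.2) {
  render_well(
    well_spec(n_cells = n_cells, image_shape = shape,
              translocation_fraction = frac,
              noise = noise_spec(background_level = 200, read_noise_sd = 0,
                                 shot_noise = FALSE),
              seed = seed),
    state_distributions(sdlog = ratio_sdlog))
}
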