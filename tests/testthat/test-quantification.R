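test_that("compartment means and ratios follow their definitions", {
  gfp <- matrix(0, 20, 20)
  nuc <- matrix(0L, 20, 20); nuc[8:12, 8:12] <- 1L
  gfp[nuc == 1L] <- 200
  rs <- make_cytoplasm_rings(nuc, ring_gap = 1, ring_width = 3)
  gfp[rs$rings == 1L] <- 100
  cells <- measure_cells(gfp, nuc, rs)
  expect_equal(cells$nc_ratio, 2.0)
  # uniform image: ratio exactly 1 regardless of masks
  uni <- matrix(137, 20, 20)
  expect_equal(measure_cells(uni, nuc, rs)$nc_ratio, 1.0)
})

test_that("pipeline measurement recovers the planted true ratio within 0.05", {
  states <- state_distributions(meanlog_resting = log(2.5),
                                meanlog_translocated = log(2.5) + 1e-9, sdlog = 0)
  f <- render_well(well_spec(n_cells = 10, image_shape = c(224, 224),
                             translocation_fraction = 0,
                             noise = noise_spec(read_noise_sd = 0,
                                                shot_noise = FALSE),
                             seed = 13),
                   states)
  cells <- analyze_field(f$dapi, f$gfp)
  expect_equal(nrow(cells), 10)
  expect_true(all(abs(cells$nc_ratio - 2.5) < 0.05))
})

test_that("cells with zero cytoplasmic signal are excluded, not fatal", {
  gfp <- matrix(0, 20, 20)
  nuc <- matrix(0L, 20, 20); nuc[8:12, 8:12] <- 1L
  gfp[nuc == 1L] <- 50   # ring stays at 0
  rs <- make_cytoplasm_rings(nuc, 1, 3)
  cells <- measure_cells(gfp, nuc, rs)
  expect_equal(nrow(cells), 0)
  expect_equal(attr(cells, "excluded")$reason, "zero_cytoplasmic_signal")
})

test_that("the translocation call is strict at the threshold", {
  expect_true(classify_translocated(2.0))
  expect_false(classify_translocated(1.8))
  expect_false(classify_translocated(0.9))
  expect_identical(classify_translocated(c(1.79, 1.8, 1.81)),
                   c(FALSE, FALSE, TRUE))
})

test_that("percent translocated is non-increasing in the threshold", {
  set.seed(5)
  ratios <- rlnorm(400, log(1.5), 0.5)
  ths <- seq(0.5, 4, by = 0.25)
  pct <- vapply(ths, function(t) mean(classify_translocated(ratios, t)), numeric(1))
  expect_true(all(diff(pct) <= 0))
})

test_that("well summaries aggregate counts, flags and degenerate wells", {
  cells <- data.frame(translocated = c(rep(TRUE, 4), rep(FALSE, 6)),
                      nuclear_vertices = rep(30L, 10))
  s <- summarize_well(cells, well = "B02", min_cells = 5)
  expect_equal(s$pct_translocated, 40)
  expect_equal(s$qc_flags, "")
  s2 <- summarize_well(cells, well = "B03", min_cells = 50)
  expect_match(s2$qc_flags, "low_count")
  s3 <- summarize_well(cells[0, ], well = "B04")
  expect_true(is.na(s3$pct_translocated))
  expect_match(s3$qc_flags, "empty")
})

test_that("observed well percentages track planted fractions within 10 points", {
  for (frac in c(0.1, 0.5, 0.9)) {
    f <- clean_field(n_cells = 60, shape = c(420, 420), frac = frac,
                     seed = 100 + round(100 * frac))
    cells <- analyze_field(f$dapi, f$gfp)
    s <- summarize_well(cells, "W", min_cells = 10)
    expect_lt(abs(s$pct_translocated - 100 * frac), 10)
  }
})

test_that("per-cell classification against planted truth exceeds 95% accuracy", {
  # states separated by >= 3 sdlog around the 1.8 cutoff, noise-free images
  f <- clean_field(n_cells = 60, shape = c(420, 420), frac = 0.5, seed = 77)
  cells <- analyze_field(f$dapi, f$gfp)
  expect_equal(nrow(cells), 60)
  # match measured cells to planted cells by nucleus position
  nuc <- segment_nuclei(f$dapi)
  coords <- which(nuc > 0, arr.ind = TRUE)
  labs <- nuc[nuc > 0]
  planted_call <- f$truth$nc_ratio_true > 1.8
  acc <- vapply(seq_len(nrow(cells)), function(i) {
    cen <- colMeans(coords[labs == cells$label[i], , drop = FALSE])
    j <- which.min((f$truth$center_row - cen[1])^2 +
                     (f$truth$center_col - cen[2])^2)
    cells$translocated[i] == planted_call[j]
  }, logical(1))
  expect_gte(mean(acc), 0.95)
})

test_that("quantification is deterministic for identical images and config", {
  f <- clean_field(n_cells = 8, shape = c(200, 200), frac = 0.3, seed = 21)
  a <- analyze_field(f$dapi, f$gfp)
  b <- analyze_field(f$dapi, f$gfp)
  expect_identical(a, b)
})
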