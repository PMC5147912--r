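test_that("an empty field is pure background with empty ground truth", {
  f <- render_well(well_spec(n_cells = 0, image_shape = c(64, 64),
                             noise = noise_spec(background_level = 300,
                                                read_noise_sd = 0,
                                                shot_noise = FALSE),
                             seed = 1))
  expect_equal(nrow(f$truth), 0)
  expect_true(all(f$dapi == 300))
  expect_true(all(f$gfp == 300))
})

test_that("identical spec and seed give bit-identical images and truth", {
  spec <- well_spec(n_cells = 15, image_shape = c(200, 200),
                    translocation_fraction = 0.4, seed = 99)
  a <- render_well(spec)
  b <- render_well(spec)
  expect_identical(a$dapi, b$dapi)
  expect_identical(a$gfp, b$gfp)
  expect_identical(a$truth, b$truth)
})

test_that("planted masks reproduce the true N/C ratio and conserve GFP", {
  # fix every cell's true ratio at 2.5 by collapsing the state distribution
  states <- state_distributions(meanlog_resting = log(2.5),
                                meanlog_translocated = log(2.5) + 1e-9,
                                sdlog = 0)
  f <- render_well(well_spec(n_cells = 20, image_shape = c(300, 300),
                             translocation_fraction = 0,
                             noise = noise_spec(read_noise_sd = 0,
                                                shot_noise = FALSE),
                             seed = 5),
                   states)
  for (i in seq_len(20)) {
    nuc <- f$gfp[f$nucleus_map == i]
    cyt <- f$gfp[f$cyto_map == i]
    expect_lt(abs(mean(nuc) / mean(cyt) - 2.5), 0.05)
    # conservation: quantization can move each pixel by at most 0.5
    expect_lt(abs(sum(nuc) + sum(cyt) - f$truth$gfp_total[i]),
              0.5 * (length(nuc) + length(cyt)) + 1)
  }
})

test_that("planted ratio fidelity holds across random draws (within 2%)", {
  f <- clean_field(n_cells = 15, shape = c(280, 280), frac = 0.5, seed = 7)
  r <- vapply(seq_len(15), function(i)
    mean(f$gfp[f$nucleus_map == i]) / mean(f$gfp[f$cyto_map == i]), numeric(1))
  expect_true(all(abs(r / f$truth$nc_ratio_true - 1) < 0.02))
})

test_that("impossible densities fail with an informative error", {
  expect_error(render_well(well_spec(n_cells = 200, image_shape = c(64, 64),
                                     seed = 1), max_tries = 50),
               "density")
})

test_that("translocation_fraction_at follows the 4PL in closed form", {
  m <- dose_model(bottom = 0.1, top = 0.8, ec50_uM = 1.5, hill = 2)
  expect_equal(translocation_fraction_at(m, 1.5), (0.1 + 0.8) / 2)
  expect_equal(translocation_fraction_at(m, 0), 0.1)
  m2 <- dose_model(bottom = 0, top = 1, ec50_uM = 1.5, hill = 1)
  expect_equal(translocation_fraction_at(m2, 4.5), 0.75)
})

test_that("predicted translocated fraction is monotone in concentration", {
  set.seed(31)
  for (k in 1:20) {
    m <- dose_model(bottom = runif(1, 0, 0.3), top = runif(1, 0.5, 1),
                    ec50_uM = 10^runif(1, -2, 2), hill = runif(1, 0.3, 4))
    conc <- sort(10^runif(15, -4, 3))
    expect_true(all(diff(translocation_fraction_at(m, conc)) >= 0))
  }
})

test_that("render_plate derives well seeds from the plate seed and well id", {
  lay <- plate_layout(2, 2)
  lay$role <- c("negative", "positive", "compound", "empty")
  lay$compound[3] <- "X"; lay$conc[3] <- 5; lay$conc_unit[3] <- "uM"
  spec <- well_spec(n_cells = 5, image_shape = c(128, 128))
  p1 <- render_plate(lay, dose_model(), spec, seed = 3)
  p2 <- render_plate(lay, dose_model(), spec, seed = 3)
  expect_identical(p1$wells[["A02"]]$gfp, p2$wells[["A02"]]$gfp)
  expect_equal(sort(names(p1$wells)), c("A01", "A02", "B01"))
  # wells differ from each other
  expect_false(identical(p1$wells[["A01"]]$dapi, p1$wells[["A02"]]$dapi))
})

test_that("render_plate rejects unknown roles and accepts empty layouts", {
  lay <- plate_layout(1, 2)
  lay$role <- c("negative", "mystery")
  expect_error(render_plate(lay, dose_model(), well_spec(n_cells = 2), 1),
               "unknown well role")
  empty <- plate_layout(2, 2)  # all wells "empty"
  p <- render_plate(empty, dose_model(), well_spec(n_cells = 2), 1)
  expect_length(p$wells, 0)
})

test_that("planted per-well fractions are monotone along a dilution series", {
  m <- dose_model(bottom = 0.05, top = 0.9, ec50_uM = 1.5, hill = 1)
  conc <- dilution_series(50, 2, 8, "uM")$concentrations
  fr <- translocation_fraction_at(m, rev(conc))
  expect_true(all(diff(fr) >= 0))
})
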