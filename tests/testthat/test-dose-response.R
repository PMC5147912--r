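test_that("dilution series are exact geometric sequences", {
  s <- dilution_series(50, 2, 8, "uM")
  expect_equal(s$concentrations, 50 / 2^(0:7))
  expect_true(all(diff(s$concentrations) < 0))
  expect_equal(dilution_series(3.7, 2, 1)$concentrations, 3.7)
  expect_error(dilution_series(-1, 2, 8), "top_conc")
  expect_error(dilution_series(50, 1, 8), "fold")
})

test_that("noiseless 4PL responses are recovered to numerical precision", {
  cc <- dilution_series(50, 2, 8)$concentrations
  resp <- 5 + (95 - 5) / (1 + (1.5 / cc)^1.3)
  fit <- fit_4pl(cc, resp)
  expect_true(fit$converged)
  expect_lt(abs(fit$midpoint - 1.5) / 1.5, 1e-6)
  expect_lt(abs(fit$hill - 1.3), 1e-5)
  expect_lt(abs(fit$bottom - 5), 1e-4)
  expect_lt(abs(fit$top - 95), 1e-4)
})

test_that("constant responses are reported as not converged", {
  cc <- dilution_series(50, 2, 8)$concentrations
  fit <- fit_4pl(cc, rep(42, 8))
  expect_false(fit$converged)
  expect_true(is.na(fit$midpoint))
  expect_error(fit_4pl(c(1, 2, 3), c(1, 2, 3)), "at least 5")
})

test_that("noisy fits recover the generator midpoint and match the grid oracle", {
  # triplicate wells per dose, the standard design for these assays
  cc <- rep(dilution_series(50, 2, 12)$concentrations, each = 3)
  set.seed(314)
  for (k in 1:4) {
    resp <- 0 + 100 / (1 + (1.5 / cc)^1) + rnorm(length(cc), 0, 5)
    fit <- fit_4pl(cc, resp)
    expect_true(fit$converged)
    expect_lt(abs(fit$midpoint - 1.5) / 1.5, 0.2)
    oracle <- grid_fit_4pl(cc, resp)
    expect_lt(abs(fit$rss - oracle$rss), 0.01 * oracle$rss + 1e-9)
    expect_lt(abs(fit$midpoint - oracle$midpoint) / oracle$midpoint, 0.01)
  }
})

test_that("rescaling concentrations rescales the midpoint by the same factor", {
  cc <- dilution_series(50, 2, 10)$concentrations
  set.seed(12)
  resp <- 2 + 90 / (1 + (3 / cc)^1.5) + rnorm(length(cc), 0, 3)
  f1 <- fit_4pl(cc, resp)
  f2 <- fit_4pl(cc * 1000, resp)    # e.g. uM -> nM
  expect_lt(abs(f2$midpoint / f1$midpoint - 1000) / 1000, 1e-6)
  expect_lt(abs(f2$hill - f1$hill), 1e-6)
})

test_that("median midpoint recovery error stays under 10% at noise sd 5", {
  cc <- rep(dilution_series(50, 2, 12)$concentrations, each = 3)
  errs <- vapply(1:50, function(k) {
    set.seed(1000 + k)
    resp <- 100 / (1 + (1.5 / cc)^1) + rnorm(length(cc), 0, 5)
    fit <- fit_4pl(cc, resp)
    abs(fit$midpoint - 1.5) / 1.5
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("viability normalization follows the absorbance formula", {
  tab <- data.frame(role = c("vehicle", "vehicle", "blank", "treated", "treated"),
                    conc_uM = c(NA, NA, NA, 10, 20),
                    absorbance = c(1.0, 1.0, 0.1, 0.55, 0.1))
  v <- viability_from_absorbance(tab)
  expect_equal(v$viability_pct[v$conc_uM == 10], 50)
  expect_equal(v$viability_pct[v$conc_uM == 20], 0)
  # treated at the vehicle level reads 100%
  tab2 <- rbind(tab, data.frame(role = "treated", conc_uM = 5, absorbance = 1.0))
  v2 <- viability_from_absorbance(tab2)
  expect_equal(v2$viability_pct[v2$conc_uM == 5], 100)
  tab$absorbance[tab$role == "blank"] <- 1.0
  expect_error(viability_from_absorbance(tab), "equal")
})

test_that("simulated MTT tables yield IC50s near the generator value", {
  tab <- simulate_viability_table(2.0, dilution_series(50, 2, 20), seed = 8)
  fit <- fit_ic50(viability_from_absorbance(tab))
  expect_true(fit$converged)
  expect_lt(abs(fit$midpoint - 2.0) / 2.0, 0.15)
  expect_lt(fit$hill, 0)   # decreasing direction
})

test_that("balanced duplicate wells fit identically to dose means", {
  cc <- dilution_series(50, 2, 8)$concentrations
  set.seed(4)
  r1 <- 100 / (1 + (2 / cc)) + rnorm(8, 0, 4)
  r2 <- 100 / (1 + (2 / cc)) + rnorm(8, 0, 4)
  dup <- fit_4pl(c(cc, cc), c(r1, r2))
  avg <- fit_4pl(cc, (r1 + r2) / 2)
  expect_lt(abs(dup$midpoint - avg$midpoint) / avg$midpoint, 1e-6)
  expect_lt(abs(dup$hill - avg$hill), 1e-6)
})

test_that("ec50_from_plate normalizes to controls and recovers the midpoint", {
  set.seed(60)
  series <- dilution_series(50, 2, 8, "uM")
  lay <- layout_dose_plate("cmpX", series, replicates = 2)
  m <- dose_model(bottom = 0.05, top = 0.9, ec50_uM = 2.5, hill = 1)
  # well percentages straight from the generative model + binomial noise
  frac <- rep(NA_real_, nrow(lay))
  frac[lay$role == "negative"] <- m$bottom
  frac[lay$role == "positive"] <- m$top
  cw <- lay$role == "compound"
  frac[cw] <- translocation_fraction_at(m, conc_to_uM(lay$conc[cw], lay$conc_unit[cw]))
  keep <- lay$role %in% c("negative", "positive", "compound")
  wells <- data.frame(well = lay$well[keep],
                      pct_translocated = 100 * rbinom(sum(keep), 150, frac[keep]) / 150)
  fits <- ec50_from_plate(wells, lay)
  expect_named(fits, "cmpX")
  expect_true(fits$cmpX$converged)
  expect_lt(abs(fits$cmpX$midpoint - 2.5) / 2.5, 0.25)
})
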