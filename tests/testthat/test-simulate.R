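test_that("identical seed and config give bit-identical simulations", {
  m <- build_linear_map()
  e <- error_config(independent_cv = 0.02, contamination_prob = 0.05,
                    measurement_noise_sd = 0.01, seed = 11)
  s1 <- simulate_plate(m, error = e, n_repeats = 2)
  s2 <- simulate_plate(m, error = e, n_repeats = 2)
  expect_identical(s1$plate$composition, s2$plate$composition)
  expect_identical(s1$readings[[2]]$absorbance, s2$readings[[2]]$absorbance)
  s3 <- simulate_plate(m, error = error_config(independent_cv = 0.02,
                                               contamination_prob = 0.05,
                                               measurement_noise_sd = 0.01,
                                               seed = 12))
  expect_false(identical(s1$plate$composition, s3$plate$composition))
})

test_that("solute gain biases realized ratios per the mass balance", {
  m <- build_linear_map()
  e <- error_config(solute_gain = 1.05)
  sp <- execute_instructions(linear_transfer_instructions(m), m, e)
  comp <- sp$composition
  samp <- comp$target_ratio > 0
  r <- comp$target_ratio[samp]
  expected <- 1.05 * r / (1.05 * r + 1 - r)
  expect_equal(comp$true_ratio[samp], expected, tolerance = 1e-12)
  # to first order at small r the bias is the full +5%
  low <- r <= 0.1
  expect_equal(comp$true_ratio[samp][low] / r[low],
               rep(1.05, sum(low)), tolerance = 0.01)
})

test_that("reservoir concentration error scales every sample ratio", {
  m <- build_linear_map()
  e <- error_config(reservoir_concentration_error = 0.1)
  sp <- execute_instructions(linear_transfer_instructions(m), m, e)
  comp <- sp$composition
  samp <- comp$target_ratio > 0
  expect_equal(comp$true_ratio[samp], 1.1 * comp$target_ratio[samp],
               tolerance = 1e-12)
})

test_that("carryover makes the realized fold exceed nominal, compounding by column", {
  g <- build_geometric_map()
  e <- error_config(carryover_excess = 20)
  sg <- execute_instructions(geometric_transfer_instructions(g), g, e)
  comp <- sg$composition
  rel <- comp$true_ratio / comp$target_ratio
  cols <- well_col(comp$well)
  mean_rel <- tapply(rel[comp$target_ratio > 0], cols[comp$target_ratio > 0],
                     mean)
  # realized fold 220/420 per transfer => relative excess grows with column
  expect_true(all(diff(mean_rel[as.character(2:10)]) > 0))
  expect_equal(unname(mean_rel[["2"]]), (220 / 420) / 0.5, tolerance = 1e-9)
})

test_that("contamination moves droplets without destroying volume conservation", {
  m <- build_linear_map()
  e <- error_config(contamination_prob = 0.2, droplet_volume = 1, seed = 3)
  sp <- execute_instructions(linear_transfer_instructions(m), m, e)
  disp <- sum(sp$volumes$realized_uL[sp$volumes$phase != "mix"])
  expect_equal(sum(sp$composition$volume_uL), disp, tolerance = 1e-9)
})

test_that("rendered absorbance follows the response model exactly without noise", {
  m <- build_linear_map()
  sim <- simulate_plate(m)
  rd <- sim$readings[[1]]
  sc <- spectrum_config()
  s <- solute_spectrum(sc)
  b <- baseline_spectrum(sc)
  i524 <- which(sc$wavelength_grid == 524)
  a1 <- rd$absorbance["A1", i524]
  expect_equal(unname(a1), 1 * s[i524] + b[i524], tolerance = 1e-12)
  # blanks are exactly the baseline
  expect_equal(unname(rd$absorbance["A11", ]), b, tolerance = 1e-12)
  # monotone in true ratio at the peak with gamma >= 0
  ord <- order(sim$plate$composition$true_ratio)
  expect_true(all(diff(rd$absorbance[ord, i524]) >= -1e-12))
})

test_that("curvature compresses the top of the response", {
  m <- build_linear_map()
  e <- error_config(curvature = 0.5)
  sim <- simulate_plate(m, error = e)
  rd <- sim$readings[[1]]
  i524 <- which(spectrum_config()$wavelength_grid == 524)
  s524 <- solute_spectrum(spectrum_config())[i524]
  b524 <- baseline_spectrum(spectrum_config())[i524]
  expect_equal(unname(rd$absorbance["A1", i524]),
               (1 / 1.5) * s524 + b524, tolerance = 1e-12)
})

test_that("transient excursions decay across repeats and vanish when disabled", {
  m <- build_linear_map()
  e0 <- error_config(seed = 5)
  reps <- render_absorbance(execute_instructions(
    linear_transfer_instructions(m), m, e0), spectrum_config(), e0,
    n_repeats = 3)
  expect_identical(reps[[1]]$absorbance, reps[[2]]$absorbance)
  expect_identical(reps[[2]]$absorbance, reps[[3]]$absorbance)

  e1 <- error_config(transient_prob = 1, transient_scale = 0.5,
                     transient_decay = 0.3, seed = 5)
  comp <- execute_instructions(linear_transfer_instructions(m), m, e1)
  reps <- render_absorbance(comp, spectrum_config(), e1, n_repeats = 12)
  i524 <- which(spectrum_config()$wavelength_grid == 524)
  clean <- render_absorbance(comp, spectrum_config(), e0, 1)[[1]]
  # A1 always excurses (weight c/cmax = 1); deviations present but shrinking
  dev <- vapply(reps, function(r) abs(r$absorbance["A1", i524] -
                                        clean$absorbance["A1", i524]), 0)
  expect_true(any(dev > 0.01))
  # blanks never excurse
  devb <- vapply(reps, function(r) abs(r$absorbance["A11", i524] -
                                         clean$absorbance["A11", i524]), 0)
  expect_true(all(devb == 0))
})

test_that("aging flattens the solute spectrum toward a peak-free background", {
  s0 <- solute_spectrum(spectrum_config(aging_flatness = 0))
  s1 <- solute_spectrum(spectrum_config(aging_flatness = 1))
  wl <- spectrum_config()$wavelength_grid
  expect_identical(s0, solute_spectrum(spectrum_config()))
  expect_identical(nrow(find_spectrum_peaks(s1, wl)), 0L)
  expect_gt(nrow(find_spectrum_peaks(s0, wl)), 0L)
})

test_that("error config validates probabilities and magnitudes", {
  expect_error(error_config(contamination_prob = 1.5), "\\[0, 1\\]")
  expect_error(error_config(independent_cv = -0.1), "nonnegative")
  expect_error(spectrum_config(aging_flatness = 2), "\\[0, 1\\]")
})
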