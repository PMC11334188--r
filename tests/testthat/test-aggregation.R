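test_that("repeat filtration selects the least-deviating repeat per well", {
  m <- build_linear_map()
  e <- error_config(measurement_noise_sd = 0.003, transient_prob = 0.3,
                    transient_scale = 0.6, transient_decay = 0.4, seed = 51)
  sim <- simulate_plate(m, error = e, n_repeats = 6)
  fp <- repeat_filtration(sim$readings, m, wavelength = 524)
  mod <- attr(fp, "model")

  # every selected value appears verbatim in some repeat
  vals <- vapply(sim$readings, function(rd) {
    rd$absorbance[match(m$well, rd$wells), which(rd$wavelength == 524)]
  }, numeric(96))
  expect_true(all(vapply(seq_len(96), function(i) {
    any(vals[i, ] == fp$selected_value[i])
  }, TRUE)))
  expect_identical(fp$selected_value,
                   vals[cbind(seq_len(96), fp$selected_repeat)])

  # plate RMSE-to-trend bound versus every single repeat
  r_f <- rmse_to_trend(fp, m, mod)
  for (k in seq_along(sim$readings)) {
    v <- stats::setNames(vals[, k], m$well)
    expect_lte(r_f, rmse_to_trend(v, m, mod) + 1e-12)
  }
})

test_that("filtration bound holds on arbitrary random inputs", {
  set.seed(77)
  m <- build_linear_map()
  for (case in 1:5) {
    n_rep <- sample(2:6, 1)
    base <- 2 * m$target_ratio + 0.05
    readings <- lapply(seq_len(n_rep), function(r) {
      a <- matrix(base + stats::rnorm(96, sd = 0.2), ncol = 1,
                  dimnames = list(m$well, 524))
      structure(list(wells = m$well, wavelength = 524, absorbance = a,
                     meta = list()), class = "plate_reading")
    })
    fp <- repeat_filtration(readings, m, wavelength = 524)
    mod <- attr(fp, "model")
    r_f <- rmse_to_trend(fp, m, mod)
    for (rd in readings) {
      v <- stats::setNames(rd$absorbance[, 1], m$well)
      expect_lte(r_f, rmse_to_trend(v, m, mod) + 1e-12)
    }
  }
})

test_that("identical repeats select repeat 1 everywhere", {
  fx <- ideal_linear()
  reps <- list(fx$reading, fx$reading, fx$reading)
  fp <- repeat_filtration(reps, fx$map, wavelength = 524)
  expect_true(all(fp$selected_repeat == 1L))
  expect_equal(fp$selected_value,
               unname(fx$reading$absorbance[match(fx$map$well,
                                                  fx$reading$wells),
                                            which(fx$reading$wavelength == 524)]))
})

test_that("single repeat passes through with a warning flag", {
  fx <- ideal_linear()
  expect_warning(fp <- repeat_filtration(list(fx$reading), fx$map, 524),
                 "single repeat")
  expect_true(attr(fp, "single_repeat"))
  expect_true(all(fp$selected_repeat == 1L))
})

test_that("iterative refiltration stabilizes", {
  m <- build_linear_map()
  e <- error_config(measurement_noise_sd = 0.003, transient_prob = 0.3,
                    transient_scale = 0.6, transient_decay = 0.4, seed = 52)
  sim <- simulate_plate(m, error = e, n_repeats = 5)
  f1 <- repeat_filtration(sim$readings, m, 524, iterate = FALSE)
  f2 <- repeat_filtration(sim$readings, m, 524, iterate = TRUE)
  expect_identical(nrow(f2), 96L)
  # iterated trend should fit its own selection at least as well
  expect_lte(rmse_to_trend(f2, m, attr(f2, "model")),
             rmse_to_trend(f1, m, attr(f2, "model")) + 1e-12)
})

test_that("combine_runs converts ratios to absolute concentrations", {
  pts <- combine_runs(
    list(r1 = data.frame(well = c("A1", "A11"), target = c(0.5, 0),
                         value = c(1, 0.04))),
    list(run_metadata("r1", c0 = 0.5, working_factor = 4 / 100)))
  expect_equal(pts$concentration, c(0.01, 0))
  # two runs with disjoint ranges concatenate
  two <- combine_runs(
    list(lo = data.frame(well = "A1", target = 1, value = 1),
         hi = data.frame(well = "A1", target = 1, value = 2)),
    list(run_metadata("lo", 0.5, 0.01), run_metadata("hi", 0.5, 0.04)))
  expect_identical(nrow(two), 2L)
  expect_error(
    combine_runs(list(x = data.frame(well = "A1", target = 1, value = 1)),
                 list(run_metadata("other", 0.5, 0.1))),
    "missing metadata for run x")
})

test_that("calibration recovers a noiseless generative line exactly", {
  fx <- ideal_linear()
  raw <- data.frame(well = fx$map$well, target = fx$map$target_ratio,
                    value = fx$reading$absorbance[
                      match(fx$map$well, fx$reading$wells),
                      which(fx$reading$wavelength == 524)])
  pts <- combine_runs(list(r1 = raw),
                      list(run_metadata("r1", c0 = 0.5,
                                        working_factor = 4 / 100)))
  cal <- build_calibration(pts, degree = 1, robust = FALSE)
  # generative: OD = S(524) * ratio + B(524); ratio = conc / (c0 * wf)
  s524 <- solute_spectrum(spectrum_config())[
    spectrum_config()$wavelength_grid == 524]
  b524 <- baseline_spectrum(spectrum_config())[
    spectrum_config()$wavelength_grid == 524]
  expect_equal(unname(coef(cal)["b"]), s524 / (0.5 * 0.04), tolerance = 1e-9)
  expect_equal(unname(coef(cal)["c"]), b524, tolerance = 1e-9)
  expect_lt(cal$metrics$rmse, 1e-9)
  expect_equal(cal$metrics$pearson, 1, tolerance = 1e-9)
})

test_that("calibration coefficients are invariant to point order and run tags", {
  set.seed(61)
  pts <- data.frame(run_id = rep(c("a", "b"), each = 20),
                    concentration = rep(seq(0.001, 0.02, length.out = 20), 2),
                    value = NA)
  pts$value <- 7 * pts$concentration + 0.03 +
    stats::rnorm(nrow(pts), sd = 0.002)
  c1 <- build_calibration(pts)
  pts2 <- pts[sample(nrow(pts)), ]
  pts2$run_id <- rev(pts2$run_id)
  c2 <- build_calibration(pts2)
  expect_equal(coef(c1), coef(c2), tolerance = 1e-9)
  expect_error(build_calibration(data.frame(concentration = c(-1, 1, 2),
                                            value = 1:3)),
               "nonnegative")
})

test_that("filtered and median aggregation agree under symmetric excursion-free noise", {
  m <- build_linear_map()
  diffs <- vapply(1:10, function(s) {
    e <- error_config(measurement_noise_sd = 0.004, seed = s)
    sim <- simulate_plate(m, error = e, n_repeats = 7)
    vals <- vapply(sim$readings, function(rd) {
      rd$absorbance[match(m$well, rd$wells), which(rd$wavelength == 524)]
    }, numeric(96))
    fp <- repeat_filtration(sim$readings, m, 524)
    med <- apply(vals, 1, stats::median)
    mod <- attr(fp, "model")
    rmse_to_trend(fp, m, mod) -
      rmse_to_trend(stats::setNames(med, m$well), m, mod)
  }, 0)
  # same order of magnitude: difference within Monte-Carlo error of zero
  expect_lt(abs(mean(diffs)), 0.002)
})
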