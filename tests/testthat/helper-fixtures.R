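# shared simulation fixtures; everything is generated in code

ideal_linear <- function() {
  m <- build_linear_map()
  sim <- simulate_plate(m)
  list(map = m, plate = sim$plate, reading = sim$readings[[1]])
}

noisy_linear <- function(seed, ..., n_repeats = 1L) {
  m <- build_linear_map()
  e <- error_config(independent_cv = 0.01, measurement_noise_sd = 0.002,
                    seed = seed, ...)
  sim <- simulate_plate(m, error = e, n_repeats = n_repeats)
  list(map = m, plate = sim$plate, readings = sim$readings,
       reading = sim$readings[[1]])
}

gen_spectrum_normalized <- function(sc = spectrum_config()) {
  s <- solute_spectrum(sc)
  s / s[which.max(s)]
}
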