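#' Solute spectrum and baseline configuration
#'
#' Defaults emulate a fresh carotenoid-like solute with the characteristic
#' three-peak visible spectrum (peaks at 458, 488, 524 nm; the 524 nm peak is
#' the tallest) on the standard 350-650 nm scan grid with 2 nm steps.
#' `aging_flatness` mixes the peaked spectrum toward a smooth, monotone,
#' scattering-like background, mimicking aged mixes that lose their
#' distinctive peaks through aggregation: 0 leaves the peaks untouched, 1
#' yields an entirely peak-free spectrum.
#'
#' @param wavelength_grid scan wavelengths in nm (strictly increasing).
#' @param peaks list of `c(center_nm, width_nm, height)` triplets (Gaussian
#'   components, heights in OD at the undiluted stock).
#' @param aging_flatness fraction in \[0, 1\] mixing toward the aged
#'   background.
#' @param baseline_level mean blank absorbance (OD).
#' @param baseline_tilt total linear change of the baseline across the scan
#'   window (OD; negative = higher baseline at short wavelengths).
#' @return a `spectrum_config` list.
#' @export
spectrum_config <- function(wavelength_grid = seq(350, 650, by = 2),
                            peaks = list(c(458, 10, 0.70),
                                         c(488, 10, 0.95),
                                         c(524, 10, 1.00)),
                            aging_flatness = 0,
                            baseline_level = 0.04,
                            baseline_tilt = -0.01) {
  if (any(diff(wavelength_grid) <= 0)) {
    stop("`wavelength_grid` must be strictly increasing", call. = FALSE)
  }
  heights <- vapply(peaks, `[`, 0, 3L)
  if (any(heights < 0)) stop("peak heights must be >= 0", call. = FALSE)
  if (aging_flatness < 0 || aging_flatness > 1) {
    stop("`aging_flatness` must be in [0, 1]", call. = FALSE)
  }
  structure(list(wavelength_grid = wavelength_grid, peaks = peaks,
                 aging_flatness = aging_flatness,
                 baseline_level = baseline_level,
                 baseline_tilt = baseline_tilt),
            class = "spectrum_config")
}

#' Evaluate the configured solute spectrum S and baseline B
#'
#' @param spectrum a [spectrum_config()].
#' @return `solute_spectrum`: numeric vector of S over the grid (OD at the
#'   undiluted stock); `baseline_spectrum`: the blank baseline B.
#' @export
solute_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_config"))
  wl <- spectrum$wavelength_grid
  s <- rep(0, length(wl))
  for (p in spectrum$peaks) s <- s + p[3L] * exp(-(wl - p[1L])^2 / (2 * p[2L]^2))
  a <- spectrum$aging_flatness
  if (a > 0) {
    h <- max(vapply(spectrum$peaks, `[`, 0, 3L), 0)
    # aggregates scatter: smooth monotone decay, no interior local maxima
    aged <- h * exp(-(wl - wl[1L]) / 180)
    s <- (1 - a) * s + a * aged
  }
  s
}

#' @rdname solute_spectrum
#' @export
baseline_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_config"))
  wl <- spectrum$wavelength_grid
  spectrum$baseline_level +
    spectrum$baseline_tilt * ((wl - wl[1L]) / (wl[length(wl)] - wl[1L]) - 0.5)
}

new_plate_reading <- function(absorbance, wavelength, wells,
                              meta = list()) {
  stopifnot(nrow(absorbance) == length(wells),
            ncol(absorbance) == length(wavelength),
            all(diff(wavelength) > 0), all(is.finite(absorbance)))
  dimnames(absorbance) <- list(wells, wavelength)
  structure(list(wells = wells, wavelength = wavelength,
                 absorbance = absorbance, meta = meta),
            class = "plate_reading")
}

#' @export
print.plate_reading <- function(x, ...) {
  cat(sprintf("plate reading: %d wells x %d wavelengths (%g-%g nm)\n",
              length(x$wells), length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  if (length(x$meta)) {
    keep <- !vapply(x$meta, is.null, TRUE)
    cat("  meta:", paste(names(x$meta)[keep], unlist(x$meta[keep]),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Render absorbance plates from a simulated composition
#'
#' Generates `n_repeats` technical-repeat readings of the plate. The
#' response is `A_i(lambda) = g(c_i) * S(lambda) * e_i + B(lambda) + noise`
#' with `g(c) = c / (1 + gamma * c)` (`gamma = curvature`; 0 gives
#' Beer-Lambert linearity) and `e_i` a per-well transient excursion factor.
#' Excursions trigger with probability `transient_prob` (weighted toward
#' high-concentration wells), perturb the solute signal multiplicatively, and
#' decay geometrically across repeats while remaining free to re-trigger -
#' emulating transient solubility events that regress toward the trend.
#'
#' @param composition a `simulated_plate` from [execute_instructions()].
#' @param spectrum a [spectrum_config()].
#' @param error an [error_config()] (measurement-side parameters:
#'   `measurement_noise_sd`, `curvature`, `transient_*`, `seed`).
#' @param n_repeats number of technical repeats to render.
#' @param run_id,plate_id,instrument_id metadata carried in each reading.
#' @return list of `plate_reading` objects (length `n_repeats`), each with
#'   `meta$repeat_index`.
#' @export
render_absorbance <- function(composition, spectrum = spectrum_config(),
                              error = error_config(), n_repeats = 1L,
                              run_id = "sim", plate_id = "01",
                              instrument_id = "SIM") {
  stopifnot(inherits(composition, "simulated_plate"),
            inherits(spectrum, "spectrum_config"),
            inherits(error, "error_config"), n_repeats >= 1L)
  wl <- spectrum$wavelength_grid
  s <- solute_spectrum(spectrum)
  b <- baseline_spectrum(spectrum)
  comp <- composition$composition
  cvec <- comp$true_ratio
  g <- cvec / (1 + error$curvature * cvec)

  set.seed(error$seed + 7919L)   # measurement stream, distinct from executor
  cmax <- max(cvec)
  excite <- if (cmax > 0) cvec / cmax else rep(0, length(cvec))
  m_exc <- rep(0, length(cvec))  # current excursion magnitude per well

  out <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    if (error$transient_prob > 0) {
      trig <- stats::runif(length(cvec)) < error$transient_prob * excite
      sign <- ifelse(stats::runif(length(cvec)) < 0.5, -1, 1)
      mag <- error$transient_scale * stats::runif(length(cvec), 0.5, 1.5)
      m_exc[trig] <- (sign * mag)[trig]
    } else {
      # keep the stream aligned whether or not excursions are enabled
      invisible(stats::runif(3L * length(cvec)))
    }
    e <- 1 + m_exc
    a <- outer(g * e, s) + matrix(b, nrow = length(cvec), ncol = length(wl),
                                  byrow = TRUE)
    if (error$measurement_noise_sd > 0) {
      a <- a + matrix(stats::rnorm(length(a), sd = error$measurement_noise_sd),
                      nrow = nrow(a))
    } else {
      invisible(stats::rnorm(length(a)))
    }
    out[[r]] <- new_plate_reading(
      a, wl, comp$well,
      meta = list(run_id = run_id, plate_id = plate_id,
                  instrument_id = instrument_id, repeat_index = r,
                  timestamp = NULL)
    )
    m_exc <- m_exc * error$transient_decay
  }
  out
}

#' One-call simulation of a measured plate
#'
#' Convenience wrapper: builds instructions for the map's scheme, executes
#' them under the error model, and renders the absorbance repeats.
#'
#' @inheritParams render_absorbance
#' @param map a `plate_map`.
#' @return list with `plate` (the `simulated_plate`) and `readings` (list of
#'   `plate_reading`).
#' @export
simulate_plate <- function(map, spectrum = spectrum_config(),
                           error = error_config(), n_repeats = 1L, ...) {
  inst <- if (identical(attr(map, "scheme"), "geometric")) {
    geometric_transfer_instructions(map)
  } else {
    linear_transfer_instructions(map)
  }
  plate <- execute_instructions(inst, map, error)
  readings <- render_absorbance(plate, spectrum, error, n_repeats, ...)
  list(plate = plate, readings = readings)
}
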