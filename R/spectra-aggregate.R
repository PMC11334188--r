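#' Aggregate normalized spectra and detect absorption peaks
#'
#' Averages normalized solute spectra from several inputs and locates the
#' absorption peaks. `spectrum_fit` inputs contribute their fitted solute
#' spectrum S; `plate_reading` inputs contribute the blank-subtracted mean
#' spectrum of their sample wells (plain mean spectrum if no map is given).
#' Each spectrum is normalized to 1 at `lambda_ref` (its maximum when
#' `NULL`) before averaging. Peaks are interior local maxima whose
#' topographic prominence exceeds `prominence` times the spectrum maximum,
#' separated by at least `min_separation` nm - defaults chosen to resolve a
#' carotenoid triplet some 30 nm apart at 2 nm sampling without reporting
#' noise wiggles. A flat spectrum yields zero peaks, not an error.
#'
#' @param x a single input or list of inputs (`spectrum_fit`,
#'   `plate_reading`, or bare numeric spectra over a shared grid).
#' @param map optional `plate_map` for blank subtraction of readings.
#' @param lambda_ref normalization wavelength (nm); `NULL` = per-spectrum
#'   maximum.
#' @param prominence minimum peak prominence as a fraction of the spectrum
#'   maximum (default 0.05).
#' @param min_separation minimum peak separation in nm (default 10).
#' @return a `spectrum_aggregate`: list with `wavelength`, `spectrum` (mean
#'   normalized), `peaks` (data frame `wavelength`, `height`), `n_spectra`.
#' @export
aggregate_spectrum <- function(x, map = NULL, lambda_ref = NULL,
                               prominence = 0.05, min_separation = 10) {
  if (!is.list(x) || inherits(x, c("spectrum_fit", "plate_reading"))) {
    x <- list(x)
  }
  stopifnot(length(x) >= 1L)
  extract <- function(obj) {
    if (inherits(obj, "spectrum_fit")) {
      return(list(wl = obj$wavelength, s = obj$S))
    }
    if (inherits(obj, "plate_reading")) {
      if (!is.null(map)) {
        samp <- match(map$well[map$role == "sample"], obj$wells)
        blk <- match(map$well[map$role == "blank"], obj$wells)
        s <- colMeans(obj$absorbance[samp, , drop = FALSE]) -
          colMeans(obj$absorbance[blk, , drop = FALSE])
      } else {
        s <- colMeans(obj$absorbance)
      }
      return(list(wl = obj$wavelength, s = as.numeric(s)))
    }
    stop("unsupported spectrum input", call. = FALSE)
  }
  parts <- lapply(x, extract)
  wl <- parts[[1L]]$wl
  for (p in parts) {
    if (!isTRUE(all.equal(p$wl, wl))) {
      stop("spectra do not share a wavelength grid", call. = FALSE)
    }
  }
  norm_one <- function(s) {
    ref <- if (is.null(lambda_ref)) which.max(s) else which.min(abs(wl - lambda_ref))
    if (abs(s[ref]) < .Machine$double.eps) return(s)   # flat/zero: leave as is
    s / s[ref]
  }
  mat <- vapply(parts, function(p) norm_one(p$s), numeric(length(wl)))
  spec <- rowMeans(mat)
  peaks <- find_spectrum_peaks(spec, wl, prominence = prominence,
                               min_separation = min_separation)
  structure(list(wavelength = wl, spectrum = spec, peaks = peaks,
                 n_spectra = length(parts), lambda_ref = lambda_ref),
            class = "spectrum_aggregate")
}

#' Locate peaks of a sampled spectrum by topographic prominence
#'
#' @param s numeric spectrum values.
#' @param wavelength matching grid in nm.
#' @param prominence minimum prominence as a fraction of `max(s)`.
#' @param min_separation minimum distance between reported peaks in nm.
#' @return data frame `wavelength`, `height`, `prominence`, sorted by
#'   height, possibly empty.
#' @export
find_spectrum_peaks <- function(s, wavelength, prominence = 0.05,
                                min_separation = 10) {
  n <- length(s)
  stopifnot(length(wavelength) == n)
  if (n < 3L || max(s) - min(s) <= .Machine$double.eps) {
    return(data.frame(wavelength = numeric(), height = numeric(),
                      prominence = numeric()))
  }
  is_max <- which(vapply(2:(n - 1L), function(i) {
    s[i] > s[i - 1L] && s[i] >= s[i + 1L]
  }, TRUE)) + 1L
  if (!length(is_max)) {
    return(data.frame(wavelength = numeric(), height = numeric(),
                      prominence = numeric()))
  }
  prom <- vapply(is_max, function(i) {
    # lowest saddle separating the peak from higher ground on each side
    left <- s[seq_len(i - 1L)]
    right <- s[seq((i + 1L), n)]
    higher_l <- which(left > s[i])
    higher_r <- which(right > s[i])
    min_l <- if (length(higher_l)) min(s[(max(higher_l) + 1L):(i - 1L)]) else min(left)
    min_r <- if (length(higher_r)) min(s[(i + 1L):(i + min(higher_r) - 1L)]) else min(right)
    s[i] - max(min_l, min_r)
  }, 0)
  keep <- prom >= prominence * max(s)
  pk <- data.frame(wavelength = wavelength[is_max][keep],
                   height = s[is_max][keep], prominence = prom[keep])
  pk <- pk[order(-pk$height), , drop = FALSE]
  # enforce minimum separation, keeping the tallest
  sel <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!any(sel & abs(pk$wavelength - pk$wavelength[i]) < min_separation)) {
      sel[i] <- TRUE
    }
  }
  pk <- pk[sel, , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' @export
print.spectrum_aggregate <- function(x, ...) {
  cat(sprintf("aggregate of %d spectra: %d peak(s)", x$n_spectra,
              nrow(x$peaks)))
  if (nrow(x$peaks)) {
    cat(" at", paste(sort(x$peaks$wavelength), collapse = ", "), "nm")
  }
  cat("\n")
  invisible(x)
}

#' Summarize spectral drift over a stability time series
#'
#' For a plate measured repeatedly over time, computes per timepoint the
#' Pearson similarity of the plate-mean spectrum to the first timepoint and
#' the retention of the main absorption peak (height at the t = 0 peak
#' wavelength relative to t = 0). Both are 1 at the first timepoint by
#' construction; aging (peak flattening) drives both down.
#'
#' @param time_series list of `plate_reading` objects on a shared grid,
#'   ordered in time.
#' @return a `drift_summary` data frame: `timepoint`, `similarity`,
#'   `peak_retention`.
#' @export
spectral_drift <- function(time_series) {
  stopifnot(is.list(time_series), length(time_series) >= 2L)
  wl <- time_series[[1L]]$wavelength
  means <- lapply(time_series, function(rd) {
    if (!isTRUE(all.equal(rd$wavelength, wl))) {
      stop("wavelength grid mismatch between timepoints", call. = FALSE)
    }
    colMeans(rd$absorbance)
  })
  ref <- means[[1L]]
  peak_idx <- which.max(ref)
  out <- data.frame(
    timepoint = seq_along(means),
    similarity = vapply(means, function(m) {
      suppressWarnings(stats::cor(m, ref))
    }, 0),
    peak_retention = vapply(means, function(m) m[peak_idx] / ref[peak_idx], 0)
  )
  class(out) <- c("drift_summary", "data.frame")
  out
}
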