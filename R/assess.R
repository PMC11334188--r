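# pull a per-well response vector out of a reading (at a wavelength) or a
# spectrum fit (the abundances), aligned to the map's well order
well_response <- function(x, map, wavelength = NULL) {
  if (inherits(x, "spectrum_fit")) {
    resp <- x$alpha[map$well]
    if (anyNA(resp)) stop("map wells missing from spectrum fit", call. = FALSE)
    return(as.numeric(resp))
  }
  stopifnot(inherits(x, "plate_reading"))
  if (is.null(wavelength)) stop("`wavelength` is required for a reading",
                                call. = FALSE)
  j <- which.min(abs(x$wavelength - wavelength))
  if (abs(x$wavelength[j] - wavelength) > diff(range(x$wavelength)) / 2) {
    stop("wavelength outside the reading's grid", call. = FALSE)
  }
  idx <- match(map$well, x$wells)
  if (anyNA(idx)) stop("map wells missing from reading", call. = FALSE)
  as.numeric(x$absorbance[idx, j])
}

#' Assess a plate: regression, inversion, residual and relative-error maps
#'
#' The three-step error-quantification workflow. Step 1 fits a response
#' model of the measurements (absorbance at a chosen wavelength, or the
#' spectrum-model abundances) on the targeted dilution ratios of the sample
#' wells. Step 2 inverts the model to estimate the realized ratio of every
#' well. Step 3 computes per-well residuals (estimated - targeted) and
#' relative errors (residual / target, defined only for sample wells), plus
#' global consistency metrics: Pearson and Spearman correlation between
#' estimated and targeted ratios, and the RMSE of estimated versus targeted
#' ratios (ratio scale). Blanks never enter the fit or the metrics; their
#' estimates are still reported.
#'
#' Internal-consistency metrics cannot see a systematic bias common to all
#' wells (the fit absorbs it); pass a reference `model` fitted on trusted
#' data to measure deviations from an external calibration instead.
#'
#' @param x a `plate_reading` or a `spectrum_fit`.
#' @param map the `plate_map`.
#' @param wavelength response wavelength in nm (ignored for a
#'   `spectrum_fit`).
#' @param degree,robust passed to [fit_response_model()].
#' @param model optional pre-fitted `response_model`; when supplied the
#'   plate is assessed against it rather than against its own fit.
#' @return a `plate_assessment`: list with `table` (per-well data frame:
#'   `well`, `target`, `response`, `estimated`, `residual`,
#'   `relative_error`, `out_of_range`, `failed`), `model`, and `metrics`
#'   (`pearson`, `spearman`, `rmse`, plus `pearson_response` /
#'   `spearman_response` computed on (response, target) pairs).
#' @export
assess_plate <- function(x, map, wavelength = 524, degree = 1L,
                         robust = FALSE, model = NULL) {
  stopifnot(inherits(map, "plate_map"))
  resp <- well_response(x, map, wavelength)
  samp <- map$role == "sample"
  if (length(unique(map$target_ratio[samp])) < 3L) {
    stop("need at least 3 distinct sample targets", call. = FALSE)
  }
  if (is.null(model)) {
    model <- fit_response_model(map$target_ratio[samp], resp[samp],
                                degree = degree, robust = robust)
  }
  est <- invert_model(model, resp, strict = FALSE)
  flags_oor <- attr(est, "out_of_range")
  flags_failed <- attr(est, "failed")
  est <- as.numeric(est)
  residual <- est - map$target_ratio
  rel <- ifelse(samp, residual / map$target_ratio, NA_real_)

  e <- est[samp]; t <- map$target_ratio[samp]
  ok <- is.finite(e)
  metrics <- list(
    pearson = suppressWarnings(stats::cor(e[ok], t[ok])),
    spearman = suppressWarnings(stats::cor(e[ok], t[ok], method = "spearman")),
    rmse = sqrt(mean((e[ok] - t[ok])^2)),
    pearson_response = suppressWarnings(stats::cor(resp[samp], t)),
    spearman_response = suppressWarnings(stats::cor(resp[samp], t,
                                                    method = "spearman"))
  )
  structure(
    list(table = data.frame(well = map$well, target = map$target_ratio,
                            response = resp, estimated = est,
                            residual = residual, relative_error = rel,
                            out_of_range = flags_oor, failed = flags_failed,
                            stringsAsFactors = FALSE),
         model = model, metrics = metrics),
    class = "plate_assessment"
  )
}

#' @export
print.plate_assessment <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("plate assessment: Pearson %.4f, Spearman %.4f, ",
                     "RMSE %.4f (estimated vs targeted ratios)\n"),
              m$pearson, m$spearman, m$rmse))
  n_flag <- sum(x$table$out_of_range | x$table$failed)
  if (n_flag) cat(sprintf("  %d well(s) flagged (out of range or failed)\n",
                          n_flag))
  invisible(x)
}

#' @export
summary.plate_assessment <- function(object, ...) {
  print(object)
  cat("\nrelative errors (sample wells):\n")
  print(summary(object$table$relative_error[!is.na(object$table$relative_error)]))
  invisible(object)
}

#' @export
as.data.frame.plate_assessment <- function(x, ...) x$table

#' Plate-shaped map of a per-well assessment quantity
#'
#' @param assessment a `plate_assessment`.
#' @param what column of the assessment table (default `"relative_error"`).
#' @return an 8 x 12 matrix in plate layout.
#' @export
error_map <- function(assessment, what = "relative_error") {
  stopifnot(inherits(assessment, "plate_assessment"))
  plate_matrix(stats::setNames(assessment$table[[what]],
                               assessment$table$well))
}

#' Estimate a systematic solute-transfer gain from assessed ratios
#'
#' In a direct (linear) dilution, a multiplicative bias `g` on the solute
#' volume yields a realized ratio `r' = g r / (g r + 1 - r)`; the mass
#' balance inverts exactly as `g = r' (1 - r) / (r (1 - r'))`. Averaging the
#' per-well implied gains over sample wells recovers the injected bias -
#' provided the estimated ratios come from an external (reference)
#' calibration, since a plate-internal fit absorbs the bias. Wells at
#' `r = 1` carry no information (their ratio is 1 for any gain) and are
#' dropped.
#'
#' @param assessment a `plate_assessment` (or a data frame with `target` and
#'   `estimated` columns).
#' @return list with `gain` (mean implied gain), `mean_relative_error` (mean
#'   of per-well relative volume errors, `gain - 1`), `n`.
#' @export
estimate_transfer_gain <- function(assessment) {
  tab <- if (inherits(assessment, "plate_assessment")) {
    assessment$table
  } else assessment
  r <- tab$target
  e <- tab$estimated
  keep <- is.finite(e) & r > 0 & r < 1 & e > 0 & e < 1
  g <- e[keep] * (1 - r[keep]) / (r[keep] * (1 - e[keep]))
  list(gain = mean(g), mean_relative_error = mean(g) - 1, n = sum(keep))
}

#' Per-wavelength correlation scan between targets and measurements
#'
#' For every wavelength of the scan, correlates the targeted dilution ratios
#' of the sample wells with the measured absorbance. Kendall's coefficient
#' is the tie-corrected tau-b. A phi-k metric is not implemented; requesting
#' it logs a note and omits the column. Wavelengths with constant
#' measurements yield `NA` (correlation undefined).
#'
#' @param reading a `plate_reading`.
#' @param map the `plate_map`.
#' @param metrics subset of `c("pearson", "spearman", "kendall", "phik")`.
#' @return a `correlation_scan` data frame: `wavelength` plus one column per
#'   computed metric, values in \[-1, 1\].
#' @export
correlation_scan <- function(reading, map,
                             metrics = c("pearson", "spearman", "kendall")) {
  stopifnot(inherits(reading, "plate_reading"), inherits(map, "plate_map"))
  metrics <- match.arg(metrics, c("pearson", "spearman", "kendall", "phik"),
                       several.ok = TRUE)
  if ("phik" %in% metrics) {
    message("phi-k correlation is not enabled in this build; omitting it")
    metrics <- setdiff(metrics, "phik")
  }
  samp <- map$role == "sample"
  if (length(unique(map$target_ratio[samp])) < 3L) {
    stop("need at least 3 distinct sample targets", call. = FALSE)
  }
  idx <- match(map$well[samp], reading$wells)
  m <- reading$absorbance[idx, , drop = FALSE]
  t <- map$target_ratio[samp]
  out <- data.frame(wavelength = reading$wavelength)
  for (met in metrics) {
    out[[met]] <- apply(m, 2L, function(col) {
      if (stats::sd(col) == 0) return(NA_real_)
      suppressWarnings(stats::cor(t, col, method = met))
    })
  }
  class(out) <- c("correlation_scan", "data.frame")
  out
}

#' Stratified column/row trend analysis with jump detection
#'
#' Fits a global response model over all sample wells and separate models
#' per column (or row) stratum, the diagnostic that exposes correlated
#' column-to-column transfer errors in serial dilutions. A stratum is
#' flagged as a "jump" when more than `jump_threshold` of its points fall
#' outside the global model's prediction band. Strata with fewer than 2
#' distinct targets are skipped with a note.
#'
#' The band's noise scale matters: a systematic column error inflates the
#' global fit's residual scale, so a band built from it masks the very
#' deviations it should expose. When the map carries replicate groups
#' (wells sharing a target, e.g. duplicated rows), the band therefore uses
#' the pure-error scale estimated from within-group scatter - the classic
#' lack-of-fit decomposition, immune to systematic misfit. Without
#' replicates it falls back to the regression residual scale.
#'
#' @param reading a `plate_reading`.
#' @param map the `plate_map`.
#' @param by `"column"` or `"row"`.
#' @param wavelength response wavelength in nm.
#' @param degree polynomial degree of the fits.
#' @param robust fit the global trend with the Huber M-estimator. An
#'   ordinary fit's prediction band is inflated by the very off-trend
#'   columns it is meant to expose (self-masking), so the robust trend is
#'   the recommended setting when screening for correlated transfer errors;
#'   the default `FALSE` reproduces the plain least-squares band.
#' @param level coverage of the global prediction band (default 0.95).
#' @param jump_threshold flagged when the outside fraction exceeds this
#'   (default 0.5).
#' @return a `stratified_trends` object: `global` (a `response_model`) and
#'   `strata` (data frame: `stratum`, `n`, `slope`, `intercept`,
#'   `frac_outside`, `flagged`, `skipped`).
#' @export
stratified_trends <- function(reading, map, by = c("column", "row"),
                              wavelength = 500, degree = 1L, robust = FALSE,
                              level = 0.95, jump_threshold = 0.5) {
  by <- match.arg(by)
  stopifnot(inherits(map, "plate_map"))
  resp <- well_response(reading, map, wavelength)
  samp <- which(map$role == "sample")
  t <- map$target_ratio[samp]
  y <- resp[samp]
  global <- fit_response_model(t, y, degree = degree, robust = robust)

  # pure-error scale from replicate groups (same target => same fitted value)
  grp <- map$replicate_group[samp]
  counts <- table(grp)
  rep_grps <- names(counts)[counts >= 2L]
  if (length(rep_grps)) {
    ss <- 0
    df <- 0L
    for (gname in rep_grps) {
      yi <- y[grp == gname]
      ss <- ss + sum((yi - mean(yi))^2)
      df <- df + length(yi) - 1L
    }
    sigma <- sqrt(ss / df)
    q <- stats::qt(1 - (1 - level) / 2, df)
  } else {
    sigma <- global$residual_scale
    q <- stats::qnorm(1 - (1 - level) / 2)
  }
  fit_global <- predict(global, t)
  # numerical floor so a noiseless plate has a zero- but not empty-width band
  floor_w <- sqrt(.Machine$double.eps) * max(abs(y), 1)
  outside <- abs(y - fit_global) > max(q * sigma, floor_w)

  key <- if (by == "column") map$column[samp] else map$row[samp]
  strata <- sort(unique(key))
  rows <- lapply(strata, function(s) {
    in_s <- key == s
    skipped <- length(unique(t[in_s])) < 2L
    slope <- intercept <- NA_real_
    if (!skipped && length(unique(t[in_s])) >= 2L) {
      sf <- stats::lm(y[in_s] ~ t[in_s])
      slope <- unname(stats::coef(sf)[2L])
      intercept <- unname(stats::coef(sf)[1L])
    }
    frac <- mean(outside[in_s])
    data.frame(stratum = as.character(s), n = sum(in_s), slope = slope,
               intercept = intercept, frac_outside = frac,
               flagged = !skipped & frac > jump_threshold,
               skipped = skipped, stringsAsFactors = FALSE)
  })
  structure(list(global = global, strata = do.call(rbind, rows),
                 by = by, level = level, jump_threshold = jump_threshold),
            class = "stratified_trends")
}

#' @export
print.stratified_trends <- function(x, ...) {
  flagged <- x$strata$stratum[x$strata$flagged]
  cat(sprintf("stratified trends by %s: %d strata, %d flagged",
              x$by, nrow(x$strata), length(flagged)))
  if (length(flagged)) cat(" (", paste(flagged, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}
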