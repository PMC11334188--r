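#' Repeat filtration: outlier-resistant aggregation of technical repeats
#'
#' Rather than averaging (suited to stationary noise), repeat filtration
#' targets transient excursions: a robust trendline is fitted on the pooled
#' (target, value) pairs of all repeats, and for each well the repeat whose
#' value deviates least from the trendline is kept (ties go to the lowest
#' repeat index). By construction the filtered plate's RMSE to the trend is
#' bounded above by that of every individual repeat. With `iterate = TRUE`
#' the trendline is refitted on the selected values and the selection
#' repeated until stable (at most 10 passes).
#'
#' @param repeats list of `plate_reading` objects sharing the map and grid.
#' @param map the `plate_map`.
#' @param wavelength response wavelength in nm.
#' @param degree,robust trendline fit parameters (robust Huber by default).
#' @param iterate refit-and-reselect until stable.
#' @return a `filtered_plate`: data frame (`well`, `target`,
#'   `selected_value`, `selected_repeat`, `deviation`, `n_repeats`) with the
#'   trend `response_model` in attribute `"model"`; attribute
#'   `"single_repeat"` is `TRUE` when only one repeat was supplied.
#' @export
repeat_filtration <- function(repeats, map, wavelength = 524, degree = 1L,
                              robust = TRUE, iterate = FALSE) {
  stopifnot(is.list(repeats), length(repeats) >= 1L,
            inherits(map, "plate_map"))
  vals <- vapply(repeats, well_response, numeric(96L), map = map,
                 wavelength = wavelength)   # 96 x n_repeats
  n_rep <- ncol(vals)
  samp <- map$role == "sample"
  single <- n_rep == 1L
  if (single) warning("single repeat supplied; returning it unchanged")

  fit_trend <- function(values) {
    fit_response_model(rep(map$target_ratio[samp], ncol(values)),
                       as.numeric(values[samp, , drop = FALSE]),
                       degree = degree, robust = robust)
  }
  select_with <- function(model) {
    trend <- predict(model, map$target_ratio)
    dev <- abs(vals - trend)                # 96 x n_repeats
    sel <- apply(dev, 1L, which.min)        # ties -> lowest index
    list(sel = sel, dev = dev[cbind(seq_len(96L), sel)])
  }

  model <- fit_trend(vals)
  s <- select_with(model)
  if (iterate && !single) {
    for (pass in 1:10) {
      model2 <- fit_response_model(map$target_ratio[samp],
                                   vals[cbind(seq_len(96L), s$sel)][samp],
                                   degree = degree, robust = robust)
      s2 <- select_with(model2)
      stable <- identical(s2$sel, s$sel)
      model <- model2
      s <- s2
      if (stable) break
    }
  }
  out <- data.frame(
    well = map$well, target = map$target_ratio,
    selected_value = vals[cbind(seq_len(96L), s$sel)],
    selected_repeat = s$sel, deviation = s$dev,
    n_repeats = n_rep, stringsAsFactors = FALSE
  )
  structure(out, model = model, single_repeat = single,
            class = c("filtered_plate", "data.frame"))
}

#' RMSE of plate values to a trendline
#'
#' @param values named per-well values (or a `filtered_plate`).
#' @param map the `plate_map`.
#' @param model a `response_model` trendline.
#' @return root-mean-square deviation over sample wells.
#' @export
rmse_to_trend <- function(values, map, model) {
  if (inherits(values, "filtered_plate")) {
    v <- stats::setNames(values$selected_value, values$well)
  } else v <- values
  samp <- map$role == "sample"
  trend <- predict(model, map$target_ratio[samp])
  sqrt(mean((as.numeric(v[map$well[samp]]) - trend)^2))
}

#' Per-run metadata for concentration bookkeeping
#'
#' The absolute concentration of a well is
#' `C_0 * working_factor * target_ratio`: the stock concentration times the
#' working-mix dilution factor (e.g. 1/10 for a low-concentration mix, 4/100
#' for a high-concentration mix) times the well's dilution ratio.
#'
#' @param run_id run identifier.
#' @param c0 stock concentration in mg/mL.
#' @param working_factor dilution factor of the working mix.
#' @param instrument_id,mix_age_days optional provenance fields.
#' @return a `run_metadata` list.
#' @export
run_metadata <- function(run_id, c0, working_factor,
                         instrument_id = NA_character_,
                         mix_age_days = NA_real_) {
  stopifnot(c0 >= 0, working_factor > 0)
  structure(list(run_id = as.character(run_id), c0 = c0,
                 working_factor = working_factor,
                 instrument_id = instrument_id, mix_age_days = mix_age_days),
            class = "run_metadata")
}

#' Pool runs into absolute-concentration calibration points
#'
#' Converts each run's per-well dilution ratios to absolute concentrations
#' via its [run_metadata()] and concatenates (concentration, value) points
#' tagged by run. Accepts `filtered_plate` objects (uses the selected
#' values) or data frames with `target` and a value column.
#'
#' @param runs named list of per-run data (`filtered_plate` or data frame
#'   with columns `well`, `target` and `selected_value`/`value`/`response`).
#' @param metadata list of [run_metadata()], one per run (matched by
#'   `run_id` or by position).
#' @return data frame `run_id`, `well`, `concentration`, `value`.
#' @export
combine_runs <- function(runs, metadata) {
  stopifnot(is.list(runs), is.list(metadata))
  if (inherits(metadata, "run_metadata")) metadata <- list(metadata)
  meta_ids <- vapply(metadata, function(m) m$run_id, "")
  run_ids <- names(runs)
  if (is.null(run_ids)) run_ids <- meta_ids[seq_along(runs)]
  pooled <- lapply(seq_along(runs), function(i) {
    id <- run_ids[i]
    j <- match(id, meta_ids)
    if (is.na(j)) {
      stop("missing metadata for run ", id, call. = FALSE)
    }
    md <- metadata[[j]]
    r <- runs[[i]]
    value_col <- intersect(c("selected_value", "value", "response"), names(r))
    if (!length(value_col)) {
      stop("run ", id, " carries no value column", call. = FALSE)
    }
    data.frame(run_id = id, well = r$well,
               concentration = md$c0 * md$working_factor * r$target,
               value = r[[value_col[1L]]], stringsAsFactors = FALSE)
  })
  do.call(rbind, pooled)
}

#' Build the final calibration curve from pooled points
#'
#' Fits the calibration model `OD = f(concentration)` (degree 1 and/or 2,
#' robust Huber regression by default) on the pooled points and reports the
#' coefficients together with Pearson/Spearman correlation and RMSE of
#' inverted (estimated) versus nominal concentrations.
#'
#' @param points data frame with `concentration` and `value` columns (from
#'   [combine_runs()]).
#' @param degree 1 or 2.
#' @param robust use Huber regression (default `TRUE`).
#' @param wavelength response wavelength recorded in the curve (metadata).
#' @return a `calibration_curve`: list with `model` (a `response_model`),
#'   `points`, `metrics` (`pearson`, `spearman`, `rmse`), `wavelength`.
#' @export
build_calibration <- function(points, degree = 1L, robust = TRUE,
                              wavelength = NA_real_) {
  stopifnot(all(c("concentration", "value") %in% names(points)))
  if (any(points$concentration < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  if (length(unique(points$concentration)) < 3L) {
    stop("fit error: need at least 3 distinct concentrations", call. = FALSE)
  }
  model <- fit_response_model(points$concentration, points$value,
                              degree = degree, robust = robust)
  est <- as.numeric(invert_model(model, points$value, strict = FALSE))
  ok <- is.finite(est)
  metrics <- list(
    pearson = suppressWarnings(stats::cor(est[ok], points$concentration[ok])),
    spearman = suppressWarnings(stats::cor(est[ok], points$concentration[ok],
                                           method = "spearman")),
    rmse = sqrt(mean((est[ok] - points$concentration[ok])^2))
  )
  structure(list(model = model, points = points, metrics = metrics,
                 wavelength = wavelength),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cf <- coef(x$model)
  cat("calibration curve",
      if (!is.na(x$wavelength)) sprintf("at %g nm", x$wavelength), "\n")
  if (x$model$degree == 2L) {
    cat(sprintf("  quadratic model: f(X) = a X^2 + b X + c;  a = %.4f; b = %.4f; c = %.4f\n",
                cf["a"], cf["b"], cf["c"]))
  } else {
    cat(sprintf("  linear model: f(X) = b X + c;  b = %.4f; c = %.4f\n",
                cf["b"], cf["c"]))
  }
  cat(sprintf("  Pearson %.4f | Spearman %.4f | RMSE %.4f\n",
              x$metrics$pearson, x$metrics$spearman, x$metrics$rmse))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) coef(object$model)

#' @export
predict.calibration_curve <- function(object, newdata = NULL, ...) {
  predict(object$model, newdata, ...)
}

#' @export
plot.calibration_curve <- function(x, ...) {
  graphics::plot(x$points$concentration, x$points$value,
                 xlab = "concentration (mg/mL)", ylab = "OD", ...)
  xs <- seq(0, max(x$points$concentration), length.out = 200)
  graphics::lines(xs, predict(x$model, xs), col = "firebrick", lwd = 2)
  invisible(x)
}
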