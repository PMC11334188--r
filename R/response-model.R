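#' Fit a response model of measurement on dilution ratio or concentration
#'
#' The workhorse regression of the toolkit: a degree-1 (affine) or degree-2
#' (quadratic, to capture saturation curvature) model
#' `f(X) = a X^2 + b X + c` of a response (absorbance at a wavelength, or
#' spectrum-model abundance) on the targeted dilution ratio or absolute
#' concentration. Ordinary least squares by default; with `robust = TRUE`
#' the fit is iteratively reweighted least squares with Huber weights
#' (tuning constant 1.345, scale by median absolute deviation), which
#' down-weights outlying wells.
#'
#' @param x numeric predictor (target dilution ratios or concentrations);
#'   at least 3 distinct values.
#' @param y numeric response, same length as `x`.
#' @param degree 1 or 2.
#' @param robust logical; use a Huber M-estimator instead of OLS.
#' @return a `response_model` object with components `coefficients`
#'   (`a`, `b`, `c`), `degree`, `robust`, `residual_scale`, `fit` (the
#'   underlying `lm`/`rlm`), `x_range`.
#' @seealso [invert_model()], [assess_plate()], [build_calibration()]
#' @examples
#' x <- seq(0, 1, 0.05)
#' fm <- fit_response_model(x, 2 * x + 0.03)
#' coef(fm)
#' @export
fit_response_model <- function(x, y, degree = 1L, robust = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 3L) {
    stop("fit error: need at least 3 distinct x values", call. = FALSE)
  }
  if (!degree %in% c(1L, 2L)) stop("`degree` must be 1 or 2", call. = FALSE)
  dat <- data.frame(x = x, y = y)
  fml <- if (degree == 1L) y ~ x else y ~ x + I(x^2)
  fit <- if (robust) {
    MASS::rlm(fml, data = dat, psi = MASS::psi.huber, k = 1.345,
              scale.est = "MAD", maxit = 100)
  } else {
    stats::lm(fml, data = dat)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("fit error: rank-deficient design", call. = FALSE)
  coefs <- c(a = if (degree == 2L) unname(cf[["I(x^2)"]]) else 0,
             b = unname(cf[["x"]]),
             c = unname(cf[["(Intercept)"]]))
  scale <- if (robust) fit$s else stats::sigma(fit)
  structure(
    list(coefficients = coefs, degree = as.integer(degree), robust = robust,
         residual_scale = scale, fit = fit, x_range = range(x),
         n = length(x)),
    class = "response_model"
  )
}

#' @export
coef.response_model <- function(object, ...) object$coefficients

#' Evaluate a response model, optionally with interval bounds
#'
#' @param object a `response_model`.
#' @param newdata numeric vector of predictor values (default: the fitted x).
#' @param interval `"none"`, `"prediction"`, or `"confidence"`. For robust
#'   fits the interval is a normal approximation `fit +/- z * scale`
#'   (prediction) since the M-estimator carries no closed-form band.
#' @param level coverage for intervals (default 0.95).
#' @param ... unused.
#' @return numeric vector of fitted values, or a matrix with columns
#'   `fit`, `lwr`, `upr`.
#' @export
predict.response_model <- function(object, newdata = NULL,
                                   interval = c("none", "prediction",
                                                "confidence"),
                                   level = 0.95, ...) {
  interval <- match.arg(interval)
  if (is.null(newdata)) newdata <- object$fit$model$x
  nd <- data.frame(x = as.numeric(newdata))
  if (!object$robust && inherits(object$fit, "lm")) {
    if (interval == "none") {
      return(as.numeric(stats::predict(object$fit, nd)))
    }
    return(stats::predict(object$fit, nd, interval = interval, level = level))
  }
  cf <- object$coefficients
  fitv <- cf["a"] * nd$x^2 + cf["b"] * nd$x + cf["c"]
  if (interval == "none") return(as.numeric(fitv))
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * object$residual_scale * if (interval == "confidence") {
    1 / sqrt(object$n)
  } else 1
  cbind(fit = as.numeric(fitv), lwr = as.numeric(fitv - half),
        upr = as.numeric(fitv + half))
}

#' @export
residuals.response_model <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.response_model <- function(object, ...) stats::fitted(object$fit)

#' @export
print.response_model <- function(x, ...) {
  cf <- x$coefficients
  form <- if (x$degree == 2L) {
    sprintf("f(X) = %.5g X^2 + %.5g X + %.5g", cf["a"], cf["b"], cf["c"])
  } else {
    sprintf("f(X) = %.5g X + %.5g", cf["b"], cf["c"])
  }
  cat(sprintf("%s response model (degree %d): %s\n",
              if (x$robust) "robust (Huber)" else "least-squares",
              x$degree, form))
  cat(sprintf("  residual scale %.4g over %d points, x in [%.4g, %.4g]\n",
              x$residual_scale, x$n, x$x_range[1L], x$x_range[2L]))
  invisible(x)
}

#' @export
summary.response_model <- function(object, ...) {
  print(object)
  summary(object$fit)
}

#' @export
simulate.response_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  xv <- object$fit$model$x
  mu <- predict(object, xv)
  out <- as.data.frame(replicate(
    nsim, mu + stats::rnorm(length(mu), sd = object$residual_scale)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.response_model <- function(x, ...) {
  dat <- x$fit$model
  graphics::plot(dat$x, dat$y, xlab = "target ratio / concentration",
                 ylab = "response", ...)
  xs <- seq(x$x_range[1L], x$x_range[2L], length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "firebrick", lwd = 2)
  pb <- predict(x, xs, interval = "prediction")
  graphics::lines(xs, pb[, "lwr"], col = "firebrick", lty = 2)
  graphics::lines(xs, pb[, "upr"], col = "firebrick", lty = 2)
  invisible(x)
}

#' Invert a response model to estimate the dilution ratio or concentration
#'
#' Degree 1 inverts analytically as `(y - c) / b`. Degree 2 solves
#' `a x^2 + b x + (c - y) = 0` and selects the real root on the monotone
#' branch covering the calibration range `[0, x_max]`; non-monotone fitted
#' ranges are an error. Estimates outside `[-0.1, 1.1 * x_max]` are flagged
#' (attribute `"out_of_range"`), never clipped.
#'
#' @param model a `response_model`.
#' @param y numeric responses to invert.
#' @param strict if `TRUE` (default) an unsolvable inversion (zero slope, no
#'   real root on the valid branch) raises an error with context; if `FALSE`
#'   such entries become `NA` and are flagged.
#' @return numeric vector of estimates with logical attributes
#'   `"out_of_range"` and `"failed"`.
#' @examples
#' fm <- fit_response_model(seq(0, 1, 0.1), 2 * seq(0, 1, 0.1) + 1)
#' invert_model(fm, 2)   # 0.5
#' @export
invert_model <- function(model, y, strict = TRUE) {
  stopifnot(inherits(model, "response_model"))
  cf <- model$coefficients
  a <- cf[["a"]]; b <- cf[["b"]]; cc <- cf[["c"]]
  xmax <- max(model$x_range[2L], 0)

  if (model$degree == 1L || abs(a) < 1e-14) {
    if (abs(b) < 1e-14) {
      stop("inversion error: zero slope (b = 0), model is not invertible",
           call. = FALSE)
    }
    est <- (y - cc) / b
    failed <- rep(FALSE, length(est))
  } else {
    dfdx0 <- b
    dfdx1 <- 2 * a * xmax + b
    if (sign(dfdx0) != sign(dfdx1) || dfdx0 == 0) {
      stop("inversion error: fitted quadratic is not monotone over [0, ",
           signif(xmax, 4), "]; refusing to invert", call. = FALSE)
    }
    trend <- sign(dfdx0)
    est <- rep(NA_real_, length(y))
    failed <- rep(FALSE, length(y))
    disc <- b^2 - 4 * a * (cc - y)
    for (i in seq_along(y)) {
      if (disc[i] < 0) {
        failed[i] <- TRUE
        next
      }
      r <- (-b + c(-1, 1) * sqrt(disc[i])) / (2 * a)
      valid <- r[sign(2 * a * r + b) == trend | 2 * a * r + b == 0]
      if (!length(valid)) {
        failed[i] <- TRUE
        next
      }
      est[i] <- valid[which.min(abs(valid - xmax / 2))]
    }
    if (strict && any(failed)) {
      stop("inversion error: no real root on the monotone branch for ",
           sum(failed), " response value(s), e.g. y = ",
           signif(y[which(failed)[1L]], 5), call. = FALSE)
    }
  }
  out_of_range <- !is.na(est) & (est < -0.1 | est > 1.1 * xmax)
  structure(as.numeric(est), out_of_range = out_of_range, failed = failed)
}
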