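#' Fit the spectrum model: shared solute spectrum, baseline, abundances
#'
#' Decomposes a plate's absorbance matrix `M` (wells x wavelengths) as
#' `M[i, l] ~ alpha_i * S[l] + B[l]`, where `S` is the common solute
#' spectrum, `B` the plate baseline, and `alpha_i` the per-well abundance of
#' signal-producing solute - all constrained nonnegative. A quadratic
#' penalty `w * sum((B - blank_mean)^2)` anchors the baseline to the mean
#' spectrum of the blank wells. The objective
#'
#' \deqn{\sum_{i,\lambda} (M_{i\lambda} - \alpha_i S_\lambda - B_\lambda)^2
#'       + w \sum_\lambda (B_\lambda - \bar{m}_\lambda)^2}
#'
#' is minimised by alternating exact coordinate updates, each a clipped
#' closed-form least squares, so the objective is nonincreasing at every
#' step. After convergence `S` is normalized to 1 at a reference wavelength
#' (default: its maximum) and the abundances are rescaled compensatingly.
#'
#' @param reading a `plate_reading`.
#' @param map the matching `plate_map`; its blanks anchor the baseline.
#' @param wavelength_range optional `c(min, max)` in nm restricting the fit.
#' @param penalty_weight baseline penalty weight `w` (default 1).
#' @param tol relative objective change for convergence (default 1e-8).
#' @param max_iter maximum alternating cycles (default 500).
#' @param lambda_ref reference wavelength for the normalization of `S`;
#'   `NULL` picks the wavelength where `S` is largest.
#' @return a `spectrum_fit` object: `wavelength`, `S`, `B`, `alpha` (named by
#'   well), `lambda_ref`, `penalty_weight`, `objective`, `objective_trace`,
#'   `n_iter`, `converged`.
#' @export
fit_spectrum_model <- function(reading, map, wavelength_range = NULL,
                               penalty_weight = 1, tol = 1e-8,
                               max_iter = 500L, lambda_ref = NULL) {
  stopifnot(inherits(reading, "plate_reading"), inherits(map, "plate_map"))
  wl <- reading$wavelength
  keep <- rep(TRUE, length(wl))
  if (!is.null(wavelength_range)) {
    if (wavelength_range[1L] < min(wl) || wavelength_range[2L] > max(wl)) {
      stop("`wavelength_range` outside the reading's grid", call. = FALSE)
    }
    keep <- wl >= wavelength_range[1L] & wl <= wavelength_range[2L]
  }
  wl <- wl[keep]
  m <- reading$absorbance[, keep, drop = FALSE]
  idx <- match(map$well, reading$wells)
  if (anyNA(idx)) stop("map wells missing from reading", call. = FALSE)
  m <- m[idx, , drop = FALSE]

  blanks <- map$role == "blank"
  if (!any(blanks)) {
    stop("precondition error: the map must contain at least one blank well",
         call. = FALSE)
  }
  if (all(abs(m) < 1e-12)) {
    stop("degenerate-fit error: all-zero plate", call. = FALSE)
  }
  blank_mean <- colMeans(m[blanks, , drop = FALSE])
  n_wells <- nrow(m)
  w <- penalty_weight

  # warm start: baseline from blanks, S from the strongest well
  b <- blank_mean
  hi <- which.max(map$target_ratio)
  s <- pmax(m[hi, ] - b, 0)
  if (sum(s^2) == 0) s <- pmax(colMeans(m) - b, 1e-6)

  objective <- function(alpha, s, b) {
    resid <- m - outer(alpha, s) - matrix(b, n_wells, length(b), byrow = TRUE)
    sum(resid^2) + w * sum((b - blank_mean)^2)
  }
  update_alpha <- function(s, b) {
    ss <- sum(s^2)
    if (ss == 0) return(rep(0, n_wells))
    pmax(as.numeric((m - matrix(b, n_wells, length(b), byrow = TRUE)) %*% s) / ss, 0)
  }

  alpha <- update_alpha(s, b)
  trace <- objective(alpha, s, b)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    aa <- sum(alpha^2)
    if (aa > 0) {
      s <- pmax(as.numeric(crossprod(m - matrix(b, n_wells, length(b),
                                                byrow = TRUE), alpha)) / aa, 0)
    }
    trace <- c(trace, objective(alpha, s, b))
    b <- pmax((colSums(m - outer(alpha, s)) + w * blank_mean) / (n_wells + w), 0)
    trace <- c(trace, objective(alpha, s, b))
    alpha <- update_alpha(s, b)
    obj <- objective(alpha, s, b)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 3L]
    if (prev - obj <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  if (is.null(lambda_ref)) lambda_ref <- wl[which.max(s)]
  ref_idx <- which.min(abs(wl - lambda_ref))
  k <- s[ref_idx]
  if (k <= 0) {
    stop("degenerate-fit error: solute spectrum vanishes at the reference ",
         "wavelength", call. = FALSE)
  }
  s <- s / k
  alpha <- alpha * k

  structure(
    list(wavelength = wl, S = as.numeric(s), B = as.numeric(b),
         alpha = stats::setNames(alpha, map$well),
         lambda_ref = wl[ref_idx], penalty_weight = w,
         objective = trace[length(trace)], objective_trace = trace,
         n_iter = iter, converged = converged),
    class = "spectrum_fit"
  )
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf(paste0("spectrum model fit: %d wavelengths, %d wells\n",
                     "  S normalized to 1 at %g nm; objective %.6g after %d ",
                     "iterations (%s)\n"),
              length(x$wavelength), length(x$alpha), x$lambda_ref,
              x$objective, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.spectrum_fit <- function(object, ...) object$alpha

#' @export
fitted.spectrum_fit <- function(object, ...) {
  out <- outer(object$alpha, object$S) +
    matrix(object$B, length(object$alpha), length(object$B), byrow = TRUE)
  dimnames(out) <- list(names(object$alpha), object$wavelength)
  out
}

#' @export
plot.spectrum_fit <- function(x, ...) {
  graphics::matplot(x$wavelength, cbind(x$S, x$B), type = "l", lty = 1,
                    col = c("darkorange", "firebrick"),
                    xlab = "wavelength (nm)", ylab = "absorbance (normalized S)",
                    ...)
  graphics::legend("topright", c("S (solute)", "B (baseline)"), lty = 1,
                   col = c("darkorange", "firebrick"), bty = "n")
  invisible(x)
}
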