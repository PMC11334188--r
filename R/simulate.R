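#' Liquid-handling and measurement error configuration
#'
#' All parameters default to their "off" value, so the default configuration
#' is an ideal, deterministic executor. Magnitudes for real platforms are not
#' well characterised in the literature (vendors quote "a few microliters");
#' the suggested values given below are order-of-magnitude placeholders for
#' exploratory simulation, not measured quantities.
#'
#' @param independent_cv coefficient of variation of each transfer volume
#'   (independent Gaussian noise, sd = `independent_cv * volume`). Typical
#'   exploratory value 0.01-0.03.
#' @param constant_offset additive bias in microliters on every transfer.
#' @param systematic_gain multiplicative bias on all transfer volumes.
#' @param solute_gain multiplicative bias applied only to transfers sourced
#'   from the solute reservoir (e.g. 1.05 = solute volumes 5% too large).
#' @param reservoir_concentration_error relative error of the solute
#'   reservoir concentration (0.05 = 5% too concentrated).
#' @param carryover_excess microliters added to every column-to-column
#'   transfer (the correlated error class of serial dilution).
#' @param contamination_prob probability, per travel, that a droplet of the
#'   carried liquid falls into a random well.
#' @param droplet_volume droplet size in microliters for contamination.
#' @param transient_prob per-well, per-repeat trigger probability of a
#'   transient measurement excursion (weighted toward high-concentration
#'   wells, which are most affected by solubility issues).
#' @param transient_scale magnitude of a freshly triggered excursion
#'   (multiplicative, relative to the solute signal).
#' @param transient_decay geometric decay rate of the excursion across
#'   repeats (0 = vanishes after one repeat; values near 1 persist).
#' @param measurement_noise_sd absorbance noise sd per well and wavelength.
#' @param curvature dimensionless saturation parameter gamma of the response
#'   transform `g(c) = c / (1 + gamma * c)`; 0 gives Beer-Lambert linearity.
#' @param seed integer seed driving one global random stream; identical seed
#'   and configuration give bit-identical simulations.
#' @return an `error_config` list.
#' @export
error_config <- function(independent_cv = 0,
                         constant_offset = 0,
                         systematic_gain = 1,
                         solute_gain = 1,
                         reservoir_concentration_error = 0,
                         carryover_excess = 0,
                         contamination_prob = 0,
                         droplet_volume = 0.5,
                         transient_prob = 0,
                         transient_scale = 0.5,
                         transient_decay = 0.5,
                         measurement_noise_sd = 0,
                         curvature = 0,
                         seed = 1L) {
  cfg <- list(independent_cv = independent_cv,
              constant_offset = constant_offset,
              systematic_gain = systematic_gain,
              solute_gain = solute_gain,
              reservoir_concentration_error = reservoir_concentration_error,
              carryover_excess = carryover_excess,
              contamination_prob = contamination_prob,
              droplet_volume = droplet_volume,
              transient_prob = transient_prob,
              transient_scale = transient_scale,
              transient_decay = transient_decay,
              measurement_noise_sd = measurement_noise_sd,
              curvature = curvature,
              seed = as.integer(seed))
  for (p in c("contamination_prob", "transient_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop("`", p, "` must be in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$independent_cv < 0 || cfg$measurement_noise_sd < 0 ||
      cfg$droplet_volume < 0) {
    stop("noise magnitudes must be nonnegative", call. = FALSE)
  }
  structure(cfg, class = "error_config")
}

#' Execute a transfer-instruction list under an error model
#'
#' Simulates the liquid handler by exact bookkeeping of solute mass and total
#' volume per well. Each transfer volume `v` is perturbed to
#' `gain * v + N(0, (cv * v)^2) + offset`, clipped at zero; column-to-column
#' transfers additionally receive `carryover_excess`; with probability
#' `contamination_prob` per travel a droplet of the carried liquid lands in a
#' uniformly chosen well. Mixing in wells is assumed perfect. The realized
#' dilution ratio of a well is its solute mass divided by its volume, on a
#' scale where the nominal reservoir stock is 1.
#'
#' @param instructions an `instruction_list`.
#' @param map the `plate_map` the instructions were generated from.
#' @param error an [error_config()].
#' @return a `simulated_plate`: list with `composition` (data frame `well`,
#'   `volume_uL`, `solute_uL`, `true_ratio`, `target_ratio`), `volumes` (per
#'   instruction realized volume log), `map`, `error`.
#' @examples
#' m <- build_linear_map()
#' sp <- execute_instructions(linear_transfer_instructions(m), m)
#' all.equal(sp$composition$true_ratio, sp$composition$target_ratio)
#' @export
execute_instructions <- function(instructions, map, error = error_config()) {
  stopifnot(inherits(instructions, "instruction_list"),
            inherits(map, "plate_map"))
  stopifnot(inherits(error, "error_config"))
  wells <- plate_wells()
  vol <- stats::setNames(numeric(96L), wells)
  sol <- stats::setNames(numeric(96L), wells)
  stock <- 1 + error$reservoir_concentration_error

  set.seed(error$seed)
  n <- nrow(instructions)
  # fixed draws per instruction keep the stream aligned across config edits
  eps <- stats::rnorm(n)
  u_contam <- stats::runif(n)
  u_well <- stats::runif(n)

  realized <- numeric(n)
  for (i in seq_len(n)) {
    src <- instructions$source[i]
    dst <- instructions$destination[i]
    phase <- instructions$phase[i]
    v <- instructions$volume_uL[i]

    if (phase == "mix") {        # perfect in-well mixing: a no-op
      realized[i] <- v
      next
    }
    gain <- error$systematic_gain
    if (src == "solute_reservoir") gain <- gain * error$solute_gain
    vr <- gain * v + error$independent_cv * v * eps[i] + error$constant_offset
    if (phase == "column_transfer") vr <- vr + error$carryover_excess
    vr <- max(vr, 0)
    realized[i] <- vr

    if (src == "solvent_reservoir") {
      conc <- 0
    } else if (src == "solute_reservoir") {
      conc <- stock
    } else {
      sw <- normalize_well(src)
      if (vol[sw] - vr < -1e-9) {
        stop("simulation error: aspirating ", vr, " uL from well ", sw,
             " holding ", vol[sw], " uL", call. = FALSE)
      }
      conc <- if (vol[sw] > 0) sol[sw] / vol[sw] else 0
      sol[sw] <- sol[sw] - vr * conc
      vol[sw] <- max(vol[sw] - vr, 0)
    }

    carried <- vr
    if (error$contamination_prob > 0 && carried > 0 &&
        u_contam[i] < error$contamination_prob) {
      drop <- min(error$droplet_volume, carried)
      target <- wells[1L + floor(u_well[i] * 96) %% 96L]
      vol[target] <- vol[target] + drop
      sol[target] <- sol[target] + drop * conc
      carried <- carried - drop
    }
    if (dst != "discard") {
      dw <- normalize_well(dst)
      vol[dw] <- vol[dw] + carried
      sol[dw] <- sol[dw] + carried * conc
    }
  }

  ord <- match(map$well, wells)
  comp <- data.frame(
    well = map$well,
    volume_uL = as.numeric(vol[ord]),
    solute_uL = as.numeric(sol[ord]),
    true_ratio = ifelse(vol[ord] > 0, sol[ord] / vol[ord], 0),
    target_ratio = map$target_ratio,
    stringsAsFactors = FALSE
  )
  structure(
    list(composition = comp,
         volumes = data.frame(step = instructions$step,
                              phase = instructions$phase,
                              nominal_uL = instructions$volume_uL,
                              realized_uL = realized),
         map = map, error = error),
    class = "simulated_plate"
  )
}

#' @export
print.simulated_plate <- function(x, ...) {
  err <- x$composition$true_ratio - x$composition$target_ratio
  cat(sprintf("simulated %s plate: max |true - target| ratio = %.3g\n",
              attr(x$map, "scheme"), max(abs(err))))
  invisible(x)
}
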