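#' Transfer instructions for the linear (direct) dilution scheme
#'
#' Every well is filled straight from the two reservoirs: first the solvent
#' volume `(1 - ratio) * total_volume`, then the solute volume
#' `ratio * total_volume` (zero-volume transfers are omitted). Solvent is
#' dispensed across the whole plate before any solute, the safer order for a
#' staining solute. All reservoir-sourced volumes must be multiples of the
#' minimum safe increment.
#'
#' @param map a `plate_map` from [build_linear_map()] (any map whose wells can
#'   be reached by direct transfers works).
#' @param min_increment minimum safe transfer volume in microliters; every
#'   per-well volume must be an integer multiple of it (default 10).
#' @return an `instruction_list` data frame with columns `step`, `phase`,
#'   `source`, `destination`, `volume_uL`.
#' @examples
#' inst <- linear_transfer_instructions(build_linear_map())
#' head(inst)
#' @export
linear_transfer_instructions <- function(map, min_increment = 10) {
  stopifnot(inherits(map, "plate_map"))
  v_total <- attr(map, "total_volume")
  solute <- map$target_ratio * v_total
  solvent <- (1 - map$target_ratio) * v_total
  mult <- function(v) abs(v / min_increment - round(v / min_increment)) < 1e-9
  bad <- !(mult(solute) & mult(solvent))
  if (any(bad)) {
    stop("instruction error: volume not a multiple of ", min_increment,
         " uL for well(s) ", paste(map$well[bad], collapse = ", "),
         call. = FALSE)
  }
  # snap to the exact multiples the checks just certified
  solute <- round(solute / min_increment) * min_increment
  solvent <- round(solvent / min_increment) * min_increment
  rows <- list()
  for (i in seq_len(nrow(map))) {
    if (solvent[i] > 0) {
      rows[[length(rows) + 1L]] <- list(phase = "direct",
                                        source = "solvent_reservoir",
                                        destination = map$well[i],
                                        volume_uL = solvent[i])
    }
  }
  for (i in seq_len(nrow(map))) {
    if (solute[i] > 0) {
      rows[[length(rows) + 1L]] <- list(phase = "direct",
                                        source = "solute_reservoir",
                                        destination = map$well[i],
                                        volume_uL = solute[i])
    }
  }
  as_instruction_list(rows)
}

#' Transfer instructions for the geometric (serial) dilution scheme
#'
#' The serial mechanics are: prefill columns 2-10 with `V_p = total_volume`
#' of solvent; fill column 1 by direct dilution to `V_p + V_t` so it can seed
#' the series; transfer `V_t` column-to-column with in-well mixing, where
#' `V_t / (V_t + V_p) = 1/fold`; finally discard `V_t` from column 10 so all
#' wells end at `total_volume`. Blanks receive `total_volume` of solvent.
#'
#' @param map a `plate_map` from [build_geometric_map()].
#' @param transfer_volume optional column-to-column volume `V_t` in
#'   microliters; when supplied it must satisfy the fold equation, otherwise
#'   it is derived as `total_volume / (fold - 1)`.
#' @return an `instruction_list` data frame (see
#'   [linear_transfer_instructions()]); phases are `prefill`, `direct`,
#'   `column_transfer`, `mix`, `discard`.
#' @examples
#' inst <- geometric_transfer_instructions(build_geometric_map())
#' table(inst$phase)
#' @export
geometric_transfer_instructions <- function(map, transfer_volume = NULL) {
  stopifnot(inherits(map, "plate_map"))
  if (!identical(attr(map, "scheme"), "geometric")) {
    stop("configuration error: geometric instructions need a geometric map",
         call. = FALSE)
  }
  fold <- attr(map, "fold")
  if (is.null(fold) || fold <= 1) {
    stop("configuration error: dilution fold must be > 1", call. = FALSE)
  }
  v_p <- attr(map, "total_volume")
  v_t <- v_p / (fold - 1)
  if (!is.null(transfer_volume)) {
    if (abs(transfer_volume / (transfer_volume + v_p) - 1 / fold) > 1e-9) {
      stop("configuration error: transfer_volume ", transfer_volume,
           " uL does not realize a 1:", fold, " dilution with ", v_p,
           " uL prefill", call. = FALSE)
    }
    v_t <- transfer_volume
  }
  v1 <- v_p + v_t   # column-1 fill so the series ends at total_volume

  rows <- list()
  add <- function(phase, source, destination, volume) {
    rows[[length(rows) + 1L]] <<- list(phase = phase, source = source,
                                       destination = destination,
                                       volume_uL = volume)
  }
  # prefill columns 2-10 with solvent
  for (j in 2:10) {
    for (r in PLATE_ROWS) add("prefill", "solvent_reservoir", paste0(r, j), v_p)
  }
  # blanks: solvent only, final volume
  for (j in 11:12) {
    for (r in PLATE_ROWS) add("direct", "solvent_reservoir", paste0(r, j), v_p)
  }
  # column 1 by direct dilution at v1
  col1 <- map[map$column == 1L, ]
  for (i in seq_len(nrow(col1))) {
    solv <- (1 - col1$target_ratio[i]) * v1
    if (solv > 0) add("direct", "solvent_reservoir", col1$well[i], solv)
  }
  for (i in seq_len(nrow(col1))) {
    sol <- col1$target_ratio[i] * v1
    if (sol > 0) add("direct", "solute_reservoir", col1$well[i], sol)
  }
  # serial transfers with mixing
  for (j in 2:10) {
    for (r in PLATE_ROWS) {
      add("column_transfer", paste0(r, j - 1L), paste0(r, j), v_t)
      add("mix", paste0(r, j), paste0(r, j), v_p / 2)
    }
  }
  # discard the excess from column 10
  for (r in PLATE_ROWS) add("discard", paste0(r, 10L), "discard", v_t)
  as_instruction_list(rows)
}

as_instruction_list <- function(rows) {
  out <- data.frame(
    step = seq_along(rows),
    phase = vapply(rows, `[[`, "", "phase"),
    source = vapply(rows, `[[`, "", "source"),
    destination = vapply(rows, `[[`, "", "destination"),
    volume_uL = vapply(rows, `[[`, 0, "volume_uL"),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$volume_uL > 0))
  class(out) <- c("instruction_list", "data.frame")
  out
}

#' @export
print.instruction_list <- function(x, ...) {
  cat(sprintf("%d transfer instructions (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$phase)), table(x$phase)),
                    collapse = ", ")))
  print.data.frame(utils::head(x, 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}
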