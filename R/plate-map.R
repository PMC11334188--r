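#' Build the linear (direct) dilution plate map
#'
#' The linear scheme fills every well straight from a solute and a solvent
#' reservoir, so arbitrary dilution ratios can be produced with independent
#' errors. The built-in layout carries two identical blocks (columns 1-5 and
#' 6-10), each holding the 20 target ratios `1.00, 0.95, ..., 0.05` descending
#' top-to-bottom in column-major order, with technical repeats every other row
#' (rows A=B, C=D, E=F, G=H). Columns 11-12 are blanks (pure diluent,
#' ratio 0). Well A1 holds the undiluted standard.
#'
#' @param step dilution increment as a fraction (default 0.05). `1/step` must
#'   be an integer and the resulting value count must tile the 20-cell block.
#' @param total_volume final per-well volume in microliters (default 200).
#' @return a `plate_map` object: a data frame with one row per well
#'   (`well`, `row`, `column`, `role`, `target_ratio`, `block`,
#'   `replicate_group`) and attributes `scheme`, `total_volume`.
#' @examples
#' m <- build_linear_map()
#' subset(m, well %in% c("A1", "G5", "A11"))
#' @export
build_linear_map <- function(step = 0.05, total_volume = 200) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0 || step > 1) {
    stop("`step` must be a fraction in (0, 1]", call. = FALSE)
  }
  n_values <- 1 / step
  if (abs(n_values - round(n_values)) > 1e-9) {
    stop("configuration error: 1/step must be an integer (got step = ",
         step, ")", call. = FALSE)
  }
  n_values <- as.integer(round(n_values))
  cells_per_block <- 20L   # 4 distinct row-pairs x 5 columns
  if (cells_per_block %% n_values != 0L) {
    stop("configuration error: ", n_values,
         " ratio values do not evenly tile a 20-cell block", call. = FALSE)
  }
  if (total_volume <= 0) stop("`total_volume` must be positive", call. = FALSE)

  # round to the decimal targets (1.00, 0.95, ...) so ratios are the
  # closest doubles to their printed values and survive text round trips
  values <- round(1 - step * (seq_len(n_values) - 1L), 12)
  reps <- cells_per_block %/% n_values
  block_values <- rep(values, each = reps)        # length 20, column-major fill

  map <- empty_map(total_volume)
  for (block in 1:2) {
    cols <- (block - 1L) * 5L + 1:5
    for (j in seq_along(cols)) {
      for (r in 1:4) {                            # distinct rows A,C,E,G
        val <- block_values[(j - 1L) * 4L + r]
        rows <- PLATE_ROWS[c(2L * r - 1L, 2L * r)]
        idx <- map$row %in% rows & map$column == cols[j]
        map$role[idx] <- "sample"
        map$target_ratio[idx] <- val
        map$block[idx] <- block
      }
    }
  }
  finish_map(map, scheme = "linear", total_volume = total_volume)
}

#' Build the geometric (serial) dilution plate map
#'
#' The geometric scheme creates column 1 by direct dilution (rows A, C, E, G
#' take `first_column`, duplicated in rows B, D, F, H) and then dilutes
#' column-to-column by a fixed fold, so column j holds column j-1 divided by
#' `fold`. Columns 11-12 are blanks. Errors in the column-to-column transfer
#' propagate and compound along the series.
#'
#' @param first_column fractions of the stock concentration for the four
#'   distinct rows of column 1; must lie in (0, 1] and be strictly decreasing.
#'   Default `c(1, 7/8, 3/4, 5/8)`.
#' @param fold dilution fold between adjacent columns (> 1; default 2,
#'   i.e. a 1:2 serial dilution).
#' @inheritParams build_linear_map
#' @return a `plate_map` object (see [build_linear_map()]); attribute `fold`
#'   records the dilution fold.
#' @examples
#' m <- build_geometric_map()
#' subset(m, well %in% c("A1", "C1", "A2", "A10"))
#' @export
build_geometric_map <- function(first_column = c(1, 7 / 8, 3 / 4, 5 / 8),
                                fold = 2, total_volume = 200) {
  if (length(first_column) != 4L || any(first_column <= 0) ||
      any(first_column > 1)) {
    stop("`first_column` must be 4 fractions in (0, 1]", call. = FALSE)
  }
  if (any(diff(first_column) >= 0)) {
    stop("configuration error: `first_column` must be strictly decreasing",
         call. = FALSE)
  }
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 1) {
    stop("configuration error: `fold` must be > 1", call. = FALSE)
  }
  if (total_volume <= 0) stop("`total_volume` must be positive", call. = FALSE)

  map <- empty_map(total_volume)
  for (r in 1:4) {
    rows <- PLATE_ROWS[c(2L * r - 1L, 2L * r)]
    for (j in 1:10) {
      val <- first_column[r] / fold^(j - 1L)
      idx <- map$row %in% rows & map$column == j
      map$role[idx] <- "sample"
      map$target_ratio[idx] <- val
    }
  }
  out <- finish_map(map, scheme = "geometric", total_volume = total_volume)
  attr(out, "fold") <- fold
  out
}

empty_map <- function(total_volume) {
  wells <- plate_wells()
  data.frame(
    well = wells,
    row = substr(wells, 1L, 1L),
    column = as.integer(substring(wells, 2L)),
    role = "blank",
    target_ratio = 0,
    block = NA_integer_,
    stringsAsFactors = FALSE
  )
}

finish_map <- function(map, scheme, total_volume) {
  stopifnot(nrow(map) == 96L, !anyDuplicated(map$well))
  ratios <- sort(unique(map$target_ratio), decreasing = TRUE)
  map$replicate_group <- match(map$target_ratio, ratios)
  structure(
    map,
    scheme = scheme,
    total_volume = total_volume,
    n_sample_wells = sum(map$role == "sample"),
    class = c("plate_map", "data.frame")
  )
}

#' @export
print.plate_map <- function(x, ...) {
  cat(sprintf("96-well plate map: %s dilution scheme\n", attr(x, "scheme")))
  cat(sprintf("  %d sample wells, %d blanks; %g uL per well\n",
              attr(x, "n_sample_wells"), sum(x$role == "blank"),
              attr(x, "total_volume")))
  cat(sprintf("  %d distinct nonzero target ratios in [%.4g, %.4g]\n",
              length(unique(x$target_ratio[x$role == "sample"])),
              min(x$target_ratio[x$role == "sample"]),
              max(x$target_ratio[x$role == "sample"])))
  invisible(x)
}

#' Lay out a per-well quantity as an 8 x 12 plate matrix
#'
#' @param values named numeric vector (names are well addresses) or a data
#'   frame with columns `well` and `value`.
#' @return an 8 x 12 matrix with row names A-H and column names 1-12.
#' @export
plate_matrix <- function(values) {
  if (is.data.frame(values)) {
    v <- values$value
    names(v) <- values$well
    values <- v
  }
  out <- matrix(NA_real_, 8L, 12L, dimnames = list(PLATE_ROWS, PLATE_COLS))
  w <- normalize_well(names(values))
  out[cbind(substr(w, 1, 1), substring(w, 2))] <- as.numeric(values)
  out
}
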