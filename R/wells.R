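#' @keywords internal
PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

#' Normalize and validate 96-well addresses
#'
#' Accepts addresses like `"A1"` or zero-padded `"A01"` and returns the
#' canonical unpadded form (`"A1"`..`"H12"`). Rows run A-H, columns 1-12.
#'
#' @param x character vector of well addresses.
#' @return character vector of canonical addresses.
#' @examples
#' normalize_well(c("A01", "h12"))
#' @export
normalize_well <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([A-H])0*([1-9][0-9]?)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("invalid well address(es): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col > 12L)) {
    stop("invalid well address(es): column out of 1-12 range: ",
         paste(unique(x[col > 12L]), collapse = ", "), call. = FALSE)
  }
  paste0(row, col)
}

#' @rdname normalize_well
#' @export
well_row <- function(x) substr(normalize_well(x), 1L, 1L)

#' @rdname normalize_well
#' @export
well_col <- function(x) {
  x <- normalize_well(x)
  as.integer(substr(x, 2L, nchar(x)))
}

# all 96 addresses in row-major order (A1..A12, B1..)
plate_wells <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}
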