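#' Read a plate reading from CSV
#'
#' Two dialects are supported. Wide: first column `well`, remaining headers
#' integer wavelengths in nm, cells absorbance. Long: columns `well`,
#' `wavelength_nm`, `absorbance`. Well IDs are normalized (`"A01"` ->
#' `"A1"`); the wavelength grid must be strictly increasing and all cells
#' numeric. A metadata sidecar JSON (same path with extension `.json`) is
#' read when present.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (default), `"wide"`, or `"long"`.
#' @return a `plate_reading`.
#' @export
read_plate_reading <- function(path, dialect = c("auto", "wide", "long")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "auto") {
    dialect <- if (all(c("wavelength_nm", "absorbance") %in% names(df))) {
      "long"
    } else "wide"
  }
  if (dialect == "long") {
    need <- c("well", "wavelength_nm", "absorbance")
    if (!all(need %in% names(df))) {
      stop("parse error: long dialect needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    df$well <- normalize_well(df$well)
    wl <- sort(unique(df$wavelength_nm))
    wells <- unique(df$well)
    if (nrow(df) != length(wl) * length(wells)) {
      stop("parse error: incomplete well x wavelength grid", call. = FALSE)
    }
    if (!is.numeric(df$absorbance)) {
      stop("parse error: non-numeric absorbance values", call. = FALSE)
    }
    m <- matrix(NA_real_, length(wells), length(wl),
                dimnames = list(wells, wl))
    m[cbind(match(df$well, wells), match(df$wavelength_nm, wl))] <-
      df$absorbance
    if (anyNA(m)) stop("parse error: duplicated or missing cells",
                       call. = FALSE)
  } else {
    if (names(df)[1L] != "well") {
      stop("parse error: wide dialect needs `well` as first column",
           call. = FALSE)
    }
    wells <- normalize_well(df$well)
    if (anyDuplicated(wells)) {
      stop("parse error: duplicate well ",
           wells[duplicated(wells)][1L], call. = FALSE)
    }
    wl <- suppressWarnings(as.numeric(names(df)[-1L]))
    if (anyNA(wl)) {
      stop("parse error: non-numeric wavelength header ",
           names(df)[-1L][which(is.na(wl))[1L] ], call. = FALSE)
    }
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      stop("parse error: non-numeric absorbance cell", call. = FALSE)
    }
    rownames(m) <- wells
  }
  wl <- as.numeric(colnames(m))
  if (any(diff(wl) <= 0)) {
    stop("parse error: wavelength grid not strictly increasing",
         call. = FALSE)
  }
  meta <- list()
  side <- sub("\\.csv$", ".json", path)
  if (side != path && file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  new_plate_reading(m, wl, rownames(m), meta = meta)
}

#' Write a plate reading to CSV
#'
#' @param reading a `plate_reading`.
#' @param path destination CSV path.
#' @param dialect `"wide"` (default) or `"long"`.
#' @param write_meta also write the metadata sidecar JSON next to the CSV.
#' @return `path`, invisibly.
#' @export
write_plate_reading <- function(reading, path, dialect = c("wide", "long"),
                                write_meta = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(reading, "plate_reading"))
  if (dialect == "wide") {
    df <- data.frame(well = reading$wells, reading$absorbance,
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      well = rep(reading$wells, times = length(reading$wavelength)),
      wavelength_nm = rep(reading$wavelength, each = length(reading$wells)),
      absorbance = as.numeric(reading$absorbance),
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (write_meta && length(reading$meta)) {
    jsonlite::write_json(reading$meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Write / read a plate map as JSON
#'
#' Schema: `{scheme, total_volume_uL, wells: [{well, role, target_ratio,
#' block, replicate_group}]}`.
#'
#' @param map a `plate_map`.
#' @param path JSON file path.
#' @return `write_plate_map`: `path` invisibly; `read_plate_map`: a
#'   `plate_map`.
#' @export
write_plate_map <- function(map, path) {
  stopifnot(inherits(map, "plate_map"))
  obj <- list(
    scheme = attr(map, "scheme"),
    total_volume_uL = attr(map, "total_volume"),
    fold = attr(map, "fold"),
    wells = lapply(seq_len(nrow(map)), function(i) {
      w <- list(well = map$well[i], role = map$role[i],
                target_ratio = map$target_ratio[i],
                block = map$block[i],
                replicate_group = map$replicate_group[i])
      if (is.na(map$block[i])) w$block <- NULL
      w
    })
  )
  jsonlite::write_json(obj[!vapply(obj, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  wells <- obj$wells
  map <- data.frame(
    well = normalize_well(vapply(wells, `[[`, "", "well")),
    role = vapply(wells, `[[`, "", "role"),
    target_ratio = vapply(wells, `[[`, 0, "target_ratio"),
    block = vapply(wells, function(w) {
      if (length(w$block) != 1L) NA_integer_ else as.integer(w$block)
    }, 0L),
    stringsAsFactors = FALSE
  )
  if (nrow(map) != 96L || anyDuplicated(map$well)) {
    stop("parse error: plate map must contain 96 unique wells",
         call. = FALSE)
  }
  if (any(map$target_ratio[map$role == "blank"] != 0)) {
    stop("parse error: blanks must have target_ratio 0", call. = FALSE)
  }
  map$row <- substr(map$well, 1L, 1L)
  map$column <- as.integer(substring(map$well, 2L))
  ord <- match(plate_wells(), map$well)
  map <- map[ord, c("well", "row", "column", "role", "target_ratio",
                    "block")]
  rownames(map) <- NULL
  out <- finish_map(map, scheme = obj$scheme,
                    total_volume = as.numeric(obj$total_volume_uL))
  if (!is.null(obj$fold)) attr(out, "fold") <- obj$fold
  out
}

#' Write / read a transfer-instruction list as CSV
#'
#' Columns: `step`, `phase`, `source`, `destination`, `volume_uL`.
#'
#' @param instructions an `instruction_list`.
#' @param path CSV file path.
#' @return `write_instructions`: `path` invisibly; `read_instructions`: an
#'   `instruction_list`.
#' @export
write_instructions <- function(instructions, path) {
  stopifnot(inherits(instructions, "instruction_list"))
  utils::write.csv(as.data.frame(instructions), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_instructions
#' @export
read_instructions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("step", "phase", "source", "destination", "volume_uL")
  if (!all(need %in% names(df))) {
    stop("parse error: instruction CSV needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$volume_uL) || any(df$volume_uL <= 0)) {
    stop("parse error: volumes must be positive numbers", call. = FALSE)
  }
  df <- df[order(df$step), need]
  rownames(df) <- NULL
  class(df) <- c("instruction_list", "data.frame")
  df
}
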