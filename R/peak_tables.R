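#' Peak tables: dose-series LC-MS peak-area observations
#'
#' A peak table is a long-format table of peak-area observations across
#' absorbed doses, emulating triplicate HPLC-HRMS measurements of antibiotic
#' solutions irradiated at a fixed set of doses. Each row is one observation
#' of one analyte (an antibiotic, or a degradation product labelled by its
#' accurate mass) in one replicate at one dose.
#'
#' Columns:
#' \describe{
#'   \item{dose_kGy}{absorbed dose in kGy, >= 0}
#'   \item{replicate}{positive integer replicate index}
#'   \item{analyte}{analyte identifier (antibiotic name or accurate-mass
#'     string such as \code{"461.1549"})}
#'   \item{mz}{accurate mass (m/z), unitless}
#'   \item{rt_min}{retention time in minutes (may be \code{NA})}
#'   \item{area}{non-negative peak area, arbitrary units; 0 when censored}
#'   \item{censored}{logical; \code{TRUE} for "not detected" (below the
#'     limit of detection), in which case \code{area} is 0}
#' }
#'
#' @param x a data frame with the columns listed above (\code{censored} may
#'   be omitted and defaults to \code{FALSE}; \code{rt_min} may be omitted
#'   and defaults to \code{NA})
#' @param metadata named list of free-form annotations (units, instrument,
#'   date, ...)
#' @return a \code{peak_table}: a tibble with class \code{"peak_table"} and
#'   a \code{"metadata"} attribute
#' @export
peak_table <- function(x, metadata = list()) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"censored" %in% names(x)) x$censored <- FALSE
  if (!"rt_min" %in% names(x)) x$rt_min <- NA_real_
  required <- c("dose_kGy", "replicate", "analyte", "mz", "rt_min", "area", "censored")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("peak table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[required]
  x$dose_kGy <- as.numeric(x$dose_kGy)
  x$replicate <- as.integer(x$replicate)
  x$analyte <- as.character(x$analyte)
  x$mz <- as.numeric(x$mz)
  x$rt_min <- as.numeric(x$rt_min)
  x$area <- as.numeric(x$area)
  x$censored <- as.logical(x$censored)
  out <- tibble::as_tibble(x)
  out <- structure(out, class = c("peak_table", class(tibble::tibble())))
  attr(out, "metadata") <- metadata
  validate_peak_table(out)
  out
}

#' Validate a peak table
#'
#' Checks the structural invariants: non-negative doses and areas, replicate
#' indices >= 1, censored observations recorded with zero area, and unique
#' (analyte, dose, replicate) triplets.
#'
#' @param table a \code{peak_table}
#' @return the table, invisibly, if valid; otherwise an error is signalled
#' @export
validate_peak_table <- function(table) {
  if (nrow(table) == 0L) return(invisible(table))
  if (anyNA(table$dose_kGy) || any(table$dose_kGy < 0)) {
    stop("invalid peak table: negative or missing dose", call. = FALSE)
  }
  if (anyNA(table$area) || any(table$area < 0)) {
    stop("invalid peak table: negative or missing area", call. = FALSE)
  }
  if (anyNA(table$replicate) || any(table$replicate < 1L)) {
    stop("invalid peak table: replicate indices must be >= 1", call. = FALSE)
  }
  if (any(table$censored & table$area != 0)) {
    stop("invalid peak table: censored observations must have area 0",
         call. = FALSE)
  }
  key <- paste(table$analyte, format(table$dose_kGy, digits = 15), table$replicate)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("invalid peak table: duplicate (analyte, dose, replicate) triplet: ",
         dup, call. = FALSE)
  }
  invisible(table)
}

#' Read a peak table from CSV
#'
#' The file must be comma-separated UTF-8 with the exact header
#' \code{dose_kGy,replicate,analyte,mz,rt_min,area}. The literal string
#' \code{ND} ("not detected") is permitted in the \code{area} column and is
#' parsed as a censored observation with area 0. Doses in Gy are accepted
#' only when \code{dose_unit = "Gy"} and are converted to kGy on input.
#'
#' @param path path to a CSV file
#' @param dose_unit unit of the dose column in the file, \code{"kGy"}
#'   (default) or \code{"Gy"}
#' @return a \code{peak_table}
#' @export
read_peak_table <- function(path, dose_unit = c("kGy", "Gy")) {
  dose_unit <- match.arg(dose_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  required <- c("dose_kGy", "replicate", "analyte", "mz", "rt_min", "area")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("peak table file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  censored <- trimws(raw$area) == "ND"
  area <- suppressWarnings(as.numeric(raw$area))
  area[censored] <- 0
  if (anyNA(area) & nrow(raw) > 0L) {
    bad <- which(is.na(area))[1L]
    stop("unparseable area value in row ", bad, ": ", raw$area[bad],
         call. = FALSE)
  }
  dose <- as.numeric(raw$dose_kGy)
  if (dose_unit == "Gy") dose <- dose / 1000
  peak_table(data.frame(
    dose_kGy = dose,
    replicate = as.integer(raw$replicate),
    analyte = raw$analyte,
    mz = as.numeric(raw$mz),
    rt_min = suppressWarnings(as.numeric(raw$rt_min)),
    area = area,
    censored = censored,
    stringsAsFactors = FALSE
  ), metadata = list(source = path, dose_unit_on_input = dose_unit))
}

#' Write a peak table to CSV
#'
#' Writes the canonical comma-separated layout with header
#' \code{dose_kGy,replicate,analyte,mz,rt_min,area}; censored observations
#' are written as the literal \code{ND} in the area column. Numeric fields
#' are written at full precision (17 significant digits) so that a
#' write/read round trip preserves all values exactly.
#'
#' @param table a \code{peak_table}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_peak_table <- function(table, path) {
  validate_peak_table(table)
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }, character(1))
    out
  }
  area_chr <- fmt(table$area)
  area_chr[table$censored] <- "ND"
  lines <- c(
    "dose_kGy,replicate,analyte,mz,rt_min,area",
    if (nrow(table) > 0L) {
      paste(fmt(table$dose_kGy), table$replicate, table$analyte,
            fmt(table$mz), fmt(table$rt_min), area_chr, sep = ",")
    }
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Rescale a dose series to a relative concentration scale
#'
#' Rescales peak areas so that the mean non-censored dose-0 area of the
#' chosen analyte maps to 100 relative units, the scale on which kinetic
#' coefficients are reported. The same scale factor is applied to the
#' analyte's degradation products when they are listed in \code{products},
#' so parent and product signals stay on a common scale.
#'
#' @param table a \code{peak_table}
#' @param analyte the antibiotic whose dose-0 mean defines the scale
#' @param products character vector of product analytes to rescale with the
#'   same factor (default none)
#' @return a \code{peak_table} with rescaled areas
#' @export
normalize_to_dose0 <- function(table, analyte, products = character()) {
  validate_peak_table(table)
  sel <- table$analyte == analyte & table$dose_kGy == 0 & !table$censored
  if (!any(sel)) {
    stop("no non-censored dose-0 observations for analyte ", analyte,
         call. = FALSE)
  }
  scale <- 100 / mean(table$area[sel])
  touch <- table$analyte %in% c(analyte, products)
  table$area[touch] <- table$area[touch] * scale
  table
}
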