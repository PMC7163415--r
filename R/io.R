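## Reading and writing the five delimited sheets. Column sets and types are
## fixed by the schema below (also shipped as inst/extdata/schema.json).
## Malformed rows are never dropped silently: they are collected into a
## reject table with a reason.

sheet_names <- c("activity", "nurses", "working_hours", "movements",
                 "discharges")

#' Sheet schema of the two data sources
#'
#' @return named list (one element per sheet) of tibbles with columns
#'   `column`, `type` and `required`.
#' @export
wardflow_schema <- function() {
  list(
    activity = tibble::tibble(
      column = c("nurse_id", "contract_id", "case_id", "unit_id", "date",
                 "activity_type", "setting"),
      type = c("character", "character", "character", "character", "date",
               "enum:care|administrative|teaching|continuous_education|absence",
               "enum:inpatient|outpatient"),
      required = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)),
    nurses = tibble::tibble(
      column = c("nurse_id", "contract_id", "group"),
      type = c("character", "character", "enum:1|2|3|4|5"),
      required = TRUE),
    working_hours = tibble::tibble(
      column = c("nurse_id", "contract_id", "date", "start_time", "end_time"),
      type = c("character", "character", "date", "clock", "clock"),
      required = TRUE),
    movements = tibble::tibble(
      column = c("case_id", "unit_id", "event", "date", "time", "setting"),
      type = c("character", "character", "enum:admission|discharge|transfer",
               "date", "clock", "enum:inpatient|outpatient"),
      required = TRUE),
    discharges = tibble::tibble(
      column = c("case_id", "age_years", "admission_date", "discharge_date",
                 "main_dx", "department", "healthy_newborn"),
      type = c("character", "numeric", "date", "date", "icd10", "character",
               "logical"),
      required = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  )
}

# validate one raw (all-character) sheet against its schema; returns
# list(data = typed tibble of good rows, rejects = tibble(sheet, row, reason))
validate_sheet <- function(raw, name, schema) {
  sch <- schema[[name]]
  missing <- setdiff(sch$column, names(raw))
  if (length(missing))
    stop("sheet '", name, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  raw <- raw[sch$column]
  n <- nrow(raw)
  bad <- character(n) # first failure reason per row, "" = ok
  out <- raw
  for (i in seq_len(nrow(sch))) {
    col <- sch$column[i]; tp <- sch$type[i]
    x <- raw[[col]]
    if (tp == "character") next
    if (tp == "date") {
      v <- as.Date(x, format = "%Y-%m-%d")
      fail <- is.na(v) & !is.na(x)
      out[[col]] <- v
    } else if (tp == "clock") {
      v <- parse_clock(x)
      fail <- is.na(v) & !is.na(x)
      out[[col]] <- v
    } else if (tp == "numeric") {
      v <- suppressWarnings(as.numeric(x))
      fail <- (is.na(v) & !is.na(x)) | v < 0
      out[[col]] <- v
    } else if (tp == "logical") {
      v <- toupper(as.character(x)) %in% c("TRUE", "T", "1")
      fail <- rep(FALSE, n)
      out[[col]] <- v
    } else if (tp == "icd10") {
      fail <- !grepl("^[A-Z][0-9]{2}", as.character(x))
      out[[col]] <- as.character(x)
    } else if (startsWith(tp, "enum:")) {
      levels <- strsplit(sub("^enum:", "", tp), "|", fixed = TRUE)[[1]]
      v <- as.character(x)
      fail <- !v %in% levels
      if (identical(col, "group")) out[[col]] <- suppressWarnings(as.integer(v))
      else out[[col]] <- v
    } else stop("unknown schema type: ", tp)
    if (sch$required[i]) fail <- fail | is.na(x)
    newly <- fail & bad == ""
    bad[newly] <- paste0(col, ": invalid or missing value")
  }
  keep <- bad == ""
  rejects <- tibble::tibble(sheet = name, row = which(!keep),
                            reason = bad[!keep])
  list(data = tibble::as_tibble(out[keep, ]), rejects = rejects)
}

#' Write the five sheets of a synthetic bundle to disk
#'
#' @param bundle a `wardflow_bundle` from [simulate_bundle()] (or any list
#'   with the five sheet elements).
#' @param dir output directory (created if needed).
#' @param format `"csv"` (default) or `"parquet"` (requires the arrow
#'   package).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in sheet_names) {
    x <- bundle[[nm]]
    if (format == "csv") {
      readr::write_csv(x, file.path(dir, paste0(nm, ".csv")), progress = FALSE)
    } else {
      if (!requireNamespace("arrow", quietly = TRUE))
        stop("parquet output requires the 'arrow' package")
      arrow::write_parquet(x, file.path(dir, paste0(nm, ".parquet")))
    }
  }
  invisible(dir)
}

#' Read and type-check the five sheets
#'
#' Reads the staffing-system sheets (activity, nurses, working hours,
#' patient movements) and the medical discharge sheet from a directory,
#' validates each against [wardflow_schema()], and collects malformed rows
#' into a reject report instead of dropping them silently. A missing
#' required column is a hard error naming the column.
#'
#' @param dir directory containing `<sheet>.csv` or `<sheet>.parquet` files.
#' @param schema schema list, defaults to [wardflow_schema()].
#' @return an object of class `wardflow_bundle` with the five typed sheets
#'   and a `rejects` tibble (`sheet`, `row`, `reason`).
#' @export
read_sources <- function(dir, schema = wardflow_schema()) {
  sheets <- list(); rejects <- list()
  for (nm in sheet_names) {
    csv <- file.path(dir, paste0(nm, ".csv"))
    pq <- file.path(dir, paste0(nm, ".parquet"))
    if (file.exists(csv)) {
      raw <- readr::read_csv(csv, col_types = readr::cols(
        .default = readr::col_character()), progress = FALSE)
    } else if (file.exists(pq)) {
      if (!requireNamespace("arrow", quietly = TRUE))
        stop("parquet input requires the 'arrow' package")
      raw <- arrow::read_parquet(pq)
      raw[] <- lapply(raw, function(col)
        if (inherits(col, "Date")) format(col, "%Y-%m-%d") else as.character(col))
      raw <- tibble::as_tibble(raw)
    } else stop("no file found for sheet '", nm, "' in ", dir)
    v <- validate_sheet(raw, nm, schema)
    sheets[[nm]] <- v$data
    rejects[[nm]] <- v$rejects
  }
  sheets$rejects <- dplyr::bind_rows(rejects)
  structure(sheets, class = "wardflow_bundle")
}
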