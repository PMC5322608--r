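#' Validate a collection-record data frame
#'
#' Checks the canonical column set and types used throughout the package:
#' `herd_id` (character), `id_type` (national/coop/missing; optional, filled
#' with "missing" when absent), `collection_date` (Date), `volume_litres`
#' (numeric litres, `NA` allowed), `scc` (x1000 cells/mL, `NA` when the
#' collection was not tested). Character dates are parsed as ISO 8601;
#' unparseable dates or non-numeric measurements raise an error naming the
#' offending rows rather than dropping them silently.
#'
#' @param records A data frame of collection-day records.
#' @return A tibble with canonical column types.
#' @export
validate_records <- function(records) {
  records <- as_tibble(records)
  needed <- c("herd_id", "collection_date", "volume_litres", "scc")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("Records are missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "bulkscc_input_error")
  }
  if (!"id_type" %in% names(records)) records$id_type <- "missing"

  if (!inherits(records$collection_date, "Date")) {
    parsed <- as.Date(as.character(records$collection_date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(records$collection_date))
    if (length(bad)) {
      abort(paste0("Unparseable collection_date in rows: ",
                   paste(head(bad, 10), collapse = ", "),
                   if (length(bad) > 10) " ..." else ""),
            class = "bulkscc_input_error")
    }
    records$collection_date <- parsed
  }
  if (anyNA(records$collection_date)) {
    abort("Missing collection_date values.", class = "bulkscc_input_error")
  }

  for (col in c("volume_litres", "scc")) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(as.character(v)))
      bad <- which(is.na(num) & !is.na(v) & as.character(v) != "")
      if (length(bad)) {
        abort(paste0("Non-numeric ", col, " in rows: ",
                     paste(head(bad, 10), collapse = ", "),
                     if (length(bad) > 10) " ..." else ""),
              class = "bulkscc_input_error")
      }
      records[[col]] <- num
    }
  }
  records$herd_id <- as.character(records$herd_id)
  records$id_type <- as.character(records$id_type)
  records
}

#' Read collection-day records from CSV
#'
#' Reads the standard interchange format: columns `herd_id`, `id_type`
#' (national|coop|missing), `collection_date` (ISO 8601), `volume_litres`,
#' `scc_cells_per_ml` (cells/mL; empty when the collection was untested).
#' SCC is converted to the x1000 cells/mL working scale in the returned
#' `scc` column.
#'
#' @param path Path to the CSV file.
#' @return A validated records tibble.
#' @export
read_collection_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      herd_id = readr::col_character(),
      id_type = readr::col_character(),
      collection_date = readr::col_character(),
      volume_litres = readr::col_character(),
      scc_cells_per_ml = readr::col_character()
    ),
    progress = FALSE
  )
  if (!"scc_cells_per_ml" %in% names(raw)) {
    abort("CSV is missing the scc_cells_per_ml column.", class = "bulkscc_input_error")
  }
  raw$scc <- suppressWarnings(as.numeric(raw$scc_cells_per_ml))
  bad <- which(is.na(raw$scc) & !is.na(raw$scc_cells_per_ml) & raw$scc_cells_per_ml != "")
  if (length(bad)) {
    abort(paste0("Non-numeric scc_cells_per_ml in rows: ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "bulkscc_input_error")
  }
  raw$scc <- raw$scc / 1000
  raw$scc_cells_per_ml <- NULL
  validate_records(raw)
}

#' Write collection-day records to CSV
#'
#' Inverse of [read_collection_csv()]: the working-scale `scc` column
#' (x1000 cells/mL) is written out as `scc_cells_per_ml` in cells/mL, the
#' unit the legislation is written in.
#'
#' @param records A records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collection_csv <- function(records, path) {
  records <- validate_records(records)
  out <- records %>%
    mutate(scc_cells_per_ml = .data$scc * 1000) %>%
    select(all_of(c("herd_id", "id_type", "collection_date",
                    "volume_litres", "scc_cells_per_ml")))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a seasonal-factor table from a YAML config
#'
#' Expected layout: a top-level `factors` mapping of year to month-factor
#' pairs, e.g. `factors: {2013: {1: 0.39, 2: 0.74, 11: 0.78, 12: 0.47}}`.
#' Months absent from the file default to a factor of 1.
#'
#' @param path Path to the YAML file.
#' @return An `scc_factors` table.
#' @export
read_seasonal_factors <- function(path) {
  cfg <- yaml::read_yaml(path)
  fac <- cfg$factors %||% cfg
  if (!is.list(fac) || !length(fac)) {
    return(seasonal_factors())
  }
  rows <- purrr::imap(fac, function(months, yr) {
    tibble(year = as.integer(yr),
           month = as.integer(names(months)),
           factor = as.double(unlist(months)))
  })
  seasonal_factors(bind_rows(rows))
}
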