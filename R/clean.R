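#' Clean raw collection-day records
#'
#' Applies the three-step cleaning procedure used for national bulk-tank
#' datasets, in a fixed order so the reported counts are deterministic:
#'
#' 1. SCC test results recorded as 0 are set to missing (a zero count is a
#'    recording artefact, not a plausible bulk-tank measurement);
#' 2. records with negative milk volume are removed (zero volumes are
#'    retained);
#' 3. multiple records for the same herd on the same day are merged: the
#'    volumes are summed and, when more than one SCC result is present, the
#'    merged SCC is the volume-weighted mean of the day's SCC values using
#'    the day's collection volumes as weights. An SCC value on a record
#'    without a volume receives a weight equal to the mean of the day's
#'    known volumes (equal weights when the day has no volumes at all).
#'
#' After cleaning, at most one record exists per herd per day.
#'
#' @param records Raw collection records (see [validate_records()] for the
#'   expected columns).
#' @return The cleaned records tibble, with a `cleaning_report` attribute;
#'   retrieve it with [cleaning_report()].
#' @examples
#' raw <- tibble::tibble(
#'   herd_id = "h1", id_type = "national",
#'   collection_date = as.Date(c("2013-06-01", "2013-06-01")),
#'   volume_litres = c(1000, 3000), scc = c(200, 400)
#' )
#' cleaned <- clean_records(raw)
#' cleaned$scc # 350: volume-weighted mean
#' cleaning_report(cleaned)
#' @export
clean_records <- function(records) {
  records <- validate_records(records)
  n_in <- nrow(records)

  # step 1: zero SCC -> missing
  zero_scc <- !is.na(records$scc) & records$scc == 0
  records$scc[zero_scc] <- NA_real_

  # step 2: drop negative volumes
  neg <- !is.na(records$volume_litres) & records$volume_litres < 0
  records <- records[!neg, , drop = FALSE]

  # step 3: merge multi-record herd-days
  records <- records %>%
    group_by(.data$herd_id, .data$collection_date)
  n_days_merged <- sum(dplyr::group_size(records) > 1L)
  cleaned <- records %>%
    summarise(
      id_type = first(.data$id_type),
      # the weighted SCC mean must see the individual collection volumes,
      # so it is computed before the volumes are summed
      scc = merge_day_scc(.data$scc, .data$volume_litres),
      volume_litres = if (all(is.na(.data$volume_litres))) NA_real_
                      else sum(.data$volume_litres, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    select(all_of(c("herd_id", "id_type", "collection_date",
                    "volume_litres", "scc"))) %>%
    arrange(.data$herd_id, .data$collection_date)

  report <- tibble(
    n_records_in = n_in,
    n_zero_scc_blanked = sum(zero_scc),
    n_negative_volume_removed = sum(neg),
    n_days_merged = n_days_merged,
    n_records_out = nrow(cleaned)
  )
  attr(cleaned, "cleaning_report") <- report
  class(cleaned) <- c("scc_cleaned", class(cleaned))
  cleaned
}

# Weighted mean of a day's SCC values; volume-less tests get the mean known
# volume as weight, or equal weights when the day carries no volumes.
merge_day_scc <- function(scc, volume) {
  known <- !is.na(scc)
  if (!any(known)) return(NA_real_)
  if (sum(known) == 1L) return(scc[known])
  w <- volume[known]
  if (all(is.na(w))) {
    w <- rep(1, sum(known))
  } else {
    w[is.na(w)] <- mean(w, na.rm = TRUE)
  }
  sum(scc[known] * w) / sum(w)
}

#' Retrieve the cleaning report
#'
#' @param cleaned The result of [clean_records()].
#' @return A one-row tibble: `n_records_in`, `n_zero_scc_blanked`,
#'   `n_negative_volume_removed`, `n_days_merged`, `n_records_out`.
#' @export
cleaning_report <- function(cleaned) {
  rep <- attr(cleaned, "cleaning_report")
  if (is.null(rep)) {
    abort("No cleaning report attached; was this produced by clean_records()?",
          class = "bulkscc_input_error")
  }
  rep
}

#' @export
glance.scc_cleaned <- function(x, ...) cleaning_report(x)
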