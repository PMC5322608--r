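#' Configuration for the synthetic bulk-tank data generator
#'
#' Parameters of a one-year national bulk-tank collection dataset. Defaults
#' emulate the 2013 Irish dataset: roughly 16,740 herds collected every few
#' days, a supply curve peaking mid-year and troughing in December-January,
#' log-normal herd SCC with a winter elevation, a majority of records
#' carrying only an anonymous co-op identifier, and the characteristic
#' data-quality defects (zero-SCC results, negative volumes, duplicated
#' herd-day records, SCC results without a volume, volumes without an SCC
#' test).
#'
#' @param n_herds Number of herds.
#' @param year Calendar year generated.
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @param frac_missing_national_id Proportion of herds identified only by a
#'   co-op code (stable within the year) instead of a national identifier.
#' @param frac_winter_break Proportion of herds with no supply during
#'   `break_months` (seasonal dry-off).
#' @param break_months Months (1-12) in which break herds have no records.
#' @param scc_log_mean,scc_log_sd Location and spread of the log-normal
#'   herd-level SCC distribution, on the log(x1000 cells/mL) scale.
#' @param scc_test_sd Log-scale SD of test-day noise around the herd level.
#' @param seasonal_scc_amplitude Relative winter elevation of SCC: the
#'   monthly multiplier is `1 + a * cos(2 * pi * (month - 1) / 12)`, peaking
#'   in January and lowest in July.
#' @param volume_curve Twelve non-negative monthly supply weights scaling
#'   daily volume (default peaks in May, troughs in December-January).
#' @param frac_high_scc_herds Proportion of chronically high-SCC herds.
#' @param high_scc_multiplier SCC inflation factor for those herds.
#' @param frac_scc_tested Probability that a collection carries an SCC test.
#' @param volume_log_mean,volume_log_sd Log-normal herd daily-volume scale
#'   (litres at a curve weight of 1); the herd-size law.
#' @param collection_interval_days Days between collections.
#' @param defect_rates Named list of per-record defect probabilities:
#'   `zero_scc`, `negative_volume`, `duplicate_day`, `scc_without_volume`.
#'   Defects are mutually exclusive per record.
#' @return A validated list of class `scc_generator_config`.
#' @export
generator_config <- function(n_herds = 16740,
                             year = 2013,
                             seed = 2013,
                             frac_missing_national_id = 0.604,
                             frac_winter_break = 0.45,
                             break_months = 1L,
                             scc_log_mean = log(177),
                             scc_log_sd = 0.42,
                             scc_test_sd = 0.28,
                             seasonal_scc_amplitude = 0.20,
                             volume_curve = c(0.35, 0.55, 0.85, 1.10, 1.25,
                                              1.20, 1.15, 1.05, 0.95, 0.80,
                                              0.55, 0.35),
                             frac_high_scc_herds = 0.04,
                             high_scc_multiplier = 2.0,
                             frac_scc_tested = 0.74,
                             volume_log_mean = log(2680),
                             volume_log_sd = 0.70,
                             collection_interval_days = 3L,
                             defect_rates = list(zero_scc = 0.028,
                                                 negative_volume = 5e-5,
                                                 duplicate_day = 0.018,
                                                 scc_without_volume = 0.0042)) {
  cfg <- list(
    n_herds = as.integer(n_herds), year = as.integer(year),
    seed = as.integer(seed),
    frac_missing_national_id = frac_missing_national_id,
    frac_winter_break = frac_winter_break,
    break_months = as.integer(break_months),
    scc_log_mean = scc_log_mean, scc_log_sd = scc_log_sd,
    scc_test_sd = scc_test_sd,
    seasonal_scc_amplitude = seasonal_scc_amplitude,
    volume_curve = as.double(volume_curve),
    frac_high_scc_herds = frac_high_scc_herds,
    high_scc_multiplier = high_scc_multiplier,
    frac_scc_tested = frac_scc_tested,
    volume_log_mean = volume_log_mean, volume_log_sd = volume_log_sd,
    collection_interval_days = as.integer(collection_interval_days),
    defect_rates = defect_rates
  )
  props <- c(cfg$frac_missing_national_id, cfg$frac_winter_break,
             cfg$frac_high_scc_herds, cfg$frac_scc_tested,
             unlist(cfg$defect_rates))
  if (cfg$n_herds < 1L) {
    abort("n_herds must be positive.", class = "bulkscc_config_error")
  }
  if (any(is.na(props)) || any(props < 0) || any(props > 1)) {
    abort("All proportions must lie in [0, 1].", class = "bulkscc_config_error")
  }
  if (sum(unlist(cfg$defect_rates)) > 1) {
    abort("Defect rates must sum to at most 1 (defects are exclusive).",
          class = "bulkscc_config_error")
  }
  if (length(cfg$volume_curve) != 12L || any(cfg$volume_curve < 0) ||
      !any(cfg$volume_curve > 0)) {
    abort("volume_curve needs 12 non-negative weights, at least one positive.",
          class = "bulkscc_config_error")
  }
  needed <- c("zero_scc", "negative_volume", "duplicate_day", "scc_without_volume")
  if (!all(needed %in% names(cfg$defect_rates))) {
    abort(paste("defect_rates needs:", paste(needed, collapse = ", ")),
          class = "bulkscc_config_error")
  }
  if (any(cfg$break_months < 1L | cfg$break_months > 12L)) {
    abort("break_months must be in 1..12.", class = "bulkscc_config_error")
  }
  structure(cfg, class = "scc_generator_config")
}

#' Generate a synthetic year of bulk-tank collection records
#'
#' Simulates collection-day records for one calendar year. Each herd has a
#' log-normal SCC level (chronically high herds inflated by
#' `high_scc_multiplier`), a seasonal SCC multiplier peaking in winter, and
#' a log-normal volume scale modulated by the monthly supply curve. Herds
#' flagged for a winter break have no records in the break months. Defect
#' records (zero SCC, negative volume, duplicated herd-day with the day's
#' volume split and independent SCC draws, SCC without volume) are injected
#' at the configured rates; the realised injection counts are attached as
#' the `defects` attribute (retrieve with [injected_defects()]).
#'
#' @param config An `scc_generator_config`.
#' @return A records tibble (see [validate_records()]) ordered by herd and
#'   date, with attribute `defects`.
#' @export
generate_herd_records <- function(config = generator_config()) {
  if (!inherits(config, "scc_generator_config")) {
    config <- do.call(generator_config, config)
  }
  withr::with_seed(config$seed, generate_records_impl(config))
}

generate_records_impl <- function(cfg) {
  n <- cfg$n_herds
  width <- max(6L, nchar(as.character(n)))

  national <- runif(n) >= cfg$frac_missing_national_id
  herd_id <- ifelse(national,
                    sprintf("IE%0*d", width, seq_len(n)),
                    sprintf("COOP-%s-%0*d",
                            sprintf("%04X", sample.int(65535L, n, replace = TRUE)),
                            width, seq_len(n)))
  id_type <- ifelse(national, "national", "coop")

  breaks <- runif(n) < cfg$frac_winter_break
  high <- runif(n) < cfg$frac_high_scc_herds
  herd_log_scc <- rnorm(n, cfg$scc_log_mean, cfg$scc_log_sd) +
    ifelse(high, log(cfg$high_scc_multiplier), 0)
  herd_vol_scale <- rlnorm(n, cfg$volume_log_mean, cfg$volume_log_sd)

  # collection calendar: every interval days, per-herd phase offset
  year_start <- as.Date(sprintf("%d-01-01", cfg$year))
  days_in_year <- as.integer(as.Date(sprintf("%d-01-01", cfg$year + 1L)) - year_start)
  offset <- sample.int(cfg$collection_interval_days, n, replace = TRUE)
  days_per_herd <- lapply(seq_len(n), function(i) {
    seq(offset[i], days_in_year, by = cfg$collection_interval_days)
  })
  n_days <- lengths(days_per_herd)
  idx <- rep.int(seq_len(n), n_days)
  doy <- unlist(days_per_herd, use.names = FALSE)
  date <- year_start + (doy - 1L)
  month <- as.integer(format(date, "%m"))

  keep <- !(breaks[idx] & month %in% cfg$break_months)
  idx <- idx[keep]; date <- date[keep]; month <- month[keep]
  m <- length(idx)

  season_scc <- 1 + cfg$seasonal_scc_amplitude * cos(2 * pi * (month - 1) / 12)
  scc <- exp(herd_log_scc[idx] + rnorm(m, 0, cfg$scc_test_sd)) * season_scc
  tested <- runif(m) < cfg$frac_scc_tested
  scc[!tested] <- NA_real_
  volume <- round(herd_vol_scale[idx] * cfg$volume_curve[month] *
                    exp(rnorm(m, 0, 0.08)))
  volume <- pmax(volume, 1)

  rec <- tibble(
    herd_id = herd_id[idx], id_type = id_type[idx], collection_date = date,
    volume_litres = as.double(volume), scc = scc
  )

  # exclusive defect assignment per record
  dr <- cfg$defect_rates
  cls <- sample(
    c("none", "zero_scc", "negative_volume", "duplicate_day", "scc_without_volume"),
    m, replace = TRUE,
    prob = c(1 - sum(unlist(dr)), dr$zero_scc, dr$negative_volume,
             dr$duplicate_day, dr$scc_without_volume)
  )
  # zero SCC / SCC-without-volume only make sense on tested records
  cls[cls %in% c("zero_scc", "scc_without_volume") & !tested] <- "none"

  rec$scc[cls == "zero_scc"] <- 0
  rec$volume_litres[cls == "negative_volume"] <- -rec$volume_litres[cls == "negative_volume"]
  rec$volume_litres[cls == "scc_without_volume"] <- NA_real_

  dup <- which(cls == "duplicate_day")
  if (length(dup)) {
    share <- runif(length(dup), 0.3, 0.7)
    base <- rec[dup, ]
    second <- base
    second$volume_litres <- round(base$volume_litres * (1 - share))
    rec$volume_litres[dup] <- round(base$volume_litres * share)
    redraw <- !is.na(base$scc)
    if (any(redraw)) {
      hi <- idx[dup][redraw]
      second$scc[redraw] <- exp(herd_log_scc[hi] +
                                  rnorm(sum(redraw), 0, cfg$scc_test_sd)) *
        season_scc[dup][redraw]
    }
    rec <- bind_rows(rec, second)
  }

  rec <- rec %>% arrange(.data$herd_id, .data$collection_date, .data$volume_litres)
  attr(rec, "defects") <- tibble(
    n_zero_scc = sum(cls == "zero_scc"),
    n_negative_volume = sum(cls == "negative_volume"),
    n_duplicate_days = length(dup),
    n_scc_without_volume = sum(cls == "scc_without_volume")
  )
  rec
}

#' Realised defect-injection counts of a generated dataset
#'
#' @param records Output of [generate_herd_records()].
#' @return A one-row tibble: `n_zero_scc`, `n_negative_volume`,
#'   `n_duplicate_days`, `n_scc_without_volume`.
#' @export
injected_defects <- function(records) {
  d <- attr(records, "defects")
  if (is.null(d)) {
    abort("No defect attribute; was this produced by generate_herd_records()?",
          class = "bulkscc_input_error")
  }
  d
}
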