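#' Geometric mean
#'
#' The n-th root of the product of n positive values, computed in the log
#' domain as `exp(mean(log(x)))` for numerical stability. This is the
#' compliance statistic mandated by EU raw-milk legislation for bulk-tank
#' somatic cell counts; it is always less than or equal to the arithmetic
#' mean of the same values.
#'
#' @param x Numeric vector of positive values. Must be non-empty.
#' @return A single positive number.
#' @examples
#' geometric_mean(c(100, 400)) # 200
#' geometric_mean(c(438, 540, 413, 402, 283, 345))
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0) {
    abort("geometric_mean() requires a non-empty input.", class = "bulkscc_domain_error")
  }
  if (anyNA(x) || any(x <= 0)) {
    abort("geometric_mean() requires all values to be positive and non-missing.",
          class = "bulkscc_domain_error")
  }
  exp(mean(log(x)))
}

#' Seasonal adjustment factor table
#'
#' Builds a factor table mapping (year, month) to the multiplicative
#' seasonality adjustment applied to SCC values. Months not listed carry a
#' factor of 1 (no adjustment). Under the Irish scheme only November to
#' February carry factors below 1, to offset the presumed winter
#' concentration of SCC at low milk volumes.
#'
#' @param factors A data frame with columns `year`, `month`, `factor`, or
#'   `NULL` for an empty table (factor 1 everywhere, i.e. no adjustment).
#' @return A tibble of class `scc_factors` with columns `year`, `month`
#'   (integer 1-12) and `factor` (positive).
#' @seealso [irish_seasonal_factors()] for the published 2013/2014 factors.
#' @export
seasonal_factors <- function(factors = NULL) {
  if (is.null(factors)) {
    factors <- tibble(year = integer(), month = integer(), factor = double())
  }
  factors <- as_tibble(factors)
  required <- c("year", "month", "factor")
  if (!all(required %in% names(factors))) {
    abort("`factors` needs columns year, month, factor.", class = "bulkscc_config_error")
  }
  factors <- factors %>%
    mutate(year = as.integer(.data$year), month = as.integer(.data$month),
           factor = as.double(.data$factor)) %>%
    select(all_of(required))
  if (any(is.na(factors$factor)) || any(factors$factor <= 0)) {
    abort("All seasonal factors must be positive.", class = "bulkscc_config_error")
  }
  if (any(factors$month < 1L | factors$month > 12L)) {
    abort("Factor months must be in 1..12.", class = "bulkscc_config_error")
  }
  if (anyDuplicated(factors[c("year", "month")])) {
    abort("Duplicate (year, month) entries in factor table.", class = "bulkscc_config_error")
  }
  class(factors) <- c("scc_factors", class(factors))
  factors
}

#' Published Irish seasonality adjustment factors
#'
#' The multiplicative SCC adjustment factors applied in Ireland during 2013
#' and 2014: January 0.39/0.39, February 0.74/0.75, November 0.78/0.9,
#' December 0.47/0.53. All other months are unadjusted (factor 1).
#'
#' @param years Years to include; default both 2013 and 2014.
#' @return An `scc_factors` table.
#' @export
irish_seasonal_factors <- function(years = c(2013L, 2014L)) {
  tab <- tibble(
    year   = rep(c(2013L, 2014L), each = 4L),
    month  = rep(c(1L, 2L, 11L, 12L), times = 2L),
    factor = c(0.39, 0.74, 0.78, 0.47,
               0.39, 0.75, 0.90, 0.53)
  )
  seasonal_factors(tab[tab$year %in% as.integer(years), ])
}

#' Look up seasonal factors for record months
#'
#' @param year,month Integer vectors (recycled to common length).
#' @param factors An `scc_factors` table.
#' @return Numeric vector of factors; 1 for unlisted (year, month).
#' @export
factor_for_month <- function(year, month, factors) {
  factors <- seasonal_factors(factors)
  key <- paste(as.integer(year), as.integer(month))
  idx <- match(key, paste(factors$year, factors$month))
  out <- factors$factor[idx]
  out[is.na(idx)] <- 1
  out
}

#' Apply the seasonal adjustment to individual SCC values
#'
#' Multiplies each SCC value by the seasonal factor of its collection month.
#' This is the pre-adjustment step of calculation method 2, where each
#' individual test result is adjusted before entering the rolling geometric
#' mean; e.g. a January test of 438 under factor 0.39 becomes 170.82.
#'
#' @param scc Numeric SCC values (any consistent scale).
#' @param year,month Collection year and month of each value.
#' @param factors An `scc_factors` table.
#' @return Adjusted SCC values.
#' @export
adjust_scc <- function(scc, year, month, factors) {
  scc * factor_for_month(year, month, factors)
}

#' Compliance thresholds for SCC categories and eligibility
#'
#' The legislated cut-points, on the x1000 cells/mL scale: herds are
#' categorised as low (< 200), mid (200-400) or high (> 400), and a rolling
#' geometric mean strictly above `suspension_threshold` (400) in the
#' preceding month counts as an exceedance in the eligibility state machine.
#'
#' @param category_low_upper Upper bound of the low category (exclusive).
#' @param category_high_lower Lower bound of the high category (exclusive).
#' @param suspension_threshold Exceedance threshold for warnings/suspension.
#' @return A list of class `scc_thresholds`.
#' @export
compliance_thresholds <- function(category_low_upper = 200,
                                  category_high_lower = 400,
                                  suspension_threshold = 400) {
  if (any(c(category_low_upper, category_high_lower, suspension_threshold) <= 0) ||
      category_low_upper >= category_high_lower) {
    abort("Thresholds must be positive with category_low_upper < category_high_lower.",
          class = "bulkscc_config_error")
  }
  structure(
    list(category_low_upper = category_low_upper,
         category_high_lower = category_high_lower,
         suspension_threshold = suspension_threshold),
    class = "scc_thresholds"
  )
}

#' SCC category levels
#' @return Character vector of category levels in increasing severity.
#' @export
scc_categories <- function() c("low", "mid", "high")

#' Categorise adjusted geometric mean SCC
#'
#' Assigns each (seasonally adjusted) monthly geometric mean to one of three
#' SCC categories: `low` strictly below 200, `mid` from 200 to 400 inclusive,
#' `high` strictly above 400 (x1000 cells/mL). The boundary values 200 and
#' 400 belong to the middle category, matching the strict "exceeded 400,000
#' cells/mL" reading used for warnings.
#'
#' @param x Numeric vector of positive SCC means (x1000 cells/mL).
#' @param thresholds An `scc_thresholds` object.
#' @return Factor with levels low, mid, high.
#' @export
categorize_scc <- function(x, thresholds = compliance_thresholds()) {
  if (anyNA(x) || any(x <= 0)) {
    abort("categorize_scc() requires positive, non-missing values.",
          class = "bulkscc_domain_error")
  }
  out <- dplyr::case_when(
    x < thresholds$category_low_upper ~ "low",
    x > thresholds$category_high_lower ~ "high",
    TRUE ~ "mid"
  )
  factor(out, levels = scc_categories())
}

#' Per-herd monthly SCC statistics
#'
#' Aggregates cleaned collection-day records to one row per herd-month with
#' at least one eligible SCC test: the number of tests, the arithmetic and
#' geometric mean SCC, the seasonally adjusted geometric mean (geometric
#' mean times that month's factor), the month's total collected volume, and
#' the SCC category of the adjusted mean.
#'
#' @param records Cleaned collection records (see [clean_records()]), a data
#'   frame with columns `herd_id`, `collection_date`, `volume_litres`, `scc`
#'   (x1000 cells/mL, `NA` when untested).
#' @param factors An `scc_factors` table; default no adjustment.
#' @param include_scc_without_volume If `TRUE` (the calculation method 1
#'   convention) SCC tests lacking a recorded volume enter the statistics;
#'   if `FALSE` (method 2) only records with both an SCC result and a volume
#'   are used.
#' @param thresholds An `scc_thresholds` object for categorisation.
#' @return A tibble with columns `herd_id`, `year`, `month`, `n_scc_tests`,
#'   `arith_mean_scc`, `geo_mean_scc`, `adjusted_geo_mean_scc`,
#'   `total_volume`, `category`. SCC columns are on the x1000 cells/mL scale.
#' @export
monthly_stats <- function(records, factors = seasonal_factors(),
                          include_scc_without_volume = TRUE,
                          thresholds = compliance_thresholds()) {
  records <- validate_records(records)
  factors <- seasonal_factors(factors)

  dated <- records %>%
    mutate(year = as.integer(format(.data$collection_date, "%Y")),
           month = as.integer(format(.data$collection_date, "%m")))

  volumes <- dated %>%
    group_by(.data$herd_id, .data$year, .data$month) %>%
    summarise(total_volume = sum(.data$volume_litres, na.rm = TRUE), .groups = "drop")

  tests <- dated %>%
    filter(!is.na(.data$scc))
  if (!include_scc_without_volume) {
    tests <- tests %>% filter(!is.na(.data$volume_litres))
  }

  stats <- tests %>%
    group_by(.data$herd_id, .data$year, .data$month) %>%
    summarise(
      n_scc_tests = dplyr::n(),
      arith_mean_scc = mean(.data$scc),
      geo_mean_scc = exp(mean(log(.data$scc))),
      .groups = "drop"
    ) %>%
    mutate(adjusted_geo_mean_scc =
             .data$geo_mean_scc * factor_for_month(.data$year, .data$month, factors)) %>%
    left_join(volumes, by = c("herd_id", "year", "month")) %>%
    mutate(total_volume = dplyr::coalesce(.data$total_volume, 0),
           category = categorize_scc(.data$adjusted_geo_mean_scc, thresholds)) %>%
    arrange(.data$herd_id, .data$year, .data$month)

  stats
}
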