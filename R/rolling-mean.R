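# Calendar-month arithmetic: a single integer index so "three consecutive
# months" is a difference of 2, across year boundaries.
ym_index <- function(year, month) as.integer(year) * 12L + (as.integer(month) - 1L)
ym_year  <- function(index) index %/% 12L
ym_month <- function(index) index %% 12L + 1L

# Month grid spanned by a dataset: every calendar month from the first to
# the last observed, so all herds share one month axis.
month_grid <- function(year, month) {
  idx <- ym_index(year, month)
  seq(min(idx), max(idx))
}

#' Three-month rolling geometric mean, calculation method 1
#'
#' The rolling value for month m is the geometric mean of the seasonally
#' adjusted monthly geometric means of months m, m-1 and m-2. It requires
#' three consecutive months each containing at least one SCC test; otherwise
#' the month is incalculable (`NA`), including the first two months after
#' any calendar month without tests (a break in supply resets the window).
#' Method 1 uses all available SCC test results, whether or not a milk
#' volume was recorded, so the monthly statistics should be computed with
#' `include_scc_without_volume = TRUE`.
#'
#' @param monthly Monthly herd statistics from [monthly_stats()]; the
#'   seasonal adjustment is already baked into `adjusted_geo_mean_scc`.
#' @return A tibble `herd_id`, `year`, `month`, `method` ("method1"),
#'   `rolling_geo_mean` (x1000 cells/mL; `NA` when incalculable), with one
#'   row per herd per calendar month of the dataset's span.
#' @export
rolling_method1 <- function(monthly) {
  if (!nrow(monthly)) {
    abort("No monthly statistics supplied.", class = "bulkscc_domain_error")
  }
  grid <- month_grid(monthly$year, monthly$month)
  monthly %>%
    mutate(ym = ym_index(.data$year, .data$month)) %>%
    select(all_of(c("herd_id", "ym", "adjusted_geo_mean_scc"))) %>%
    rolling_from_month_values(grid, "method1")
}

#' Three-month rolling geometric mean, calculation method 2
#'
#' The rolling value for month m is the geometric mean of all individual
#' SCC test results in months m, m-1 and m-2, each test first multiplied by
#' its month's seasonal factor. By default only collection-day records with
#' both an SCC result and a milk volume are used (the DAFM convention); set
#' `include_scc_without_volume = TRUE` to admit volume-less tests. The same
#' three-consecutive-months calculability rule applies, evaluated on the
#' records eligible under the inclusion flag.
#'
#' @param records Cleaned collection records.
#' @param factors An `scc_factors` table.
#' @param include_scc_without_volume Whether SCC tests lacking a recorded
#'   volume enter the calculation (default `FALSE`).
#' @return A tibble as in [rolling_method1()], with `method` = "method2".
#' @export
rolling_method2 <- function(records, factors = seasonal_factors(),
                            include_scc_without_volume = FALSE) {
  records <- validate_records(records)
  factors <- seasonal_factors(factors)

  tests <- records %>%
    filter(!is.na(.data$scc))
  if (!include_scc_without_volume) {
    tests <- tests %>% filter(!is.na(.data$volume_litres))
  }
  if (!nrow(tests)) {
    abort("No eligible SCC tests in the record set.", class = "bulkscc_domain_error")
  }
  tests <- tests %>%
    mutate(year = as.integer(format(.data$collection_date, "%Y")),
           month = as.integer(format(.data$collection_date, "%m")),
           ym = ym_index(.data$year, .data$month),
           adj_scc = adjust_scc(.data$scc, .data$year, .data$month, factors))

  grid <- month_grid(tests$year, tests$month)

  # per herd-month: count of tests and sum of log adjusted values, so a
  # 3-month window pools individual tests exactly
  by_month <- tests %>%
    group_by(.data$herd_id, .data$ym) %>%
    summarise(n_tests = dplyr::n(),
              sum_log = sum(log(.data$adj_scc)), .groups = "drop")

  full <- tidyr::expand_grid(herd_id = unique(by_month$herd_id), ym = grid) %>%
    left_join(by_month, by = c("herd_id", "ym")) %>%
    mutate(n_tests = dplyr::coalesce(.data$n_tests, 0L),
           sum_log = dplyr::coalesce(.data$sum_log, 0)) %>%
    arrange(.data$herd_id, .data$ym) %>%
    group_by(.data$herd_id) %>%
    mutate(
      window_n = .data$n_tests + lag(.data$n_tests, 1, default = 0L) +
        lag(.data$n_tests, 2, default = 0L),
      window_sum = .data$sum_log + lag(.data$sum_log, 1, default = 0) +
        lag(.data$sum_log, 2, default = 0),
      calculable = row_number() >= 3L &
        .data$n_tests > 0L & lag(.data$n_tests, 1, default = 0L) > 0L &
        lag(.data$n_tests, 2, default = 0L) > 0L,
      rolling_geo_mean = ifelse(.data$calculable,
                                exp(.data$window_sum / .data$window_n), NA_real_)
    ) %>%
    ungroup()

  full %>%
    mutate(year = ym_year(.data$ym), month = ym_month(.data$ym),
           method = "method2") %>%
    select(all_of(c("herd_id", "year", "month", "method", "rolling_geo_mean"))) %>%
    arrange(.data$herd_id, .data$year, .data$month)
}

# Shared window logic for method 1: monthly summary values -> rolling
# geometric mean over 3 consecutive present months.
rolling_from_month_values <- function(values, grid, method) {
  full <- tidyr::expand_grid(herd_id = unique(values$herd_id), ym = grid) %>%
    left_join(values, by = c("herd_id", "ym")) %>%
    arrange(.data$herd_id, .data$ym) %>%
    group_by(.data$herd_id) %>%
    mutate(
      m0 = .data$adjusted_geo_mean_scc,
      m1 = lag(.data$m0, 1),
      m2 = lag(.data$m0, 2),
      calculable = row_number() >= 3L & !is.na(.data$m0) & !is.na(.data$m1) &
        !is.na(.data$m2),
      rolling_geo_mean = ifelse(.data$calculable,
                                exp((log(.data$m0) + log(.data$m1) + log(.data$m2)) / 3),
                                NA_real_)
    ) %>%
    ungroup()

  full %>%
    mutate(year = ym_year(.data$ym), month = ym_month(.data$ym), method = method) %>%
    select(all_of(c("herd_id", "year", "month", "method", "rolling_geo_mean"))) %>%
    arrange(.data$herd_id, .data$year, .data$month)
}

#' Three-month rolling geometric mean under either calculation method
#'
#' Convenience dispatcher: method 1 aggregates monthly geometric means,
#' method 2 pools individual adjusted tests.
#'
#' @param records Cleaned collection records.
#' @param factors An `scc_factors` table.
#' @param method 1/"method1" or 2/"method2".
#' @param include_scc_without_volume Inclusion flag for SCC tests without a
#'   recorded volume; defaults to the method's own convention (`TRUE` for
#'   method 1, `FALSE` for method 2).
#' @return A rolling-series tibble (see [rolling_method1()]).
#' @export
rolling_geo_mean <- function(records, factors = seasonal_factors(),
                             method = c("method1", "method2"),
                             include_scc_without_volume = NULL) {
  method <- normalize_method(method)
  if (method == "method1") {
    inc <- include_scc_without_volume %||% TRUE
    rolling_method1(monthly_stats(records, factors, include_scc_without_volume = inc))
  } else {
    inc <- include_scc_without_volume %||% FALSE
    rolling_method2(records, factors, include_scc_without_volume = inc)
  }
}

normalize_method <- function(method) {
  m <- as.character(method[[1]])
  if (m %in% c("1", "method1")) return("method1")
  if (m %in% c("2", "method2")) return("method2")
  abort("`method` must be 1/'method1' or 2/'method2'.", class = "bulkscc_config_error")
}
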