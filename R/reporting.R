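#' Run a full compliance scenario
#'
#' Executes the whole pipeline on cleaned records — monthly statistics,
#' three-month rolling geometric mean under the chosen calculation method,
#' the eligibility state machine, and the summary surfaces — either with the
#' seasonal adjustment applied or with the factor table replaced by all
#' ones.
#'
#' @param records Cleaned collection records.
#' @param factors An `scc_factors` table (ignored, i.e. replaced by the
#'   all-ones table, when `use_adjustment = FALSE`).
#' @param method Calculation method, 1/"method1" or 2/"method2".
#' @param use_adjustment Apply the seasonal adjustment?
#' @param include_scc_without_volume Inclusion flag for SCC tests without a
#'   recorded volume; default follows the method convention (`TRUE` for
#'   method 1, `FALSE` for method 2).
#' @param thresholds An `scc_thresholds` object.
#' @return An object of class `scc_scenario`: a list with
#'   `monthly_category_counts` (herds per SCC category per month),
#'   `monthly_category_volume` (litres per category per month),
#'   `monthly_status_counts` (herds per eligibility status per month),
#'   `max_levels` (per-herd maximum non-compliance),
#'   `max_level_counts` (herds per maximum level, all levels present),
#'   plus the `timeline`, `rolling` series, scenario metadata and the two
#'   denominators `n_herds_total` (all herds in the record set) and
#'   `n_herds_by_month` (herds supplying each month).
#' @export
run_scenario <- function(records, factors = irish_seasonal_factors(),
                         method = c("method1", "method2"),
                         use_adjustment = TRUE,
                         include_scc_without_volume = NULL,
                         thresholds = compliance_thresholds()) {
  records <- validate_records(records)
  if (!nrow(records)) {
    abort("Empty record set.", class = "bulkscc_domain_error")
  }
  method <- normalize_method(method)
  inc <- include_scc_without_volume %||% (method == "method1")
  fac <- if (use_adjustment) seasonal_factors(factors) else seasonal_factors()

  monthly <- monthly_stats(records, fac, include_scc_without_volume = inc,
                           thresholds = thresholds)
  rolling <- if (method == "method1") rolling_method1(monthly)
             else rolling_method2(records, fac, include_scc_without_volume = inc)
  timeline <- assign_statuses(rolling, thresholds)
  max_levels <- max_noncompliance(timeline)

  cat_counts <- monthly %>%
    count(.data$year, .data$month, .data$category, .drop = FALSE, name = "n_herds")
  cat_volume <- monthly %>%
    group_by(.data$year, .data$month, .data$category) %>%
    summarise(volume_litres = sum(.data$total_volume), .groups = "drop")
  status_counts <- timeline %>%
    count(.data$year, .data$month, .data$status, .drop = FALSE, name = "n_herds")
  max_counts <- max_levels %>%
    count(.data$level, .drop = FALSE, name = "n_herds")

  by_month <- records %>%
    mutate(year = as.integer(format(.data$collection_date, "%Y")),
           month = as.integer(format(.data$collection_date, "%m"))) %>%
    group_by(.data$year, .data$month) %>%
    summarise(n_herds = n_distinct(.data$herd_id), .groups = "drop")

  structure(
    list(
      scenario = if (use_adjustment) "with_adjustment" else "without_adjustment",
      method = method,
      include_scc_without_volume = inc,
      monthly_category_counts = cat_counts,
      monthly_category_volume = cat_volume,
      monthly_status_counts = status_counts,
      max_levels = max_levels,
      max_level_counts = max_counts,
      timeline = timeline,
      rolling = rolling,
      n_herds_total = n_distinct(records$herd_id),
      n_herds_by_month = by_month
    ),
    class = "scc_scenario"
  )
}

#' @export
print.scc_scenario <- function(x, ...) {
  cat("<scc_scenario> ", x$scenario, ", ", x$method,
      if (x$include_scc_without_volume) ", incl. SCC without volume" else "",
      "\n", sep = "")
  cat("  herds:", x$n_herds_total, "\n")
  print(x$max_level_counts)
  invisible(x)
}

#' @describeIn run_scenario `tidy()` returns the monthly status counts in
#'   long form, with the share of all herds in the dataset.
#' @param x An `scc_scenario` object.
#' @param ... Unused.
#' @export
tidy.scc_scenario <- function(x, ...) {
  x$monthly_status_counts %>%
    mutate(scenario = x$scenario, method = x$method,
           share_of_herds = .data$n_herds / x$n_herds_total)
}

#' @describeIn run_scenario `glance()` returns a one-row summary: herd
#'   count, number liable for suspension, number ever under warning.
#' @export
glance.scc_scenario <- function(x, ...) {
  counts <- setNames(x$max_level_counts$n_herds,
                     as.character(x$max_level_counts$level))
  tibble(
    scenario = x$scenario,
    method = x$method,
    n_herds = x$n_herds_total,
    n_always_compliant = counts[["always_compliant"]],
    n_ever_warned = sum(counts) - counts[["always_compliant"]],
    n_liable = counts[["liable_for_suspension"]],
    pct_liable = 100 * counts[["liable_for_suspension"]] / x$n_herds_total
  )
}

#' Cross-tabulate maximum non-compliance with vs without the adjustment
#'
#' Joint classification of each herd's maximum non-compliance level under
#' the two scenarios. Because every seasonal factor is at most 1, removing
#' the adjustment can never lower a herd's rolling means, so the
#' below-diagonal cells (less severe without adjustment) are structurally
#' zero. Also reports the relative change in the liable-for-suspension
#' count, (without - with) / with.
#'
#' @param with_adj,without_adj Either `scc_scenario` objects or the
#'   `max_levels` tibbles from [max_noncompliance()], computed on the same
#'   herd set.
#' @return An object of class `scc_crosstab`: list with `table` (long-form
#'   counts), `matrix` (5x5 count matrix, with-adjustment rows), liable
#'   counts under both scenarios and `relative_change_liable`.
#' @export
cross_tabulate <- function(with_adj, without_adj) {
  w <- if (inherits(with_adj, "scc_scenario")) with_adj$max_levels else as_tibble(with_adj)
  wo <- if (inherits(without_adj, "scc_scenario")) without_adj$max_levels else as_tibble(without_adj)
  if (!setequal(w$herd_id, wo$herd_id) || nrow(w) != nrow(wo)) {
    abort("The two scenarios cover different herd sets.", class = "bulkscc_domain_error")
  }
  lv <- noncompliance_levels()
  joined <- inner_join(
    w %>% select(all_of(c("herd_id", "level"))) %>% rename(level_with = "level"),
    wo %>% select(all_of(c("herd_id", "level"))) %>% rename(level_without = "level"),
    by = "herd_id"
  )
  tab_long <- joined %>%
    count(.data$level_with, .data$level_without, .drop = FALSE, name = "n_herds")
  mat <- matrix(tab_long$n_herds, nrow = length(lv), byrow = TRUE,
                dimnames = list(with_adjustment = lv, without_adjustment = lv))
  liable_with <- sum(joined$level_with == "liable_for_suspension")
  liable_without <- sum(joined$level_without == "liable_for_suspension")
  structure(
    list(
      table = tab_long,
      matrix = mat,
      n_herds = nrow(joined),
      liable_with = liable_with,
      liable_without = liable_without,
      relative_change_liable =
        if (liable_with > 0) (liable_without - liable_with) / liable_with else NA_real_
    ),
    class = "scc_crosstab"
  )
}

#' @export
print.scc_crosstab <- function(x, ...) {
  cat("<scc_crosstab> maximum non-compliance, with (rows) vs without (cols) adjustment\n")
  print(x$matrix)
  cat("liable for suspension:", x$liable_with, "->", x$liable_without)
  if (!is.na(x$relative_change_liable)) {
    cat(sprintf(" (%+.1f%%)", 100 * x$relative_change_liable))
  }
  cat("\n")
  invisible(x)
}

#' @describeIn cross_tabulate `tidy()` returns the long-form joint counts.
#' @param x An `scc_crosstab` object.
#' @param ... Unused.
#' @export
tidy.scc_crosstab <- function(x, ...) x$table

#' @describeIn cross_tabulate `glance()` returns the liable counts and the
#'   relative change in one row.
#' @export
glance.scc_crosstab <- function(x, ...) {
  tibble(n_herds = x$n_herds,
         liable_with = x$liable_with,
         liable_without = x$liable_without,
         relative_change_liable = x$relative_change_liable)
}

#' Descriptive statistics by record usability
#'
#' Records carrying a national herd identifier can be linked across years
#' and are termed usable; the rest (co-op codes or no identifier) unusable.
#' For each stratum this summarises the SCC test results and the herd-level
#' monthly volumes: record counts, mean, standard deviation and the
#' 5/25/50/75/95th percentiles. Percentiles use the default interpolation
#' convention of [stats::quantile()] (type 7).
#'
#' @param records Collection records with an `id_type` column.
#' @return A tibble with one row per stratum and variable (`scc`, on the
#'   x1000 cells/mL scale, and `monthly_volume` in litres).
#' @export
describe_usability <- function(records) {
  records <- validate_records(records)
  records <- records %>%
    mutate(usable = dplyr::if_else(.data$id_type == "national", "usable", "unusable"),
           year = as.integer(format(.data$collection_date, "%Y")),
           month = as.integer(format(.data$collection_date, "%m")))

  scc_part <- records %>%
    filter(!is.na(.data$scc)) %>%
    group_by(.data$usable) %>%
    summarise(variable = "scc", n = dplyr::n(),
              mean = mean(.data$scc), sd = sd(.data$scc),
              p5 = quantile(.data$scc, 0.05, names = FALSE),
              p25 = quantile(.data$scc, 0.25, names = FALSE),
              p50 = quantile(.data$scc, 0.50, names = FALSE),
              p75 = quantile(.data$scc, 0.75, names = FALSE),
              p95 = quantile(.data$scc, 0.95, names = FALSE), .groups = "drop")

  vol_part <- records %>%
    filter(!is.na(.data$volume_litres)) %>%
    group_by(.data$usable, .data$herd_id, .data$year, .data$month) %>%
    summarise(v = sum(.data$volume_litres), .groups = "drop") %>%
    group_by(.data$usable) %>%
    summarise(variable = "monthly_volume", n = dplyr::n(),
              mean = mean(.data$v), sd = sd(.data$v),
              p5 = quantile(.data$v, 0.05, names = FALSE),
              p25 = quantile(.data$v, 0.25, names = FALSE),
              p50 = quantile(.data$v, 0.50, names = FALSE),
              p75 = quantile(.data$v, 0.75, names = FALSE),
              p95 = quantile(.data$v, 0.95, names = FALSE), .groups = "drop")

  bind_rows(scc_part, vol_part) %>%
    select(all_of(c("usable", "variable", "n", "mean", "sd",
                    "p5", "p25", "p50", "p75", "p95"))) %>%
    arrange(.data$variable, dplyr::desc(.data$usable))
}
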