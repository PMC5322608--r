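#' Eligibility status levels
#'
#' Statuses in escalation order. `incalculable` is not a severity level; the
#' severity ordering used for maximum non-compliance is compliant <
#' warning_1 < warning_2 < warning_3 < liable_for_suspension.
#'
#' @return Character vector of all status levels.
#' @export
eligibility_statuses <- function() {
  c("incalculable", "compliant", "warning_1", "warning_2", "warning_3",
    "liable_for_suspension")
}

#' Maximum non-compliance levels
#' @return Character vector of levels in increasing severity.
#' @export
noncompliance_levels <- function() {
  c("always_compliant", "at_least_one_first_warning",
    "at_least_one_second_warning", "at_least_one_third_warning",
    "liable_for_suspension")
}

#' Assign monthly eligibility-to-supply statuses
#'
#' Runs the legislated state machine over a herd's rolling geometric mean
#' series. The status in month m is determined by the rolling mean of the
#' preceding month (a one-month lag):
#'
#' * `incalculable` when the preceding month's rolling mean is incalculable
#'   or outside the data;
#' * `compliant` when it does not exceed the suspension threshold (400 x1000
#'   cells/mL); compliance also ends a suspension;
#' * on an exceedance (strictly above the threshold), the warning level
#'   rises one step above the previous month's level — starting at
#'   `warning_1` from compliant or incalculable, and capping at
#'   `liable_for_suspension` after four consecutive exceedances.
#'
#' An incalculable gap resets the warning ladder: warnings do not survive a
#' break in supply. Together with the three-month burn-in of the rolling
#' mean, this means no herd can become liable for suspension during the
#' first six months after a break, and the first warning cannot occur before
#' the fourth month of supply.
#'
#' @param rolling A rolling-series tibble from [rolling_geo_mean()] (or
#'   either method function), covering every calendar month of the span.
#' @param thresholds An `scc_thresholds` object.
#' @return A tibble `herd_id`, `year`, `month`, `method`, `status` (factor
#'   over [eligibility_statuses()]).
#' @export
assign_statuses <- function(rolling, thresholds = compliance_thresholds()) {
  if (!nrow(rolling)) {
    abort("Empty rolling series.", class = "bulkscc_domain_error")
  }
  thr <- thresholds$suspension_threshold

  out <- rolling %>%
    arrange(.data$herd_id, ym_index(.data$year, .data$month)) %>%
    group_by(.data$herd_id) %>%
    mutate(prev_rolling = lag(.data$rolling_geo_mean, 1)) %>%
    ungroup()

  # warning level: 0 compliant, 1..3 warnings, 4 liable; NA incalculable.
  # level(m) = 0 if prev_rolling <= thr, min(level(m-1)+1, 4) if exceeded,
  # with NA (incalculable) treated as level 0 for escalation purposes.
  out <- out %>%
    group_by(.data$herd_id) %>%
    mutate(level = purrr::accumulate(
      .data$prev_rolling,
      function(prev_level, r) {
        if (is.na(r)) return(NA_integer_)
        if (r <= thr) return(0L)
        base <- if (is.na(prev_level)) 0L else prev_level
        min(base + 1L, 4L)
      },
      .init = NA_integer_
    )[-1]) %>%
    ungroup()

  statuses <- eligibility_statuses()
  out %>%
    mutate(status = factor(
      dplyr::if_else(is.na(.data$level), "incalculable",
                     statuses[.data$level + 2L]),
      levels = statuses
    )) %>%
    select(all_of(c("herd_id", "year", "month", "method", "status")))
}

#' Maximum level of non-compliance per herd
#'
#' Reduces a monthly eligibility timeline to the most severe status each
#' herd ever reached: herds whose calculable months were all compliant (or
#' that never had a calculable month) are `always_compliant`; otherwise the
#' highest warning or suspension level attained.
#'
#' @param timeline Output of [assign_statuses()].
#' @return A tibble `herd_id`, `method`, `level` (factor over
#'   [noncompliance_levels()]).
#' @export
max_noncompliance <- function(timeline) {
  if (!nrow(timeline)) {
    abort("Timeline has no months.", class = "bulkscc_domain_error")
  }
  sev <- c(incalculable = 0L, compliant = 0L, warning_1 = 1L, warning_2 = 2L,
           warning_3 = 3L, liable_for_suspension = 4L)
  lv <- noncompliance_levels()
  timeline %>%
    group_by(.data$herd_id, .data$method) %>%
    summarise(max_sev = max(sev[as.character(.data$status)]), .groups = "drop") %>%
    mutate(level = factor(lv[.data$max_sev + 1L], levels = lv)) %>%
    select(all_of(c("herd_id", "method", "level")))
}
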