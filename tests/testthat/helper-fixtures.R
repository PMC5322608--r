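# Shared fixtures, built in code.

# The published three-month worked example: a single herd resuming supply in
# January after a winter break. SCC on the x1000 cells/mL scale.
table2_scc <- list(
  jan = c(438, 540, 413, 402, 283, 345),
  feb = c(513, 328, 463, 662, 408, 504, 414),
  mar = c(659, 555, 394, 407, 288, 226, 287)
)

table2_records <- function(volume = 1000) {
  dates <- c(
    as.Date("2013-01-01") + (seq_along(table2_scc$jan) - 1) * 4,
    as.Date("2013-02-01") + (seq_along(table2_scc$feb) - 1) * 4,
    as.Date("2013-03-01") + (seq_along(table2_scc$mar) - 1) * 4
  )
  tibble::tibble(
    herd_id = "T2", id_type = "national", collection_date = dates,
    volume_litres = volume, scc = unlist(table2_scc, use.names = FALSE)
  )
}

# Records giving one herd a chosen adjusted monthly geometric mean per month
# (single test per month at the exact value; factor table all ones).
monthly_value_records <- function(values, months, herd_id = "h1", year = 2013) {
  tibble::tibble(
    herd_id = herd_id, id_type = "national",
    collection_date = as.Date(sprintf("%d-%02d-10", year, months)),
    volume_litres = 1000, scc = values
  )
}

# A rolling-series tibble from a named month -> value vector (NA allowed).
rolling_fixture <- function(values, months, herd_id = "h1",
                            method = "method1", year = 2013) {
  tibble::tibble(
    herd_id = herd_id, year = year, month = as.integer(months),
    method = method, rolling_geo_mean = values
  )
}

# Independent log-domain oracle for the 3-month rolling geometric mean of a
# set of per-month test values (list indexed by month number). Method 1
# averages the monthly mean-logs; method 2 pools all individual logs.
oracle_rolling <- function(tests_by_month, month, factors = NULL,
                           year = 2013, method = "method2") {
  window <- (month - 2):month
  if (any(window < 1)) return(NA_real_)
  logs <- lapply(window, function(m) {
    v <- if (m <= length(tests_by_month)) tests_by_month[[m]] else NULL
    if (is.null(v) || !length(v)) return(NULL)
    f <- if (is.null(factors)) 1 else bulkscc::factor_for_month(year, m, factors)
    log(v * f)
  })
  if (any(vapply(logs, is.null, logical(1)))) return(NA_real_)
  if (method == "method1") {
    exp(mean(vapply(logs, mean, numeric(1))))
  } else {
    exp(mean(unlist(logs)))
  }
}
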