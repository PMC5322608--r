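# A small population with known compliance structure: one herd always low,
# one chronically above 400 all year, one mid-year break that resets the
# window before a warning can accrue.
three_herd_records <- function() {
  dplyr::bind_rows(
    monthly_value_records(rep(120, 12), 1:12, herd_id = "low"),
    monthly_value_records(rep(480, 12), 1:12, herd_id = "high"),
    monthly_value_records(rep(480, 4), c(1:2, 7:8), herd_id = "broken")
  )
}

test_that("run_scenario wires the full pipeline with consistent counts", {
  rec <- three_herd_records()
  scn <- run_scenario(rec, seasonal_factors(), method = 1)

  expect_s3_class(scn, "scc_scenario")
  expect_equal(scn$n_herds_total, 3)
  lvl <- setNames(as.character(scn$max_levels$level), scn$max_levels$herd_id)
  expect_equal(lvl[["low"]], "always_compliant")
  expect_equal(lvl[["high"]], "liable_for_suspension")
  expect_equal(lvl[["broken"]], "always_compliant")

  # per month, category counts sum to herds with a monthly stat
  ms <- monthly_stats(rec)
  cat_by_month <- scn$monthly_category_counts %>%
    dplyr::group_by(month) %>% dplyr::summarise(n = sum(n_herds))
  stat_by_month <- ms %>% dplyr::count(month)
  expect_equal(cat_by_month$n[match(stat_by_month$month, cat_by_month$month)],
               stat_by_month$n)
  # per month, status counts sum to all herds on the grid
  st_by_month <- scn$monthly_status_counts %>%
    dplyr::group_by(month) %>% dplyr::summarise(n = sum(n_herds))
  expect_true(all(st_by_month$n == 3))
  # max-level counts sum to the herd total
  expect_equal(sum(scn$max_level_counts$n_herds), 3)

  expect_error(run_scenario(rec[0, ]), class = "bulkscc_domain_error")
})

test_that("a scenario on the worked-example herd assigns the March category from the adjusted mean", {
  scn <- run_scenario(table2_records(), irish_seasonal_factors(), method = 1)
  cc <- scn$monthly_category_counts
  expect_equal(cc$n_herds[cc$month == 3 & cc$category == "mid"], 1L)
  expect_equal(cc$n_herds[cc$month == 1 & cc$category == "low"], 1L)
})

test_that("all-ones factors with adjustment on equal the without-adjustment scenario", {
  rec <- three_herd_records()
  a <- run_scenario(rec, seasonal_factors(), method = 2, use_adjustment = TRUE)
  b <- run_scenario(rec, seasonal_factors(), method = 2, use_adjustment = FALSE)
  expect_equal(a$monthly_status_counts$n_herds, b$monthly_status_counts$n_herds)
  expect_equal(a$max_level_counts$n_herds, b$max_level_counts$n_herds)
  expect_equal(a$rolling$rolling_geo_mean, b$rolling$rolling_geo_mean)
})

test_that("removing the adjustment never lowers severity; lower triangle is zero", {
  rec <- clean_records(generate_herd_records(
    generator_config(n_herds = 150, seed = 77, scc_log_mean = log(320),
                     seasonal_scc_amplitude = 0.35)
  ))
  fac <- irish_seasonal_factors()
  for (m in 1:2) {
    with_adj <- run_scenario(rec, fac, method = m, use_adjustment = TRUE)
    without_adj <- run_scenario(rec, fac, method = m, use_adjustment = FALSE)
    xt <- cross_tabulate(with_adj, without_adj)
    expect_true(all(xt$matrix[lower.tri(xt$matrix)] == 0))
    expect_equal(sum(xt$matrix), xt$n_herds)
    expect_gte(xt$liable_without, xt$liable_with)
  }
})

test_that("cross-tabulation handles identical and toy scenarios", {
  lv <- noncompliance_levels()
  mk <- function(levels) tibble::tibble(
    herd_id = paste0("h", seq_along(levels)), method = "method1",
    level = factor(levels, levels = lv)
  )
  same <- mk(c("always_compliant", "liable_for_suspension", "at_least_one_first_warning"))
  xt <- cross_tabulate(same, same)
  expect_true(all(xt$matrix[row(xt$matrix) != col(xt$matrix)] == 0))
  expect_equal(xt$relative_change_liable, 0)

  w <- mk("always_compliant"); wo <- mk("at_least_one_first_warning")
  xt2 <- cross_tabulate(w, wo)
  expect_equal(xt2$matrix["always_compliant", "at_least_one_first_warning"], 1L)

  # 10 -> 11 liable is a +10% relative change
  w11 <- mk(c(rep("liable_for_suspension", 10), "at_least_one_third_warning"))
  wo_11 <- mk(rep("liable_for_suspension", 11))
  expect_equal(cross_tabulate(w11, wo_11)$relative_change_liable, 0.1)

  expect_error(cross_tabulate(mk("always_compliant"), mk(rep("always_compliant", 2))),
               class = "bulkscc_domain_error")
})

test_that("glance and tidy summarise scenarios and cross-tabs", {
  rec <- three_herd_records()
  scn <- run_scenario(rec, seasonal_factors(), method = 1)
  g <- glance(scn)
  expect_equal(g$n_herds, 3)
  expect_equal(g$n_liable, 1)
  td <- tidy(scn)
  expect_true(all(c("month", "status", "n_herds", "share_of_herds") %in% names(td)))
  expect_true(all(td$share_of_herds <= 1))

  xt <- cross_tabulate(scn, scn)
  expect_equal(glance(xt)$relative_change_liable, 0)
  expect_equal(sum(tidy(xt)$n_herds), 3)
})

test_that("usability descriptives stratify by national identifier", {
  rec <- dplyr::bind_rows(
    monthly_value_records(rep(150, 6), 1:6, herd_id = "u1"),
    monthly_value_records(rep(150, 6), 1:6, herd_id = "a1")
  )
  rec$id_type[rec$herd_id == "a1"] <- "coop"
  d <- describe_usability(rec)
  expect_equal(nrow(d), 4)  # 2 strata x 2 variables
  scc_rows <- d[d$variable == "scc", ]
  expect_true(all(scc_rows$p5 == 150 & scc_rows$p95 == 150 & scc_rows$sd == 0))
  # percentile ordering on arbitrary data
  rec2 <- generate_herd_records(generator_config(n_herds = 60, seed = 5))
  d2 <- describe_usability(clean_records(rec2))
  expect_true(all(d2$p5 <= d2$p25 & d2$p25 <= d2$p50 &
                    d2$p50 <= d2$p75 & d2$p75 <= d2$p95))
})

test_that("a tuned population reproduces the published monthly-volume median", {
  rec <- generate_herd_records(generator_config(n_herds = 800, seed = 2013))
  d <- describe_usability(rec)
  vol_usable <- d[d$variable == "monthly_volume" & d$usable == "usable", ]
  expect_equal(vol_usable$p50, 22164, tolerance = 0.10)
})

test_that("autoplot methods return ggplot objects", {
  scn <- run_scenario(three_herd_records(), seasonal_factors(), method = 1)
  expect_s3_class(autoplot(scn), "ggplot")
  expect_s3_class(autoplot(scn, what = "category"), "ggplot")
  expect_s3_class(autoplot(cross_tabulate(scn, scn)), "ggplot")
  expect_s3_class(plot_rolling_series(scn$rolling), "ggplot")
})
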