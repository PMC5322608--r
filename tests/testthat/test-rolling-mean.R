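test_that("both calculation methods reproduce the worked March rolling means", {
  rec <- table2_records()
  fac <- irish_seasonal_factors()

  r1 <- rolling_method1(monthly_stats(rec, fac))
  expect_equal(r1$method, rep("method1", 3))
  expect_true(all(is.na(r1$rolling_geo_mean[r1$month %in% 1:2])))
  expect_equal(round(r1$rolling_geo_mean[r1$month == 3], 2), 270.79,
               tolerance = 0.03 / 270.79)

  r2 <- rolling_method2(rec, fac)
  expect_true(all(is.na(r2$rolling_geo_mean[r2$month %in% 1:2])))
  expect_equal(round(r2$rolling_geo_mean[r2$month == 3], 2), 278.51,
               tolerance = 0.03 / 278.51)

  # dispatcher agrees with the method functions
  expect_equal(rolling_geo_mean(rec, fac, method = 1), r1)
  expect_equal(rolling_geo_mean(rec, fac, method = "method2"), r2)
})

test_that("three equal adjusted monthly means give a rolling mean equal to them", {
  rec <- monthly_value_records(c(250, 250, 250), 3:5)
  r1 <- rolling_geo_mean(rec, method = 1)
  expect_equal(r1$rolling_geo_mean[r1$month == 5], 250)
})

test_that("a missing month makes the two following months incalculable", {
  # data Jan-Aug except February: Mar + Apr incalculable, May first calculable
  months <- c(1, 3, 4, 5, 6, 7, 8)
  rec <- monthly_value_records(rep(300, length(months)), months)
  for (m in c("method1", "method2")) {
    r <- rolling_geo_mean(rec, method = m)
    calculable <- r$month[!is.na(r$rolling_geo_mean)]
    expect_equal(calculable, 5:8)
  }
})

test_that("methods agree when monthly test counts are equal, diverge otherwise", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n_per_month <- sample(1:4, 1)
      tests <- replicate(3, rlnorm(n_per_month, 5.5, 0.5), simplify = FALSE)
      rec <- tibble::tibble(
        herd_id = "h1", id_type = "national",
        collection_date = as.Date(unlist(lapply(4:6, function(m)
          sprintf("2013-%02d-%02d", m, seq_len(n_per_month))))),
        volume_litres = 1000,
        scc = unlist(tests)
      )
      v1 <- rolling_geo_mean(rec, method = 1)$rolling_geo_mean
      v2 <- rolling_geo_mean(rec, method = 2)$rolling_geo_mean
      expect_equal(v1[3], v2[3], tolerance = 1e-9)
    }
  })
  # unequal counts: method 2 weights months by test count
  rec <- tibble::tibble(
    herd_id = "h1", id_type = "national",
    collection_date = as.Date(c("2013-04-01", "2013-05-01", "2013-06-01",
                                "2013-06-02", "2013-06-03")),
    volume_litres = 1000, scc = c(100, 100, 400, 400, 400)
  )
  v1 <- rolling_geo_mean(rec, method = 1)$rolling_geo_mean[3]
  v2 <- rolling_geo_mean(rec, method = 2)$rolling_geo_mean[3]
  expect_equal(v1, exp(mean(log(c(100, 100, 400)))))
  expect_equal(v2, exp(mean(log(c(100, 100, 400, 400, 400)))))
  expect_gt(v2, v1)
})

test_that("both methods match a brute-force log-domain oracle on random histories", {
  fac <- irish_seasonal_factors()
  withr::with_seed(41, {
    for (i in 1:60) {
      # random per-month test counts, including empty months (breaks)
      counts <- sample(0:3, 12, replace = TRUE, prob = c(0.25, 0.3, 0.3, 0.15))
      tests <- lapply(counts, function(k) if (k) rlnorm(k, 5.4, 0.5) else numeric())
      rows <- purrr::imap(tests, function(v, m) {
        if (!length(v)) return(NULL)
        tibble::tibble(herd_id = "h1", id_type = "national",
                       collection_date = as.Date(sprintf("2013-%02d-%02d", m, seq_along(v))),
                       volume_litres = 1000, scc = v)
      })
      rec <- dplyr::bind_rows(rows)
      if (sum(counts > 0) < 1) next
      r1 <- rolling_geo_mean(rec, fac, method = 1)
      r2 <- rolling_geo_mean(rec, fac, method = 2)
      grid_months <- r1$month
      for (m in grid_months) {
        e1 <- oracle_rolling(tests, m, fac, method = "method1")
        e2 <- oracle_rolling(tests, m, fac, method = "method2")
        a1 <- r1$rolling_geo_mean[r1$month == m]
        a2 <- r2$rolling_geo_mean[r2$month == m]
        # the dataset boundary rule: oracle sees month 1 as the first month too
        expect_equal(is.na(a1), is.na(e1))
        if (!is.na(e1)) expect_equal(a1, e1, tolerance = 1e-12)
        expect_equal(is.na(a2), is.na(e2))
        if (!is.na(e2)) expect_equal(a2, e2, tolerance = 1e-12)
      }
    }
  })
})

test_that("the rolling value only depends on the 3-month window", {
  rec <- monthly_value_records(c(100, 200, 300, 400, 500), 2:6)
  base <- rolling_geo_mean(rec, method = 2)
  perturbed <- rec
  perturbed$scc[perturbed$collection_date == as.Date("2013-02-10")] <- 9999
  after <- rolling_geo_mean(perturbed, method = 2)
  # months 6 window = Apr..Jun, unaffected by the February edit
  expect_equal(after$rolling_geo_mean[after$month == 6],
               base$rolling_geo_mean[base$month == 6])
  expect_false(isTRUE(all.equal(after$rolling_geo_mean[after$month == 4],
                                base$rolling_geo_mean[base$month == 4])))
})

test_that("method 2 calculability follows its own eligible record set", {
  # May's only SCC test lacks a volume: method 2 (excluding such tests) sees
  # a break, method 1 does not
  rec <- monthly_value_records(rep(300, 4), 4:7)
  rec$volume_litres[rec$collection_date == as.Date("2013-05-10")] <- NA
  r1 <- rolling_geo_mean(rec, method = 1)
  r2 <- rolling_geo_mean(rec, method = 2)
  r2inc <- rolling_geo_mean(rec, method = 2, include_scc_without_volume = TRUE)
  expect_false(is.na(r1$rolling_geo_mean[r1$month == 6]))
  expect_true(is.na(r2$rolling_geo_mean[r2$month == 6]))
  expect_true(is.na(r2$rolling_geo_mean[r2$month == 7]))
  expect_false(is.na(r2inc$rolling_geo_mean[r2inc$month == 6]))
})
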