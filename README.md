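# bulkscc

Compliance analysis of bulk-tank somatic cell counts (SCC) for dairy herds
supplying raw milk for manufacture.

## The problem

EU regulations make a herd's eligibility to supply raw milk depend on its
bulk-tank SCC: the three-month rolling geometric mean must not exceed
400,000 cells/mL, with up to three monthly warnings before the herd becomes
liable for suspension. In Ireland, SCC values from November to February are
additionally multiplied by seasonal adjustment factors below 1 (e.g. 0.39 in
January 2013), introduced to offset a presumed winter concentration of SCC
at low milk volumes — a dilution effect that recent Irish evidence does not
support. `bulkscc` is for veterinary epidemiologists, milk purchasers and
regulators who need to compute these statistics from collection-day records
and to quantify what removing the seasonality adjustment would do to herd
eligibility.

The core statistic is the three-month rolling geometric mean. For a herd
with adjusted SCC values in months *m*−2, *m*−1, *m*, the two calculation
methods the legislation admits are

* **method 1**: GM(GM(month *m*−2), GM(month *m*−1), GM(month *m*)) of the
  seasonally adjusted monthly geometric means, where
  GM(x₁…xₙ) = (x₁·…·xₙ)^(1/n) = exp(mean(log xᵢ));
* **method 2**: GM of **all individual** adjusted tests in the window, so
  months are weighted by their test counts.

A rolling value exists only when all three months contain at least one
eligible test; a calendar month without supply resets the window. The
status of month *m* follows from the rolling mean of month *m*−1:
compliant (≤ 400), or one warning step above the previous month's level on
a strict exceedance, capping at liable-for-suspension after four
consecutive exceedances.

## Worked example

A herd resumes supply in January after a winter break, with 6, 7 and 7 SCC
tests (×1000 cells/mL) in January–March:

```r
library(bulkscc)
library(dplyr)

jan <- c(438, 540, 413, 402, 283, 345)
feb <- c(513, 328, 463, 662, 408, 504, 414)
mar <- c(659, 555, 394, 407, 288, 226, 287)
herd <- tibble::tibble(
  herd_id = "example", id_type = "national",
  collection_date = c(as.Date("2013-01-01") + (seq_along(jan) - 1) * 4,
                      as.Date("2013-02-01") + (seq_along(feb) - 1) * 4,
                      as.Date("2013-03-01") + (seq_along(mar) - 1) * 4),
  volume_litres = 1000, scc = c(jan, feb, mar)
)

fac <- irish_seasonal_factors()
monthly_stats(clean_records(herd), fac) %>%
  transmute(month, n_scc_tests,
            across(c(arith_mean_scc, geo_mean_scc, adjusted_geo_mean_scc),
                   ~round(.x, 2)),
            category)
#>   month n_scc_tests arith_mean_scc geo_mean_scc adjusted_geo_mean_scc category
#> 1     1           6         403.50       395.62                154.29      low
#> 2     2           7         470.29       460.49                340.76      mid
#> 3     3           7         402.29       377.65                377.65      mid
```

January's geometric mean 395.62 is multiplied by the 2013 January factor
0.39 to give the adjusted mean 154.29, moving the herd from the high to the
low SCC category. March is the first month with three consecutive months of
tests, so it carries the first rolling value:

```r
rolling_geo_mean(clean_records(herd), fac, method = 1)$rolling_geo_mean[3]
#> 270.79   # geometric mean of the three adjusted monthly means
rolling_geo_mean(clean_records(herd), fac, method = 2)$rolling_geo_mean[3]
#> 278.51   # geometric mean of all 20 individually adjusted tests
```

Both are below 400, so the herd would be compliant in April. On a synthetic
population (no national bulk-tank dataset is public; the generator emulates
its structure), the with/without-adjustment comparison runs end to end:

```r
rec <- clean_records(generate_herd_records(
  generator_config(n_herds = 250, seed = 101,
                   scc_log_mean = log(310), seasonal_scc_amplitude = 0.35)))
w  <- run_scenario(rec, fac, method = 2, use_adjustment = TRUE)
wo <- run_scenario(rec, fac, method = 2, use_adjustment = FALSE)
glance(w)
#>   scenario        method  n_herds n_always_compliant n_ever_warned n_liable pct_liable
#> 1 with_adjustment method2     250                187            63       19        7.6
cross_tabulate(w, wo)
#> liable for suspension: 19 -> 21 (+10.5%)
```

Removing the adjustment never moves a herd to a *less* severe maximum
level (all factors are ≤ 1), so the cross-tabulation's lower triangle is
structurally zero and the liable count can only rise — here from 19 to 21
herds (+10.5%).

A command-line wrapper with `simulate`, `clean`, `run` and `compare`
subcommands is installed at
`system.file("scripts", "bulkscc", package = "bulkscc")`.

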