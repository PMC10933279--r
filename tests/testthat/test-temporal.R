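make_panel <- function(values_by_area, dates, variable = "X") {
  dplyr::bind_rows(lapply(names(values_by_area), function(a) {
    tibble::tibble(area_id = a, date = dates, variable = variable,
                   value = values_by_area[[a]])
  }))
}

test_that("region-mean series averages areas day by day", {
  dates <- as.Date("2020-01-01") + 0:9
  one <- make_panel(list(A = 1:10), dates)
  expect_equal(bw_mean_series(one)$X, as.numeric(1:10))

  two <- make_panel(list(A = 1:10, B = 3:12), dates)
  expect_equal(bw_mean_series(two)$X, as.numeric(2:11))
})

test_that("region-mean series matches an independent two-loop oracle", {
  study <- local({
    cfg <- synthetic_config(nx = 3, ny = 3, n_days = 15, seed = 8)
    simulate_panel(cfg, make_lattice(3, 3, seed = 8))
  })
  series <- bw_mean_series(study)
  sub <- study[study$variable == "NO2", ]
  oracle <- oracle_group_mean(as.character(sub$date), sub$value)
  expect_equal(series$NO2, unname(oracle[as.character(series$date)]),
               tolerance = 1e-12)
})

test_that("correlation matrices handle exact, hand-computed and degenerate cases", {
  rec <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3),
                        up = 1:4 * 2, down = -(1:4), flat = rep(5, 4))
  m <- correlation_matrix(rec, c("x", "y", "up", "down", "flat"))
  expect_equal(m$r["x", "up"], 1)
  expect_equal(m$r["x", "down"], -1)
  expect_equal(m$r["x", "y"], 0.6)
  expect_true(all(is.na(m$r["flat", ])))      # constant: undefined, not zero
  expect_equal(m$r, t(m$r))
  expect_equal(diag(m$r)[c("x", "y")], c(x = 1, y = 1))
  expect_equal(m$n["x", "y"], 4)
  td <- tidy(m)
  expect_equal(nrow(td), choose(5, 2))
})

test_that("strength taxonomy reproduces the printed cut points and is total", {
  expect_equal(as.character(classify_strength(0.94)), "almost perfect")
  expect_equal(as.character(classify_strength(-0.68)), "large")
  expect_equal(as.character(classify_strength(0.1)), "trivial")
  expect_equal(
    as.character(classify_strength(c(-1, -0.9, 0.3, 0.5, 0.7, 0.9, 1))),
    c("almost perfect", "very large", "small", "moderate", "large",
      "very large", "almost perfect")
  )
  expect_false(anyNA(classify_strength(seq(-1, 1, by = 0.01))))
  expect_error(classify_strength(1.2), class = "stressorscape_domain_error")
})

test_that("monthly matrices isolate season-specific coupling", {
  # NO2 = -O3 + noise in January; positively coupled in July
  dates <- as.Date("2020-01-01") + 0:365
  mon <- as.integer(format(dates, "%m"))
  set.seed(42)
  o3 <- 50 + rnorm(length(dates), sd = 10)
  no2 <- ifelse(mon == 1, 60 - o3, ifelse(mon == 7, o3 - 40, rnorm(length(dates))))
  no2 <- no2 + rnorm(length(dates), sd = 0.1)
  panel <- dplyr::bind_rows(
    tibble::tibble(area_id = "A", date = dates, variable = "O3", value = o3),
    tibble::tibble(area_id = "A", date = dates, variable = "NO2", value = no2)
  )
  mm <- monthly_matrices(panel, variables = c("NO2", "O3"))
  expect_length(mm, 12)
  expect_lt(mm[["01"]]$r["NO2", "O3"], -0.99)
  expect_gt(mm[["07"]]$r["NO2", "O3"], 0.99)
  expect_equal(mm[["03"]]$stratum, "month=03")
  # pure function of its input
  mm2 <- monthly_matrices(panel, variables = c("NO2", "O3"))
  expect_identical(lapply(mm, `[[`, "r"), lapply(mm2, `[[`, "r"))
})

test_that("sign-change accounting counts strictly opposite pairs", {
  rec <- tibble::tibble(a = rnorm(20))
  rec$b <- rec$a + rnorm(20, sd = 0.1)
  rec$c <- -rec$a + rnorm(20, sd = 0.1)
  m1 <- correlation_matrix(rec, c("a", "b", "c"), "s1")
  expect_equal(sign_change_count(m1, m1)$count, 0)

  m2 <- m1
  m2$r <- -m1$r
  full_flip <- sign_change_count(m1, m2)
  expect_equal(full_flip$count, full_flip$total_pairs)

  m3 <- m1
  m3$r["a", "c"] <- m3$r["c", "a"] <- -m1$r["a", "c"]  # flip one pair back
  one <- sign_change_count(m1, m3)
  expect_equal(one$count, 1)
  expect_equal(sort(c(one$pairs$var_a, one$pairs$var_b)), c("a", "c"))

  # symmetry and the C(V,2) bound
  expect_equal(sign_change_count(m3, m1)$count, one$count)
  expect_lte(one$count, choose(3, 2))

  m4 <- correlation_matrix(rec[, c("a", "b")], c("a", "b"))
  expect_error(sign_change_count(m1, m4), class = "stressorscape_frame_error")
})

test_that("eight stressor variables give 28 distinct pairs", {
  study <- local({
    cfg <- synthetic_config(nx = 3, ny = 3, n_days = 400, seed = 2)
    simulate_panel(cfg, make_lattice(3, 3, seed = 2))
  })
  rep <- sign_change_report(monthly_matrices(study))
  expect_equal(rep$total_pairs, 28)
  expect_equal(sign_change_report(monthly_matrices(study), "04", "04")$count, 0)
})

test_that("cross-correlation matches the direct-evaluation oracle at all lags", {
  set.seed(7)
  x <- rnorm(50)
  y <- 0.5 * x + rnorm(50)
  cc <- cross_correlation(x, y, 20)
  expect_lt(max(abs(cc$ccf - oracle_ccf(x, y, 20))), 1e-12)
  expect_true(all(abs(cc$ccf) <= 1 + 1e-12))
  expect_equal(cc$ccf[cc$lag == 0], cor(x, y))
  expect_true(all(diff(cc$n_overlap[cc$lag >= 0]) <= 0))
})

test_that("cross-correlation honors its sign convention and symmetry", {
  set.seed(8)
  x <- rnorm(400)
  y <- dplyr::lag(x, 5)  # y(t) = x(t - 5): x leads y by 5
  cc <- cross_correlation(x, y, 12)
  expect_equal(cc$lag[which.max(cc$ccf)], 5)

  ccr <- cross_correlation(y, x, 12)
  expect_equal(cc$ccf, rev(ccr$ccf), tolerance = 1e-12)

  t <- 1:1095
  cs <- cross_correlation(sin(2 * pi * t / 365), cos(2 * pi * t / 365), 120)
  expect_lt(abs(cs$ccf[cs$lag == 0]), 0.01)
  expect_gt(abs(cs$ccf[cs$lag == 91]), 0.99)
  expect_gt(abs(cs$ccf[cs$lag == -91]), 0.99)

  expect_error(cross_correlation(1:5, 1:6, 2), class = "stressorscape_frame_error")
  expect_error(cross_correlation(1:5, 1:5, 10), class = "stressorscape_domain_error")
})

test_that("autocorrelation reproduces known closed forms", {
  expect_equal(autocorrelation(rnorm(30), 5)$ccf[6], 1)

  set.seed(9)
  n <- 10000
  wn <- rnorm(n)
  aw <- autocorrelation(wn, 20)
  expect_lt(max(abs(aw$ccf[aw$lag != 0])), 0.05)  # ~2/sqrt(n) bound

  rho <- 0.8
  ar <- numeric(n)
  ar[1] <- rnorm(1)
  for (i in 2:n) ar[i] <- rho * ar[i - 1] + rnorm(1)
  ac <- autocorrelation(ar, 5)
  expect_equal(ac$ccf[ac$lag %in% 1:5], rho^(1:5), tolerance = 0.08)

  t <- 1:1095
  per <- autocorrelation(sin(2 * pi * t / 365), 365)
  expect_gt(per$ccf[per$lag == 365], 0.999)
})

test_that("monthly ccf aggregates to calendar months before lagging", {
  dates <- as.Date("2018-01-01") + 0:1094
  t <- seq_along(dates)
  x <- sin(2 * pi * t / 365.25)
  panel <- dplyr::bind_rows(
    tibble::tibble(area_id = "A", date = dates, variable = "UV", value = x),
    tibble::tibble(area_id = "A", date = dates, variable = "NO2", value = -x)
  )
  cc <- monthly_ccf(panel, "UV", "NO2", 8)
  expect_lt(cc$ccf[cc$lag == 0], -0.95)   # anti-phase at lag 0
  expect_gt(cc$ccf[cc$lag == 6], 0.9)     # back in phase after ~half a year
  expect_gt(cc$ccf[cc$lag == -6], 0.9)

  # month aggregation equals a brute-force per-month mean: the lag-0
  # coefficient must equal the correlation of the oracle monthly means
  series <- bw_mean_series(panel)
  key <- format(series$date, "%Y-%m")
  ox <- oracle_group_mean(key, series$UV)
  oy <- oracle_group_mean(key, series$NO2)
  expect_equal(cc$ccf[cc$lag == 0], cor(ox, oy), tolerance = 1e-12)

  flat <- dplyr::mutate(panel, value = 1)
  ccf_flat <- monthly_ccf(flat, "UV", "NO2", 3)
  expect_true(all(is.na(ccf_flat$ccf)))
})
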