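test_that("contiguity weights enumerate lattice neighborhoods correctly", {
  a3 <- make_lattice(3, 3, seed = 1)
  wq <- build_weights(a3, "queen")
  deg_q <- lengths(wq$neighbors)
  # corners 3, edge midpoints 5, center 8
  expect_equal(sort(unique(deg_q)), c(3, 5, 8))
  expect_equal(deg_q[5], 8)
  expect_equal(sum(deg_q == 3), 4)

  wr <- build_weights(a3, "rook")
  expect_equal(lengths(wr$neighbors)[5], 4)
  expect_equal(sort(unique(lengths(wr$neighbors))), c(2, 3, 4))

  # adjacency is symmetric; standardized rows sum to one
  wm <- weights_matrix(wq)
  expect_equal((wm > 0), t(wm > 0))
  expect_equal(unname(rowSums(wm)), rep(1, 9))
  wb <- weights_matrix(build_weights(a3, "queen", standardize = FALSE))
  expect_true(all(wb %in% c(0, 1)))

  expect_error(build_weights(a3[0, ]), class = "stressorscape_frame_error")
})

# islands need >= 3 included areas; pad the fixture with a second pair
padded_island_weights <- function(areas) {
  sq <- function(x0, y0) {
    cbind(x = c(x0, x0 + 1, x0 + 1, x0, x0), y = c(y0, y0, y0 + 1, y0 + 1, y0))
  }
  extra <- tibble::tibble(id = c("L2", "R2"), x = c(0.5, 1.5), y = c(5.5, 5.5),
                          area_km2 = 1, population = 1L,
                          geometry = list(sq(0, 5), sq(1, 5)))
  all <- dplyr::bind_rows(areas, extra)
  class(all) <- c("area_set", class(all))
  build_weights(all, "queen")
}

test_that("areas without neighbors are reported as islands", {
  areas <- island_area_set()
  W <- build_weights(areas, "queen")
  expect_equal(W$islands, "FAR")
  expect_equal(W$ids[W$neighbors[[1]]], "R")
  # islands carry no statistic downstream
  Wp <- padded_island_weights(areas)
  lm <- local_moran(
    tibble::tibble(area_id = Wp$ids, value = c(1, 2, 99, 1.5, 2.5)), Wp
  )
  expect_true(is.na(lm$I[lm$area_id == "FAR"]))
})

test_that("per-area period means reduce the panel faithfully", {
  cfg <- synthetic_config(nx = 3, ny = 3, n_days = 10, seed = 4)
  areas <- make_lattice(3, 3, seed = 4)
  panel <- simulate_panel(cfg, areas)

  one_day <- period_mean_by_area(panel, "O3",
                                 window = c(cfg$start_date, cfg$start_date))
  d1 <- panel[panel$variable == "O3" & panel$date == cfg$start_date, ]
  expect_equal(one_day$value[match(d1$area_id, one_day$area_id)], d1$value)

  full <- period_mean_by_area(panel, "O3")
  sub <- panel[panel$variable == "O3", ]
  oracle <- oracle_group_mean(sub$area_id, sub$value)
  expect_equal(full$value, unname(oracle[full$area_id]), tolerance = 1e-12)

  expect_error(period_mean_by_area(panel, "XX"),
               class = "stressorscape_key_error")
})

test_that("local Moran's I matches the literal formula transcription", {
  withr::with_seed(21, {
    for (rep in 1:6) {
      nx <- sample(3:6, 1)
      ny <- sample(3:6, 1)
      areas <- make_lattice(nx, ny, seed = rep)
      x <- rnorm(nx * ny)
      for (scheme in c("queen", "rook")) {
        for (std in c(TRUE, FALSE)) {
          W <- build_weights(areas, scheme, standardize = std)
          got <- local_moran(tibble::tibble(area_id = areas$id, value = x), W)
          want <- oracle_local_moran(x, weights_matrix(W))
          expect_lt(max(abs(got$I - want)), 1e-12)
        }
      }
    }
  })
})

test_that("local Moran's I has the expected invariances and degeneracies", {
  areas <- make_lattice(5, 5, seed = 3)
  W <- build_weights(areas, "queen")
  x <- withr::with_seed(5, rnorm(25))
  v <- function(vals) tibble::tibble(area_id = areas$id, value = vals)
  base <- local_moran(v(x), W)$I
  expect_equal(local_moran(v(x + 100), W)$I, base, tolerance = 1e-9)
  expect_equal(local_moran(v(3 * x), W)$I, base, tolerance = 1e-9)

  expect_error(local_moran(v(rep(1, 25)), W),
               class = "stressorscape_degenerate_error")

  # checkerboard: pure negative spatial association under rook contiguity
  a4 <- make_lattice(4, 4, seed = 1)
  chk <- ifelse((a4$row + a4$col) %% 2 == 0, 1, -1)
  lm <- local_moran(tibble::tibble(area_id = a4$id, value = chk),
                    build_weights(a4, "rook"))
  expect_true(all(lm$I < 0))
})

test_that("mean of local statistics equals global Moran's I under row standardization", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      areas <- make_lattice(sample(4:6, 1), sample(4:6, 1), seed = rep)
      W <- build_weights(areas, "queen", standardize = TRUE)
      x <- rnorm(nrow(areas))
      lm <- local_moran(tibble::tibble(area_id = areas$id, value = x), W,
                        variance = "global")
      expect_equal(mean(lm$I), oracle_global_moran(x, weights_matrix(W)),
                   tolerance = 1e-9)
    }
  })
})

test_that("conditional permutation p-values are seeded, positive and bounded", {
  areas <- make_lattice(5, 5, seed = 2)
  W <- build_weights(areas, "queen")
  vals <- tibble::tibble(area_id = areas$id, value = withr::with_seed(6, rnorm(25)))

  p1 <- permutation_pvalues(vals, W, n_perm = 199, seed = 11)
  p2 <- permutation_pvalues(vals, W, n_perm = 199, seed = 11)
  expect_identical(p1$p, p2$p)
  expect_true(all(p1$p > 0 & p1$p <= 1))

  # directional one-sided floor is 1/(n_perm + 1)
  pd <- permutation_pvalues(vals, W, n_perm = 999, seed = 12,
                            alternative = "directional")
  expect_gte(min(pd$p), 1 / 1000)

  expect_error(permutation_pvalues(vals, W, n_perm = 50),
               class = "stressorscape_config_error")
})

test_that("quadrant classification recovers planted structure", {
  areas <- make_lattice(10, 10, seed = 4)
  W <- build_weights(areas, "queen")
  block <- areas$id[areas$row %in% 3:5 & areas$col %in% 3:5]
  base <- withr::with_seed(13, rnorm(100))

  for (delta in c(8, -8)) {
    x <- base + ifelse(areas$id %in% block, delta, 0)
    vals <- tibble::tibble(area_id = areas$id, value = x)
    p <- permutation_pvalues(vals, W, n_perm = 499, seed = 14)
    res <- classify_quadrants(vals, W, p, alpha = 0.05)
    want <- if (delta > 0) "HH" else "LL"
    hits <- res$label[res$area_id %in% block]
    expect_gte(sum(hits == want), 8)
  }

  # checkerboard: any significant area is a spatial outlier, never HH/LL
  a4 <- make_lattice(4, 4, seed = 1)
  W4 <- build_weights(a4, "rook")
  chk <- tibble::tibble(area_id = a4$id,
                        value = ifelse((a4$row + a4$col) %% 2 == 0, 1, -1))
  p4 <- permutation_pvalues(chk, W4, n_perm = 199, seed = 15)
  r4 <- classify_quadrants(chk, W4, p4, alpha = 0.05)
  expect_true(all(r4$label %in% c("HL", "LH", "ns")))

  # every area gets exactly one label
  expect_true(all(table(r4$area_id) == 1))
  expect_true(all(r4$label %in% c("HH", "LL", "HL", "LH", "ns")))
})

test_that("significance bins follow the display thresholds", {
  expect_equal(as.character(significance_bins(c(0.0005, 0.005, 0.03, 0.2))),
               c("0.001", "0.01", "0.05", "ns"))
  expect_error(significance_bins(0), class = "stressorscape_domain_error")
  expect_error(significance_bins(1.1), class = "stressorscape_domain_error")
})

test_that("stratum tables partition areas and recover planted contrasts", {
  cfg <- synthetic_config(nx = 6, ny = 6, n_days = 120, seed = 16)
  areas <- make_lattice(6, 6, seed = 16)
  panel <- simulate_panel(cfg, areas)
  block <- areas$id[areas$row %in% 2:4 & areas$col %in% 2:4]
  delta <- 12
  planted_hot <- plant_cluster(panel, block, "NO2", delta)
  cold <- areas$id[areas$row == 6 & areas$col %in% 1:3]
  planted <- plant_cluster(planted_hot, cold, "NO2", -delta)

  res <- lisa_hotspots(planted, areas, "NO2", n_perm = 499, seed = 17)
  tab <- lisa_strata_summary(planted, res, "NO2")
  expect_equal(sum(tab$n_areas), nrow(areas))
  hot_mean <- tab$mean[tab$stratum == "hot"]
  cold_mean <- tab$mean[tab$stratum == "cold"]
  expect_gt(hot_mean - cold_mean, delta)  # planted 2*delta contrast, minus noise

  # with nothing significant, the non-significant stratum is the whole panel
  flat_lisa <- res
  flat_lisa$label <- "ns"
  flat_lisa$island <- FALSE
  tab2 <- lisa_strata_summary(panel, flat_lisa, "O3")
  o3 <- panel$value[panel$variable == "O3"]
  expect_equal(tab2$n_obs[tab2$stratum == "non-significant"], length(o3))
  expect_equal(tab2$mean[tab2$stratum == "non-significant"], mean(o3))
  expect_equal(tab2$n_obs[tab2$stratum == "hot"], 0L)
})

test_that("density stratum summaries match a brute-force groupby", {
  cfg <- synthetic_config(nx = 5, ny = 5, n_days = 60, seed = 18)
  areas <- make_lattice(5, 5, seed = 18)
  panel <- simulate_panel(cfg, areas)
  tab <- density_strata_summary(panel, areas)

  cats <- categorize_density(population_density(areas$population, areas$area_km2))
  sub <- panel[panel$variable == "NO2", ]
  sub$cat <- cats[match(sub$area_id, areas$id)]
  for (cc in unique(sub$cat)) {
    vals <- sub$value[sub$cat == cc]
    row <- tab[tab$variable == "NO2" & tab$category == cc, ]
    expect_equal(row$mean, mean(vals), tolerance = 1e-12)
    expect_equal(row$sd, sd(vals), tolerance = 1e-12)
    expect_equal(row$median, median(vals), tolerance = 1e-12)
    expect_equal(c(row$min, row$max), range(vals))
  }

  # single-category frame reduces to whole-panel statistics
  uniform <- areas
  uniform$population <- 100L
  tab1 <- density_strata_summary(panel, uniform)
  expect_equal(nrow(tab1), 8)
  expect_equal(tab1$mean[tab1$variable == "NO2"], mean(sub$value))
})
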