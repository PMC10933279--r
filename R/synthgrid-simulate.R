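#' Configuration for the synthetic stressor panel generator
#'
#' Collects every tunable of the generator in one validated object. The
#' defaults emulate the qualitative covariation structure of a regional
#' daily panel of meteorology and air quality: an annual temperature
#' cycle with dewpoint tracking temperature (so vapor pressure and
#' temperature are near-perfectly correlated), a shared summer UV driver
#' for ozone, a winter-weighted NO2 titration term that flips the
#' NO2-O3 correlation sign between winter and summer, particulate matter
#' as fine mode plus an independent coarse mode, monotone density
#' gradients for NO2/PM (up) and O3 (down), zero-inflated precipitation
#' anti-coupled to UV, and a smooth spatial Gaussian random field per
#' variable so that spatial clusters exist for hot-spot detection.
#'
#' @param nx,ny Lattice dimensions (cells), each at least 3.
#' @param n_days Number of days simulated (default three years).
#' @param start_date First calendar day (Date or string).
#' @param seed Integer seed for the whole simulation.
#' @param range Correlation length of the spatial fields, in cell units.
#' @param beta_uv_o3 Coefficient of UV (W/m2) in the O3 equation.
#' @param titration_strength Winter-weighted coefficient of the NO2
#'   anomaly subtracted from O3 (the NO-titration surrogate).
#' @param c_no2_uv Summer-weighted coefficient coupling NO2 to the UV
#'   anomaly (shared photochemical driver).
#' @param density_effect_no2,density_effect_o3,density_effect_pm Change
#'   in the variable's mean (ug/m3) per log10 unit of population
#'   density; NO2 and PM increase, O3 decreases, with urbanization.
#' @param pm_coarse_frac Mean coarse-mode PM as a fraction of the fine
#'   (PM2.5) base level; PM10 = PM2.5 + coarse.
#' @param rho Named vector of AR(1) coefficients for the region-wide
#'   daily noise of each driver (all in `[0, 1)`).
#' @param ar_sd Named vector of stationary AR(1) marginal sds.
#' @param spatial_sd Named vector of spatial-field sds (the static
#'   between-area variation of each variable).
#' @param noise_sd Named vector of iid per-record measurement noise sds.
#' @param seasonal Named list of seasonal cycle parameters (bases,
#'   amplitudes, peak days of year).
#' @param prec_wet_prob Probability that a day is wet (region-wide).
#' @param prec_shape,prec_mean_wet Gamma shape and mean (mm/day) of
#'   wet-day precipitation amounts.
#' @param cloud_uv_reduction Fractional UV reduction on wet days.
#' @param urban_centers Passed to [make_lattice()] when the lattice is
#'   generated by the pipeline; `NULL` for the default single center.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(nx = 20, ny = 20, n_days = 1095,
                             start_date = "2015-01-01", seed = 42L,
                             range = 1.0,
                             beta_uv_o3 = 0.9,
                             titration_strength = 1.0,
                             c_no2_uv = 0.12,
                             density_effect_no2 = 3.0,
                             density_effect_o3 = 4.0,
                             density_effect_pm = 1.5,
                             pm_coarse_frac = 0.35,
                             rho = c(Temp = 0.7, UV = 0.5, NO2 = 0.6,
                                     O3 = 0.5, PM2.5 = 0.65, coarse = 0.5,
                                     depression = 0.5),
                             ar_sd = c(Temp = 3.0, UV = 1.5, NO2 = 2.5,
                                       O3 = 4.0, PM2.5 = 3.5, coarse = 1.2,
                                       depression = 1.5),
                             spatial_sd = c(Temp = 0.8, Prec = 0.15, UV = 0.5,
                                            NO2 = 2.0, O3 = 3.0, PM2.5 = 1.2,
                                            coarse = 0.8, depression = 0.3),
                             noise_sd = c(Temp = 0.5, UV = 0.8, NO2 = 0.8,
                                          O3 = 1.5, PM2.5 = 0.5, coarse = 0.4,
                                          depression = 0.5),
                             seasonal = list(
                               temp_base = 9.7, temp_amp = 9.0, temp_peak = 197,
                               uv_base = 16.0, uv_amp = 13.0, uv_peak = 172,
                               no2_base = 12.2, no2_winter_amp = 4.5,
                               pm_base = 11.0, pm_winter_amp = 3.0,
                               o3_base = 20.0, o3_warm_amp = 5.0,
                               winter_peak = 15,
                               depression_mean = 4.0
                             ),
                             prec_wet_prob = 0.45,
                             prec_shape = 0.9,
                             prec_mean_wet = 7.5,
                             cloud_uv_reduction = 0.55,
                             urban_centers = NULL) {
  cfg <- list(
    nx = as.integer(nx), ny = as.integer(ny), n_days = as.integer(n_days),
    start_date = as.Date(start_date), seed = as.integer(seed), range = range,
    beta_uv_o3 = beta_uv_o3, titration_strength = titration_strength,
    c_no2_uv = c_no2_uv,
    density_effect_no2 = density_effect_no2,
    density_effect_o3 = density_effect_o3,
    density_effect_pm = density_effect_pm,
    pm_coarse_frac = pm_coarse_frac,
    rho = rho, ar_sd = ar_sd, spatial_sd = spatial_sd, noise_sd = noise_sd,
    seasonal = seasonal,
    prec_wet_prob = prec_wet_prob, prec_shape = prec_shape,
    prec_mean_wet = prec_mean_wet,
    cloud_uv_reduction = cloud_uv_reduction,
    urban_centers = urban_centers
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$nx < 3 || cfg$ny < 3) {
    stop_config("lattice dimensions must be at least 3 x 3.")
  }
  if (cfg$n_days < 1) stop_config("`n_days` must be at least 1.")
  if (cfg$range <= 0) stop_config("spatial `range` must be positive.")
  if (any(cfg$rho < 0 | cfg$rho >= 1)) {
    stop_config("all AR(1) `rho` must satisfy 0 <= rho < 1.")
  }
  if (any(c(cfg$ar_sd, cfg$spatial_sd, cfg$noise_sd) < 0)) {
    stop_config("all standard deviations must be nonnegative.")
  }
  if (cfg$prec_wet_prob < 0 || cfg$prec_wet_prob > 1) {
    stop_config("`prec_wet_prob` must be in [0, 1].")
  }
  invisible(cfg)
}

#' Simulate a daily stressor panel on a synthetic lattice
#'
#' Generates daily values of the eight stressor variables for every area
#' of `areas`. Each variable is the sum of a static spatial Gaussian
#' random field (exponential covariance with correlation length
#' `config$range`), a seasonal sinusoid keyed to day of year over
#' 365.25, a region-wide stationary AR(1) daily noise and iid
#' measurement noise. Dewpoint is temperature minus a positive
#' depression and vapor pressure is derived from it via
#' [magnus_vapor_pressure()], which guarantees the near-perfect Temp-VP
#' correlation; PM10 is PM2.5 plus an independent coarse mode;
#' NO2 peaks in winter and scales with population density; O3 is driven
#' by UV and a warm-season term, reduced by a winter-weighted NO2
#' titration term and by density; precipitation is zero-inflated and
#' anti-coupled to UV through the shared wet-day indicator.
#'
#' @param config A [synthetic_config()].
#' @param areas An `area_set` with `config$nx * config$ny` areas, e.g.
#'   from [make_lattice()].
#' @return A long tibble (`area_id`, `date`, `variable`, `value`) with
#'   one record per area, day and variable. Deterministic given
#'   `config$seed`.
#' @examples
#' cfg <- synthetic_config(nx = 4, ny = 4, n_days = 30)
#' areas <- make_lattice(4, 4, seed = cfg$seed)
#' panel <- simulate_panel(cfg, areas)
#' dplyr::count(panel, variable)
#' @export
simulate_panel <- function(config, areas) {
  validate_synthetic_config(config)
  check_area_set(areas)
  n_areas <- nrow(areas)
  if (n_areas != config$nx * config$ny) {
    stop_frame(sprintf(
      "`areas` has %d areas but `config` describes a %d x %d lattice.",
      n_areas, config$nx, config$ny
    ))
  }
  nd <- config$n_days
  dates <- config$start_date + seq_len(nd) - 1
  doy <- day_of_year(dates)
  s <- config$seasonal

  winter_w <- (1 + cos(2 * pi * (doy - s$winter_peak) / 365.25)) / 2
  warm <- cos(2 * pi * (doy - s$temp_peak) / 365.25)

  dens <- pmax(areas$population / areas$area_km2, 1)
  dens_score <- log10(dens) - 2

  withr::with_seed(config$seed, {
    ch <- if (any(config$spatial_sd > 0)) {
      exp_cov_chol(areas$x, areas$y, config$range)
    } else NULL
    sp <- function(name) {
      sdv <- config$spatial_sd[[name]]
      if (sdv == 0 || is.null(ch)) rep(0, n_areas) else sdv * grf_draw(ch)
    }
    sp_temp <- sp("Temp"); sp_prec <- sp("Prec"); sp_uv <- sp("UV")
    sp_no2 <- sp("NO2"); sp_o3 <- sp("O3"); sp_pm <- sp("PM2.5")
    sp_coarse <- sp("coarse"); sp_dep <- sp("depression")

    ar <- function(name) ar1_series(nd, config$rho[[name]], config$ar_sd[[name]])
    ar_temp <- ar("Temp"); ar_uv <- ar("UV"); ar_no2 <- ar("NO2")
    ar_o3 <- ar("O3"); ar_pm <- ar("PM2.5"); ar_coarse <- ar("coarse")
    ar_dep <- ar("depression")

    wet <- rbinom(nd, 1, config$prec_wet_prob)

    iid <- function(name) {
      sdv <- config$noise_sd[[name]]
      if (sdv == 0) matrix(0, n_areas, nd) else
        matrix(rnorm(n_areas * nd, sd = sdv), n_areas, nd)
    }

    # area x day matrices; rows follow areas$id
    day_row <- function(v) matrix(v, n_areas, nd, byrow = TRUE)
    area_col <- function(v) matrix(v, n_areas, nd)

    temp <- s$temp_base + s$temp_amp * day_row(warm) +
      area_col(sp_temp) + day_row(ar_temp) + iid("Temp")

    depression <- pmax(
      0.2,
      s$depression_mean + day_row(ar_dep) + area_col(sp_dep) + iid("depression")
    )
    dewpoint <- temp - depression
    vp <- magnus_vapor_pressure(dewpoint)

    clear_sky <- pmax(0.5, s$uv_base + s$uv_amp *
                        cos(2 * pi * (doy - s$uv_peak) / 365.25))
    uv_region <- clear_sky * (1 - config$cloud_uv_reduction * wet) + ar_uv
    uv <- pmax(0.2, day_row(uv_region) + area_col(sp_uv) + iid("UV"))

    prec_amount <- matrix(
      rgamma(n_areas * nd, shape = config$prec_shape,
             rate = config$prec_shape / config$prec_mean_wet),
      n_areas, nd
    )
    prec <- prec_amount * day_row(wet) * exp(area_col(sp_prec))

    uv_anom <- uv_region - mean(uv_region)
    no2 <- pmax(
      0.5,
      s$no2_base + s$no2_winter_amp * day_row(winter_w - 0.5) +
        config$density_effect_no2 * area_col(dens_score) +
        config$c_no2_uv * day_row(uv_anom * (1 - winter_w)) +
        day_row(ar_no2) + area_col(sp_no2) + iid("NO2")
    )

    o3 <- pmax(
      0.3,
      s$o3_base + config$beta_uv_o3 * uv + s$o3_warm_amp * day_row(warm) -
        config$titration_strength * (no2 - s$no2_base) * day_row(winter_w) -
        config$density_effect_o3 * area_col(dens_score) +
        day_row(ar_o3) + area_col(sp_o3) + iid("O3")
    )

    pm25 <- pmax(
      0.3,
      s$pm_base + s$pm_winter_amp * day_row(winter_w - 0.5) +
        config$density_effect_pm * area_col(dens_score) +
        day_row(ar_pm) + area_col(sp_pm) + iid("PM2.5")
    )
    coarse <- pmax(
      0.05,
      config$pm_coarse_frac * s$pm_base + day_row(ar_coarse) +
        area_col(sp_coarse) + iid("coarse")
    )
    pm10 <- pm25 + coarse

    mats <- list(
      Temp = temp, Prec = prec, VP = vp, UV = uv,
      O3 = o3, NO2 = no2, `PM2.5` = pm25, PM10 = pm10
    )
    panel <- purrr::imap(mats, function(m, nm) {
      tibble(
        area_id = rep(areas$id, times = nd),
        date = rep(dates, each = n_areas),
        variable = nm,
        value = as.vector(m)
      )
    })
    out <- dplyr::bind_rows(panel)
    stopifnot(all(is.finite(out$value)))
    out
  })
}

#' Add a constant offset to a variable over a set of areas
#'
#' Planting tool for cluster-recovery experiments: adds `delta` to every
#' daily value of `variable` in the listed areas and leaves every other
#' record untouched.
#'
#' @param panel A stressor panel tibble.
#' @param area_ids Character vector of area ids to perturb.
#' @param variable Variable name to perturb.
#' @param delta Offset added to each affected value.
#' @return The modified panel, same row order.
#' @export
plant_cluster <- function(panel, area_ids, variable, delta) {
  check_panel(panel)
  missing_ids <- setdiff(area_ids, unique(panel$area_id))
  if (length(missing_ids)) {
    stop_key(sprintf("unknown area ids: %s",
                     paste(missing_ids, collapse = ", ")))
  }
  if (!variable %in% panel$variable) {
    stop_key(sprintf("variable `%s` is not present in the panel.", variable))
  }
  idx <- panel$area_id %in% area_ids & panel$variable == variable
  panel$value[idx] <- panel$value[idx] + delta
  panel
}

#' Simulate a gridded daily raster
#'
#' Cell-centered rectangular raster used to exercise
#' [aggregate_grid_to_areas()]. The deterministic field types have known
#' analytic cell values; the `"grf"` field adds a seeded spatial random
#' field plus seasonal cycle.
#'
#' @param config A [synthetic_config()]; supplies extent (covering the
#'   `nx` x `ny` lattice), number of days, start date and seed.
#' @param cell_size Raster cell side length (same planar units as the
#'   lattice, default 1).
#' @param field One of `"grf"`, `"constant"`, `"linear_x"`.
#' @param constant Cell value used when `field = "constant"`.
#' @return A tibble (`date`, `row`, `col`, `x`, `y`, `value`) with cell
#'   centers `x`, `y`; the cell size is recorded in attribute
#'   `cell_size`.
#' @export
simulate_grid <- function(config, cell_size = 1,
                          field = c("grf", "constant", "linear_x"),
                          constant = 1) {
  validate_synthetic_config(config)
  field <- match.arg(field)
  ncol_g <- ceiling(config$nx / cell_size)
  nrow_g <- ceiling(config$ny / cell_size)
  col <- rep(seq_len(ncol_g), times = nrow_g)
  row <- rep(seq_len(nrow_g), each = ncol_g)
  x <- (col - 0.5) * cell_size
  y <- (row - 0.5) * cell_size
  dates <- config$start_date + seq_len(config$n_days) - 1

  base <- switch(field,
    constant = rep(constant, length(x)),
    linear_x = x,
    grf = withr::with_seed(child_seed(config$seed, 101), {
      ch <- exp_cov_chol(x, y, config$range)
      10 + 2 * grf_draw(ch)
    })
  )
  per_day <- switch(field,
    constant = ,
    linear_x = rep(0, length(dates)),
    grf = 3 * cos(2 * pi * (day_of_year(dates) - 197) / 365.25)
  )

  n_cells <- length(x)
  n_dates <- length(dates)
  out <- tibble(
    date = rep(dates, each = n_cells),
    row = rep(row, times = n_dates),
    col = rep(col, times = n_dates),
    x = rep(x, times = n_dates),
    y = rep(y, times = n_dates),
    value = rep(base, times = n_dates) + rep(per_day, each = n_cells)
  )
  attr(out, "cell_size") <- cell_size
  out
}
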