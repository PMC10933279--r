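#' Configuration for an end-to-end analysis run
#'
#' Exactly one input source must be given: either a
#' [synthetic_config()] (the run simulates its own lattice and panel)
#' or paths to an areas GeoJSON and a panel CSV.
#'
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param areas_path,panel_path Input file paths, or `NULL`.
#' @param out_dir Output directory for the report bundle.
#' @param seed Top-level seed; per-stage seeds are derived from it by a
#'   fixed splitting rule.
#' @param pooled,monthly Toggles for the pooled and the 12 monthly
#'   correlation matrices.
#' @param ccf_pairs List of 2-vectors of variable names for daily
#'   cross-correlation functions.
#' @param max_lag Maximum |lag| in days for the ccf stage.
#' @param lisa_variables Variables mapped by the hot-spot stage.
#' @param lisa_strata_variables Variables summarized by LISA stratum.
#' @param scheme,n_perm,alpha,alternative LISA settings (see
#'   [lisa_hotspots()]).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       areas_path = NULL, panel_path = NULL,
                       out_dir = tempfile("stressorscape_run_"),
                       seed = 1L,
                       pooled = TRUE, monthly = TRUE,
                       ccf_pairs = list(c("NO2", "O3")),
                       max_lag = 50,
                       lisa_variables = stressor_variables,
                       lisa_strata_variables = c("NO2", "O3", "PM2.5"),
                       scheme = "queen", n_perm = 999, alpha = 0.05,
                       alternative = "two.sided") {
  from_files <- !is.null(areas_path) || !is.null(panel_path)
  if (from_files && !is.null(synthetic)) {
    stop_config("give either `synthetic` or file paths, not both.")
  }
  if (from_files && (is.null(areas_path) || is.null(panel_path))) {
    stop_config("file input needs both `areas_path` and `panel_path`.")
  }
  if (!from_files && is.null(synthetic)) {
    stop_config("one input source is required.")
  }
  all_vars <- c(stressor_variables, "Dewpoint")
  referenced <- unique(c(unlist(ccf_pairs), lisa_variables,
                         lisa_strata_variables))
  bad <- setdiff(referenced, all_vars)
  if (length(bad)) {
    stop_config(sprintf("unknown variables referenced: %s",
                        paste(bad, collapse = ", ")))
  }
  structure(
    list(synthetic = synthetic, areas_path = areas_path,
         panel_path = panel_path, out_dir = out_dir,
         seed = as.integer(seed),
         pooled = pooled, monthly = monthly, ccf_pairs = ccf_pairs,
         max_lag = max_lag, lisa_variables = lisa_variables,
         lisa_strata_variables = lisa_strata_variables,
         scheme = scheme, n_perm = n_perm, alpha = alpha,
         alternative = alternative),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a
#' `synthetic:` mapping is passed to [synthetic_config()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  } else if (!is.null(y$areas_path)) {
    y$synthetic <- NULL
  }
  if (!is.null(y$ccf_pairs)) {
    y$ccf_pairs <- lapply(y$ccf_pairs, unlist)
  }
  do.call(run_config, y)
}

write_cormat_csv <- function(m, path) {
  df <- as.data.frame(round(m$r, 10))
  df <- cbind(variable = rownames(m$r), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Executes the enabled stages in dependency order -- simulate (or
#' load), pooled and monthly correlation matrices, daily
#' cross-correlations, LISA hot-spot maps for each variable, density
#' and LISA stratum tables, and the January-vs-July sign-change report
#' -- and writes every product to `config$out_dir` together with a
#' manifest listing each file with its MD5 checksum. A rerun with the
#' same configuration and seed reproduces identical checksums.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return An object of class `report_bundle`: list with the in-memory
#'   results (`areas`, `panel`, `cormat_all`, `monthly`, `ccf`,
#'   `lisa`, `density_table`, `lisa_table`, `sign_changes`), the
#'   `files` written, and the `manifest`.
#' @export
run_stressorscape <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) {
    stop_config("`config` must be a `run_config` object.")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir

  # pre-flight checks before any computation or output
  if (!is.null(config$panel_path)) {
    for (p in c(config$areas_path, config$panel_path)) {
      if (!file.exists(p)) {
        stop_config(sprintf("input file does not exist: %s", p))
      }
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  keep <- function(path) { files <<- c(files, path); path }

  # --- input stage ----------------------------------------------------
  if (!is.null(config$synthetic)) {
    cfg <- config$synthetic
    cfg$seed <- child_seed(config$seed, 1)
    areas <- make_lattice(cfg$nx, cfg$ny, seed = cfg$seed,
                          urban_centers = cfg$urban_centers)
    say("simulate: %d areas, %d days", nrow(areas), cfg$n_days)
    panel <- simulate_panel(cfg, areas)
  } else {
    areas <- read_areas(config$areas_path)
    panel <- read_panel(config$panel_path)
    say("ingest: %d areas, %d records", nrow(areas), nrow(panel))
  }
  write_areas(areas, keep(file.path(out_dir, "areas.geojson")))
  write_panel(panel, keep(file.path(out_dir, "panel.csv")))

  tidy_rows <- list()

  # --- temporal stage -------------------------------------------------
  cormat_all <- NULL
  if (isTRUE(config$pooled)) {
    wide <- tidyr::pivot_wider(panel, names_from = "variable",
                               values_from = "value")
    cormat_all <- correlation_matrix(
      wide, intersect(stressor_variables, unique(panel$variable)),
      stratum = "all"
    )
    write_cormat_csv(cormat_all, keep(file.path(out_dir, "cormat_all.csv")))
    tidy_rows <- c(tidy_rows, list(tidy(cormat_all)))
    say("correlate: pooled matrix over %d records", nrow(wide))
  }
  monthly <- NULL
  if (isTRUE(config$monthly)) {
    monthly <- monthly_matrices(panel)
    for (mm in names(monthly)) {
      write_cormat_csv(monthly[[mm]],
                       keep(file.path(out_dir, sprintf("cormat_month_%s.csv", mm))))
      tidy_rows <- c(tidy_rows, list(tidy(monthly[[mm]])))
    }
    say("correlate: 12 monthly matrices")
  }
  if (length(tidy_rows)) {
    utils::write.csv(dplyr::bind_rows(tidy_rows),
                     keep(file.path(out_dir, "correlations_tidy.csv")),
                     row.names = FALSE, quote = FALSE)
  }

  series <- bw_mean_series(panel)
  ccfs <- list()
  for (pair in config$ccf_pairs) {
    cc <- cross_correlation(series[[pair[1]]], series[[pair[2]]],
                            max_lag = config$max_lag,
                            x_name = pair[1], y_name = pair[2])
    nm <- paste(pair, collapse = "_")
    utils::write.csv(as.data.frame(cc),
                     keep(file.path(out_dir, sprintf("ccf_%s.csv", nm))),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(x = pair[1], y = pair[2], lag_unit = attr(cc, "lag_unit"),
           convention = attr(cc, "convention")),
      keep(file.path(out_dir, sprintf("ccf_%s_meta.json", nm))),
      auto_unbox = TRUE
    )
    ccfs[[nm]] <- cc
    say("ccf: %s vs %s, max lag %d", pair[1], pair[2], config$max_lag)
  }

  # --- spatial stage --------------------------------------------------
  W <- build_weights(areas, scheme = config$scheme, standardize = TRUE)
  if (length(W$islands)) {
    say("weights: %d island(s) excluded: %s", length(W$islands),
        paste(W$islands, collapse = ", "))
  }
  lisa <- list()
  for (k in seq_along(config$lisa_variables)) {
    v <- config$lisa_variables[k]
    vals <- period_mean_by_area(panel, v)
    p <- permutation_pvalues(vals, W, n_perm = config$n_perm,
                             seed = child_seed(config$seed, 100 + k),
                             alternative = config$alternative)
    res <- classify_quadrants(vals, W, p, alpha = config$alpha)
    attr(res, "variable") <- v
    lisa[[v]] <- res
    safe <- gsub("[^A-Za-z0-9]", "", v)
    utils::write.csv(as.data.frame(res),
                     keep(file.path(out_dir, sprintf("lisa_%s.csv", safe))),
                     row.names = FALSE, quote = FALSE)
    write_lisa_geojson(res, areas,
                       keep(file.path(out_dir, sprintf("lisa_%s.geojson", safe))))
    say("lisa: %s -> %d HH, %d LL at alpha=%.3g", v,
        sum(res$label == "HH", na.rm = TRUE),
        sum(res$label == "LL", na.rm = TRUE), config$alpha)
  }

  density_table <- density_strata_summary(panel, areas)
  utils::write.csv(density_table,
                   keep(file.path(out_dir, "table_density_strata.csv")),
                   row.names = FALSE, quote = FALSE)
  lisa_table <- NULL
  if (length(config$lisa_strata_variables)) {
    lisa_table <- dplyr::bind_rows(lapply(
      intersect(config$lisa_strata_variables, names(lisa)),
      function(v) {
        dplyr::mutate(lisa_strata_summary(panel, lisa[[v]], v),
                      variable = v, .before = 1)
      }
    ))
    utils::write.csv(lisa_table,
                     keep(file.path(out_dir, "table_lisa_strata.csv")),
                     row.names = FALSE, quote = FALSE)
  }

  # --- report stage ---------------------------------------------------
  sign_changes <- NULL
  if (!is.null(monthly)) {
    sign_changes <- sign_change_count(monthly[["01"]], monthly[["07"]])
    jsonlite::write_json(
      list(month_a = "01", month_b = "07",
           count = sign_changes$count,
           total_pairs = sign_changes$total_pairs,
           pairs = sign_changes$pairs),
      keep(file.path(out_dir, "sign_changes_jan_jul.json")),
      auto_unbox = TRUE, digits = NA
    )
    say("report: %d of %d pairs flip sign between January and July",
        sign_changes$count, sign_changes$total_pairs)
  }

  manifest <- list(
    package = "stressorscape",
    version = as.character(utils::packageVersion("stressorscape")),
    seed = config$seed,
    created = format(Sys.time(), tz = "UTC"),
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)

  structure(
    list(areas = areas, panel = panel, cormat_all = cormat_all,
         monthly = monthly, ccf = ccfs, lisa = lisa,
         density_table = density_table, lisa_table = lisa_table,
         sign_changes = sign_changes,
         out_dir = out_dir, files = c(files, manifest_path),
         manifest = manifest),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d files in %s\n",
              length(x$files), x$out_dir))
  invisible(x)
}

#' Sign-change report between two calendar months
#'
#' Counts the variable pairs whose correlation coefficients have
#' opposite signs in two monthly matrices and names them.
#'
#' @param x A `report_bundle` or a list of monthly matrices from
#'   [monthly_matrices()].
#' @param month_a,month_b Two-digit month strings (defaults January and
#'   July).
#' @return A `sign_change` object (see [sign_change_count()]).
#' @export
sign_change_report <- function(x, month_a = "01", month_b = "07") {
  monthly <- if (inherits(x, "report_bundle")) x$monthly else x
  if (is.null(monthly) || !all(c(month_a, month_b) %in% names(monthly))) {
    stop_key("requested months are not present in the monthly matrices.")
  }
  sign_change_count(monthly[[month_a]], monthly[[month_b]])
}
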