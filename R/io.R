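#' Read a census table from CSV/TSV
#'
#' Required columns: `tree_id`, `species`, `plot`, `x`, `y`, `date`
#' (decimal years), `dbh_mm`; optional `genotype` and `block` for clonal
#' data, `row`/`col` for planting grids. Rows with missing or non-positive
#' DBH, or missing dates/coordinates, are reported with their line numbers
#' and dropped. A unit plausibility check warns when the median DBH is
#' below 30 — tree diameters at breast height in mm should rarely sit
#' there, so the file likely carries cm.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @param date_origin when `date` parses as a calendar date rather than a
#'   number, it is converted to decimal years using 365.25 days per year.
#' @return a census tibble.
#' @export
read_census <- function(path, date_origin = "1970-01-01") {
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("tree_id", "species", "plot", "x", "y", "date", "dbh_mm")
  miss <- setdiff(required, names(raw))
  abort_if(length(miss) > 0,
           paste0("census file is missing column(s): ",
                  paste(miss, collapse = ", ")))
  if (inherits(raw$date, "Date")) {
    raw$date <- 1970 + as.numeric(raw$date - as.Date(date_origin)) / 365.25
  }
  suppressWarnings({
    raw$dbh_mm <- as.numeric(raw$dbh_mm)
    raw$date <- as.numeric(raw$date)
    raw$x <- as.numeric(raw$x)
    raw$y <- as.numeric(raw$y)
  })
  bad <- !is.finite(raw$dbh_mm) | raw$dbh_mm <= 0 |
    !is.finite(raw$date) | !is.finite(raw$x) | !is.finite(raw$y)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped (lines ",
            paste(head(which(bad) + 1L, 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", ")", call. = FALSE)
    raw <- raw[!bad, , drop = FALSE]
  }
  if (is.finite(median(raw$dbh_mm)) && median(raw$dbh_mm) < 30) {
    warning("median DBH is below 30; values may be in cm, expected mm",
            call. = FALSE)
  }
  raw
}

pipeline_defaults <- function() {
  list(
    mode = "forest",
    seed = 1L,
    # spatial thresholds
    radius = 100, alpha = 0.05, min_neighbors = 5, min_pairs = 5,
    max_sample = 3000, min_individuals = 5, min_hetero_neighbors = 5,
    max_per_species = NULL,
    # growth filters
    min_dbh = 100, g_min = -2, g_max = 100,
    # MCMC
    test_mode = TRUE,
    # virtual-experiment parameters
    sim = list(C = 100L, N = 10L, T_dates = 2L, I = 100L, J = 2L,
               range = 10, coef_scale = 0.3, dynamic_dims = 2:6),
    # forest generator overrides (passed to forest_inventory_config)
    forest = list()
  )
}

#' Read and validate a pipeline run configuration
#'
#' YAML key-value file; keys not in the default set are rejected (typo
#' guard). Values given in the file override the defaults, which are
#' the package's standard thresholds (radius 100 m, alpha 0.05,
#' eligibility thresholds 5, growth bounds -2..100 mm / year, min DBH
#' 100 mm).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return a named list of class `iv_run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  config <- pipeline_defaults()
  apply_keys <- function(config, vals, where) {
    unknown <- setdiff(names(vals), names(config))
    abort_if(length(unknown) > 0,
             paste0("unknown config key(s) in ", where, ": ",
                    paste(unknown, collapse = ", ")))
    for (k in names(vals)) {
      config[[k]] <- if (k == "forest") {
        # forest generator arguments; validated by forest_inventory_config()
        bad <- setdiff(names(vals[[k]]),
                       names(formals(forest_inventory_config)))
        abort_if(length(bad) > 0,
                 paste0("unknown config key(s) in ", where, "$forest: ",
                        paste(bad, collapse = ", ")))
        utils::modifyList(config[[k]], vals[[k]])
      } else if (is.list(config[[k]]) && is.list(vals[[k]])) {
        apply_keys(config[[k]], vals[[k]], paste0(where, "$", k))
      } else {
        vals[[k]]
      }
    }
    config
  }
  if (!is.null(path)) {
    config <- apply_keys(config, yaml::read_yaml(path), "file")
  }
  config <- apply_keys(config, overrides, "overrides")
  structure(config, class = c("iv_run_config", "list"))
}

#' Run an end-to-end analysis pipeline on synthetic data
#'
#' Two modes, mirroring the two halves of the workflow:
#' * `mode = "virtual"`: landscape simulation -> deterministic attribute ->
#'   imperfect-knowledge fit -> per-species / pooled semivariogram curves.
#' * `mode = "forest"`: synthetic forest inventory -> growth preparation and
#'   filtering -> Moran's I screen -> intra- vs interspecific semivariance
#'   comparison.
#' Every stage output lands in the returned bundle together with a manifest
#' (config echo, seed, package version) so reruns are reproducible; with the
#' same config the deterministic stages are identical.
#'
#' @param config an [read_run_config()] list (or a path to a YAML file).
#' @return a named list of stage outputs plus `manifest`.
#' @export
run_pipeline <- function(config = read_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  abort_if(!inherits(config, "iv_run_config"),
           "`config` must come from read_run_config()")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out <- list()
  if (config$mode == "virtual") {
    sim <- config$sim
    out$landscape <- stage("simulate", generate_environment(
      C = sim$C, N = sim$N, T_dates = sim$T_dates,
      autocorr_range = sim$range, dynamic_dims = sim$dynamic_dims,
      seed = config$seed))
    placements <- place_individuals(sim$I, sim$J, sim$C,
                                    seed = config$seed + 1L)
    responses <- draw_species_responses(sim$J, sim$N, sim$coef_scale,
                                        seed = config$seed + 2L)
    out$attributes <- stage("simulate",
                            simulate_attribute(out$landscape, placements, responses))
    out$responses <- responses
    out$fit <- stage("fit-imperfect", fit_imperfect_model(
      out$attributes, mcmc_config(test_mode = config$test_mode,
                                  seed = config$seed)))
    mean_y <- out$attributes |>
      dplyr::group_by(.data$i, .data$j, .data$x, .data$y) |>
      dplyr::summarise(mean_growth = mean(.data$Y), .groups = "drop") |>
      dplyr::rename(tree_id = "i", species = "j")
    out$semivariogram <- stage("semivariogram", semivariogram_curves(
      mean_y, bin_edges = seq(0, sim$C / 2, length.out = 11)))
  } else if (config$mode == "forest") {
    fcfg <- do.call(forest_inventory_config,
                    c(config$forest, list(seed = config$seed)))
    out$inventory <- stage("synth-forest", generate_forest_inventory(fcfg))
    out$growth <- stage("prep-growth", {
      g <- annualized_growth(out$inventory$censuses)
      apply_growth_filters(g, min_dbh = config$min_dbh,
                           g_min = config$g_min, g_max = config$g_max)
    })
    out$mean_growth <- stage("prep-growth", {
      keep <- unique(out$growth$tree_id)
      mean_individual_growth(
        dplyr::filter(out$inventory$censuses, .data$tree_id %in% keep))
    })
    out$moran_screen <- stage("spatial-screen", species_autocorrelation_screen(
      out$mean_growth, radius = config$radius,
      min_neighbors = config$min_neighbors, min_pairs = config$min_pairs,
      max_sample = config$max_sample, alpha = config$alpha,
      seed = config$seed))
    out$semivar_comparison <- stage("semivar-compare", compare_intra_inter(
      out$mean_growth, radius = config$radius,
      min_individuals = config$min_individuals,
      min_hetero_neighbors = config$min_hetero_neighbors,
      alpha = config$alpha, max_per_species = config$max_per_species,
      seed = config$seed))
  } else {
    stop("unknown pipeline mode: ", config$mode, call. = FALSE)
  }
  out$manifest <- list(
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ivstruct")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  out
}

#' Write a fitted model's summary and draws to disk
#'
#' Parameter summaries and convergence diagnostics as JSON, draws as CSV
#' (one column per parameter, chains stacked with a `chain` column).
#'
#' @param fit an `iv_fit`.
#' @param path_json,path_csv output paths (either may be `NULL` to skip).
#' @return invisibly, the list written to JSON.
#' @export
write_fit <- function(fit, path_json = NULL, path_csv = NULL) {
  abort_if(!inherits(fit, "iv_fit"), "`fit` must be an iv_fit")
  conv <- check_convergence(fit, rhat_max = Inf, ess_min = 0)
  payload <- list(
    class = class(fit)[1L],
    summary = fit$summary,
    diagnostics = conv$table,
    config = fit$config[c("n_chains", "n_iter", "n_warmup", "thin", "seed")]
  )
  if (!is.null(path_json)) {
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_csv)) {
    mats <- lapply(seq_along(fit$draws), function(c) {
      df <- as.data.frame(as.matrix(fit$draws[[c]]))
      df$chain <- c
      df
    })
    readr::write_csv(dplyr::bind_rows(mats), path_csv, progress = FALSE)
  }
  invisible(payload)
}
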