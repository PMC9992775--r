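#' Configuration for the synthetic clonal trial
#'
#' Emulates a replicated clonal plantation trial: `n_genotypes` genotypes,
#' each planted as a square plot of `trees_per_plot` trees in every one of
#' `n_blocks` blocks, censused `n_censuses` times over `duration_years`
#' years. Planting density of 1,666 trees per hectare gives 6 m2 per tree,
#' i.e. a grid spacing of about 2.45 m. Growth is generated from the same
#' hierarchical form the clonal model fits: with effects drawn once per
#' block / genotype / census interval / tree,
#' `ln(G + 1) = beta0 + b_block + b_geno + b_date + b_tree +
#'  beta1 (ln D - ln dbh_init) + beta2 (ln C - ln c_ref) + eps`.
#' Default variance components place the census date first, the individual
#' second at twice the genotype component, and the block last — the
#' ordering such trials are designed to reveal.
#'
#' @param n_blocks,n_genotypes,trees_per_plot,n_censuses,duration_years
#'   design dimensions (defaults 10, 14, 100, 5, 6).
#' @param spacing_m planting grid spacing in meters (default `sqrt(6)`).
#' @param sigma2_block,sigma2_geno,sigma2_date,sigma2_ind,sigma2_resid true
#'   variance components of the generative model (defaults 0.02, 0.06, 0.40,
#'   0.12, 0.15; individual = 2 x genotype).
#' @param beta0,beta1,beta2 fixed effects of the generative linear predictor
#'   (on the `ln(G + 1)` scale, diameter and competition covariates centred
#'   at `ln dbh_init` and the reference competition).
#' @param dbh_init_mean,dbh_init_sd initial DBH distribution (mm).
#' @param seed integer seed.
#' @return list of class `iv_clonal_config`.
#' @export
clonal_trial_config <- function(n_blocks = 10L, n_genotypes = 14L,
                                trees_per_plot = 100L, n_censuses = 5L,
                                duration_years = 6, spacing_m = sqrt(6),
                                sigma2_block = 0.02, sigma2_geno = 0.06,
                                sigma2_date = 0.40, sigma2_ind = 0.12,
                                sigma2_resid = 0.15,
                                beta0 = 2.2, beta1 = 0.4, beta2 = -0.2,
                                dbh_init_mean = 50, dbh_init_sd = 5,
                                seed = 1L) {
  side <- sqrt(trees_per_plot)
  abort_if(side != floor(side),
           "`trees_per_plot` must be a square number (square planting plots)")
  structure(
    list(n_blocks = check_count(n_blocks, "n_blocks"),
         n_genotypes = check_count(n_genotypes, "n_genotypes"),
         trees_per_plot = check_count(trees_per_plot, "trees_per_plot"),
         n_censuses = check_count(n_censuses, "n_censuses", min = 2L),
         duration_years = check_positive(duration_years, "duration_years"),
         spacing_m = check_positive(spacing_m, "spacing_m"),
         sigma2 = c(block = sigma2_block, geno = sigma2_geno,
                    date = sigma2_date, ind = sigma2_ind,
                    resid = sigma2_resid),
         beta = c(beta0 = beta0, beta1 = beta1, beta2 = beta2),
         dbh_init_mean = check_positive(dbh_init_mean, "dbh_init_mean"),
         dbh_init_sd = dbh_init_sd,
         seed = as.integer(seed)),
    class = "iv_clonal_config"
  )
}

#' Generate a synthetic clonal-trial census table
#'
#' Builds the trial described by the config: every genotype in every block
#' as a square planting grid, initial DBH drawn once per tree, then DBH
#' trajectories accumulated census by census with annual growth generated
#' exactly from the clonal hierarchical model (see [clonal_trial_config()]).
#' The competition index (sum of the 8 grid neighbours' basal areas,
#' recomputed each interval from current DBH) feeds back into growth, as in
#' a real stand.
#'
#' @param config a [clonal_trial_config()].
#' @return list with `censuses` (tibble: `tree_id`, `genotype`, `block`,
#'   `plot`, `row`, `col`, `x`, `y`, `date`, `dbh_mm`), `growth` (the
#'   per-interval records actually generated, incl. `G`, `dbh_start`,
#'   `comp_index`) and `truth` (all drawn effects, the variance components
#'   and fixed effects, and the reference constants) — enough to recompute
#'   every generated response exactly.
#' @export
generate_clonal_trial <- function(config = clonal_trial_config()) {
  abort_if(!inherits(config, "iv_clonal_config"),
           "`config` must come from clonal_trial_config()")
  set.seed(config$seed)
  side <- as.integer(sqrt(config$trees_per_plot))
  n_int <- config$n_censuses - 1L
  dates <- seq(0, config$duration_years, length.out = config$n_censuses)
  s2 <- config$sigma2

  trees <- tidyr::expand_grid(
    block = seq_len(config$n_blocks),
    genotype = seq_len(config$n_genotypes),
    row = seq_len(side), col = seq_len(side)
  ) |>
    dplyr::mutate(
      plot = paste0("b", .data$block, "g", .data$genotype),
      tree_id = dplyr::row_number(),
      # blocks side by side, genotype plots in a row within each block
      x = (.data$genotype - 1L) * (side + 2L) * config$spacing_m +
        (.data$col - 0.5) * config$spacing_m,
      y = (.data$block - 1L) * (side + 2L) * config$spacing_m +
        (.data$row - 0.5) * config$spacing_m
    )
  n <- nrow(trees)
  dbh0 <- pmax(rnorm(n, config$dbh_init_mean, config$dbh_init_sd), 5)

  eff <- list(
    block = rnorm(config$n_blocks, 0, sqrt(s2[["block"]])),
    geno = rnorm(config$n_genotypes, 0, sqrt(s2[["geno"]])),
    date = rnorm(n_int, 0, sqrt(s2[["date"]])),
    ind = rnorm(n, 0, sqrt(s2[["ind"]]))
  )
  beta <- config$beta
  ln_d_ref <- log(config$dbh_init_mean)
  c_ref <- 8 * pi * (config$dbh_init_mean / 2)^2

  dbh <- matrix(NA_real_, n, config$n_censuses)
  dbh[, 1L] <- dbh0
  growth_rows <- vector("list", n_int)
  resid <- matrix(rnorm(n * n_int, 0, sqrt(s2[["resid"]])), n, n_int)
  for (t in seq_len(n_int)) {
    ci <- competition_index(dplyr::mutate(trees, dbh_mm = dbh[, t]))
    comp <- ci$comp_index[match(trees$tree_id, ci$tree_id)]
    lp <- beta[["beta0"]] + eff$block[trees$block] + eff$geno[trees$genotype] +
      eff$date[t] + eff$ind +
      beta[["beta1"]] * (log(dbh[, t]) - ln_d_ref) +
      beta[["beta2"]] * (log(comp) - log(c_ref)) +
      resid[, t]
    G <- exp(lp) - 1
    dt <- dates[t + 1L] - dates[t]
    dbh[, t + 1L] <- dbh[, t] + G * dt
    growth_rows[[t]] <- dplyr::mutate(
      trees[, c("tree_id", "genotype", "block", "plot", "row", "col", "x", "y")],
      date = t, date_start = dates[t], date_end = dates[t + 1L],
      dbh_start = dbh[, t], comp_index = comp, G = G
    )
  }
  censuses <- tidyr::expand_grid(tree_id = trees$tree_id,
                                 census = seq_len(config$n_censuses)) |>
    dplyr::mutate(
      date = dates[.data$census],
      dbh_mm = dbh[cbind(.data$tree_id, .data$census)]
    ) |>
    dplyr::left_join(trees[, c("tree_id", "genotype", "block", "plot",
                               "row", "col", "x", "y")],
                     by = "tree_id") |>
    dplyr::select("tree_id", "genotype", "block", "plot", "row", "col",
                  "x", "y", "date", "dbh_mm")

  list(
    censuses = censuses,
    growth = dplyr::bind_rows(growth_rows),
    truth = list(sigma2 = s2, beta = beta, effects = eff,
                 ln_d_ref = ln_d_ref, c_ref = c_ref, dates = dates,
                 resid = resid, config = config)
  )
}

#' Configuration for the synthetic forest inventory
#'
#' Emulates a mapped multi-census tropical forest plot: `n_species` species
#' with log-series abundances summing to `n_trees` individuals scattered
#' uniformly over an `extent_m` x `extent_m` plot, censused `n_censuses`
#' times every `periodicity_years` years, DBH >= the observation floor.
#' Individual growth follows the forest hierarchical model's generative
#' form: `ln(G + 2) = beta0 + b_species + b_ind + beta1 (ln D - ln D_ref)
#' + eps`, where the individual effect `b_ind` is, per `iv_mode`:
#' * `"environmental"` — the individual's species-specific response to `n_dims`
#'   latent spatially autocorrelated environmental fields evaluated at its
#'   position (spatially structured IV); coefficients are scaled so the
#'   marginal variance is exactly `sigma2_ind`;
#' * `"unstructured"` — an i.i.d. draw `N(0, sigma2_ind)` (the matched-variance
#'   contract: same marginal IV magnitude, no spatial structure).
#'
#' @param n_species number of species (default 25).
#' @param n_trees total number of individuals (default 2500; with the
#'   default extent this is 400 trees/ha, conservative for tropical plots
#'   censused at DBH >= 100 mm).
#' @param extent_m plot side in meters (default 250, a typical large-plot
#'   side).
#' @param cell_m environmental-field grid resolution in meters (default 4).
#' @param n_censuses,periodicity_years census design (defaults 4 and 2).
#' @param n_dims number of latent environmental fields (default 5).
#' @param env_range_m correlation range of the fields in meters (default 30).
#' @param iv_mode `"environmental"` or `"unstructured"`.
#' @param sigma2_species,sigma2_ind,sigma2_resid true variance components
#'   on the `ln(G + 2)` scale (defaults 0.25, 0.25, 0.10).
#' @param beta0,beta1 fixed effects (defaults `log(5 + 2)` and -0.1: mean
#'   growth near 5 mm / year, mildly declining with diameter).
#' @param logseries_alpha Fisher's log-series parameter steering the
#'   rank-abundance shape (default 8; smaller = more dominance).
#' @param dbh_min observation floor in mm (default 100).
#' @param dbh_init_meanlog,dbh_init_sdlog lognormal initial-DBH parameters
#'   (defaults give a median near 160 mm).
#' @param seed integer seed.
#' @return list of class `iv_forest_config`.
#' @export
forest_inventory_config <- function(n_species = 25L, n_trees = 2500L,
                                    extent_m = 250, cell_m = 4,
                                    n_censuses = 4L, periodicity_years = 2,
                                    n_dims = 5L, env_range_m = 30,
                                    iv_mode = c("environmental", "unstructured"),
                                    sigma2_species = 0.25, sigma2_ind = 0.25,
                                    sigma2_resid = 0.10,
                                    beta0 = log(7), beta1 = -0.1,
                                    logseries_alpha = 8,
                                    dbh_min = 100,
                                    dbh_init_meanlog = log(160),
                                    dbh_init_sdlog = 0.35,
                                    seed = 1L) {
  iv_mode <- match.arg(iv_mode)
  structure(
    list(n_species = check_count(n_species, "n_species", min = 2L),
         n_trees = check_count(n_trees, "n_trees", min = 10L),
         extent_m = check_positive(extent_m, "extent_m"),
         cell_m = check_positive(cell_m, "cell_m"),
         n_censuses = check_count(n_censuses, "n_censuses", min = 2L),
         periodicity_years = check_positive(periodicity_years, "periodicity_years"),
         n_dims = check_count(n_dims, "n_dims"),
         env_range_m = check_positive(env_range_m, "env_range_m"),
         iv_mode = iv_mode,
         sigma2 = c(species = sigma2_species, ind = sigma2_ind,
                    resid = sigma2_resid),
         beta = c(beta0 = beta0, beta1 = beta1),
         logseries_alpha = check_positive(logseries_alpha, "logseries_alpha"),
         dbh_min = dbh_min,
         dbh_init_meanlog = dbh_init_meanlog,
         dbh_init_sdlog = dbh_init_sdlog,
         seed = as.integer(seed)),
    class = "iv_forest_config"
  )
}

# Log-series-shaped species abundances summing to n_trees, every species
# with at least one individual.
logseries_abundances <- function(n_species, n_trees, alpha) {
  # expected log-series rank profile: p_k proportional to x^k / k
  x <- n_trees / (n_trees + alpha)
  k <- seq_len(n_species)
  p <- x^k / k
  p <- p / sum(p)
  ab <- pmax(1L, round(p * n_trees))
  # adjust the most abundant species so the total matches
  ab[1L] <- ab[1L] + (n_trees - sum(ab))
  abort_if(ab[1L] < 1L, "abundance adjustment failed; increase n_trees")
  ab
}

#' Generate a synthetic forest-inventory census table
#'
#' See [forest_inventory_config()] for the generative model. DBH
#' trajectories accumulate the generated annual growth between censuses;
#' only trees at or above the observation floor at a census appear in that
#' census (as in a real inventory with a minimum measured diameter).
#'
#' @param config a [forest_inventory_config()].
#' @return list with `censuses` (tibble: `tree_id`, `species`, `plot`, `x`,
#'   `y`, `date`, `dbh_mm`), `growth` (generated per-interval records) and
#'   `truth` (species effects, individual effects, field coefficients and
#'   the latent landscape in environmental mode, variance components).
#' @export
generate_forest_inventory <- function(config = forest_inventory_config()) {
  abort_if(!inherits(config, "iv_forest_config"),
           "`config` must come from forest_inventory_config()")
  set.seed(config$seed)
  s2 <- config$sigma2
  ab <- logseries_abundances(config$n_species, config$n_trees,
                             config$logseries_alpha)
  n <- sum(ab)
  species <- rep(sprintf("sp%02d", seq_len(config$n_species)), times = ab)
  x <- runif(n, 0, config$extent_m)
  y <- runif(n, 0, config$extent_m)
  b_species <- rnorm(config$n_species, 0, sqrt(s2[["species"]]))

  C <- ceiling(config$extent_m / config$cell_m)
  range_cells <- config$env_range_m / config$cell_m
  landscape <- NULL
  coef <- NULL
  if (config$iv_mode == "environmental") {
    fields <- array(NA_real_, dim = c(C, C, config$n_dims))
    for (d in seq_len(config$n_dims)) {
      fields[, , d] <- gaussian_random_field(C, range_cells)
    }
    landscape <- fields
    # species response coefficients, scaled so sum(coef^2) = sigma2_ind
    coef <- matrix(rnorm(config$n_species * config$n_dims),
                   config$n_species, config$n_dims)
    coef <- coef * sqrt(s2[["ind"]]) / sqrt(rowSums(coef^2))
    cell_r <- pmin(C, floor(y / config$cell_m) + 1L)
    cell_c <- pmin(C, floor(x / config$cell_m) + 1L)
    env <- vapply(seq_len(config$n_dims),
                  function(d) fields[, , d][cbind(cell_r, cell_c)],
                  numeric(n))
    sp_idx <- as.integer(factor(species, levels = unique(species)))
    b_ind <- rowSums(env * coef[sp_idx, , drop = FALSE])
  } else {
    b_ind <- rnorm(n, 0, sqrt(s2[["ind"]]))
  }

  n_int <- config$n_censuses - 1L
  dates <- (seq_len(config$n_censuses) - 1L) * config$periodicity_years
  dbh0 <- rlnorm(n, config$dbh_init_meanlog, config$dbh_init_sdlog)
  dbh0 <- pmax(dbh0, config$dbh_min)
  ln_d_ref <- config$dbh_init_meanlog
  beta <- config$beta

  dbh <- matrix(NA_real_, n, config$n_censuses)
  dbh[, 1L] <- dbh0
  resid <- matrix(rnorm(n * n_int, 0, sqrt(s2[["resid"]])), n, n_int)
  growth_rows <- vector("list", n_int)
  sp_idx <- as.integer(factor(species, levels = unique(species)))
  for (t in seq_len(n_int)) {
    lp <- beta[["beta0"]] + b_species[sp_idx] + b_ind +
      beta[["beta1"]] * (log(dbh[, t]) - ln_d_ref) + resid[, t]
    G <- exp(lp) - 2
    dt <- dates[t + 1L] - dates[t]
    dbh[, t + 1L] <- pmax(dbh[, t] + G * dt, 1)
    growth_rows[[t]] <- tibble::tibble(
      tree_id = seq_len(n), species = species, plot = 1L, x = x, y = y,
      date_start = dates[t], date_end = dates[t + 1L],
      dbh_start = dbh[, t], G = G
    )
  }
  censuses <- tidyr::expand_grid(tree_id = seq_len(n),
                                 census = seq_len(config$n_censuses)) |>
    dplyr::mutate(
      species = species[.data$tree_id],
      plot = 1L,
      x = x[.data$tree_id], y = y[.data$tree_id],
      date = dates[.data$census],
      dbh_mm = dbh[cbind(.data$tree_id, .data$census)]
    ) |>
    dplyr::filter(.data$dbh_mm >= config$dbh_min) |>
    dplyr::select("tree_id", "species", "plot", "x", "y", "date", "dbh_mm")

  list(
    censuses = censuses,
    growth = dplyr::bind_rows(growth_rows),
    truth = list(sigma2 = s2, beta = beta, b_species = b_species,
                 b_ind = b_ind, species = species, abundances = ab,
                 coef = coef, landscape = landscape, ln_d_ref = ln_d_ref,
                 dates = dates, resid = resid, config = config)
  )
}
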