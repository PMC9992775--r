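#' Annualized diameter growth between consecutive censuses
#'
#' One growth record per consecutive census pair per tree:
#' `G = (DBH_end - DBH_start) / (date_end - date_start)` in mm / year.
#' Trees with a single census contribute no record.
#'
#' @param censuses census tibble with at least `tree_id`, `date` (decimal
#'   years) and `dbh_mm`; any other columns (species, plot, coordinates,
#'   genotype, block, grid indices) are carried through from the interval's
#'   first census.
#' @return a tibble with, per interval, `tree_id`, carried columns,
#'   `date_start`, `date_end`, `dbh_start`, `dbh_end`, `interval_years`, `G`.
#' @examples
#' cen <- tibble::tibble(tree_id = 1, date = c(2000, 2002), dbh_mm = c(100, 110))
#' annualized_growth(cen)$G  # 5 mm/year
#' @export
annualized_growth <- function(censuses) {
  abort_if(!all(c("tree_id", "date", "dbh_mm") %in% names(censuses)),
           "`censuses` needs columns tree_id, date, dbh_mm")
  carried <- setdiff(names(censuses), c("date", "dbh_mm"))
  out <- censuses |>
    dplyr::arrange(.data$tree_id, .data$date) |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::mutate(
      date_start = .data$date,
      date_end = dplyr::lead(.data$date),
      dbh_start = .data$dbh_mm,
      dbh_end = dplyr::lead(.data$dbh_mm)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$date_end))
  bad <- out$date_end <= out$date_start
  abort_if(any(bad),
           paste0("non-increasing census dates for tree id(s): ",
                  paste(unique(out$tree_id[bad]), collapse = ", ")))
  out |>
    dplyr::mutate(
      interval_years = .data$date_end - .data$date_start,
      G = (.data$dbh_end - .data$dbh_start) / .data$interval_years
    ) |>
    dplyr::select(dplyr::all_of(carried), "date_start", "date_end",
                  "dbh_start", "dbh_end", "interval_years", "G")
}

#' Mean individual growth from first to last census
#'
#' `(DBH_last - DBH_first) / (t_last - t_first)` per tree, in mm / year;
#' intermediate censuses do not enter (endpoint formula). Trees measured only
#' once are dropped and counted.
#'
#' @inheritParams annualized_growth
#' @return a tibble with one row per retained tree: carried columns plus
#'   `n_censuses`, `first_date`, `last_date`, `dbh_first`, `dbh_last`,
#'   `mean_growth`. The number of single-census trees dropped is attached as
#'   attribute `n_single_census`.
#' @export
mean_individual_growth <- function(censuses) {
  abort_if(!all(c("tree_id", "date", "dbh_mm") %in% names(censuses)),
           "`censuses` needs columns tree_id, date, dbh_mm")
  carried <- setdiff(names(censuses), c("date", "dbh_mm"))
  by_tree <- censuses |>
    dplyr::arrange(.data$tree_id, .data$date) |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(setdiff(carried, "tree_id")), dplyr::first),
      n_censuses = dplyr::n(),
      first_date = dplyr::first(.data$date),
      last_date = dplyr::last(.data$date),
      dbh_first = dplyr::first(.data$dbh_mm),
      dbh_last = dplyr::last(.data$dbh_mm),
      .groups = "drop"
    )
  n_single <- sum(by_tree$n_censuses < 2L)
  out <- by_tree |>
    dplyr::filter(.data$n_censuses >= 2L) |>
    dplyr::mutate(
      mean_growth = (.data$dbh_last - .data$dbh_first) /
        (.data$last_date - .data$first_date)
    )
  attr(out, "n_single_census") <- n_single
  out
}

#' Filter growth records the way tropical-forest growth analyses do
#'
#' Applies, in order: (1) minimum-diameter rule on the start-of-interval DBH
#' (keep `dbh_start >= min_dbh`); (2) growth bounds with *strict* inequality
#' (remove `G < g_min` or `G > g_max`; records at exactly the bound are
#' kept); (3) removal of records whose species is unidentified (`NA`, empty,
#' or matching `unidentified_pattern`); (4) removal of individuals left with
#' a single record; (5) removal of species left with a single individual.
#' Steps 4-5 run once, not to a fixed point.
#'
#' @param growth a growth tibble (e.g. from [annualized_growth()]) with
#'   columns `tree_id`, `species`, `G` and (for the DBH rule) `dbh_start`.
#' @param min_dbh minimum start-of-interval DBH in mm (default 100; set to 0
#'   to disable, e.g. when the census reader already enforced it).
#' @param g_min,g_max growth bounds in mm / year (defaults -2 and 100).
#' @param unidentified_pattern regular expression flagging incompletely
#'   identified species names.
#' @return the filtered tibble, with a `filter_log` attribute (named integer
#'   vector of removal counts per rule plus `input` and `retained`);
#'   read it with [filter_log()].
#' @export
apply_growth_filters <- function(growth, min_dbh = 100, g_min = -2, g_max = 100,
                                 unidentified_pattern = "(?i)^(indet|unknown|sp)\\.?$") {
  abort_if(!all(c("tree_id", "species", "G") %in% names(growth)),
           "`growth` needs columns tree_id, species, G")
  abort_if(g_min >= g_max, "`g_min` must be below `g_max`")
  n_input <- nrow(growth)

  if (min_dbh > 0) {
    abort_if(!"dbh_start" %in% names(growth),
             "`growth` needs a dbh_start column for the min_dbh rule")
    keep <- growth$dbh_start >= min_dbh
  } else {
    keep <- rep(TRUE, n_input)
  }
  n_dbh <- sum(!keep)
  growth <- growth[keep, , drop = FALSE]

  keep <- growth$G >= g_min & growth$G <= g_max
  n_bounds <- sum(!keep)
  growth <- growth[keep, , drop = FALSE]

  sp <- as.character(growth$species)
  unident <- is.na(sp) | sp == "" | grepl(unidentified_pattern, sp, perl = TRUE)
  n_unident <- sum(unident)
  growth <- growth[!unident, , drop = FALSE]

  n_obs <- table(growth$tree_id)
  singles <- names(n_obs)[n_obs < 2L]
  keep <- !(as.character(growth$tree_id) %in% singles)
  n_single_obs <- sum(!keep)
  growth <- growth[keep, , drop = FALSE]

  n_ind <- tapply(growth$tree_id, growth$species,
                  function(id) length(unique(id)))
  lone_sp <- names(n_ind)[n_ind < 2L]
  keep <- !(as.character(growth$species) %in% lone_sp)
  n_single_sp <- sum(!keep)
  growth <- growth[keep, , drop = FALSE]

  attr(growth, "filter_log") <- c(
    input = n_input,
    removed_min_dbh = n_dbh,
    removed_growth_bounds = n_bounds,
    removed_unidentified_species = n_unident,
    removed_single_observation = n_single_obs,
    removed_singleton_species = n_single_sp,
    retained = nrow(growth)
  )
  growth
}

#' Read the filter log attached by [apply_growth_filters()]
#' @param x a filtered growth tibble.
#' @return named integer vector of counts (input, per-rule removals, retained).
#' @export
filter_log <- function(x) {
  log <- attr(x, "filter_log")
  abort_if(is.null(log), "no filter_log attribute on this object")
  log
}

#' Competition index on a planting grid
#'
#' For each tree, the sum of the basal areas \eqn{\pi (DBH/2)^2} of its (up
#' to) eight direct grid neighbours (Moore neighbourhood), per plot. Edge and
#' corner trees keep their partial sums and are flagged.
#'
#' @param trees tibble with `tree_id`, `row`, `col` (planting-grid indices),
#'   `dbh_mm`, and optionally `plot` (neighbourhoods never cross plots).
#' @return the input with columns `comp_index` (mm^2), `n_neighbors`, and
#'   `edge` (TRUE when fewer than 8 neighbours).
#' @export
competition_index <- function(trees) {
  abort_if(!all(c("tree_id", "row", "col", "dbh_mm") %in% names(trees)),
           "`trees` needs columns tree_id, row, col, dbh_mm")
  if (!"plot" %in% names(trees)) trees$plot <- 1L
  one_plot <- function(df) {
    n <- nrow(df)
    ba <- pi * (df$dbh_mm / 2)^2
    dr <- abs(outer(df$row, df$row, "-"))
    dc <- abs(outer(df$col, df$col, "-"))
    nb <- dr <= 1L & dc <= 1L & !(dr == 0L & dc == 0L)
    df$comp_index <- as.vector(nb %*% ba)
    df$n_neighbors <- rowSums(nb)
    df
  }
  trees |>
    dplyr::group_by(.data$plot) |>
    dplyr::group_modify(~ one_plot(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(edge = .data$n_neighbors < 8L) |>
    dplyr::relocate(dplyr::all_of(setdiff(names(trees), "plot")))
}

#' Shifted-log transform followed by z-scoring
#'
#' `z = (ln(v + shift) - mean) / sd`, with mean and sd computed on the
#' log-transformed sample and stored so the transform can be inverted.
#' This is the response/covariate preparation used by the growth models
#' (shift 1 mm for the clonal model, 2 mm for the forest model, 0 for plain
#' covariates).
#'
#' @param values numeric vector.
#' @param shift constant added before the log; `values + shift` must be
#'   strictly positive.
#' @return list with `values` (transformed vector) and `scaler` (list
#'   `shift`, `mean`, `sd`), invertible with [inv_log_shift_scale()].
#' @export
log_shift_scale <- function(values, shift = 0) {
  bad <- which(values + shift <= 0)
  abort_if(length(bad) > 0,
           paste0("values + shift must be positive; offending rows: ",
                  paste(head(bad, 10), collapse = ", ")))
  lv <- log(values + shift)
  m <- mean(lv)
  s <- sd(lv)
  abort_if(is.na(s) || s == 0, "constant input: sd of log-values is zero")
  list(values = (lv - m) / s, scaler = list(shift = shift, mean = m, sd = s))
}

#' Invert [log_shift_scale()]
#' @param z transformed values.
#' @param scaler the `scaler` element returned by [log_shift_scale()].
#' @return values on the original scale.
#' @export
inv_log_shift_scale <- function(z, scaler) {
  exp(z * scaler$sd + scaler$mean) - scaler$shift
}
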