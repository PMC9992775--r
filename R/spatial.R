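#' Build the within-radius, same-plot pair set around a focal species
#'
#' Enumerates all unordered pairs of individuals lying in the same plot and
#' at Euclidean distance <= `radius`, and classes each pair relative to the
#' focal species: `conspecific` (both individuals of the focal species) or
#' `heterospecific` (exactly one of them is). With `focal_species = "all"`
#' every qualifying pair is returned with class `conspecific` when the two
#' species match and `heterospecific` otherwise.
#'
#' @param table tibble with `tree_id`, `species`, `x`, `y` and optionally
#'   `plot` (single plot assumed when absent).
#' @param radius pair cutoff in the units of `x`/`y` (meters), default 100.
#' @param focal_species a species present in `table`, or `"all"`.
#' @return tibble of pairs: `id_a`, `id_b`, `distance`, `pair_class`.
#' @export
build_neighbor_pairs <- function(table, radius = 100, focal_species = "all") {
  abort_if(!all(c("tree_id", "species", "x", "y") %in% names(table)),
           "`table` needs columns tree_id, species, x, y")
  if (!"plot" %in% names(table)) table$plot <- 1L
  radius <- check_positive(radius, "radius")
  pieces <- lapply(split(table, table$plot), function(df) {
    n <- nrow(df)
    if (n < 2L) return(NULL)
    d <- as.matrix(stats::dist(cbind(df$x, df$y)))
    idx <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    tibble::tibble(
      id_a = df$tree_id[idx[, 1L]],
      id_b = df$tree_id[idx[, 2L]],
      species_a = df$species[idx[, 1L]],
      species_b = df$species[idx[, 2L]],
      distance = d[idx]
    )
  })
  pairs <- dplyr::bind_rows(pieces)
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(id_a = integer(), id_b = integer(),
                          distance = numeric(), pair_class = character()))
  }
  if (identical(focal_species, "all")) {
    pairs$pair_class <- ifelse(pairs$species_a == pairs$species_b,
                               "conspecific", "heterospecific")
  } else {
    in_a <- pairs$species_a == focal_species
    in_b <- pairs$species_b == focal_species
    pairs <- pairs[in_a | in_b, , drop = FALSE]
    pairs$pair_class <- ifelse(in_a[in_a | in_b] & in_b[in_a | in_b],
                               "conspecific", "heterospecific")
  }
  pairs[, c("id_a", "id_b", "distance", "pair_class")]
}

#' Moran's I with a one-tailed normal-approximation test
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{i \ne j} w_{ij} (y_i - \bar y)(y_j - \bar y)}
#'       {\sum_i (y_i - \bar y)^2}}
#' The null expectation is \eqn{E[I] = -1/(n-1)}; the variance is the
#' standard randomization (permutation) variance, and the p-value is the
#' upper tail of the normal approximation (test for *positive* spatial
#' autocorrelation), matching the usual R implementation of the test.
#'
#' @param values numeric vector (length >= 3, non-constant).
#' @param weights n x n nonnegative weight matrix (diagonal ignored); need
#'   not be symmetric or row-standardized.
#' @return a one-row tibble: `n`, `observed` (I), `expected`, `sd`, `p_value`.
#' @examples
#' y <- c(0, 0, 1, 1)
#' w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- w[3, 4] <- w[4, 3] <- 1
#' morans_i(y, w)$observed  # exactly 1
#' @export
morans_i <- function(values, weights) {
  n <- length(values)
  abort_if(n < 3L, "need at least 3 values")
  weights <- as.matrix(weights)
  abort_if(!all(dim(weights) == n), "`weights` must be n x n")
  abort_if(any(weights < 0), "`weights` must be nonnegative")
  diag(weights) <- 0
  S0 <- sum(weights)
  abort_if(S0 == 0, "all weights are zero")
  d <- values - mean(values)
  m2 <- sum(d^2)
  abort_if(m2 == 0, "constant values: Moran's I undefined")
  I <- (n / S0) * as.numeric(crossprod(d, weights %*% d)) / m2
  EI <- -1 / (n - 1)
  S1 <- sum((weights + t(weights))^2) / 2
  S2 <- sum((rowSums(weights) + colSums(weights))^2)
  b2 <- n * sum(d^4) / m2^2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  sdI <- sqrt(VI)
  tibble::tibble(
    n = n, observed = I, expected = EI, sd = sdI,
    p_value = pnorm((I - EI) / sdI, lower.tail = FALSE)
  )
}

# Binary within-radius same-plot weight matrix for one species' table.
# Individuals with no qualifying neighbour are dropped (the test is built
# from qualifying pairs only); returns NULL when fewer than 3 remain.
conspecific_weights <- function(df, radius) {
  n <- nrow(df)
  if (n < 2L) return(NULL)
  d <- as.matrix(stats::dist(cbind(df$x, df$y)))
  w <- (d <= radius) * outer(df$plot, df$plot, "==")
  diag(w) <- 0
  has_nb <- rowSums(w) > 0
  if (sum(has_nb) < 3L) return(NULL)
  list(df = df[has_nb, , drop = FALSE],
       w = w[has_nb, has_nb, drop = FALSE])
}

#' Per-species Moran's I screen for spatial autocorrelation of growth
#'
#' For every species: take its individuals' mean growth values, build binary
#' weights linking same-plot conspecific pairs within `radius`, and run the
#' one-tailed Moran test for positive autocorrelation. Species are eligible
#' when (a) more than `min_neighbors` of their individuals have at least one
#' qualifying conspecific neighbour and (b) the species has more than
#' `min_pairs` qualifying pairs. Species above `max_sample` individuals are
#' subsampled uniformly to `max_sample` first.
#'
#' @param table mean-growth tibble with `tree_id`, `species`, `x`, `y`,
#'   `mean_growth`, optionally `plot`.
#' @param radius neighbour radius in meters (default 100).
#' @param min_neighbors eligibility threshold (strictly more than this many
#'   individuals with a conspecific neighbour; default 5).
#' @param min_pairs eligibility threshold on the number of qualifying
#'   conspecific pairs (strictly greater; default 5).
#' @param max_sample cap on individuals per species (default 3000).
#' @param alpha significance level for the summary (default 0.05).
#' @param seed seed for the subsampling.
#' @return an object of class `iv_moran_screen`: list with `results` (per
#'   species: `species`, `n_individuals`, `n_used`, `n_pairs`, `eligible`,
#'   `observed`, `expected`, `sd`, `p_value`, `significant`) and `summary`
#'   (tibble: `n_species_tested`, `pct_species_significant`,
#'   `pct_individuals_significant`, where percentages are over eligible
#'   species and over the individuals belonging to them).
#' @export
species_autocorrelation_screen <- function(table, radius = 100,
                                           min_neighbors = 5, min_pairs = 5,
                                           max_sample = 3000, alpha = 0.05,
                                           seed = 1L) {
  abort_if(!all(c("tree_id", "species", "x", "y", "mean_growth") %in% names(table)),
           "`table` needs columns tree_id, species, x, y, mean_growth")
  if (!"plot" %in% names(table)) table$plot <- 1L
  set.seed(as.integer(seed))
  res <- lapply(split(table, table$species), function(df) {
    n_ind <- nrow(df)
    if (n_ind > max_sample) df <- df[sample.int(n_ind, max_sample), , drop = FALSE]
    row <- tibble::tibble(
      species = df$species[1L], n_individuals = n_ind, n_used = NA_integer_,
      n_pairs = 0L, eligible = FALSE, observed = NA_real_,
      expected = NA_real_, sd = NA_real_, p_value = NA_real_,
      significant = FALSE
    )
    cw <- conspecific_weights(df, radius)
    if (is.null(cw)) return(row)
    n_pairs <- sum(cw$w) / 2
    row$n_used <- nrow(cw$df)
    row$n_pairs <- as.integer(n_pairs)
    if (!(row$n_used > min_neighbors && n_pairs > min_pairs)) return(row)
    if (var(cw$df$mean_growth) == 0) return(row)
    row$eligible <- TRUE
    mi <- morans_i(cw$df$mean_growth, cw$w)
    row$observed <- mi$observed
    row$expected <- mi$expected
    row$sd <- mi$sd
    row$p_value <- mi$p_value
    row$significant <- mi$p_value < alpha
    row
  })
  results <- dplyr::bind_rows(res)
  elig <- dplyr::filter(results, .data$eligible)
  summary <- tibble::tibble(
    n_species = nrow(results),
    n_species_tested = nrow(elig),
    pct_species_significant =
      100 * mean(elig$significant),
    pct_individuals_significant =
      100 * sum(elig$n_individuals[elig$significant]) / sum(elig$n_individuals),
    alpha = alpha, radius = radius
  )
  structure(list(results = results, summary = summary,
                 denominators = "eligible species; individuals of eligible species"),
            class = "iv_moran_screen")
}

#' @export
print.iv_moran_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<iv_moran_screen> %d species, %d tested: %.1f%% significant (%.1f%% of individuals)\n",
    s$n_species, s$n_species_tested,
    s$pct_species_significant, s$pct_individuals_significant))
  invisible(x)
}

#' Semivariance of a set of value pairs
#'
#' The mean of the squared differences over all supplied pairs,
#' \eqn{\gamma = \frac{1}{|P|} \sum_{(i,j) \in P} (v_i - v_j)^2}. Note the
#' convention: no 1/2 factor by default (set `classic = TRUE` for the
#' conventional geostatistical semivariance, half this value). Rank-based
#' comparisons between pair classes are invariant to that factor.
#'
#' @param v_a,v_b values of the first and second member of each pair.
#' @param classic halve the mean squared difference (default FALSE).
#' @return a single nonnegative number.
#' @examples
#' pairwise_semivariance(c(0, 0, 1), c(1, 2, 2))  # all pairs of {0,1,2} -> 2
#' @export
pairwise_semivariance <- function(v_a, v_b, classic = FALSE) {
  abort_if(length(v_a) != length(v_b), "pair vectors must have equal length")
  abort_if(length(v_a) == 0L, "empty pair set")
  g <- mean((v_a - v_b)^2)
  if (classic) g / 2 else g
}

#' Compare intra- vs interspecific semivariance per species
#'
#' For each eligible focal species: the squared differences in mean growth
#' over conspecific pairs form one sample, over heterospecific pairs (one
#' member of the focal species) the other; the two are compared with a
#' two-sided Mann-Whitney test. Classification:
#' `intra<inter` when significant and the conspecific semivariance is the
#' smaller, `intra>inter` when significant the other way, `ns` otherwise.
#' Eligibility: more than `min_individuals` individuals and more than
#' `min_hetero_neighbors` distinct heterospecific neighbours within the
#' radius. `max_per_species` (e.g. 10) enables the abundance control:
#' before pairing, every species is subsampled to at most that many
#' individuals.
#'
#' @inheritParams species_autocorrelation_screen
#' @param min_individuals eligibility: species must have strictly more
#'   individuals than this (default 5).
#' @param min_hetero_neighbors eligibility: strictly more distinct
#'   heterospecific neighbours within `radius` (default 5).
#' @param max_per_species optional cap per species (abundance control);
#'   `NULL` (default) uses all individuals.
#' @return an object of class `iv_semivar_comparison`: list with `results`
#'   (per species: semivariances, pair counts, `p_value`, `classification`)
#'   and `summary` (percent of eligible species, and of their individuals,
#'   per classification).
#' @export
compare_intra_inter <- function(table, radius = 100, min_individuals = 5,
                                min_hetero_neighbors = 5, alpha = 0.05,
                                max_per_species = NULL, seed = 1L) {
  abort_if(!all(c("tree_id", "species", "x", "y", "mean_growth") %in% names(table)),
           "`table` needs columns tree_id, species, x, y, mean_growth")
  if (!"plot" %in% names(table)) table$plot <- 1L
  set.seed(as.integer(seed))
  if (!is.null(max_per_species)) {
    table <- table |>
      dplyr::group_by(.data$species) |>
      dplyr::slice_sample(n = max_per_species) |>
      dplyr::ungroup()
  }
  n_by_species <- table |>
    dplyr::count(.data$species, name = "n_individuals")
  pairs <- build_neighbor_pairs(table, radius = radius, focal_species = "all")
  vals <- setNames(table$mean_growth, as.character(table$tree_id))
  sp_of <- setNames(as.character(table$species), as.character(table$tree_id))
  pairs$v_a <- vals[as.character(pairs$id_a)]
  pairs$v_b <- vals[as.character(pairs$id_b)]
  pairs$sp_a <- sp_of[as.character(pairs$id_a)]
  pairs$sp_b <- sp_of[as.character(pairs$id_b)]
  pairs$sqdiff <- (pairs$v_a - pairs$v_b)^2

  res <- lapply(sort(unique(as.character(table$species))), function(sp) {
    n_ind <- n_by_species$n_individuals[n_by_species$species == sp]
    intra <- pairs$sqdiff[pairs$sp_a == sp & pairs$sp_b == sp]
    het <- pairs[(pairs$sp_a == sp) != (pairs$sp_b == sp), , drop = FALSE]
    hetero_ids <- unique(c(het$id_b[het$sp_a == sp], het$id_a[het$sp_b == sp]))
    row <- tibble::tibble(
      species = sp, n_individuals = n_ind,
      n_intra_pairs = length(intra), n_inter_pairs = nrow(het),
      n_hetero_neighbors = length(hetero_ids),
      intra_semivariance = if (length(intra)) mean(intra) else NA_real_,
      inter_semivariance = if (nrow(het)) mean(het$sqdiff) else NA_real_,
      eligible = n_ind > min_individuals &&
        length(hetero_ids) > min_hetero_neighbors &&
        length(intra) > 0L,
      p_value = NA_real_, classification = NA_character_
    )
    if (!row$eligible) return(row)
    wt <- suppressWarnings(wilcox.test(intra, het$sqdiff, exact = FALSE))
    row$p_value <- wt$p.value
    row$classification <- if (wt$p.value >= alpha) "ns"
      else if (row$intra_semivariance < row$inter_semivariance) "intra<inter"
      else "intra>inter"
    row
  })
  results <- dplyr::bind_rows(res)
  elig <- dplyr::filter(results, .data$eligible)
  classes <- c("intra<inter", "ns", "intra>inter")
  n_sp <- vapply(classes, function(cl) sum(elig$classification == cl), 0L)
  summary <- tibble::tibble(
    classification = classes,
    n_species = n_sp,
    pct_species = 100 * n_sp / max(nrow(elig), 1L),
    pct_individuals = vapply(classes, function(cl) {
      100 * sum(elig$n_individuals[elig$classification == cl]) /
        max(sum(elig$n_individuals), 1L)
    }, 0)
  )
  structure(list(results = results, summary = summary, alpha = alpha,
                 radius = radius,
                 denominators = "eligible species; individuals of eligible species"),
            class = "iv_semivar_comparison")
}

#' @export
print.iv_semivar_comparison <- function(x, ...) {
  cat(sprintf("<iv_semivar_comparison> %d species tested (alpha %.2f)\n",
              sum(x$results$eligible), x$alpha))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Empirical semivariogram by distance bins
#'
#' Mean squared difference (no 1/2 factor by default, see
#' [pairwise_semivariance()]) over all point pairs whose separation falls in
#' each distance bin. Empty bins are reported with `n_pairs = 0` and `NA`
#' semivariance.
#'
#' @param values numeric vector of point values.
#' @param coords two-column matrix or data frame of coordinates.
#' @param bin_edges strictly increasing vector of bin edges; pairs at
#'   distance d are binned into `[edge_k, edge_{k+1})`.
#' @param classic use the conventional 1/2 factor.
#' @return a tibble of class `iv_semivariogram`: `bin_mid`, `bin_lo`,
#'   `bin_hi`, `semivariance`, `n_pairs`.
#' @export
empirical_semivariogram <- function(values, coords, bin_edges, classic = FALSE) {
  coords <- as.matrix(coords)
  n <- length(values)
  abort_if(n < 2L, "need at least 2 points")
  abort_if(nrow(coords) != n, "`coords` must have one row per value")
  abort_if(any(diff(bin_edges) <= 0), "`bin_edges` must be strictly increasing")
  d <- as.matrix(stats::dist(coords))
  ut <- upper.tri(d)
  dd <- d[ut]
  sq <- (outer(values, values, "-")^2)[ut]
  bin <- cut(dd, breaks = bin_edges, right = FALSE, labels = FALSE)
  k <- length(bin_edges) - 1L
  gamma <- vapply(seq_len(k), function(b) {
    s <- sq[!is.na(bin) & bin == b]
    if (length(s)) mean(s) else NA_real_
  }, 0)
  np <- vapply(seq_len(k), function(b) sum(!is.na(bin) & bin == b), 0L)
  if (classic) gamma <- gamma / 2
  out <- tibble::tibble(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1L],
    bin_mid = (bin_edges[-length(bin_edges)] + bin_edges[-1L]) / 2,
    semivariance = gamma,
    n_pairs = np
  )
  class(out) <- c("iv_semivariogram", class(out))
  out
}

#' Per-species and pooled semivariogram curves
#'
#' Convenience wrapper producing the curves of the classic within- vs
#' between-species comparison figure: one empirical semivariogram per
#' species plus one for all individuals pooled, on shared distance bins.
#'
#' @param table tibble with `species`, `x`, `y`, and the value column.
#' @param value name of the value column (default `"mean_growth"`).
#' @param bin_edges distance bin edges.
#' @inheritParams empirical_semivariogram
#' @return a tibble: `group` ("all" or the species), `bin_mid`,
#'   `semivariance`, `n_pairs`, of class `iv_semivariogram_set`.
#' @export
semivariogram_curves <- function(table, value = "mean_growth", bin_edges,
                                 classic = FALSE) {
  abort_if(!all(c("species", "x", "y", value) %in% names(table)),
           sprintf("`table` needs columns species, x, y, %s", value))
  one <- function(df, label) {
    sv <- empirical_semivariogram(df[[value]], df[, c("x", "y")], bin_edges,
                                  classic = classic)
    sv$group <- label
    sv
  }
  out <- dplyr::bind_rows(
    one(table, "all"),
    dplyr::bind_rows(lapply(split(table, table$species), function(df) {
      if (nrow(df) < 2L) return(NULL)
      one(df, as.character(df$species[1L]))
    }))
  )
  class(out) <- c("iv_semivariogram_set", class(out))
  out
}
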