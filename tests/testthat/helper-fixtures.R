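# Fixtures built in code; no data files.

# Ten growth records covering every filter rule: 2 out of bounds (one
# below, one above), one unidentified-species record, one single-record
# individual of its own species, and 6 clean records that survive.
toy_growth_table <- function() {
  tibble::tibble(
    tree_id = c(1, 1, 2, 2, 2, 3, 3, 3, 4, 5),
    species = c("A", "A", "A", "A", "A", "A", "A", "A", "Indet.", "C"),
    dbh_start = rep(150, 10),
    G = c(2, 3, -3, 4, 1, 101, 5, -2, 1, 2)
  )
}

# Small census table: 2 trees, 3 censuses each.
toy_census_table <- function() {
  tibble::tibble(
    tree_id = rep(c(1, 2), each = 3),
    species = rep(c("A", "B"), each = 3),
    plot = 1,
    x = rep(c(0, 10), each = 3),
    y = 0,
    date = rep(c(2000, 2002, 2005), 2),
    dbh_mm = c(100, 110, 120, 200, 200, 230)
  )
}

# Brute-force Moran's I: plain double loop, no linear algebra.
brute_force_moran <- function(y, w) {
  n <- length(y)
  yb <- mean(y)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      num <- num + w[i, j] * (y[i] - yb) * (y[j] - yb)
      s0 <- s0 + w[i, j]
    }
  }
  (n / s0) * num / sum((y - yb)^2)
}

# Brute-force mean squared pairwise difference over an explicit pair list.
brute_force_semivariance <- function(values, pairs) {
  tot <- 0
  for (k in seq_len(nrow(pairs))) {
    tot <- tot + (values[pairs[k, 1]] - values[pairs[k, 2]])^2
  }
  tot / nrow(pairs)
}

# Synthetic draws shaped like an mcmc.list: `chains` vectors of equal length.
fake_chains <- function(..., params = "theta") {
  chains <- list(...)
  coda::mcmc.list(lapply(chains, function(v) {
    m <- matrix(v, ncol = length(params))
    colnames(m) <- params
    coda::mcmc(m)
  }))
}

# Fast MCMC settings for fits inside tests.
test_config <- function(seed = 1L) mcmc_config(test_mode = TRUE, seed = seed)
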