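test_that("Moran's I reproduces the hand-computed two-cluster case and the analytic null mean", {
  y <- c(0, 0, 1, 1)
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- w[3, 4] <- w[4, 3] <- 1
  mi <- morans_i(y, w)
  expect_equal(mi$observed, 1.0, tolerance = 1e-14)
  expect_equal(mi$expected, -1 / 3, tolerance = 1e-14)
  # null expectation for arbitrary n
  set.seed(1)
  for (n in c(5, 17, 40)) {
    w <- matrix(runif(n * n), n, n); w <- w + t(w); diag(w) <- 0
    expect_equal(morans_i(rnorm(n), w)$expected, -1 / (n - 1),
                 tolerance = 1e-14)
  }
  expect_error(morans_i(c(1, 1, 1), matrix(1, 3, 3)), "constant")
  expect_error(morans_i(c(1, 2, 3), matrix(0, 3, 3)), "zero")
  expect_error(morans_i(c(1, 2), matrix(1, 2, 2)), "at least 3")
})

test_that("Moran's I agrees with a brute-force double loop and with the ape implementation", {
  skip_if_not_installed("ape")
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    y <- rnorm(n)
    xy <- matrix(runif(2 * n), ncol = 2)
    d <- as.matrix(dist(xy))
    w <- (d <= quantile(d[upper.tri(d)], 0.3)) * 1
    diag(w) <- 0
    if (sum(w) == 0) next
    mi <- morans_i(y, w)
    expect_equal(mi$observed, brute_force_moran(y, w), tolerance = 1e-12)
    # ape row-standardizes its weights internally; feed both sides the same
    # effective matrix to compare statistic, randomization sd and p-value
    rs <- rowSums(w)
    w_std <- w / ifelse(rs == 0, 1, rs)
    mi_std <- morans_i(y, w_std)
    ref <- ape::Moran.I(y, w, alternative = "greater")
    expect_equal(mi_std$observed, ref$observed, tolerance = 1e-12)
    expect_equal(mi_std$expected, ref$expected, tolerance = 1e-12)
    expect_equal(mi_std$sd, ref$sd, tolerance = 1e-10)
    expect_equal(mi_std$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("pairwise semivariance matches enumeration, is translation invariant, and halves under the classic convention", {
  # all pairs of {0, 1, 2}: (1 + 4 + 1) / 3 = 2
  expect_equal(pairwise_semivariance(c(0, 0, 1), c(1, 2, 2)), 2.0)
  expect_equal(pairwise_semivariance(c(3, 3), c(3, 3)), 0)
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pairwise_semivariance(a, b),
               pairwise_semivariance(a + 17.3, b + 17.3), tolerance = 1e-12)
  expect_equal(pairwise_semivariance(a, b, classic = TRUE),
               pairwise_semivariance(a, b) / 2, tolerance = 1e-14)
  expect_error(pairwise_semivariance(numeric(0), numeric(0)), "empty")
})

test_that("neighbour pairs respect radius, plot boundaries, and focal-species classing", {
  tb <- tibble::tibble(
    tree_id = 1:4, species = c("A", "A", "B", "B"),
    x = c(0, 10, 20, 30), y = 0, plot = 1,
    mean_growth = 1:4
  )
  pr <- build_neighbor_pairs(tb, radius = 100, focal_species = "all")
  expect_equal(nrow(pr), 6)   # C(4,2), all within radius
  expect_equal(sum(pr$pair_class == "conspecific"), 2)
  expect_equal(sum(pr$pair_class == "heterospecific"), 4)
  # radius cutoff
  expect_equal(nrow(build_neighbor_pairs(tb, radius = 5)), 0)
  two <- tb[1:2, ]
  expect_equal(nrow(build_neighbor_pairs(two, radius = 100)), 1)
  # different plots never pair
  tb2 <- tb
  tb2$plot <- c(1, 2, 1, 2)
  pr2 <- build_neighbor_pairs(tb2, radius = 100)
  expect_equal(nrow(pr2), 2)  # (1,3) and (2,4) only
  # focal species restriction
  prA <- build_neighbor_pairs(tb, radius = 100, focal_species = "A")
  expect_equal(nrow(prA), 5)  # drops the B-B pair
  expect_equal(sum(prA$pair_class == "conspecific"), 1)
})

test_that("the empirical semivariogram is consistent with the single-pair-set semivariance and flat for white noise", {
  set.seed(3)
  n <- 80
  coords <- matrix(runif(2 * n, 0, 100), ncol = 2)
  v <- rnorm(n, sd = 2)
  # one bin covering everything equals the plain pairwise semivariance
  sv1 <- empirical_semivariogram(v, coords, bin_edges = c(0, 1000))
  pairs <- t(combn(n, 2))
  expect_equal(sv1$semivariance, brute_force_semivariance(v, pairs),
               tolerance = 1e-12)
  expect_equal(sv1$n_pairs, nrow(pairs))
  # i.i.d. values: every bin hovers around 2 * variance (no-1/2 convention)
  sv <- empirical_semivariogram(v, coords, bin_edges = seq(0, 100, by = 25))
  filled <- sv[sv$n_pairs > 30, ]
  expect_true(all(abs(filled$semivariance / (2 * var(v)) - 1) < 0.35))
  # empty bins are reported, not dropped
  sv0 <- empirical_semivariogram(v, coords, bin_edges = c(0, 1e-9, 1000))
  expect_equal(sv0$n_pairs[1], 0L)
  expect_true(is.na(sv0$semivariance[1]))
  expect_error(empirical_semivariogram(v, coords, bin_edges = c(10, 5)),
               "increasing")
})

test_that("the Moran screen flags low-abundance species as ineligible and is deterministic under a fixed seed", {
  set.seed(5)
  n <- 60
  tb <- tibble::tibble(
    tree_id = 1:(n + 3),
    species = c(rep("big", n), rep("tiny", 3)),
    x = runif(n + 3, 0, 100), y = runif(n + 3, 0, 100),
    plot = 1, mean_growth = rnorm(n + 3)
  )
  scr <- species_autocorrelation_screen(tb, radius = 50, seed = 9)
  tiny <- scr$results[scr$results$species == "tiny", ]
  expect_false(tiny$eligible)
  expect_true(is.na(tiny$p_value))
  big <- scr$results[scr$results$species == "big", ]
  expect_true(big$eligible)
  expect_true(is.finite(big$p_value))
  scr2 <- species_autocorrelation_screen(tb, radius = 50, seed = 9)
  expect_equal(scr$results, scr2$results)
  expect_equal(scr$summary$n_species_tested, 1)
})

test_that("a locally clustered conspecific pattern is classified intra<inter", {
  # conspecific values tightly clustered, heterospecific neighbours divergent
  set.seed(6)
  nf <- 12; nh <- 30
  tb <- tibble::tibble(
    tree_id = seq_len(nf + nh),
    species = c(rep("focal", nf), rep(paste0("o", 1:3), each = nh / 3)),
    x = runif(nf + nh, 0, 50), y = runif(nf + nh, 0, 50),
    plot = 1,
    mean_growth = c(rnorm(nf, 5, 0.05), rnorm(nh, c(1, 9, 15), 0.5))
  )
  cmp <- compare_intra_inter(tb, radius = 100, seed = 1)
  focal <- cmp$results[cmp$results$species == "focal", ]
  expect_true(focal$eligible)
  expect_equal(focal$classification, "intra<inter")
  expect_lt(focal$intra_semivariance, focal$inter_semivariance)
  # summary percentages over eligible species only
  expect_equal(sum(cmp$summary$pct_species), 100, tolerance = 1e-9)
  # abundance control subsamples reproducibly
  cmp10 <- compare_intra_inter(tb, radius = 100, max_per_species = 10, seed = 2)
  cmp10b <- compare_intra_inter(tb, radius = 100, max_per_species = 10, seed = 2)
  expect_equal(cmp10$results, cmp10b$results)
  expect_true(all(cmp10$results$n_individuals <= 10))
})
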