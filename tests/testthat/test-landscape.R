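test_that("landscapes are reproducible, positive in X1, and static where declared", {
  a <- generate_environment(C = 30, N = 4, T_dates = 3, autocorr_range = 6,
                            dynamic_dims = c(2, 3), seed = 7)
  b <- generate_environment(C = 30, N = 4, T_dates = 3, autocorr_range = 6,
                            dynamic_dims = c(2, 3), seed = 7)
  expect_identical(a$fields, b$fields)
  expect_true(all(is.finite(a$fields)))
  expect_true(all(a$fields[, , 1, ] > 0))          # X1 is lognormal
  # static dimensions bit-identical across dates, dynamic ones not
  expect_identical(a$fields[, , 1, 1], a$fields[, , 1, 3])
  expect_identical(a$fields[, , 4, 1], a$fields[, , 4, 2])
  expect_false(identical(a$fields[, , 2, 1], a$fields[, , 2, 2]))
  expect_false(identical(a$fields[, , 3, 1], a$fields[, , 3, 2]))
  # different seed, different fields
  c <- generate_environment(C = 30, N = 4, T_dates = 3, autocorr_range = 6,
                            dynamic_dims = c(2, 3), seed = 8)
  expect_false(identical(a$fields, c$fields))
  expect_error(generate_environment(C = 0, N = 1, T_dates = 1, autocorr_range = 1),
               "C")
  expect_message(generate_environment(C = 10, N = 2, T_dates = 2,
                                      autocorr_range = 3, dynamic_dims = 1:2,
                                      seed = 1),
                 "observed covariate")
})

test_that("simulated fields carry autocorrelation at the requested range and lose it in the white-noise limit", {
  set.seed(11)
  f_corr <- gaussian_random_field(60, 12)
  f_white <- gaussian_random_field(60, 1e-6)
  # marginal variance close to 1 either way
  expect_lt(abs(var(as.vector(f_corr)) - 1), 0.35)
  expect_lt(abs(var(as.vector(f_white)) - 1), 0.1)
  # sample points; lag-1-ish Moran positive for the correlated field only
  idx <- expand.grid(r = seq(2, 58, by = 4), c = seq(2, 58, by = 4))
  coords <- as.matrix(idx)
  d <- as.matrix(dist(coords))
  w <- (d <= 4.5) * 1; diag(w) <- 0
  mi_corr <- morans_i(f_corr[coords], w)
  mi_white <- morans_i(f_white[coords], w)
  expect_lt(mi_corr$p_value, 0.001)
  expect_gt(mi_white$p_value, 0.01)
  expect_lt(abs(mi_white$observed - mi_white$expected), 4 * mi_white$sd)
  # semivariogram of the correlated field rises with distance
  vals <- f_corr[coords]
  sv <- empirical_semivariogram(vals, coords, bin_edges = c(0, 6, 12, 24, 48))
  expect_lt(sv$semivariance[1], sv$semivariance[3])
})

test_that("placements stay on the grid with stable unique ids", {
  p <- place_individuals(I = 300, J = 2, C = 500, seed = 1)
  expect_equal(nrow(p), 600)
  expect_equal(unname(table(p$j)), c(300L, 300L), ignore_attr = TRUE)
  expect_false(any(duplicated(p$i)))
  expect_true(all(p$row >= 1 & p$row <= 500 & p$col >= 1 & p$col <= 500))
  expect_true(all(p$x > 0 & p$x < 500 & p$y > 0 & p$y < 500))
  expect_identical(p, place_individuals(300, 2, 500, seed = 1))
  single <- place_individuals(1, 1, 10, seed = 2)
  expect_equal(nrow(single), 1)
})

test_that("species response vectors are distinct and reproducible; degenerate scale is rejected", {
  r <- draw_species_responses(J = 2, N = 10, seed = 3)
  expect_equal(dim(r$beta), c(2, 11))
  expect_false(identical(r$beta[1, ], r$beta[2, ]))
  expect_identical(r$beta, draw_species_responses(2, 10, seed = 3)$beta)
  expect_error(draw_species_responses(2, 10, coef_scale = 0), "coef_scale")
})

test_that("the attribute is an exact deterministic function of the cell environment", {
  land <- generate_environment(C = 40, N = 5, T_dates = 2, autocorr_range = 8,
                               seed = 5)
  pl <- place_individuals(40, 2, 40, seed = 6)
  rs <- draw_species_responses(2, 5, seed = 7)
  att <- simulate_attribute(land, pl, rs)
  expect_equal(nrow(att), 40 * 2 * 2)
  expect_true(all(att$Y > 0))
  # recompute ln Y from the stored covariates: exact to full precision
  design <- cbind(1, log(att$X1), as.matrix(att[, paste0("X", 2:5)]))
  expect_equal(log(att$Y), unname(rowSums(design * rs$beta[att$j, ])),
               tolerance = 1e-14)
  # intercept-only responses: Y = exp(a) everywhere
  rs0 <- rs
  rs0$beta[] <- 0
  rs0$beta[, 1] <- c(1.5, -0.5)
  att0 <- simulate_attribute(land, pl, rs0)
  expect_equal(att0$Y, exp(c(1.5, -0.5))[att0$j], tolerance = 1e-14)
  # identity on the log scale: N = 1, beta = [0, 1] reproduces X1
  land1 <- generate_environment(C = 20, N = 1, T_dates = 1, autocorr_range = 4,
                                seed = 8)
  pl1 <- place_individuals(10, 1, 20, seed = 9)
  rs1 <- draw_species_responses(1, 1, seed = 10)
  rs1$beta[] <- c(0, 1)
  att1 <- simulate_attribute(land1, pl1, rs1)
  expect_equal(att1$Y, att1$X1, tolerance = 1e-14)
  # dimension mismatch is an error
  expect_error(simulate_attribute(land1, pl1, rs), "dimensions")
})

test_that("with two distinct species, mean within-species semivariance does not exceed the pooled semivariance", {
  for (seed in 1:3) {
    land <- generate_environment(C = 50, N = 6, T_dates = 1, autocorr_range = 8,
                                 seed = seed)
    pl <- place_individuals(60, 2, 50, seed = seed + 10)
    rs <- draw_species_responses(2, 6, seed = seed + 20)
    att <- simulate_attribute(land, pl, rs)
    # brute-force enumeration of all pairs
    n <- nrow(att)
    pairs <- t(combn(n, 2))
    same <- att$j[pairs[, 1]] == att$j[pairs[, 2]]
    v <- att$Y
    within <- brute_force_semivariance(v, pairs[same, , drop = FALSE])
    pooled <- brute_force_semivariance(v, pairs)
    expect_lte(within, pooled)
  }
})

test_that("landscape tidying exposes one row per cell, dimension and date", {
  land <- generate_environment(C = 5, N = 2, T_dates = 2, autocorr_range = 2,
                               seed = 1)
  tb <- tibble::as_tibble(land)
  expect_equal(nrow(tb), 5 * 5 * 2 * 2)
  expect_equal(tb$value[tb$dim == 1 & tb$t == 1],
               as.vector(land$fields[, , 1, 1]))
  expect_equal(tb$x, tb$col - 0.5)
})
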