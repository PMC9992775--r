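test_that("variance partitioning is exact, permutation invariant, and guards degenerate input", {
  p <- partition_variance(c(V_i = 0.23, V_b = 0.06, V_g = 0.13,
                            V_t = 1.3, V = 0.51))
  expect_equal(sum(p$percentage), 100, tolerance = 1e-12)
  # permutation invariance
  p2 <- partition_variance(c(V = 0.51, V_t = 1.3, V_g = 0.13,
                             V_b = 0.06, V_i = 0.23))
  expect_equal(p$percentage[match(p2$component, p$component)], p2$percentage,
               tolerance = 1e-14)
  expect_equal(partition_variance(c(A = 1))$percentage, 100)
  expect_error(partition_variance(c(A = 0, B = 0)), "zero")
  expect_error(partition_variance(c(A = -1, B = 2)), "nonnegative")
  expect_error(partition_variance(setNames(1, "")), "named")
})

test_that("MCMC configuration applies the stated defaults and validates its schedule", {
  cfg <- mcmc_config()
  expect_equal(cfg$n_chains, 4L)
  expect_equal(cfg$n_iter, 10000L)
  expect_equal(cfg$n_warmup, 5000L)
  expect_equal(cfg$thin, 5L)
  expect_equal(cfg$prior_var_df, 3L)
  expect_equal(cfg$prior_var_scale, 2.5)
  expect_equal(cfg$prior_mean_sd, 1)
  tst <- mcmc_config(test_mode = TRUE)
  expect_equal(tst$n_chains, 2L)
  expect_equal(tst$n_iter, 2000L)
  expect_error(mcmc_config(n_iter = 100, n_warmup = 200), "n_warmup")
})

test_that("convergence checks pass same-target chains and fail divergent or constant ones", {
  set.seed(8)
  ok <- fake_chains(rnorm(800), rnorm(800))
  conv <- check_convergence(ok)
  expect_true(conv$pass)
  expect_lt(max(conv$table$rhat), 1.05)
  # chains centred at different values
  apart <- fake_chains(rnorm(800, 0), rnorm(800, 5))
  conv2 <- check_convergence(apart)
  expect_false(conv2$pass)
  expect_gt(max(conv2$table$rhat), 2)
  # constant chains: degenerate ESS flagged
  const <- fake_chains(rep(1, 800), rep(1, 800))
  conv3 <- check_convergence(const)
  expect_false(conv3$pass)
  expect_equal(conv3$table$ess, 0)
  expect_error(check_convergence(fake_chains(rnorm(800))), "2 chains")
})

test_that("the imperfect-knowledge fit shrinks individual variance to zero when X1 explains everything", {
  set.seed(10)
  n_ind <- 60; T_d <- 3
  x1 <- exp(rnorm(n_ind * T_d))
  ind <- rep(seq_len(n_ind), each = T_d)
  dat <- tibble::tibble(
    i = ind, j = rep(1:2, each = n_ind / 2 * T_d),
    X1 = x1,
    Y = exp(ifelse(j == 1, 0.5 + 0.8 * log(x1), -0.2 + 0.3 * log(x1)) +
              rnorm(n_ind * T_d, 0, 0.02))
  )
  fit <- fit_imperfect_model(dat, test_config(3))
  td <- tidy(fit)
  vu <- td$estimate[td$term %in% c("V_u[1]", "V_u[2]")]
  expect_true(all(vu < 0.01))
  expect_equal(td$estimate[td$term == "b1[1]"], 0.8, tolerance = 0.05)
  expect_equal(td$estimate[td$term == "b1[2]"], 0.3, tolerance = 0.05)
  expect_error(fit_imperfect_model(dplyr::mutate(dat, Y = -Y)), "positive")
})

test_that("the imperfect-knowledge model recovers its own generative parameters with calibrated intervals", {
  # 20 replicates from the model's own generative form; pooled 95% CI
  # coverage over (b0, b1, V_u, V_e) x 2 species must reach 85%, and the
  # first replicate's posterior means must sit within 3 posterior sds
  n_ind <- 100; T_d <- 3
  truth <- list(b0 = c(0.4, -0.3), b1 = c(0.6, 0.2),
                V_u = c(0.5, 0.3), V_e = c(0.2, 0.4))
  hits <- 0; total <- 0
  for (rep in 1:20) {
    set.seed(100 + rep)
    spi <- rep(1:2, each = n_ind / 2)
    u <- rnorm(n_ind, 0, sqrt(truth$V_u[spi]))
    ind <- rep(seq_len(n_ind), each = T_d)
    sp <- spi[ind]
    lx1 <- rnorm(n_ind * T_d)
    lnY <- truth$b0[sp] + u[ind] + truth$b1[sp] * lx1 +
      rnorm(n_ind * T_d, 0, sqrt(truth$V_e[sp]))
    dat <- tibble::tibble(i = ind, j = sp, X1 = exp(lx1), Y = exp(lnY))
    fit <- fit_imperfect_model(dat, test_config(rep))
    td <- tidy(fit)
    tv <- c(truth$b0, truth$b1, truth$V_u, truth$V_e)
    names(tv) <- c("b0[1]", "b0[2]", "b1[1]", "b1[2]",
                   "V_u[1]", "V_u[2]", "V_e[1]", "V_e[2]")
    row <- td[match(names(tv), td$term), ]
    hits <- hits + sum(tv >= row$conf.low & tv <= row$conf.high)
    total <- total + length(tv)
    if (rep == 1) {
      expect_true(all(abs(row$estimate - tv) <= 3 * row$std.error))
    }
  }
  expect_gte(hits / total, 0.85)
})

test_that("the clonal growth model recovers generated variance components", {
  cc <- clonal_trial_config(n_blocks = 3, n_genotypes = 5, trees_per_plot = 25,
                            n_censuses = 4, seed = 11)
  ct <- generate_clonal_trial(cc)
  fit <- fit_clonal_growth_model(ct$growth, test_config(11))
  s_y2 <- fit$scalers$response$sd^2
  truth <- ct$truth$sigma2[c("block", "geno", "date", "ind", "resid")] / s_y2
  td <- tidy(fit)
  terms <- c("V_b", "V_g", "V_t", "V_i", "V")
  row <- td[match(terms, td$term), ]
  expect_true(all(abs(row$estimate - unname(truth)) <= 3 * row$std.error))
  # slope recovery: generative slope maps through the two z-scalers
  slope_truth <- ct$truth$beta[["beta1"]] * fit$scalers$ln_d$sd /
    fit$scalers$response$sd
  b1 <- td[td$term == "b1", ]
  expect_true(abs(b1$estimate - slope_truth) <= 3 * b1$std.error)
  expect_error(fit_clonal_growth_model(ct$growth[, setdiff(names(ct$growth), "genotype")]),
               "genotype")
})

test_that("the forest growth model recovers matched species and individual variances and rejects one species", {
  set.seed(12)
  fc <- forest_inventory_config(n_species = 15, n_trees = 400, extent_m = 150,
                                iv_mode = "unstructured",
                                sigma2_species = 0.3, sigma2_ind = 0.3,
                                seed = 12)
  fi <- generate_forest_inventory(fc)
  fit <- fit_forest_growth_model(fi$growth, test_config(12))
  s_y2 <- fit$scalers$response$sd^2
  td <- tidy(fit)
  vbj <- td[td$term == "V_bj", ]
  vbi <- td[td$term == "V_bi", ]
  expect_true(abs(vbj$estimate - 0.3 / s_y2) <= 3 * vbj$std.error)
  expect_true(abs(vbi$estimate - 0.3 / s_y2) <= 3 * vbi$std.error)
  # generated equal -> posterior ratio near 1 within Monte-Carlo tolerance
  expect_gt(vbi$estimate / vbj$estimate, 1 / 3)
  expect_lt(vbi$estimate / vbj$estimate, 3)
  one <- dplyr::filter(fi$growth, species == "sp01")
  expect_error(fit_forest_growth_model(one), "2 species")
})

test_that("the predictive envelope collapses without variance, widens with it, and covers new individuals", {
  # doctored fit: constant coefficient draws, controllable variances
  make_fit <- function(vu, ve) {
    n_draw <- 200
    mat <- cbind(`b0[1]` = rep(0.5, n_draw), `b1[1]` = rep(1, n_draw),
                 `V_u[1]` = rep(vu, n_draw), `V_e[1]` = rep(ve, n_draw))
    structure(list(draws = coda::mcmc.list(coda::mcmc(mat)),
                   species_levels = "1"),
              class = c("iv_fit_imperfect", "iv_fit"))
  }
  grid <- c(0.5, 1, 2)
  env0 <- predictive_envelope(make_fit(0, 0), grid)
  expect_equal(env0$lower, env0$mean, tolerance = 1e-7)
  expect_equal(env0$upper, env0$mean, tolerance = 1e-7)
  env1 <- predictive_envelope(make_fit(0.3, 0.1), grid)
  env2 <- predictive_envelope(make_fit(0.6, 0.1), grid)
  expect_true(all(env2$upper - env2$lower > env1$upper - env1$lower))
  expect_error(predictive_envelope(make_fit(0.1, 0.1), numeric(0)), "empty")
  # coverage: ~95% of freshly simulated individuals fall inside the band
  set.seed(13)
  vu <- 0.4; ve <- 0.2
  envc <- predictive_envelope(make_fit(vu, ve), 1)  # ln x1 = 0
  y_new <- 0.5 + rnorm(4000, 0, sqrt(vu)) + rnorm(4000, 0, sqrt(ve))
  cover <- mean(y_new >= envc$lower & y_new <= envc$upper)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("tidy and glance expose posterior summaries and diagnostics", {
  set.seed(14)
  dat <- tibble::tibble(
    i = rep(1:40, each = 2), j = rep(1:2, each = 40),
    X1 = exp(rnorm(80)), Y = exp(rnorm(80))
  )
  fit <- fit_imperfect_model(dat, test_config(14))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high")
                  %in% names(td)))
  expect_false(any(grepl("^u\\[", td$term)))
  expect_true(any(grepl("^u\\[", tidy(fit, individuals = TRUE)$term)))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 80)
  expect_equal(gl$n_chains, 2)
  expect_true(is.logical(gl$converged))
})
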