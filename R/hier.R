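#' MCMC configuration for the hierarchical growth models
#'
#' Defaults follow the study design the models were built for: 4 chains of
#' 10,000 iterations with a 5,000-step warm-up and thinning of one fifth
#' (1,000 retained draws per chain), Normal(0, 1) priors on mean parameters
#' and half-Student-t(3, 0, 2.5) priors on standard-deviation parameters.
#' `test_mode = TRUE` switches to 2 chains x 2,000 iterations (1,000
#' warm-up, thin 2) with the same priors, for quick runs.
#'
#' @param n_chains,n_iter,n_warmup,thin MCMC schedule; `n_warmup < n_iter`.
#' @param seed integer seed; chain c uses RNG seed `seed + c`.
#' @param prior_mean_sd sd of the normal prior on mean parameters.
#' @param prior_var_df,prior_var_scale degrees of freedom and scale of the
#'   half-Student-t prior on sd parameters.
#' @param test_mode shortcut applying the reduced schedule above.
#' @return a list of class `iv_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 10000L, n_warmup = 5000L,
                        thin = 5L, seed = 1L, prior_mean_sd = 1,
                        prior_var_df = 3L, prior_var_scale = 2.5,
                        test_mode = FALSE) {
  if (isTRUE(test_mode)) {
    n_chains <- 2L; n_iter <- 2000L; n_warmup <- 1000L; thin <- 2L
  }
  n_chains <- check_count(n_chains, "n_chains")
  n_iter <- check_count(n_iter, "n_iter")
  n_warmup <- check_count(n_warmup, "n_warmup", min = 0L)
  thin <- check_count(thin, "thin")
  abort_if(n_warmup >= n_iter, "`n_warmup` must be below `n_iter`")
  structure(
    list(n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup,
         thin = thin, seed = as.integer(seed),
         prior_mean_sd = check_positive(prior_mean_sd, "prior_mean_sd"),
         prior_var_df = check_count(prior_var_df, "prior_var_df"),
         prior_var_scale = check_positive(prior_var_scale, "prior_var_scale")),
    class = "iv_mcmc_config"
  )
}

# Run a JAGS model and return the retained draws as a coda::mcmc.list.
run_jags <- function(model_string, data, monitor, config) {
  inits <- lapply(seq_len(config$n_chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed + c)
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = config$n_chains,
                          n.adapt = max(500L, config$n_warmup %/% 5L),
                          quiet = TRUE)
  update(jm, config$n_warmup, progress.bar = "none")
  rjags::coda.samples(jm, monitor,
                      n.iter = config$n_iter - config$n_warmup,
                      thin = config$thin, progress.bar = "none")
}

# Posterior summary tibble (mean and sd = "estimation error") per parameter.
summarize_draws <- function(draws) {
  mat <- as.matrix(draws)
  tibble::tibble(
    term = colnames(mat),
    estimate = unname(colMeans(mat)),
    std_error = unname(apply(mat, 2, sd))
  )
}

new_iv_fit <- function(subclass, draws, summary, config, extra = list()) {
  structure(
    c(list(draws = draws, summary = summary, config = config), extra),
    class = c(subclass, "iv_fit")
  )
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("<%s> %d chains x %d retained draws, %d parameters\n",
              class(x)[1L], length(x$draws), nrow(as.matrix(x$draws[[1L]])),
              ncol(as.matrix(x$draws[[1L]]))))
  main <- x$summary[!grepl("^u\\[", x$summary$term), ]
  print(as.data.frame(main), row.names = FALSE, digits = 3)
  invisible(x)
}

jags_prior_lines <- function(config) {
  sprintf(
    "  tau_mean <- 1 / %g\n  pr_tau <- 1 / %g\n  pr_df <- %d",
    config$prior_mean_sd^2, config$prior_var_scale^2, config$prior_var_df
  )
}

#' Fit the "imperfect knowledge" hierarchical model
#'
#' The statistical model an ecologist fits when only part of the environment
#' is observed: for individual `i` of species `j` at date `t`,
#' \deqn{\ln Y_{ijt} = \beta'_{0,j} + b_{0,i} + \beta'_{1,j} \ln X_{1,ijt}
#'       + \varepsilon_{ijt}, \quad \varepsilon_{ijt} \sim N(0, V_j),
#'       \quad b_{0,i} \sim N(0, V_{b_j}).}
#' The species-specific individual-effect variance \eqn{V_{b_j}} is the
#' model's estimate of intraspecific variability; the unobserved
#' environmental dimensions are absorbed into \eqn{b_{0,i}} and
#' \eqn{\varepsilon}. Additional observed covariates can be supplied via
#' `covariates` (each gets a species-specific linear coefficient, covariate
#' `"X1"` entering as `ln X1`), which turns the model into its
#' perfect-knowledge limit when all dimensions are included.
#'
#' @param data tibble with columns `i` (individual), `j` (species), `Y` and
#'   the covariates (at least `X1`); typically a [simulate_attribute()]
#'   result.
#' @param config an [mcmc_config()].
#' @param covariates character vector of covariate columns, default `"X1"`.
#' @return an `iv_fit_imperfect` object: posterior `draws`
#'   (coda `mcmc.list` over `b0[j]`, `b1[j]`, extra coefficients `Bx[j,n]`,
#'   `V_u[j]` = \eqn{V_{b_j}}, `V_e[j]` = \eqn{V_j}, `sd_u[j]`, `sd_e[j]`,
#'   individual effects `u[i]`), a `summary` tibble, species/individual
#'   level tables and the config.
#' @export
fit_imperfect_model <- function(data, config = mcmc_config(),
                                covariates = "X1") {
  abort_if(!all(c("i", "j", "Y") %in% names(data)),
           "`data` needs columns i, j, Y")
  abort_if(!"X1" %in% covariates, "`covariates` must include X1")
  abort_if(!all(covariates %in% names(data)),
           "missing covariate columns in `data`")
  abort_if(any(data$Y <= 0), "Y must be strictly positive")
  abort_if(any(data$X1 <= 0), "X1 must be strictly positive")
  sp <- factor(data$j)
  ind <- factor(data$i)
  J <- nlevels(sp)
  I <- nlevels(ind)
  spi <- as.integer(sp[match(levels(ind), ind)])
  extra <- setdiff(covariates, "X1")
  P <- length(extra)
  Xmat <- if (P > 0) as.matrix(data[, extra, drop = FALSE]) else NULL

  model <- paste0("model {\n", jags_prior_lines(config), "\n",
    "  for (k in 1:K) {\n",
    "    mu[k] <- b0[sp[k]] + b1[sp[k]] * lx1[k] + u[ind[k]]",
    if (P > 0) " + inprod(Bx[sp[k], ], X[k, ])" else "", "\n",
    "    y[k] ~ dnorm(mu[k], tau_e[sp[k]])\n",
    "  }\n",
    "  for (i in 1:I) { u[i] ~ dnorm(0, tau_u[spi[i]]) }\n",
    "  for (j in 1:J) {\n",
    "    b0[j] ~ dnorm(0, tau_mean)\n",
    "    b1[j] ~ dnorm(0, tau_mean)\n",
    if (P > 0) "    for (p in 1:P) { Bx[j, p] ~ dnorm(0, tau_mean) }\n" else "",
    "    sd_u[j] ~ dt(0, pr_tau, pr_df) T(0,)\n",
    "    sd_e[j] ~ dt(0, pr_tau, pr_df) T(0,)\n",
    "    tau_u[j] <- 1 / (sd_u[j]^2)\n",
    "    tau_e[j] <- 1 / (sd_e[j]^2)\n",
    "    V_u[j] <- sd_u[j]^2\n",
    "    V_e[j] <- sd_e[j]^2\n",
    "  }\n}\n")

  jdata <- list(y = log(data$Y), lx1 = log(data$X1),
                sp = as.integer(sp), ind = as.integer(ind), spi = spi,
                K = nrow(data), I = I, J = J)
  monitor <- c("b0", "b1", "sd_u", "sd_e", "V_u", "V_e", "u")
  if (P > 0) {
    jdata$X <- Xmat
    jdata$P <- P
    monitor <- c(monitor, "Bx")
  }
  draws <- run_jags(model, jdata, monitor, config)
  new_iv_fit("iv_fit_imperfect", draws, summarize_draws(draws), config,
             list(species_levels = levels(sp), individual_levels = levels(ind),
                  covariates = covariates, n_obs = nrow(data)))
}

#' Fit the clonal-trial hierarchical growth model
#'
#' Growth model for a replicated clonal trial: with `z` the z-scored
#' `ln(G + 1)` response (G in mm / year) and z-scored `ln D` (diameter) and
#' `ln C` (competition index) covariates,
#' \deqn{z_{it} = \beta_0 + b_{0,b} + b_{0,g} + b_{0,t} + b_{0,i}
#'   + \beta_1 \ln D_{it} + \beta_2 \ln C_{it} + \varepsilon_{it}}
#' with independent normal random intercepts for block (\eqn{V_b}),
#' genotype (\eqn{V_g}), census date (\eqn{V_t}) and individual (\eqn{V_i}),
#' and residual variance \eqn{V}. Comparing \eqn{V_i} with \eqn{V_g}
#' separates micro-environmental from genetic sources of intraspecific
#' variability.
#'
#' @param growth growth tibble with `tree_id`, `block`, `genotype`, `date`,
#'   `G`, `dbh_start`, `comp_index`.
#' @param config an [mcmc_config()].
#' @param growth_shift constant (mm) added to G before the log; default 1.
#' @return an `iv_fit_clonal` object; `scalers` holds the response and
#'   covariate [log_shift_scale()] scalers (truth on the data scale maps to
#'   the fitted scale by dividing variances by `scalers$response$sd^2`).
#' @export
fit_clonal_growth_model <- function(growth, config = mcmc_config(),
                                    growth_shift = 1) {
  need <- c("tree_id", "block", "genotype", "date", "G", "dbh_start", "comp_index")
  miss <- setdiff(need, names(growth))
  abort_if(length(miss) > 0,
           paste0("`growth` is missing column(s): ", paste(miss, collapse = ", ")))
  resp <- log_shift_scale(growth$G, shift = growth_shift)
  ld <- log_shift_scale(growth$dbh_start, shift = 0)
  lc <- log_shift_scale(growth$comp_index, shift = 0)
  fb <- factor(growth$block); fg <- factor(growth$genotype)
  ft <- factor(growth$date); fi <- factor(growth$tree_id)

  model <- paste0("model {\n", jags_prior_lines(config), "\n",
    "  for (k in 1:K) {\n",
    "    mu[k] <- b0 + bb[blk[k]] + bg[gen[k]] + bt[dat[k]] + bi[ind[k]]",
    " + b1 * ld[k] + b2 * lc[k]\n",
    "    y[k] ~ dnorm(mu[k], tau)\n",
    "  }\n",
    "  for (m in 1:B) { bb[m] ~ dnorm(0, tau_b) }\n",
    "  for (m in 1:G) { bg[m] ~ dnorm(0, tau_g) }\n",
    "  for (m in 1:T) { bt[m] ~ dnorm(0, tau_t) }\n",
    "  for (m in 1:I) { bi[m] ~ dnorm(0, tau_i) }\n",
    "  b0 ~ dnorm(0, tau_mean)\n  b1 ~ dnorm(0, tau_mean)\n",
    "  b2 ~ dnorm(0, tau_mean)\n",
    "  sd_b ~ dt(0, pr_tau, pr_df) T(0,)\n  sd_g ~ dt(0, pr_tau, pr_df) T(0,)\n",
    "  sd_t ~ dt(0, pr_tau, pr_df) T(0,)\n  sd_i ~ dt(0, pr_tau, pr_df) T(0,)\n",
    "  sd_e ~ dt(0, pr_tau, pr_df) T(0,)\n",
    "  tau_b <- 1/(sd_b^2)\n  tau_g <- 1/(sd_g^2)\n  tau_t <- 1/(sd_t^2)\n",
    "  tau_i <- 1/(sd_i^2)\n  tau <- 1/(sd_e^2)\n",
    "  V_b <- sd_b^2\n  V_g <- sd_g^2\n  V_t <- sd_t^2\n  V_i <- sd_i^2\n",
    "  V <- sd_e^2\n}\n")

  jdata <- list(y = resp$values, ld = ld$values, lc = lc$values,
                blk = as.integer(fb), gen = as.integer(fg),
                dat = as.integer(ft), ind = as.integer(fi),
                K = nrow(growth), B = nlevels(fb), G = nlevels(fg),
                T = nlevels(ft), I = nlevels(fi))
  monitor <- c("b0", "b1", "b2", "V_b", "V_g", "V_t", "V_i", "V",
               "sd_b", "sd_g", "sd_t", "sd_i", "sd_e")
  draws <- run_jags(model, jdata, monitor, config)
  new_iv_fit("iv_fit_clonal", draws, summarize_draws(draws), config,
             list(scalers = list(response = resp$scaler, ln_d = ld$scaler,
                                 ln_c = lc$scaler),
                  n_obs = nrow(growth), n_individuals = nlevels(fi)))
}

#' Fit the forest-inventory hierarchical growth model
#'
#' Multi-species growth model separating inter- from intraspecific
#' variability: with `z` the z-scored `ln(G + 2)` response and z-scored
#' `ln D` covariate,
#' \deqn{z_{ijt} = \beta_0 + b_{0,j} + b_{0,i} + \beta_1 \ln D_{ijt}
#'   + \varepsilon_{ijt}}
#' with species random intercepts \eqn{b_{0,j} \sim N(0, V_{b_j})},
#' individual random intercepts \eqn{b_{0,i} \sim N(0, V_{b_i})} and
#' residual variance \eqn{V}. \eqn{V_{b_i}} quantifies observed
#' intraspecific variability; \eqn{V_{b_j}} interspecific variability.
#'
#' @param growth growth tibble with `tree_id`, `species`, `G`, `dbh_start`.
#' @param config an [mcmc_config()].
#' @param growth_shift constant (mm) added to G before the log; default 2.
#' @return an `iv_fit_forest` object (draws over `b0`, `b1`, `V_bj`,
#'   `V_bi`, `V` and the sds), with `scalers` as in
#'   [fit_clonal_growth_model()].
#' @export
fit_forest_growth_model <- function(growth, config = mcmc_config(),
                                    growth_shift = 2) {
  need <- c("tree_id", "species", "G", "dbh_start")
  miss <- setdiff(need, names(growth))
  abort_if(length(miss) > 0,
           paste0("`growth` is missing column(s): ", paste(miss, collapse = ", ")))
  fj <- factor(growth$species)
  abort_if(nlevels(fj) < 2L,
           "need at least 2 species: the species variance is unidentifiable with one")
  n_ind <- tapply(growth$tree_id, fj, function(id) length(unique(id)))
  if (any(n_ind < 2L)) {
    warning(sum(n_ind < 2L),
            " species with a single individual; upstream filtering usually removes these",
            call. = FALSE)
  }
  resp <- log_shift_scale(growth$G, shift = growth_shift)
  ld <- log_shift_scale(growth$dbh_start, shift = 0)
  fi <- factor(growth$tree_id)

  model <- paste0("model {\n", jags_prior_lines(config), "\n",
    "  for (k in 1:K) {\n",
    "    mu[k] <- b0 + bj[spp[k]] + bi[ind[k]] + b1 * ld[k]\n",
    "    y[k] ~ dnorm(mu[k], tau)\n",
    "  }\n",
    "  for (m in 1:J) { bj[m] ~ dnorm(0, tau_j) }\n",
    "  for (m in 1:I) { bi[m] ~ dnorm(0, tau_i) }\n",
    "  b0 ~ dnorm(0, tau_mean)\n  b1 ~ dnorm(0, tau_mean)\n",
    "  sd_j ~ dt(0, pr_tau, pr_df) T(0,)\n  sd_i ~ dt(0, pr_tau, pr_df) T(0,)\n",
    "  sd_e ~ dt(0, pr_tau, pr_df) T(0,)\n",
    "  tau_j <- 1/(sd_j^2)\n  tau_i <- 1/(sd_i^2)\n  tau <- 1/(sd_e^2)\n",
    "  V_bj <- sd_j^2\n  V_bi <- sd_i^2\n  V <- sd_e^2\n}\n")

  jdata <- list(y = resp$values, ld = ld$values,
                spp = as.integer(fj), ind = as.integer(fi),
                K = nrow(growth), J = nlevels(fj), I = nlevels(fi))
  monitor <- c("b0", "b1", "V_bj", "V_bi", "V", "sd_j", "sd_i", "sd_e")
  draws <- run_jags(model, jdata, monitor, config)
  new_iv_fit("iv_fit_forest", draws, summarize_draws(draws), config,
             list(scalers = list(response = resp$scaler, ln_d = ld$scaler),
                  species_levels = levels(fj),
                  n_obs = nrow(growth), n_individuals = nlevels(fi)))
}

#' Posterior-mean variance components of a fitted model
#'
#' @param fit an `iv_fit` object.
#' @return named numeric vector of the posterior means of the model's
#'   variance parameters (terms starting `V`), ready for
#'   [partition_variance()].
#' @export
variance_components <- function(fit) {
  abort_if(!inherits(fit, "iv_fit"), "`fit` must be an iv_fit")
  s <- fit$summary[grepl("^V", fit$summary$term), ]
  setNames(s$estimate, s$term)
}

#' Partition variance among named components
#'
#' Expresses each variance component as a percentage of the sum of all
#' supplied components,
#' `percentage_k = 100 * component_k / sum(components)` — the partitioning
#' of a model's unexplained variance among its random effects and residual.
#'
#' @param components named nonnegative numeric vector (or named list), at
#'   least one component, sum > 0.
#' @return a tibble of class `iv_variance_partition`: `component`,
#'   `variance`, `percentage` (full precision; print rounds to 2 decimals).
#' @examples
#' partition_variance(c(V_i = 0.23, V_b = 0.06, V_g = 0.13, V_t = 1.3, V = 0.51))
#' @export
partition_variance <- function(components) {
  components <- unlist(components)
  abort_if(length(components) < 1L, "need at least one component")
  abort_if(is.null(names(components)) || any(!nzchar(names(components))),
           "components must be named")
  abort_if(any(!is.finite(components)) || any(components < 0),
           "components must be finite and nonnegative")
  total <- sum(components)
  abort_if(total == 0, "all components are zero: partition undefined")
  out <- tibble::tibble(
    component = names(components),
    variance = as.numeric(components),
    percentage = 100 * as.numeric(components) / total
  )
  class(out) <- c("iv_variance_partition", class(out))
  out
}

#' @export
print.iv_variance_partition <- function(x, ...) {
  df <- as.data.frame(x)
  df$percentage <- sprintf("%.2f%%", df$percentage)
  print(df, row.names = FALSE)
  invisible(x)
}

# Split-R-hat (each chain split in half) for one parameter given an
# iterations x chains matrix of draws.
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) return(ifelse(B == 0, 1, Inf))
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence diagnostics for a fitted model
#'
#' Split-R-hat (each chain halved) and effective sample size per monitored
#' parameter; the fit passes when every R-hat is at most `rhat_max` and
#' every ESS at least `ess_min`. Parameters with (near-)constant draws get
#' an infinite R-hat / zero ESS and fail, rather than passing silently.
#'
#' @param fit an `iv_fit` (or a bare `coda::mcmc.list`).
#' @param rhat_max maximum acceptable split-R-hat (default 1.05).
#' @param ess_min minimum acceptable effective sample size (default 400).
#' @return list of class `iv_convergence`: `table` (tibble `term`, `rhat`,
#'   `ess`) and `pass` (logical).
#' @export
check_convergence <- function(fit, rhat_max = 1.05, ess_min = 400) {
  draws <- if (inherits(fit, "iv_fit")) fit$draws else fit
  abort_if(!inherits(draws, "mcmc.list"), "no mcmc.list draws found")
  abort_if(length(draws) < 2L, "need at least 2 chains to assess convergence")
  mats <- lapply(draws, as.matrix)
  terms <- colnames(mats[[1L]])
  rhat <- vapply(seq_along(terms), function(p) {
    split_rhat(vapply(mats, function(m) m[, p], numeric(nrow(mats[[1L]]))))
  }, 0)
  ess_raw <- coda::effectiveSize(draws)
  const <- vapply(seq_along(terms), function(p) {
    all(vapply(mats, function(m) var(m[, p]) == 0, TRUE))
  }, TRUE)
  ess <- as.numeric(ess_raw[terms])
  ess[const] <- 0
  tab <- tibble::tibble(term = terms, rhat = rhat, ess = ess)
  structure(
    list(table = tab,
         pass = all(tab$rhat <= rhat_max) && all(tab$ess >= ess_min),
         rhat_max = rhat_max, ess_min = ess_min),
    class = "iv_convergence"
  )
}

#' @export
print.iv_convergence <- function(x, ...) {
  cat(sprintf("<iv_convergence> %s (R-hat <= %.2f, ESS >= %d)\n",
              if (x$pass) "PASS" else "FAIL", x$rhat_max, round(x$ess_min)))
  cat(sprintf("  max R-hat %.3f, min ESS %.0f over %d parameters\n",
              max(x$table$rhat), min(x$table$ess), nrow(x$table)))
  invisible(x)
}

# Quantile of a mixture of normals (one component per posterior draw),
# by root-finding on the mixture CDF. Degenerate sd = 0 components are
# point masses.
mixture_quantile <- function(mu, s, p) {
  cdf <- function(q) mean(ifelse(s > 0, pnorm(q, mu, s), as.numeric(q >= mu)))
  lo <- min(mu - 10 * max(s, 0) - 1e-12)
  hi <- max(mu + 10 * max(s, 0) + 1e-12)
  if (cdf(lo) >= p) return(lo)
  if (cdf(hi) <= p) return(hi)
  stats::uniroot(function(q) cdf(q) - p, c(lo, hi), tol = 1e-9)$root
}

#' Posterior predictive envelope of the imperfect-knowledge model
#'
#' Per-species mean curve and credible band of `ln Y` against `X1`,
#' marginalised over individuals: each posterior draw contributes a normal
#' predictive component with mean \eqn{\beta'_{0,j} + \beta'_{1,j} \ln x_1}
#' and variance \eqn{V_{b_j} + V_j} (a new individual carries a fresh
#' individual effect and a fresh residual), and the band is the
#' `level`-quantile envelope of that posterior mixture. The band therefore
#' visualises the intraspecific variability the model attributes to
#' unobserved environmental dimensions, and widens monotonically with
#' \eqn{V_{b_j}}.
#'
#' @param fit an `iv_fit_imperfect`.
#' @param x1_grid strictly positive grid of `X1` values.
#' @param level credible level (default 0.95).
#' @return tibble: `species`, `x1`, `mean` (posterior mean of the mean
#'   curve, on the `ln Y` scale), `lower`, `upper`.
#' @export
predictive_envelope <- function(fit, x1_grid, level = 0.95) {
  abort_if(!inherits(fit, "iv_fit_imperfect"),
           "`fit` must come from fit_imperfect_model()")
  abort_if(length(x1_grid) == 0L, "`x1_grid` is empty")
  abort_if(any(x1_grid <= 0), "`x1_grid` must be strictly positive")
  mat <- as.matrix(fit$draws)
  a <- (1 - level) / 2
  out <- lapply(seq_along(fit$species_levels), function(j) {
    b0 <- mat[, sprintf("b0[%d]", j)]
    b1 <- mat[, sprintf("b1[%d]", j)]
    s <- sqrt(mat[, sprintf("V_u[%d]", j)] + mat[, sprintf("V_e[%d]", j)])
    lx <- log(x1_grid)
    tibble::tibble(
      species = fit$species_levels[j],
      x1 = x1_grid,
      mean = vapply(lx, function(l) mean(b0 + b1 * l), 0),
      lower = vapply(lx, function(l) mixture_quantile(b0 + b1 * l, s, a), 0),
      upper = vapply(lx, function(l) mixture_quantile(b0 + b1 * l, s, 1 - a), 0)
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("iv_envelope", class(out))
  out
}
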