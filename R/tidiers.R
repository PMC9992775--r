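#' Tidy a fitted hierarchical growth model
#'
#' One row per monitored parameter with posterior mean (`estimate`) and
#' posterior sd (`std.error`, the "estimation error"), plus 95% quantile
#' bounds. Per-individual effects (`u[...]`, `bi[...]`) are excluded unless
#' `individuals = TRUE`.
#'
#' @param x an `iv_fit`.
#' @param individuals include per-individual random effects.
#' @param conf_level credible-interval level (default 0.95).
#' @param ... unused.
#' @return a tibble: `term`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.iv_fit <- function(x, individuals = FALSE, conf_level = 0.95, ...) {
  mat <- as.matrix(x$draws)
  a <- (1 - conf_level) / 2
  keep <- colnames(mat)
  if (!individuals) keep <- keep[!grepl("^(u|bi)\\[", keep)]
  q <- apply(mat[, keep, drop = FALSE], 2, quantile, probs = c(a, 1 - a))
  tibble::tibble(
    term = keep,
    estimate = unname(colMeans(mat[, keep, drop = FALSE])),
    std.error = unname(apply(mat[, keep, drop = FALSE], 2, sd)),
    conf.low = unname(q[1L, ]),
    conf.high = unname(q[2L, ])
  )
}

#' Glance at a fitted hierarchical growth model
#'
#' @param x an `iv_fit`.
#' @param ... unused.
#' @return a one-row tibble: `n_obs`, `n_chains`, `n_draws` (retained, all
#'   chains), `max_rhat`, `min_ess`, `converged` (at the default 1.05 / 400
#'   thresholds).
#' @export
glance.iv_fit <- function(x, ...) {
  conv <- check_convergence(x)
  tibble::tibble(
    n_obs = x$n_obs %||% NA_integer_,
    n_chains = length(x$draws),
    n_draws = length(x$draws) * nrow(as.matrix(x$draws[[1L]])),
    max_rhat = max(conv$table$rhat),
    min_ess = min(conv$table$ess),
    converged = conv$pass
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
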