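#' Simulate a stationary Gaussian random field on a square grid
#'
#' Draws one realisation of a zero-mean, unit-variance Gaussian random field
#' with isotropic exponential covariance \eqn{\rho(h) = \exp(-h / range)} on a
#' `C` x `C` grid of unit cells, using circulant embedding of the covariance
#' on a torus at least twice the grid side and FFT sampling. Negative
#' embedding eigenvalues (possible for the exponential model at short ranges)
#' are clipped to zero, a standard approximation that leaves the marginal
#' variance within a fraction of a percent of 1.
#'
#' Uses the current RNG state; seed via [set.seed()] or the callers' `seed`
#' arguments.
#'
#' @param C grid side (cells).
#' @param range correlation range in cell units; as `range -> 0` the field
#'   degenerates to i.i.d. standard normal noise.
#' @return a `C` x `C` numeric matrix (rows = grid rows).
#' @export
gaussian_random_field <- function(C, range) {
  C <- check_count(C, "C", min = 2L)
  range <- check_positive(range, "range")
  M <- 2L^ceiling(log2(2L * C))
  # wrapped (toroidal) lag along one axis: 0, 1, ..., M/2, ..., 1
  lag <- pmin(0:(M - 1L), M - (0:(M - 1L)))
  h <- sqrt(outer(lag^2, lag^2, "+"))
  S <- exp(-h / range)
  lambda <- Re(fft(S))
  lambda[lambda < 0] <- 0
  Z <- matrix(rnorm(M * M), M, M) + 1i * matrix(rnorm(M * M), M, M)
  F <- fft(sqrt(lambda) * Z) / M
  Re(F)[seq_len(C), seq_len(C)]
}

#' Generate a multi-dimensional virtual environmental landscape
#'
#' Builds `N` mutually independent spatially autocorrelated environmental
#' layers on a `C` x `C` grid, replicated over `T_dates` dates. Layers whose
#' index is in `dynamic_dims` are regenerated independently at every date;
#' all others are held fixed (bit-identical) across dates. Layer 1 plays the
#' role of the single environmental variable assumed observable in the field
#' (e.g. light); because the attribute model takes its logarithm, layer 1 is
#' the exponential of its Gaussian field (lognormal, strictly positive),
#' while layers 2..N stay Gaussian.
#'
#' @param C grid side (cells per side), >= 2.
#' @param N number of environmental dimensions, >= 1.
#' @param T_dates number of dates, >= 1.
#' @param autocorr_range correlation range of every layer, in cell units.
#' @param dynamic_dims integer vector of layer indices regenerated between
#'   dates; default `2:N` (layer 1 static). Including 1 is allowed but
#'   flagged with a message, since layer 1 is the "observed" covariate.
#' @param seed integer seed; identical seeds give bit-identical landscapes.
#' @return an object of class `iv_landscape`: a list with `fields` (numeric
#'   array `C` x `C` x `N` x `T_dates`), and the generating parameters.
#' @examples
#' land <- generate_environment(C = 40, N = 3, T_dates = 2,
#'                              autocorr_range = 8, seed = 1)
#' dim(land$fields)
#' @export
generate_environment <- function(C, N, T_dates, autocorr_range,
                                 dynamic_dims = NULL, seed = 1L) {
  C <- check_count(C, "C", min = 2L)
  N <- check_count(N, "N")
  T_dates <- check_count(T_dates, "T_dates")
  autocorr_range <- check_positive(autocorr_range, "autocorr_range")
  if (is.null(dynamic_dims)) dynamic_dims <- if (N >= 2L) 2L:N else integer(0)
  dynamic_dims <- as.integer(dynamic_dims)
  abort_if(length(dynamic_dims) > 0 && any(dynamic_dims < 1L | dynamic_dims > N),
           "`dynamic_dims` must be layer indices in 1..N")
  if (1L %in% dynamic_dims) {
    message("layer 1 (the observed covariate X1) is dynamic; ",
            "its values will change between dates")
  }
  set.seed(as.integer(seed))
  fields <- array(NA_real_, dim = c(C, C, N, T_dates))
  for (n in seq_len(N)) {
    for (t in seq_len(T_dates)) {
      if (t == 1L || n %in% dynamic_dims) {
        layer <- gaussian_random_field(C, autocorr_range)
        fields[, , n, t] <- if (n == 1L) exp(layer) else layer
      } else {
        fields[, , n, t] <- fields[, , n, 1L]
      }
    }
  }
  structure(
    list(fields = fields, C = C, N = N, T_dates = T_dates,
         autocorr_range = autocorr_range, dynamic_dims = dynamic_dims,
         seed = as.integer(seed)),
    class = "iv_landscape"
  )
}

#' @export
print.iv_landscape <- function(x, ...) {
  cat(sprintf(
    "<iv_landscape> %d x %d grid, %d dimensions, %d date(s), range %.1f cells\n",
    x$C, x$C, x$N, x$T_dates, x$autocorr_range))
  cat(sprintf("  dynamic dimensions: %s\n",
              if (length(x$dynamic_dims)) paste(x$dynamic_dims, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Tidy a landscape into a long tibble
#'
#' One row per (cell, dimension, date), with the cell-centre coordinates used
#' throughout the package (0-based cells; centre of cell `(r, c)` is
#' `(c + 0.5, r + 0.5)` in cell units).
#'
#' @param x an `iv_landscape`.
#' @param ... unused.
#' @return a tibble with columns `row`, `col`, `x`, `y`, `dim`, `t`, `value`.
#' @export
as_tibble.iv_landscape <- function(x, ...) {
  grid <- tidyr::expand_grid(t = seq_len(x$T_dates), dim = seq_len(x$N),
                             col = seq_len(x$C), row = seq_len(x$C))
  grid$value <- as.vector(x$fields)
  dplyr::mutate(grid,
                x = .data$col - 0.5, y = .data$row - 0.5,
                .after = "col")[, c("row", "col", "x", "y", "dim", "t", "value")]
}

#' Place individuals of several species uniformly on the grid
#'
#' Individuals are assigned to cells uniformly at random and keep their cell
#' across all dates (sessile organisms). Several individuals may share a cell.
#'
#' @param I individuals per species.
#' @param J number of species.
#' @param C grid side (cells).
#' @param seed integer seed.
#' @return a tibble (`I * J` rows) with columns `i` (individual id, unique),
#'   `j` (species id), `row`, `col` (1-based cell indices), `x`, `y`
#'   (cell-centre coordinates, cell units).
#' @export
place_individuals <- function(I, J, C, seed = 1L) {
  I <- check_count(I, "I")
  J <- check_count(J, "J")
  C <- check_count(C, "C")
  set.seed(as.integer(seed))
  n <- I * J
  tibble::tibble(
    i = seq_len(n),
    j = rep(seq_len(J), each = I),
    row = sample.int(C, n, replace = TRUE),
    col = sample.int(C, n, replace = TRUE)
  ) |>
    dplyr::mutate(x = .data$col - 0.5, y = .data$row - 0.5)
}

#' Draw species-specific response coefficients
#'
#' Each species receives a coefficient vector
#' \eqn{\beta_j = (\beta_{0,j}, \ldots, \beta_{N,j})} of length `N + 1`,
#' drawn i.i.d. Normal(0, `coef_scale`^2). Conspecific individuals share
#' \eqn{\beta_j} exactly; species differ. Draws are repeated until no two
#' species vectors coincide (an event of probability zero for
#' `coef_scale > 0`; the check guards degenerate inputs).
#'
#' @param J number of species.
#' @param N number of environmental dimensions (slopes per species).
#' @param coef_scale standard deviation of the coefficient distribution;
#'   must be > 0 (a zero scale would make all species identical). The
#'   default 0.3 keeps `Var(ln Y)` near 1 for `N = 10` unit-variance
#'   layers, a realistic growth-like spread (about one order of magnitude
#'   across individuals).
#' @param seed integer seed.
#' @return an object of class `iv_responses`: list with `beta` (J x (N+1)
#'   matrix, column 1 the intercept), `J`, `N`, `coef_scale`, `seed`.
#' @export
draw_species_responses <- function(J, N, coef_scale = 0.3, seed = 1L) {
  J <- check_count(J, "J")
  N <- check_count(N, "N")
  coef_scale <- check_positive(coef_scale, "coef_scale")
  set.seed(as.integer(seed))
  repeat {
    beta <- matrix(rnorm(J * (N + 1L), sd = coef_scale), nrow = J)
    if (J == 1L || !any(duplicated(beta))) break
  }
  colnames(beta) <- c("beta0", paste0("beta", seq_len(N)))
  structure(list(beta = beta, J = J, N = N, coef_scale = coef_scale,
                 seed = as.integer(seed)),
            class = "iv_responses")
}

#' @export
print.iv_responses <- function(x, ...) {
  cat(sprintf("<iv_responses> %d species x %d coefficients (scale %.2f)\n",
              x$J, x$N + 1L, x$coef_scale))
  print(round(x$beta, 3))
  invisible(x)
}

#' Compute the deterministic individual attribute on the landscape
#'
#' The "perfect knowledge" response model: for individual `i` of species `j`
#' at date `t`,
#' \deqn{\ln Y_{ijt} = \beta_{0,j} + \beta_{1,j} \ln X_{1,ijt} +
#'       \beta_{2,j} X_{2,ijt} + \ldots + \beta_{N,j} X_{N,ijt}}
#' with covariates read off the individual's grid cell at date `t`. There is
#' no noise term: conspecific individuals differ in `Y` only through the
#' environment they experience.
#'
#' @param landscape an [generate_environment()] result.
#' @param placements a [place_individuals()] table.
#' @param responses a [draw_species_responses()] set; its `N` must match the
#'   landscape's.
#' @return a tibble, one row per (individual, date): columns `i`, `j`, `t`,
#'   `x`, `y`, `Y`, `X1` .. `XN`.
#' @export
simulate_attribute <- function(landscape, placements, responses) {
  abort_if(!inherits(landscape, "iv_landscape"), "`landscape` must be an iv_landscape")
  abort_if(!inherits(responses, "iv_responses"), "`responses` must be an iv_responses")
  abort_if(landscape$N != responses$N,
           "landscape and responses disagree on the number of dimensions N")
  abort_if(max(placements$j) > responses$J,
           "placements reference species beyond the response set")
  N <- landscape$N
  C <- landscape$C
  xnames <- paste0("X", seq_len(N))
  out <- tidyr::expand_grid(placements, t = seq_len(landscape$T_dates))
  cell <- cbind(out$row, out$col)
  covar <- matrix(NA_real_, nrow = nrow(out), ncol = N,
                  dimnames = list(NULL, xnames))
  for (t in seq_len(landscape$T_dates)) {
    sel <- out$t == t
    for (n in seq_len(N)) {
      layer <- landscape$fields[, , n, t]
      covar[sel, n] <- layer[cell[sel, , drop = FALSE]]
    }
  }
  abort_if(any(covar[, 1L] <= 0),
           "X1 must be strictly positive at every occupied cell")
  beta <- responses$beta
  design <- cbind(1, log(covar[, 1L]), covar[, -1L, drop = FALSE])
  lnY <- rowSums(design * beta[out$j, , drop = FALSE])
  dplyr::bind_cols(
    out[, c("i", "j", "t", "x", "y")],
    tibble::tibble(Y = exp(lnY)),
    tibble::as_tibble(covar)
  )
}
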