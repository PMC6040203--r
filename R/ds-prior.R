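#' DS(G, m) prior
#'
#' A conjugate prior \eqn{g(\theta;\alpha,\beta)} multiplied by an m-term
#' orthogonal-series correction in the rank-polynomial basis:
#' \deqn{\pi(\theta) = g(\theta)\,\bigl[1 + \sum_{j=1}^m c_j T_j(\theta; G)\bigr].}
#' Because every \eqn{T_j}, \eqn{j \ge 1}, integrates to zero against
#' \eqn{G}, the density integrates to one for any coefficient vector
#' (possibly after truncating negative regions, see [ds_sample()]).
#' \code{m = 0} (empty \code{coef}) recovers the pure conjugate prior.
#'
#' @param family A [conjugate_family()] object (the anchor \eqn{G}).
#' @param coef Numeric vector of LP-Fourier coefficients \eqn{c_1, ..., c_m}.
#' @return An object of class \code{"ds_prior"}.
#' @examples
#' fam <- conjugate_family("binomial", alpha = 2.3, beta = 14.08)
#' pr <- ds_prior(fam, c(0, 0, -0.5))
#' qlp(pr)
#' @export
ds_prior <- function(family, coef = numeric(0)) {
  stopifnot(inherits(family, "conj_family"))
  coef <- as.numeric(coef)
  if (any(!is.finite(coef))) stop("coefficients must be finite")
  structure(list(family = family, coef = coef, m = length(coef)),
            class = "ds_prior")
}

#' @export
print.ds_prior <- function(x, ...) {
  print(x$family)
  if (x$m == 0 || all(x$coef == 0)) {
    cat("DS correction: none (pure conjugate prior, m = 0)\n")
  } else {
    nz <- which(x$coef != 0)
    cat("DS correction: ",
        paste(sprintf("%+.4f T%d", x$coef[nz], nz), collapse = " "), "\n", sep = "")
    cat("qLP =", signif(qlp(x), 4), "\n")
  }
  invisible(x)
}

#' DS prior density
#'
#' Evaluates \eqn{\pi(\theta) = g(\theta)(1 + \sum_j c_j T_j(\theta;G))}.
#' The bracket can dip below zero for aggressive coefficients; the signed
#' value is returned and a warning is raised so diagnostics stay faithful to
#' the series representation (sampling and entropy calculations truncate at
#' zero instead).
#'
#' @param theta Evaluation points in the support.
#' @param prior A [ds_prior()] object.
#' @param warn Warn when the density is negative somewhere on the grid.
#' @return Density values (possibly signed).
#' @export
ds_density <- function(theta, prior, warn = TRUE) {
  stopifnot(inherits(prior, "ds_prior"))
  check_support(prior$family, theta)
  g <- g_density(prior$family, theta)
  d <- u_function(g_cdf(prior$family, theta), prior)
  out <- g * d
  if (warn && any(out < 0, na.rm = TRUE))
    warning("DS density is negative on part of the support; ",
            "interpret as a signed series approximation")
  out
}

#' U-function (comparison density of the prior correction)
#'
#' The prior density ratio on the rank-transform scale,
#' \eqn{d(u) = \pi(G^{-1}(u)) / g(G^{-1}(u)) = 1 + \sum_j c_j \mathrm{Leg}_j(u)}.
#' A flat U-function (\eqn{d \equiv 1}) means the conjugate prior is adequate;
#' departures from flatness localise the prior-data conflict.
#'
#' @param u Points in \eqn{[0,1]} (default: 1001-point diagnostic grid).
#' @param prior A [ds_prior()] object.
#' @return Values of \eqn{d(u)}; with the default grid, a data frame with
#'   columns \code{u} and \code{d}.
#' @export
u_function <- function(u = NULL, prior) {
  stopifnot(inherits(prior, "ds_prior"))
  grid_out <- is.null(u)
  if (grid_out) u <- seq(0, 1, length.out = 1001)
  if (any(u < 0 | u > 1)) stop("'u' must lie in [0, 1]")
  d <- rep(1, length(u))
  if (prior$m > 0) d <- d + as.vector(leg_matrix(u, prior$m) %*% prior$coef)
  if (grid_out) data.frame(u = u, d = d) else d
}

#' qLP prior-uncertainty statistic
#'
#' The sum of squared LP-Fourier coefficients,
#' \eqn{\mathrm{qLP} = \sum_j c_j^2}.  By Parseval's identity
#' \eqn{\int_0^1 d^2(u)\,du = 1 + \mathrm{qLP}}, so qLP measures the
#' departure of the U-function from flatness; for small corrections it is
#' approximately twice the Kullback-Leibler divergence of the corrected
#' prior from the conjugate anchor.
#'
#' @param prior A [ds_prior()] object (or a fitted [ds_fit()] model).
#' @return Non-negative scalar.
#' @export
qlp <- function(prior) {
  if (inherits(prior, "ds_fit")) prior <- prior$prior
  stopifnot(inherits(prior, "ds_prior"))
  sum(prior$coef^2)
}

#' Kullback-Leibler divergence KL(Pi || G)
#'
#' \eqn{\int_0^1 d(u) \log d(u)\, du}, computed by trapezoid quadrature on a
#' fine u-grid; regions where the signed density is non-positive are
#' truncated at a small floor (they carry no probability mass after the
#' sampler's truncation rule).
#'
#' @param prior A [ds_prior()] object.
#' @param grid_size Number of u-grid points.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(prior, grid_size = 10001) {
  stopifnot(inherits(prior, "ds_prior"))
  u <- seq(0, 1, length.out = grid_size)
  d <- u_function(u, prior)
  if (all(d > 0)) {
    return(max(0, trapezoid(u, d * log(d))))
  }
  # truncate and renormalise, consistent with the sampler
  d <- pmax(d, 0)
  z <- trapezoid(u, d)
  if (z <= 0) stop("degenerate prior: correction is non-positive almost everywhere")
  d <- d / z
  pos <- d > 0
  val <- d
  val[pos] <- d[pos] * log(d[pos])
  val[!pos] <- 0
  max(0, trapezoid(u, val))
}

#' Sample from a DS prior
#'
#' Draws are generated on the u-scale: the correction density \eqn{d(u)}
#' (truncated at zero and renormalised if needed) is inverted numerically on
#' a fine grid and the draws are mapped back through \eqn{G^{-1}}.  Since
#' \eqn{\pi(\theta)\,d\theta = d(u)\,du}, this is exact up to grid
#' resolution, and reproducible given a seed.
#'
#' @param prior A [ds_prior()] object.
#' @param k Number of draws (positive integer).
#' @param seed Optional integer seed.
#' @param grid_size Resolution of the inverse-CDF grid.
#' @return Numeric vector of \code{k} draws from \eqn{\pi}.
#' @export
ds_sample <- function(prior, k, seed = NULL, grid_size = 10000) {
  stopifnot(inherits(prior, "ds_prior"))
  if (length(k) != 1L || k <= 0 || k != round(k)) stop("'k' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  u <- seq(0, 1, length.out = grid_size)
  d <- pmax(u_function(u, prior), 0)
  cw <- cumsum((utils::head(d, -1) + utils::tail(d, -1)) / 2 * diff(u))
  cw <- c(0, cw / cw[length(cw)])
  v <- stats::runif(k)
  draws_u <- stats::approx(cw, u, xout = v, ties = "ordered")$y
  g_quantile(prior$family, draws_u)
}

#' Modes of a DS prior density
#'
#' Interior local maxima of \eqn{\pi(\theta)} located by a 2001-point grid
#' scan followed by golden-section refinement, sorted by location.  Boundary
#' maxima are ignored unless no interior mode exists, in which case an empty
#' set is returned with the \code{boundary} flag set (e.g. a U-shaped
#' Jeffreys prior).
#'
#' @param prior A [ds_prior()] object.
#' @param grid_size Scan resolution.
#' @return A data frame with columns \code{location} and \code{density};
#'   attribute \code{boundary} is \code{TRUE} when the only maxima sit on
#'   the support boundary.
#' @export
ds_modes <- function(prior, grid_size = 2001) {
  stopifnot(inherits(prior, "ds_prior"))
  fam <- prior$family
  rng <- switch(fam$family,
    binomial = c(0, 1),
    normal = fam$hyper["mu"] + c(-1, 1) * 6 * sqrt(fam$hyper["tau2"]),
    {  # gamma-type support: cover all but 1e-7 of prior mass
      c(0, g_quantile(fam, 1 - 1e-7))
    })
  eps <- diff(rng) / (grid_size - 1)
  th <- seq(rng[1] + eps / 2, rng[2] - eps / 2, length.out = grid_size)
  dens <- suppressWarnings(ds_density(th, prior, warn = FALSE))
  dens[!is.finite(dens)] <- -Inf
  i <- 2:(grid_size - 1)
  is_peak <- dens[i] > dens[i - 1] & dens[i] >= dens[i + 1]
  idx <- i[is_peak]
  f <- function(x) suppressWarnings(ds_density(x, prior, warn = FALSE))
  locs <- vapply(idx, function(ii) {
    opt <- stats::optimize(f, lower = th[ii - 1], upper = th[ii + 1], maximum = TRUE)
    opt$maximum
  }, numeric(1))
  boundary <- length(locs) == 0L
  out <- data.frame(location = sort(locs),
                    density = f(sort(locs)))
  if (boundary) out <- data.frame(location = numeric(0), density = numeric(0))
  attr(out, "boundary") <- boundary
  out
}

#' Export the U-function grid as delimited text
#'
#' Writes a two-column (u, d) table for external plotting.
#'
#' @param prior A [ds_prior()] object.
#' @param path Output file path.
#' @param grid_size Number of grid points.
#' @export
write_u_function <- function(prior, path, grid_size = 1001) {
  u <- seq(0, 1, length.out = grid_size)
  uf <- data.frame(u = u, d = u_function(u, prior))
  utils::write.csv(uf, path, row.names = FALSE)
  invisible(path)
}
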