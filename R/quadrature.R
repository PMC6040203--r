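# Quadrature rules used across the package.
#
# Two regimes coexist, on purpose:
#  * Gauss-Legendre on (0,1) for the exact posterior-expectation operators
#    (posterior_expect_T and friends) -- the integrands are smooth after the
#    change of variables to the posterior CDF scale, so 64 nodes give
#    near machine accuracy;
#  * fixed equispaced grids for the model-fitting pipeline and the applied
#    posterior summaries.  There the (1/B)-quantile trim at the support
#    endpoints is a deliberate part of the method: it regularises the
#    otherwise unbounded influence of the extreme prior quantiles, and the
#    fitted coefficients are defined relative to it (see the methods
#    vignette).

.quad_env <- new.env(parent = emptyenv())

# Cached Gauss-Legendre nodes/weights on (0, 1).
gauss_nodes <- function(n = 64) {
  key <- paste0("gl", n)
  if (is.null(.quad_env[[key]])) {
    gq <- pracma::gaussLegendre(n, 0, 1)
    .quad_env[[key]] <- list(x = gq$x, w = gq$w)
  }
  .quad_env[[key]]
}

# Equispaced interior grid on (0,1): B points at 1/B .. 1-1/B, weight 1/B each.
trimmed_ugrid <- function(B = 150) {
  seq(1 / B, 1 - 1 / B, length.out = B)
}

# Composite Simpson after linear interpolation onto 2n+1 equispaced points.
# This is the package's integration rule for functions tabulated on a
# non-uniform u-grid (posterior summaries); the resampling step controls the
# effective resolution near integrable spikes and is part of the method's
# defined numerics.
simpson_interp <- function(x, y, n_pts = max(256, length(x))) {
  ap <- stats::approx(x, y, n = 2 * n_pts + 1, ties = list("ordered", mean))
  dx <- ap$x[2] - ap$x[1]
  n <- length(ap$x)
  sum(ap$y[seq(1, n - 2, 2)] + 4 * ap$y[seq(2, n - 1, 2)] + ap$y[seq(3, n, 2)]) * dx / 3
}

# Precomputed weight vector w such that sum(w * y) reproduces
# simpson_interp(x, y) for fixed x: the interpolation and Simpson steps are
# both linear in y.  Duplicated x values (saturated CDF grids) receive the
# averaged weight, matching approx()'s tie handling.
simpson_weights <- function(x, n_pts = max(256, length(x))) {
  grp <- match(x, x)                  # first index of each distinct x
  cnt <- tabulate(grp, nbins = length(x))[grp]
  ux <- x[!duplicated(x)]
  ugrp <- grp[!duplicated(x)]
  tx <- seq(x[1], x[length(x)], length.out = 2 * n_pts + 1)
  dx <- tx[2] - tx[1]
  n <- length(tx)
  simp <- rep(c(2, 4), length.out = n) * dx / 3
  simp[1] <- simp[n] <- dx / 3
  j <- pmin(pmax(findInterval(tx, ux), 1L), length(ux) - 1L)
  lam <- (tx - ux[j]) / (ux[j + 1] - ux[j])
  lam <- pmin(pmax(lam, 0), 1)
  w_first <- numeric(length(x))
  acc_lo <- tapply(simp * (1 - lam), j, sum)
  acc_hi <- tapply(simp * lam, j + 1L, sum)
  w_first[ugrp[as.integer(names(acc_lo))]] <-
    w_first[ugrp[as.integer(names(acc_lo))]] + acc_lo
  w_first[ugrp[as.integer(names(acc_hi))]] <-
    w_first[ugrp[as.integer(names(acc_hi))]] + acc_hi
  w_first[grp] / cnt
}

# Plain trapezoid on a tabulated (x, y); used where the tabulation itself is
# already adapted to the integrand (CDF inversion, KL on a fine u-grid).
trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
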