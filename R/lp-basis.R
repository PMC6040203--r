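#' Shifted orthonormal Legendre polynomials on the unit interval
#'
#' Evaluates the degree-\code{j} shifted Legendre polynomial, orthonormalised
#' with respect to Lebesgue measure on \eqn{[0,1]}:
#' \eqn{\mathrm{Leg}_j(u) = \sqrt{2j+1}\, P_j(2u-1)}, where \eqn{P_j} is the
#' classical Legendre polynomial.  \code{Leg_0 \equiv 1} and
#' \eqn{\int_0^1 \mathrm{Leg}_i \mathrm{Leg}_j \,du = \delta_{ij}}.
#'
#' Evaluation uses the stable three-term recurrence
#' \eqn{(j+1) P_{j+1}(x) = (2j+1) x P_j(x) - j P_{j-1}(x)} on \eqn{x = 2u-1};
#' explicit monomial coefficients would lose precision through cancellation
#' for \eqn{j \ge 8}.
#'
#' @param j Polynomial degree, a single non-negative integer.
#' @param u Evaluation points in \eqn{[0,1]}; vectorised.
#' @return Numeric vector of the same length as \code{u}.
#' @examples
#' leg_poly(0, c(0.1, 0.9))          # constant 1
#' leg_poly(1, 0.5)                  # 0: odd about the midpoint
#' leg_poly(2, 0.5)                  # -sqrt(5)/2
#' @export
leg_poly <- function(j, u) {
  if (length(j) != 1L || is.na(j) || j < 0 || j != round(j))
    stop("'j' must be a single non-negative integer")
  if (any(is.na(u)) || any(u < 0) || any(u > 1))
    stop("'u' must lie in [0, 1]")
  x <- 2 * u - 1
  if (j == 0) return(rep(1, length(u)))
  p_prev <- rep(1, length(u))
  p <- x
  if (j >= 2) {
    for (jj in seq_len(j - 1)) {
      p_next <- ((2 * jj + 1) * x * p - jj * p_prev) / (jj + 1)
      p_prev <- p
      p <- p_next
    }
  }
  sqrt(2 * j + 1) * p
}

# Matrix of Leg_1..Leg_m at points u (columns indexed by degree).
# Single recurrence pass; used throughout the estimation machinery.
leg_matrix <- function(u, m) {
  out <- matrix(0, length(u), m)
  if (m == 0L) return(out)
  x <- 2 * u - 1
  p_prev <- rep(1, length(u))
  p <- x
  out[, 1] <- sqrt(3) * p
  if (m >= 2) {
    for (jj in 1:(m - 1)) {
      p_next <- ((2 * jj + 1) * x * p - jj * p_prev) / (jj + 1)
      p_prev <- p
      p <- p_next
      out[, jj + 1] <- sqrt(2 * (jj + 1) + 1) * p
    }
  }
  out
}

#' Rank-transform Legendre polynomials T_j(theta; G)
#'
#' The orthonormal basis of \eqn{L^2(G)} obtained by composing the shifted
#' Legendre polynomials with the prior distribution function:
#' \eqn{T_j(\theta; G) = \mathrm{Leg}_j(G(\theta))}.  Because \eqn{G(\Theta)}
#' is uniform under \eqn{\Theta \sim G}, the system is orthonormal in
#' \eqn{L^2(G)} for any continuous \eqn{G}; these polynomials of the rank
#' transform are the building blocks of the DS(G,m) prior correction.
#'
#' @param j Polynomial degree, a single non-negative integer.
#' @param theta Points in the support of the prior; vectorised.
#' @param family A [conjugate_family()] object supplying \eqn{G}.
#' @return Numeric vector \eqn{\mathrm{Leg}_j(G(\theta))}.
#' @examples
#' fam <- conjugate_family("binomial", alpha = 2, beta = 5)
#' rank_poly(1, qbeta(0.5, 2, 5), fam)   # 0 at the prior median
#' @export
rank_poly <- function(j, theta, family) {
  stopifnot(inherits(family, "conj_family"))
  check_support(family, theta)
  leg_poly(j, g_cdf(family, theta))
}
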