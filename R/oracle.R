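# Independent numerical oracle for Coulomb repulsion integrals.
#
# The Coulomb kernel is opened with the Gaussian transform
#   1/r12 = 2/sqrt(pi) * integral_0^infty exp(-u^2 r12^2) du,
# under which the 6-dimensional repulsion integral factorizes into a product
# of three 2-dimensional integrals per u.  Each 2-D integral is a polynomial
# times a bivariate Gaussian and is evaluated exactly by a product
# Gauss-Hermite rule on the principal axes of the quadratic form; the outer
# u-integral is done by adaptive quadrature after mapping to (0, 1).  The
# only shared ground with the analytic engine is the definition of the
# integrand itself, evaluated pointwise.

#' Describe one Gaussian factor of a charge distribution
#'
#' A charge distribution for [eri_quadrature_oracle()] is a list of one or
#' two such factors (two factors describe an orbital product).
#'
#' @param type `"cartesian"` (`(x-A)^i (y-A)^j (z-A)^k exp(-zeta r_A^2)`) or
#'   `"hermite"` (the (t,u,v) center-derivative of `exp(-zeta r_A^2)`).
#' @param center Numeric length-3 center (bohr).
#' @param exponent Gaussian exponent (bohr^-2).
#' @param powers Integer length-3: Cartesian powers or Hermite indices.
#' @param coefficient Scalar prefactor (e.g. a normalization constant).
#' @return A `gauss_factor` list.
#' @export
gauss_factor <- function(type = c("cartesian", "hermite"), center, exponent,
                         powers = c(0L, 0L, 0L), coefficient = 1) {
  type <- match.arg(type)
  stopifnot(length(center) == 3L, length(powers) == 3L, exponent > 0)
  structure(list(type = type, center = as.numeric(center),
                 exponent = as.numeric(exponent), powers = as.integer(powers),
                 coefficient = as.numeric(coefficient)),
            class = "gauss_factor")
}

# physicists' Hermite polynomial H_n evaluated by recurrence
.hermite_poly <- function(n, x) {
  h0 <- rep(1, length(x))
  if (n == 0L) return(h0)
  h1 <- 2 * x
  if (n == 1L) return(h1)
  for (k in 2:n) {
    h2 <- 2 * x * h1 - 2 * (k - 1) * h0
    h0 <- h1; h1 <- h2
  }
  h1
}

# 1-D polynomial part of a factor along dimension d, evaluated at x
.factor_poly1d <- function(f, d, x) {
  y <- x - f$center[d]
  n <- f$powers[d]
  if (f$type == "cartesian") {
    y^n
  } else {
    # (d/dA)^n exp(-a (x - A)^2) = a^(n/2) H_n(sqrt(a) (x - A)) exp(...)
    f$exponent^(n / 2) * .hermite_poly(n, sqrt(f$exponent) * y)
  }
}

# combined 1-D polynomial and Gaussian parameters of a distribution
# (1 or 2 factors): total exponent, weighted center, constant from the
# cross-term completion, and a closure evaluating the polynomial part
.dist_1d <- function(factors, d) {
  a <- vapply(factors, `[[`, numeric(1), "exponent")
  A <- vapply(factors, function(f) f$center[d], numeric(1))
  p <- sum(a)
  ctr <- sum(a * A) / p
  logK <- -(sum(a * A^2) - p * ctr^2)   # exp of this is the Gaussian prefactor
  poly <- function(x) {
    out <- rep(1, length(x))
    for (f in factors) out <- out * .factor_poly1d(f, d, x)
    out
  }
  list(p = p, ctr = ctr, logK = logK, poly = poly,
       degree = sum(vapply(factors, function(f) f$powers[d], integer(1))))
}

# I_d(u) = int int poly1(x1) poly2(x2) exp(-p1 (x1-c1)^2 - p2 (x2-c2)^2
#          - u^2 (x1-x2)^2) dx1 dx2, exactly via principal-axis Gauss-Hermite;
# vectorized over u.
.pair_integral_1d <- function(d1, d2, u, gh) {
  vapply(u, function(uu) {
    u2 <- uu * uu
    M <- matrix(c(d1$p + u2, -u2, -u2, d2$p + u2), 2L, 2L)
    bv <- c(d1$p * d1$ctr, d2$p * d2$ctr)
    cc <- d1$p * d1$ctr^2 + d2$p * d2$ctr^2
    xstar <- solve(M, bv)
    eg <- eigen(M, symmetric = TRUE)
    lam <- eg$values
    # nodes on principal axes
    z1 <- gh$x / sqrt(lam[1]); z2 <- gh$x / sqrt(lam[2])
    X1 <- xstar[1] + outer(eg$vectors[1, 1] * z1, eg$vectors[1, 2] * z2, "+")
    X2 <- xstar[2] + outer(eg$vectors[2, 1] * z1, eg$vectors[2, 2] * z2, "+")
    vals <- d1$poly(X1) * d2$poly(X2)
    quad <- sum(outer(gh$w, gh$w) * vals) / sqrt(lam[1] * lam[2])
    quad * exp(-(cc - sum(bv * xstar)) + d1$logK + d2$logK)
  }, numeric(1))
}

#' Numerical-quadrature Coulomb repulsion oracle
#'
#' Coulomb repulsion between two analytically specified charge
#' distributions, each a product of one or two Gaussian factors.  Intended
#' as an independent cross-check of the analytic engine for well-scaled
#' inputs; the contract is a relative accuracy of about 1e-8 or better.
#'
#' @param distA,distB Lists of one or two [gauss_factor()] objects.
#' @param rel_tol Requested relative tolerance of the outer u-quadrature.
#' @param nodes Gauss-Hermite node count per axis (default 24, exact for
#'   polynomial degrees up to 47).
#' @return The repulsion integral (scalar).
#' @export
eri_quadrature_oracle <- function(distA, distB, rel_tol = 1e-10, nodes = 24L) {
  if (inherits(distA, "gauss_factor")) distA <- list(distA)
  if (inherits(distB, "gauss_factor")) distB <- list(distB)
  co <- prod(vapply(c(distA, distB), `[[`, numeric(1), "coefficient"))
  gh <- pracma::gaussHermite(nodes)
  dA <- lapply(1:3, function(d) .dist_1d(distA, d))
  dB <- lapply(1:3, function(d) .dist_1d(distB, d))
  f_u <- function(u) {
    .pair_integral_1d(dA[[1]], dB[[1]], u, gh) *
      .pair_integral_1d(dA[[2]], dB[[2]], u, gh) *
      .pair_integral_1d(dA[[3]], dB[[3]], u, gh)
  }
  # u = t / (1 - t) maps (0, infty) to (0, 1)
  g_t <- function(t) f_u(t / (1 - t)) / (1 - t)^2
  q <- tryCatch(
    stats::integrate(g_t, 0, 1, rel.tol = rel_tol, abs.tol = 0,
                     subdivisions = 400L, stop.on.error = TRUE),
    error = function(e) stop("oracle quadrature did not converge: ",
                             conditionMessage(e)))
  if (is.finite(q$value) && abs(q$value) > 0 &&
      q$abs.error > 1e-7 * abs(q$value))
    stop(sprintf("oracle quadrature error estimate too large (%.2e rel)",
                 q$abs.error / abs(q$value)))
  2 / sqrt(pi) * co * q$value
}
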