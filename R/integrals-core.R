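# Analytic integral engine core: Boys function, McMurchie-Davidson Hermite
# expansion (E) coefficients and Hermite Coulomb (R) integrals.

#' Boys function
#'
#' `F_m(T) = integral_0^1 t^(2m) exp(-T t^2) dt`, evaluated through the
#' regularized lower incomplete gamma function
#' `F_m(T) = Gamma(m + 1/2) P(m + 1/2, T) / (2 T^(m + 1/2))`,
#' accurate to well below 1e-13 absolute.
#'
#' @param m Order (integer >= 0, vectorized).
#' @param T Argument (>= 0, vectorized).
#' @return F_m(T).
#' @export
boys <- function(m, T) {
  if (any(m < 0)) stop("Boys order m must be >= 0")
  if (any(T < 0)) stop("Boys argument T must be >= 0")
  n <- max(length(m), length(T))
  m <- rep_len(m, n)
  T <- rep_len(T, n)
  a <- m + 0.5
  out <- ifelse(T < .Machine$double.xmin, 1 / (2 * m + 1),
                exp(lgamma(a) + stats::pgamma(T, a, log.p = TRUE) -
                      a * log(pmax(T, .Machine$double.xmin))) / 2)
  out
}

# F_0..F_mmax at one argument
.boys_all <- function(mmax, T) boys(0:mmax, T)

# double factorial (2n-1)!! with (2*0-1)!! = 1
.dfact <- function(n) vapply(n, function(k) {
  if (k <= 0L) 1 else prod(seq.int(1, 2 * k - 1, by = 2))
}, numeric(1))

# Cartesian power triples for angular momentum l, descending lexicographic
# in (i, j, k) with i taking precedence: l=1 -> (100),(010),(001);
# l=2 -> (200),(110),(101),(020),(011),(002).
.cart_components <- function(l) {
  out <- matrix(0L, nrow = ((l + 1L) * (l + 2L)) %/% 2L, ncol = 3L)
  r <- 1L
  for (i in l:0) for (j in (l - i):0) {
    out[r, ] <- c(i, j, l - i - j)
    r <- r + 1L
  }
  out
}

# Hermite index triples (t,u,v) with t+u+v <= L, grouped by total degree,
# descending lexicographic within each degree.
.hermite_components <- function(L) {
  do.call(rbind, lapply(0:L, .cart_components))
}

# One-dimensional Hermite expansion coefficients E_t^{ij} for the product of
# Cartesian Gaussians x_A^i exp(-a x_A^2) * x_B^j exp(-b x_B^2):
# returns array [i+1, j+1, t+1].  Standard two-term-plus-transfer recurrence.
.e_table <- function(l1, l2, a, b, AB) {
  p <- a + b
  mu <- a * b / p
  PA <- -b * AB / p   # P - A with AB = A - B
  PB <- a * AB / p    # P - B
  E <- array(0, dim = c(l1 + 1L, l2 + 1L, l1 + l2 + 1L))
  E[1L, 1L, 1L] <- exp(-mu * AB * AB)
  ooz <- 1 / (2 * p)
  if (l1 > 0L) for (i in 1:l1) {
    for (t in 0:i) {
      v <- PA * E[i, 1L, t + 1L]
      if (t > 0L) v <- v + ooz * E[i, 1L, t]
      if (t + 2L <= i) v <- v + (t + 1) * E[i, 1L, t + 2L]
      E[i + 1L, 1L, t + 1L] <- v
    }
  }
  if (l2 > 0L) for (j in 1:l2) {
    for (i in 0:l1) for (t in 0:(i + j)) {
      v <- PB * E[i + 1L, j, t + 1L]
      if (t > 0L) v <- v + ooz * E[i + 1L, j, t]
      if (t + 2L <= i + j) v <- v + (t + 1) * E[i + 1L, j, t + 2L]
      E[i + 1L, j + 1L, t + 1L] <- v
    }
  }
  E
}

#' Hermite expansion coefficients of a Gaussian product
#'
#' Expands the one-dimensional product of two Cartesian Gaussians with
#' angular factors `x^l1`, `x^l2` into Hermite Gaussians at the composite
#' center P = (zeta1 A + zeta2 B)/(zeta1 + zeta2).
#'
#' @param l1,l2 Cartesian powers (<= 6).
#' @param zeta1,zeta2 Exponents.
#' @param separation A - B along this dimension.
#' @return Array `[i+1, j+1, t+1]` of E coefficients, `E[l1+1, l2+1, ]` being
#'   the requested expansion.
#' @export
hermite_expansion <- function(l1, l2, zeta1, zeta2, separation) {
  if (l1 > 6L || l2 > 6L) stop("angular powers above 6 are not supported")
  .e_table(l1, l2, zeta1, zeta2, separation)
}

# Hermite Coulomb integrals R^0_{tuv}(p, PC) for all t+u+v <= nmax with
# per-dimension caps (tmax, umax, vmax).  Downward m-recursion on
# R^m_{000} = (-2p)^m F_m(p |PC|^2).
.r_table <- function(tmax, umax, vmax, nmax, p, PC) {
  Tm <- p * sum(PC * PC)
  Fm <- .boys_all(nmax, Tm)
  prev <- NULL
  dims <- c(tmax + 1L, umax + 1L, vmax + 1L)
  for (m in nmax:0) {
    cur <- array(0, dim = dims)
    cur[1L, 1L, 1L] <- (-2 * p)^m * Fm[m + 1L]
    nlim <- nmax - m
    if (nlim > 0L) for (n in 1:nlim) {
      for (t in 0:min(tmax, n)) {
        ur <- min(umax, n - t)
        for (u in 0:ur) {
          v <- n - t - u
          if (v > vmax) next
          if (t > 0L) {
            val <- PC[1] * prev[t, u + 1L, v + 1L]
            if (t > 1L) val <- val + (t - 1) * prev[t - 1L, u + 1L, v + 1L]
          } else if (u > 0L) {
            val <- PC[2] * prev[1L, u, v + 1L]
            if (u > 1L) val <- val + (u - 1) * prev[1L, u - 1L, v + 1L]
          } else {
            val <- PC[3] * prev[1L, 1L, v]
            if (v > 1L) val <- val + (v - 1) * prev[1L, 1L, v - 1L]
          }
          cur[t + 1L, u + 1L, v + 1L] <- val
        }
      }
    }
    prev <- cur
  }
  prev
}
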