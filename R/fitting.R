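# Variational density fitting of the Coulomb and Fock-exchange energies of a
# supplied closed-shell density.  The fitting system G x = J is solved
# directly (Cholesky), by truncated eigendecomposition (TED), or by MINRES;
# TED discards near-null eigenpairs of the Coulomb metric, which keeps the
# fit variational (non-negative Coulomb fitting error) even when G is
# numerically indefinite.

#' Assemble the two-center Coulomb metric G
#'
#' `G_kl = <k-bar || l-bar>` over all auxiliary functions.  With the default
#' Coulomb normalization the diagonal is exactly 1.  G is symmetric and
#' formally positive semidefinite; finite precision can make it slightly
#' indefinite, which is what the TED solver guards against.
#'
#' @param iaux An [index_aux_basis()] result.
#' @return Symmetric `n_aux x n_aux` matrix.
#' @export
assemble_G <- function(iaux) {
  stopifnot(inherits(iaux, "indexed_aux"))
  n <- iaux$n_fun
  G <- matrix(0, n, n)
  for (k1 in seq_along(iaux$sets)) for (k2 in seq_len(k1)) {
    A <- iaux$sets[[k1]]; B <- iaux$sets[[k2]]
    blk <- eri_2c(A, B)
    ri <- A$offset + seq_len(A$ncomp); ci <- B$offset + seq_len(B$ncomp)
    G[ri, ci] <- blk
    G[ci, ri] <- t(blk)
  }
  (G + t(G)) / 2
}

#' Assemble the Coulomb fitting vector J
#'
#' `J_k = sum_mu_nu P_mu_nu <mu nu || k-bar>`.
#'
#' @param P Closed-shell density matrix (`n_basis x n_basis`, symmetric).
#' @param eri3 Three-center tensor from [eri_3c_tensor()].
#' @return Numeric vector of length `n_aux`.
#' @export
assemble_J <- function(P, eri3) {
  d <- dim(eri3)
  if (nrow(P) != d[1] || ncol(P) != d[2])
    stop("density matrix dimensions do not match the 3c tensor")
  as.vector(crossprod(matrix(eri3, d[1] * d[2], d[3]), as.vector(P)))
}

#' Solve the Coulomb fitting system G x = J
#'
#' @param G Coulomb metric.
#' @param J Coulomb vector (or a matrix of right-hand sides in columns).
#' @param method `"direct"` (Cholesky; errors on numerically non-PD G),
#'   `"ted"` (truncated eigendecomposition: eigenpairs with
#'   `lambda < tau * lambda_max` are discarded and the pseudo-inverse
#'   applied), or `"minres"` (Krylov iteration to relative residual
#'   <= `tol` or at most `5 * dim` iterations).
#' @param tau TED drop threshold relative to the largest eigenvalue
#'   (default 1e-9).
#' @param tol MINRES relative residual tolerance (default 1e-10).
#' @return List with `x` (same shape as `J`), `method`, and `diagnostics`
#'   (`dropped` eigenpair count for ted, `iterations` and `residual` for
#'   minres, `residual` for all).
#' @export
solve_fit <- function(G, J, method = c("direct", "ted", "minres"),
                      tau = 1e-9, tol = 1e-10) {
  method <- match.arg(method)
  Jm <- as.matrix(J)
  if (nrow(Jm) != nrow(G)) stop("J not conformable with G")
  diag_out <- list()
  if (method == "direct") {
    ch <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(ch))
      stop("G is numerically not positive definite; use method = 'ted'")
    X <- backsolve(ch, forwardsolve(t(ch), Jm))
  } else if (method == "ted") {
    eg <- eigen(G, symmetric = TRUE)
    lmax <- max(eg$values)
    keep <- eg$values >= tau * lmax
    diag_out$dropped <- sum(!keep)
    V <- eg$vectors[, keep, drop = FALSE]
    X <- V %*% (crossprod(V, Jm) / eg$values[keep])
  } else {
    sols <- lapply(seq_len(ncol(Jm)), function(k)
      .minres(G, Jm[, k], tol = tol, maxit = 5L * nrow(G)))
    X <- vapply(sols, `[[`, numeric(nrow(G)), "x")
    X <- matrix(X, nrow = nrow(G))
    diag_out$iterations <- max(vapply(sols, `[[`, integer(1), "iterations"))
  }
  res <- G %*% X - Jm
  diag_out$residual <- max(sqrt(colSums(res^2)) / pmax(sqrt(colSums(Jm^2)),
                                                       .Machine$double.xmin))
  x <- if (is.matrix(J)) X else as.vector(X)
  list(x = x, method = method, diagnostics = diag_out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# MINRES for symmetric (possibly indefinite) systems: Lanczos
# tridiagonalization with Givens-rotation QR updates (Paige & Saunders).
.minres <- function(A, b, tol = 1e-10, maxit = 5L * length(b)) {
  n <- length(b)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(list(x = numeric(n), iterations = 0L, residual = 0))
  x <- numeric(n)
  v_prev <- numeric(n)
  v <- b / bnorm
  beta <- 0                       # beta_k (0 for k = 1)
  eta <- bnorm
  c0 <- 1; c1 <- 1; s0 <- 0; s1 <- 0
  w <- numeric(n); w_prev <- numeric(n)
  resid <- bnorm
  it <- 0L
  while (resid > tol * bnorm && it < maxit) {
    it <- it + 1L
    Av <- as.vector(A %*% v)
    alpha <- sum(v * Av)
    r <- Av - alpha * v - beta * v_prev
    beta_next <- sqrt(sum(r * r))
    delta <- c1 * alpha - c0 * s1 * beta
    rho1 <- sqrt(delta * delta + beta_next * beta_next)
    rho2 <- s1 * alpha + c0 * c1 * beta
    rho3 <- s0 * beta
    c0 <- c1; s0 <- s1
    c1 <- delta / rho1; s1 <- beta_next / rho1
    w_next <- (v - rho3 * w_prev - rho2 * w) / rho1
    x <- x + (c1 * eta) * w_next
    eta <- -s1 * eta
    resid <- abs(eta)
    w_prev <- w; w <- w_next
    v_prev <- v
    if (beta_next > 0) v <- r / beta_next else break
    beta <- beta_next
  }
  if (resid > tol * bnorm && it >= maxit)
    warning("MINRES did not reach the requested residual")
  list(x = x, iterations = it, residual = resid / bnorm)
}

#' Fitted and exact Coulomb repulsion energies
#'
#' Evaluates the exact two-electron Coulomb repulsion
#' `E_H = 1/2 sum P P <mu nu || lambda sigma>` and the four algebraically
#' equivalent fitted expressions at the fitting coefficients `x`:
#' `E_a = x.J - 1/2 x'Gx` (the variational MinMax form), `E_b = 1/2 x.J`,
#' `E_c = 1/2 x'Gx`, and `E_d = 1/2 sum_k x_k J_k` with `J` recomputed from a
#' fresh three-center contraction.  The Coulomb fitting error
#' `eps2H = E_H - E_a` is non-negative for any density (positive
#' semidefiniteness of the Coulomb metric); TED regularization preserves
#' this bound.
#'
#' @param P Closed-shell density matrix.
#' @param x Fitting coefficients from [solve_fit()].
#' @param G Coulomb metric.
#' @param J Coulomb vector used in the solve.
#' @param eri4 Four-center tensor from [eri_4c_tensor()].
#' @param eri3 Three-center tensor (for the fresh `E_d` contraction).
#' @param solver Solver result for diagnostics (optional).
#' @return List of class `coulomb_fit` with `E_H`, `E_a`, `E_b`, `E_c`,
#'   `E_d`, `eps2H`, `x`, and `diagnostics`.
#' @export
coulomb_energies <- function(P, x, G, J, eri4, eri3, solver = NULL) {
  nb <- nrow(P)
  v <- as.vector(P)
  E_H <- 0.5 * sum(v * as.vector(matrix(eri4, nb * nb, nb * nb) %*% v))
  xGx <- sum(x * as.vector(G %*% x))
  xJ <- sum(x * J)
  E_a <- xJ - 0.5 * xGx
  E_b <- 0.5 * xJ
  E_c <- 0.5 * xGx
  E_d <- 0.5 * sum(x * assemble_J(P, eri3))
  structure(list(E_H = E_H, E_a = E_a, E_b = E_b, E_c = E_c, E_d = E_d,
                 eps2H = E_H - E_a, x = x, G = G, J = J,
                 diagnostics = if (is.null(solver)) list() else
                   c(list(method = solver$method), solver$diagnostics)),
            class = "coulomb_fit")
}

#' @export
print.coulomb_fit <- function(x, ...) {
  cat(sprintf("<coulomb_fit> E_H = %.10f  E_fit = %.10f  eps2H = %.3e\n",
              x$E_H, x$E_a, x$eps2H))
  invisible(x)
}

#' Variational fit of the Fock exchange energy
#'
#' For every occupied MO pair (i, j) the orbital product density is expanded
#' in the full auxiliary basis under the Coulomb metric:
#' `J_ij,k = sum_mu_nu c_mu_i c_nu_j <mu nu || k-bar>`, fitted pair repulsion
#' `J_ij' G+ J_ij`, giving `E_F_fit = - sum_ij J_ij' G+ J_ij` versus the
#' exact `E_F = - sum_ij <psi_i psi_j || psi_i psi_j>`.  Each fitted pair
#' repulsion is bounded above by the exact one (projection in the Coulomb
#' metric), so `eps2F = E_F - E_F_fit <= 0`.
#'
#' @param c_occ Occupied orbital coefficients (`n_basis x n_occ`),
#'   orthonormal in the overlap metric.
#' @param eri3 Three-center tensor.
#' @param G Coulomb metric.
#' @param eri4 Four-center tensor.
#' @param S Overlap matrix; if supplied, orthonormality of `c_occ` is checked.
#' @param method,tau,tol Solver options, see [solve_fit()].
#' @return List of class `exchange_fit` with `E_F`, `E_F_fit`, `eps2F`,
#'   `pair_exact`, `pair_fit` (matrices `n_occ x n_occ`), `diagnostics`.
#' @export
exchange_fit <- function(c_occ, eri3, G, eri4, S = NULL,
                         method = c("ted", "direct", "minres"),
                         tau = 1e-9, tol = 1e-10) {
  method <- match.arg(method)
  c_occ <- as.matrix(c_occ)
  nocc <- ncol(c_occ)
  nb <- nrow(c_occ)
  if (!is.null(S)) {
    dev <- max(abs(crossprod(c_occ, S %*% c_occ) - diag(nocc)))
    if (dev > 1e-8)
      stop(sprintf("occupied orbitals not S-orthonormal (deviation %.2e)", dev))
  }
  na <- dim(eri3)[3]
  # half-transform the 3c tensor to the occupied MO pair basis
  Tm <- matrix(eri3, nb, nb * na)                       # mu x (nu k)
  H1 <- crossprod(c_occ, Tm)                            # i x (nu k)
  H1 <- array(H1, dim = c(nocc, nb, na))
  Jij <- matrix(0, nocc * nocc, na)
  for (k in seq_len(na))
    Jij[, k] <- as.vector(H1[, , k] %*% c_occ)          # (i,j) x k
  sol <- solve_fit(G, t(Jij), method = method, tau = tau, tol = tol)
  Xf <- t(sol$x)                                        # (i,j) x k
  pair_fit <- matrix(rowSums(Jij * Xf), nocc, nocc)
  # exact MO-pair repulsions from the 4c tensor
  M4 <- matrix(eri4, nb * nb, nb * nb)
  pair_exact <- matrix(0, nocc, nocc)
  for (i in seq_len(nocc)) for (j in seq_len(i)) {
    dij <- as.vector(tcrossprod(c_occ[, i], c_occ[, j]))
    val <- sum(dij * as.vector(M4 %*% dij))
    pair_exact[i, j] <- val
    pair_exact[j, i] <- val
  }
  E_F <- -sum(pair_exact)
  E_F_fit <- -sum(pair_fit)
  structure(list(E_F = E_F, E_F_fit = E_F_fit, eps2F = E_F - E_F_fit,
                 pair_exact = pair_exact, pair_fit = pair_fit,
                 diagnostics = c(list(method = method), sol$diagnostics)),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf("<exchange_fit> E_F = %.10f  E_F_fit = %.10f  eps2F = %.3e\n",
              x$E_F, x$E_F_fit, x$eps2F))
  invisible(x)
}

#' Suite-level error statistics
#'
#' Mean signed error, mean absolute error, sample standard deviation
#' (denominator n - 1) and the mean auxiliary-to-basis function ratio.
#'
#' @param deltas Signed energy differences.
#' @param gammas Auxiliary/basis function ratios (optional).
#' @return List with `mse`, `mae`, `sigma`, `gamma_bar`, `count`.
#' @export
error_metrics <- function(deltas, gammas = numeric()) {
  if (length(deltas) == 0L) stop("no deltas supplied")
  list(mse = mean(deltas), mae = mean(abs(deltas)),
       sigma = if (length(deltas) > 1L) stats::sd(deltas) else 0,
       gamma_bar = if (length(gammas)) mean(gammas) else NA_real_,
       count = length(deltas))
}
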