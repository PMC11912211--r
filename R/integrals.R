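# Assembly of overlap and 2-/3-/4-center electron repulsion integrals from
# the McMurchie-Davidson core.  Orbital bras are expanded into Hermite
# Gaussians via E coefficients; Hermite auxiliary kets are used directly
# (no Cartesian transformation).  Small gather-index tables are cached per
# angular momentum combination so the inner loops are vectorized.

.gather_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, make) {
  if (!exists(key, envir = .gather_cache)) assign(key, make(), envir = .gather_cache)
  get(key, envir = .gather_cache)
}

# W gather: for a shell pair (l1, l2), linear indices into the three 1D
# E-coefficient arrays for every (component pair, Hermite triple).
.w_gather <- function(l1, l2) {
  .cache_get(sprintf("W_%d_%d", l1, l2), function() {
    c1 <- .cart_components(l1); c2 <- .cart_components(l2)
    H <- .hermite_components(l1 + l2)
    n1 <- nrow(c1); n2 <- nrow(c2); nH <- nrow(H)
    d <- c(l1 + 1L, l2 + 1L, l1 + l2 + 1L)
    idx1 <- function(a, b, t) a + 1L + d[1] * (b + d[2] * t)  # 1-based linear
    rc <- cbind(rep(seq_len(n1), times = n2), rep(seq_len(n2), each = n1))
    gx <- matrix(0L, n1 * n2, nH); gy <- gx; gz <- gx
    for (h in seq_len(nH)) {
      gx[, h] <- idx1(c1[rc[, 1], 1], c2[rc[, 2], 1], H[h, 1])
      gy[, h] <- idx1(c1[rc[, 1], 2], c2[rc[, 2], 2], H[h, 2])
      gz[, h] <- idx1(c1[rc[, 1], 3], c2[rc[, 2], 3], H[h, 3])
    }
    list(gx = gx, gy = gy, gz = gz, H = H, n1 = n1, n2 = n2, nH = nH)
  })
}

# R gather: linear indices into an R table of per-dim cap `cap` for the sum
# triples of bra Hermite set H1 and ket Hermite set H2.
.r_gather <- function(H1, H2, cap) {
  n1 <- nrow(H1); n2 <- nrow(H2)
  d1 <- cap + 1L
  ix <- matrix(0L, n1, n2)
  for (h2 in seq_len(n2)) {
    ix[, h2] <- (H1[, 1] + H2[h2, 1] + 1L) +
      d1 * ((H1[, 2] + H2[h2, 2]) + d1 * (H1[, 3] + H2[h2, 3]))
  }
  ix
}

.w_matrix <- function(g, Ex, Ey, Ez) {
  matrix(Ex[g$gx] * Ey[g$gy] * Ez[g$gz], g$n1 * g$n2, g$nH)
}

#' Overlap matrix of the indexed orbital basis
#'
#' @param iobs An [index_orbital_basis()] result.
#' @return Symmetric `n_fun x n_fun` matrix with unit diagonal.
#' @export
overlap_matrix <- function(iobs) {
  stopifnot(inherits(iobs, "indexed_obs"))
  n <- iobs$n_fun
  S <- matrix(0, n, n)
  for (s1 in seq_along(iobs$shells)) for (s2 in seq_len(s1)) {
    A <- iobs$shells[[s1]]; B <- iobs$shells[[s2]]
    AB <- A$center - B$center
    blk <- matrix(0, A$ncomp, B$ncomp)
    for (p in seq_along(A$zeta)) for (q in seq_along(B$zeta)) {
      a <- A$zeta[p]; b <- B$zeta[q]; pp <- a + b
      Ex <- .e_table(A$l, B$l, a, b, AB[1])
      Ey <- .e_table(A$l, B$l, a, b, AB[2])
      Ez <- .e_table(A$l, B$l, a, b, AB[3])
      w <- A$coef[p] * B$coef[q] * (pi / pp)^1.5
      c1 <- A$comps; c2 <- B$comps
      pb <- matrix(0, A$ncomp, B$ncomp)
      for (i1 in seq_len(A$ncomp)) for (i2 in seq_len(B$ncomp)) {
        pb[i1, i2] <- Ex[c1[i1, 1] + 1L, c2[i2, 1] + 1L, 1L] *
          Ey[c1[i1, 2] + 1L, c2[i2, 2] + 1L, 1L] *
          Ez[c1[i1, 3] + 1L, c2[i2, 3] + 1L, 1L]
      }
      blk <- blk + w * pb
    }
    blk <- blk * outer(A$cscale, B$cscale)
    ri <- A$offset + seq_len(A$ncomp); ci <- B$offset + seq_len(B$ncomp)
    S[ri, ci] <- blk
    S[ci, ri] <- t(blk)
  }
  S
}

#' Two-center Coulomb repulsion block between Hermite auxiliary sets
#'
#' `<a-bar || b-bar>` for all functions of two shared-exponent sets, with the
#' sets' normalization applied.  Symmetric under set exchange.
#'
#' @param setA,setB Set descriptors from [index_aux_basis()] (`$sets[[k]]`).
#' @return Matrix `ncomp(A) x ncomp(B)`.
#' @export
eri_2c <- function(setA, setB) {
  AB <- setA$center - setB$center
  a <- setA$alpha; b <- setB$alpha
  th <- a * b / (a + b)
  cap <- setA$L + setB$L
  R <- .r_table(cap, cap, cap, cap, th, AB)
  ix <- .r_gather(setA$comps, setB$comps, cap)
  sgn <- (-1)^rowSums(setB$comps)
  pref <- 2 * pi^2.5 / (a * b * sqrt(a + b))
  blk <- pref * matrix(R[ix], nrow(setA$comps), nrow(setB$comps))
  blk <- sweep(blk, 2L, sgn, "*")
  blk * outer(setA$norms, setB$norms)
}

#' Three-center repulsion block: orbital shell pair with one auxiliary set
#'
#' `<mu nu || k-bar>` for all Cartesian components of two contracted shells
#' and all Hermite functions of one shared-exponent auxiliary set.  The
#' Hermite ket is evaluated directly.
#'
#' @param shellA,shellB Shell descriptors from [index_orbital_basis()].
#' @param set Set descriptor from [index_aux_basis()].
#' @return Array `ncomp(A) x ncomp(B) x ncomp(set)`.
#' @export
eri_3c <- function(shellA, shellB, set) {
  AB <- shellA$center - shellB$center
  g <- .w_gather(shellA$l, shellB$l)
  cap <- shellA$l + shellB$l + set$L
  ix <- .r_gather(g$H, set$comps, cap)
  sgn <- (-1)^rowSums(set$comps) * set$norms
  out <- matrix(0, g$n1 * g$n2, set$ncomp)
  for (p in seq_along(shellA$zeta)) for (q in seq_along(shellB$zeta)) {
    a <- shellA$zeta[p]; b <- shellB$zeta[q]; pp <- a + b
    P <- (a * shellA$center + b * shellB$center) / pp
    Ex <- .e_table(shellA$l, shellB$l, a, b, AB[1])
    Ey <- .e_table(shellA$l, shellB$l, a, b, AB[2])
    Ez <- .e_table(shellA$l, shellB$l, a, b, AB[3])
    W <- .w_matrix(g, Ex, Ey, Ez)
    th <- pp * set$alpha / (pp + set$alpha)
    R <- .r_table(cap, cap, cap, cap, th, P - set$center)
    Rm <- matrix(R[ix], g$nH, set$ncomp)
    pref <- 2 * pi^2.5 / (pp * set$alpha * sqrt(pp + set$alpha))
    out <- out + (shellA$coef[p] * shellB$coef[q] * pref) * (W %*% Rm)
  }
  out <- out * rep(outer(shellA$cscale, shellB$cscale), times = set$ncomp)
  array(sweep(out, 2L, sgn, "*"), dim = c(g$n1, g$n2, set$ncomp))
}

#' Four-center repulsion block for a shell quartet
#'
#' `<mu nu || lambda sigma>` over the Cartesian components of four contracted
#' orbital shells (l <= 2 each).
#'
#' @param shellA,shellB,shellC,shellD Shell descriptors from
#'   [index_orbital_basis()].
#' @return Array `ncomp(A) x ncomp(B) x ncomp(C) x ncomp(D)`.
#' @export
eri_4c <- function(shellA, shellB, shellC, shellD) {
  for (sh in list(shellA, shellB, shellC, shellD))
    if (sh$l > 2L) stop("four-center integrals support l <= 2 only")
  AB <- shellA$center - shellB$center
  CD <- shellC$center - shellD$center
  g1 <- .w_gather(shellA$l, shellB$l)
  g2 <- .w_gather(shellC$l, shellD$l)
  cap <- shellA$l + shellB$l + shellC$l + shellD$l
  ix <- .r_gather(g1$H, g2$H, cap)
  sgn <- (-1)^rowSums(g2$H)
  out <- matrix(0, g1$n1 * g1$n2, g2$n1 * g2$n2)
  for (p in seq_along(shellA$zeta)) for (q in seq_along(shellB$zeta)) {
    a <- shellA$zeta[p]; b <- shellB$zeta[q]; pp <- a + b
    P <- (a * shellA$center + b * shellB$center) / pp
    W1 <- .w_matrix(g1, .e_table(shellA$l, shellB$l, a, b, AB[1]),
                    .e_table(shellA$l, shellB$l, a, b, AB[2]),
                    .e_table(shellA$l, shellB$l, a, b, AB[3]))
    for (r in seq_along(shellC$zeta)) for (s in seq_along(shellD$zeta)) {
      cz <- shellC$zeta[r]; dz <- shellD$zeta[s]; qq <- cz + dz
      Q <- (cz * shellC$center + dz * shellD$center) / qq
      W2 <- .w_matrix(g2, .e_table(shellC$l, shellD$l, cz, dz, CD[1]),
                      .e_table(shellC$l, shellD$l, cz, dz, CD[2]),
                      .e_table(shellC$l, shellD$l, cz, dz, CD[3]))
      W2 <- sweep(W2, 2L, sgn, "*")
      th <- pp * qq / (pp + qq)
      R <- .r_table(cap, cap, cap, cap, th, P - Q)
      Rm <- matrix(R[ix], g1$nH, g2$nH)
      w <- shellA$coef[p] * shellB$coef[q] * shellC$coef[r] * shellD$coef[s] *
        2 * pi^2.5 / (pp * qq * sqrt(pp + qq))
      out <- out + w * (W1 %*% Rm %*% t(W2))
    }
  }
  out <- out * outer(as.vector(outer(shellA$cscale, shellB$cscale)),
                     as.vector(outer(shellC$cscale, shellD$cscale)))
  array(out, dim = c(g1$n1, g1$n2, g2$n1, g2$n2))
}

#' Full three-center ERI tensor
#'
#' @param iobs,iaux Indexed bases.
#' @return Array `n_basis x n_basis x n_aux`.
#' @export
eri_3c_tensor <- function(iobs, iaux) {
  nb <- iobs$n_fun; na <- iaux$n_fun
  T3 <- array(0, dim = c(nb, nb, na))
  for (s1 in seq_along(iobs$shells)) for (s2 in seq_len(s1)) {
    A <- iobs$shells[[s1]]; B <- iobs$shells[[s2]]
    ri <- A$offset + seq_len(A$ncomp); ci <- B$offset + seq_len(B$ncomp)
    for (st in iaux$sets) {
      ki <- st$offset + seq_len(st$ncomp)
      blk <- eri_3c(A, B, st)
      T3[ri, ci, ki] <- blk
      if (s1 != s2) T3[ci, ri, ki] <- aperm(blk, c(2L, 1L, 3L))
    }
  }
  T3
}

#' Full four-center ERI tensor
#'
#' @param iobs Indexed orbital basis.
#' @return Array `n x n x n x n` with the full 8-fold index symmetry.
#' @export
eri_4c_tensor <- function(iobs) {
  nb <- iobs$n_fun
  T4 <- array(0, dim = c(nb, nb, nb, nb))
  ns <- length(iobs$shells)
  for (s1 in seq_len(ns)) for (s2 in seq_len(s1)) {
    A <- iobs$shells[[s1]]; B <- iobs$shells[[s2]]
    i1 <- A$offset + seq_len(A$ncomp); i2 <- B$offset + seq_len(B$ncomp)
    for (s3 in seq_len(s1)) {
      s4max <- if (s3 == s1) s2 else s3
      for (s4 in seq_len(s4max)) {
        C <- iobs$shells[[s3]]; D <- iobs$shells[[s4]]
        i3 <- C$offset + seq_len(C$ncomp); i4 <- D$offset + seq_len(D$ncomp)
        blk <- eri_4c(A, B, C, D)
        T4[i1, i2, i3, i4] <- blk
        T4[i2, i1, i3, i4] <- aperm(blk, c(2, 1, 3, 4))
        T4[i1, i2, i4, i3] <- aperm(blk, c(1, 2, 4, 3))
        T4[i2, i1, i4, i3] <- aperm(blk, c(2, 1, 4, 3))
        T4[i3, i4, i1, i2] <- aperm(blk, c(3, 4, 1, 2))
        T4[i4, i3, i1, i2] <- aperm(blk, c(4, 3, 1, 2))
        T4[i3, i4, i2, i1] <- aperm(blk, c(3, 4, 2, 1))
        T4[i4, i3, i2, i1] <- aperm(blk, c(4, 3, 2, 1))
      }
    }
  }
  T4
}
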