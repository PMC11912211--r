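# Variational fitting: metric assembly, solver strategies, the four
# equivalent Coulomb energy expressions, and the sign laws of the
# second-order error functionals.

one_s_system <- function(zeta = 1, alpha = NULL) {
  # one H-like atom with a single s orbital; aux defaults to the exact
  # self-product exponent 2*zeta, so the density is exactly representable
  m <- molecule("H", matrix(0, 1, 3))
  obs <- list(H = orbital_basis("H", list(orbital_shell(0, zeta))))
  aux <- list(H = aux_basis("H", if (is.null(alpha)) 2 * zeta else alpha, 0L))
  iobs <- index_orbital_basis(m, obs)
  iaux <- index_aux_basis(m, aux)
  list(iobs = iobs, iaux = iaux, S = overlap_matrix(iobs),
       G = assemble_G(iaux), eri3 = eri_3c_tensor(iobs, iaux),
       eri4 = eri_4c_tensor(iobs))
}

test_that("the Coulomb metric has unit diagonal, symmetry and PSD spectrum", {
  s1 <- one_s_system()
  expect_equal(s1$G, matrix(1, 1, 1), tolerance = 1e-13)

  for (name in c("h2", "heh+", "h2o_toy")) {
    G <- cached_prep(name, 2)$G
    expect_equal(diag(G), rep(1, nrow(G)), tolerance = 1e-12)
    expect_equal(G, t(G), tolerance = 1e-13)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(ev))
  }

  # duplicated function: fully degenerate 2x2 block with eigenvalues {2, 0}
  dup <- duplicate_first_set(s1$iaux)
  G2 <- assemble_G(dup)
  expect_equal(G2, matrix(c(1, 1, 1, 1), 2, 2), tolerance = 1e-12)
  expect_equal(eigen(G2, symmetric = TRUE, only.values = TRUE)$values,
               c(2, 0), tolerance = 1e-12)
})

test_that("the Coulomb vector is the density contraction of the 3c tensor", {
  s1 <- one_s_system(zeta = 1, alpha = 1)
  P <- matrix(2, 1, 1)
  J <- assemble_J(P, s1$eri3)
  expect_equal(J, 2 * s1$eri3[1, 1, 1], tolerance = 1e-14)
  # independently: the coincident-center closed form with D8 normalization
  oracle <- eri_quadrature_oracle(
    list(gauss_factor("cartesian", c(0, 0, 0), 1, c(0, 0, 0), (2 / pi)^0.75),
         gauss_factor("cartesian", c(0, 0, 0), 1, c(0, 0, 0), (2 / pi)^0.75)),
    gauss_factor("hermite", c(0, 0, 0), 1, c(0, 0, 0),
                 s1$iaux$sets[[1]]$norms[1]))
  expect_equal(J, 2 * oracle, tolerance = 1e-8)

  expect_equal(assemble_J(matrix(0, 1, 1), s1$eri3), 0)
  prep <- cached_prep("h2", 2)
  P1 <- random_density(prep$S, 1, 1)$P
  P2 <- random_density(prep$S, 1, 2)$P
  expect_equal(assemble_J(P1 + P2, prep$eri3),
               assemble_J(P1, prep$eri3) + assemble_J(P2, prep$eri3),
               tolerance = 1e-12)
  expect_error(assemble_J(matrix(0, 2, 2), s1$eri3), "dimensions")
})

test_that("all solver strategies agree where G is well conditioned", {
  expect_equal(solve_fit(diag(2), c(1, 2), "direct")$x, c(1, 2))
  expect_equal(solve_fit(diag(2), c(1, 2), "ted")$x, c(1, 2))
  expect_equal(solve_fit(diag(2), c(1, 2), "minres")$x, c(1, 2),
               tolerance = 1e-12)

  sol <- solve_fit(diag(c(4, 1e-14)), c(2, 1), "ted")
  expect_equal(sol$x, c(0.5, 0))
  expect_equal(sol$diagnostics$dropped, 1L)

  set.seed(5)
  B <- matrix(rnorm(900), 30)
  G <- crossprod(B) + diag(30)          # well-conditioned SPD
  J <- rnorm(30)
  xd <- solve_fit(G, J, "direct")$x
  xt <- solve_fit(G, J, "ted")$x
  sm <- solve_fit(G, J, "minres")
  expect_lt(max(abs(xt - xd)) / max(abs(xd)), 1e-8)
  expect_lt(max(abs(sm$x - xd)) / max(abs(xd)), 1e-8)
  expect_gt(sm$diagnostics$iterations, 0L)
  expect_lt(sm$diagnostics$residual, 1e-9)

  expect_error(solve_fit(diag(c(1, -1)), c(1, 1), "direct"), "ted")
})

test_that("a density inside the auxiliary span is fitted exactly", {
  s1 <- one_s_system()          # aux = AO self-product
  P <- matrix(2, 1, 1)
  J <- assemble_J(P, s1$eri3)
  sol <- solve_fit(s1$G, J, "direct")
  cf <- coulomb_energies(P, sol$x, s1$G, J, s1$eri4, s1$eri3, solver = sol)
  expect_lt(abs(cf$eps2H), 1e-10 * abs(cf$E_H))
  for (E in c(cf$E_a, cf$E_b, cf$E_c, cf$E_d))
    expect_equal(E, cf$E_H, tolerance = 1e-12)

  cmat <- matrix(1, 1, 1)       # the single AO, S-orthonormal by construction
  xf <- exchange_fit(cmat, s1$eri3, s1$G, s1$eri4, S = s1$S, method = "direct")
  expect_lt(abs(xf$eps2F), 1e-10 * abs(xf$E_F))
  expect_equal(xf$pair_fit, xf$pair_exact, tolerance = 1e-12)
})

test_that("the four Coulomb expressions coincide at the unregularized solution", {
  for (name in c("h2", "heh+", "h2o_toy", "dimer_scan")) {
    prep <- cached_prep(name, 2)
    nocc <- prep$sys$electrons %/% 2L
    dens <- random_density(prep$S, nocc, 42)
    J <- assemble_J(dens$P, prep$eri3)
    sol <- solve_fit(prep$G, J, "direct")
    cf <- coulomb_energies(dens$P, sol$x, prep$G, J, prep$eri4, prep$eri3)
    spread <- max(abs(c(cf$E_a - cf$E_b, cf$E_a - cf$E_c, cf$E_a - cf$E_d)))
    expect_lt(spread, 1e-10 * abs(cf$E_H))
    # with TED regularization, E_b = E_c still holds
    solt <- solve_fit(prep$G, J, "ted", tau = 1e-6)
    cft <- coulomb_energies(dens$P, solt$x, prep$G, J, prep$eri4, prep$eri3)
    expect_lt(abs(cft$E_b - cft$E_c), 1e-10 * abs(cft$E_H))
    expect_gte(cft$eps2H, -1e-10 * abs(cft$E_H))
  }
})

test_that("the sign laws hold for every fixture, solver and n", {
  for (name in c("h2", "heh+")) {
    for (n in 2:3) {
      prep <- cached_prep(name, n)
      nocc <- prep$sys$electrons %/% 2L
      for (sd in 1:5) for (meth in c("direct", "ted", "minres")) {
        dens <- random_density(prep$S, nocc, sd)
        fit <- fit_density(prep, dens, meth)
        expect_gte(fit$coulomb$eps2H, -1e-10 * abs(fit$coulomb$E_H))
        expect_lte(fit$exchange$eps2F, 1e-10 * abs(fit$exchange$E_F))
        expect_true(all(fit$checks))
      }
    }
  }
})

test_that("fitted MO-pair repulsions never exceed the exact ones", {
  prep <- cached_prep("h2o_toy", 2)
  for (sd in 1:5) {
    dens <- random_density(prep$S, 5, sd)
    xf <- exchange_fit(dens$c, prep$eri3, prep$G, prep$eri4, S = prep$S)
    expect_true(all(xf$pair_fit <= xf$pair_exact +
                      1e-10 * pmax(abs(xf$pair_exact), 1)))
  }
  expect_error(
    exchange_fit(dens$c * 2, prep$eri3, prep$G, prep$eri4, S = prep$S),
    "orthonormal")
})

test_that("enlarging the auxiliary basis never increases the Coulomb error", {
  sys <- fixture_system("h2")
  small <- generate_genx(sys$obs_map$H, 2)
  # superset: extend the ladder downward by one more even-tempered step
  big <- aux_basis("H", c(small$exponents,
                          min(small$exponents) / small$beta),
                   c(small$L_set, 2L))
  iobs <- index_orbital_basis(sys$mol, sys$obs_map)
  S <- overlap_matrix(iobs)
  eri4 <- eri_4c_tensor(iobs)
  eps <- vapply(list(small, big), function(aux) {
    iaux <- index_aux_basis(sys$mol, list(H = aux))
    G <- assemble_G(iaux)
    eri3 <- eri_3c_tensor(iobs, iaux)
    dens <- random_density(S, 1, 9)
    J <- assemble_J(dens$P, eri3)
    sol <- solve_fit(G, J, "ted")
    coulomb_energies(dens$P, sol$x, G, J, eri4, eri3)$eps2H
  }, numeric(1))
  expect_lte(eps[2], eps[1] + 1e-12 * abs(eps[1]))
})

test_that("fitted energies are invariant under auxiliary renormalization", {
  sys <- fixture_system("heh+")
  aux_map <- lapply(sys$obs_map, generate_genx, n = 2)
  iobs <- index_orbital_basis(sys$mol, sys$obs_map)
  S <- overlap_matrix(iobs)
  eri4 <- eri_4c_tensor(iobs)
  res <- lapply(c("coulomb", "none"), function(nrm) {
    iaux <- index_aux_basis(sys$mol, aux_map, normalization = nrm)
    G <- assemble_G(iaux)
    eri3 <- eri_3c_tensor(iobs, iaux)
    dens <- random_density(S, 1, 4)
    J <- assemble_J(dens$P, eri3)
    sol <- solve_fit(G, J, "ted")
    cf <- coulomb_energies(dens$P, sol$x, G, J, eri4, eri3)
    xf <- exchange_fit(dens$c, eri3, G, eri4, S = S)
    c(cf$E_a, xf$E_F_fit)
  })
  expect_equal(res[[1]], res[[2]], tolerance = 1e-10)
})

test_that("Hermite and Cartesian auxiliary sets span the same fit", {
  # transform every L <= 2 set to its Cartesian-Gaussian equivalents via the
  # exact single-Gaussian Hermite expansion; the fitted energies must agree
  prep <- cached_prep("h2", 2)
  iaux <- prep$iaux
  expect_true(all(vapply(iaux$sets, `[[`, integer(1), "L") <= 2L))
  # a lone Cartesian Gaussian x^i y^j z^k exp(-alpha r^2) expands exactly in
  # the Hermite functions of the same exponent: E coefficients with a
  # zero-exponent dummy partner
  Tblocks <- lapply(seq_along(iaux$sets), function(k) {
    st <- iaux$sets[[k]]
    n <- st$ncomp
    Tb <- matrix(0, n, n)
    E1 <- hermite_expansion(st$L, 0L, st$alpha, 0, 0)
    for (r in seq_len(n)) {
      ijk <- st$comps[r, ]
      for (h in seq_len(n)) {
        tuv <- st$comps[h, ]
        if (all(tuv <= ijk))
          Tb[r, h] <- E1[ijk[1] + 1, 1, tuv[1] + 1] *
            E1[ijk[2] + 1, 1, tuv[2] + 1] *
            E1[ijk[3] + 1, 1, tuv[3] + 1] / st$norms[h]
      }
    }
    Tb
  })
  Tfull <- matrix(0, iaux$n_fun, iaux$n_fun)
  for (k in seq_along(iaux$sets)) {
    idx <- iaux$sets[[k]]$offset + seq_len(iaux$sets[[k]]$ncomp)
    Tfull[idx, idx] <- Tblocks[[k]]
  }
  expect_gt(abs(det(Tfull)), 0)       # invertible: same span
  dens <- random_density(prep$S, 1, 6)
  J <- assemble_J(dens$P, prep$eri3)
  solH <- solve_fit(prep$G, J, "direct")
  cfH <- coulomb_energies(dens$P, solH$x, prep$G, J, prep$eri4, prep$eri3)
  Gc <- Tfull %*% prep$G %*% t(Tfull)
  Jc <- as.vector(Tfull %*% J)
  solC <- solve_fit(Gc, Jc, "direct")
  Ec <- sum(solC$x * Jc) - 0.5 * sum(solC$x * as.vector(Gc %*% solC$x))
  expect_equal(Ec, cfH$E_a, tolerance = 1e-10)
})

test_that("TED keeps the fit variational on a degenerate metric", {
  prep <- cached_prep("h2", 2)
  dup <- duplicate_first_set(prep$iaux)
  G <- assemble_G(dup)
  eri3 <- eri_3c_tensor(prep$iobs, dup)
  expect_error(solve_fit(G, assemble_J(random_density(prep$S, 1, 1)$P, eri3),
                         "direct"), "ted")
  for (sd in 1:3) {
    dens <- random_density(prep$S, 1, sd)
    J <- assemble_J(dens$P, eri3)
    sol <- solve_fit(G, J, "ted")
    expect_gte(sol$diagnostics$dropped, 1L)
    cf <- coulomb_energies(dens$P, sol$x, G, J, prep$eri4, eri3, solver = sol)
    expect_gte(cf$eps2H, -1e-10 * abs(cf$E_H))
  }
})

test_that("error metrics follow their definitions", {
  em <- error_metrics(c(-1, 1))
  expect_equal(em$mse, 0)
  expect_equal(em$mae, 1)
  em2 <- error_metrics(c(0.04, 0.04), gammas = c(5, 7))
  expect_equal(em2$mse, 0.04)
  expect_equal(em2$mae, 0.04)
  expect_equal(em2$sigma, 0)
  expect_equal(em2$gamma_bar, 6)
  expect_error(error_metrics(numeric()), "no deltas")
  set.seed(8)
  for (k in 1:10) {
    d <- rnorm(sample(2:30, 1))
    em3 <- error_metrics(d)
    expect_gte(em3$mae, abs(em3$mse))
    expect_equal(em3$sigma, stats::sd(d))
  }
})
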