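# Fixtures, synthetic densities and the validation pipeline tying
# generator -> integrals -> fitting into reproducible property suites.
#
# The fixture systems are deliberately desk-scale: few atoms, orbital
# angular momentum up to d, exponents of order 0.1..50 bohr^-2.  They
# exercise every bound property of the variational fit (which holds
# pointwise for ANY valid closed-shell density) without an SCF.

# the s/p/d toy orbital basis used across fixtures (on the heavy atom)
.toy_spd_basis <- function(element = "O") {
  orbital_basis(element, list(
    orbital_shell(0L, 50),
    orbital_shell(0L, 0.1),
    orbital_shell(1L, 5),
    orbital_shell(1L, 0.5),
    orbital_shell(2L, 0.8)
  ))
}

#' Deterministic fixture systems
#'
#' Registry of small test systems with fixed geometries and bases:
#' \describe{
#'   \item{`h2`}{two H at 1.4 bohr, two uncontracted s primitives each,
#'     2 electrons.}
#'   \item{`heh+`}{He-H cation at 1.46 bohr, s-only bases, 2 electrons.}
#'   \item{`h2o_toy`}{a bent 3-atom molecule with the s/p/d toy basis on the
#'     central atom and s bases on the hydrogens, 10 electrons.}
#'   \item{`dimer_scan`}{two stacked H2 units (4 atoms), s bases,
#'     4 electrons.}
#'   \item{`random_obs`}{one atom at the origin with a seeded random basis
#'     (l up to 2, exponents in 0.05..500 bohr^-2), 2 electrons.}
#' }
#'
#' @param name Registry name.
#' @param seed Seed for `random_obs` (ignored otherwise).
#' @return List of class `fixture_system` with `name`, `mol`, `obs_map`,
#'   `electrons`.
#' @export
fixture_system <- function(name, seed = 1L) {
  sys <- switch(name,
    h2 = list(
      mol = molecule(c("H", "H"), rbind(c(0, 0, -0.7), c(0, 0, 0.7))),
      obs_map = list(H = orbital_basis("H", list(orbital_shell(0L, 1.3),
                                                 orbital_shell(0L, 0.25)))),
      electrons = 2L),
    `heh+` = list(
      mol = molecule(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, 1.46))),
      obs_map = list(He = orbital_basis("He", list(orbital_shell(0L, 2.0),
                                                   orbital_shell(0L, 0.6))),
                     H = orbital_basis("H", list(orbital_shell(0L, 0.8)))),
      electrons = 2L),
    h2o_toy = list(
      mol = molecule(c("O", "H", "H"),
                     rbind(c(0, 0, 0),
                           c(0, 1.43, 1.11),
                           c(0, -1.43, 1.11))),
      obs_map = list(O = .toy_spd_basis("O"),
                     H = orbital_basis("H", list(orbital_shell(0L, 1.2)))),
      electrons = 10L),
    dimer_scan = list(
      mol = molecule(c("H", "H", "H", "H"),
                     rbind(c(0, 0, -0.7), c(0, 0, 0.7),
                           c(0, 6.0, -0.7), c(0, 6.0, 0.7))),
      obs_map = list(H = orbital_basis("H", list(orbital_shell(0L, 1.3),
                                                 orbital_shell(0L, 0.25)))),
      electrons = 4L),
    random_obs = {
      # emulates the structure of practitioner basis sets: the s range is
      # widest and each higher angular momentum spans a nested, narrower
      # exponent range, so polarization shells sit in the interior
      rs <- .with_seed(seed, {
        lmax <- sample(0:2, 1L)
        lo <- exp(stats::runif(1, log(0.05), log(0.3)))
        hi <- exp(stats::runif(1, log(30), log(500)))
        shells <- list()
        for (l in 0:lmax) {
          lo_l <- lo * 3^l
          hi_l <- hi / 5^l
          if (lo_l >= hi_l) lo_l <- hi_l <- sqrt(lo_l * hi_l)
          nsh <- sample(1:2, 1L) + (l == 0L)
          for (k in seq_len(nsh)) {
            z <- exp(stats::runif(1, log(lo_l), log(hi_l)))
            shells[[length(shells) + 1L]] <- orbital_shell(l, z)
          }
        }
        shells
      })
      list(mol = molecule("C", matrix(0, 1, 3)),
           obs_map = list(C = orbital_basis("C", rs)),
           electrons = 2L)
    },
    stop(sprintf("unknown fixture system '%s'", name))
  )
  structure(c(list(name = name), sys), class = "fixture_system")
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Seeded random closed-shell density
#'
#' Draws a random coefficient matrix, orthonormalizes `n_occ` columns in the
#' overlap metric (symmetric Loewdin orthogonalization of the random
#' columns), and forms `P = 2 c c'`.  The same seed gives bit-identical
#' output; the caller's RNG state is left untouched.
#'
#' @param S Overlap matrix of the basis.
#' @param n_occ Number of doubly occupied orbitals.
#' @param seed Integer seed.
#' @return List of class `density_state` with `P`, `c` (basis x n_occ) and
#'   `n_electrons`.
#' @export
random_density <- function(S, n_occ, seed) {
  n <- nrow(S)
  if (n_occ > n) stop("n_occ exceeds the basis dimension")
  if (n_occ < 1L) stop("n_occ must be >= 1")
  C0 <- .with_seed(seed, matrix(stats::rnorm(n * n_occ), n, n_occ))
  M <- crossprod(C0, S %*% C0)
  eg <- eigen(M, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values))
    stop("random columns nearly dependent in the S metric; change the seed")
  Mi <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  cmat <- C0 %*% Mi
  structure(list(P = 2 * tcrossprod(cmat), c = cmat,
                 n_electrons = 2L * n_occ),
            class = "density_state")
}

#' Assemble all fitting inputs for a fixture system
#'
#' Generates the GEN-Xn auxiliary bases for every element, indexes the
#' bases, and computes the overlap matrix, the Coulomb metric G and the
#' three- and four-center ERI tensors.
#'
#' @param sys A [fixture_system()].
#' @param n Generator parameter (2, 3 or 4).
#' @param L_max Angular cap for the generator.
#' @return List with `sys`, `aux_map`, `iobs`, `iaux`, `S`, `G`, `eri3`,
#'   `eri4`, `counts`.
#' @export
prepare_system <- function(sys, n, L_max = 6L) {
  stopifnot(inherits(sys, "fixture_system"))
  aux_map <- lapply(sys$obs_map, generate_genx, n = n, L_max = L_max)
  iobs <- index_orbital_basis(sys$mol, sys$obs_map)
  iaux <- index_aux_basis(sys$mol, aux_map)
  list(sys = sys, aux_map = aux_map, iobs = iobs, iaux = iaux,
       S = overlap_matrix(iobs), G = assemble_G(iaux),
       eri3 = eri_3c_tensor(iobs, iaux), eri4 = eri_4c_tensor(iobs),
       counts = basis_counts(sys$mol, sys$obs_map, aux_map))
}

#' Fit one density on a prepared system
#'
#' Runs the Coulomb and exchange fits and evaluates the bound checks.
#'
#' @param prep A [prepare_system()] result.
#' @param dens A [random_density()] result (or compatible list with `P`, `c`).
#' @param method Solver method for both fits.
#' @param tau,tol Solver parameters, see [solve_fit()].
#' @return List with `coulomb` ([coulomb_energies()] result), `exchange`
#'   ([exchange_fit()] result), `gamma`, and `checks` (named logicals).
#' @export
fit_density <- function(prep, dens, method = c("ted", "direct", "minres"),
                        tau = 1e-9, tol = 1e-10) {
  method <- match.arg(method)
  J <- assemble_J(dens$P, prep$eri3)
  sol <- solve_fit(prep$G, J, method = method, tau = tau, tol = tol)
  cf <- coulomb_energies(dens$P, sol$x, prep$G, J, prep$eri4, prep$eri3,
                         solver = sol)
  xf <- exchange_fit(dens$c, prep$eri3, prep$G, prep$eri4, S = prep$S,
                     method = method, tau = tau, tol = tol)
  checks <- c(
    coulomb_bound = cf$eps2H >= -1e-10 * abs(cf$E_H),
    exchange_bound = xf$E_F_fit >= xf$E_F - 1e-10 * abs(xf$E_F),
    pair_bounds = all(xf$pair_fit <= xf$pair_exact +
                        1e-10 * pmax(abs(xf$pair_exact), 1))
  )
  list(coulomb = cf, exchange = xf, gamma = prep$counts$gamma,
       checks = checks)
}

#' Run the validation suite
#'
#' For each (system, n, seed) combination: generate the GEN-Xn auxiliary
#' bases, assemble the integrals, fit a seeded random density, and evaluate
#' every variational bound check.  Aggregates suite-level error statistics.
#'
#' @param config List with `systems` (character), `n_values` (subset of
#'   2:4), `solver`, `seeds` (integer vector), and optional `tau`, `tol`,
#'   `L_max`.
#' @return List of class `validation_report` with `records` (one per run),
#'   `metrics` (per n: [error_metrics()] of the Coulomb and exchange
#'   errors), `config`, `all_pass`, `timestamp`.
#' @export
validate_run <- function(config) {
  systems <- config$systems
  if (is.null(systems) || length(systems) == 0L)
    stop("config$systems must list at least one fixture system")
  n_values <- config$n_values %||% c(2L, 3L)
  solver <- config$solver %||% "ted"
  seeds <- config$seeds %||% 1:5
  tau <- config$tau %||% 1e-9
  tol <- config$tol %||% 1e-10
  L_max <- config$L_max %||% 6L
  records <- list()
  for (sname in systems) {
    sys <- fixture_system(sname, seed = config$fixture_seed %||% 1L)
    for (n in n_values) {
      prep <- prepare_system(sys, n, L_max = L_max)
      nocc <- sys$electrons %/% 2L
      for (sd in seeds) {
        dens <- random_density(prep$S, nocc, sd)
        fit <- fit_density(prep, dens, method = solver, tau = tau, tol = tol)
        records[[length(records) + 1L]] <- list(
          system = sname, n = n, seed = sd, gamma = fit$gamma,
          n_basis = prep$counts$n_basis, n_aux = prep$counts$n_aux,
          E_H = fit$coulomb$E_H, eps2H = fit$coulomb$eps2H,
          E_F = fit$exchange$E_F, eps2F = fit$exchange$eps2F,
          solver = fit$coulomb$diagnostics,
          checks = as.list(fit$checks))
      }
    }
  }
  per_n <- lapply(sort(unique(vapply(records, `[[`, integer(1), "n"))),
                  function(n) {
    rs <- Filter(function(r) r$n == n, records)
    list(n = n,
         coulomb = error_metrics(vapply(rs, `[[`, numeric(1), "eps2H"),
                                 vapply(rs, `[[`, numeric(1), "gamma")),
         exchange = error_metrics(vapply(rs, `[[`, numeric(1), "eps2F"),
                                  vapply(rs, `[[`, numeric(1), "gamma")))
  })
  all_pass <- all(vapply(records,
                         function(r) all(unlist(r$checks)), logical(1)))
  structure(list(records = records, metrics = per_n,
                 config = list(systems = systems, n_values = n_values,
                               solver = solver, seeds = seeds, tau = tau,
                               tol = tol, L_max = L_max),
                 all_pass = all_pass,
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d run(s), all bound checks %s\n",
              length(x$records), if (x$all_pass) "PASS" else "FAIL"))
  for (m in x$metrics)
    cat(sprintf("  n=%d: median|eps2H|=%.3e median|eps2F|=%.3e gamma_bar=%.2f\n",
                m$n,
                stats::median(abs(vapply(Filter(function(r) r$n == m$n,
                                                x$records),
                                         `[[`, numeric(1), "eps2H"))),
                stats::median(abs(vapply(Filter(function(r) r$n == m$n,
                                                x$records),
                                         `[[`, numeric(1), "eps2F"))),
                m$coulomb$gamma_bar))
  invisible(x)
}
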