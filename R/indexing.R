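# Flattened per-atom function lists with absolute indices for integral
# assembly.  Orbital functions are Cartesian Gaussians normalized to unit
# self-overlap per component; auxiliary functions are primitive Hermite
# Gaussians normalized (by default) to unit Coulomb self-repulsion, which
# conditions the Coulomb metric G (unit diagonal).  Fitted energies are
# invariant under any function rescaling, so the choice is a conditioning
# device, not physics.

#' Index the orbital basis of a molecule
#'
#' Builds the flat list of contracted Cartesian orbital functions used by the
#' integral engine.  Cartesian components are ordered descending-lexicographic
#' in (i, j, k) with i taking precedence.  Primitives are normalized to unit
#' self-overlap per component and each contracted function is renormalized to
#' unit self-overlap.
#'
#' @param mol A [molecule()].
#' @param obs_map Named list: element symbol -> [orbital_basis()].
#' @return An object of class `indexed_obs`: list of shells (center, l,
#'   exponents, contraction coefficients with normalization folded in,
#'   per-component scale factors, absolute offset) plus `n_fun`.
#' @export
index_orbital_basis <- function(mol, obs_map) {
  stopifnot(inherits(mol, "molecule"))
  shells <- list()
  off <- 0L
  for (ia in seq_along(mol$symbols)) {
    obs <- obs_map[[mol$symbols[ia]]]
    if (is.null(obs))
      stop(sprintf("no orbital basis for element '%s'", mol$symbols[ia]))
    for (sh in obs$shells) {
      if (sh$l > 2L)
        stop("orbital angular momentum above d (l = 2) is not supported")
      z <- sh$exponents
      # primitive normalization, component-independent part:
      # (2 zeta / pi)^(3/4) (4 zeta)^(l/2); the 1/sqrt((2i-1)!!(2j-1)!!(2k-1)!!)
      # part is exponent-independent and applied per component below
      cpr <- sh$coefficients * (2 * z / pi)^0.75 * (4 * z)^(sh$l / 2)
      # contracted self-overlap (df-free part); renormalize to unity
      ps <- outer(z, z, "+")
      s0 <- sum(outer(cpr, cpr) * (pi / ps)^1.5 / (2 * ps)^sh$l)
      cpr <- cpr / sqrt(s0)
      comps <- .cart_components(sh$l)
      cscale <- 1 / sqrt(.dfact(comps[, 1]) * .dfact(comps[, 2]) *
                           .dfact(comps[, 3]))
      shells[[length(shells) + 1L]] <- list(
        atom = ia, center = mol$coords[ia, ], l = sh$l, zeta = z,
        coef = cpr, comps = comps, cscale = cscale, offset = off,
        ncomp = nrow(comps))
      off <- off + nrow(comps)
    }
  }
  structure(list(shells = shells, n_fun = off), class = "indexed_obs")
}

#' Index the auxiliary basis of a molecule
#'
#' Builds the flat list of primitive Hermite auxiliary functions.  Within a
#' shared-exponent set the Hermite triples (t, u, v) are enumerated by total
#' degree, descending-lexicographic within each degree.
#'
#' @param mol A [molecule()].
#' @param aux_map Named list: element symbol -> [aux_basis()].
#' @param normalization `"coulomb"` (unit self-repulsion, the default),
#'   `"overlap"` (unit self-overlap) or `"none"` (raw Hermite derivatives).
#' @return An object of class `indexed_aux`: list of sets (center, alpha, L,
#'   Hermite triples, per-function norms, absolute offset) plus `n_fun`.
#' @export
index_aux_basis <- function(mol, aux_map,
                            normalization = c("coulomb", "overlap", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(mol, "molecule"))
  sets <- list()
  off <- 0L
  for (ia in seq_along(mol$symbols)) {
    aux <- aux_map[[mol$symbols[ia]]]
    if (is.null(aux))
      stop(sprintf("no auxiliary basis for element '%s'", mol$symbols[ia]))
    for (k in seq_along(aux$exponents)) {
      a <- aux$exponents[k]
      L <- aux$L_set[k]
      comps <- .hermite_components(L)
      norms <- switch(normalization,
        coulomb = 1 / sqrt(.hermite_self_repulsion(a, comps)),
        overlap = 1 / sqrt(.hermite_self_overlap(a, comps)),
        none = rep(1, nrow(comps)))
      sets[[length(sets) + 1L]] <- list(
        atom = ia, center = mol$coords[ia, ], alpha = a, L = L,
        comps = comps, norms = norms, offset = off, ncomp = nrow(comps))
      off <- off + nrow(comps)
    }
  }
  structure(list(sets = sets, n_fun = off), class = "indexed_aux")
}

# Coulomb self-repulsion <Lambda_tuv || Lambda_tuv> of an unnormalized
# Hermite Gaussian of exponent a:
# (-1)^(t+u+v) 2 pi^(5/2) / (a^2 sqrt(2a)) R_{2t,2u,2v}(a/2, 0)
.hermite_self_repulsion <- function(a, comps) {
  L <- max(rowSums(comps))
  R <- .r_table(2L * L, 2L * L, 2L * L, 2L * L, a / 2, c(0, 0, 0))
  pref <- 2 * pi^2.5 / (a * a * sqrt(2 * a))
  vapply(seq_len(nrow(comps)), function(r) {
    t <- comps[r, 1]; u <- comps[r, 2]; v <- comps[r, 3]
    (-1)^(t + u + v) * pref * R[2L * t + 1L, 2L * u + 1L, 2L * v + 1L]
  }, numeric(1))
}

# Self-overlap of an unnormalized Hermite Gaussian: per dimension
# (pi/(2a))^(1/2) (a/2)^t (2t)!/t!
.hermite_self_overlap <- function(a, comps) {
  dim1 <- function(t) sqrt(pi / (2 * a)) * (a / 2)^t * factorial(2 * t) /
    factorial(t)
  dim1(comps[, 1]) * dim1(comps[, 2]) * dim1(comps[, 3])
}
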