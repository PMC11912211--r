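# GEN-Xn automatic auxiliary basis generation: an even-tempered exponent
# ladder seeded at the polarization self-product, with set angularities
# assigned from the per-l orbital product-exponent ranges.

#' Exponent profile of an orbital basis
#'
#' Flattens all contractions and records, for every angular momentum l
#' present, the range of primitive exponents, plus the global range and the
#' largest l.
#'
#' @param obs An [orbital_basis()].
#' @return A list of class `obs_profile` with `l_max`, `ranges` (named list
#'   `l -> c(min, max)`) and `global` (`c(min, max)`).
#' @export
obs_profile <- function(obs) {
  stopifnot(inherits(obs, "orbital_basis"))
  ls <- vapply(obs$shells, `[[`, integer(1), "l")
  ranges <- list()
  for (l in sort(unique(ls))) {
    ex <- unlist(lapply(obs$shells[ls == l], `[[`, "exponents"))
    ranges[[as.character(l)]] <- c(min(ex), max(ex))
  }
  allex <- unlist(lapply(obs$shells, `[[`, "exponents"))
  lmax <- max(ls)
  structure(list(l_max = lmax, ranges = ranges,
                 global = c(min(allex), max(allex)),
                 lmax_exponents = unlist(lapply(obs$shells[ls == lmax],
                                                `[[`, "exponents"))),
            class = "obs_profile")
}

#' Even-tempered progression factor
#'
#' The generator's initialization rule: beta = 6 - n.  Larger n gives a
#' denser exponent ladder and therefore more auxiliary functions.
#'
#' @param n Generator parameter, one of 2, 3, 4.
#' @return beta (4, 3 or 2).
#' @export
scaling_factor <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || !(n %in% 2:4))
    stop("n must be 2, 3 or 4")
  6 - n
}

#' Start exponent for the even-tempered ladder
#'
#' The ladder is seeded at the self-product of the highest-angular-momentum
#' (usually polarization) functions: alpha0 = 2 zeta for a single primitive.
#' With several primitives at l_max, alpha0 = 2 x their geometric mean,
#' which reduces to the single-primitive rule and is scale-covariant.
#'
#' @param profile An [obs_profile()].
#' @return alpha0 (bohr^-2).
#' @export
start_exponent <- function(profile) {
  stopifnot(inherits(profile, "obs_profile"))
  # geometric mean over all l_max primitives; a single primitive is used
  # exactly so that alpha0 hits a zero-width polarization product range
  ex <- profile$lmax_exponents
  if (length(ex) == 1L) 2 * ex else 2 * exp(mean(log(ex)))
}

#' Even-tempered exponent ladder
#'
#' Generates `alpha0 * beta^k` for consecutive integers k, extended upward
#' until the first value >= `hi` (inclusive) and downward until the first
#' value <= `lo` (inclusive) -- the "fuzzy bounds": the extreme ladder values
#' may overshoot the product range.  Values are computed as explicit powers
#' (no cumulative multiplication drift), returned in descending order.
#'
#' @param alpha0 Start exponent, must lie in `[lo, hi]`.
#' @param beta Progression factor (> 1).
#' @param lo,hi Product-range bounds (`2 zeta_min`, `2 zeta_max`).
#' @return Descending numeric vector of exponents containing `alpha0`.
#' @export
exponent_ladder <- function(alpha0, beta, lo, hi) {
  if (!is.finite(beta) || beta <= 1) stop("beta must be > 1")
  if (lo > hi) stop("lo must be <= hi")
  if (alpha0 < lo || alpha0 > hi) stop("alpha0 must lie within [lo, hi]")
  k_up <- 0L
  while (alpha0 * beta^k_up < hi) k_up <- k_up + 1L
  k_dn <- 0L
  while (alpha0 * beta^(-k_dn) > lo) k_dn <- k_dn + 1L
  alpha0 * beta^seq.int(k_up, -k_dn)
}

#' Orbital product-exponent ranges
#'
#' For each angular momentum l present in the basis, the range of same-l
#' Gaussian product exponents `[2 zeta_min^l, 2 zeta_max^l]` (closed).
#'
#' @param profile An [obs_profile()].
#' @return Named list `l -> c(alpha_min, alpha_max)`.
#' @export
product_ranges <- function(profile) {
  stopifnot(inherits(profile, "obs_profile"))
  lapply(profile$ranges, function(r) 2 * r)
}

#' Assign set angularities to an exponent ladder
#'
#' Base rule: a ladder exponent lying inside the product range of angular
#' momentum l gets angularity `min(2l, L_max)`; the largest such value over
#' all matching l wins, default 0 (an s set).  Interval membership is
#' inclusive at both endpoints.  A coverage repair then guarantees, for every
#' l with target `L* = min(2l, L_max)`, that some set with angularity >= L*
#' sits at or below `2 zeta_min^l` and some at or above `2 zeta_max^l`, by
#' promoting the nearest bracketing ladder exponents when a product range is
#' narrower than one ladder step.
#'
#' @param ladder Descending exponents from [exponent_ladder()].
#' @param ranges Product ranges from [product_ranges()].
#' @param L_max Angular cap (even, <= 6; default 6).
#' @return Integer vector of even set angularities, parallel to `ladder`.
#' @export
assign_angularities <- function(ladder, ranges, L_max = 6L) {
  L_max <- as.integer(L_max)
  if (L_max %% 2L != 0L || L_max < 0L || L_max > 6L)
    stop("L_max must be even and in 0..6")
  if (is.unsorted(rev(ladder), strictly = TRUE))
    stop("ladder must be strictly descending")
  L <- integer(length(ladder))
  for (lch in names(ranges)) {
    l <- as.integer(lch)
    r <- ranges[[lch]]
    inside <- ladder >= r[1] & ladder <= r[2]
    L[inside] <- pmax(L[inside], min(2L * l, L_max))
  }
  # coverage repair: every target angularity must bracket its product range
  for (lch in names(ranges)) {
    l <- as.integer(lch)
    tgt <- min(2L * l, L_max)
    r <- ranges[[lch]]
    below <- which(ladder <= r[1])
    if (length(below) && !any(L[below] >= tgt))
      L[below[1]] <- tgt                      # largest exponent at/below
    above <- which(ladder >= r[2])
    if (length(above) && !any(L[above] >= tgt))
      L[above[length(above)]] <- tgt          # smallest exponent at/above
  }
  L
}

#' Generate a GEN-Xn auxiliary basis
#'
#' Composes the profile, scaling factor, start exponent, even-tempered
#' ladder, product ranges and angularity assignment into the atomic
#' shared-exponent Hermite auxiliary basis.
#'
#' @param obs An [orbital_basis()].
#' @param n Generator parameter, 2, 3 or 4.
#' @param L_max Angular cap (even, default 6).
#' @return An [aux_basis()], sets ordered highest to lowest exponent.
#' @export
generate_genx <- function(obs, n, L_max = 6L) {
  stopifnot(inherits(obs, "orbital_basis"))
  prof <- obs_profile(obs)
  beta <- scaling_factor(n)
  alpha0 <- start_exponent(prof)
  lad <- exponent_ladder(alpha0, beta, 2 * prof$global[1], 2 * prof$global[2])
  Ls <- assign_angularities(lad, product_ranges(prof), L_max)
  aux_basis(obs$element, lad, Ls, n = n, beta = beta, alpha0 = alpha0,
            l_max = L_max)
}

#' Basis and auxiliary function counts of a molecule
#'
#' Counts Cartesian orbital functions (a shell of angular momentum l has
#' (l+1)(l+2)/2 components) and Hermite auxiliary functions, and their ratio
#' gamma = N_aux / N_basis, the cost prefactor of three-center algorithms.
#'
#' @param mol A [molecule()].
#' @param obs_map Named list: element symbol -> [orbital_basis()].
#' @param aux_map Named list: element symbol -> [aux_basis()].
#' @return List with `n_basis`, `n_aux`, `gamma`.
#' @export
basis_counts <- function(mol, obs_map, aux_map) {
  stopifnot(inherits(mol, "molecule"))
  nb <- 0L; na <- 0L
  for (sym in mol$symbols) {
    obs <- obs_map[[sym]]
    aux <- aux_map[[sym]]
    if (is.null(obs) || is.null(aux))
      stop(sprintf("no basis registered for element '%s'", sym))
    nb <- nb + sum(vapply(obs$shells, function(sh) {
      ((sh$l + 1L) * (sh$l + 2L)) %/% 2L
    }, integer(1)))
    na <- na + sum(set_function_count(aux$L_set))
  }
  list(n_basis = nb, n_aux = na, gamma = na / nb)
}
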