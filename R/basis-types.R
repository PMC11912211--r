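# Elements H-Kr (Z = 1..36); heavier symbols are accepted with a warning.
.elements_hkr <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

.shell_labels <- c("s", "p", "d", "f", "g", "h", "i")

#' Contracted Gaussian shell
#'
#' A contracted shell of primitive Cartesian Gaussians sharing one angular
#' momentum index `l`.  Primitives are stored in descending exponent order;
#' exponents are in bohr^-2.
#'
#' @param l Angular momentum index (integer, 0 <= l <= 6).
#' @param exponents Numeric vector of primitive exponents (> 0, bohr^-2).
#' @param coefficients Contraction coefficients, same length as `exponents`.
#'   Defaults to an uncontracted shell (all 1).
#' @return An object of class `orbital_shell`.
#' @export
orbital_shell <- function(l, exponents, coefficients = rep(1, length(exponents))) {
  l <- as.integer(l)
  if (length(l) != 1L || is.na(l) || l < 0L || l > 6L)
    stop("angular momentum index l must be a single integer in 0..6")
  exponents <- as.numeric(exponents)
  coefficients <- as.numeric(coefficients)
  if (length(exponents) < 1L)
    stop("a shell needs at least one primitive")
  if (any(!is.finite(exponents)) || any(exponents <= 0))
    stop("primitive exponents must be finite and > 0")
  if (any(!is.finite(coefficients)))
    stop("contraction coefficients must be finite")
  if (length(coefficients) != length(exponents))
    stop("coefficients and exponents must have the same length")
  ord <- order(exponents, decreasing = TRUE)
  structure(
    list(l = l, exponents = exponents[ord], coefficients = coefficients[ord]),
    class = "orbital_shell"
  )
}

#' Atomic orbital basis set
#'
#' The contracted Gaussian orbital basis (OBS) of one element.
#'
#' @param element Element symbol (H-Kr expected; others accepted with warning).
#' @param shells List of [orbital_shell()] objects (at least one).
#' @return An object of class `orbital_basis`.
#' @export
orbital_basis <- function(element, shells) {
  element <- as.character(element)
  if (length(element) != 1L || !nzchar(element))
    stop("element symbol required")
  if (!(element %in% .elements_hkr))
    warning(sprintf("element '%s' is outside H-Kr; accepted as-is", element))
  if (!is.list(shells) || length(shells) < 1L)
    stop("at least one shell required")
  ok <- vapply(shells, inherits, logical(1), what = "orbital_shell")
  if (!all(ok)) stop("shells must all be orbital_shell objects")
  structure(list(element = element, shells = shells), class = "orbital_basis")
}

#' @export
print.orbital_basis <- function(x, ...) {
  cat(sprintf("<orbital_basis> %s: %d shell(s)\n", x$element, length(x$shells)))
  for (sh in x$shells) {
    cat(sprintf("  %s  zeta = %s\n", .shell_labels[sh$l + 1L],
                paste(format(sh$exponents), collapse = ", ")))
  }
  invisible(x)
}

#' Number of Hermite functions in a shared-exponent set
#'
#' A shared-exponent auxiliary set with highest (even) angular index `L`
#' contains all primitive Hermite Gaussians with total index 0..L on one
#' exponent, i.e. (L+1)(L+2)(L+3)/6 functions (a d set: 1 s + 3 p + 6 d = 10).
#'
#' @param L Highest angular index of the set (integer, 0 <= L <= 6).
#' @return Integer function count.
#' @export
set_function_count <- function(L) {
  L <- as.integer(L)
  if (any(is.na(L)) || any(L < 0L) || any(L > 6L))
    stop("set angularity L must be in 0..6")
  ((L + 1L) * (L + 2L) * (L + 3L)) %/% 6L
}

#' Shared-exponent Hermite auxiliary basis of one element
#'
#' An ordered list of shared-exponent primitive Hermite Gaussian sets:
#' exponents strictly descending in a geometric progression with ratio `beta`,
#' each carrying an even set angularity `L_set`.
#'
#' @param element Element symbol.
#' @param exponents Set exponents, strictly descending (bohr^-2).
#' @param L_set Even set angularities (0..6), same length as `exponents`.
#' @param n Generator parameter n (2, 3 or 4), or NA for hand-built sets.
#' @param beta Even-tempered progression factor; consecutive exponent ratios
#'   must equal `beta` to 1e-12 relative.  NA skips the check (single set).
#' @param alpha0 Generator start exponent (metadata).
#' @param l_max Angular cap used at generation (metadata).
#' @return An object of class `aux_basis`.
#' @export
aux_basis <- function(element, exponents, L_set, n = NA_integer_,
                      beta = NA_real_, alpha0 = NA_real_, l_max = 6L) {
  exponents <- as.numeric(exponents)
  L_set <- as.integer(L_set)
  if (length(exponents) < 1L) stop("at least one set required")
  if (length(L_set) != length(exponents))
    stop("L_set and exponents must have the same length")
  if (any(exponents <= 0) || any(!is.finite(exponents)))
    stop("set exponents must be finite and > 0")
  if (any(diff(exponents) >= 0))
    stop("set exponents must be strictly descending")
  if (any(L_set %% 2L != 0L) || any(L_set < 0L) || any(L_set > 6L))
    stop("set angularities must be even and in 0..6")
  if (!is.na(beta) && length(exponents) > 1L) {
    ratio <- exponents[-length(exponents)] / exponents[-1L]
    if (any(abs(ratio - beta) > 1e-12 * beta))
      stop("consecutive exponent ratios must equal beta to 1e-12 relative")
  }
  structure(
    list(element = as.character(element), exponents = exponents, L_set = L_set,
         n = as.integer(n), beta = as.numeric(beta),
         alpha0 = as.numeric(alpha0), l_max = as.integer(l_max)),
    class = "aux_basis"
  )
}

#' @export
print.aux_basis <- function(x, ...) {
  lab <- if (is.na(x$n)) "custom" else sprintf("GEN-X%d", x$n)
  cat(sprintf("<aux_basis> %s %s: %d set(s), %d functions\n", x$element, lab,
              length(x$exponents), sum(set_function_count(x$L_set))))
  for (i in seq_along(x$exponents)) {
    cat(sprintf("  %2d  L=%d  alpha = %s\n", i, x$L_set[i], format(x$exponents[i])))
  }
  invisible(x)
}

#' Molecular geometry
#'
#' @param symbols Character vector of element symbols.
#' @param coords Numeric matrix (n_atoms x 3) of Cartesian positions in bohr.
#' @return An object of class `molecule`.
#' @export
molecule <- function(symbols, coords) {
  symbols <- as.character(symbols)
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (length(symbols) < 1L) stop("at least one atom required")
  if (nrow(coords) != length(symbols))
    stop("coords must have one row per atom")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (length(symbols) > 1L) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    if (any(d == 0)) stop("two atoms exactly coincide")
  }
  structure(list(symbols = symbols, coords = coords), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atom(s) (bohr)\n", length(x$symbols)))
  for (i in seq_along(x$symbols))
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$symbols[i],
                x$coords[i, 1], x$coords[i, 2], x$coords[i, 3]))
  invisible(x)
}

# Angstrom -> bohr conversion used at the XYZ boundary; everything internal
# is bohr (Gaussian exponents are conventionally bohr^-2).
.ang2bohr <- 1.8897261254578281
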