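# Text I/O for orbital bases, auxiliary bases and geometries.
# All numbers are written with 17 significant digits so that a
# write -> parse round trip is the identity up to binary representation.

.fmt_num <- function(x) sprintf("%.17g", x)

.parse_num <- function(s, what, line = NA) {
  v <- suppressWarnings(as.numeric(gsub("[dD]", "e", s)))
  if (any(is.na(v)))
    stop(sprintf("cannot parse %s%s: '%s'", what,
                 if (is.na(line)) "" else sprintf(" at line %d", line),
                 paste(s[is.na(v)], collapse = "', '")))
  v
}

#' Parse an atomic orbital basis set
#'
#' Reads one element's contracted Gaussian basis from text.  The
#' `gaussian_text` dialect is the common element-header / shell-label /
#' primitive-lines layout:
#'
#' ```
#' O 0
#' S   2   1.00
#'    50.0    1.0
#'     0.1    0.4
#' D   1   1.00
#'     0.8    1.0
#' ****
#' ```
#'
#' The `json` dialect is `{element, shells: [{l, primitives:
#' [{exponent, coefficient}]}]}`.
#'
#' @param text Basis definition text (single string or character vector of lines).
#' @param dialect `"gaussian_text"` or `"json"`.
#' @return An [orbital_basis()].
#' @export
parse_orbital_basis <- function(text, dialect = c("gaussian_text", "json")) {
  dialect <- match.arg(dialect)
  if (length(text) == 0L || !any(nzchar(trimws(text))))
    stop("empty basis text")
  if (dialect == "json") {
    obj <- jsonlite::fromJSON(paste(text, collapse = "\n"), simplifyVector = FALSE)
    if (is.null(obj$element) || is.null(obj$shells))
      stop("JSON basis must have 'element' and 'shells'")
    shells <- lapply(obj$shells, function(sh) {
      prims <- sh$primitives
      if (is.null(prims) || length(prims) == 0L)
        stop("shell without primitives in JSON basis")
      ex <- vapply(prims, function(p) as.numeric(p$exponent), numeric(1))
      co <- vapply(prims, function(p) {
        if (is.null(p$coefficient)) 1 else as.numeric(p$coefficient)
      }, numeric(1))
      orbital_shell(sh$l, ex, co)
    })
    return(orbital_basis(obj$element, shells))
  }
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*(!|#)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty basis text")
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  i <- 1L
  # element header: symbol, optionally followed by a charge/flag field
  head <- toks[[i]]
  element <- head[[1]]
  if (grepl("^[0-9.+-]", element))
    stop(sprintf("expected element header at line %d", idx[i]))
  i <- i + 1L
  shells <- list()
  while (i <= length(toks)) {
    t <- toks[[i]]
    if (identical(t[[1]], "****")) break
    lab <- tolower(t[[1]])
    l <- match(lab, .shell_labels) - 1L
    if (is.na(l))
      stop(sprintf("unknown shell label '%s' at line %d", t[[1]], idx[i]))
    if (length(t) < 2L)
      stop(sprintf("shell header needs a primitive count at line %d", idx[i]))
    nprim <- as.integer(.parse_num(t[[2]], "primitive count", idx[i]))
    if (is.na(nprim) || nprim < 1L)
      stop(sprintf("bad primitive count at line %d", idx[i]))
    i <- i + 1L
    if (i + nprim - 1L > length(toks))
      stop(sprintf("shell at line %d declares %d primitives but text ends",
                   idx[i - 1L], nprim))
    ex <- numeric(nprim); co <- numeric(nprim)
    for (k in seq_len(nprim)) {
      pt <- toks[[i]]
      if (length(pt) < 1L)
        stop(sprintf("missing primitive line at line %d", idx[i]))
      ex[k] <- .parse_num(pt[[1]], "exponent", idx[i])
      co[k] <- if (length(pt) >= 2L) .parse_num(pt[[2]], "coefficient", idx[i]) else 1
      i <- i + 1L
    }
    if (any(ex <= 0))
      stop(sprintf("non-positive exponent in shell ending at line %d", idx[i - 1L]))
    shells[[length(shells) + 1L]] <- orbital_shell(l, ex, co)
  }
  if (length(shells) == 0L) stop("no shells found in basis text")
  orbital_basis(element, shells)
}

#' Write an atomic orbital basis set
#'
#' Inverse of [parse_orbital_basis()]; both dialects round-trip.
#'
#' @param obs An [orbital_basis()].
#' @param dialect `"gaussian_text"` or `"json"`.
#' @return A single string.
#' @export
write_orbital_basis <- function(obs, dialect = c("gaussian_text", "json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(obs, "orbital_basis"))
  if (dialect == "json") {
    obj <- list(
      element = obs$element,
      shells = lapply(obs$shells, function(sh) {
        list(l = sh$l, primitives = lapply(seq_along(sh$exponents), function(k) {
          list(exponent = sh$exponents[k], coefficient = sh$coefficients[k])
        }))
      })
    )
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))))
  }
  out <- c(sprintf("%s 0", obs$element))
  for (sh in obs$shells) {
    out <- c(out, sprintf("%s   %d   1.00", toupper(.shell_labels[sh$l + 1L]),
                          length(sh$exponents)))
    out <- c(out, sprintf("   %s   %s", .fmt_num(sh$exponents),
                          .fmt_num(sh$coefficients)))
  }
  paste(c(out, "****", ""), collapse = "\n")
}

#' Write a shared-exponent auxiliary basis
#'
#' The `demon_text` dialect is one header line
#' `ELEMENT GEN-Xn beta=B alpha0=A lmax=L` followed by one line
#' `k L_set alpha` per set, in descending-exponent order.  The `json`
#' dialect mirrors the same fields.
#'
#' @param aux An [aux_basis()].
#' @param dialect `"demon_text"` or `"json"`.
#' @return A single string, parseable by [parse_aux_basis()].
#' @export
write_aux_basis <- function(aux, dialect = c("demon_text", "json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(aux, "aux_basis"))
  if (dialect == "json") {
    obj <- list(element = aux$element, n = aux$n, beta = aux$beta,
                alpha0 = aux$alpha0, lmax = aux$l_max,
                sets = lapply(seq_along(aux$exponents), function(k) {
                  list(index = k, L_set = aux$L_set[k], alpha = aux$exponents[k])
                }))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                         na = "null")))
  }
  label <- if (is.na(aux$n)) "CUSTOM" else sprintf("GEN-X%d", aux$n)
  hdr <- sprintf("%s %s beta=%s alpha0=%s lmax=%s", aux$element, label,
                 .fmt_num(aux$beta), .fmt_num(aux$alpha0),
                 if (is.na(aux$l_max)) "NA" else aux$l_max)
  body <- sprintf("%d %d %s", seq_along(aux$exponents), aux$L_set,
                  .fmt_num(aux$exponents))
  paste(c(hdr, body, ""), collapse = "\n")
}

#' Parse a shared-exponent auxiliary basis
#'
#' @param text Text produced by [write_aux_basis()] (either dialect).
#' @param dialect `"demon_text"` or `"json"`.
#' @return An [aux_basis()].
#' @export
parse_aux_basis <- function(text, dialect = c("demon_text", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    obj <- jsonlite::fromJSON(paste(text, collapse = "\n"), simplifyVector = FALSE)
    ex <- vapply(obj$sets, function(s) as.numeric(s$alpha), numeric(1))
    Ls <- vapply(obj$sets, function(s) as.integer(s$L_set), integer(1))
    nn <- if (is.null(obj$n)) NA_integer_ else as.integer(obj$n)
    bt <- if (is.null(obj$beta)) NA_real_ else as.numeric(obj$beta)
    a0 <- if (is.null(obj$alpha0)) NA_real_ else as.numeric(obj$alpha0)
    lm <- if (is.null(obj$lmax)) NA_integer_ else as.integer(obj$lmax)
    return(aux_basis(obj$element, ex, Ls, n = nn, beta = bt, alpha0 = a0,
                     l_max = lm))
  }
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("auxiliary basis text needs a header and sets")
  h <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  element <- h[[1]]
  nn <- NA_integer_
  if (grepl("^GEN-X[0-9]$", h[[2]])) nn <- as.integer(sub("GEN-X", "", h[[2]]))
  kv <- h[grepl("=", h)]
  getv <- function(key, default = NA_real_) {
    hit <- kv[startsWith(kv, paste0(key, "="))]
    if (length(hit) == 0L) return(default)
    v <- sub(".*=", "", hit[[1]])
    if (identical(v, "NA")) default else as.numeric(v)
  }
  beta <- getv("beta"); alpha0 <- getv("alpha0"); lmax <- getv("lmax")
  rows <- lapply(lines[-1], function(s) strsplit(trimws(s), "\\s+")[[1]])
  bad <- which(vapply(rows, length, integer(1)) < 3L)
  if (length(bad))
    stop(sprintf("malformed set line %d: expected 'index L_set alpha'", bad[1] + 1L))
  Ls <- vapply(rows, function(r) as.integer(r[[2]]), integer(1))
  ex <- vapply(rows, function(r) .parse_num(r[[3]], "set exponent"), numeric(1))
  aux_basis(element, ex, Ls, n = nn, beta = beta, alpha0 = alpha0,
            l_max = if (is.na(lmax)) NA_integer_ else as.integer(lmax))
}

#' Parse an XYZ geometry
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `symbol x y z` line per atom.  Positions are stored internally in bohr;
#' angstrom input is converted (1 Angstrom = 1.8897261254578281 bohr).
#'
#' @param text XYZ text (string or lines).
#' @param units `"angstrom"` or `"bohr"` for the coordinates in `text`.
#' @return A [molecule()] with coordinates in bohr.
#' @export
parse_molecule <- function(text, units = c("angstrom", "bohr")) {
  units <- match.arg(units)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 1L) stop("empty XYZ text")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) stop("first XYZ line must be the atom count")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop(sprintf("XYZ header declares %d atoms but body has %d", n, length(body)))
  toks <- lapply(body, function(s) strsplit(trimws(s), "\\s+")[[1]])
  bad <- which(vapply(toks, length, integer(1)) < 4L)
  if (length(bad)) stop(sprintf("malformed XYZ atom line %d", bad[1] + 2L))
  sym <- vapply(toks, `[[`, character(1), 1L)
  xyz <- t(vapply(toks, function(t) .parse_num(t[2:4], "coordinate"), numeric(3)))
  if (units == "angstrom") xyz <- xyz * .ang2bohr
  molecule(sym, xyz)
}

#' Write an XYZ geometry
#'
#' @param mol A [molecule()] (coordinates in bohr).
#' @param units Output units, `"angstrom"` or `"bohr"`.
#' @param comment Comment line content.
#' @return XYZ text as a single string.
#' @export
write_molecule <- function(mol, units = c("angstrom", "bohr"), comment = "") {
  units <- match.arg(units)
  stopifnot(inherits(mol, "molecule"))
  xyz <- mol$coords
  if (units == "angstrom") xyz <- xyz / .ang2bohr
  lines <- c(sprintf("%d", length(mol$symbols)), comment,
             sprintf("%s %s %s %s", mol$symbols, .fmt_num(xyz[, 1]),
                     .fmt_num(xyz[, 2]), .fmt_num(xyz[, 3])))
  paste(c(lines, ""), collapse = "\n")
}
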