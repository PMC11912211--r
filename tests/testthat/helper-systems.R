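# Shared fixtures: the s/p/d toy basis used in the generator worked example,
# and a cache of prepared fixture systems so the integral tensors are
# computed once per test run.

toy_spd_obs <- function(element = "O") {
  orbital_basis(element, list(
    orbital_shell(0L, 50),
    orbital_shell(0L, 0.1),
    orbital_shell(1L, 5),
    orbital_shell(1L, 0.5),
    orbital_shell(2L, 0.8)
  ))
}

.prep_cache <- new.env(parent = emptyenv())

cached_prep <- function(name, n) {
  key <- sprintf("%s_%d", name, n)
  if (!exists(key, envir = .prep_cache))
    assign(key, prepare_system(fixture_system(name), n), envir = .prep_cache)
  get(key, envir = .prep_cache)
}

# a deliberately degenerate indexed auxiliary basis: the first set duplicated
duplicate_first_set <- function(iaux) {
  s <- iaux$sets[[1]]
  s$offset <- iaux$n_fun
  iaux$sets[[length(iaux$sets) + 1L]] <- s
  iaux$n_fun <- iaux$n_fun + s$ncomp
  iaux
}

# random single-atom orbital basis within stated exponent bounds
random_obs_basis <- function(seed) {
  fixture_system("random_obs", seed = seed)$obs_map$C
}
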