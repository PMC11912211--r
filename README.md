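# auxgen

Automatic generation of even-tempered, shared-exponent primitive Hermite
Gaussian **auxiliary basis sets** (the GEN-Xn family, n = 2, 3, 4) from an
atomic orbital basis, plus a self-contained **variational density-fitting**
engine that verifies the variational error bounds of Coulomb and
Fock-exchange fitting on desk-scale systems.

## Who this is for

Quantum-chemistry method developers and students who need (a) a transparent
reference implementation of automatic auxiliary-basis construction for
density fitting / resolution-of-the-identity methods, and (b) a verifiable,
oracle-checked playground for the variational structure of the fit —
without depending on a full SCF code.

## The method in brief

Density fitting expands the electron density `ρ` (and, for exchange, each
occupied orbital-pair density `ρ_ij`) in an auxiliary basis under the
Coulomb metric `⟨f‖g⟩ = ∬ f(r₁)g(r₂)/r₁₂ dr₁dr₂`.  Positive
semidefiniteness of that metric makes the fit variational:

* Coulomb: `ε₂ᴴ = ½⟨ρ−ρ̃‖ρ−ρ̃⟩ ≥ 0`, so the fitted repulsion
  `Ẽ_H = x̄·J − ½x̄ᵀGx̄` never exceeds the exact `E_H`;
* exchange: `ε₂ᶠ = −Σ_ij ⟨ρ_ij−ρ̃_ij‖ρ_ij−ρ̃_ij⟩ ≤ 0`, so the fitted
  exchange `Ẽ_F` never falls below the exact `E_F`.

Here `G_kl = ⟨k̄‖l̄⟩` is the two-center Coulomb metric of the auxiliary
functions, `J_k = Σ_μν P_μν⟨μν‖k̄⟩` the density-contracted three-center
vector, and `x̄` solves `Gx̄ = J` (directly, by truncated
eigendecomposition when `G` is numerically indefinite, or by MINRES).

The GEN-Xn generator builds, per element, an even-tempered exponent ladder
`α₀·βᵏ` with `β = 6 − n`, seeded at the polarization self-product
`α₀ = 2ζ(l_max)` and extended over the doubled orbital exponent range; each
ladder exponent becomes a shared-exponent Hermite set whose angularity
`min(2l, 6)` is dictated by the orbital product ranges it falls in.

## Worked example

```r
library(auxgen)

obs <- orbital_basis("O", list(
  orbital_shell(0, 50), orbital_shell(0, 0.1),   # two s primitives
  orbital_shell(1, 5),  orbital_shell(1, 0.5),   # two p primitives
  orbital_shell(2, 0.8)))                        # one d (polarization)
generate_genx(obs, n = 2)
#> <aux_basis> O GEN-X2: 6 set(s), 67 functions
#>    1  L=0  alpha = 102.4
#>    2  L=2  alpha = 25.6
#>    3  L=2  alpha = 6.4
#>    4  L=4  alpha = 1.6
#>    5  L=2  alpha = 0.4
#>    6  L=0  alpha = 0.1
```

The d self-product 2·0.8 = 1.6 anchors the ladder (β = 4); the p-product
range [1, 10] promotes the neighbouring sets to L = 2; the end exponents
overshoot the global product range [0.2, 100] ("fuzzy bounds").  Six sets,
1+10+10+35+10+1 = 67 functions.

Fitting a seeded random closed-shell density on the H₂ fixture:

```r
sys  <- fixture_system("h2")
prep <- prepare_system(sys, n = 2)
fit  <- fit_density(prep, random_density(prep$S, n_occ = 1, seed = 7))
fit$coulomb
#> <coulomb_fit> E_H = 1.6141547233  E_fit = 1.5992090481  eps2H = 1.495e-02
fit$exchange
#> <exchange_fit> E_F = -0.8070773617  E_F_fit = -0.7996045241  eps2F = -7.473e-03
```

`eps2H ≥ 0` (fitted Coulomb below exact) and `eps2F ≤ 0` (fitted exchange
above exact) are the variational sign laws; the suite checks them for 204
seeded densities across four fixture systems, three solvers and
GEN-X2/3/4, along with the equivalence of all four fitted-energy
expressions and the agreement of every integral class with an independent
quadrature oracle.

A thin command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/auxgen.R", package = "auxgen"))')" \
  gen --obs O.txt --n 2 --format demon_text
```

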