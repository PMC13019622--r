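# nofpair

Electron-pairing natural orbital functionals (PNOF5, GNOF, GNOFm) in R.

Natural orbital functional (NOF) theory sidesteps both the wavefunction
expansion of correlated quantum chemistry and the density-only ansatz of
DFT: the energy is a functional of the one-particle reduced density matrix
through its natural orbitals {φ_p} and occupation numbers n_p. The
electron-pairing family divides the orbital space into disjoint subspaces
Ω_g — one strongly occupied reference plus N_g weakly occupied partners —
constrained by Σ_{p∈Ω_g} n_p = 1, so every subspace holds exactly one
electron pair and the 1RDM trace equals N by construction. On top of the
intrapair energy

    E_g = 2 Σ_{p∈Ω_g} n_p H_pp + Σ_{q,p∈Ω_g} Π(n_q, n_p) L_pq,
    Π(n_q, n_p) = c(n_q) c(n_p),  c(n_p) = ±√n_p

and the intersubspace Hartree–Fock term Σ′ n_q n_p (2J_pq − K_pq), the GNOF
functional adds static correlation built from Φ_p = √(n_p h_p) and dynamic
correlation built from Gaussian-damped occupancies
n_p^d = n_p·exp(−(h_g/h_c)²); the GNOFm variant replaces the static term by
the compact −Σ′ Φ_q Φ_p K_pq, reinstating strong–strong pair coupling. All
three functionals collapse to restricted Hartree–Fock when the occupancies
are pinned at 1/0, and are exact for two-electron systems.

The package is aimed at method developers and students who want a small,
fully testable implementation: every energy term is verified against literal
loop transcriptions of its defining sums, two-electron problems against
closed-form and determinant-FCI references, and the Hartree–Fock limit
against an independent SCF oracle.

## What is in the box

* FCIDUMP reader/writer and a Hubbard-model generator (`read_fcidump`,
  `write_fcidump`, `build_hubbard`), four-index basis transforms and the
  J/K/L integral matrices.
* Pairing schemes (`build_scheme`), constraint-preserving softmax occupancy
  parametrization, phases, pairing amplitudes and dynamic occupancies.
* The three functionals with term-by-term breakdowns (`total_energy`) and
  analytic occupation/orbital gradients.
* A two-level solver (`solve_nof`): ADAM + BFGS occupancy optimization
  alternated with recentered-BFGS orthogonal orbital rotations, plus a
  pinned-occupancy mode (`rhf_reference`) for the Hartree–Fock baseline.
* Brute-force oracles for testing (`fci_ground_energy`, `rhf_energy`).
* Analysis: correlation energies in mE_h (`correlation_energy`),
  complete-basis-set extrapolation (inverse-cube, exponential, power;
  `cbs_extrapolate`), dipole moments from the converged 1RDM
  (`dipole_moment`), RMS deviations.
* A command-line front end (`inst/scripts/nofpair`) with `run`, `hubbard`,
  `extrapolate`, `fci` and `validate` subcommands.
* Minimal-basis H2/He/LiH FCIDUMP fixtures under `inst/extdata/`,
  regenerable from scratch with `data-raw/make_fixtures.py`.

## Worked example: the Hubbard dimer

The half-filled two-site Hubbard model (hopping t, on-site repulsion U) is
exactly solvable — ground energy (U − √(U² + 16t²))/2 — and every pairing
functional is exact for two electrons, which makes it the natural first
check:

```r
library(nofpair)

ints   <- build_hubbard(2, 1, 4, 2)           # 2 sites, t = 1, U = 4, N = 2
scheme <- build_scheme(2, 1, 2, coupling = "max")
res    <- solve_nof(ints, scheme, solver_settings("gnof"))
res
#> <SolverResult> gnof, converged in 3 sweeps
#>   E_total = -0.828427125 hartree
#>   occupancies: 0.853553 0.146447

hf <- rhf_reference(ints, scheme)             # pinned-occupancy baseline
correlation_energy(res$breakdown$e_total, hf$breakdown$e_total)
#> [1] -828.4271
```

The total energy matches the closed form −0.8284271 hartree; the natural
occupancies are cos²θ and sin²θ with tan 2θ = 4t/U; and since the
restricted Hartree–Fock energy of this dimer is exactly 0, the whole
−828.427 mE_h is correlation energy. The term breakdown shows that for a
single electron pair all intersubspace contributions vanish:

```r
res$breakdown
#> <EnergyBreakdown> functional: gnof
#>   e_intra          -0.828427124739 hartree
#>   e_hf_inter        0.000000000000 hartree
#>   e_sta_inter      -0.000000000000 hartree
#>   e_dyn_inter       0.000000000000 hartree
#>   e_core            0.000000000000 hartree
#>   e_electronic     -0.828427124739 hartree
#>   e_total          -0.828427124739 hartree
```

The same workflow runs on any FCIDUMP file, e.g. the packaged minimal-basis
H2 fixture, where the optimized energy of every functional lands on the
full-CI value −1.1372759 hartree to better than 10⁻⁶:

```r
ints <- read_fcidump(system.file("extdata", "h2_sto3g.fcidump", package = "nofpair"))
solve_nof(ints, build_scheme(2, 1, 2), solver_settings("gnofm"))$breakdown$e_total
#> [1] -1.137276
```

From a shell, the same run is:

```sh
Rscript inst/scripts/nofpair hubbard --sites 2 --t 1 --u 4 --electrons 2 --out dimer.fcidump
Rscript inst/scripts/nofpair run --fcidump dimer.fcidump --functional gnof --out dimer
```

which writes the breakdown, occupancies, scheme table, convergence trace
and a summary with E_corr in mE_h.

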