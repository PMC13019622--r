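---
title: "Electron-pairing natural orbital functionals: models, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron-pairing natural orbital functionals: models, parameters and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nofpair)
```

## The model

Natural orbital functional (NOF) theory expresses the electronic energy as a
functional of the one-particle reduced density matrix (1RDM) in its
eigenbasis: the natural orbitals $\{\varphi_p\}$ and their occupation
numbers $n_p \in [0,1]$ (spatial, spin-summed convention). The two-particle
density matrix is reconstructed from the occupancies, so the energy takes
the generic form

$$E = \sum_p 2\,n_p H_{pp} + \sum_{pq} \big[ A_{pq} J_{pq} + B_{pq} K_{pq}
      + D_{pq} L_{pq} \big],$$

with the Coulomb, exchange and exchange-time-inversion integrals
$J_{pq}=\langle pq|pq\rangle$, $K_{pq}=\langle pq|qp\rangle$,
$L_{pq}=\langle pp|qq\rangle$ (for real orbitals $L = K$), and
occupancy-dependent coefficient matrices $A, B, D$ specific to the
functional. `nofpair` implements the electron-pairing family PNOF5, GNOF
and GNOFm in exactly this form.

**Pairing ansatz.** With $N_{\mathrm{I}}$ unpaired electrons (multiplicity
$N_{\mathrm{I}}+1$) and $N_{\mathrm{II}} = N - N_{\mathrm{I}}$ paired ones,
the orbital space is partitioned into $N_{\mathrm{II}}/2$ disjoint pair
subspaces $\Omega_g = \{|g\rangle, |p_1\rangle, \dots, |p_{N_g}\rangle\}$
— one strongly occupied reference plus $N_g$ weakly occupied partners —
and $N_{\mathrm{I}}$ singleton subspaces pinned at $n = 1/2$. Each pair
subspace carries exactly one electron pair,
$\sum_{p \in \Omega_g} n_p = 1$, from which the 1RDM trace
$2\sum_p n_p = N$ follows identically.

**Energy terms.**

* *Intrapair*: $E_g = 2\sum_{p\in\Omega_g} n_p H_{pp} +
  \sum_{q,p\in\Omega_g} \Pi(n_q,n_p) L_{pq}$ with
  $\Pi(n_q,n_p) = c(n_q)c(n_p)$ and the sign rule
  $c(n_p) = +\sqrt{n_p}$ for strong references, $-\sqrt{n_p}$ otherwise.
  The diagonal $q=p$ is retained ($\Pi(n_p,n_p) = n_p$, contributing
  $n_p L_{pp}$); this reading is forced by the Hartree–Fock limit (below).
  Singles contribute their one-electron energy $H_{gg}$ once.
* *Intersubspace Hartree–Fock*: $\sum' n_q n_p (2J_{pq}-K_{pq})$ over
  orbital pairs in different subspaces.
* *Static correlation* (GNOF): products $\Phi_q \Phi_p$ of the
  occupancy–hole amplitudes $\Phi_p = \sqrt{n_p(1-n_p)}$ against $L$
  across the occupied/virtual windows split at $N_{\mathrm{II}}/2$,
  $N_\Omega$ and $N_B$, with block weights $-1$, $-1/2$, and a $-\Phi_q
  \Phi_p K_{pq}$ block inside the singles window. GNOFm replaces all of
  this by the compact $-\sum' \Phi_q\Phi_p K_{pq}$ over every
  intersubspace pair, reinstating the coupling between strongly occupied
  orbitals; the two functionals differ *only* in this term. For
  closed-shell systems the singles-window block of GNOF is empty; it is
  implemented as written and exercised by open-shell states in the tests.
* *Dynamic correlation* (GNOF and GNOFm): built from Gaussian-damped
  dynamic occupancies $n_p^d = n_p\,e^{-(h_g/h_c)^2}$, where
  $h_g = 1 - n_g$ is the hole of the subspace's reference orbital:
  $\sum'' [\Pi(n_q^d,n_p^d) + n_q^d n_p^d] L_{pq}$. The double prime
  excludes same-subspace pairs and pairs with *both* orbitals in the
  strongly occupied window — the only reading under which strong–weak
  dynamic correlation survives while the Hartree–Fock limit stays exact.
  The $\Pi$ built from dynamic occupancies reuses the ordinary sign rule.

PNOF5 keeps only the first two terms (independent electron pairs); GNOF
and GNOFm add the static and dynamic ones.

**Hartree–Fock limit.** At pinned occupancies ($n = 1$ or $0$, singles at
$1/2$) every $\Phi_p$ and every weak $n_p^d$ vanishes, and the intrapair
plus intersubspace Hartree–Fock terms reassemble the closed-shell RHF
energy expression exactly. The test suite asserts this identity to
$10^{-10}$ hartree against an independent SCF oracle; it is what forces
the retained $\Pi$ diagonal and the singles bookkeeping above.

## Tunable parameters

* `h_c` (dimensionless hole scale, default `0.02 * sqrt(2)` ≈ 0.0283):
  controls how fast dynamic occupancies are damped as a pair splits. The
  default is chosen so that the ceiling of the weak-orbital dynamic
  occupancy — maximizing $h\,e^{-(h/h_c)^2}$ over the feasible line
  $n_p = h_g$ — equals $0.02/\sqrt{e} \approx 0.012$, matching Pulay's
  criterion that an occupancy deviation of about $0.01$ from pinned values
  marks a natural orbital as dynamically correlated. The value $0.022$
  also quoted in the NOF literature yields a ceiling of $\approx 0.0094$
  instead; both are available through the `h_c` argument and both are
  exercised in the tests.
* `coupling` (per-pair weak partner count, default `"max"`): all virtual
  orbitals are correlated, i.e. dealt to pair subspaces — every electron
  correlated across every available orbital. A fixed integer coupling is
  accepted for reduced calculations. When the virtual pool does not divide
  evenly, earlier (deeper) pairs receive the extra orbitals.
* `dealing` (`"stacked"`, default, or `"interleaved"`): how weak orbitals
  are apportioned. Stacked dealing gives pair 1 the contiguous block
  counting down from the highest virtual, mirroring common NOF practice of
  coupling the deepest orbital to the highest virtuals; the interleaved
  round-robin alternative is exposed because the choice is a convention,
  not physics.
* Solver settings (`solver_settings()`): `tol_energy = 1e-6` hartree and
  `tol_gradient = 1e-5` on inner gradient norms; ADAM rate/decays
  (0.05, 0.9, 0.999) for the occupancy inner solver; iteration caps
  (300 occupancy steps, 150 orbital steps per sweep, 50 outer sweeps).
  Desk-scale problems (2–8 orbitals) converge well inside these caps.

## Optimization strategy

Occupancies are parametrized as normalized exponentials (softmax) of
unconstrained parameters within each pair subspace, so the pairing sums
equal one electron pair *identically at every iterate* — the constraint is
structural, not penalized. The occupancy inner solver is ADAM with the
analytic chain-rule gradient, followed by a BFGS polish: ADAM moves quickly
through the early landscape but crawls along the flat softmax tails (e.g.
toward pinned solutions of weakly correlated systems), which a quasi-Newton
tail pass tightens to machine-level gradients. The seeded start places each
strong reference at $n = 1-\delta$ with $\delta = 0.02$ spread evenly over
its partners: exactly pinned starts are stationary points of every
functional and would trap the optimizer.

Orbitals are optimized over the orthogonal group: the rotation is updated
as $C \leftarrow C\,e^{X}$ with $X$ skew-symmetric, so orthogonality is
exact up to round-off (a Löwdin re-orthonormalization guards drift beyond
$10^{-8}$). The gradient at the current basis is assembled analytically
from the non-symmetric generalized-Fock matrix
$F_{tp} = 2 w_p H_{tp} + 4\sum_q [A_{pq}(tp|qq) + B_{pq}(tq|qp) +
D_{pq}(tq|pq)]$ as $F - F^\top$ (a central finite-difference route is
available via `orbital_gradient = "numeric"` and is used to cross-check
the analytic one in the tests). The minimization itself is BFGS over the
generator, recentered each round so the analytic gradient is exact at
every round's origin.

The outer loop alternates the two inner solvers until the energy is
stationary on two consecutive sweeps. A stationary point of this
alternation can still be a saddle of the orbital landscape (lattice models
at half filling are prone to this), so the converged solution is probed
with two small seeded random rotations; a probe that relaxes to a lower
energy restarts the alternation there. The probe directions derive from
`solver_settings(seed = )`, so a solve is fully deterministic for fixed
inputs and settings, and the caller's RNG stream is left untouched.

## What the synthetic generator emulates

`build_hubbard()` produces nearest-neighbour Hubbard chains and rings:
hopping $-t$, on-site repulsion $U$, optional periodicity. Scanning $U/t$
sweeps the full correlation range — uncorrelated ($U = 0$, pinned
occupancies), dynamically correlated (small $U$), strongly correlated
(large $U$, strongly fractional occupancies) — with closed-form references
at the two-site half-filled point: ground energy
$(U - \sqrt{U^2 + 16t^2})/2$ and natural occupancies
$\cos^2\theta, \sin^2\theta$ with $\tan 2\theta = 4t/U$. The packaged
molecular fixtures (H2, He, LiH in a minimal Gaussian basis, FCIDUMP
format, regenerable with `data-raw/make_fixtures.py`) add realistic
integral structure: non-diagonal one-electron matrices, dense two-electron
tensors and a nuclear-repulsion offset.

What these test systems do *not* probe: basis-set convergence toward the
complete-basis-set limit (minimal bases have no cardinal series), large
correlation-consistent bases, point-group symmetry handling, and the
behaviour of the functionals on systems with many interacting pairs at
chemical accuracy. Passing tests therefore certify the functional algebra,
the constraint machinery, the optimizers and the analysis layer — not
quantitative agreement with experiment for real molecules, which requires
externally generated integrals (any FCIDUMP producer) fed to the same
pipeline.

## Numerical choices

* Two-electron tensors are stored dense in chemist (Mulliken) convention —
  FCIDUMP's native ordering — and converted to physicist brackets only
  inside `jkl_matrices()`. No resolution-of-identity factorization is
  attempted; correctness at desk scale over throughput.
* All double sums run over ordered index pairs exactly as the functional
  expressions are written; no factor-of-two shortcuts.
* The FCI oracle enumerates determinants in a fixed-$S_z$ sector with
  explicit bitmask sign bookkeeping and dense diagonalization (guarded at
  $10^5$ determinants, 15 spatial orbitals); the SCF oracle is plain
  damped Fock iteration converged to $10^{-12}$ in energy. Both are
  deliberately transparent rather than fast.
* Complete-basis-set extrapolation: the inverse-cube law
  $E(X) = E_\infty + bX^{-3}$ is linear and solved by least squares over
  all points (an option restricts to the two largest cardinals, the common
  two-point practice — both modes are reported because overdetermination
  handling is a convention). The exponential $E_\infty + Ae^{-\gamma X}$
  and power $E_\infty + AX^{-\gamma}$ forms are solved by
  Levenberg–Marquardt with closed-form starts built from successive
  differences; on model-generated data all three recover the generating
  parameters to at least eight digits.
* Occupancy gradients at exactly pinned states are singular
  ($\mathrm{d}\sqrt{n}/\mathrm{d}n \to \infty$); the softmax keeps
  iterates interior, and the dynamic-term gradient is written directly in
  the ordinary occupancies so it stays finite even when the Gaussian
  damping underflows.
* Degenerate inputs: eigenvector sign/order gauges are fixed
  deterministically (largest component positive, ascending eigenvalues),
  so repeated runs produce byte-identical reports.

## Known limitations

Dense $O(N_B^4)$ tensor storage and $O(N_B^5)$ transforms limit practical
use to small orbital counts; no frozen-core or active-space machinery (by
design — the pairing scheme correlates everything); no complex orbitals
(the $L = K$ real-orbital identity is assumed and asserted); spin handling
is restricted to the highest-multiplicity ensemble with singles pinned at
$n = 1/2$; lattice dipoles use site positions and are meant for testing
the 1RDM dipole machinery rather than for physical lattice polarization
studies.
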