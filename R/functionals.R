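## Energy expressions of the electron-pairing functionals PNOF5, GNOF and
## GNOFm. Every term is a bilinear form in occupancy-derived vectors against
## the J/K/L matrices, restricted by index masks built from the pairing
## scheme:
##
##   E_intra     sum over pair subspaces of  2 n_p H_pp + Pi(n_q,n_p) L_pq
##               (both indices inside the subspace, diagonal q = p included,
##               Pi(n,n) = n so the diagonal contributes n_p L_pp), plus
##               H_gg once per singly occupied subspace.
##   E_HF^inter  n_q n_p (2 J_pq - K_pq) over orbital pairs in different
##               subspaces.
##   E_sta^inter (GNOF) five Phi_q Phi_p blocks split at N_II/2, N_omega and
##               N_B with weights -1, -1/2, -1 (see gnof_static_weights);
##               (GNOFm) -Phi_q Phi_p K_pq over all intersubspace pairs.
##   E_dyn^inter [Pi(n^d_q, n^d_p) + n^d_q n^d_p] L_pq over intersubspace
##               pairs excluding those with both orbitals at or below
##               N_II/2; Pi on dynamic occupancies uses the same sign rule.
##
## All sums run over ordered index pairs exactly as the double sums are
## written; no factor-of-two shortcuts.

functional_ids <- c("pnof5", "gnof", "gnofm")

## TRUE where the two orbitals belong to different subspaces (uncorrelated
## orbitals count as mutually distinct); diagonal always FALSE.
inter_mask <- function(scheme) {
  s <- scheme$subspace_of
  m <- outer(s, s, function(a, b) is.na(a) | is.na(b) | a != b)
  diag(m) <- FALSE
  m
}

## Mask of pairs inside the same *pair* subspace (singles excluded),
## diagonal included.
intra_pair_mask <- function(scheme) {
  s <- scheme$subspace_of
  pairish <- !is.na(s) & s <= scheme$n_pairs
  outer(seq_along(s), seq_along(s), function(p, q) {
    pairish[p] & pairish[q] & s[p] == s[q]
  })
}

## Weight matrices of the GNOF static term: W multiplies -Phi_q Phi_p L_pq,
## V multiplies -Phi_q Phi_p K_pq. Windows: strong references (1..N_II/2),
## singles (N_II/2+1..N_omega), weak/virtual (N_omega+1..N_B). Both include
## the intersubspace restriction.
gnof_static_weights <- function(scheme) {
  nb <- scheme$n_basis
  n2 <- scheme$n_pairs          # N_II/2
  nom <- scheme$n_subspaces     # N_omega
  idx <- seq_len(nb)
  below <- idx <= nom
  above <- idx > nom
  strong <- idx <= n2
  mid <- idx > n2 & idx <= nom
  w <- outer(below, above, `&`) + outer(above, below, `&`) +
    outer(above, above, `&`)
  w <- w + 0.5 * (outer(strong, mid, `&`) + outer(mid, strong, `&`))
  v <- outer(mid, mid, `&`) * 1
  m <- inter_mask(scheme)
  list(W = w * m, V = v * m)
}

## Mask of the dynamic term: intersubspace pairs, excluding pairs with both
## orbitals at or below N_II/2.
dynamic_mask <- function(scheme) {
  strong <- seq_len(scheme$n_basis) <= scheme$n_pairs
  inter_mask(scheme) & !outer(strong, strong, `&`)
}

## One-electron coefficient vector: E_1e = sum_p w_p H_pp.
one_electron_weights <- function(scheme, state) {
  w <- numeric(scheme$n_basis)
  for (g in seq_len(scheme$n_pairs)) {
    idx <- scheme$members[[g]]
    w[idx] <- 2 * state$occ[idx]
  }
  if (scheme$n_unpaired > 0) {
    w[scheme$n_pairs + seq_len(scheme$n_unpaired)] <- 1
  }
  w
}

check_inputs <- function(ints, scheme, state) {
  stopifnot(inherits(ints, "IntegralSet"), inherits(scheme, "PairingScheme"),
            inherits(state, "OccupancyState"))
  if (ints$n_basis != scheme$n_basis) {
    stop("integral set and pairing scheme disagree on the orbital count",
         call. = FALSE)
  }
}

#' Intrapair energy
#'
#' Sum over pair subspaces of the pair energies (one-electron part plus the
#' pair-coupling term `Pi(n_q, n_p) L_pq` over both indices inside the
#' subspace, including the diagonal which contributes `n_p L_pp`), plus the
#' one-electron energy `H_gg` of each singly occupied subspace.
#'
#' @param ints,scheme,occ_state Integrals, pairing scheme and occupancy
#'   state in the same orbital basis.
#' @return Energy in hartree.
#' @export
energy_intra <- function(ints, scheme, occ_state) {
  check_inputs(ints, scheme, occ_state)
  jkl <- jkl_matrices(ints)
  e1 <- sum(one_electron_weights(scheme, occ_state) * diag(ints$h_one))
  pim <- outer(occ_state$phases, occ_state$phases)
  e1 + sum(intra_pair_mask(scheme) * pim * jkl$L)
}

#' Intersubspace Hartree-Fock energy
#'
#' `sum n_q n_p (2 J_pq - K_pq)` over ordered orbital pairs belonging to
#' different subspaces. Together with [energy_intra()] at pinned occupancies
#' this reproduces the closed-shell Hartree-Fock energy expression.
#'
#' @inheritParams energy_intra
#' @return Energy in hartree.
#' @export
energy_hf_inter <- function(ints, scheme, occ_state) {
  check_inputs(ints, scheme, occ_state)
  jkl <- jkl_matrices(ints)
  nn <- outer(occ_state$occ, occ_state$occ)
  sum(inter_mask(scheme) * nn * (2 * jkl$J - jkl$K))
}

#' Static intersubspace correlation energy (GNOF form)
#'
#' The five-block static term: `-Phi_q Phi_p L_pq` over pairs coupling the
#' occupied window (up to `N_omega`) with the virtual window and the virtual
#' window with itself, `-1/2 Phi_q Phi_p L_pq` between strong references and
#' singles, and `-Phi_q Phi_p K_pq` within the singles window; all blocks
#' intersubspace only. `Phi_p = sqrt(n_p h_p)`.
#'
#' @inheritParams energy_intra
#' @return Energy in hartree.
#' @export
energy_static_gnof <- function(ints, scheme, occ_state) {
  check_inputs(ints, scheme, occ_state)
  jkl <- jkl_matrices(ints)
  wv <- gnof_static_weights(scheme)
  pp <- outer(occ_state$phi, occ_state$phi)
  -sum(wv$W * pp * jkl$L) - sum(wv$V * pp * jkl$K)
}

#' Static intersubspace correlation energy (GNOFm form)
#'
#' The compact modified static term `-Phi_q Phi_p K_pq` over all
#' intersubspace ordered pairs, which reinstates the coupling between
#' strongly occupied orbitals of different pairs.
#'
#' @inheritParams energy_intra
#' @return Energy in hartree.
#' @export
energy_static_gnofm <- function(ints, scheme, occ_state) {
  check_inputs(ints, scheme, occ_state)
  jkl <- jkl_matrices(ints)
  pp <- outer(occ_state$phi, occ_state$phi)
  -sum(inter_mask(scheme) * pp * jkl$K)
}

#' Dynamic intersubspace correlation energy
#'
#' `[Pi(n^d_q, n^d_p) + n^d_q n^d_p] L_pq` over ordered intersubspace pairs,
#' excluding pairs with both orbitals in the strongly occupied window
#' (at or below `N_II/2`). The pair-coupling matrix is built from the
#' dynamic occupancies with the same sign rule as for the ordinary
#' occupancies.
#'
#' @inheritParams energy_intra
#' @return Energy in hartree.
#' @export
energy_dynamic <- function(ints, scheme, occ_state) {
  check_inputs(ints, scheme, occ_state)
  jkl <- jkl_matrices(ints)
  nd <- occ_state$dyn_occ
  cd <- phase_signs(scheme) * sqrt(nd)
  sum(dynamic_mask(scheme) * (outer(cd, cd) + outer(nd, nd)) * jkl$L)
}

#' Total energy and term breakdown for a functional
#'
#' Assembles `E_intra + E_HF^inter` (PNOF5) or
#' `E_intra + E_HF^inter + E_sta^inter + E_dyn^inter` (GNOF, GNOFm; the two
#' differ only in the static term) and adds the core constant.
#'
#' @inheritParams energy_intra
#' @param functional_id One of `"pnof5"`, `"gnof"`, `"gnofm"`.
#' @return Object of class `EnergyBreakdown`: `e_intra`, `e_hf_inter`,
#'   `e_sta_inter`, `e_dyn_inter`, `e_core`, `e_electronic`, `e_total`,
#'   `functional_id`.
#' @export
total_energy <- function(ints, scheme, occ_state, functional_id = "gnof") {
  functional_id <- match.arg(functional_id, functional_ids)
  e_intra <- energy_intra(ints, scheme, occ_state)
  e_hf <- energy_hf_inter(ints, scheme, occ_state)
  e_sta <- switch(functional_id,
                  pnof5 = 0,
                  gnof = energy_static_gnof(ints, scheme, occ_state),
                  gnofm = energy_static_gnofm(ints, scheme, occ_state))
  e_dyn <- if (functional_id == "pnof5") 0 else {
    energy_dynamic(ints, scheme, occ_state)
  }
  e_el <- e_intra + e_hf + e_sta + e_dyn
  structure(
    list(e_intra = e_intra, e_hf_inter = e_hf, e_sta_inter = e_sta,
         e_dyn_inter = e_dyn, e_core = ints$core_constant,
         e_electronic = e_el, e_total = e_el + ints$core_constant,
         functional_id = functional_id),
    class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat(sprintf("<EnergyBreakdown> functional: %s\n", x$functional_id))
  for (f in c("e_intra", "e_hf_inter", "e_sta_inter", "e_dyn_inter",
              "e_core", "e_electronic", "e_total")) {
    cat(sprintf("  %-13s %18.12f hartree\n", f, x[[f]]))
  }
  invisible(x)
}

#' Serialize an energy breakdown to machine-readable lines
#'
#' @param breakdown An `EnergyBreakdown`.
#' @return Character vector, `term value` pairs at 12 significant digits.
#' @export
format_breakdown <- function(breakdown) {
  f <- c("e_intra", "e_hf_inter", "e_sta_inter", "e_dyn_inter", "e_core",
         "e_electronic", "e_total")
  c(sprintf("functional %s", breakdown$functional_id),
    sprintf("%s %.12g", f, unlist(breakdown[f])))
}

## Gradient of the electronic energy with respect to the occupancies
## (length n_basis; entries for singles/uncorrelated orbitals are reported
## but unused by the optimizer, which only varies pair-subspace orbitals).
energy_gradient_occ <- function(ints, scheme, occ_state, functional_id) {
  functional_id <- match.arg(functional_id, functional_ids)
  jkl <- jkl_matrices(ints)
  nb <- scheme$n_basis
  n <- occ_state$occ
  s <- phase_signs(scheme)
  grad <- numeric(nb)
  pair_orbs <- which(!is.na(scheme$subspace_of) &
                       scheme$subspace_of <= scheme$n_pairs)

  ## intrapair: 2 H_pp + (s_p / sqrt(n_p)) sum_{q in same pair} c_q L_pq
  cvec <- occ_state$phases
  ipm <- intra_pair_mask(scheme)
  for (p in pair_orbs) {
    qs <- which(ipm[p, ])
    grad[p] <- grad[p] + 2 * ints$h_one[p, p] +
      (s[p] / sqrt(max(n[p], .Machine$double.xmin))) *
        sum(cvec[qs] * jkl$L[p, qs])
  }

  ## intersubspace HF: 2 sum_q n_q (2J - K)
  m <- inter_mask(scheme)
  grad <- grad + 2 * as.vector((m * (2 * jkl$J - jkl$K)) %*% n)

  ## static term: -2 Phi'_p sum_q [weights] Phi_q M_pq
  if (functional_id != "pnof5") {
    phi <- occ_state$phi
    dphi <- ifelse(phi > 0, (1 - 2 * n) / (2 * pmax(phi, 1e-300)), 0)
    if (functional_id == "gnof") {
      wv <- gnof_static_weights(scheme)
      inner <- as.vector((wv$W * jkl$L + wv$V * jkl$K) %*% phi)
    } else {
      inner <- as.vector((m * jkl$K) %*% phi)
    }
    grad <- grad - 2 * dphi * inner
    grad <- grad + dynamic_gradient_occ(scheme, occ_state, jkl$L)
  }
  grad
}

## Occupancy gradient of the dynamic term, written directly in n to stay
## finite when the Gaussian damping factor underflows.
dynamic_gradient_occ <- function(scheme, occ_state, lmat) {
  nb <- scheme$n_basis
  n <- occ_state$occ
  nd <- occ_state$dyn_occ
  s <- phase_signs(scheme)
  cd <- s * sqrt(nd)
  m2 <- dynamic_mask(scheme)
  h_c <- occ_state$h_c
  grad <- numeric(nb)
  cd_inner <- as.vector((m2 * lmat) %*% cd)   # sum_q M2 cd_q L_pq
  nd_inner <- as.vector((m2 * lmat) %*% nd)
  for (g in seq_len(scheme$n_pairs)) {
    idx <- scheme$members[[g]]
    h_g <- 1 - n[g]
    f <- exp(-(h_g / h_c)^2)
    ## direct dependence through n_p at fixed damping
    grad[idx] <- grad[idx] +
      sqrt(f) * s[idx] * cd_inner[idx] / sqrt(pmax(n[idx], .Machine$double.xmin)) +
      2 * f * nd_inner[idx]
    ## chain through the damping factor, driven by the reference hole
    grad[g] <- grad[g] + (2 * h_g / h_c^2) *
      sum(cd[idx] * cd_inner[idx] + 2 * nd[idx] * nd_inner[idx])
  }
  grad
}

#' Gradient of the total energy with respect to the unconstrained parameters
#'
#' Analytic chain rule: the occupancy gradient of each energy term composed
#' with the softmax Jacobian of [params_to_occupancies()]. Matches central
#' finite differences to high accuracy at interior points.
#'
#' @inheritParams total_energy
#' @return Numeric vector, one entry per parameter.
#' @export
occupation_gradient <- function(ints, scheme, occ_state, functional_id = "gnof") {
  check_inputs(ints, scheme, occ_state)
  g_occ <- energy_gradient_occ(ints, scheme, occ_state, functional_id)
  as.vector(crossprod(occupancy_jacobian(scheme, occ_state), g_occ))
}
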