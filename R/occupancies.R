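## Occupation numbers under the pairing constraint. Each pair subspace's
## occupancies are normalized exponentials (softmax) of an unconstrained
## parameter block, so the pairing sum equals one electron pair identically;
## singles are fixed at 1/2 and uncorrelated orbitals at 0.

#' Default Gaussian hole-damping constant for dynamic occupancies
#'
#' The dynamic part of an occupation number is `n_p^d = n_p *
#' exp(-(h_g/h_c)^2)` where `h_g` is the hole of the subspace's reference
#' orbital. With `h_c = 0.02 * sqrt(2)` the largest dynamic occupancy a
#' weakly occupied orbital can attain (at `n_p = h_g`) is `0.02/sqrt(e)`,
#' approximately 0.012 — an occupancy deviation of about 0.01 from pinned
#' values, the classic threshold for a natural orbital to contribute to
#' dynamic correlation (Pulay's criterion).
#'
#' @return `0.02 * sqrt(2)`.
#' @export
default_hc <- function() 0.02 * sqrt(2)

#' Map unconstrained parameters to a constrained occupancy state
#'
#' Within each pair subspace the occupancies are the normalized exponentials
#' of the subspace's parameter block (softmax), so they are positive and sum
#' to exactly 1 for any parameter values; the map is smooth and surjective
#' onto the open feasible set. Singles are fixed at 1/2, uncorrelated
#' orbitals at 0.
#'
#' @param scheme A [build_scheme()] result.
#' @param params Numeric vector with one entry per orbital belonging to a
#'   pair subspace, blocks concatenated in subspace order, each block in
#'   member order (strong orbital first, then weak partners ascending).
#' @param h_c Hole-damping constant for dynamic occupancies.
#' @return Object of class `OccupancyState` with fields `occ`, `holes`,
#'   `phases` (`c(n_p)`), `phi` (`sqrt(n_p h_p)`), `dyn_occ`, `params`,
#'   `h_c`.
#' @export
params_to_occupancies <- function(scheme, params, h_c = default_hc()) {
  stopifnot(inherits(scheme, "PairingScheme"))
  sizes <- pair_block_sizes(scheme)
  if (length(params) != sum(sizes)) {
    stop(sprintf("params length %d != total pair-subspace orbitals %d",
                 length(params), sum(sizes)), call. = FALSE)
  }
  occ <- numeric(scheme$n_basis)
  off <- 0L
  for (g in seq_len(scheme$n_pairs)) {
    idx <- scheme$members[[g]]
    x <- params[off + seq_along(idx)]
    x <- x - max(x)                      # shift invariance, overflow-safe
    e <- exp(x)
    occ[idx] <- e / sum(e)
    off <- off + length(idx)
  }
  if (scheme$n_unpaired > 0) {
    occ[scheme$n_pairs + seq_len(scheme$n_unpaired)] <- 0.5
  }
  occupancy_state(scheme, occ, params = params, h_c = h_c)
}

pair_block_sizes <- function(scheme) {
  if (scheme$n_pairs == 0) return(integer(0))
  vapply(scheme$members[seq_len(scheme$n_pairs)], length, integer(1))
}

#' Construct an occupancy state from explicit occupancies
#'
#' Used for pinned (Hartree-Fock limit) states and tests; [params_to_occupancies()]
#' is the optimizer's route. Derived quantities (holes, phases, pairing
#' amplitudes, dynamic occupancies) are populated.
#'
#' @param scheme A [build_scheme()] result.
#' @param occ Occupancy vector in `[0, 1]`, length `n_basis`.
#' @param params Optional generating parameter vector.
#' @param h_c Hole-damping constant.
#' @return An `OccupancyState`.
#' @export
occupancy_state <- function(scheme, occ, params = NULL, h_c = default_hc()) {
  if (any(occ < -1e-12)) stop("negative occupancy", call. = FALSE)
  occ <- pmin(pmax(occ, 0), 1)
  structure(
    list(occ = occ,
         holes = 1 - occ,
         phases = phase_coefficients(scheme, occ),
         phi = sqrt(occ * (1 - occ)),
         dyn_occ = dynamic_occupancies(scheme, occ, h_c),
         params = params,
         h_c = h_c),
    class = "OccupancyState")
}

#' Pinned (Hartree-Fock limit) occupancy state
#'
#' Strong references and singles take their uncorrelated values (1 and 1/2),
#' every weak orbital is 0. In this limit every functional in the package
#' reduces to restricted Hartree-Fock.
#'
#' @param scheme A [build_scheme()] result.
#' @param h_c Hole-damping constant (irrelevant at pinned occupancies).
#' @return An `OccupancyState`.
#' @export
pinned_state <- function(scheme, h_c = default_hc()) {
  occ <- numeric(scheme$n_basis)
  if (scheme$n_pairs > 0) occ[seq_len(scheme$n_pairs)] <- 1
  if (scheme$n_unpaired > 0) occ[scheme$n_pairs + seq_len(scheme$n_unpaired)] <- 0.5
  occupancy_state(scheme, occ, h_c = h_c)
}

#' Phase coefficients of the pair-coupling matrix
#'
#' `c(n_p) = +sqrt(n_p)` for strongly occupied references (`p <= N_II/2`),
#' `-sqrt(n_p)` otherwise; the product `c(n_q) c(n_p)` forms the
#' pair-coupling element between orbitals of a subspace.
#'
#' @param scheme A [build_scheme()] result.
#' @param occ Occupancy vector.
#' @return Numeric vector of phases.
#' @export
phase_coefficients <- function(scheme, occ) {
  if (any(occ < -1e-12)) stop("negative occupancy", call. = FALSE)
  s <- phase_signs(scheme)
  s * sqrt(pmax(occ, 0))
}

## +1 for orbitals up to N_II/2, -1 beyond (the printed sign rule).
phase_signs <- function(scheme) {
  ifelse(seq_len(scheme$n_basis) <= scheme$n_pairs, 1, -1)
}

#' Dynamic occupancies
#'
#' Gaussian-damped occupancies isolating the dynamic-correlation part:
#' `n_p^d = n_p * exp(-(h_g/h_c)^2)` for `p` in pair subspace `g`, where
#' `h_g = 1 - n_g` is the hole of the subspace's strongly occupied reference.
#' When a pair is nearly intact (`h_g` near 0) its orbitals keep their full
#' occupancy; strongly split pairs (static correlation) are damped out.
#' Singles and uncorrelated orbitals carry no dynamic occupancy.
#'
#' @param scheme A [build_scheme()] result.
#' @param occ Occupancy vector.
#' @param h_c Hole-damping constant; see [default_hc()].
#' @return Numeric vector `n_p^d`, same length as `occ`.
#' @export
dynamic_occupancies <- function(scheme, occ, h_c = default_hc()) {
  stopifnot(h_c > 0)
  nd <- numeric(scheme$n_basis)
  for (g in seq_len(scheme$n_pairs)) {
    idx <- scheme$members[[g]]
    h_g <- 1 - occ[g]                     # hole of the reference orbital
    nd[idx] <- occ[idx] * exp(-(h_g / h_c)^2)
  }
  nd
}

#' Jacobian of occupancies with respect to the unconstrained parameters
#'
#' Softmax Jacobian, block-diagonal over pair subspaces:
#' `d n_i / d x_j = n_i (delta_ij - n_j)` within a block, zero across blocks
#' and for singles/uncorrelated orbitals.
#'
#' @param scheme A [build_scheme()] result.
#' @param state An `OccupancyState` carrying `params`.
#' @return Matrix `n_basis x length(params)`.
#' @export
occupancy_jacobian <- function(scheme, state) {
  sizes <- pair_block_sizes(scheme)
  jac <- matrix(0, scheme$n_basis, sum(sizes))
  off <- 0L
  for (g in seq_len(scheme$n_pairs)) {
    idx <- scheme$members[[g]]
    n <- state$occ[idx]
    jac[idx, off + seq_along(idx)] <- diag(n, length(idx)) - outer(n, n)
    off <- off + length(idx)
  }
  jac
}

#' Seeded starting parameters near the Hartree-Fock solution
#'
#' Gives each strong reference occupancy `1 - delta` with the remainder
#' spread evenly over its weak partners. Exactly pinned starts are stationary
#' points of every functional, so a small correlation seed is required.
#'
#' @param scheme A [build_scheme()] result.
#' @param delta Correlation seed (default 0.02).
#' @return Parameter vector accepted by [params_to_occupancies()].
#' @export
initial_params <- function(scheme, delta = 0.02) {
  sizes <- pair_block_sizes(scheme)
  unlist(lapply(sizes, function(m) {
    n_weak <- m - 1L
    if (n_weak == 0L) return(0)
    c(log((1 - delta) * n_weak / delta), rep(0, n_weak))
  }), use.names = FALSE)
}
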