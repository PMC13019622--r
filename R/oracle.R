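## Brute-force exact solvers used as independent references in tests and
## diagnostics: determinant-enumeration FCI (dense diagonalization in the
## fixed-Sz Slater determinant basis, spin-orbital second quantization with
## explicit bitmask sign bookkeeping) and a plain closed-shell SCF.

popcount_below <- function(mask, pos) {
  ## number of set bits strictly below bit position pos (0-based)
  if (pos == 0) return(0L)
  sum(bitwAnd(mask, bitwShiftL(1L, 0:(pos - 1L))) != 0L)
}

## apply annihilation (create = FALSE) or creation operator for spin-orbital
## `so` (0-based) to determinant mask; returns list(mask, sign) or NULL.
apply_op <- function(mask, so, create) {
  bit <- bitwShiftL(1L, so)
  occupied <- bitwAnd(mask, bit) != 0L
  if (create == occupied) return(NULL)
  sign <- if (popcount_below(mask, so) %% 2L == 0L) 1 else -1
  list(mask = bitwXor(mask, bit), sign = sign)
}

#' Exact (full CI) ground-state energy by determinant enumeration
#'
#' Enumerates all Slater determinants with the requested electron count and
#' spin projection, builds the dense Hamiltonian with spin-orbital
#' second-quantization rules, and diagonalizes. Intended purely as a test
#' oracle; guarded to at most `1e5` determinants (and 15 spatial orbitals by
#' the 31-bit mask representation).
#'
#' @param ints An [integral_set()] (chemist convention).
#' @param n_electrons Electron count (defaults to the integral set's).
#' @param ms2 Twice the spin projection (defaults to the integral set's).
#' @return List of class `FCISolution`: `energy` (hartree, includes the core
#'   constant), `n_determinants`, `ground_vector_norm`.
#' @export
fci_ground_energy <- function(ints, n_electrons = ints$n_electrons,
                              ms2 = ints$ms2) {
  nb <- ints$n_basis
  if (nb > 15) stop("FCI oracle limited to 15 spatial orbitals", call. = FALSE)
  if ((n_electrons + ms2) %% 2L != 0L) {
    stop("n_electrons and ms2 have incompatible parity", call. = FALSE)
  }
  n_a <- (n_electrons + ms2) %/% 2L
  n_b <- (n_electrons - ms2) %/% 2L
  if (n_a > nb || n_b > nb || n_b < 0) stop("impossible occupation", call. = FALSE)
  dim_fci <- choose(nb, n_a) * choose(nb, n_b)
  if (dim_fci > 1e5) stop("FCI dimension guard exceeded", call. = FALSE)

  masks_of <- function(k) {
    if (k == 0) return(0L)
    combs <- utils::combn(nb, k)
    apply(combs, 2, function(orbs) {
      Reduce(bitwOr, bitwShiftL(1L, 2L * (orbs - 1L)), 0L)
    })
  }
  ## spin-orbital index: 2*(p-1) for alpha, 2*(p-1)+1 for beta
  amasks <- masks_of(n_a)
  bmasks <- bitwShiftL(masks_of(n_b), 1L)
  dets <- as.integer(outer(amasks, bmasks, bitwOr))
  index <- seq_along(dets)
  names(index) <- as.character(dets)

  nso <- 2L * nb
  hmat <- matrix(0, dim_fci, dim_fci)
  g <- ints$eri
  h1 <- ints$h_one
  spatial <- function(so) so %/% 2L + 1L
  for (ket in seq_along(dets)) {
    d <- dets[ket]
    occ <- which(bitwAnd(d, bitwShiftL(1L, 0:(nso - 1L))) != 0L) - 1L
    ## one-electron: sum_pq h_pq a+_p a_q (same spin)
    for (q in occ) {
      a1 <- apply_op(d, q, FALSE)
      for (pso in seq(q %% 2L, nso - 1L, by = 2L)) {
        a2 <- apply_op(a1$mask, pso, TRUE)
        if (is.null(a2)) next
        bra <- index[[as.character(a2$mask)]]
        hmat[bra, ket] <- hmat[bra, ket] +
          h1[spatial(pso), spatial(q)] * a1$sign * a2$sign
      }
    }
    ## two-electron: 1/2 sum <ij|kl> a+_i a+_j a_l a_k, spin-orbital
    ## brackets; <ij|kl> = (ik|jl) on spatial parts, spins i~k, j~l.
    for (k in occ) {
      a1 <- apply_op(d, k, FALSE)
      for (l in occ) {
        if (l == k) next
        a2 <- apply_op(a1$mask, l, FALSE)
        sgn2 <- a1$sign * a2$sign
        for (jso in seq(l %% 2L, nso - 1L, by = 2L)) {
          a3 <- apply_op(a2$mask, jso, TRUE)
          if (is.null(a3)) next
          for (iso in seq(k %% 2L, nso - 1L, by = 2L)) {
            a4 <- apply_op(a3$mask, iso, TRUE)
            if (is.null(a4)) next
            val <- g[spatial(iso), spatial(k), spatial(jso), spatial(l)]
            if (val == 0) next
            bra <- index[[as.character(a4$mask)]]
            hmat[bra, ket] <- hmat[bra, ket] +
              0.5 * val * sgn2 * a3$sign * a4$sign
          }
        }
      }
    }
  }
  es <- eigen((hmat + t(hmat)) / 2, symmetric = TRUE)
  vec <- es$vectors[, dim_fci]
  structure(
    list(energy = es$values[dim_fci] + ints$core_constant,
         n_determinants = dim_fci,
         ground_vector_norm = vnorm(vec)),
    class = "FCISolution")
}

#' Closed-shell restricted Hartree-Fock energy (SCF oracle)
#'
#' Plain self-consistent field by repeated Fock diagonalization, with simple
#' density damping for robustness; converged when the energy change drops
#' below `1e-12` and the DIIS-style error `[F, D]` below `1e-8`. Intended as
#' an independent reference for the pinned-occupancy limit of the
#' functionals.
#'
#' @param ints An [integral_set()] (chemist convention).
#' @param n_electrons Even electron count (defaults to the integral set's).
#' @param max_iter Iteration cap.
#' @param damping Density mixing weight for the new density in `[0.5, 1]`.
#' @return List with `energy` (hartree, includes core constant), `coeff`
#'   (MO coefficient matrix, columns ordered by orbital energy),
#'   `orbital_energies`, `converged`, `iterations`.
#' @export
rhf_energy <- function(ints, n_electrons = ints$n_electrons,
                       max_iter = 200L, damping = 0.7) {
  if (n_electrons %% 2L != 0L) stop("RHF oracle requires a closed shell", call. = FALSE)
  nb <- ints$n_basis
  nocc <- n_electrons %/% 2L
  g <- ints$eri
  h1 <- ints$h_one
  ## Coulomb/exchange builds from the density: G(D)_mn = sum_ls D_ls
  ## [(mn|sl) - (ml|sn)/2], D = 2 C_occ C_occ^T
  gmat <- function(dm) {
    out <- matrix(0, nb, nb)
    for (mu in 1:nb) for (nu in 1:nb) {
      out[mu, nu] <- sum(dm * (g[mu, nu, , ] - 0.5 * g[mu, , , nu]))
    }
    out
  }
  coeff <- fix_gauge(eigen(h1, symmetric = TRUE)$vectors)
  dm <- 2 * tcrossprod(coeff[, seq_len(nocc), drop = FALSE])
  e_old <- Inf
  converged <- FALSE
  iterations <- max_iter
  eps <- NULL
  for (it in seq_len(max_iter)) {
    f <- h1 + gmat(dm)
    err <- f %*% dm - dm %*% f
    es <- eigen(f, symmetric = TRUE)
    ord <- order(es$values)
    coeff <- fix_gauge(es$vectors[, ord, drop = FALSE])
    eps <- es$values[ord]
    dm_new <- 2 * tcrossprod(coeff[, seq_len(nocc), drop = FALSE])
    dm <- damping * dm_new + (1 - damping) * dm
    e <- 0.5 * sum(dm * (h1 + f))
    if (abs(e - e_old) < 1e-12 && max(abs(err)) < 1e-8) {
      converged <- TRUE
      iterations <- it
      break
    }
    e_old <- e
  }
  if (!converged) {
    stop("RHF oracle did not converge within the iteration cap", call. = FALSE)
  }
  ## final energy from an idempotent density
  dm <- 2 * tcrossprod(coeff[, seq_len(nocc), drop = FALSE])
  f <- h1 + gmat(dm)
  energy <- 0.5 * sum(dm * (h1 + f)) + ints$core_constant
  list(energy = energy, coeff = coeff, orbital_energies = eps,
       converged = converged, iterations = iterations)
}
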