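## Shared fixtures and independent brute-force oracles for the test suite.
## The oracle energy terms below are literal nested-loop transcriptions of
## the functionals' printed sum windows, written against the raw two-electron
## tensor; they deliberately share no code with the package's vectorized
## implementations.

## Random integral set with exact 8-fold permutational eri symmetry.
random_sym_ints <- function(n, n_electrons = 2L, scale = 0.3, core = 0) {
  h <- matrix(rnorm(n * n), n)
  h <- (h + t(h)) / 2
  eri <- array(0, rep(n, 4))
  for (i in 1:n) for (j in 1:i) for (k in 1:i) {
    lmax <- if (k == i) j else k
    for (l in 1:lmax) {
      v <- rnorm(1) * scale
      for (idx in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                       c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                       c(k, l, j, i), c(l, k, j, i))) {
        eri[idx[1], idx[2], idx[3], idx[4]] <- v
      }
    }
  }
  integral_set(h, eri, core_constant = core, n_electrons = n_electrons)
}

## Random feasible occupancy state for a scheme (via random softmax params).
random_occ_state <- function(scheme, spread = 1.5, h_c = default_hc()) {
  npar <- sum(vapply(scheme$members[seq_len(scheme$n_pairs)], length,
                     integer(1)))
  params_to_occupancies(scheme, rnorm(npar) * spread, h_c = h_c)
}

## Raw integral accessors in physicist notation from chemist storage.
oracle_jkl <- function(ints) {
  n <- ints$n_basis
  jm <- matrix(0, n, n); km <- jm; lm <- jm
  for (p in 1:n) for (q in 1:n) {
    jm[p, q] <- ints$eri[p, p, q, q]   # <pq|pq>
    km[p, q] <- ints$eri[p, q, q, p]   # <pq|qp>
    lm[p, q] <- ints$eri[p, q, p, q]   # <pp|qq>
  }
  list(J = jm, K = km, L = lm)
}

oracle_phase <- function(scheme, occ) {
  sgn <- ifelse(seq_along(occ) <= scheme$n_pairs, 1, -1)
  sgn * sqrt(occ)
}

same_subspace <- function(scheme, p, q) {
  sp <- scheme$subspace_of[p]
  sq <- scheme$subspace_of[q]
  !is.na(sp) && !is.na(sq) && sp == sq
}

## Pair energies plus singles one-electron terms.
oracle_e_intra <- function(ints, scheme, occ) {
  cvec <- oracle_phase(scheme, occ)
  lmat <- oracle_jkl(ints)$L
  e <- 0
  for (g in seq_len(scheme$n_pairs)) {
    idx <- scheme$members[[g]]
    for (p in idx) e <- e + 2 * occ[p] * ints$h_one[p, p]
    for (q in idx) for (p in idx) e <- e + cvec[q] * cvec[p] * lmat[q, p]
  }
  for (g in seq_len(scheme$n_unpaired)) {
    orb <- scheme$members[[scheme$n_pairs + g]]
    e <- e + ints$h_one[orb, orb]
  }
  e
}

oracle_e_hf_inter <- function(ints, scheme, occ) {
  jkl <- oracle_jkl(ints)
  nb <- scheme$n_basis
  e <- 0
  for (p in 1:nb) for (q in 1:nb) {
    if (p == q || same_subspace(scheme, p, q)) next
    e <- e + occ[q] * occ[p] * (2 * jkl$J[p, q] - jkl$K[p, q])
  }
  e
}

oracle_e_sta_gnof <- function(ints, scheme, occ) {
  jkl <- oracle_jkl(ints)
  phi <- sqrt(occ * (1 - occ))
  nb <- scheme$n_basis
  n2 <- scheme$n_pairs
  nom <- scheme$n_subspaces
  distinct <- function(p, q) p != q && !same_subspace(scheme, p, q)
  s_l <- 0
  if (nom < nb) {
    for (p in 1:nom) for (q in (nom + 1):nb) {
      if (distinct(p, q)) s_l <- s_l + phi[q] * phi[p] * jkl$L[p, q]
    }
    for (p in (nom + 1):nb) for (q in 1:nom) {
      if (distinct(p, q)) s_l <- s_l + phi[q] * phi[p] * jkl$L[p, q]
    }
    for (p in (nom + 1):nb) for (q in (nom + 1):nb) {
      if (distinct(p, q)) s_l <- s_l + phi[q] * phi[p] * jkl$L[p, q]
    }
  }
  s_half <- 0
  if (nom > n2 && n2 >= 1) {
    for (p in 1:n2) for (q in (n2 + 1):nom) {
      if (distinct(p, q)) s_half <- s_half + phi[q] * phi[p] * jkl$L[p, q]
    }
    for (p in (n2 + 1):nom) for (q in 1:n2) {
      if (distinct(p, q)) s_half <- s_half + phi[q] * phi[p] * jkl$L[p, q]
    }
  }
  s_k <- 0
  if (nom > n2) {
    for (p in (n2 + 1):nom) for (q in (n2 + 1):nom) {
      if (distinct(p, q)) s_k <- s_k + phi[q] * phi[p] * jkl$K[p, q]
    }
  }
  -s_l - 0.5 * s_half - s_k
}

oracle_e_sta_gnofm <- function(ints, scheme, occ) {
  kmat <- oracle_jkl(ints)$K
  phi <- sqrt(occ * (1 - occ))
  nb <- scheme$n_basis
  e <- 0
  for (p in 1:nb) for (q in 1:nb) {
    if (p == q || same_subspace(scheme, p, q)) next
    e <- e - phi[q] * phi[p] * kmat[p, q]
  }
  e
}

oracle_e_dyn <- function(ints, scheme, occ, h_c = default_hc()) {
  lmat <- oracle_jkl(ints)$L
  nb <- scheme$n_basis
  nd <- numeric(nb)
  for (g in seq_len(scheme$n_pairs)) {
    for (p in scheme$members[[g]]) {
      nd[p] <- occ[p] * exp(-((1 - occ[g]) / h_c)^2)
    }
  }
  cd <- ifelse(seq_len(nb) <= scheme$n_pairs, 1, -1) * sqrt(nd)
  e <- 0
  for (p in 1:nb) for (q in 1:nb) {
    if (p == q || same_subspace(scheme, p, q)) next
    if (p <= scheme$n_pairs && q <= scheme$n_pairs) next
    e <- e + (cd[q] * cd[p] + nd[q] * nd[p]) * lmat[p, q]
  }
  e
}

## Closed-shell restricted HF energy expression at the given orbitals
## (not self-consistent): 2 sum_i h_ii + sum_ij (2 J_ij - K_ij), i,j occupied.
oracle_rhf_expression <- function(ints, nocc) {
  jkl <- oracle_jkl(ints)
  occ <- seq_len(nocc)
  2 * sum(diag(ints$h_one)[occ]) +
    sum(2 * jkl$J[occ, occ] - jkl$K[occ, occ]) + ints$core_constant
}

## Central finite differences of the total energy in the softmax parameters.
fd_occupation_gradient <- function(ints, scheme, params, functional_id,
                                   h_c = default_hc(), step = 1e-6) {
  vapply(seq_along(params), function(i) {
    up <- params; up[i] <- up[i] + step
    dn <- params; dn[i] <- dn[i] - step
    (total_energy(ints, scheme, params_to_occupancies(scheme, up, h_c),
                  functional_id)$e_total -
       total_energy(ints, scheme, params_to_occupancies(scheme, dn, h_c),
                    functional_id)$e_total) / (2 * step)
  }, numeric(1))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "nofpair", mustWork = TRUE)
}

fixture_meta <- function() {
  read.table(fixture_path("fixtures_meta.txt"), header = TRUE)
}

hubbard_dimer_exact <- function(u, t = 1) (u - sqrt(u^2 + 16 * t^2)) / 2

## Natural occupancies of the dimer ground state: cos^2/sin^2 of the mixing
## angle with tan(2 theta) = 4t/U.
hubbard_dimer_occ <- function(u, t = 1) {
  theta <- atan2(4 * t, u) / 2
  c(cos(theta)^2, sin(theta)^2)
}
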