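## The Hubbard dimer in its molecular-orbital basis is the workhorse here:
## h = diag(-1, +1) and J = K = L = U/2 everywhere, so every term can be
## evaluated by hand.
dimer_mo <- function(u = 4) {
  transform_basis(build_hubbard(2, 1, u, 2),
                  matrix(c(1, 1, 1, -1) / sqrt(2), 2))
}

test_that("intrapair energy reproduces hand evaluations on the dimer", {
  mo <- dimer_mo(4)
  s <- build_scheme(2, 1, 2, "max")
  ## pinned: 2 h_11 + J_11 = -2 + 2 = 0
  expect_equal(energy_intra(mo, s, occupancy_state(s, c(1, 0))), 0,
               tolerance = 1e-12)
  ## exact natural occupancies: the closed-form correlated energy
  occ <- hubbard_dimer_occ(4)
  expect_equal(energy_intra(mo, s, occupancy_state(s, occ)),
               hubbard_dimer_exact(4), tolerance = 1e-6)
  ## one-electron limit
  zero <- integral_set(mo$h_one, array(0, rep(2, 4)), n_electrons = 2)
  st <- occupancy_state(s, c(0.7, 0.3))
  expect_equal(energy_intra(zero, s, st),
               2 * sum(st$occ * diag(mo$h_one)), tolerance = 1e-12)
})

test_that("single-pair systems have no intersubspace terms", {
  mo <- dimer_mo(4)
  s <- build_scheme(2, 1, 2, "max")
  st <- occupancy_state(s, c(0.85, 0.15))
  expect_equal(energy_hf_inter(mo, s, st), 0)
  expect_equal(energy_static_gnof(mo, s, st), 0)
  expect_equal(energy_static_gnofm(mo, s, st), 0)
  expect_equal(energy_dynamic(mo, s, st), 0)
  ## hence GNOF and GNOFm breakdowns coincide for any two-electron system
  bg <- total_energy(mo, s, st, "gnof")
  bm <- total_energy(mo, s, st, "gnofm")
  expect_identical(unclass(bg)[1:7], unclass(bm)[1:7])
})

test_that("two singleton subspaces expand as the printed double sums", {
  set.seed(71)
  ints <- random_sym_ints(2, 4)        # N = 4: two strong-only pairs
  s <- build_scheme(4, 1, 2, "max")
  jkl <- jkl_matrices(ints)
  ## occ (1,1): both orderings of the HF term
  stp <- pinned_state(s)
  expect_equal(energy_hf_inter(ints, s, stp),
               2 * (2 * jkl$J[1, 2] - jkl$K[1, 2]), tolerance = 1e-12)
  ## vanishing occupancy kills its terms
  st0 <- occupancy_state(s, c(1, 0))
  expect_equal(energy_hf_inter(ints, s, st0), 0)
  ## GNOFm static at occ (1/2, 1/2): Phi = 1/2 each, both orderings
  sth <- occupancy_state(s, c(0.5, 0.5))
  expect_equal(energy_static_gnofm(ints, s, sth), -jkl$K[1, 2] / 2,
               tolerance = 1e-12)
  ## pinned occupancies: Phi = 0 kills both static forms
  expect_equal(energy_static_gnof(ints, s, stp), 0)
  expect_equal(energy_static_gnofm(ints, s, stp), 0)
  expect_equal(energy_dynamic(ints, s, stp), 0)
})

test_that("every term matches its literal loop transcription", {
  set.seed(81)
  for (rep in 1:8) {
    nb <- sample(4:8, 1)
    mult <- sample(c(1L, 3L), 1)
    n_el <- 4L
    sch <- build_scheme(n_el, mult, nb, "max")
    ints <- random_sym_ints(nb, n_el)
    st <- random_occ_state(sch)
    occ <- st$occ
    expect_equal(energy_intra(ints, sch, st),
                 oracle_e_intra(ints, sch, occ), tolerance = 1e-12)
    expect_equal(energy_hf_inter(ints, sch, st),
                 oracle_e_hf_inter(ints, sch, occ), tolerance = 1e-12)
    expect_equal(energy_static_gnof(ints, sch, st),
                 oracle_e_sta_gnof(ints, sch, occ), tolerance = 1e-12)
    expect_equal(energy_static_gnofm(ints, sch, st),
                 oracle_e_sta_gnofm(ints, sch, occ), tolerance = 1e-12)
    expect_equal(energy_dynamic(ints, sch, st),
                 oracle_e_dyn(ints, sch, occ), tolerance = 1e-12)
  }
})

test_that("pinned occupancies reduce every functional to Hartree-Fock", {
  set.seed(91)
  cases <- list(
    list(ints = random_sym_ints(5, 4), nocc = 2L),
    list(ints = random_sym_ints(6, 6), nocc = 3L),
    list(ints = dimer_mo(4), nocc = 1L))
  for (cs in cases) {
    sch <- build_scheme(2L * cs$nocc, 1, cs$ints$n_basis, "max")
    stp <- pinned_state(sch)
    e_hf <- oracle_rhf_expression(cs$ints, cs$nocc)
    for (f in c("pnof5", "gnof", "gnofm")) {
      bd <- total_energy(cs$ints, sch, stp, f)
      expect_equal(bd$e_total, e_hf, tolerance = 1e-10)
      expect_equal(bd$e_sta_inter, 0)
      expect_equal(bd$e_dyn_inter, 0)
    }
  }
})

test_that("GNOF and GNOFm share all terms except the static one", {
  set.seed(101)
  sch <- build_scheme(4, 1, 6, "max")
  ints <- random_sym_ints(6, 4)
  st <- random_occ_state(sch)
  bg <- total_energy(ints, sch, st, "gnof")
  bm <- total_energy(ints, sch, st, "gnofm")
  expect_identical(bg$e_intra, bm$e_intra)
  expect_identical(bg$e_hf_inter, bm$e_hf_inter)
  expect_identical(bg$e_dyn_inter, bm$e_dyn_inter)
  expect_false(isTRUE(all.equal(bg$e_sta_inter, bm$e_sta_inter)))
  ## PNOF5 has no static/dynamic terms at all
  bp <- total_energy(ints, sch, st, "pnof5")
  expect_identical(bp$e_sta_inter, 0)
  expect_identical(bp$e_dyn_inter, 0)
  expect_equal(bp$e_electronic, bp$e_intra + bp$e_hf_inter)
  expect_error(total_energy(ints, sch, st, "pnof7"), "arg")
})

test_that("terms are covariant under relabeling weak partners", {
  set.seed(111)
  sch <- build_scheme(2, 1, 4, "max")      # one pair: {1, 2, 3, 4}
  ints <- random_sym_ints(4, 2)
  st <- random_occ_state(sch)
  ## swap weak orbitals 3 and 4 in both the integrals and the occupancies
  perm <- c(1L, 2L, 4L, 3L)
  pints <- ints
  pints$h_one <- ints$h_one[perm, perm]
  pints$eri <- ints$eri[perm, perm, perm, perm]
  pst <- occupancy_state(sch, st$occ[perm])
  for (f in c("pnof5", "gnof", "gnofm")) {
    expect_equal(total_energy(pints, sch, pst, f)$e_total,
                 total_energy(ints, sch, st, f)$e_total, tolerance = 1e-12)
  }
})

test_that("occupation gradients match finite differences and vanish at optima", {
  set.seed(121)
  for (rep in 1:4) {
    nb <- sample(4:6, 1)
    sch <- build_scheme(4, 1, nb, "max")
    ints <- random_sym_ints(nb, 4)
    p <- rnorm(nb) * 0.8
    st <- params_to_occupancies(sch, p)
    for (f in c("pnof5", "gnof", "gnofm")) {
      g <- occupation_gradient(ints, sch, st, f)
      fd <- fd_occupation_gradient(ints, sch, p, f)
      expect_equal(g, fd, tolerance = 1e-6)
    }
  }
  ## stationarity at the dimer's exact natural occupancies
  mo <- dimer_mo(4)
  s2 <- build_scheme(2, 1, 2, "max")
  occ <- hubbard_dimer_occ(4)
  stx <- params_to_occupancies(s2, c(log(occ[1] / occ[2]), 0))
  expect_lt(max(abs(occupation_gradient(mo, s2, stx, "gnof"))), 1e-6)
  ## symmetric point on a symmetric problem: components sum to zero
  sts <- params_to_occupancies(s2, c(0, 0))
  gs <- occupation_gradient(mo, s2, sts, "gnof")
  expect_equal(sum(gs), 0, tolerance = 1e-10)
})
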