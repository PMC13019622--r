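dimer_mo_basis <- function(u = 4) {
  ints <- build_hubbard(2, 1, u, 2)
  es <- eigen(ints$h_one, symmetric = TRUE)
  transform_basis(ints, es$vectors[, order(es$values)])
}

test_that("occupancy optimization recovers the dimer's natural occupancies", {
  s <- build_scheme(2, 1, 2, "max")
  cfg <- solver_settings("gnof")
  mo <- dimer_mo_basis(4)
  st <- optimize_occupancies(mo, s,
                             params_to_occupancies(s, initial_params(s)), cfg)
  expect_equal(st$occ, hubbard_dimer_occ(4), tolerance = 1e-5)
  expect_lt(attr(st, "gnorm"), cfg$tol_gradient)
  expect_lt(attr(st, "max_constraint_defect"), 1e-10)

  ## non-interacting limit pins the occupancies
  mo0 <- dimer_mo_basis(0)
  st0 <- optimize_occupancies(mo0, s,
                              params_to_occupancies(s, initial_params(s)), cfg)
  expect_equal(st0$occ, c(1, 0), tolerance = 1e-5)

  ## a start at the optimum stays there
  pstar <- c(log(hubbard_dimer_occ(4)[1] / hubbard_dimer_occ(4)[2]), 0)
  st1 <- optimize_occupancies(mo, s, params_to_occupancies(s, pstar), cfg)
  expect_equal(st1$occ, hubbard_dimer_occ(4), tolerance = 1e-7)
})

test_that("orbital optimization is stationary at symmetry-fixed orbitals", {
  s <- build_scheme(2, 1, 2, "max")
  cfg <- solver_settings("gnof")
  ints <- build_hubbard(2, 1, 4, 2)
  es <- eigen(ints$h_one, symmetric = TRUE)
  cmo <- es$vectors[, order(es$values)]
  st <- occupancy_state(s, hubbard_dimer_occ(4))
  rot <- optimize_orbitals(ints, s, st, orbital_rotation(cmo), cfg)
  expect_lt(attr(rot, "gnorm"), cfg$tol_gradient)
  ## energy unchanged from the symmetry-determined molecular orbitals
  e0 <- total_energy(transform_basis(ints, cmo), s, st, "gnof")$e_total
  e1 <- total_energy(transform_basis(ints, rot), s, st, "gnof")$e_total
  expect_equal(e1, e0, tolerance = 1e-8)
})

test_that("zero-interaction pinned orbitals reach the one-electron minimum", {
  set.seed(131)
  h <- matrix(rnorm(16), 4); h <- (h + t(h)) / 2
  ints <- integral_set(h, array(0, rep(4, 4)), n_electrons = 4)
  s <- build_scheme(4, 1, 4, "max")
  stp <- pinned_state(s)
  start <- orbital_rotation(qr.Q(qr(matrix(rnorm(16), 4))))
  rot <- optimize_orbitals(ints, s, stp, start, solver_settings("gnof"))
  e <- total_energy(transform_basis(ints, rot), s, stp, "gnof")$e_total
  aufbau <- 2 * sum(sort(eigen(h, symmetric = TRUE)$values)[1:2])
  expect_equal(e, aufbau, tolerance = 1e-8)
})

test_that("a perturbed converged rotation re-enters the same minimum", {
  set.seed(141)
  ints <- build_hubbard(4, 1, 2, 4)
  s <- build_scheme(4, 1, 4, "max")
  cfg <- solver_settings("gnof")
  res <- solve_nof(ints, s, cfg)
  kappa <- matrix(0, 4, 4)
  kappa[lower.tri(kappa)] <- rnorm(6) * 0.02
  kappa <- kappa - t(kappa)
  pert <- orbital_rotation(res$rotation$coeff %*% nofpair:::expm_dense(kappa))
  rot2 <- optimize_orbitals(ints, s, res$occ_state, pert, cfg)
  e2 <- total_energy(transform_basis(ints, rot2), s, res$occ_state,
                     "gnof")$e_total
  expect_equal(e2, res$breakdown$e_total, tolerance = cfg$tol_energy)
})

test_that("analytic orbital gradient agrees with finite differences", {
  set.seed(151)
  for (mult in c(1L, 3L)) {
    nb <- 5
    sch <- build_scheme(4, mult, nb, "max")
    ints <- random_sym_ints(nb, 4)
    st <- random_occ_state(sch)
    for (f in c("pnof5", "gnof", "gnofm")) {
      ga <- orbital_gradient(ints, sch, st, f, "analytic")
      gn <- orbital_gradient(ints, sch, st, f, "numeric")
      expect_equal(ga, gn, tolerance = 1e-6)
      expect_equal(ga, -t(ga), tolerance = 1e-12)   # skew symmetry
    }
  }
})

test_that("the full solver hits the exact two-electron answers", {
  s <- build_scheme(2, 1, 2, "max")
  ints <- build_hubbard(2, 1, 4, 2)
  for (f in c("pnof5", "gnof", "gnofm")) {
    res <- solve_nof(ints, s, solver_settings(f))
    expect_true(res$converged)
    expect_equal(res$breakdown$e_total, hubbard_dimer_exact(4),
                 tolerance = 1e-6)
    expect_equal(sort(res$occ_state$occ, decreasing = TRUE),
                 hubbard_dimer_occ(4), tolerance = 1e-5)
  }
})

test_that("solver honours its monotonicity and determinism contracts", {
  ints <- build_hubbard(4, 1, 2, 4)
  s <- build_scheme(4, 1, 4, "max")
  cfg <- solver_settings("gnofm")
  r1 <- solve_nof(ints, s, cfg)
  r2 <- solve_nof(ints, s, cfg)
  expect_identical(r1$breakdown$e_total, r2$breakdown$e_total)
  expect_identical(r1$occ_state$occ, r2$occ_state$occ)
  expect_identical(r1$rotation$coeff, r2$rotation$coeff)
  tr <- r1$energy_trace
  expect_lte(tr[length(tr)], tr[1] + cfg$tol_energy)
  expect_lt(r1$max_constraint_defect, 1e-10)
  expect_true(r1$converged)
})

test_that("pinned-occupancy solve reproduces the SCF oracle", {
  ## dimer: closed form 2h + J = 0
  s <- build_scheme(2, 1, 2, "max")
  res <- rhf_reference(build_hubbard(2, 1, 4, 2), s)
  expect_equal(res$breakdown$e_total, 0, tolerance = 1e-8)
  expect_identical(res$breakdown$e_sta_inter, 0)
  expect_identical(res$breakdown$e_dyn_inter, 0)
  ## H2 fixture from a deliberately scrambled basis
  ints <- read_fcidump(fixture_path("h2_sto3g.fcidump"))
  set.seed(161)
  q <- qr.Q(qr(matrix(rnorm(4), 2)))
  scr <- transform_basis(ints, q)
  resH <- rhf_reference(scr, s)
  expect_equal(resH$breakdown$e_total, rhf_energy(scr)$energy,
               tolerance = 1e-8)
  ## zero-eri limit: aufbau one-electron energy
  set.seed(171)
  h <- matrix(rnorm(9), 3); h <- (h + t(h)) / 2
  zints <- integral_set(h, array(0, rep(3, 4)), n_electrons = 2)
  rz <- rhf_reference(zints, build_scheme(2, 1, 3, "max"))
  expect_equal(rz$breakdown$e_total,
               2 * min(eigen(h, symmetric = TRUE)$values), tolerance = 1e-8)
})

test_that("correlation energy is negative for interacting systems", {
  for (u in c(1, 4)) {
    ints <- build_hubbard(2, 1, u, 2)
    s <- build_scheme(2, 1, 2, "max")
    e_m <- solve_nof(ints, s, solver_settings("gnof"))$breakdown$e_total
    e_hf <- rhf_reference(ints, s)$breakdown$e_total
    expect_lt(e_m, e_hf)
  }
  ints <- read_fcidump(fixture_path("h2_sto3g.fcidump"))
  s <- build_scheme(2, 1, 2, "max")
  e_m <- solve_nof(ints, s, solver_settings("gnofm"))$breakdown$e_total
  expect_lt(e_m, rhf_reference(ints, s)$breakdown$e_total)
})
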