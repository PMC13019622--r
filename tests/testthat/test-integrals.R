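test_that("Hubbard construction matches its definition and exact limits", {
  ints <- build_hubbard(2, 1, 4, 2)
  expect_equal(ints$h_one, matrix(c(0, -1, -1, 0), 2))
  expect_equal(ints$eri[1, 1, 1, 1], 4)
  expect_equal(ints$eri[2, 2, 2, 2], 4)
  expect_equal(sum(abs(ints$eri)), 8)          # only the two on-site elements
  expect_equal(ints$core_constant, 0)
  expect_error(build_hubbard(2, 1, 4, 5), "exceeds")
  expect_error(build_hubbard(1, 1, 4, 2), "n_sites")

  ## periodic ring has the wrap bond
  ring <- build_hubbard(4, 1, 0, 4, periodic = TRUE)
  expect_equal(ring$h_one[1, 4], -1)

  ## tight-binding limit and the closed-form interacting dimer downstream
  expect_equal(fci_ground_energy(build_hubbard(2, 1, 0, 2))$energy, -2,
               tolerance = 1e-10)
  expect_equal(fci_ground_energy(build_hubbard(2, 1, 4, 2))$energy,
               hubbard_dimer_exact(4), tolerance = 1e-7)
})

test_that("FCIDUMP write/read round-trips field by field", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dimer.fcidump")
  ints <- build_hubbard(2, 1, 4, 2)
  write_fcidump(ints, path)
  back <- read_fcidump(path)
  expect_equal(back$h_one, ints$h_one, tolerance = 1e-12)
  expect_equal(back$eri, ints$eri, tolerance = 1e-12)
  expect_equal(back$core_constant, ints$core_constant)
  expect_identical(back$n_electrons, ints$n_electrons)
  expect_identical(back$ms2, ints$ms2)

  ## random dense tensor with full 8-fold symmetry
  set.seed(11)
  rnd <- random_sym_ints(4, 4, core = 0.37)
  path2 <- file.path(dir, "rand.fcidump")
  write_fcidump(rnd, path2)
  back2 <- read_fcidump(path2)
  expect_equal(back2$eri, rnd$eri, tolerance = 1e-12)
  expect_equal(back2$h_one, rnd$h_one, tolerance = 1e-12)
  expect_equal(back2$core_constant, rnd$core_constant, tolerance = 1e-12)

  ## all-zero eri emits no four-index records
  zero <- integral_set(matrix(c(0, -1, -1, 0), 2), array(0, rep(2, 4)),
                       n_electrons = 2)
  path3 <- file.path(dir, "zero.fcidump")
  write_fcidump(zero, path3)
  body <- readLines(path3)
  recs <- body[grepl("^\\s*-?[0-9]", body)]
  idx <- do.call(rbind, lapply(strsplit(trimws(recs), "\\s+"),
                               function(x) as.integer(x[2:5])))
  expect_true(all(idx[, 3] == 0 & idx[, 4] == 0))
})

test_that("FCIDUMP parser handles dialects and rejects malformed input", {
  dir <- withr::local_tempdir()
  ## single-record file, slash-terminated header
  p <- file.path(dir, "one.fcidump")
  writeLines(c("&FCI NORB=2,NELEC=2,MS2=0,", "/", "2.0 1 1 1 1"), p)
  ints <- read_fcidump(p)
  expect_equal(ints$eri[1, 1, 1, 1], 2)
  expect_equal(sum(abs(ints$eri)), 2)   # all other elements zero
  expect_equal(sum(abs(ints$h_one)), 0)

  p2 <- file.path(dir, "bad_header.fcidump")
  writeLines(c("&FCI NOTHING=2", "&END", "1.0 1 1 1 1"), p2)
  expect_error(read_fcidump(p2), "NORB")

  p3 <- file.path(dir, "bad_index.fcidump")
  writeLines(c("&FCI NORB=2,NELEC=2,MS2=0,", "&END", "1.0 3 1 1 1"), p3)
  expect_error(read_fcidump(p3), "out of range")

  expect_error(read_fcidump(file.path(dir, "missing")), "not found")
})

test_that("basis transformation preserves invariants and composes", {
  ints <- build_hubbard(2, 1, 4, 2)
  expect_equal(transform_basis(ints, diag(2))$eri, ints$eri)

  ## 45-degree rotation to the molecular-orbital basis (hand transform)
  cmat <- matrix(c(1, 1, 1, -1) / sqrt(2), 2)
  mo <- transform_basis(ints, cmat)
  expect_equal(mo$h_one, diag(c(-1, 1)), tolerance = 1e-12)
  expect_equal(unique(round(mo$eri[abs(mo$eri) > 1e-12], 10)), 2)  # U/2
  jkl <- jkl_matrices(mo)
  expect_equal(jkl$J, matrix(2, 2, 2), tolerance = 1e-12)
  expect_equal(jkl$K, matrix(2, 2, 2), tolerance = 1e-12)
  expect_equal(jkl$L, matrix(2, 2, 2), tolerance = 1e-12)

  ## composition law and conservation under a random orthogonal rotation
  set.seed(21)
  ints4 <- random_sym_ints(4, 4)
  r1 <- qr.Q(qr(matrix(rnorm(16), 4)))
  r2 <- qr.Q(qr(matrix(rnorm(16), 4)))
  once <- transform_basis(ints4, r1 %*% r2)
  twice <- transform_basis(transform_basis(ints4, r1), r2)
  expect_equal(twice$eri, once$eri, tolerance = 1e-10)
  expect_equal(twice$h_one, once$h_one, tolerance = 1e-10)
  rot <- transform_basis(ints4, r1)
  expect_equal(sum(diag(rot$h_one)), sum(diag(ints4$h_one)), tolerance = 1e-8)
  ## full-contraction eri invariant under orthogonal rotation of all indices
  expect_equal(sum(rot$eri * rot$eri), sum(ints4$eri * ints4$eri),
               tolerance = 1e-8)
  expect_error(transform_basis(ints4, matrix(rnorm(16), 4)), "orthogonal")
})

test_that("J, K, L obey the real-orbital identities", {
  set.seed(31)
  for (n in c(3, 5)) {
    ints <- random_sym_ints(n, 2)
    jkl <- jkl_matrices(ints)
    expect_equal(jkl$K, jkl$L, tolerance = 1e-12)
    expect_equal(diag(jkl$J), diag(jkl$K), tolerance = 1e-12)
    expect_equal(jkl$J, t(jkl$J), tolerance = 1e-12)
  }
  zero <- integral_set(diag(2), array(0, rep(2, 4)), n_electrons = 2)
  expect_equal(jkl_matrices(zero)$J, matrix(0, 2, 2))
})

test_that("packaged fixtures parse and carry the documented electron counts", {
  meta <- fixture_meta()
  for (i in seq_len(nrow(meta))) {
    ints <- read_fcidump(fixture_path(paste0(meta$system[i], "_sto3g.fcidump")))
    expect_identical(ints$n_basis, meta$n_orbitals[i])
    expect_true(ints$n_electrons %in% c(2L, 4L))
    expect_silent(jkl_matrices(ints))
  }
})
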