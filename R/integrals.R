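## Spin-free Hamiltonian integrals: construction, FCIDUMP I/O, orbital
## transformations, and the J/K/L matrices the functionals consume.
##
## Two-electron integrals are stored internally in chemist (Mulliken)
## convention, (ij|kl) = integral of i(1)j(1) r12^-1 k(2)l(2), the FCIDUMP
## native ordering. Physicist brackets <ij|kl> relate to it by
## <ij|kl> = (ik|jl); the conversion happens only at the jkl_matrices
## boundary.

#' Construct an integral set
#'
#' Bundles the spin-free one-electron matrix, the rank-4 two-electron tensor,
#' the scalar core (nuclear-repulsion) energy, and the electron/spin counts
#' that together define a molecular or lattice-model Hamiltonian.
#'
#' @param h_one Symmetric `n_basis x n_basis` one-electron matrix (hartree).
#' @param eri Rank-4 two-electron tensor, `dim = rep(n_basis, 4)` (hartree),
#'   with 8-fold permutational symmetry in the stored convention.
#' @param core_constant Scalar energy offset (nuclear repulsion), hartree.
#' @param n_electrons Number of electrons.
#' @param ms2 Twice the spin projection (`2*Sz`); non-negative.
#' @param convention `"chemist"` (default, FCIDUMP native) or `"physicist"`.
#' @param dipole_ints Optional list with `x`, `y`, `z` (symmetric matrices of
#'   position-operator integrals, atomic units) and `nuclear` (length-3
#'   nuclear dipole vector).
#'
#' @return An object of class `IntegralSet`.
#' @export
integral_set <- function(h_one, eri, core_constant = 0, n_electrons,
                         ms2 = 0L, convention = c("chemist", "physicist"),
                         dipole_ints = NULL) {
  convention <- match.arg(convention)
  h_one <- as.matrix(h_one)
  n_basis <- nrow(h_one)
  stopifnot_symmetric(h_one, 1e-10, "h_one")
  if (!identical(dim(eri), as.integer(rep(n_basis, 4)))) {
    stop("eri must be an n_basis^4 array", call. = FALSE)
  }
  if (n_electrons > 2 * n_basis) {
    stop("n_electrons exceeds 2*n_basis", call. = FALSE)
  }
  if (ms2 < 0) stop("ms2 must be non-negative", call. = FALSE)
  structure(
    list(n_basis = n_basis, n_electrons = as.integer(n_electrons),
         ms2 = as.integer(ms2), core_constant = core_constant,
         h_one = h_one, eri = eri, convention = convention,
         dipole_ints = dipole_ints),
    class = "IntegralSet")
}

#' @export
print.IntegralSet <- function(x, ...) {
  cat(sprintf("<IntegralSet> %d orbitals, %d electrons (ms2 = %d), %s convention\n",
              x$n_basis, x$n_electrons, x$ms2, x$convention))
  cat(sprintf("  core constant: %.10f hartree\n", x$core_constant))
  if (!is.null(x$dipole_ints)) cat("  dipole integrals attached\n")
  invisible(x)
}

#' Orbital rotation
#'
#' A real orthogonal matrix mapping the stored integral basis to the current
#' natural-orbital basis (columns are the new orbitals).
#'
#' @param coeff Square real matrix, orthogonal to within `tol`.
#' @param tol Orthogonality tolerance.
#' @return Object of class `OrbitalRotation`.
#' @export
orbital_rotation <- function(coeff, tol = 1e-8) {
  coeff <- as.matrix(coeff)
  if (!is_orthogonal(coeff, tol)) {
    stop("rotation matrix is not orthogonal within tolerance", call. = FALSE)
  }
  structure(list(coeff = coeff), class = "OrbitalRotation")
}

## Complete an eri tensor over the 8 permutational images of (i,j,k,l).
eri_set8 <- function(eri, i, j, k, l, value) {
  eri[i, j, k, l] <- value; eri[j, i, k, l] <- value
  eri[i, j, l, k] <- value; eri[j, i, l, k] <- value
  eri[k, l, i, j] <- value; eri[l, k, i, j] <- value
  eri[k, l, j, i] <- value; eri[l, k, j, i] <- value
  eri
}

#' Build Hubbard-model integrals
#'
#' Nearest-neighbour Hubbard chain (or ring) in the site basis: hopping `-t`
#' on bonds, on-site repulsion `(ii|ii) = u`, zero core constant. The 2-site
#' dimer at half filling is exactly solvable and serves as the main oracle
#' system: its ground-state energy is `(U - sqrt(U^2 + 16 t^2))/2`.
#'
#' @param n_sites Number of lattice sites (>= 2).
#' @param t Hopping amplitude (hartree).
#' @param u On-site repulsion (hartree).
#' @param n_electrons Electron count (<= 2 * n_sites).
#' @param periodic Add the wrap-around bond?
#' @return An [integral_set()].
#' @export
build_hubbard <- function(n_sites, t, u, n_electrons, periodic = FALSE) {
  if (n_sites < 2) stop("n_sites must be >= 2", call. = FALSE)
  if (n_electrons > 2 * n_sites) {
    stop("n_electrons exceeds 2*n_sites", call. = FALSE)
  }
  h <- matrix(0, n_sites, n_sites)
  for (i in seq_len(n_sites - 1)) h[i, i + 1] <- h[i + 1, i] <- -t
  if (periodic && n_sites > 2) h[1, n_sites] <- h[n_sites, 1] <- -t
  eri <- array(0, rep(n_sites, 4))
  for (i in seq_len(n_sites)) eri[i, i, i, i] <- u
  integral_set(h, eri, core_constant = 0, n_electrons = n_electrons, ms2 = 0L)
}

#' Attach site-position dipole integrals to a lattice integral set
#'
#' Positions are taken along x; the diagonal position operator in the site
#' basis is the natural dipole operator for lattice models and is used in
#' tests of the 1RDM dipole machinery.
#'
#' @param ints An [integral_set()] in the site basis.
#' @param positions Site coordinates (atomic units), length `n_basis`.
#' @param nuclear Length-3 nuclear dipole vector (defaults to cancelling
#'   charges `+1` per site at the same positions for a neutral lattice).
#' @return The integral set with `dipole_ints` populated.
#' @export
attach_site_dipole <- function(ints, positions,
                               nuclear = c(sum(positions), 0, 0)) {
  stopifnot(length(positions) == ints$n_basis)
  zero <- matrix(0, ints$n_basis, ints$n_basis)
  ints$dipole_ints <- list(x = diag(positions, ints$n_basis), y = zero,
                           z = zero, nuclear = nuclear)
  ints
}

#' Read an FCIDUMP file
#'
#' Parses the standard text format: a Fortran namelist header (`&FCI ... &END`
#' or terminated by `/`) declaring `NORB`, `NELEC`, `MS2`, followed by one
#' value and four indices per line. Indices follow the usual conventions:
#' `(i j k l)` two-electron records in chemist ordering, `(i j 0 0)`
#' one-electron records, `(0 0 0 0)` the core constant. Orbital symmetry
#' labels in the header are accepted and ignored. Tensors are
#' symmetry-completed on read.
#'
#' @param path Path to an FCIDUMP file.
#' @return An [integral_set()] with `convention = "chemist"`.
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ## locate end of namelist header
  hdr_end <- grep("(&END|^\\s*/\\s*$|/\\s*$)", lines, ignore.case = TRUE)[1]
  if (is.na(hdr_end)) stop("malformed FCIDUMP: unterminated header", call. = FALSE)
  header <- paste(lines[1:hdr_end], collapse = " ")
  getfield <- function(name) {
    m <- regmatches(header,
                    regexpr(paste0("(?i)", name, "\\s*=\\s*-?[0-9]+"), header,
                            perl = TRUE))
    if (length(m) == 0) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  norb <- getfield("NORB")
  nelec <- getfield("NELEC")
  ms2 <- getfield("MS2")
  if (is.na(norb) || is.na(nelec)) {
    stop("malformed FCIDUMP header: NORB/NELEC missing", call. = FALSE)
  }
  if (is.na(ms2)) ms2 <- 0L
  h <- matrix(0, norb, norb)
  eri <- array(0, rep(norb, 4))
  core <- 0
  body <- lines[-(1:hdr_end)]
  body <- body[nzchar(trimws(body))]
  for (ln in body) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) != 5) stop("malformed FCIDUMP record: ", ln, call. = FALSE)
    val <- as.numeric(tok[1])
    idx <- as.integer(tok[2:5])
    if (anyNA(idx) || is.na(val)) stop("malformed FCIDUMP record: ", ln, call. = FALSE)
    if (any(idx > norb) || any(idx < 0)) {
      stop("FCIDUMP index out of range in record: ", ln, call. = FALSE)
    }
    nz <- sum(idx > 0)
    if (nz == 0) {
      core <- val
    } else if (nz == 2 && all(idx[3:4] == 0)) {
      h[idx[1], idx[2]] <- val
      h[idx[2], idx[1]] <- val
    } else if (nz == 4) {
      eri <- eri_set8(eri, idx[1], idx[2], idx[3], idx[4], val)
    } else {
      stop("FCIDUMP index pattern not recognized: ", ln, call. = FALSE)
    }
  }
  integral_set(h, eri, core_constant = core, n_electrons = nelec, ms2 = ms2)
}

#' Write an FCIDUMP file
#'
#' Emits the standard namelist header and one record per symmetry-unique
#' element with magnitude above `1e-12`, in chemist convention.
#'
#' @param ints An [integral_set()] (chemist convention).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(ints, path) {
  stopifnot(inherits(ints, "IntegralSet"))
  if (ints$convention != "chemist") {
    stop("write_fcidump expects chemist-convention integrals", call. = FALSE)
  }
  n <- ints$n_basis
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf(" &FCI NORB=%d,NELEC=%d,MS2=%d,", n, ints$n_electrons, ints$ms2),
    sprintf("  ORBSYM=%s", paste(rep("1,", n), collapse = "")),
    "  ISYM=1,",
    " &END"), con)
  fmt <- function(v, i, j, k, l) sprintf("%23.16E %4d %4d %4d %4d", v, i, j, k, l)
  out <- character(0)
  for (i in 1:n) for (j in 1:i) for (k in 1:i) {
    lmax <- if (k == i) j else k
    for (l in 1:lmax) {
      v <- ints$eri[i, j, k, l]
      if (abs(v) > 1e-12) out <- c(out, fmt(v, i, j, k, l))
    }
  }
  for (i in 1:n) for (j in 1:i) {
    if (abs(ints$h_one[i, j]) > 1e-12) {
      out <- c(out, fmt(ints$h_one[i, j], i, j, 0, 0))
    }
  }
  out <- c(out, fmt(ints$core_constant, 0, 0, 0, 0))
  writeLines(out, con)
  invisible(path)
}

#' Transform integrals to a rotated orbital basis
#'
#' Applies the one-electron similarity transform and the four-index transform
#' to express the Hamiltonian in the natural-orbital basis defined by `rot`.
#' The stored convention and core constant are unchanged.
#'
#' @param ints An [integral_set()].
#' @param rot An [orbital_rotation()] (or bare orthogonal matrix).
#' @return The transformed [integral_set()].
#' @export
transform_basis <- function(ints, rot) {
  c_mat <- if (inherits(rot, "OrbitalRotation")) rot$coeff else as.matrix(rot)
  n <- ints$n_basis
  if (!identical(dim(c_mat), c(n, n))) stop("dimension mismatch", call. = FALSE)
  if (!is_orthogonal(c_mat, 1e-8)) {
    stop("rotation is not orthogonal within 1e-8", call. = FALSE)
  }
  h_new <- crossprod(c_mat, ints$h_one %*% c_mat)
  ## four-index transform, one index at a time: O(n^5)
  g <- ints$eri
  g <- apply_1index(g, c_mat, 1)
  g <- apply_1index(g, c_mat, 2)
  g <- apply_1index(g, c_mat, 3)
  g <- apply_1index(g, c_mat, 4)
  out <- ints
  out$h_one <- (h_new + t(h_new)) / 2
  out$eri <- g
  if (!is.null(ints$dipole_ints)) {
    out$dipole_ints <- lapply(ints$dipole_ints, function(m) {
      if (is.matrix(m)) crossprod(c_mat, m %*% c_mat) else m
    })
  }
  out
}

## Contract one index of a rank-4 tensor with the rotation matrix.
apply_1index <- function(g, c_mat, which_index) {
  n <- dim(g)[1]
  gm <- aperm(g, c(which_index, setdiff(1:4, which_index)))
  dim(gm) <- c(n, n^3)
  gm <- crossprod(c_mat, gm)
  dim(gm) <- rep(n, 4)
  aperm(gm, order(c(which_index, setdiff(1:4, which_index))))
}

#' Coulomb, exchange, and exchange-time-inversion matrices
#'
#' Computes `J_pq = <pq|pq>`, `K_pq = <pq|qp>`, and `L_pq = <pp|qq>` from the
#' stored tensor. In chemist storage these are `(pp|qq)`, `(pq|qp)`, and
#' `(pq|pq)` respectively. For real orbitals `K = L` elementwise; this is
#' asserted to `1e-10`.
#'
#' @param ints An [integral_set()] in chemist convention.
#' @return List with symmetric matrices `J`, `K`, `L` (hartree).
#' @export
jkl_matrices <- function(ints) {
  stopifnot(inherits(ints, "IntegralSet"))
  if (ints$convention != "chemist") {
    stop("jkl_matrices expects chemist-convention storage", call. = FALSE)
  }
  n <- ints$n_basis
  g <- ints$eri
  jm <- matrix(0, n, n); km <- jm; lm <- jm
  for (p in 1:n) for (q in 1:n) {
    jm[p, q] <- g[p, p, q, q]
    km[p, q] <- g[p, q, q, p]
    lm[p, q] <- g[p, q, p, q]
  }
  if (max(abs(km - lm)) > 1e-10) {
    stop("K and L differ beyond 1e-10: integrals are not real-orbital symmetric",
         call. = FALSE)
  }
  list(J = jm, K = km, L = lm)
}
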