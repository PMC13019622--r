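## Electron-pairing scheme: the partition of the orbital space into mutually
## disjoint subspaces, each carrying one electron pair (or one unpaired
## electron), that underpins every functional in the package.

#' Build an electron-pairing scheme
#'
#' Partitions the orbital space into `N_II/2` pair subspaces and `N_I`
#' singly occupied singleton subspaces. With `N_I = multiplicity - 1`
#' unpaired electrons, orbitals `1..N_II/2` are the strongly occupied
#' references, orbitals `N_II/2+1 .. N_omega` are the singles
#' (`N_omega = N_II/2 + N_I`), and the remaining (weakly occupied) orbitals
#' are dealt to the pair subspaces from orbital `N_omega+1` upward.
#'
#' Orbitals are assumed ordered by ascending orbital energy (the optimizer's
#' core guess produces this ordering); the scheme itself is purely an index
#' partition.
#'
#' @param n_electrons Total electron count `N`.
#' @param multiplicity Spin multiplicity `2S+1`; `N_I = multiplicity - 1`.
#' @param n_basis Number of orbitals available.
#' @param coupling `"max"` (deal every remaining orbital, the default and the
#'   recommended choice: all electrons correlated across all orbitals) or a
#'   fixed integer number of weak partners per pair.
#' @param dealing `"stacked"` (pair 1 takes the highest-index block, counting
#'   down) or `"interleaved"` (weak orbitals dealt round-robin in ascending
#'   order).
#' @return Object of class `PairingScheme` with fields `n_electrons`,
#'   `n_unpaired`, `n_paired`, `n_pairs`, `n_subspaces`, `n_basis`,
#'   `coupling` (per-pair weak counts), `subspace_of` (orbital -> subspace
#'   index, `NA` for uncorrelated orbitals), `role_of` (orbital ->
#'   `"strong"`, `"weak"`, `"single"`, or `"none"`), and `members` (list of
#'   orbital indices per subspace).
#' @export
build_scheme <- function(n_electrons, multiplicity, n_basis,
                         coupling = "max",
                         dealing = c("stacked", "interleaved")) {
  dealing <- match.arg(dealing)
  n_electrons <- as.integer(n_electrons)
  multiplicity <- as.integer(multiplicity)
  n_basis <- as.integer(n_basis)
  n_unpaired <- multiplicity - 1L
  n_paired <- n_electrons - n_unpaired
  if (n_paired < 0 || n_paired %% 2 != 0) {
    stop("multiplicity incompatible with electron count: N_II = N - (2S) must be even and non-negative",
         call. = FALSE)
  }
  n_pairs <- n_paired %/% 2L
  n_sub <- n_pairs + n_unpaired
  if (n_basis < n_sub) {
    stop("n_basis smaller than the number of subspaces", call. = FALSE)
  }
  n_virtual <- n_basis - n_sub
  if (identical(coupling, "max")) {
    if (n_pairs > 0) {
      base <- n_virtual %/% n_pairs
      extra <- n_virtual %% n_pairs
      ## earlier pairs receive the extras
      n_g <- rep(base, n_pairs) + as.integer(seq_len(n_pairs) <= extra)
    } else n_g <- integer(0)
  } else {
    coupling <- as.integer(coupling)
    if (coupling < 1) stop("coupling must be >= 1 or \"max\"", call. = FALSE)
    if (n_pairs * coupling > n_virtual) {
      stop("insufficient virtual orbitals for requested coupling", call. = FALSE)
    }
    n_g <- rep(coupling, max(n_pairs, 0L))
  }
  subspace_of <- rep(NA_integer_, n_basis)
  role_of <- rep("none", n_basis)
  members <- vector("list", n_sub)
  if (n_pairs > 0) {
    for (g in seq_len(n_pairs)) {
      subspace_of[g] <- g
      role_of[g] <- "strong"
      members[[g]] <- g
    }
  }
  if (n_unpaired > 0) {
    for (k in seq_len(n_unpaired)) {
      orb <- n_pairs + k
      subspace_of[orb] <- n_pairs + k
      role_of[orb] <- "single"
      members[[n_pairs + k]] <- orb
    }
  }
  if (n_pairs > 0 && sum(n_g) > 0) {
    if (dealing == "stacked") {
      ## pair 1 takes the contiguous block counting down from n_basis
      cursor <- n_basis
      for (g in seq_len(n_pairs)) {
        if (n_g[g] == 0) next
        blk <- as.integer(seq(cursor, by = -1L, length.out = n_g[g]))
        cursor <- cursor - n_g[g]
        subspace_of[blk] <- g
        role_of[blk] <- "weak"
        members[[g]] <- c(members[[g]], sort(blk))
      }
    } else {
      ## round-robin: deal ascending virtuals to pairs 1,2,...,n_pairs cyclically
      pool <- seq(n_sub + 1L, n_basis)
      counts <- integer(n_pairs)
      g <- 1L
      for (orb in pool) {
        tried <- 0L
        while (counts[g] >= n_g[g] && tried < n_pairs) {
          g <- (g %% n_pairs) + 1L
          tried <- tried + 1L
        }
        if (counts[g] >= n_g[g]) break  # all pairs full (fixed coupling)
        subspace_of[orb] <- g
        role_of[orb] <- "weak"
        members[[g]] <- c(members[[g]], orb)
        counts[g] <- counts[g] + 1L
        g <- (g %% n_pairs) + 1L
      }
    }
  }
  structure(
    list(n_electrons = as.integer(n_electrons),
         n_unpaired = as.integer(n_unpaired),
         n_paired = as.integer(n_paired),
         n_pairs = as.integer(n_pairs),
         n_subspaces = as.integer(n_sub),
         n_basis = as.integer(n_basis),
         coupling = n_g,
         subspace_of = subspace_of,
         role_of = role_of,
         members = members,
         dealing = dealing),
    class = "PairingScheme")
}

#' @export
print.PairingScheme <- function(x, ...) {
  cat(sprintf("<PairingScheme> N = %d (%d paired + %d unpaired), %d orbitals\n",
              x$n_electrons, x$n_paired, x$n_unpaired, x$n_basis))
  for (g in seq_along(x$members)) {
    kind <- if (g <= x$n_pairs) "pair" else "single"
    cat(sprintf("  subspace %d (%s): {%s}\n", g, kind,
                paste(x$members[[g]], collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a pairing scheme to a plain-text table
#'
#' @param scheme A [build_scheme()] result.
#' @return Character vector, one line per orbital (`orbital  subspace  role`).
#' @export
format_scheme_table <- function(scheme) {
  c("orbital subspace role",
    sprintf("%7d %8s %4s", seq_len(scheme$n_basis),
            ifelse(is.na(scheme$subspace_of), "-", scheme$subspace_of),
            scheme$role_of))
}

#' Check occupancies against the pairing constraints
#'
#' Reports, per pair subspace, the defect of the pairing sum
#' `|sum_{p in subspace} n_p - 1|`; per single, `|n_g - 1/2|`; and the trace
#' defect `|2 sum_p n_p - N|`. Passes iff every defect is below `tol`.
#'
#' @param scheme A [build_scheme()] result.
#' @param occ Occupancy vector of length `n_basis`, entries in `[0, 1]`.
#' @param tol Pass tolerance (default `1e-8`).
#' @return List with `pass`, `pair_defects`, `single_defects`, `trace_defect`,
#'   `max_defect`.
#' @export
validate_occupancies <- function(scheme, occ, tol = 1e-8) {
  stopifnot(inherits(scheme, "PairingScheme"))
  if (length(occ) != scheme$n_basis) {
    stop("occ length must equal n_basis", call. = FALSE)
  }
  if (any(occ < -1e-12 | occ > 1 + 1e-12)) {
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  }
  pair_defects <- if (scheme$n_pairs > 0) {
    vapply(seq_len(scheme$n_pairs),
           function(g) abs(sum(occ[scheme$members[[g]]]) - 1), numeric(1))
  } else numeric(0)
  single_defects <- if (scheme$n_unpaired > 0) {
    vapply(seq_len(scheme$n_unpaired) + scheme$n_pairs,
           function(g) abs(occ[scheme$members[[g]]] - 0.5), numeric(1))
  } else numeric(0)
  trace_defect <- abs(2 * sum(occ) - scheme$n_electrons)
  defects <- c(pair_defects, single_defects, trace_defect)
  list(pass = all(defects < tol),
       pair_defects = pair_defects,
       single_defects = single_defects,
       trace_defect = trace_defect,
       max_defect = max(defects))
}
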