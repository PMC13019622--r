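## Two-level solver: momentum (ADAM) optimization of the occupation
## parameters at fixed orbitals, alternated with orthogonal-rotation
## optimization of the orbitals at fixed occupancies, until the outer energy
## is stationary. The pairing constraint holds at every iterate by
## construction (softmax parametrization); orthogonality is preserved by
## exponential (skew-symmetric generator) updates.

#' Solver settings
#'
#' @param functional_id One of `"pnof5"`, `"gnof"`, `"gnofm"`.
#' @param max_outer Maximum outer (occupancy/orbital alternation) sweeps.
#' @param tol_energy Outer convergence threshold on the energy change
#'   (hartree).
#' @param tol_gradient Inner convergence threshold on gradient norms.
#' @param adam_rate,adam_beta1,adam_beta2 ADAM step size and momentum decays.
#' @param max_occ_steps,max_orb_steps Inner iteration caps per sweep.
#' @param h_c Hole-damping constant for dynamic occupancies.
#' @param orbital_gradient `"analytic"` (generalized-Fock assembly) or
#'   `"numeric"` (central differences; reference route for small systems).
#' @param seed Integer seed, used only by optional random-perturbation
#'   diagnostics; the default solve path is deterministic.
#' @return List of class `SolverSettings`.
#' @export
solver_settings <- function(functional_id = "gnof", max_outer = 50L,
                            tol_energy = 1e-6, tol_gradient = 1e-5,
                            adam_rate = 0.05, adam_beta1 = 0.9,
                            adam_beta2 = 0.999, max_occ_steps = 300L,
                            max_orb_steps = 150L, h_c = default_hc(),
                            orbital_gradient = c("analytic", "numeric"),
                            seed = 1L) {
  stopifnot(tol_energy > 0, tol_gradient > 0,
            adam_rate > 0, adam_rate < 1,
            adam_beta1 > 0, adam_beta1 < 1, adam_beta2 > 0, adam_beta2 < 1)
  structure(
    list(functional_id = match.arg(functional_id, functional_ids),
         max_outer = as.integer(max_outer), tol_energy = tol_energy,
         tol_gradient = tol_gradient, adam_rate = adam_rate,
         adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
         max_occ_steps = as.integer(max_occ_steps),
         max_orb_steps = as.integer(max_orb_steps), h_c = h_c,
         orbital_gradient = match.arg(orbital_gradient),
         seed = as.integer(seed)),
    class = "SolverSettings")
}

## One ADAM run over a generic objective; returns the final point and the
## iterate trace (used for constraint monitoring).
adam_minimize <- function(x0, fn_grad, rate, beta1, beta2, max_steps, tol,
                          eps = 1e-8, callback = NULL) {
  x <- x0
  m <- numeric(length(x))
  v <- numeric(length(x))
  gnorm <- Inf
  for (step in seq_len(max_steps)) {
    g <- fn_grad(x)
    gnorm <- vnorm(g)
    if (!is.null(callback)) callback(x)
    if (gnorm < tol) break
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^step)
    vhat <- v / (1 - beta2^step)
    x <- x - rate * mhat / (sqrt(vhat) + eps)
  }
  list(x = x, gnorm = gnorm, steps = step)
}

#' Optimize occupation numbers at fixed orbitals
#'
#' ADAM descent on the unconstrained softmax parameters; the pairing sums
#' equal one electron pair at every iterate by construction.
#'
#' @param ints Integrals in the current (fixed) orbital basis.
#' @param scheme A [build_scheme()] result.
#' @param start An `OccupancyState` carrying `params` (see
#'   [params_to_occupancies()], [initial_params()]).
#' @param settings A [solver_settings()].
#' @return The optimized `OccupancyState`, with attributes `gnorm` (final
#'   gradient norm) and `max_constraint_defect` (largest pairing/trace
#'   defect over all iterates).
#' @export
optimize_occupancies <- function(ints, scheme, start, settings) {
  stopifnot(inherits(start, "OccupancyState"), !is.null(start$params))
  max_defect <- 0
  fn_grad <- function(p) {
    st <- params_to_occupancies(scheme, p, h_c = settings$h_c)
    g <- occupation_gradient(ints, scheme, st, settings$functional_id)
    if (!all(is.finite(g))) {
      stop("non-finite occupation gradient encountered", call. = FALSE)
    }
    g
  }
  track <- function(p) {
    st <- params_to_occupancies(scheme, p, h_c = settings$h_c)
    rep_ <- validate_occupancies(scheme, st$occ)
    max_defect <<- max(max_defect, rep_$max_defect)
  }
  if (length(start$params) == 0) {
    out <- list(x = start$params, gnorm = 0)
  } else {
    out <- adam_minimize(start$params, fn_grad, settings$adam_rate,
                         settings$adam_beta1, settings$adam_beta2,
                         settings$max_occ_steps, settings$tol_gradient,
                         callback = track)
    if (out$gnorm >= settings$tol_gradient) {
      ## quasi-Newton polish: the parameters are unconstrained, so BFGS with
      ## the analytic gradient tightens the tail ADAM crawls through
      fn <- function(p) {
        st <- params_to_occupancies(scheme, p, h_c = settings$h_c)
        total_energy(ints, scheme, st, settings$functional_id)$e_total
      }
      gr <- function(p) {
        track(p)
        fn_grad(p)
      }
      fit <- stats::optim(out$x, fn, gr, method = "BFGS",
                          control = list(maxit = settings$max_occ_steps,
                                         reltol = 1e-15))
      out <- list(x = fit$par, gnorm = vnorm(fn_grad(fit$par)))
    }
  }
  st <- params_to_occupancies(scheme, out$x, h_c = settings$h_c)
  e <- total_energy(ints, scheme, st, settings$functional_id)$e_total
  if (!is.finite(e)) stop("non-finite energy encountered", call. = FALSE)
  attr(st, "gnorm") <- out$gnorm
  attr(st, "max_constraint_defect") <- max_defect
  st
}

## Lower-triangle vectorization of a skew-symmetric generator.
skew_from_vec <- function(kappa, n) {
  x <- matrix(0, n, n)
  x[lower.tri(x)] <- kappa
  x - t(x)
}

vec_from_skew <- function(x) x[lower.tri(x)]

#' Orbital-rotation energy gradient
#'
#' Gradient of the total energy with respect to the skew-symmetric generator
#' of an orbital rotation about the current basis (evaluated at zero
#' rotation). The analytic route assembles the non-symmetric
#' generalized-Fock (Lagrangian-style) matrix
#' `F_tp = 2 w_p H_tp + 4 sum_q [A_pq (tp|qq) + B_pq (tq|qp) + D_pq (tq|pq)]`
#' from the occupancy-dependent coefficient matrices of the functional's
#' J/K/L bilinear forms; the gradient is its antisymmetric part
#' `F - t(F)`. The numeric route uses central finite differences.
#'
#' @param ints Integrals in the current orbital basis.
#' @param scheme,occ_state,functional_id As in [total_energy()].
#' @param method `"analytic"` or `"numeric"`.
#' @return Skew-symmetric `n_basis x n_basis` gradient matrix.
#' @export
orbital_gradient <- function(ints, scheme, occ_state, functional_id = "gnof",
                             method = c("analytic", "numeric")) {
  method <- match.arg(method)
  if (method == "numeric") return(orbital_gradient_fd(ints, scheme, occ_state,
                                                      functional_id))
  cf <- functional_coefficients(scheme, occ_state, functional_id)
  n <- ints$n_basis
  g <- ints$eri
  h <- ints$h_one
  fmat <- matrix(0, n, n)
  for (p in 1:n) {
    m1 <- matrix(0, n, n); m2 <- m1; m3 <- m1
    for (q in 1:n) {
      m1[, q] <- g[, p, q, q]   # (tp|qq)
      m2[, q] <- g[, q, q, p]   # (tq|qp)
      m3[, q] <- g[, q, p, q]   # (tq|pq)
    }
    fmat[, p] <- 2 * cf$w[p] * h[, p] +
      4 * (m1 %*% cf$A[p, ] + m2 %*% cf$B[p, ] + m3 %*% cf$D[p, ])
  }
  fmat - t(fmat)
}

## Occupancy-dependent coefficient matrices such that the electronic energy
## is sum_p w_p H_pp + sum_pq [A_pq J_pq + B_pq K_pq + D_pq L_pq].
functional_coefficients <- function(scheme, occ_state, functional_id) {
  functional_id <- match.arg(functional_id, functional_ids)
  nb <- scheme$n_basis
  a <- matrix(0, nb, nb); b <- a; d <- a
  m <- inter_mask(scheme)
  nn <- outer(occ_state$occ, occ_state$occ)
  a <- a + 2 * m * nn
  b <- b - m * nn
  d <- d + intra_pair_mask(scheme) * outer(occ_state$phases, occ_state$phases)
  if (functional_id != "pnof5") {
    pp <- outer(occ_state$phi, occ_state$phi)
    if (functional_id == "gnof") {
      wv <- gnof_static_weights(scheme)
      d <- d - wv$W * pp
      b <- b - wv$V * pp
    } else {
      b <- b - m * pp
    }
    nd <- occ_state$dyn_occ
    cd <- phase_signs(scheme) * sqrt(nd)
    d <- d + dynamic_mask(scheme) * (outer(cd, cd) + outer(nd, nd))
  }
  list(w = one_electron_weights(scheme, occ_state), A = a, B = b, D = d)
}

## Finite-difference orbital gradient (reference route).
orbital_gradient_fd <- function(ints, scheme, occ_state, functional_id,
                                h = 1e-5) {
  n <- ints$n_basis
  npar <- n * (n - 1) / 2
  g <- numeric(npar)
  for (k in seq_len(npar)) {
    kp <- numeric(npar); kp[k] <- h
    km <- numeric(npar); km[k] <- -h
    ep <- total_energy(transform_basis(ints, expm_dense(skew_from_vec(kp, n))),
                       scheme, occ_state, functional_id)$e_total
    em <- total_energy(transform_basis(ints, expm_dense(skew_from_vec(km, n))),
                       scheme, occ_state, functional_id)$e_total
    g[k] <- (ep - em) / (2 * h)
  }
  skew_from_vec(g, n)
}

#' Optimize orbitals at fixed occupancies
#'
#' Quasi-Newton (BFGS) minimization over the skew-symmetric rotation
#' generator, recentered every round: each round optimizes the energy as a
#' function of a generator applied on top of the accumulated rotation, then
#' folds the result in through an exponential (exactly orthogonal) update,
#' with a Loewdin re-orthonormalization whenever numerical drift exceeds
#' `1e-8`. The gradient is the analytic generalized-Fock antisymmetry (or
#' central finite differences, per `settings$orbital_gradient`), evaluated
#' at the rotated basis; recentering keeps it exact at each round's origin.
#' Declared converged when its norm drops below `tol_gradient`.
#'
#' @param ints Integrals in the stored (reference) basis.
#' @param scheme,occ_state As in [total_energy()].
#' @param start An [orbital_rotation()] (defaults to identity).
#' @param settings A [solver_settings()]; `max_orb_steps` is the total
#'   quasi-Newton iteration budget.
#' @return The optimized [orbital_rotation()], with attribute `gnorm`.
#' @export
optimize_orbitals <- function(ints, scheme, occ_state,
                              start = orbital_rotation(diag(ints$n_basis)),
                              settings = solver_settings()) {
  n <- ints$n_basis
  cmat <- start$coeff
  npar <- n * (n - 1) / 2
  grad_at <- function(cm) {
    gmat <- orbital_gradient(transform_basis(ints, cm), scheme, occ_state,
                             settings$functional_id,
                             settings$orbital_gradient)
    vec_from_skew(gmat)
  }
  if (npar == 0) {
    out <- orbital_rotation(cmat)
    attr(out, "gnorm") <- 0
    return(out)
  }
  gnorm <- vnorm(grad_at(cmat))
  budget <- settings$max_orb_steps
  round_iters <- max(20L, min(50L, budget))
  while (budget > 0 && gnorm >= settings$tol_gradient) {
    fn <- function(kappa) {
      cur <- cmat %*% expm_dense(skew_from_vec(kappa, n))
      total_energy(transform_basis(ints, cur), scheme, occ_state,
                   settings$functional_id)$e_total
    }
    gr <- function(kappa) grad_at(cmat %*% expm_dense(skew_from_vec(kappa, n)))
    fit <- stats::optim(numeric(npar), fn, gr, method = "BFGS",
                        control = list(maxit = min(round_iters, budget),
                                       reltol = 1e-15))
    budget <- budget - round_iters
    cmat <- cmat %*% expm_dense(skew_from_vec(fit$par, n))
    if (!is_orthogonal(cmat, 1e-8)) cmat <- reorthogonalize(cmat)
    gnorm_new <- vnorm(grad_at(cmat))
    if (gnorm_new >= gnorm * (1 - 1e-12) && vnorm(fit$par) == 0) break
    gnorm <- gnorm_new
  }
  out <- orbital_rotation(cmat)
  attr(out, "gnorm") <- gnorm
  out
}

#' Solve a functional: alternate occupancy and orbital optimization
#'
#' Starting from the core-guess orbitals (eigenvectors of the one-electron
#' matrix, ascending eigenvalues) and a near-pinned seeded occupancy start,
#' the two inner solvers are alternated until the outer energy changes by
#' less than `tol_energy` on two consecutive sweeps. Because a stationary
#' point of the alternation can be a saddle of the orbital-rotation
#' landscape, the converged solution is probed with small seeded random
#' rotations; if a probe relaxes to a lower energy the alternation resumes
#' from there. The probe directions are drawn from `settings$seed`, so the
#' whole solve remains deterministic for fixed inputs and settings.
#'
#' @param ints An [integral_set()].
#' @param scheme A [build_scheme()] result (consistent electron count).
#' @param settings A [solver_settings()].
#' @param pinned If `TRUE`, occupancies are held at their Hartree-Fock
#'   values (1/0 and 1/2) and only orbitals are optimized.
#' @param start_rotation Optional initial [orbital_rotation()]; by default
#'   the core guess, or the identity when `ints` is already a converged
#'   basis.
#' @return Object of class `SolverResult`: `breakdown` (an
#'   `EnergyBreakdown`), `occ_state`, `rotation`, `converged`,
#'   `outer_iterations`, `energy_trace`, `max_constraint_defect`.
#' @export
solve_nof <- function(ints, scheme, settings = solver_settings(),
                      pinned = FALSE, start_rotation = NULL) {
  stopifnot(inherits(ints, "IntegralSet"), inherits(scheme, "PairingScheme"))
  if (is.null(start_rotation)) {
    es <- eigen(ints$h_one, symmetric = TRUE)
    ord <- order(es$values)
    start_rotation <- orbital_rotation(fix_gauge(es$vectors[, ord, drop = FALSE]))
  }
  n <- ints$n_basis
  npar <- n * (n - 1L) / 2L
  state <- if (pinned) pinned_state(scheme, h_c = settings$h_c) else {
    params_to_occupancies(scheme, initial_params(scheme), h_c = settings$h_c)
  }
  env <- new.env()
  env$trace <- numeric(0)
  env$max_defect <- 0
  env$sweeps <- 0L

  energy_at <- function(rot, st) {
    total_energy(transform_basis(ints, rot), scheme, st,
                 settings$functional_id)$e_total
  }

  alternate <- function(rot, st) {
    e_prev <- energy_at(rot, st)
    env$trace <- c(env$trace, e_prev)
    converged <- FALSE
    occ_gnorm <- 0
    orb_gnorm <- 0
    small_changes <- 0L
    while (env$sweeps < settings$max_outer) {
      env$sweeps <- env$sweeps + 1L
      if (!pinned) {
        cur <- transform_basis(ints, rot)
        st <- optimize_occupancies(cur, scheme, st, settings)
        occ_gnorm <- attr(st, "gnorm")
        env$max_defect <- max(env$max_defect,
                              attr(st, "max_constraint_defect"))
      }
      rot <- optimize_orbitals(ints, scheme, st, rot, settings)
      orb_gnorm <- attr(rot, "gnorm")
      e <- energy_at(rot, st)
      env$trace <- c(env$trace, e)
      small_changes <- if (abs(e - e_prev) < settings$tol_energy) {
        small_changes + 1L
      } else 0L
      e_prev <- e
      if (small_changes >= 2L) {
        converged <- occ_gnorm < settings$tol_gradient &&
          orb_gnorm < settings$tol_gradient
        if (converged || small_changes >= 4L) break
      }
    }
    list(rot = rot, st = st, converged = converged, energy = e_prev)
  }

  sol <- alternate(start_rotation, state)
  ## saddle probes: perturb the converged orbitals, relax, keep improvements;
  ## the user's RNG stream is saved and restored around the seeded draws
  if (npar > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    }, add = TRUE)
    for (probe in 1:2) {
      if (env$sweeps >= settings$max_outer) break
      set.seed(settings$seed + probe)
      kappa <- skew_from_vec(stats::rnorm(npar) * 0.02, n)
      pert <- orbital_rotation(sol$rot$coeff %*% expm_dense(kappa))
      relaxed <- optimize_orbitals(ints, scheme, sol$st, pert, settings)
      if (energy_at(relaxed, sol$st) < sol$energy - settings$tol_energy) {
        sol <- alternate(relaxed, sol$st)
      }
    }
  }
  breakdown <- total_energy(transform_basis(ints, sol$rot), scheme, sol$st,
                            settings$functional_id)
  structure(
    list(breakdown = breakdown, occ_state = sol$st, rotation = sol$rot,
         converged = sol$converged, outer_iterations = env$sweeps,
         energy_trace = env$trace, max_constraint_defect = env$max_defect),
    class = "SolverResult")
}

## Deterministic sign gauge for eigenvector columns.
fix_gauge <- function(v) {
  for (j in seq_len(ncol(v))) {
    k <- which.max(abs(v[, j]))
    if (v[k, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' @export
print.SolverResult <- function(x, ...) {
  cat(sprintf("<SolverResult> %s, %sconverged in %d sweeps\n",
              x$breakdown$functional_id, if (x$converged) "" else "NOT ",
              x$outer_iterations))
  cat(sprintf("  E_total = %.9f hartree\n", x$breakdown$e_total))
  cat(sprintf("  occupancies: %s\n",
              paste(sprintf("%.6f", x$occ_state$occ), collapse = " ")))
  invisible(x)
}

#' Convergence trace as tabular text
#'
#' @param result A `SolverResult`.
#' @return Character vector (`sweep energy` per line, hartree to 9 decimals).
#' @export
format_trace <- function(result) {
  c("sweep energy_hartree",
    sprintf("%5d %.9f", seq_along(result$energy_trace) - 1L,
            result$energy_trace))
}

#' Hartree-Fock baseline via the functional machinery
#'
#' Runs [solve_nof()] with occupancies pinned at their uncorrelated values,
#' so every static/dynamic correlation term vanishes identically and only
#' the orbitals are optimized. Provides the `E_HF` entering the correlation
#' energy `E_corr = E_M - E_HF`.
#'
#' @inheritParams solve_nof
#' @return A `SolverResult` whose breakdown has zero static/dynamic terms.
#' @export
rhf_reference <- function(ints, scheme, settings = solver_settings()) {
  solve_nof(ints, scheme, settings, pinned = TRUE)
}
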