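## Post-processing: correlation energies, complete-basis-set extrapolation
## over cardinal-number series, and dipole moments from the converged
## (diagonal-in-NO) one-particle reduced density matrix.

#' Correlation energy in millihartree
#'
#' `E_corr = E_M - E_HF`, reported in mE_h.
#'
#' @param e_method Correlated total energy (hartree).
#' @param e_hf Hartree-Fock total energy from the same integrals (hartree).
#' @return Correlation energy in millihartree.
#' @export
correlation_energy <- function(e_method, e_hf) {
  (e_method - e_hf) * 1000
}

#' Cardinal-number energy series for basis-set extrapolation
#'
#' @param x Cardinal numbers (integers >= 2, strictly increasing).
#' @param energy Energies at each cardinal (hartree or millihartree; the
#'   fitted limit inherits the unit).
#' @param scheme Extrapolation form: `"power3"` (`E_inf + b X^-3`, the
#'   inverse-cube law standard for correlation-consistent basis sets),
#'   `"exponential"` (`E_inf + A exp(-gamma X)`), or `"power"`
#'   (`E_inf + A X^-gamma`).
#' @return Object of class `CBSSeries`.
#' @export
cbs_series <- function(x, energy, scheme = c("power3", "exponential", "power")) {
  scheme <- match.arg(scheme)
  stopifnot(length(x) == length(energy), length(x) >= 2)
  if (any(diff(x) <= 0)) stop("cardinal numbers must be strictly increasing",
                              call. = FALSE)
  if (any(x < 2)) stop("cardinal numbers must be >= 2", call. = FALSE)
  need <- if (scheme == "power3") 2L else 3L
  if (length(x) < need) {
    stop(sprintf("scheme %s needs at least %d points", scheme, need),
         call. = FALSE)
  }
  structure(list(points = data.frame(x = x, energy = energy),
                 scheme = scheme, fitted = NULL, residuals = NULL),
            class = "CBSSeries")
}

#' Fit a complete-basis-set extrapolation
#'
#' `power3` is linear in `X^-3` and solved by least squares over all points
#' (exact interpolation with two points); `two_point = TRUE` restricts it to
#' the two largest cardinals (the common two-point practice). The
#' 3-parameter exponential and power forms are solved by Levenberg-Marquardt
#' nonlinear least squares, started from a closed-form estimate built from
#' successive energy differences (for the exponential,
#' `gamma = log(d1/d2)` with `d_i` consecutive differences; analogously on
#' `log X` for the power form).
#'
#' @param series A [cbs_series()].
#' @param two_point Restrict the `power3` fit to the two largest cardinals?
#' @return The series with `fitted` (`e_inf`, `b`, `gamma`) and `residuals`
#'   populated.
#' @export
cbs_extrapolate <- function(series, two_point = FALSE) {
  stopifnot(inherits(series, "CBSSeries"))
  x <- series$points$x
  y <- series$points$energy
  if (series$scheme == "power3") {
    if (two_point) {
      keep <- order(x, decreasing = TRUE)[1:2]
      xs <- x[keep]; ys <- y[keep]
    } else {
      xs <- x; ys <- y
    }
    fit <- stats::lm(ys ~ I(xs^-3))
    e_inf <- unname(stats::coef(fit)[1])
    b <- unname(stats::coef(fit)[2])
    series$fitted <- list(e_inf = e_inf, b = b, gamma = 3)
    series$residuals <- y - (e_inf + b * x^-3)
    return(series)
  }
  if (series$scheme == "exponential") {
    d <- diff(y)
    ratio <- d[1] / d[2]
    gamma0 <- if (is.finite(ratio) && ratio > 0) {
      log(ratio) / (x[2] - x[1])
    } else 1
    a0 <- d[1] / (exp(-gamma0 * x[1]) * (exp(-gamma0 * (x[2] - x[1])) - 1))
    e0 <- y[length(y)] - a0 * exp(-gamma0 * x[length(x)])
    fit <- minpack.lm::nlsLM(
      y ~ e_inf + a * exp(-gamma * x),
      start = list(e_inf = e0, a = a0, gamma = gamma0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15))
  } else {
    d <- diff(y)
    gamma0 <- tryCatch({
      r <- (y[1] - y[2]) / (y[2] - y[3])
      stats::uniroot(function(gm) {
        (x[1]^-gm - x[2]^-gm) / (x[2]^-gm - x[3]^-gm) - r
      }, c(1e-3, 50))$root
    }, error = function(e) 3)
    a0 <- d[1] / (x[2]^-gamma0 - x[1]^-gamma0)
    e0 <- y[length(y)] - a0 * x[length(x)]^-gamma0
    fit <- minpack.lm::nlsLM(
      y ~ e_inf + a * x^-gamma,
      start = list(e_inf = e0, a = a0, gamma = gamma0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15))
  }
  cf <- stats::coef(fit)
  series$fitted <- list(e_inf = unname(cf["e_inf"]), b = unname(cf["a"]),
                        gamma = unname(cf["gamma"]))
  series$residuals <- unname(stats::residuals(fit))
  series
}

#' @export
print.CBSSeries <- function(x, ...) {
  cat(sprintf("<CBSSeries> scheme %s, %d points\n", x$scheme, nrow(x$points)))
  if (!is.null(x$fitted)) {
    cat(sprintf("  E_inf = %.9f, b/A = %.6g, gamma = %.6g, max|res| = %.3g\n",
                x$fitted$e_inf, x$fitted$b, x$fitted$gamma,
                max(abs(x$residuals))))
  }
  invisible(x)
}

#' Dipole moment from the one-particle reduced density matrix
#'
#' In the natural-orbital basis the 1RDM is diagonal, so the electronic
#' dipole is `-2 sum_p n_p <phi_p| r |phi_p>` (spin-summed occupancies); the
#' nuclear dipole is added.
#'
#' @param ints An [integral_set()] with `dipole_ints` attached, in the
#'   stored basis.
#' @param rotation [orbital_rotation()] from the stored basis to the
#'   converged natural orbitals.
#' @param occ_state Converged `OccupancyState`.
#' @param reference Optional experimental dipole magnitude (a.u.).
#' @return Object of class `DipoleResult`: `vector` (a.u.), `magnitude`,
#'   `reference`, `deviation`.
#' @export
dipole_moment <- function(ints, rotation, occ_state, reference = NULL) {
  if (is.null(ints$dipole_ints)) {
    stop("integral set has no dipole integrals", call. = FALSE)
  }
  cmat <- if (inherits(rotation, "OrbitalRotation")) rotation$coeff else rotation
  n <- occ_state$occ
  elec <- vapply(c("x", "y", "z"), function(ax) {
    d_no <- crossprod(cmat, ints$dipole_ints[[ax]] %*% cmat)
    -2 * sum(n * diag(d_no))
  }, numeric(1))
  vec <- elec + ints$dipole_ints$nuclear
  mag <- vnorm(vec)
  structure(
    list(vector = vec, magnitude = mag, reference = reference,
         deviation = if (is.null(reference)) NULL else mag - reference),
    class = "DipoleResult")
}

#' Root-mean-square deviation
#'
#' @param values Computed values.
#' @param references Reference values (same length, nonempty).
#' @return `sqrt(mean((values - references)^2))`.
#' @export
rms_deviation <- function(values, references) {
  if (length(values) != length(references) || length(values) == 0) {
    stop("values and references must be nonempty and of equal length",
         call. = FALSE)
  }
  sqrt(mean((values - references)^2))
}
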