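#' @keywords internal
"_PACKAGE"

## Numerical helpers shared across modules. Tolerances here are structural
## (symmetry/orthogonality checks), not physical convergence thresholds.

stopifnot_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("%s is not symmetric within %g", what, tol), call. = FALSE)
  }
  invisible(TRUE)
}

is_orthogonal <- function(m, tol = 1e-8) {
  max(abs(crossprod(m) - diag(nrow(m)))) <= tol
}

## Matrix exponential of a (small, dense) real matrix by scaling and squaring
## with a Taylor series; used for orthogonal updates exp(skew). Accurate to
## machine precision for the step sizes the optimizer takes.
expm_dense <- function(a) {
  n <- nrow(a)
  nrm <- max(abs(a))
  if (nrm == 0) return(diag(n))
  k <- max(0L, ceiling(log2(nrm / 0.25)))
  a <- a / 2^k
  term <- diag(n)
  out <- diag(n)
  for (i in 1:30) {
    term <- term %*% a / i
    out <- out + term
    if (max(abs(term)) < 1e-17) break
  }
  for (i in seq_len(k)) out <- out %*% out
  out
}

## Re-orthonormalize a nearly orthogonal matrix (symmetric Loewdin step).
reorthogonalize <- function(m) {
  s <- svd(m)
  s$u %*% t(s$v)
}

vnorm <- function(x) sqrt(sum(x^2))
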