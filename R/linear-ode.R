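# Exact solution of linear compartmental systems
#
#   dx/dt = A x + b(t),   b piecewise constant, plus instantaneous boluses.
#
# All kinetic models in this package (plasma compartmental models, the CNS
# PBPK system, and their block-triangular combination) are linear and
# time-invariant between dose events, so the solution is computed exactly
# via the eigendecomposition of A (or, when A is ill-conditioned for that
# route, via Pade matrix exponentials from the Matrix package).  This
# replaces an adaptive stiff integrator: stiffness is irrelevant because
# the propagator is closed-form, and the only error is round-off.

#' Build an exact propagator for a linear system
#'
#' Returns stepping and integration kernels for `dx/dt = A x + b` with
#' constant `b`.  Used internally by every simulator in the package.
#'
#' @param A square numeric matrix (must be nonsingular for constant-input
#'   segments; singular matrices fall back to augmented matrix
#'   exponentials with bolus-only input).
#' @return object of class `lin_propagator` with elements `step(x0, b, dt)`
#'   (state after `dt`) and `integral(x0, b, dt)` (componentwise
#'   \eqn{\int_0^{dt} x(s) ds}).
#' @keywords internal
lin_propagator <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  stopifnot(n == ncol(A))
  eg <- eigen(A)
  V <- eg$vectors
  lam <- eg$values
  use_eigen <- FALSE
  Vi <- NULL
  if (!anyNA(lam)) {
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (!is.null(Vi)) {
      resid <- max(Mod(V %*% Vi - diag(n)))
      use_eigen <- is.finite(resid) && resid < 1e-8
    }
  }
  particular <- function(b) {
    if (all(b == 0)) return(numeric(n))
    # xp solves A xp + b = 0; requires nonsingular A
    solve(A, -b)
  }
  if (use_eigen) {
    step <- function(x0, b, dt) {
      xp <- particular(b)
      drop(Re(V %*% (exp(lam * dt) * (Vi %*% (x0 - xp))))) + xp
    }
    integral <- function(x0, b, dt) {
      xp <- particular(b)
      phi <- ifelse(Mod(lam) > 1e-14, (exp(lam * dt) - 1) / lam, dt)
      xp * dt + drop(Re(V %*% (phi * (Vi %*% (x0 - xp)))))
    }
  } else {
    # fallback: augmented matrix exponential exp([[A, b], [0, 0]] dt)
    step <- function(x0, b, dt) {
      aug <- rbind(cbind(A, b), 0)
      M <- as.matrix(Matrix::expm(aug * dt))
      drop(M[seq_len(n), , drop = FALSE] %*% c(x0, 1))
    }
    integral <- function(x0, b, dt) {
      # second augmentation accumulates the running integral
      aug <- rbind(
        cbind(A, b, matrix(0, n, n)),
        rep(0, 2 * n + 1),
        cbind(diag(n), rep(0, n), matrix(0, n, n))
      )
      M <- as.matrix(Matrix::expm(aug * dt))
      drop(M[n + 1 + seq_len(n), , drop = FALSE] %*% c(x0, 1, numeric(n)))
    }
  }
  structure(list(step = step, integral = integral, n = n,
                 eigenvalues = lam, exact = use_eigen),
            class = "lin_propagator")
}

#' Solve a piecewise-forced linear system at requested times
#'
#' @param A system matrix (n x n).
#' @param x0 initial state at `t0`.
#' @param times sorted non-negative output times.
#' @param infusions list of `list(start=, end=, rate=)` giving constant
#'   input-rate vectors active on `[start, end)`.
#' @param boluses list of `list(time=, amount=)` instantaneous additions.
#' @param t0 start of integration (default 0).
#' @param cumulative logical; also return componentwise running integrals
#'   of the state (needed for mass-balance audits).
#' @return list with `times`, `state` (n x length(times)) and, when
#'   requested, `integral` (same shape).
#' @keywords internal
solve_linear_system <- function(A, x0, times, infusions = list(),
                                boluses = list(), t0 = 0,
                                cumulative = FALSE) {
  n <- nrow(A)
  stopifnot(length(x0) == n, !is.unsorted(times))
  prop <- lin_propagator(A)
  edges <- unlist(lapply(infusions, function(z) c(z$start, z$end)))
  btimes <- vapply(boluses, `[[`, numeric(1), "time")
  breaks <- sort(unique(c(t0, times, edges, btimes)))
  breaks <- breaks[breaks >= t0]
  rate_at <- function(t) {
    b <- numeric(n)
    for (z in infusions)
      if (t >= z$start && t < z$end) b <- b + z$rate
    b
  }
  out <- matrix(NA_real_, n, length(times))
  outI <- if (cumulative) matrix(NA_real_, n, length(times)) else NULL
  x <- as.numeric(x0)
  I <- numeric(n)
  for (bt in boluses)
    if (bt$time <= t0) x <- x + bt$amount
  emit <- function(t_idx, xv, Iv) {
    out[, t_idx] <<- xv
    if (cumulative) outI[, t_idx] <<- Iv
  }
  for (k in which(times == breaks[1])) emit(k, x, I)
  if (length(breaks) > 1) {
    for (j in seq_len(length(breaks) - 1)) {
      a <- breaks[j]; bnd <- breaks[j + 1]
      b <- rate_at(a)
      dt <- bnd - a
      if (cumulative) I <- I + prop$integral(x, b, dt)
      x <- prop$step(x, b, dt)
      for (bt in boluses)
        if (bt$time == bnd) x <- x + bt$amount
      for (k in which(times == bnd)) emit(k, x, I)
    }
  }
  list(times = times, state = out, integral = outI, propagator = prop)
}
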