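# Stationary Ornstein-Uhlenbeck (linear Langevin) algebra: the Lyapunov
# equation linking connectivity A, noise Q and the stationary covariance
# Sigma0, lagged covariances, and the analytic solutions for A.

#' Linear Langevin network model
#'
#' Container for the linear stationary stochastic system
#' `dx/dt = A x + Q xi`, where `x` is the vector of deviations from the mean,
#' `A` (N x N) is the network connectivity matrix (`A[j, i]` is the rate of
#' change of species j per unit deviation of species i, units 1/time), `Q`
#' (N x M) sets the magnitudes of the M independent white-noise drives, and
#' `xi` is delta-correlated white noise.
#'
#' A stationary process requires every eigenvalue of `A` to have a strictly
#' negative real part; this is validated lazily by [solve_lyapunov()] rather
#' than at construction so that marginal models can still be inspected.
#'
#' @param A square numeric connectivity matrix (1/time).
#' @param Q numeric noise-magnitude matrix with `nrow(Q) == nrow(A)`;
#'   defaults to a diagonal built from `diag_q` if supplied.
#' @param labels optional character vector of species names.
#' @return An object of class `network_model` with elements `A`, `Q`,
#'   `labels`, `N`, `M`.
#' @examples
#' m <- network_model(A = matrix(c(-1, 1, 0, -1), 2), Q = diag(sqrt(2), 2))
#' solve_lyapunov(m)
#' @export
network_model <- function(A, Q, labels = NULL) {
  A <- as.matrix(A)
  Q <- as.matrix(Q)
  if (nrow(A) != ncol(A))
    stop_induce("A must be square", "induce_input_error")
  if (nrow(Q) != nrow(A))
    stop_induce(sprintf("Q has %d rows but A is %d x %d", nrow(Q), nrow(A), ncol(A)),
                "induce_input_error")
  if (!is.null(labels) && length(labels) != nrow(A))
    stop_induce("labels length must match the number of species", "induce_input_error")
  labels <- labels %||% paste0("x", seq_len(nrow(A)))
  dimnames(A) <- list(labels, labels)
  rownames(Q) <- labels
  structure(list(A = A, Q = Q, labels = labels, N = nrow(A), M = ncol(Q)),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d species, %d noise drives\n", x$N, x$M))
  cat("A (1/time):\n"); print(x$A)
  cat("Q:\n"); print(x$Q)
  ev <- eigen(x$A, only.values = TRUE)$values
  cat(sprintf("max Re(eig A) = %.4g (%s)\n", max(Re(ev)),
              if (is_stable(x$A)) "stable" else "NOT stable"))
  invisible(x)
}

#' Stationary covariance matrix
#'
#' Wraps a symmetric positive-semidefinite matrix `Sigma0`, the stationary
#' (unlagged) covariance of the Langevin system. The matrix is symmetrized on
#' construction to remove round-off asymmetry; positive semidefiniteness is
#' checked to a relative tolerance of 1e-10 on the eigenvalues.
#'
#' @param Sigma0 square numeric matrix.
#' @param labels optional species names.
#' @return Object of class `stationary_cov` (a matrix with species dimnames).
#' @seealso [variance_of()], [covariance_of()]
#' @export
stationary_covariance <- function(Sigma0, labels = NULL) {
  S <- as.matrix(Sigma0)
  if (nrow(S) != ncol(S))
    stop_induce("Sigma0 must be square", "induce_input_error")
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1e-300))
    stop_induce(sprintf("Sigma0 is not positive semidefinite (min eigenvalue %.3g)",
                        min(ev)), "induce_numerical_error")
  labels <- labels %||% (rownames(S) %||% paste0("x", seq_len(nrow(S))))
  dimnames(S) <- list(labels, labels)
  structure(S, class = c("stationary_cov", "matrix"))
}

#' @rdname stationary_covariance
#' @param S a `stationary_cov` object.
#' @param i,j species index (integer) or name.
#' @export
variance_of <- function(S, i) as.matrix(S)[i, i]

#' @rdname stationary_covariance
#' @export
covariance_of <- function(S, i, j) as.matrix(S)[i, j]

#' @export
print.stationary_cov <- function(x, ...) {
  cat("<stationary_cov>\n")
  print(matrix(x, nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

#' Test asymptotic stability of a connectivity matrix
#'
#' A matrix is accepted as stable when the largest real part among its
#' eigenvalues is below `-tol`; the tolerance separates marginal from stable
#' cases at double precision.
#'
#' @param A square numeric matrix.
#' @param tol stability tolerance on the maximal eigenvalue real part.
#' @return `TRUE` iff `max(Re(eigen(A))) < -tol`.
#' @export
is_stable <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop_induce("A must be square", "induce_input_error")
  max(Re(eigen(A, only.values = TRUE)$values)) < -tol
}

#' Solve the Lyapunov equation for the stationary covariance
#'
#' Computes the stationary covariance `Sigma0` of the linear Langevin system,
#' i.e. the unique symmetric solution of `A Sigma0 + Sigma0 A' + Q Q' = 0`.
#' The solve is a direct dense one (Kronecker vectorization of the Sylvester
#' system, exact up to round-off), appropriate for the small networks (2-4
#' nodes) this method addresses. The result is symmetrized and its residual
#' checked against `1e-8` relative to `||QQ'||_F`.
#'
#' @param model a [network_model()].
#' @return A [stationary_covariance()].
#' @examples
#' m <- network_model(matrix(c(-1, 1, 0, -1), 2), diag(sqrt(2), 2))
#' solve_lyapunov(m)  # [[1, .5], [.5, 1.5]]
#' @export
solve_lyapunov <- function(model) {
  stopifnot(inherits(model, "network_model"))
  A <- model$A
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) >= -1e-10) {
    worst <- ev[which.max(Re(ev))]
    stop_induce(sprintf(
      "A is not stable: eigenvalue %s has real part %.3g >= -1e-10",
      format(worst, digits = 6), max(Re(ev))), "induce_stability_error")
  }
  QQt <- model$Q %*% t(model$Q)
  n <- nrow(A)
  I <- diag(n)
  # vec(A S + S A') = (I (x) A + A (x) I) vec(S)
  K <- kronecker(I, A) + kronecker(A, I)
  S <- matrix(solve(K, -as.vector(QQt)), n, n)
  S <- (S + t(S)) / 2
  res <- norm(A %*% S + S %*% t(A) + QQt, "F") / max(norm(QQt, "F"), 1e-300)
  if (res > 1e-8)
    stop_induce(sprintf("Lyapunov residual %.3g exceeds 1e-8", res),
                "induce_numerical_error")
  stationary_covariance(S, labels = model$labels)
}

#' Lagged covariance of the stationary process
#'
#' For the stationary Langevin system the time-lagged covariance factorizes
#' as `Sigma(tau) = Sigma0 expm(A' tau)`; its Frobenius norm decays to zero
#' for stable `A`. The matrix exponential uses the scaling-and-squaring
#' algorithm (via the Matrix package).
#'
#' @param model a [network_model()].
#' @param Sigma0 the stationary covariance solving the Lyapunov equation for
#'   `model` (computed with [solve_lyapunov()] if omitted).
#' @param tau nonnegative time lag.
#' @return A list of class `lagged_cov` with fields `tau` and `Sigma_tau`.
#' @export
lagged_covariance <- function(model, Sigma0 = solve_lyapunov(model), tau) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0)
    stop_induce("tau must be a single nonnegative number", "induce_input_error")
  E <- as.matrix(Matrix::expm(t(model$A) * tau))
  structure(list(tau = tau, Sigma_tau = as.matrix(Sigma0) %*% E),
            class = "lagged_cov")
}

#' Family of connectivity matrices consistent with a covariance
#'
#' The Lyapunov equation constrains `A` only up to an antisymmetric matrix
#' `U`: every `A = (-QQ'/2 + U) Sigma0^{-1}` reproduces the same stationary
#' covariance. This degeneracy is the formal reason why correlation alone
#' does not determine causation for snapshot data.
#'
#' @param Q noise-magnitude matrix.
#' @param U antisymmetric matrix (checked against `tol`).
#' @param Sigma0 invertible stationary covariance.
#' @param tol tolerance on `||U + U'||` relative to `||U||` for the
#'   antisymmetry check.
#' @return A [network_model()] whose Lyapunov solution is `Sigma0`.
#' @export
network_from_U <- function(Q, U, Sigma0, tol = 1e-8) {
  Q <- as.matrix(Q); U <- as.matrix(U); S <- as.matrix(Sigma0)
  if (nrow(U) != ncol(U) || nrow(U) != nrow(S))
    stop_induce("dimension mismatch between U and Sigma0", "induce_input_error")
  if (norm(U + t(U), "F") > tol * max(norm(U, "F"), 1))
    stop_induce("U is not antisymmetric", "induce_input_error")
  Sinv <- tryCatch(solve(S), error = function(e)
    stop_induce("Sigma0 is singular", "induce_numerical_error"))
  A <- (-0.5 * Q %*% t(Q) + U) %*% Sinv
  network_model(A, Q, labels = rownames(S))
}

#' Connectivity of a thermal-equilibrium (conservative) system
#'
#' For a conservative physical system in contact with a thermal bath the
#' noise is isotropic and the connectivity is symmetric and fully
#' determined by the covariance: `A = -Sigma0^{-1} kB*T`. The noise
#' intensity is set by the fluctuation-dissipation relation,
#' `QQ' = 2 kB*T * I`, which is exactly the strength required for the
#' Lyapunov equation to return `Sigma0`. Included as the special case in
#' which snapshot covariances alone do identify the network.
#'
#' @param Sigma0 symmetric positive-definite covariance.
#' @param kBT bath energy scale (kB times temperature), positive.
#' @return A [network_model()] with `A = -kBT * Sigma0^{-1}` and
#'   `Q = sqrt(2 kBT) * I`.
#' @export
thermal_network <- function(Sigma0, kBT = 1) {
  if (!is.numeric(kBT) || kBT <= 0)
    stop_induce("kBT must be positive", "induce_input_error")
  S <- as.matrix(Sigma0)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop_induce("Sigma0 is singular", "induce_numerical_error"))
  A <- -kBT * (Sinv + t(Sinv)) / 2
  network_model(A, diag(sqrt(2 * kBT), nrow(S)), labels = rownames(S))
}

#' Serialize and restore a network model
#'
#' Round-trips a [network_model()] through a plain-text YAML file storing
#' `A` and `Q` as row-major nested lists plus the species labels.
#'
#' @param model a [network_model()].
#' @param path file path.
#' @return `write_network_model` returns `path` invisibly;
#'   `read_network_model` returns the restored [network_model()].
#' @export
write_network_model <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  obj <- list(
    labels = as.list(model$labels),
    A = lapply(seq_len(nrow(model$A)), function(i) as.list(unname(model$A[i, ]))),
    Q = lapply(seq_len(nrow(model$Q)), function(i) as.list(unname(model$Q[i, ])))
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_network_model
#' @export
read_network_model <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$A) || is.null(obj$Q))
    stop_induce(sprintf("malformed network model file '%s': missing A or Q", path),
                "induce_parse_error")
  A <- do.call(rbind, lapply(obj$A, unlist))
  Q <- do.call(rbind, lapply(obj$Q, unlist))
  network_model(A, Q, labels = unlist(obj$labels))
}
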