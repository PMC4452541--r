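# Shared fixtures and independent oracles, built in code at test time.

# random stable (Hurwitz) connectivity: negative-definite symmetric part
# guarantees all eigenvalues have negative real part
rand_stable_A <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n)
  -(M %*% t(M) + 0.1 * diag(n)) + 0.5 * (function(R) R - t(R))(matrix(rnorm(n * n), n))
}

rand_stable_model <- function(n, seed) {
  A <- rand_stable_A(n, seed)
  Q <- matrix(rnorm(n * n, sd = 0.7), n)
  network_model(A, Q)
}

# Independent quadrature oracle for the stationary covariance:
# Sigma0 = integral_0^inf exp(A t) QQ' exp(A' t) dt, composite Simpson on a
# truncated grid using powers of the one-step matrix exponential.
sigma_integral_oracle <- function(A, Q, n_steps = 20000) {
  decay <- -max(Re(eigen(A, only.values = TRUE)$values))
  t_max <- 40 / decay
  h <- t_max / n_steps
  Eh <- as.matrix(Matrix::expm(A * h))
  QQt <- Q %*% t(Q)
  Ek <- diag(nrow(A))
  acc <- matrix(0, nrow(A), ncol(A))
  for (k in 0:n_steps) {
    w <- if (k == 0 || k == n_steps) 1 else if (k %% 2 == 1) 4 else 2
    acc <- acc + w * Ek %*% QQt %*% t(Ek)
    Ek <- Ek %*% Eh
  }
  acc * h / 3
}

rel_diff <- function(a, b) {
  norm(as.matrix(a) - as.matrix(b), "F") / max(norm(as.matrix(b), "F"), 1e-300)
}

# standard two-node study design used across inference tests
test_two_node <- function() example_motifs()$two_node_activation

# symmetric disconnected (k = 0) design: the edge is driven far into
# saturation so the linearized gain is numerically zero, and both nodes
# carry identical intrinsic noise
null_two_node <- function() {
  list(motif = motif_spec(
         "two_node", lambda = c(1, 1), q = c(sqrt(0.08), sqrt(0.08)),
         edges = list("1->2" = hill_transfer(nu = 10, K = 1e-4, n = 1)),
         labels = c("S", "T")),
       doses = 10^seq(-2, 2, length.out = 23),
       drive = hill_transfer(nu = 10, K = 1, n = 1))
}

# direction comparison without the bootstrap, as used in the power and
# type-I simulations
quick_direction_call <- function(ds, s1 = "S", s2 = "T") {
  dl <- normalize_dataset(ds)
  fc <- dose_covariances(dl, s1, s2, B = 0)
  fwd <- fit_two_node(fc, "12")
  rev <- fit_two_node(fc, "21")
  list(fwd = fwd, rev = rev,
       result = compare_directions(model_errors(fwd, rev)))
}
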