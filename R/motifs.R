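# Network motifs (isolated edge, convergent regulation, linear cascade),
# their linearized log-deviation dynamics, and the variance-vs-covariance
# trajectories traced as a dose sweeps the connection strengths.

MOTIF_KINDS <- c("two_node", "convergent", "cascade")

# canonical edge sets, as (source, target) pairs
motif_edge_sets <- list(
  two_node   = list(c(1L, 2L)),
  convergent = list(c(1L, 2L), c(3L, 2L)),
  cascade    = list(c(3L, 1L), c(1L, 2L))
)

#' Network motif specification
#'
#' Parameterizes one of the three small motifs the method analyzes:
#' `two_node` (isolated edge 1 -> 2), `convergent` (1 -> 2 and an unmeasured
#' 3 -> 2), and `cascade` (unmeasured 3 -> 1 -> 2). Nodes 1 and 2 are the
#' measured species; node 3, when present, is an unmeasured noise source.
#' Each node j has a decay rate `lambda[j]` (1/time) and an intrinsic
#' log-noise magnitude `q[j]`; each edge carries a [hill_transfer()]
#' describing the production rate of the target as a function of the source
#' concentration (linear scale).
#'
#' @param kind one of `"two_node"`, `"convergent"`, `"cascade"`.
#' @param lambda numeric vector of per-node decay rates, all > 0.
#' @param q numeric vector of per-node intrinsic log-noise magnitudes,
#'   all >= 0 (units 1/sqrt(time)).
#' @param edges named list of [hill_transfer()] objects keyed as
#'   `"<source>-><target>"` using node indices, matching the motif kind
#'   (`two_node`: `1->2`; `convergent`: `1->2`, `3->2`; `cascade`: `3->1`,
#'   `1->2`).
#' @param labels species names (length = number of nodes).
#' @param measured indices of the measured nodes (default `c(1, 2)`).
#' @return Object of class `motif_spec`.
#' @export
motif_spec <- function(kind, lambda, q, edges, labels = NULL, measured = c(1L, 2L)) {
  kind <- match.arg(kind, MOTIF_KINDS)
  n_nodes <- if (kind == "two_node") 2L else 3L
  if (length(lambda) != n_nodes || any(lambda <= 0))
    stop_induce("lambda must be positive, one per node", "induce_input_error")
  if (length(q) != n_nodes || any(q < 0))
    stop_induce("q must be nonnegative, one per node", "induce_input_error")
  want <- vapply(motif_edge_sets[[kind]], function(e) sprintf("%d->%d", e[1], e[2]), "")
  if (!setequal(names(edges), want))
    stop_induce(sprintf("motif '%s' requires edges {%s}, got {%s}",
                        kind, paste(want, collapse = ", "),
                        paste(names(edges), collapse = ", ")),
                "induce_input_error")
  for (e in edges)
    if (!inherits(e, "hill_transfer"))
      stop_induce("every edge must carry a hill_transfer", "induce_input_error")
  labels <- labels %||% paste0("x", seq_len(n_nodes))
  structure(list(kind = kind, lambda = lambda, q = q, edges = edges[want],
                 labels = labels, measured = as.integer(measured),
                 n_nodes = n_nodes),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("<motif_spec> kind=%s nodes=%d measured=(%s)\n", x$kind,
              x$n_nodes, paste(x$labels[x$measured], collapse = ", ")))
  cat(sprintf("  lambda = %s; q = %s\n", paste(signif(x$lambda, 4), collapse = ", "),
              paste(signif(x$q, 4), collapse = ", ")))
  for (nm in names(x$edges)) {
    h <- x$edges[[nm]]
    cat(sprintf("  edge %s: %s nu=%g K=%g n=%g\n", nm,
                if (h$repression) "repression" else "activation", h$nu, h$K, h$n))
  }
  invisible(x)
}

# input nodes = nodes with no incoming edge (driven by the ligand dose)
motif_input_nodes <- function(m) {
  targets <- vapply(motif_edge_sets[[m$kind]], `[`, integer(1), 2L)
  setdiff(seq_len(m$n_nodes), targets)
}

#' Two-node noise parameters
#'
#' The isolated directed edge with equal decay rates has a closed-form
#' stationary covariance determined by `alpha = q1^2/(2 lambda)` (source
#' log-variance floor), `beta = q2^2/(2 lambda)` (target intrinsic
#' log-variance floor), the shared decay `lam`, and the connection strength
#' `k`.
#'
#' @param alpha,beta nonnegative log-variance floors.
#' @param lam shared decay rate > 0.
#' @param k connection strength (1/time); sign encodes activation/repression.
#' @return Object of class `two_node_params`.
#' @export
two_node_params <- function(alpha, beta, lam, k) {
  if (alpha < 0 || beta < 0) stop_induce("alpha, beta must be >= 0", "induce_input_error")
  if (lam <= 0) stop_induce("lam must be > 0", "induce_input_error")
  structure(list(alpha = alpha, beta = beta, lam = lam, k = k),
            class = "two_node_params")
}

#' Closed-form covariance of the isolated directed edge
#'
#' For `A = [[-lam, 0], [k, -lam]]` and diagonal noise the stationary
#' covariance is `var1 = alpha`, `cov12 = alpha k / (2 lam)`,
#' `var2 = beta + alpha k^2 / (2 lam^2)`. The source variance does not
#' depend on the connection; the covariance is linear and the target
#' variance quadratic in `k` -- the differential sensitivity the inference
#' exploits.
#'
#' @param p a [two_node_params()].
#' @return A [stationary_covariance()] (2 x 2).
#' @export
two_node_covariance <- function(p) {
  stopifnot(inherits(p, "two_node_params"))
  s12 <- p$alpha * p$k / (2 * p$lam)
  S <- matrix(c(p$alpha, s12, s12, p$beta + p$alpha * p$k^2 / (2 * p$lam^2)), 2, 2)
  stationary_covariance(S)
}

#' Target variance as a function of the covariance
#'
#' The quadratic law of the isolated edge: eliminating the connection
#' strength from the closed-form covariance leaves
#' `var2 = beta + 2 cov12^2 / alpha`, a single-valued even function of the
#' covariance. This is the curve fitted to per-dose covariance estimates by
#' [fit_two_node()].
#'
#' @param sigma12 covariance value(s).
#' @param alpha source log-variance, > 0.
#' @param beta target intrinsic log-variance floor.
#' @return Predicted target variance(s).
#' @export
var2_of_cov <- function(sigma12, alpha, beta) {
  if (!is.numeric(alpha) || alpha <= 0)
    stop_induce("alpha must be > 0", "induce_input_error")
  beta + 2 * sigma12^2 / alpha
}

# Deterministic steady state of the motif in linear concentration scale:
# production f = lambda * x for every non-input node, solved by damped
# fixed-point iteration (the motifs are feedback-free, so this converges).
motif_steady_state <- function(m, input_means, tol = 1e-12, max_iter = 1e5,
                               damping = 0.5) {
  x <- rep(NA_real_, m$n_nodes)
  inputs <- motif_input_nodes(m)
  if (length(input_means) != length(inputs) || any(input_means <= 0))
    stop_induce("input_means must be positive, one per input node",
                "induce_input_error")
  x[inputs] <- input_means
  free <- setdiff(seq_len(m$n_nodes), inputs)
  x[free] <- 1
  edge_idx <- motif_edge_sets[[m$kind]]
  for (iter in seq_len(max_iter)) {
    x_new <- x
    for (ei in seq_along(edge_idx)) {
      src <- edge_idx[[ei]][1]; tgt <- edge_idx[[ei]][2]
      # accumulate production into targets, then balance against decay
      if (ei == 1 || tgt != edge_idx[[ei - 1]][2]) prod_tgt <- 0
      prod_tgt <- prod_tgt + hill_response(x[src], m$edges[[ei]])
      x_new[tgt] <- prod_tgt / m$lambda[tgt]
    }
    x_next <- (1 - damping) * x + damping * x_new
    delta <- max(abs(x_next - x) / pmax(abs(x), 1e-300))
    x <- x_next
    if (delta < tol) break
  }
  if (delta >= tol)
    stop_induce("steady-state iteration did not converge", "induce_numerical_error")
  if (any(x <= 0))
    stop_induce("steady state has nonpositive concentrations", "induce_input_error")
  x
}

# Linearized log-deviation dynamics at a fixed point: A has diagonal
# -lambda_j and off-diagonal gains a_ji = lambda_j dln f_ji / dln x_i;
# Q = diag(q_j).
motif_linearize <- function(m, x_star) {
  A <- diag(-m$lambda, m$n_nodes)
  gains <- numeric(0)
  edge_idx <- motif_edge_sets[[m$kind]]
  for (ei in seq_along(edge_idx)) {
    src <- edge_idx[[ei]][1]; tgt <- edge_idx[[ei]][2]
    a <- log_gain(x_star[src], m$edges[[ei]], m$lambda[tgt])
    A[tgt, src] <- a
    gains[sprintf("a_%d%d", tgt, src)] <- a
  }
  list(A = A, Q = diag(m$q, m$n_nodes), gains = gains)
}

#' Variance-vs-covariance trajectory of a motif along a dose sweep
#'
#' At each dose the ligand sets the mean concentration of the motif's input
#' node(s) through the drive transfer function(s); the remaining steady-state
#' means follow from rate balance, the dynamics are linearized in log
#' coordinates ([log_gain()]) and the stationary covariance of the log
#' deviations is obtained from the Lyapunov equation. The ordered sequence of
#' covariance elements among the measured nodes is the motif's
#' variance-vs-covariance path.
#'
#' @param m a [motif_spec()].
#' @param doses increasing numeric dose grid.
#' @param drive a [hill_transfer()] mapping dose to the mean concentration of
#'   the single input node, or a named list of transfers keyed by input node
#'   index when the motif has several input nodes (convergent motif).
#' @return A data frame of class `varcov_path` with columns `dose`, the
#'   log-scale means `mean_<label>`, the gains `a_<target><source>`, and the
#'   measured-node covariance elements `sigma11`, `sigma22`, `sigma12`.
#'   The full per-dose linearizations are attached as attribute `points`.
#' @export
motif_trajectory <- function(m, doses, drive) {
  stopifnot(inherits(m, "motif_spec"))
  if (is.unsorted(doses, strictly = TRUE))
    stop_induce("doses must be strictly increasing", "induce_input_error")
  inputs <- motif_input_nodes(m)
  if (inherits(drive, "hill_transfer")) drive <- setNames(list(drive), inputs[1])
  if (!setequal(names(drive), as.character(inputs)))
    stop_induce(sprintf("drive must be keyed by input nodes (%s)",
                        paste(inputs, collapse = ", ")), "induce_input_error")
  i1 <- m$measured[1]; i2 <- m$measured[2]
  rows <- vector("list", length(doses))
  points <- vector("list", length(doses))
  for (d in seq_along(doses)) {
    input_means <- vapply(as.character(inputs), function(nd)
      hill_response(doses[d], drive[[nd]]), numeric(1))
    if (any(input_means <= 0))
      stop_induce(sprintf("drive gives nonpositive mean at dose %g", doses[d]),
                  "induce_input_error")
    x_star <- motif_steady_state(m, input_means)
    lin <- motif_linearize(m, x_star)
    if (!is_stable(lin$A))
      stop_induce(sprintf("linearized dynamics unstable at dose %g", doses[d]),
                  "induce_stability_error")
    S <- solve_lyapunov(network_model(lin$A, lin$Q, labels = m$labels))
    rows[[d]] <- c(dose = doses[d], setNames(log(x_star), paste0("mean_", m$labels)),
                   lin$gains,
                   sigma11 = variance_of(S, i1), sigma22 = variance_of(S, i2),
                   sigma12 = covariance_of(S, i1, i2))
    points[[d]] <- list(dose = doses[d], x_star = x_star, gains = lin$gains,
                        A = lin$A, Sigma0 = S)
  }
  path <- as.data.frame(do.call(rbind, rows))
  class(path) <- c("varcov_path", "data.frame")
  attr(path, "motif") <- m
  attr(path, "points") <- points
  path
}

#' Detect an open-loop variance-vs-covariance trajectory
#'
#' An isolated directed edge traces a single-valued quadratic in the
#' (covariance, variance) plane; when several noise sources with disparate
#' dose sensitivities feed the measured pair, the path can fail to be
#' single-valued ("open loop"), implicating an unmeasured upstream noise
#' source. Operationally the path is compared to its own best-fit quadratic
#' `variance ~ covariance + covariance^2`: the path is called looped when
#' two points with nearly equal covariance (within `eps_c` of the covariance
#' range) have quadratic-fit residuals differing by more than `eps_v` of the
#' variance range. The loop score is the largest such residual gap
#' normalized by the variance range.
#'
#' @param path a `varcov_path` from [motif_trajectory()] (or any data frame
#'   with `sigma12` and `sigma11`/`sigma22` columns), at least 4 points.
#' @param which which measured node's variance to examine (1 or 2).
#' @param eps_c covariance matching tolerance, fraction of covariance range.
#' @param eps_v variance gap threshold, fraction of variance range.
#' @return List of class `loop_test`: `loop` (logical), `score`, and the
#'   indices of the worst-offending point pair.
#' @export
detect_open_loop <- function(path, which = 2, eps_c = 0.02, eps_v = 0.05) {
  v_col <- if (which == 1) "sigma11" else "sigma22"
  if (nrow(path) < 4)
    stop_induce("need at least 4 path points", "induce_input_error")
  cc <- path$sigma12
  vv <- path[[v_col]]
  range_c <- diff(range(cc))
  range_v <- diff(range(vv))
  if (range_v <= 0)
    return(structure(list(loop = FALSE, score = 0, pair = c(NA, NA)),
                     class = "loop_test"))
  # residuals about the best single-valued quadratic; an exactly quadratic
  # (two-node) path has residuals at round-off level
  if (range_c > 0) {
    fit <- lm(vv ~ cc + I(cc^2))
    res <- stats::residuals(fit)
  } else {
    res <- vv - mean(vv)
  }
  tol_c <- eps_c * max(range_c, 1e-300)
  best <- 0; pair <- c(NA, NA)
  n <- length(cc)
  for (i in seq_len(n - 1)) {
    close <- which(abs(cc[(i + 1):n] - cc[i]) <= tol_c) + i
    if (!length(close)) next
    gaps <- abs(res[close] - res[i])
    j <- close[which.max(gaps)]
    if (max(gaps) > best) { best <- max(gaps); pair <- c(i, j) }
  }
  score <- best / range_v
  structure(list(loop = score > eps_v, score = score, pair = pair),
            class = "loop_test")
}

#' @export
print.loop_test <- function(x, ...) {
  cat(sprintf("<loop_test> loop=%s score=%.3g\n", x$loop, x$score))
  invisible(x)
}

#' Export a trajectory as a tidy table
#'
#' @param path a `varcov_path`.
#' @param file CSV destination.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(path, file) {
  write.csv(as.data.frame(path), file, row.names = FALSE)
  invisible(file)
}

#' Serialize and restore a motif specification
#'
#' Round-trips a [motif_spec()] through the same plain-text YAML dialect as
#' [write_network_model()].
#'
#' @param m a [motif_spec()].
#' @param path file path.
#' @return `write_motif_spec` returns `path` invisibly; `read_motif_spec`
#'   the restored [motif_spec()].
#' @export
write_motif_spec <- function(m, path) {
  stopifnot(inherits(m, "motif_spec"))
  obj <- list(kind = m$kind, lambda = as.list(m$lambda), q = as.list(m$q),
              labels = as.list(m$labels), measured = as.list(m$measured),
              edges = lapply(m$edges, function(h)
                list(nu = h$nu, K = h$K, n = h$n, repression = h$repression)))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_motif_spec
#' @export
read_motif_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$kind) || is.null(obj$edges))
    stop_induce(sprintf("malformed motif file '%s': missing kind or edges", path),
                "induce_parse_error")
  edges <- lapply(obj$edges, function(e)
    hill_transfer(nu = e$nu, K = e$K, n = e$n, repression = isTRUE(e$repression)))
  motif_spec(obj$kind, lambda = unlist(obj$lambda), q = unlist(obj$q),
             edges = edges, labels = unlist(obj$labels),
             measured = unlist(obj$measured))
}

#' Example motif parameterizations
#'
#' Named reference parameterizations, one per motif family, chosen to
#' reproduce the qualitative trajectory shapes the theory predicts: the
#' isolated edge's constant source variance and quadratic target variance
#' (activating and repressive variants), a convergent motif whose second
#' input has a displaced dose sensitivity, and a cascade whose disparate
#' sensitivities produce an open-loop trajectory. Each entry pairs a
#' [motif_spec()] with the dose grid and upstream drive used to sweep it.
#'
#' @return Named list; each element has fields `motif`, `doses`, `drive`,
#'   and `direction` (the true source/target labels).
#' @export
example_motifs <- function() {
  doses <- 10^seq(-2, 2, length.out = 23)
  drive <- hill_transfer(nu = 10, K = 1, n = 1)
  two_act <- motif_spec(
    "two_node", lambda = c(1, 1), q = c(sqrt(0.08), sqrt(0.04)),
    edges = list("1->2" = hill_transfer(nu = 10, K = 1, n = 2)),
    labels = c("S", "T"))
  two_rep <- motif_spec(
    "two_node", lambda = c(1, 1), q = c(sqrt(0.08), sqrt(0.04)),
    edges = list("1->2" = hill_transfer(nu = 10, K = 1, n = 2, repression = TRUE)),
    labels = c("G1", "G2"))
  convergent <- motif_spec(
    "convergent", lambda = c(1, 1, 1), q = c(sqrt(0.08), sqrt(0.02), sqrt(0.4)),
    edges = list("1->2" = hill_transfer(nu = 10, K = 1, n = 2),
                 "3->2" = hill_transfer(nu = 10, K = 1, n = 2)),
    labels = c("S", "T", "U"))
  # double-repression cascade with disparate half-responses, a slow target
  # and a noisy unmeasured source: traces open loops in both
  # variance-vs-covariance planes
  cascade <- motif_spec(
    "cascade", lambda = c(2.3, 0.13, 8), q = sqrt(c(0.018, 0.34, 0.2)),
    edges = list("3->1" = hill_transfer(nu = 19, K = 1.6, n = 1.5, repression = TRUE),
                 "1->2" = hill_transfer(nu = 9, K = 2.3, n = 1.7, repression = TRUE)),
    labels = c("S", "T", "U"))
  list(
    two_node_activation = list(motif = two_act, doses = doses, drive = drive,
                               direction = c("S", "T")),
    two_node_repression = list(motif = two_rep, doses = doses, drive = drive,
                               direction = c("G1", "G2")),
    convergent = list(
      motif = convergent, doses = doses,
      drive = list("1" = hill_transfer(nu = 10, K = 1, n = 1),
                   "3" = hill_transfer(nu = 10, K = 30, n = 1)),
      direction = c("S", "T")),
    cascade = list(motif = cascade, doses = doses,
                   drive = hill_transfer(nu = 4, K = 4, n = 1.7),
                   direction = c("S", "T"))
  )
}
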