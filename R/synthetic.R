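# Synthetic single-cell, per-dose ensembles with the statistical structure
# the analysis assumes: lognormal marginals, Hill dose-response means, and
# cross-species covariance generated by directed noise propagation. Two
# sampling routes are provided and cross-validated: a direct draw from the
# stationary Gaussian of the linearized log dynamics, and Euler-Maruyama
# integration of the log-deviation SDE.

#' Dose-response experimental design
#'
#' @param doses strictly increasing ligand doses (arbitrary units).
#' @param n_cells number of cells measured per dose, >= 2.
#' @param seed master RNG seed; per-dose streams are derived from it
#'   deterministically, so datasets are reproducible dose by dose.
#' @return Object of class `dose_design`.
#' @export
dose_design <- function(doses, n_cells = 10000L, seed = 1L) {
  if (length(doses) < 1 || is.unsorted(doses, strictly = TRUE))
    stop_induce("doses must be strictly increasing", "induce_input_error")
  if (n_cells < 2) stop_induce("n_cells must be >= 2", "induce_input_error")
  structure(list(doses = as.numeric(doses), n_cells = as.integer(n_cells),
                 seed = as.integer(seed)),
            class = "dose_design")
}

# deterministic per-dose substream seeds below 2^31
dose_stream_seed <- function(seed, d) {
  as.integer((as.numeric(seed) * 48271 + d * 16807) %% 2147483647)
}

#' Simulate a per-dose single-cell ensemble from the stationary law
#'
#' Under ergodicity, a snapshot of many clonal cells at stationarity is
#' statistically equivalent to one cell sampled over time, so the ensemble
#' at each dose is drawn directly from the stationary distribution of the
#' linearized log dynamics: `n_cells` independent log-deviation vectors from
#' the zero-mean multivariate normal with covariance `Sigma0(dose)` (from
#' [motif_trajectory()]), shifted by the log-scale means and exponentiated.
#' Marginals are therefore exactly lognormal.
#'
#' @param m a [motif_spec()].
#' @param design a [dose_design()].
#' @param drive upstream drive (see [motif_trajectory()]).
#' @param meas_noise_sd optional multiplicative measurement noise: the
#'   log-sd of an independent lognormal factor applied per cell and species
#'   (default 0 = off).
#' @return A `dose_dataset`: list with `data` (data.frame with columns
#'   `dose`, `cell_id`, one column per measured species, linear scale),
#'   `species`, and `meta` (motif kind, true direction, seed, design).
#' @export
simulate_ensemble <- function(m, design, drive, meas_noise_sd = 0) {
  stopifnot(inherits(m, "motif_spec"), inherits(design, "dose_design"))
  path <- motif_trajectory(m, design$doses, drive)
  points <- attr(path, "points")
  species <- m$labels[m$measured]
  blocks <- vector("list", length(design$doses))
  for (d in seq_along(design$doses)) {
    pt <- points[[d]]
    mu <- log(pt$x_star)[m$measured]
    S <- as.matrix(pt$Sigma0)[m$measured, m$measured, drop = FALSE]
    set.seed(dose_stream_seed(design$seed, d))
    dev <- MASS::mvrnorm(design$n_cells, mu = mu, Sigma = S)
    if (meas_noise_sd > 0)
      dev <- dev + matrix(rnorm(length(dev), sd = meas_noise_sd), nrow(dev))
    intens <- exp(dev)
    colnames(intens) <- species
    blocks[[d]] <- data.frame(dose = design$doses[d],
                              cell_id = seq_len(design$n_cells), intens,
                              check.names = FALSE)
  }
  structure(list(
    data = do.call(rbind, blocks), species = species,
    meta = list(motif = m$kind, true_direction = species[1:2],
                seed = design$seed, n_cells = design$n_cells,
                doses = design$doses, meas_noise_sd = meas_noise_sd,
                scale = "linear")),
    class = "dose_dataset")
}

#' @export
print.dose_dataset <- function(x, ...) {
  cat(sprintf("<dose_dataset> %d doses x %d cells, species: %s (%s scale)\n",
              length(unique(x$data$dose)), x$meta$n_cells,
              paste(x$species, collapse = ", "), x$meta$scale))
  invisible(x)
}

#' Euler-Maruyama simulation of the log-deviation SDE
#'
#' Integrates the linearized log-deviation dynamics
#' `d dy = A dy dt + Q dW` for `n_cells` independent cells from the
#' deterministic fixed point at one dose, and returns the terminal snapshot
#' in linear intensity scale. Used to cross-validate the stationary-Gaussian
#' sampling route and the Lyapunov solution end to end.
#'
#' @param m a [motif_spec()].
#' @param dose single dose value.
#' @param drive upstream drive (see [motif_trajectory()]).
#' @param n_cells number of independent cells.
#' @param t_end integration time; should exceed ~10 / min(lambda) so the
#'   ensemble relaxes to stationarity.
#' @param dt time step; must satisfy `dt < 0.1 / max rate` where the rate
#'   scale includes decays and gain magnitudes.
#' @param seed RNG seed.
#' @return Matrix `n_cells x length(measured)` of linear-scale intensities
#'   (columns named by measured species), with the per-dose linearization
#'   attached as attribute `linearization`.
#' @export
simulate_sde <- function(m, dose, drive, n_cells, t_end, dt, seed = 1L) {
  stopifnot(inherits(m, "motif_spec"))
  lin <- sde_linearization(m, dose, drive)
  rate <- max(c(m$lambda, abs(lin$gains), 0))
  if (dt >= 0.1 / rate)
    stop_induce(sprintf("dt = %g too large for max rate %g (need dt < %g)",
                        dt, rate, 0.1 / rate), "induce_input_error")
  n_steps <- ceiling(t_end / dt)
  set.seed(seed)
  n <- m$n_nodes
  Y <- matrix(0, n, n_cells)       # log deviations, cells in columns
  qs <- m$q * sqrt(dt)
  for (s in seq_len(n_steps)) {
    Y <- Y + dt * (lin$A %*% Y) + qs * matrix(rnorm(n * n_cells), n)
  }
  out <- exp(t(Y[m$measured, , drop = FALSE]) +
               matrix(log(lin$x_star)[m$measured], n_cells,
                      length(m$measured), byrow = TRUE))
  colnames(out) <- m$labels[m$measured]
  attr(out, "linearization") <- lin
  out
}

#' Single-cell temporal trajectory of the log-deviation SDE
#'
#' Euler-Maruyama path of one cell, returned as a matrix of log deviations
#' sampled every `thin` steps after discarding `burn_in` time units. Used
#' for ergodicity checks (temporal versus ensemble statistics) and for
#' validating the lagged-covariance factorization.
#'
#' @inheritParams simulate_sde
#' @param burn_in time discarded before sampling.
#' @param thin keep every `thin`-th step.
#' @return Matrix (samples x nodes) of log deviations with attributes
#'   `dt_sample` (time between kept samples) and `linearization`.
#' @export
simulate_sde_trajectory <- function(m, dose, drive, t_end, dt, seed = 1L,
                                    burn_in = 10 / min(m$lambda), thin = 1L) {
  lin <- sde_linearization(m, dose, drive)
  rate <- max(c(m$lambda, abs(lin$gains), 0))
  if (dt >= 0.1 / rate)
    stop_induce(sprintf("dt = %g too large for max rate %g", dt, rate),
                "induce_input_error")
  n_steps <- ceiling((t_end + burn_in) / dt)
  skip <- ceiling(burn_in / dt)
  set.seed(seed)
  n <- m$n_nodes
  y <- numeric(n)
  qs <- m$q * sqrt(dt)
  keep <- matrix(NA_real_, floor((n_steps - skip) / thin), n)
  k <- 0L
  for (s in seq_len(n_steps)) {
    y <- y + dt * (lin$A %*% y)[, 1] + qs * rnorm(n)
    if (s > skip && (s - skip) %% thin == 0L) {
      k <- k + 1L
      keep[k, ] <- y
    }
  }
  colnames(keep) <- m$labels
  structure(keep[seq_len(k), , drop = FALSE], dt_sample = dt * thin,
            linearization = lin)
}

sde_linearization <- function(m, dose, drive) {
  inputs <- motif_input_nodes(m)
  if (inherits(drive, "hill_transfer")) drive <- setNames(list(drive), inputs[1])
  input_means <- vapply(as.character(inputs), function(nd)
    hill_response(dose, drive[[nd]]), numeric(1))
  x_star <- motif_steady_state(m, input_means)
  lin <- motif_linearize(m, x_star)
  if (!is_stable(lin$A))
    stop_induce(sprintf("linearized dynamics unstable at dose %g", dose),
                "induce_stability_error")
  lin$x_star <- x_star
  lin
}

#' Write and read a dose dataset
#'
#' The event table goes to CSV (columns `dose`, `cell_id`, then one column
#' per species, linear scale, full double precision) and the metadata to a
#' JSON sidecar `<path>.json`. The round trip is lossless.
#'
#' @param ds a `dose_dataset`.
#' @param path CSV file path (sidecar written next to it).
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   restored `dose_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "dose_dataset"))
  df <- ds$data
  num_cols <- setdiff(names(df), "cell_id")
  fmt <- df
  for (cl in num_cols) fmt[[cl]] <- sprintf("%.17g", df[[cl]])
  write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  meta <- ds$meta
  meta$species <- ds$species
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path))
    stop_induce(sprintf("no such dataset file: '%s'", path), "induce_parse_error")
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop_induce(
                   sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
                   "induce_parse_error"))
  if (nrow(df) == 0)
    stop_induce(sprintf("'%s' has no event rows", path), "induce_parse_error")
  need <- c("dose", "cell_id")
  if (!all(need %in% names(df)))
    stop_induce(sprintf("'%s' lacks required columns %s", path,
                        paste(setdiff(need, names(df)), collapse = ", ")),
                "induce_parse_error")
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else list(scale = "linear")
  species <- meta$species %||% setdiff(names(df), need)
  meta$species <- NULL
  meta$doses <- as.numeric(meta$doses %||% sort(unique(df$dose)))
  structure(list(data = df, species = species, meta = meta),
            class = "dose_dataset")
}
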