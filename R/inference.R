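# The INDUCE estimation pipeline: Hill fits to the mean dose-responses,
# linear-scale normalization, per-dose bivariate-normal covariance
# estimation with bootstrap uncertainties, and the constrained two-node
# variance-vs-covariance model fit in a specified direction.

# dose-wise means of log intensities for one species (positive events only)
dose_mean_logs <- function(ds, species) {
  x <- ds$data[[species]]
  ok <- is.finite(x) & x > 0
  agg <- aggregate(list(meanlog = log(x[ok])), list(dose = ds$data$dose[ok]), mean)
  agg[order(agg$dose), ]
}

fit_hill_meanlog <- function(dose, meanlog, repression = FALSE) {
  # least squares of dose-wise mean logs against log of a Hill response
  nu0 <- exp(max(meanlog))
  mid <- (max(meanlog) + min(meanlog)) / 2
  K0 <- dose[which.min(abs(meanlog - mid))]
  K0 <- max(K0, min(dose[dose > 0]))
  start <- list(lnu = log(nu0), lK = log(K0), ln = 0)
  form <- if (repression)
    meanlog ~ lnu + exp(ln) * lK - log(exp(exp(ln) * lK) + dose^exp(ln))
  else
    meanlog ~ lnu + exp(ln) * log(dose) - log(exp(exp(ln) * lK) + dose^exp(ln))
  # work with K^n = exp(n lK) to keep the parameterization smooth
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(dose = dose, meanlog = meanlog),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    sse <- sum(stats::residuals(fit)^2)
  } else {
    # responses that are not exactly Hill in dose (e.g. a saturating
    # upstream) can make the Jacobian singular at the LM optimum; a direct
    # simplex minimization of the same objective is slower but robust
    model <- if (repression) {
      function(p) p[1] + exp(p[3]) * p[2] - log(exp(exp(p[3]) * p[2]) + dose^exp(p[3]))
    } else {
      function(p) p[1] + exp(p[3]) * log(dose) - log(exp(exp(p[3]) * p[2]) + dose^exp(p[3]))
    }
    obj <- function(p) {
      r <- model(p)
      if (any(!is.finite(r))) return(1e10)
      sum((meanlog - r)^2)
    }
    opt <- optim(unlist(start), obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    cf <- setNames(opt$par, c("lnu", "lK", "ln"))
    sse <- opt$value
  }
  list(h = hill_transfer(nu = exp(cf[["lnu"]]), K = exp(cf[["lK"]]),
                         n = exp(cf[["ln"]]), repression = repression),
       sse = sse)
}

#' Fit Hill transfer functions to the mean dose-responses
#'
#' For each species, fits the Hill form to the dose-wise mean log
#' intensities by least squares (both orientations are tried and the better
#' one kept), and records the sign of the target-versus-source transfer
#' function slope (activation vs repression). The fitted half-response
#' constant and amplitude of each species provide the normalization scales
#' used downstream.
#'
#' @param ds a `dose_dataset` in linear scale.
#' @param source,target species names (source = putative regulator).
#' @return List of class `transfer_fit`: per-species [hill_transfer()] fits,
#'   `normalization` (per-species scale: `K` for the source, `nu` for the
#'   target), `transfer_slope_sign` (+1 activation / -1 repression),
#'   `degenerate` flag (near-flat target response), and dose-wise mean-log
#'   tables.
#' @export
fit_transfer <- function(ds, source, target) {
  stopifnot(inherits(ds, "dose_dataset"))
  if (!all(c(source, target) %in% names(ds$data)))
    stop_induce(sprintf("species not in dataset: %s",
                        paste(setdiff(c(source, target), names(ds$data)),
                              collapse = ", ")), "induce_input_error")
  if (length(unique(ds$data$dose)) < 5)
    stop_induce("need at least 5 doses", "induce_input_error")
  ml <- lapply(setNames(c(source, target), c(source, target)),
               function(sp) dose_mean_logs(ds, sp))
  hills <- list()
  for (sp in c(source, target)) {
    d <- ml[[sp]]
    cand <- list()
    for (rep_flag in c(FALSE, TRUE)) {
      cand[[length(cand) + 1]] <- tryCatch(
        fit_hill_meanlog(d$dose, d$meanlog, repression = rep_flag),
        error = function(e) NULL)
    }
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand))
      stop_induce(sprintf(
        "Hill fit failed to converge for species '%s' (dose range %g-%g, response range %.3g)",
        sp, min(d$dose), max(d$dose), diff(range(d$meanlog))), "induce_fit_error")
    hills[[sp]] <- cand[[which.min(vapply(cand, `[[`, numeric(1), "sse"))]]$h
  }
  # transfer slope: target mean log regressed on source mean log
  sl <- coef(lm(ml[[target]]$meanlog ~ ml[[source]]$meanlog))[2]
  degenerate <- diff(range(ml[[target]]$meanlog)) < 0.1
  structure(list(
    hills = hills,
    normalization = setNames(list(list(scale = hills[[source]]$K, type = "K"),
                                  list(scale = hills[[target]]$nu, type = "nu")),
                             c(source, target)),
    transfer_slope = unname(sl),
    transfer_slope_sign = sign(unname(sl)),
    degenerate = degenerate,
    mean_logs = ml, source = source, target = target),
    class = "transfer_fit")
}

#' Normalize a dataset and move to log scale
#'
#' Linear-scale intensities are divided by the species' fitted scale (the
#' half-response constant for the source, the response amplitude for the
#' target) and the natural log is taken. Because the normalization is a
#' pure shift in log coordinates, every covariance element is invariant to
#' it; it only serves to put different experiments on a common axis.
#' Nonpositive intensities (possible after instrument compensation) are
#' dropped; the count is recorded in the metadata.
#'
#' @param ds a `dose_dataset` in linear scale.
#' @param norm a `transfer_fit` (its `normalization` field) or a named list
#'   of per-species scales; species without an entry get scale 1 (plain log
#'   transform).
#' @param min_intensity positivity threshold below which events are dropped.
#' @return A `dose_dataset` with `meta$scale == "log"`.
#' @export
normalize_dataset <- function(ds, norm = NULL, min_intensity = 0) {
  stopifnot(inherits(ds, "dose_dataset"))
  if (identical(ds$meta$scale, "log"))
    stop_induce("dataset already log scale", "induce_input_error")
  scales <- setNames(rep(1, length(ds$species)), ds$species)
  if (inherits(norm, "transfer_fit")) norm <- norm$normalization
  for (sp in names(norm)) {
    s <- if (is.list(norm[[sp]])) norm[[sp]]$scale else norm[[sp]]
    if (!is.numeric(s) || s <= 0)
      stop_induce(sprintf("normalization scale for '%s' must be > 0", sp),
                  "induce_input_error")
    scales[sp] <- s
  }
  df <- ds$data
  keep <- rep(TRUE, nrow(df))
  for (sp in ds$species) keep <- keep & is.finite(df[[sp]]) & df[[sp]] > min_intensity
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  for (sp in ds$species) df[[sp]] <- log(df[[sp]] / scales[sp])
  meta <- ds$meta
  meta$scale <- "log"
  meta$dropped_nonpositive <- dropped
  meta$norm_scales <- as.list(scales)
  structure(list(data = df, species = ds$species, meta = meta),
            class = "dose_dataset")
}

#' Maximum-likelihood bivariate-normal covariance of one dose ensemble
#'
#' The per-dose covariance matrix of the log intensities is estimated by
#' fitting the bivariate normal, i.e. the sample mean vector and the
#' maximum-likelihood sample covariance (denominator n).
#'
#' @param Y numeric matrix (cells x 2) of log intensities at one dose.
#' @return List: `mean` (length 2), `v1`, `v2`, `c12`, `n`.
#' @export
estimate_covariance <- function(Y) {
  Y <- as.matrix(Y)
  if (ncol(Y) != 2) stop_induce("Y must have two species columns", "induce_input_error")
  n <- nrow(Y)
  if (n < 10)
    stop_induce(sprintf("need >= 10 cells per dose, got %d", n),
                "induce_insufficient_data")
  mu <- colMeans(Y)
  S <- crossprod(sweep(Y, 2, mu)) / n
  list(mean = mu, v1 = S[1, 1], v2 = S[2, 2], c12 = S[1, 2], n = n)
}

#' Bootstrap standard deviations of the covariance elements
#'
#' Cells are resampled with replacement within the dose and the
#' maximum-likelihood covariance recomputed `B` times; returns the standard
#' deviation of each element over the resamples.
#'
#' @param Y numeric matrix (cells x 2) of log intensities at one dose.
#' @param B number of bootstrap resamples (>= 100; default 1000).
#' @param seed RNG seed.
#' @return Named numeric vector `sd_v1`, `sd_v2`, `sd_c12`.
#' @export
bootstrap_covariance <- function(Y, B = 1000L, seed = 1L) {
  Y <- as.matrix(Y)
  if (B < 100) stop_induce("B must be >= 100", "induce_input_error")
  n <- nrow(Y)
  set.seed(seed)
  stats <- matrix(NA_real_, B, 3)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    Yb <- Y[idx, , drop = FALSE]
    mu <- colMeans(Yb)
    S <- crossprod(sweep(Yb, 2, mu)) / n
    stats[b, ] <- c(S[1, 1], S[2, 2], S[1, 2])
  }
  c(sd_v1 = sd(stats[, 1]), sd_v2 = sd(stats[, 2]), sd_c12 = sd(stats[, 3]))
}

#' Per-dose covariance table with bootstrap uncertainties
#'
#' Applies [estimate_covariance()] (and optionally [bootstrap_covariance()])
#' to every dose of a log-scale dataset for one ordered species pair.
#'
#' @param ds log-scale `dose_dataset` (see [normalize_dataset()]).
#' @param species1,species2 ordered pair of species columns.
#' @param B bootstrap resamples per dose (0 disables the bootstrap; the SD
#'   columns are then `NA`).
#' @param seed RNG seed for the bootstrap.
#' @return Data frame of class `fitted_covariance` with one row per dose:
#'   `dose`, `n`, `mean1`, `mean2`, `v1`, `v2`, `c12`, `sd_v1`, `sd_v2`,
#'   `sd_c12`.
#' @export
dose_covariances <- function(ds, species1, species2, B = 1000L, seed = 1L) {
  stopifnot(inherits(ds, "dose_dataset"))
  if (!identical(ds$meta$scale, "log"))
    stop_induce("dataset must be log scale (normalize_dataset first)",
                "induce_input_error")
  doses <- sort(unique(ds$data$dose))
  rows <- vector("list", length(doses))
  for (d in seq_along(doses)) {
    Y <- as.matrix(ds$data[ds$data$dose == doses[d], c(species1, species2)])
    est <- estimate_covariance(Y)
    sds <- if (B > 0) bootstrap_covariance(Y, B = B, seed = dose_stream_seed(seed, d))
           else c(sd_v1 = NA_real_, sd_v2 = NA_real_, sd_c12 = NA_real_)
    rows[[d]] <- data.frame(dose = doses[d], n = est$n,
                            mean1 = est$mean[1], mean2 = est$mean[2],
                            v1 = est$v1, v2 = est$v2, c12 = est$c12,
                            sd_v1 = sds[["sd_v1"]], sd_v2 = sds[["sd_v2"]],
                            sd_c12 = sds[["sd_c12"]])
  }
  fc <- do.call(rbind, rows)
  attr(fc, "species") <- c(species1, species2)
  class(fc) <- c("fitted_covariance", "data.frame")
  fc
}

#' Fit the constrained two-node model to per-dose covariances
#'
#' The isolated-edge model in a given direction constrains the per-dose
#' covariance elements jointly: the source variance is a dose-independent
#' `alpha` and the target variance follows the quadratic
#' `beta + 2 (c12 - c0)^2 / alpha`, where the optional offset `c0` (third
#' noise parameter) defaults to 0. Both residuals enter the least-squares
#' objective; `alpha > 0` is enforced by log-parameterization, started from
#' the median source variance.
#'
#' @param fc a `fitted_covariance` table (>= 4 doses).
#' @param direction which species is the source: `"12"` fits species 1 ->
#'   species 2 (v1 constant, v2 quadratic), `"21"` the reverse.
#' @param third_param if `TRUE`, fit the covariance offset `c0` as well.
#' @param weights `"none"` (default) for unweighted least squares, or
#'   `"bootstrap"` for inverse-bootstrap-variance weighting of the two
#'   residual streams.
#' @return List of class `two_node_fit`: `alpha`, `beta`, `c0`, `direction`,
#'   per-dose `predicted` (data frame with predicted source/target
#'   variances), per-dose squared errors `errors`, `sse`, and a
#'   `boundary_warning` flag when `alpha` runs to the search boundary.
#' @export
fit_two_node <- function(fc, direction = c("12", "21"), third_param = FALSE,
                         weights = c("none", "bootstrap")) {
  direction <- match.arg(direction)
  weights <- match.arg(weights)
  if (nrow(fc) < 4)
    stop_induce("need at least 4 doses to fit the two-node model",
                "induce_input_error")
  if (direction == "12") {
    v_src <- fc$v1; v_tgt <- fc$v2
    sd_src <- fc$sd_v1; sd_tgt <- fc$sd_v2
  } else {
    v_src <- fc$v2; v_tgt <- fc$v1
    sd_src <- fc$sd_v2; sd_tgt <- fc$sd_v1
  }
  cc <- fc$c12
  if (weights == "bootstrap") {
    if (anyNA(c(sd_src, sd_tgt)))
      stop_induce("bootstrap weights requested but SDs are missing",
                  "induce_input_error")
    w_src <- 1 / pmax(sd_src, 1e-12)^2
    w_tgt <- 1 / pmax(sd_tgt, 1e-12)^2
  } else {
    w_src <- w_tgt <- rep(1, nrow(fc))
  }
  obj_beta <- function(alpha, c0) {
    # beta closed form given (alpha, c0): weighted mean of the residual
    beta <- sum(w_tgt * (v_tgt - 2 * (cc - c0)^2 / alpha)) / sum(w_tgt)
    sse <- sum(w_src * (v_src - alpha)^2) +
      sum(w_tgt * (v_tgt - beta - 2 * (cc - c0)^2 / alpha)^2)
    list(beta = beta, sse = sse)
  }
  a0 <- max(stats::median(v_src), 1e-12)
  lo <- log(a0) - log(1e4); hi <- log(a0) + log(1e4)
  if (third_param) {
    opt <- optim(c(log(a0), 0),
                 function(p) obj_beta(exp(min(max(p[1], lo), hi)), p[2])$sse,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    pol <- stats::nlminb(opt$par, function(p) obj_beta(exp(p[1]), p[2])$sse,
                         lower = c(lo, -Inf), upper = c(hi, Inf),
                         control = list(rel.tol = 1e-15, abs.tol = 0))
    la <- pol$par[1]; c0 <- pol$par[2]
  } else {
    opt <- optimize(function(la) obj_beta(exp(la), 0)$sse, c(lo, hi),
                    tol = 1e-10)
    pol <- stats::nlminb(opt$minimum, function(la) obj_beta(exp(la), 0)$sse,
                         lower = lo, upper = hi,
                         control = list(rel.tol = 1e-15, abs.tol = 0))
    la <- pol$par; c0 <- 0
  }
  # polish alpha on the analytic stationarity condition: with beta the
  # weighted mean residual, dSSE/dalpha = -2 sum w_s (v_s - alpha)
  # + (4/alpha^2) sum w_t r_i ct_i^2, a smooth 1-D root
  grad_alpha <- function(alpha) {
    ct2 <- (cc - c0)^2
    beta <- sum(w_tgt * (v_tgt - 2 * ct2 / alpha)) / sum(w_tgt)
    r <- v_tgt - beta - 2 * ct2 / alpha
    -2 * sum(w_src * (v_src - alpha)) + (4 / alpha^2) * sum(w_tgt * r * ct2)
  }
  a_hat <- exp(la)
  br <- c(a_hat * (1 - 1e-3), a_hat * (1 + 1e-3))
  g <- vapply(br, grad_alpha, numeric(1))
  if (is.finite(g[1]) && is.finite(g[2]) && g[1] * g[2] < 0) {
    a_hat <- stats::uniroot(grad_alpha, br, tol = 1e-14 * a_hat)$root
    la <- log(a_hat)
  }
  alpha <- exp(la)
  boundary <- la <= lo + 1e-6 || la >= hi - 1e-6
  if (boundary)
    warning("alpha ran to the search boundary; fit is likely degenerate")
  ob <- obj_beta(alpha, c0)
  pred_tgt <- ob$beta + 2 * (cc - c0)^2 / alpha
  pred_src <- rep(alpha, nrow(fc))
  errors <- (v_src - pred_src)^2 + (v_tgt - pred_tgt)^2
  sp <- attr(fc, "species")
  structure(list(
    alpha = alpha, beta = ob$beta, c0 = c0, direction = direction,
    source = if (direction == "12") sp[1] else sp[2],
    target = if (direction == "12") sp[2] else sp[1],
    predicted = data.frame(dose = fc$dose, v_src = pred_src, v_tgt = pred_tgt,
                           c12 = cc),
    actual = data.frame(dose = fc$dose, v_src = v_src, v_tgt = v_tgt),
    errors = errors, sse = ob$sse, weights = weights,
    boundary_warning = boundary),
    class = "two_node_fit")
}

#' @export
print.two_node_fit <- function(x, ...) {
  cat(sprintf("<two_node_fit> %s -> %s: alpha=%.4g beta=%.4g%s sse=%.4g\n",
              x$source %||% "src", x$target %||% "tgt", x$alpha, x$beta,
              if (x$c0 != 0) sprintf(" c0=%.4g", x$c0) else "", x$sse))
  invisible(x)
}
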