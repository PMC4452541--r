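# Statistical test for causation: per-dose fit-error statistic, exact
# paired Wilcoxon signed-rank comparison of the two directed models, and
# the end-to-end INDUCE driver.

#' Per-dose fit error of a directed model
#'
#' The fit error at one dose is the sum of squared differences between the
#' actual and model-predicted variances of both measured species:
#' `(var1_actual - var1_model)^2 + (var2_actual - var2_model)^2`. It is
#' symmetric in the species order.
#'
#' @param actual length-2 numeric: the two species' actual variances.
#' @param predicted length-2 numeric: the model-predicted variances, same
#'   species order.
#' @return Nonnegative scalar (log-variance^2 units).
#' @export
fit_error <- function(actual, predicted) {
  if (length(actual) != 2 || length(predicted) != 2)
    stop_induce("actual and predicted must each hold two variances",
                "induce_input_error")
  sum((actual - predicted)^2)
}

#' Paired per-dose error table for two directed fits
#'
#' @param fit1,fit2 [fit_two_node()] results for the two directions, fitted
#'   on the same doses.
#' @return Data frame of class `model_errors`: `dose`, `e1`, `e2`.
#' @export
model_errors <- function(fit1, fit2) {
  if (!isTRUE(all.equal(fit1$predicted$dose, fit2$predicted$dose)))
    stop_induce("the two fits cover different dose sets", "induce_input_error")
  out <- data.frame(dose = fit1$predicted$dose, e1 = fit1$errors, e2 = fit2$errors)
  class(out) <- c("model_errors", "data.frame")
  out
}

# exact null distribution of W+ (sum of positive signed ranks) by
# shift-convolution over sign assignments; ranks may be half-integers under
# average-rank ties, so work on doubled ranks
signed_rank_null_counts <- function(ranks2) {
  counts <- rep(0, sum(ranks2) + 1)  # counts[w + 1] = #assignments with 2*W+ = w
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test with exact small-sample enumeration
#'
#' Tests whether paired differences are centered at zero. Zero differences
#' are dropped (their count is reported) and ties among the absolute values
#' receive average ranks. For `N <= exact_limit` the p-value is exact: the
#' full null distribution of the positive-rank sum over all `2^N` sign
#' assignments is enumerated (by convolution, which is equivalent to the
#' explicit enumeration). Above the limit a normal approximation with tie
#' correction and continuity correction is used.
#'
#' With every one of N differences favoring the same side, the one-sided
#' exact p-value attains its floor `2^-N` -- e.g. `2^-23 ~= 1.2e-7` when the
#' better-fitting model wins at all 23 doses.
#'
#' @param d numeric vector of paired differences.
#' @param alternative `"greater"` (differences tend positive), `"less"`, or
#'   `"two.sided"`.
#' @param exact_limit largest N for which the exact enumeration is used.
#' @return List of class `signed_rank_test`: `p_value`, `statistic` (W+,
#'   the positive-rank sum), `n` (pairs used), `n_zero` (dropped),
#'   `alternative`, `method` (`"exact"` or `"normal"`), `degenerate`.
#' @export
wilcoxon_signed_rank <- function(d, alternative = c("greater", "less", "two.sided"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; degenerate test, p = 1")
    return(structure(list(p_value = 1, statistic = 0, n = 0, n_zero = n_zero,
                          alternative = alternative, method = "degenerate",
                          degenerate = TRUE), class = "signed_rank_test"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    counts <- signed_rank_null_counts(ranks2)
    total <- 2^n
    w2 <- round(2 * W)
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p_le <- sum(counts[1:(w2 + 1)]) / total
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p_ge <- pnorm((W - 0.5 - mu) / sqrt(sig2), lower.tail = FALSE)
    p_le <- pnorm((W + 0.5 - mu) / sqrt(sig2))
    method <- "normal"
  }
  p <- switch(alternative,
              greater = p_ge, less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  structure(list(p_value = p, statistic = W, n = n, n_zero = n_zero,
                 alternative = alternative, method = method,
                 degenerate = FALSE),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("<signed_rank_test> W+=%g, n=%d (%d zeros dropped), %s %s p=%.4g\n",
              x$statistic, x$n, x$n_zero, x$method, x$alternative, x$p_value))
  invisible(x)
}

#' Compare the fit errors of the two directed models
#'
#' Paired comparison of the per-dose fit errors (the data fitted by both
#' models are identical, so the comparison is paired). First the two-sided
#' Wilcoxon signed-rank test of the null "the two models have statistically
#' similar fitting errors" is run on `d = e2 - e1`; if the null is rejected
#' at `alpha`, the model with consistently smaller errors is favored and its
#' one-sided p-value reported as the headline number.
#'
#' @param e a `model_errors` table (see [model_errors()]), or a data frame
#'   with columns `e1`, `e2`.
#' @param alpha rejection level of the two-sided gate (default 0.05).
#' @param sign_call optional `"activation"`/`"repression"` annotation
#'   carried through from the covariance sign rule.
#' @param labels optional character(2): names of model 1 and model 2 (e.g.
#'   `"A->B"`, `"B->A"`).
#' @return Object of class `causation_result`: `favored` (1, 2, or `NA` if
#'   the null is retained), `favored_label`, `one_sided_p`, `two_sided_p`,
#'   `N`, `sign_call`, and the error table.
#' @export
compare_directions <- function(e, alpha = 0.05, sign_call = NA_character_,
                               labels = c("model1", "model2")) {
  if (!all(c("e1", "e2") %in% names(e)))
    stop_induce("e must have columns e1 and e2", "induce_input_error")
  if (any(e$e1 < 0 | e$e2 < 0))
    stop_induce("fit errors must be nonnegative", "induce_input_error")
  d <- e$e2 - e$e1                       # positive when model 1 fits better
  two <- wilcoxon_signed_rank(d, "two.sided")
  if (two$degenerate) {
    return(structure(list(favored = NA_integer_, favored_label = NA_character_,
                          one_sided_p = 1, two_sided_p = 1, N = nrow(e),
                          sign_call = sign_call, errors = e, labels = labels,
                          degenerate = TRUE),
                     class = "causation_result"))
  }
  # which model has consistently the smaller errors: sign of the rank sum
  r <- rank(abs(d[d != 0]))
  lean1 <- sum(r[d[d != 0] > 0]) > sum(r) / 2
  one <- wilcoxon_signed_rank(d, if (lean1) "greater" else "less")
  favored <- if (two$p_value < alpha) (if (lean1) 1L else 2L) else NA_integer_
  structure(list(
    favored = favored,
    favored_label = if (!is.na(favored)) labels[favored] else NA_character_,
    one_sided_p = one$p_value, two_sided_p = two$p_value,
    N = two$n + two$n_zero, n_zero = two$n_zero, method = two$method,
    sign_call = sign_call, errors = e, labels = labels, degenerate = FALSE),
    class = "causation_result")
}

#' @export
print.causation_result <- function(x, ...) {
  cat("<causation_result>\n")
  if (isTRUE(x$degenerate) || is.na(x$favored)) {
    cat(sprintf("  no direction favored (two-sided p = %.3g, N = %d)\n",
                x$two_sided_p, x$N))
  } else {
    cat(sprintf("  inference: %s (%s), one-sided p = %.3g, N = %d\n",
                x$favored_label, x$sign_call %||% "sign n/a", x$one_sided_p, x$N))
  }
  invisible(x)
}

# covariance sign rule: bootstrap-precision-weighted sum of per-dose
# covariances; positive -> activation, negative -> repression
covariance_sign_call <- function(fc) {
  w <- if (all(is.finite(fc$sd_c12))) 1 / pmax(fc$sd_c12, 1e-12) else rep(1, nrow(fc))
  score <- sum(w * fc$c12)
  if (score == 0) return(NA_character_)
  if (score > 0) "activation" else "repression"
}

#' Run the full INDUCE pipeline on a dataset
#'
#' Composes the whole analysis for one ordered species pair: Hill transfer
#' fit, linear-scale normalization and log transform, per-dose covariance
#' estimation with bootstrap uncertainties, constrained two-node fits in
#' both directions, per-dose fit errors, and the paired Wilcoxon comparison.
#' Deterministic under a fixed seed.
#'
#' @param ds a `dose_dataset` in linear scale with >= 5 doses.
#' @param source,target species names; "source -> target" is model 1.
#' @param bootstrap bootstrap resamples per dose (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param alpha rejection level of the two-sided gate.
#' @param third_param,weights passed to [fit_two_node()].
#' @param normalize if `FALSE`, skip the Hill fit and use a plain log
#'   transform (covariances are invariant to the normalization shift).
#' @return List of class `induce_run`: `transfer`, `covariances`,
#'   `fit_forward`, `fit_reverse`, `errors`, and `result` (a
#'   `causation_result`).
#' @export
run_induce <- function(ds, source, target, bootstrap = 1000L, seed = 1L,
                       alpha = 0.05, third_param = FALSE,
                       weights = c("none", "bootstrap"), normalize = TRUE) {
  stopifnot(inherits(ds, "dose_dataset"))
  weights <- match.arg(weights)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop_induce(
      sprintf("[%s] %s", name, conditionMessage(e)),
      paste0("induce_stage_", name)))
  }
  transfer <- if (normalize) stage("transfer", fit_transfer(ds, source, target))
              else NULL
  ds_log <- stage("normalize",
                  normalize_dataset(ds, norm = transfer))
  fc <- stage("covariance",
              dose_covariances(ds_log, source, target, B = bootstrap, seed = seed))
  fwd <- stage("fit", fit_two_node(fc, "12", third_param = third_param,
                                   weights = weights))
  rev <- stage("fit", fit_two_node(fc, "21", third_param = third_param,
                                   weights = weights))
  errs <- model_errors(fwd, rev)
  res <- compare_directions(errs, alpha = alpha,
                            sign_call = covariance_sign_call(fc),
                            labels = c(paste0(source, "->", target),
                                       paste0(target, "->", source)))
  structure(list(transfer = transfer, covariances = fc, fit_forward = fwd,
                 fit_reverse = rev, errors = errs, result = res,
                 source = source, target = target, seed = seed),
            class = "induce_run")
}

#' @export
print.induce_run <- function(x, ...) {
  cat(sprintf("<induce_run> %s vs %s over %d doses\n", x$source, x$target,
              nrow(x$covariances)))
  print(x$fit_forward); print(x$fit_reverse); print(x$result)
  invisible(x)
}
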