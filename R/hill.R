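# Hill transfer functions and their local log-gains.

#' Hill transfer function
#'
#' Saturating dose-response kernel used for every regulatory edge and for
#' the upstream (ligand) drive. Activation takes the increasing form
#' `nu * x^n / (K^n + x^n)`; repression the complementary decreasing form
#' `nu * K^n / (K^n + x^n)`. Repression is encoded by the flag rather than a
#' negative Hill coefficient, so `n > 0` always.
#'
#' @param nu saturated response amplitude (concentration units), > 0.
#' @param K half-response input concentration, > 0.
#' @param n Hill coefficient (cooperativity), > 0.
#' @param repression logical; decreasing response if `TRUE`.
#' @return Object of class `hill_transfer`.
#' @examples
#' h <- hill_transfer(nu = 1, K = 1, n = 2)
#' hill_response(3, h)  # 9/10
#' @export
hill_transfer <- function(nu, K, n = 1, repression = FALSE) {
  if (!is.numeric(nu) || nu <= 0) stop_induce("nu must be > 0", "induce_input_error")
  if (!is.numeric(K) || K <= 0) stop_induce("K must be > 0", "induce_input_error")
  if (!is.numeric(n) || n <= 0) stop_induce("n must be > 0", "induce_input_error")
  structure(list(nu = nu, K = K, n = n, repression = isTRUE(repression)),
            class = "hill_transfer")
}

#' @export
print.hill_transfer <- function(x, ...) {
  cat(sprintf("<hill_transfer> %s: nu=%g K=%g n=%g\n",
              if (x$repression) "repression" else "activation", x$nu, x$K, x$n))
  invisible(x)
}

#' Evaluate a Hill transfer function
#'
#' @param x input concentration(s), >= 0.
#' @param h a [hill_transfer()].
#' @return Response in concentration units (vectorized over `x`).
#' @export
hill_response <- function(x, h) {
  stopifnot(inherits(h, "hill_transfer"))
  if (any(x < 0)) stop_induce("x must be nonnegative", "induce_input_error")
  r <- (x / h$K)^h$n            # dimensionless; avoids overflow for large K^n
  if (h$repression) h$nu / (1 + r) else h$nu * r / (1 + r)
}

#' Local log-gain of a regulatory edge
#'
#' The linearized connection strength of the log-deviation dynamics is
#' `a = lambda * d ln f / d ln x` evaluated at the operating point: for an
#' activating Hill edge `a = lambda * n * K^n / (K^n + x^n)` (maximal
#' `lambda * n` at low occupancy, vanishing at saturation); for a repressive
#' edge the log-derivative of the decreasing form gives
#' `a = -lambda * n * x^n / (K^n + x^n)`. The sign encodes activation (+)
#' versus repression (-).
#'
#' @param x operating-point input concentration, strictly positive (the
#'   log-derivative is undefined at 0).
#' @param h a [hill_transfer()].
#' @param lam decay rate of the target species (1/time).
#' @return Gain in 1/time (vectorized over `x`).
#' @export
log_gain <- function(x, h, lam) {
  stopifnot(inherits(h, "hill_transfer"))
  if (any(x <= 0))
    stop_induce("x must be strictly positive for the log-coordinate gain",
                "induce_domain_error")
  if (!is.numeric(lam) || lam <= 0)
    stop_induce("lam must be a positive decay rate", "induce_input_error")
  occ <- (x / h$K)^h$n / (1 + (x / h$K)^h$n)   # fractional occupancy
  if (h$repression) -lam * h$n * occ else lam * h$n * (1 - occ)
}

#' Slope of the transfer function against log-input
#'
#' `d f / d ln x = n * f * (1 - f/nu)` (absolute value for repression), the
#' slope of the response curve plotted against log concentration. It peaks
#' exactly at half-maximal activation `x = K` for every Hill coefficient,
#' which is why the strength of a regulatory effect read off a dose-response
#' plot is largest in the middle of the dynamic range.
#'
#' @inheritParams log_gain
#' @return Signed slope in concentration units (negative for repression).
#' @export
transfer_slope <- function(x, h) {
  stopifnot(inherits(h, "hill_transfer"))
  if (any(x < 0)) stop_induce("x must be nonnegative", "induce_input_error")
  f <- hill_response(x, h)
  s <- h$n * f * (1 - f / h$nu)
  if (h$repression) -s else s
}
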