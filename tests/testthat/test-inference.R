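# Estimation pipeline: transfer fits, normalization, per-dose covariance
# estimation, bootstrap, and the constrained two-node fit.

make_dataset <- function(entry = test_two_node(), n_cells = 10000, seed = 1) {
  simulate_ensemble(entry$motif, dose_design(entry$doses, n_cells = n_cells,
                                             seed = seed), entry$drive)
}

test_that("transfer fits recover the upstream drive and slope signs", {
  ds <- make_dataset(seed = 4)
  tf <- fit_transfer(ds, "S", "T")
  # the source's mean dose-response is exactly the drive Hill (nu=10, K=1)
  expect_equal(tf$hills$S$K, 1, tolerance = 0.2)
  expect_equal(tf$hills$S$nu, 10, tolerance = 0.2 * 10)
  expect_gt(tf$transfer_slope_sign, 0)
  expect_false(tf$degenerate)
  rep_ds <- make_dataset(example_motifs()$two_node_repression, seed = 4)
  tf_rep <- fit_transfer(rep_ds, "G1", "G2")
  expect_lt(tf_rep$transfer_slope_sign, 0)
})

test_that("flat responses are flagged degenerate", {
  nl <- null_two_node()
  ds <- simulate_ensemble(nl$motif, dose_design(nl$doses, n_cells = 300,
                                                seed = 2), nl$drive)
  tf <- fit_transfer(ds, "S", "T")
  expect_true(tf$degenerate)
  expect_error(fit_transfer(ds, "S", "missing"), class = "induce_input_error")
})

test_that("normalization is a pure log shift: covariances are invariant", {
  ds <- make_dataset(n_cells = 800, seed = 6)
  plain <- normalize_dataset(ds)                       # scale 1 = plain log
  scaled <- normalize_dataset(ds, norm = list(S = 3.7, T = 210))
  expect_equal(scaled$data$S, plain$data$S - log(3.7), tolerance = 1e-12)
  fc1 <- dose_covariances(plain, "S", "T", B = 0)
  fc2 <- dose_covariances(scaled, "S", "T", B = 0)
  expect_equal(fc1$v1, fc2$v1, tolerance = 1e-12)
  expect_equal(fc1$v2, fc2$v2, tolerance = 1e-12)
  expect_equal(fc1$c12, fc2$c12, tolerance = 1e-12)
  # intensities equal to the scale map to zero
  one <- ds
  one$data$S[] <- 3.7
  expect_true(all(normalize_dataset(one, norm = list(S = 3.7))$data$S == 0))
  expect_error(normalize_dataset(plain), class = "induce_input_error")
})

test_that("nonpositive intensities are dropped and counted", {
  ds <- make_dataset(n_cells = 100, seed = 8)
  ds$data$S[c(1, 5, 9)] <- 0
  ds$data$T[2] <- -1
  out <- normalize_dataset(ds)
  expect_equal(out$meta$dropped_nonpositive, 4)
  expect_true(all(is.finite(out$data$S)))
})

test_that("covariance estimation is the ML bivariate-normal fit", {
  Y <- rbind(c(0, 0), c(2, 2), c(0, 0), c(2, 2), c(0, 0), c(2, 2),
             c(0, 0), c(2, 2), c(0, 0), c(2, 2))
  est <- estimate_covariance(Y)
  expect_equal(est$v1, 1)    # ML denominator n
  expect_equal(est$v2, 1)
  expect_equal(est$c12, 1)
  anti <- cbind(1:20, -(1:20))
  expect_lt(estimate_covariance(anti)$c12, 0)
  expect_error(estimate_covariance(Y[1:5, ]), class = "induce_insufficient_data")
})

test_that("per-dose estimates match the generator covariance on big ensembles", {
  ex <- test_two_node()
  doses <- ex$doses[c(9, 13)]
  ds <- simulate_ensemble(ex$motif, dose_design(doses, n_cells = 1e5, seed = 11),
                          ex$drive)
  fc <- dose_covariances(normalize_dataset(ds), "S", "T", B = 0)
  tr <- motif_trajectory(ex$motif, doses, ex$drive)
  expect_equal(fc$v1, tr$sigma11, tolerance = 0.02)
  expect_equal(fc$v2, tr$sigma22, tolerance = 0.02)
  expect_equal(fc$c12, tr$sigma12, tolerance = 0.02)
})

test_that("bootstrap SDs behave: zero on degenerate data, near asymptotics on normal", {
  Y0 <- matrix(1, 50, 2)
  expect_equal(unname(bootstrap_covariance(Y0, B = 200, seed = 1)), c(0, 0, 0))
  set.seed(33)
  n <- 10000
  S <- matrix(c(1, 0.4, 0.4, 1.5), 2)
  Y <- MASS::mvrnorm(n, c(0, 0), S)
  sds <- bootstrap_covariance(Y, B = 500, seed = 9)
  asym <- sqrt((S[1, 1] * S[2, 2] + S[1, 2]^2) / n)   # Var(s12) under normality
  expect_lt(abs(sds[["sd_c12"]] / asym - 1), 0.25)
  expect_identical(bootstrap_covariance(Y, B = 100, seed = 4),
                   bootstrap_covariance(Y, B = 100, seed = 4))
  expect_error(bootstrap_covariance(Y, B = 50), class = "induce_input_error")
})

test_that("noiseless quadratic trajectories are fitted exactly", {
  ex <- test_two_node()
  tr <- motif_trajectory(ex$motif, ex$doses, ex$drive)
  fc <- data.frame(dose = tr$dose, n = NA, mean1 = 0, mean2 = 0,
                   v1 = tr$sigma11, v2 = tr$sigma22, c12 = tr$sigma12,
                   sd_v1 = NA, sd_v2 = NA, sd_c12 = NA)
  attr(fc, "species") <- c("S", "T")
  class(fc) <- c("fitted_covariance", "data.frame")
  fit <- fit_two_node(fc, "12")
  alpha <- ex$motif$q[1]^2 / 2
  beta <- ex$motif$q[2]^2 / 2
  expect_equal(fit$alpha, alpha, tolerance = 1e-8)
  expect_equal(fit$beta, beta, tolerance = 1e-8)
  expect_lt(fit$sse, 1e-16)
  # fitted quadratic passes through (0, beta-hat) by construction
  expect_equal(var2_of_cov(fit$c0, fit$alpha, fit$beta), fit$beta)
  expect_error(fit_two_node(fc[1:3, ], "12"), class = "induce_input_error")
})

test_that("sampled two-node data recover the noise parameters within 10 percent", {
  ex <- test_two_node()
  ds <- make_dataset(seed = 12)
  fc <- dose_covariances(normalize_dataset(ds), "S", "T", B = 200, seed = 12)
  fit <- fit_two_node(fc, "12")
  alpha <- ex$motif$q[1]^2 / 2
  beta <- ex$motif$q[2]^2 / 2
  expect_lt(abs(fit$alpha / alpha - 1), 0.10)
  expect_lt(abs(fit$beta / beta - 1), 0.10)
  # alpha-hat sits within the bootstrap uncertainty of the mean source variance
  expect_lt(abs(fit$alpha - mean(fc$v1)), 3 * mean(fc$sd_v1) / sqrt(nrow(fc)) + 1e-4)
  # weighting and the covariance-offset variant stay close to the default
  fit_w <- fit_two_node(fc, "12", weights = "bootstrap")
  expect_lt(abs(fit_w$alpha / alpha - 1), 0.10)
  fit_c <- fit_two_node(fc, "12", third_param = TRUE)
  expect_lt(abs(fit_c$alpha / alpha - 1), 0.10)
  expect_lt(abs(fit_c$c0), 0.01)
})

test_that("the reverse-direction fit is consistently worse on directed data", {
  worse <- 0
  for (s in 1:25) {
    ds <- make_dataset(n_cells = 4000, seed = 400 + s)
    fc <- dose_covariances(normalize_dataset(ds), "S", "T", B = 0)
    f <- fit_two_node(fc, "12")
    r <- fit_two_node(fc, "21")
    worse <- worse + (sum(r$errors) > sum(f$errors))
  }
  expect_gte(worse, 24)
})
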