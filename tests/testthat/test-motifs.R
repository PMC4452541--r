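# Hill transfer functions, closed-form two-node covariance, motif
# trajectories and open-loop detection.

test_that("Hill response obeys its defining values and limits", {
  h <- hill_transfer(nu = 1, K = 1, n = 2)
  expect_equal(hill_response(1, h), 0.5)       # half-maximal at x = K
  expect_equal(hill_response(3, h), 9 / 10)
  expect_equal(hill_response(0, h), 0)
  expect_equal(hill_response(1e9, h), 1, tolerance = 1e-12)
  hr <- hill_transfer(nu = 2, K = 5, n = 3, repression = TRUE)
  expect_equal(hill_response(5, hr), 1)         # nu/2 at x = K
  expect_equal(hill_response(0, hr), 2)
  expect_lt(hill_response(1e6, hr), 1e-9)
  expect_error(hill_response(-1, h), class = "induce_input_error")
  expect_error(hill_transfer(nu = 1, K = 1, n = -2), class = "induce_input_error")
})

test_that("log-gain matches a central-difference derivative of ln f vs ln x", {
  num_gain <- function(x, h, lam, eps = 1e-6) {
    lam * (log(hill_response(x * exp(eps), h)) -
             log(hill_response(x * exp(-eps), h))) / (2 * eps)
  }
  for (rep_flag in c(FALSE, TRUE)) {
    h <- hill_transfer(nu = 3, K = 2, n = 2.5, repression = rep_flag)
    for (x in c(0.1, 0.5, 2, 7, 40)) {
      expect_equal(log_gain(x, h, lam = 1.3), num_gain(x, h, 1.3),
                   tolerance = 1e-6)
    }
  }
  h <- hill_transfer(nu = 1, K = 2, n = 2)
  expect_equal(log_gain(2, h, lam = 3), 3 * 2 / 2)       # lambda n / 2 at x = K
  expect_equal(log_gain(1e-8, h, lam = 3), 3 * 2, tolerance = 1e-8)
  expect_lt(abs(log_gain(1e6, h, lam = 3)), 1e-10)
  hr <- hill_transfer(nu = 1, K = 2, n = 2, repression = TRUE)
  expect_equal(log_gain(2, hr, lam = 3), -3)             # sign flip at x = K
  expect_error(log_gain(0, h, lam = 1), class = "induce_domain_error")
})

test_that("transfer-function slope peaks at half-maximal activation for any n", {
  x_grid <- 10^seq(-2, 2, length.out = 401)   # grid contains x = K = 1
  for (n in c(0.5, 1, 2, 4, 8)) {
    for (rep_flag in c(FALSE, TRUE)) {
      h <- hill_transfer(nu = 5, K = 1, n = n, repression = rep_flag)
      peak <- x_grid[which.max(abs(transfer_slope(x_grid, h)))]
      expect_equal(log10(peak), 0, tolerance = 0.011)
    }
  }
})

test_that("closed-form two-node covariance equals the Lyapunov solve on random draws", {
  set.seed(314)
  worst <- 0
  for (i in 1:1000) {
    alpha <- 10^runif(1, -3, 1); beta <- 10^runif(1, -3, 1)
    lam <- 10^runif(1, -1, 1); k <- runif(1, -4, 4)
    p <- two_node_params(alpha, beta, lam, k)
    A <- matrix(c(-lam, k, 0, -lam), 2)
    Q <- diag(c(sqrt(2 * lam * alpha), sqrt(2 * lam * beta)))
    worst <- max(worst, rel_diff(two_node_covariance(p),
                                 solve_lyapunov(network_model(A, Q))))
  }
  expect_lt(worst, 1e-10)
})

test_that("disconnected and signed cases of the closed form behave as stated", {
  p0 <- two_node_covariance(two_node_params(0.3, 0.7, 2, 0))
  expect_equal(covariance_of(p0, 1, 2), 0)
  expect_equal(variance_of(p0, 2), 0.7)
  for (k in c(-3, -0.1, 0.2, 5)) {
    s <- two_node_covariance(two_node_params(1, 1, 1, k))
    expect_equal(sign(covariance_of(s, 1, 2)), sign(k))
  }
  expect_equal(var2_of_cov(0, alpha = 2, beta = 0.5), 0.5)
  expect_equal(var2_of_cov(0.5, 1, 1), 1.5)
  expect_equal(var2_of_cov(-0.4, 1.3, 0.2), var2_of_cov(0.4, 1.3, 0.2))
  expect_error(var2_of_cov(1, alpha = 0, beta = 1), class = "induce_input_error")
})

test_that("two-node trajectories keep the source variance constant on the quadratic law", {
  ex <- test_two_node()
  tr <- motif_trajectory(ex$motif, ex$doses, ex$drive)
  alpha <- ex$motif$q[1]^2 / (2 * ex$motif$lambda[1])
  beta <- ex$motif$q[2]^2 / (2 * ex$motif$lambda[2])
  expect_lt(diff(range(tr$sigma11)) / mean(tr$sigma11), 1e-10)
  expect_equal(tr$sigma11[1], alpha, tolerance = 1e-10)
  expect_equal(tr$sigma22, var2_of_cov(tr$sigma12, alpha, beta),
               tolerance = 1e-10)
  expect_true(all(tr$sigma12 > 0))  # activating edge
  rep_ex <- example_motifs()$two_node_repression
  tr_rep <- motif_trajectory(rep_ex$motif, rep_ex$doses, rep_ex$drive)
  expect_true(all(tr_rep$sigma12 < 0))
  expect_equal(tr_rep$sigma22, var2_of_cov(tr_rep$sigma12, alpha, beta),
               tolerance = 1e-10)
})

test_that("convergent motif with a silenced third node collapses onto the quadratic", {
  m <- motif_spec("convergent", lambda = c(1, 1, 1),
                  q = c(sqrt(0.08), sqrt(0.04), 0),
                  edges = list("1->2" = hill_transfer(nu = 10, K = 1, n = 2),
                               "3->2" = hill_transfer(nu = 10, K = 1e-6, n = 1)),
                  labels = c("S", "T", "U"))
  doses <- 10^seq(-2, 2, length.out = 23)
  drive <- list("1" = hill_transfer(nu = 10, K = 1, n = 1),
                "3" = hill_transfer(nu = 5, K = 1, n = 1))
  tr <- motif_trajectory(m, doses, drive)
  # q3 = 0 and a saturated (flat) 3->2 transfer: node 3 contributes nothing
  fit <- lm(sigma22 ~ I(sigma12^2), data = as.data.frame(tr))
  expect_lt(max(abs(residuals(fit))) / diff(range(tr$sigma22)), 1e-6)
  expect_false(detect_open_loop(tr)$loop)
})

test_that("the cascade example opens loops in both variance-covariance planes", {
  ex <- example_motifs()$cascade
  tr <- motif_trajectory(ex$motif, ex$doses, ex$drive)
  l2 <- detect_open_loop(tr, which = 2)
  l1 <- detect_open_loop(tr, which = 1)
  expect_true(l2$loop)
  expect_true(l1$loop)
  expect_gt(l2$score, 0.2)
  expect_gt(l1$score, 0.2)
})

test_that("open-loop detection never fires on exact two-node paths", {
  set.seed(99)
  for (i in 1:1000) {
    alpha <- 10^runif(1, -2, 0); beta <- 10^runif(1, -2, 0)
    lam <- 10^runif(1, -0.5, 0.5)
    k_max <- runif(1, 0.5, 2) * lam
    ks <- k_max * (1 - seq(0, 1, length.out = 12)^runif(1, 0.5, 2))
    rows <- t(vapply(ks, function(k) {
      s <- two_node_covariance(two_node_params(alpha, beta, lam, k))
      c(sigma11 = variance_of(s, 1), sigma22 = variance_of(s, 2),
        sigma12 = covariance_of(s, 1, 2))
    }, numeric(3)))
    expect_false(detect_open_loop(as.data.frame(rows))$loop)
  }
  # a path traversing out and back along the same quadratic
  ks <- c(seq(0, 2, length.out = 8), seq(2, 0, length.out = 8))
  rows <- t(vapply(ks, function(k) {
    s <- two_node_covariance(two_node_params(0.5, 0.2, 1, k))
    c(sigma11 = variance_of(s, 1), sigma22 = variance_of(s, 2),
      sigma12 = covariance_of(s, 1, 2))
  }, numeric(3)))
  expect_false(detect_open_loop(as.data.frame(rows))$loop)
  expect_error(detect_open_loop(as.data.frame(rows)[1:3, ]),
               class = "induce_input_error")
})

test_that("motif validation rejects mismatched edge sets and bad parameters", {
  expect_error(motif_spec("two_node", lambda = c(1, 1), q = c(1, 1),
                          edges = list("2->1" = hill_transfer(1, 1, 1))),
               class = "induce_input_error")
  expect_error(motif_spec("cascade", lambda = c(1, 1, -1), q = c(1, 1, 1),
                          edges = list("3->1" = hill_transfer(1, 1, 1),
                                       "1->2" = hill_transfer(1, 1, 1))),
               class = "induce_input_error")
  ex <- test_two_node()
  expect_error(motif_trajectory(ex$motif, rev(ex$doses), ex$drive),
               class = "induce_input_error")
})

test_that("motif specifications round-trip through the plain-text config", {
  m <- example_motifs()$cascade$motif
  f <- withr::local_tempfile(fileext = ".yaml")
  write_motif_spec(m, f)
  m2 <- read_motif_spec(f)
  expect_identical(m2$kind, m$kind)
  expect_equal(m2$lambda, m$lambda, tolerance = 1e-15)
  expect_equal(m2$q, m$q, tolerance = 1e-15)
  expect_identical(names(m2$edges), names(m$edges))
  for (nm in names(m$edges)) expect_equal(m2$edges[[nm]], m$edges[[nm]])
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("kind: cascade", bad)
  expect_error(read_motif_spec(bad), class = "induce_parse_error")
})

test_that("trajectories export as tidy tables", {
  ex <- test_two_node()
  tr <- motif_trajectory(ex$motif, ex$doses[1:6], ex$drive)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 6)
  expect_true(all(c("dose", "sigma11", "sigma22", "sigma12") %in% names(back)))
})
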