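test_that("BCa interval matches a brute-force implementation on the same resample stream", {
  values <- c(2.1, 3.7, 1.4, 5.2, 4.8, 2.9, 3.3, 6.1, 0.9, 4.2)
  B <- 2000L
  seed <- 17L
  ci <- bca_bootstrap_median(values, iterations = B, seed = seed)

  # independent brute-force BCa, reproducing the identical resample stream
  n <- length(values)
  thetas <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, B * n, replace = TRUE), nrow = B)
    apply(idx, 1, function(i) median(values[i]))
  })
  theta_hat <- median(values)
  z0 <- qnorm(mean(thetas < theta_hat))
  jack <- vapply(seq_len(n), function(i) median(values[-i]), numeric(1))
  jm <- mean(jack)
  a <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
  zq <- qnorm(c(0.025, 0.975))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  expected <- unname(quantile(thetas, adj))
  expect_equal(ci$lower, expected[1], tolerance = 1e-12)
  expect_equal(ci$upper, expected[2], tolerance = 1e-12)
  expect_equal(ci$estimate, theta_hat)
})

test_that("BCa interval is deterministic under a seed and degenerate on constants", {
  v <- c(1.2, 5.3, 2.2, 8.8, 4.1, 0.3, 6.6)
  a <- bca_bootstrap_median(v, iterations = 1000, seed = 5L)
  b <- bca_bootstrap_median(v, iterations = 1000, seed = 5L)
  expect_identical(a, b)
  d <- bca_bootstrap_median(c(5, 5, 5, 5), iterations = 1000, seed = 1L)
  expect_equal(d$lower, 5)
  expect_equal(d$upper, 5)
})

test_that("BCa reduces to the percentile interval for a symmetric resample distribution", {
  # constructed replicates symmetric about the estimate, symmetric jackknife:
  # z0 = 0 and a = 0, so the adjusted quantiles are the plain ones
  thetas <- c(seq(-1, -0.01, length.out = 500), seq(0.01, 1, length.out = 500))
  jack <- c(-2, -1, 1, 2)
  ci <- hawkpursuit:::bca_interval(thetas, 0, jack, 0.95)
  expect_equal(ci, unname(quantile(thetas, c(0.025, 0.975))),
               tolerance = 1e-12)
})

test_that("BCa agrees with the boot package on a common fixture", {
  values <- withr::with_seed(99, rnorm(40, mean = 10, sd = 2))
  ci <- bca_bootstrap_median(values, iterations = 20000, seed = 4L)
  bt <- withr::with_seed(8L, {
    b <- boot::boot(values, function(d, i) median(d[i]), R = 20000)
    boot::boot.ci(b, type = "bca")$bca[4:5]
  })
  # different resample streams and quantile interpolation; agreement to the
  # scale of adjacent order statistics of the data
  expect_lt(abs(ci$lower - bt[1]), 0.5)
  expect_lt(abs(ci$upper - bt[2]), 0.5)
})

test_that("paired sign test reproduces exact binomial tail probabilities", {
  # 8 pairs, all A > B
  expect_equal(paired_sign_test(2:9, 1:8), 2 * 0.5^8)
  # 10 pairs, 5 each direction
  expect_equal(paired_sign_test(c(1:5, 11:15), c(6:10, 6:10)), 1)
  # ties dropped: 8 pairs, 2 ties, 5 of 6 positive
  a <- c(5, 5, 2, 3, 4, 5, 6, 1)
  b <- c(5, 5, 1, 1, 1, 1, 1, 2)
  # enumerate the two-tailed tail for k = 5, n = 6 at p = 1/2
  probs <- dbinom(0:6, 6, 0.5)
  p_exp <- sum(probs[probs <= dbinom(5, 6, 0.5) + 1e-12])
  expect_equal(paired_sign_test(a, b), p_exp)
  # symmetry under swapping the two models
  expect_equal(paired_sign_test(a, b), paired_sign_test(b, a))
  # all-tied input warns and caps at 1
  expect_warning(p <- paired_sign_test(c(1, 2), c(1, 2)), "zero")
  expect_equal(p, 1)
})

test_that("bootstrap of the global fit covers the generating parameters", {
  flights <- generate_cohort(
    8, synthetic_spec(law = "inertial_pn", N = 1, K = 0, tau = 0.055,
                      dt = test_dt, noise_sigma = 0.01, seed = 31L))
  g <- build_error_grid(flights, "inertial_pn",
                        guidance_grids(tau = seq(0.035, 0.075, 0.005)))
  cis <- bootstrap_global(g, iterations = 200, seed = 6L)
  expect_setequal(cis$quantity,
                  c("N_breve", "K_breve", "tau_breve", "eps_tilde"))
  nrow_ci <- cis[cis$quantity == "N_breve", ]
  expect_lte(nrow_ci$lower, 1.0)
  expect_gte(nrow_ci$upper, 1.0)
  # identical flights give zero-width intervals at the common optimum
  g1 <- g[g$flight_id == g$flight_id[1], ]
  same <- dplyr::bind_rows(lapply(1:4, function(i) {
    gg <- g1
    gg$flight_id <- paste0("copy", i)
    gg
  }))
  attr(same, "law") <- "inertial_pn"
  attr(same, "grids") <- attr(g, "grids")
  class(same) <- c("error_grid", class(same))
  cz <- bootstrap_global(same, iterations = 100, seed = 2L)
  expect_true(all(cz$upper == cz$lower))
})

test_that("k-fold cross-validation partitions flights and scores held-out folds", {
  # bookkeeping on a synthetic error grid: 24 flights, 4 folds
  cells <- tidyr::expand_grid(tau = seq(0, 0.01, 0.005), N = c(0.9, 1, 1.1),
                              K = 0)
  fake <- dplyr::bind_rows(lapply(1:24, function(i) {
    eps <- abs(cells$N - 1) + cells$tau + 0.001 * i
    tibble::tibble(flight_id = sprintf("f%02d", i), N = cells$N, K = cells$K,
                   tau = cells$tau, eps = eps)
  }))
  attr(fake, "law") <- "inertial_pn"
  class(fake) <- c("error_grid", class(fake))
  cv <- kfold_crossval(fake, k = 4, seed = 9L)
  expect_equal(sort(table(cv$folds$fold)), sort(c(6, 6, 6, 6)),
               ignore_attr = TRUE)
  expect_setequal(cv$folds$flight_id, sprintf("f%02d", 1:24))
  expect_equal(nrow(cv$per_fold), 4)
  # every training fit lands on the common optimum (N = 1, tau = 0)
  expect_true(all(cv$per_fold$N == 1))
  expect_true(all(cv$per_fold$tau == 0))
  expect_identical(kfold_crossval(fake, k = 4, seed = 9L)$folds, cv$folds)
  expect_error(kfold_crossval(fake, k = 30, seed = 1L), "exceeds")
})
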