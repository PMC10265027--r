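#' BCa bootstrap confidence interval for the median
#'
#' Bias-corrected and accelerated percentile bootstrap interval for the
#' median of per-flight statistics: flights are resampled with replacement,
#' the bias correction comes from the fraction of bootstrap replicates below
#' the point estimate, and the acceleration from the jackknife. Deterministic
#' under a fixed seed.
#'
#' @param values Numeric vector of per-flight statistics (length >= 2).
#' @param iterations Number of bootstrap resamples; the production default of
#'   1e6 matches the per-flight analysis, tests and interactive use run
#'   smaller.
#' @param seed Integer seed.
#' @param level Confidence level, default 0.95.
#' @return A one-row tibble of class `bootstrap_ci`: `estimate`, `lower`,
#'   `upper`, `level`, `iterations`, `seed`.
#' @export
bca_bootstrap_median <- function(values, iterations = 1e6, seed = 1L,
                                 level = 0.95) {
  stopifnot(length(values) >= 2, iterations >= 100)
  if (all(values == values[1])) {
    return(new_bootstrap_ci(values[1], values[1], values[1], level,
                            iterations, seed))
  }
  n <- length(values)
  theta_hat <- median(values)
  thetas <- withr::with_seed(seed, {
    chunk <- 100000L
    done <- 0L
    acc <- vector("list", ceiling(iterations / chunk))
    k <- 0L
    while (done < iterations) {
      b <- min(chunk, as.integer(iterations) - done)
      idx <- matrix(sample.int(n, b * n, replace = TRUE), nrow = b)
      k <- k + 1L
      acc[[k]] <- resample_medians_cpp(values, idx)
      done <- done + b
    }
    unlist(acc[seq_len(k)])
  })
  jack <- vapply(seq_len(n), function(i) median(values[-i]), numeric(1))
  ci <- bca_interval(thetas, theta_hat, jack, level)
  new_bootstrap_ci(theta_hat, ci[1], ci[2], level, iterations, seed)
}

# BCa interval from bootstrap replicates + jackknife values of the statistic.
bca_interval <- function(thetas, theta_hat, jack, level) {
  alpha <- (1 - level) / 2
  prop <- mean(thetas < theta_hat)
  if (prop <= 0 || prop >= 1) {
    # statistic pinned to one side; fall back to percentile quantiles
    return(unname(quantile(thetas, c(alpha, 1 - alpha), names = FALSE)))
  }
  z0 <- qnorm(prop)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den == 0) 0 else num / den
  zl <- qnorm(alpha); zu <- qnorm(1 - alpha)
  a1 <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  unname(quantile(thetas, c(a1, a2), names = FALSE))
}

new_bootstrap_ci <- function(est, lower, upper, level, iterations, seed) {
  out <- tibble::tibble(estimate = est, lower = lower, upper = upper,
                        level = level, iterations = iterations, seed = seed)
  class(out) <- c("bootstrap_ci", class(out))
  out
}

#' Bootstrap the globally fitted parameters
#'
#' Resamples flights with replacement from a cached error grid, recomputes
#' the cell-wise median and its argmin for each resample (no re-simulation),
#' and returns BCa intervals for the globally fitted `N`, `K`, `tau` and the
#' median RMS error.
#'
#' @param grid An [build_error_grid()] result.
#' @param iterations Number of resamples; default 1e3 as in the global
#'   analysis.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A tibble of class `bootstrap_ci` with one row per quantity
#'   (`N_breve`, `K_breve`, `tau_breve`, `eps_tilde`).
#' @export
bootstrap_global <- function(grid, iterations = 1e3, seed = 1L,
                             level = 0.95) {
  gm <- grid_matrix(grid)
  n <- ncol(gm$m)
  stopifnot(n >= 2)
  stat <- function(cols) {
    med <- rowmed_subset_cpp(gm$m, as.integer(cols))
    i <- which.min(med)
    c(N = gm$key$N[i], K = gm$key$K[i], tau = gm$key$tau[i], eps = med[i])
  }
  theta_hat <- stat(seq_len(n))
  boots <- withr::with_seed(seed, {
    t(vapply(seq_len(iterations),
             function(b) stat(sample.int(n, n, replace = TRUE)),
             numeric(4)))
  })
  jack <- t(vapply(seq_len(n), function(i) stat(setdiff(seq_len(n), i)),
                   numeric(4)))
  qty <- c("N_breve", "K_breve", "tau_breve", "eps_tilde")
  out <- purrr::map_dfr(seq_len(4), function(j) {
    if (all(boots[, j] == boots[1, j])) {
      ci <- c(boots[1, j], boots[1, j])
    } else {
      ci <- bca_interval(boots[, j], theta_hat[j], jack[, j], level)
    }
    tibble::tibble(quantity = qty[j], estimate = unname(theta_hat[j]),
                   lower = ci[1], upper = ci[2], level = level,
                   iterations = iterations, seed = seed)
  })
  class(out) <- c("bootstrap_ci", class(out))
  out
}

#' Paired sign test between two models' per-flight errors
#'
#' Exact two-tailed binomial test on the sign of `eps_A - eps_B` over the
#' non-zero differences (ties dropped, the classical conditional sign test).
#'
#' @param eps_A,eps_B Equal-length per-flight RMS errors (m).
#' @return The two-tailed p-value in (0, 1].
#' @export
paired_sign_test <- function(eps_A, eps_B) {
  stopifnot(length(eps_A) == length(eps_B))
  d <- eps_A - eps_B
  d <- d[d != 0]
  if (length(d) == 0) {
    warn("all paired differences are zero; p = 1")
    return(1)
  }
  binom.test(sum(d > 0), length(d), p = 0.5,
             alternative = "two.sided")$p.value
}

#' k-fold cross-validation of a globally fitted model
#'
#' Randomly partitions the flights of a cached error grid into `k` near-equal
#' folds, fits the model globally on the other `k - 1` folds, and evaluates
#' the median RMS error on the held-out fold at those parameters. Reported as
#' the mean of the `k` validation medians.
#'
#' @param grid An [build_error_grid()] result.
#' @param k Number of folds (default 12).
#' @param seed Integer seed for the fold assignment (uniform random
#'   permutation).
#' @return A list of class `crossval_report`: `folds` (tibble `flight_id`,
#'   `fold`), `per_fold` (tibble `fold`, `N`, `K`, `tau`,
#'   `eps_tilde_train`, `eps_tilde_val`, `n_val`), `mean_of_medians`, `k`,
#'   `seed`.
#' @export
kfold_crossval <- function(grid, k = 12, seed = 1L) {
  gm <- grid_matrix(grid)
  n <- ncol(gm$m)
  if (k < 2) abort("k must be at least 2")
  if (k > n) abort("k exceeds the number of flights")
  fold <- withr::with_seed(seed, {
    sample(rep_len(seq_len(k), n))
  })
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    train <- which(fold != f); val <- which(fold == f)
    med_tr <- rowmed_subset_cpp(gm$m, as.integer(train))
    i <- which.min(med_tr)
    med_val <- rowmed_subset_cpp(gm$m, as.integer(val))
    tibble::tibble(fold = f, N = gm$key$N[i], K = gm$key$K[i],
                   tau = gm$key$tau[i], eps_tilde_train = med_tr[i],
                   eps_tilde_val = med_val[i], n_val = length(val))
  })
  structure(
    list(folds = tibble::tibble(flight_id = gm$ids, fold = fold),
         per_fold = per_fold,
         mean_of_medians = mean(per_fold$eps_tilde_val),
         k = k, seed = seed),
    class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report>  k = %d folds over %d flights (seed %d)\n",
              x$k, nrow(x$folds), x$seed))
  cat(sprintf("  mean of validation median RMS errors: %.4f m\n",
              x$mean_of_medians))
  invisible(x)
}

#' @method glance crossval_report
#' @export
glance.crossval_report <- function(x, ...) {
  tibble::tibble(k = x$k, n_flights = nrow(x$folds),
                 mean_of_medians = x$mean_of_medians,
                 mean_train_median = mean(x$per_fold$eps_tilde_train))
}
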