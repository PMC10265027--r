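#' Default parameter grids
#'
#' The exhaustive-search grids over which guidance models are fitted
#' globally: navigation gain `N` on \[0, 1.5\] in steps of 0.1, pursuit gain
#' `K` on \[0, 5\] 1/s in steps of 0.2, delay `tau` on \[0, 0.15\] s in steps
#' of 0.005 s (the 200 Hz frame period).
#'
#' @param N,K,tau Override any axis with a custom numeric grid.
#' @return A named list of the three grids.
#' @export
guidance_grids <- function(N = seq(0, 1.5, by = 0.1),
                           K = seq(0, 5, by = 0.2),
                           tau = seq(0, 0.15, by = 0.005)) {
  stopifnot(all(tau >= 0))
  list(N = N, K = K, tau = tau)
}

#' RMS position error between a simulated and a measured trajectory
#'
#' Root mean square Euclidean distance between simulated and measured
#' horizontal positions, evaluated at the 200 Hz measurement frames on
#' `[tau_max, intercept_time]` (so the error is independent of the
#' integration rate).
#'
#' @param sim Simulated trajectory from [simulate_pursuit()].
#' @param flight The flight supplying the measured frames.
#' @return RMS error in metres.
#' @export
rms_error <- function(sim, flight) {
  ev <- eval_frames(flight)
  i0 <- as.integer(round(flight$tau_max / flight$dt))
  pos <- ev$idx - i0 + 1L
  if (any(pos < 1 | pos > nrow(sim)))
    abort("simulated trajectory does not cover all evaluation frames")
  sqrt(mean((sim$x[pos] - ev$x)^2 + (sim$y[pos] - ev$y)^2))
}

# Shared per-flight inputs for the C++ RMS evaluator.
flight_arrays <- function(flight) {
  d <- flight$dense
  if (anyNA(d)) abort("input-coverage error: dense tracks contain missing values")
  ev <- eval_frames(flight)
  list(target = cbind(d$lure_x, d$lure_y, d$lure_vx, d$lure_vy),
       hawk = cbind(d$hawk_x, d$hawk_y, d$hawk_vx, d$hawk_vy),
       speed = d$hawk_speed,
       i0 = as.integer(round(flight$tau_max / flight$dt)),
       dt = flight$dt, ev = ev)
}

# eps for a matrix of (N, K, tau) under one law on one flight.
flight_rms <- function(fa, law, N, K, tau) {
  dlag <- as.integer(round(tau / fa$dt))
  params <- cbind(N, K, dlag)
  pursuit_rms_cpp(fa$target, fa$hawk, fa$speed, fa$i0, fa$dt,
                  law_code(law), params, fa$ev$idx, fa$ev$x, fa$ev$y)
}

#' Fit a guidance model to a single flight
#'
#' For each delay on the `tau` grid, minimises the RMS error over the law's
#' continuous gain(s) by Nelder-Mead from a multi-start (gains unconstrained
#' in sign), then returns the delay/gain combination with the smallest error.
#'
#' @param flight A `hawk_flight`.
#' @param law One of [guidance_laws].
#' @param tau_grid Candidate delays (s); default [guidance_grids()] `tau`
#'   (31 values, 0-0.15 s).
#' @param starts_N,starts_K Multi-start values for the gains.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @return A one-row tibble of class `guidance_fit`: `flight_id`, `law`,
#'   `N_hat`, `K_hat`, `tau_hat`, `eps_hat` (m).
#' @export
fit_flight <- function(flight, law, tau_grid = guidance_grids()$tau,
                       starts_N = c(0, 0.5, 1), starts_K = c(0, 1, 3),
                       reltol = 1e-8) {
  law <- match.arg(law, guidance_laws)
  if (flight$intercept_time <= flight$tau_max)
    abort("flight shorter than tau_max")
  fa <- flight_arrays(flight)
  useN <- law_uses_N(law); useK <- law_uses_K(law)
  starts <- if (useN && useK) {
    as.matrix(expand.grid(N = starts_N, K = starts_K))
  } else if (useN) cbind(N = starts_N) else cbind(K = starts_K)

  best <- list(eps = Inf)
  for (tau in tau_grid) {
    obj <- function(g) {
      N <- if (useN) g[[1]] else 0
      K <- if (useK) g[[length(g)]] else 0
      e <- flight_rms(fa, law, N, K, tau)
      if (!is.finite(e)) 1e6 else e
    }
    for (s in seq_len(nrow(starts))) {
      fit <- suppressWarnings(
        optim(starts[s, ], obj, method = "Nelder-Mead",
              control = list(reltol = reltol, maxit = 500)))
      if (fit$value < best$eps) {
        g <- fit$par
        best <- list(eps = fit$value, tau = tau,
                     N = if (useN) g[[1]] else 0,
                     K = if (useK) g[[length(g)]] else 0)
      }
    }
  }
  out <- tibble::tibble(flight_id = flight$id, law = law, N_hat = best$N,
                        K_hat = best$K, tau_hat = best$tau,
                        eps_hat = best$eps)
  class(out) <- c("guidance_fit", class(out))
  out
}

#' Fit a guidance model to each flight in a cohort
#'
#' @param flights List of `hawk_flight` objects.
#' @inheritParams fit_flight
#' @param ... Passed on to [fit_flight()].
#' @return A `guidance_fit` tibble, one row per flight.
#' @export
fit_flights <- function(flights, law, ...) {
  out <- dplyr::bind_rows(purrr::map(flights, fit_flight, law = law, ...))
  class(out) <- c("guidance_fit", class(out))
  out
}

#' Evaluate the RMS error over the full parameter grid
#'
#' Computes the RMS error for every flight at every grid point of the law's
#' parameter grid. PN laws use the `K = 0` slice (N x tau grid), PP the
#' `N = 0` slice (K x tau grid), the PNP laws the full N x K x tau grid; the
#' PN/PP grids are therefore exactly the corresponding slices of a PNP grid.
#' Simulation failures score `+Inf` and are kept in the grid.
#'
#' @param flights List of `hawk_flight` objects.
#' @param law One of [guidance_laws].
#' @param grids Parameter grids, default [guidance_grids()].
#' @return A tibble of class `error_grid` with columns `flight_id`, `N`,
#'   `K`, `tau`, `eps`; attributes `law` and `grids`.
#' @export
build_error_grid <- function(flights, law, grids = guidance_grids()) {
  law <- match.arg(law, guidance_laws)
  Ng <- if (law_uses_N(law)) grids$N else 0
  Kg <- if (law_uses_K(law)) grids$K else 0
  cells <- tidyr::expand_grid(tau = grids$tau, N = Ng, K = Kg)
  per_flight <- purrr::map(flights, function(fl) {
    fa <- flight_arrays(fl)
    tibble::tibble(flight_id = fl$id, N = cells$N, K = cells$K,
                   tau = cells$tau,
                   eps = flight_rms(fa, law, cells$N, cells$K, cells$tau))
  })
  out <- dplyr::bind_rows(per_flight)
  attr(out, "law") <- law
  attr(out, "grids") <- grids
  class(out) <- c("error_grid", class(out))
  out
}

# Cells x flights eps matrix in lexicographic (tau, N, K) cell order, so
# which.min on row medians lands on the lexicographically smallest tie.
grid_matrix <- function(grid) {
  key <- dplyr::distinct(grid[, c("tau", "N", "K")])
  key <- dplyr::arrange(key, .data$tau, .data$N, .data$K)
  ids <- unique(grid$flight_id)
  m <- matrix(NA_real_, nrow(key), length(ids),
              dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    g <- grid[grid$flight_id == ids[j], , drop = FALSE]
    ord <- order(g$tau, g$N, g$K)
    m[, j] <- g$eps[ord]
  }
  list(key = key, m = m, ids = ids)
}

#' Globally fit a guidance model from an error grid
#'
#' Takes the cell-wise median of the RMS error over flights and returns the
#' grid point minimising it. Ties are broken deterministically towards the
#' lexicographically smallest `(tau, N, K)`.
#'
#' @param grid An [build_error_grid()] result.
#' @param flight_ids Optional subset of flights to fit over (used by
#'   cross-validation and the bootstrap).
#' @return A one-row tibble of class `global_fit`: `law`, `N_breve`,
#'   `K_breve`, `tau_breve`, `eps_tilde` (median RMS error, m), `n_flights`.
#' @export
global_fit <- function(grid, flight_ids = NULL) {
  gm <- grid_matrix(grid)
  cols <- if (is.null(flight_ids)) seq_along(gm$ids) else
    match(flight_ids, gm$ids)
  if (anyNA(cols)) abort("unknown flight_id in subset")
  med <- rowmed_subset_cpp(gm$m, as.integer(cols))
  i <- which.min(med)
  out <- tibble::tibble(law = attr(grid, "law"),
                        N_breve = gm$key$N[i], K_breve = gm$key$K[i],
                        tau_breve = gm$key$tau[i], eps_tilde = med[i],
                        n_flights = length(cols))
  class(out) <- c("global_fit", class(out))
  out
}

#' @method tidy guidance_fit
#' @export
tidy.guidance_fit <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("flight_id", "law", "N_hat", "K_hat", "tau_hat")],
    c("N_hat", "K_hat", "tau_hat"),
    names_to = "term", values_to = "estimate")
}

#' @method glance guidance_fit
#' @export
glance.guidance_fit <- function(x, ...) {
  tibble::tibble(law = x$law[1], n_flights = nrow(x),
                 eps_tilde = median(x$eps_hat),
                 N_tilde = median(x$N_hat), K_tilde = median(x$K_hat),
                 tau_tilde = median(x$tau_hat))
}

#' @method tidy global_fit
#' @export
tidy.global_fit <- function(x, ...) {
  tibble::tibble(law = x$law,
                 term = c("N_breve", "K_breve", "tau_breve"),
                 estimate = c(x$N_breve, x$K_breve, x$tau_breve))
}

#' @method glance global_fit
#' @export
glance.global_fit <- function(x, ...) {
  tibble::as_tibble(x)[, c("law", "eps_tilde", "n_flights")]
}

#' Plot the median-error surface of a fitted grid
#'
#' Median RMS error over flights as a function of `N` and `K` at the globally
#' optimal delay (tile plot); for single-gain laws, a line over the active
#' gain.
#'
#' @param object An `error_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot error_grid
#' @export
autoplot.error_grid <- function(object, ...) {
  law <- attr(object, "law")
  gm <- grid_matrix(object)
  med <- rowmed_subset_cpp(gm$m, seq_len(ncol(gm$m)))
  df <- dplyr::mutate(gm$key, eps_tilde = med)
  best <- global_fit(object)
  if (law_uses_N(law) && law_uses_K(law)) {
    df <- df[abs(df$tau - best$tau_breve) < 1e-12, , drop = FALSE]
    ggplot2::ggplot(df, ggplot2::aes(.data$N, .data$K,
                                     fill = .data$eps_tilde)) +
      ggplot2::geom_tile() +
      ggplot2::geom_point(data = best,
                          ggplot2::aes(.data$N_breve, .data$K_breve),
                          inherit.aes = FALSE, colour = "red") +
      ggplot2::scale_fill_viridis_c(name = "median RMS (m)") +
      ggplot2::labs(title = paste0(law, ": median RMS error at tau = ",
                                   best$tau_breve, " s"),
                    x = "N", y = "K (1/s)") +
      ggplot2::theme_minimal()
  } else {
    gain <- if (law_uses_N(law)) "N" else "K"
    df <- dplyr::summarise(dplyr::group_by(df, .data[[gain]]),
                           eps_tilde = min(.data$eps_tilde), .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(.data[[gain]], .data$eps_tilde)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = paste0(law, ": median RMS error (best tau per ",
                                   gain, ")"),
                    x = gain, y = "median RMS error (m)") +
      ggplot2::theme_minimal()
  }
}
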