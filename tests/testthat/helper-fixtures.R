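# Shared fixtures, built once per test run and cached. All simulations in the
# test suite run at dt = 1e-3 s: generate-and-refit checks are invariant to
# the integration step (generator and fitter share the same discrete
# dynamics), and the delta-conservation check, which is dt-sensitive, runs at
# the production 5e-5 s in its own test.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, fixture_env)) assign(name, build(), fixture_env)
  get(name, fixture_env)
}

test_dt <- 1e-3

# one clean inertial-PN flight (no noise), truth N = 1, tau = 0.055 s
fx_flight_pn <- function() fixture("flight_pn", function() {
  generate_hawk_flight(
    synthetic_spec(law = "inertial_pn", N = 1, K = 0, tau = 0.055,
                   dt = test_dt, noise_sigma = 0, seed = 3L),
    id = "pn1")
})

# one clean inertial-PNP flight, truth N = 0.8, K = 2.4, tau = 0.05 s
fx_flight_pnp <- function() fixture("flight_pnp", function() {
  generate_hawk_flight(
    synthetic_spec(law = "inertial_pnp", N = 0.8, K = 2.4, tau = 0.05,
                   dt = test_dt, noise_sigma = 0, seed = 3L),
    id = "pnp1")
})

# hand-built flight with a stationary target and a 30 degree initial heading
# offset; measured pursuer flies straight during the pre-start window
fx_stationary_target_flight <- function(offset_deg = 30, speed = 6,
                                        duration = 2.5) {
  dt <- test_dt
  M <- as.integer(round(duration / dt))
  times <- (0:M) * dt
  tpos <- c(14, 3)
  p0 <- c(0.5, 3)
  los <- (tpos - p0) / sqrt(sum((tpos - p0)^2))
  th <- offset_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  v0 <- speed * as.numeric(R %*% los)
  dense <- tibble::tibble(
    time_s = times,
    lure_x = tpos[1], lure_y = tpos[2], lure_vx = 0, lure_vy = 0,
    hawk_x = p0[1] + v0[1] * times, hawk_y = p0[2] + v0[2] * times,
    hawk_vx = v0[1], hawk_vy = v0[2], hawk_speed = speed)
  fidx <- seq(1, M + 1, by = as.integer(round(1 / (200 * dt))))
  frames <- tibble::tibble(
    time_s = times[fidx],
    hawk_x = dense$hawk_x[fidx], hawk_y = dense$hawk_y[fidx],
    lure_x = tpos[1], lure_y = tpos[2])
  as_flight("stationary", frames, dense, dt, intercept_time = duration,
            meta = list())
}

# smooth weaving (maneuvering) target arrays for direct simulator calls
weave_target <- function(M, dt) {
  times <- (0:M) * dt
  cbind(4 + 5 * times,
        3 + 1.2 * sin(1.5 * times),
        rep(5, M + 1),
        1.2 * 1.5 * cos(1.5 * times))
}

random_state <- function() {
  r <- runif(2, -5, 5)
  while (sum(r^2) < 1e-4) r <- runif(2, -5, 5)
  v_P <- runif(2, -10, 10)
  while (sum(v_P^2) < 1e-4) v_P <- runif(2, -10, 10)
  list(r = r, v_T = runif(2, -10, 10), v_P = v_P)
}

# single flight with intercept-retry (deterministic seed sequence)
gen_flight <- function(spec, id = "flight") {
  fl <- generate_cohort(1, spec)[[1]]
  fl$id <- id
  fl
}
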