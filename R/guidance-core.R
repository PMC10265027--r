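#' Guidance laws
#'
#' The five candidate guidance laws. All command a turn rate that steers the
#' pursuer's velocity vector; they differ in the feedback signal used:
#'
#' * `"pp"` — proportional pursuit: turn rate `-K * delta`, where `delta` is
#'   the signed deviation angle between the pursuer's velocity and the
#'   line-of-sight to the target.
#' * `"inertial_pn"` — proportional navigation on the inertial line-of-sight
#'   rate: turn rate `N * los_rate_inertial`.
#' * `"background_pn"` — proportional navigation on the background
#'   line-of-sight rate (the target's motion relative to the visual background
#'   directly behind it): turn rate `N * los_rate_background`.
#' * `"inertial_pnp"` — mixed law `N * los_rate_inertial - K * delta`.
#' * `"background_pnp"` — mixed law `N * los_rate_background - K * delta`.
#'
#' @format A character vector of the five law names.
#' @export
guidance_laws <- c("pp", "inertial_pn", "background_pn",
                   "inertial_pnp", "background_pnp")

law_code <- function(law) {
  law <- match.arg(law, guidance_laws)
  match(law, guidance_laws)
}

law_uses_N <- function(law) law != "pp"
law_uses_K <- function(law) law %in% c("pp", "inertial_pnp", "background_pnp")

#' Guidance parameter set
#'
#' Bundles a guidance law with its gains and sensorimotor delay. Gains that a
#' law does not use are forced to zero: `K` for the PN laws, `N` for PP.
#'
#' @param law One of [guidance_laws].
#' @param N Navigation gain (dimensionless).
#' @param K Pursuit gain (1/s).
#' @param tau Sensorimotor delay (s), `>= 0`.
#' @return A one-row tibble of class `guidance_params` with columns `law`,
#'   `N`, `K`, `tau`.
#' @examples
#' guidance_params("inertial_pn", N = 1, tau = 0.055)
#' @export
guidance_params <- function(law, N = 0, K = 0, tau = 0) {
  law <- match.arg(law, guidance_laws)
  stopifnot(is.numeric(N), is.numeric(K), is.numeric(tau), length(tau) == 1)
  if (tau < 0) abort("tau must be non-negative")
  if (!law_uses_N(law)) N <- 0
  if (!law_uses_K(law)) K <- 0
  out <- tibble::tibble(law = law, N = N, K = K, tau = tau)
  class(out) <- c("guidance_params", class(out))
  out
}

#' Simulation configuration
#'
#' @param dt Integration step (s); the production default of 5e-5 s (20 kHz)
#'   matches the rate at which smoothed tracks are evaluated.
#' @param tau_max Largest admissible delay (s). Simulations start at
#'   `t_start = tau_max` so that measured pursuer states exist on
#'   `[t_start - tau, t_start]` for every admissible `tau`.
#' @param t_start Simulation start time (s); defaults to `tau_max`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 5e-5, tau_max = 0.15, t_start = tau_max) {
  stopifnot(dt > 0, tau_max >= 0, t_start >= 0)
  structure(list(dt = dt, tau_max = tau_max, t_start = t_start),
            class = "sim_config")
}

#' Signed deviation angle
#'
#' Signed angle from the line-of-sight vector `r` to the pursuer velocity
#' `v_P`, positive when `v_P` lies counterclockwise of `r`. Equivalent to
#' `atan2(cross(r, v_P), dot(r, v_P))`; magnitude in `[0, pi]`.
#'
#' @param r Line-of-sight vector, numeric length 2 (m).
#' @param v_P Pursuer velocity, numeric length 2 (m/s).
#' @return Signed angle in radians.
#' @examples
#' deviation_angle(c(1, 0), c(0, 3))  # +pi/2
#' @export
deviation_angle <- function(r, v_P) {
  check_vec2(r, "r"); check_vec2(v_P, "v_P")
  if (sum(r^2) == 0 || sum(v_P^2) == 0)
    abort("degenerate geometry: zero-length input vector")
  atan2(r[1] * v_P[2] - r[2] * v_P[1], sum(r * v_P))
}

#' Inertial line-of-sight rate
#'
#' Angular rate of the line-of-sight in a fixed (inertial) frame:
#' `cross(r, v_T - v_P) / |r|^2` (scalar z-component; counterclockwise
#' positive).
#'
#' @inheritParams deviation_angle
#' @param v_T Target velocity, numeric length 2 (m/s).
#' @return Signed rate in rad/s.
#' @export
los_rate_inertial <- function(r, v_T, v_P) {
  check_vec2(r, "r"); check_vec2(v_T, "v_T"); check_vec2(v_P, "v_P")
  r2 <- sum(r^2)
  if (r2 == 0) abort("degenerate geometry: zero-length line-of-sight")
  (r[1] * (v_T[2] - v_P[2]) - r[2] * (v_T[1] - v_P[1])) / r2
}

#' Background line-of-sight rate
#'
#' Angular rate of the line-of-sight measured against the visual background
#' directly behind the target: `cross(r, v_T) / |r|^2`. Depends only on the
#' target's own motion, not the pursuer's.
#'
#' @inheritParams los_rate_inertial
#' @return Signed rate in rad/s.
#' @export
los_rate_background <- function(r, v_T) {
  check_vec2(r, "r"); check_vec2(v_T, "v_T")
  r2 <- sum(r^2)
  if (r2 == 0) abort("degenerate geometry: zero-length line-of-sight")
  (r[1] * v_T[2] - r[2] * v_T[1]) / r2
}

#' Commanded centripetal acceleration
#'
#' Acceleration commanded by a guidance law given the delayed feedback terms:
#' `a = (N * los_rate - K * delta) * R90(v_P)`, where `R90` rotates a vector
#' +90 degrees (counterclockwise) — the planar equivalent of crossing a
#' vertical angular-rate vector with `v_P`. The scalar prefactor is the
#' commanded inertial turn rate. `a` is exactly perpendicular to `v_P`.
#'
#' @param params A [guidance_params()] row.
#' @param los_rate Delayed line-of-sight rate (rad/s), evaluated at `t - tau`
#'   in whichever frame the law uses.
#' @param delta Delayed signed deviation angle (rad) at `t - tau`.
#' @param v_P Current pursuer velocity, numeric length 2 (m/s).
#' @return Acceleration vector, numeric length 2 (m/s^2).
#' @export
commanded_acceleration <- function(params, los_rate, delta, v_P) {
  check_vec2(v_P, "v_P")
  if (sum(v_P^2) == 0) abort("degenerate geometry: zero pursuer velocity")
  N <- if (law_uses_N(params$law)) params$N else 0
  K <- if (law_uses_K(params$law)) params$K else 0
  turn <- N * los_rate - K * delta
  turn * c(-v_P[2], v_P[1])
}

check_vec2 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2 || !all(is.finite(x)))
    abort(paste0(name, " must be a finite numeric vector of length 2"))
  invisible(x)
}

#' Simulate a pursuit under a guidance law
#'
#' Forward-Euler integration of the pursuer's trajectory against a flight's
#' measured target track, with the simulated flight speed forced to match the
#' measured speed at each step (speed matching): only heading is governed by
#' the guidance law. The simulation starts at `t_start = tau_max` from the
#' measured pursuer state there; delayed feedback terms at `t - tau` are
#' computed from the simulated pursuer state when `t - tau >= t_start` and
#' from the measured pursuer states on the pre-start window otherwise.
#'
#' @param flight A `hawk_flight` object (see [as_flight()] or
#'   [generate_hawk_flight()]); its dense tracks supply the target
#'   positions/velocities and the measured pursuer speed at the integration
#'   step `dt`.
#' @param params A [guidance_params()] row. `tau` is realised as
#'   `round(tau / dt)` integration steps.
#' @param t_start Simulation start time (s); defaults to the flight's
#'   `tau_max` attribute (0.15 s).
#' @return A tibble with columns `time_s`, `x`, `y`, `vx`, `vy`, `delta`,
#'   `los_rate`, `turn_rate`, one row per integration step on
#'   `[t_start, intercept_time]`.
#' @export
simulate_pursuit <- function(flight, params, t_start = NULL) {
  stopifnot(inherits(flight, "hawk_flight"))
  dt <- flight$dt
  if (is.null(t_start)) t_start <- flight$tau_max
  i0 <- as.integer(round(t_start / dt))
  d <- flight$dense
  if (i0 >= nrow(d)) abort("t_start beyond end of flight")
  dlag <- as.integer(round(params$tau / dt))
  target <- cbind(d$lure_x, d$lure_y, d$lure_vx, d$lure_vy)
  hawk <- cbind(d$hawk_x, d$hawk_y, d$hawk_vx, d$hawk_vy)
  if (anyNA(target) || anyNA(hawk) || anyNA(d$hawk_speed))
    abort("input-coverage error: dense tracks contain missing values")
  sim <- pursuit_sim_cpp(target, hawk, d$hawk_speed, i0, dt,
                         law_code(params$law), params$N, params$K, dlag)
  tibble::tibble(
    time_s = d$time_s[(i0 + 1):nrow(d)],
    x = sim$x, y = sim$y, vx = sim$vx, vy = sim$vy,
    delta = sim$delta, los_rate = sim$los_rate, turn_rate = sim$turn_rate
  )
}
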