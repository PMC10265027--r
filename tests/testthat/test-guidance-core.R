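test_that("deviation angle has the documented magnitude and sign convention", {
  expect_equal(deviation_angle(c(1, 0), c(2, 0)), 0)
  expect_equal(deviation_angle(c(1, 0), c(0, 3)), pi / 2)
  expect_equal(deviation_angle(c(0, 1), c(1, 1)), -pi / 4)
  # magnitude equals arccos of the normalised dot product on random states
  withr::with_seed(42, {
    for (i in 1:200) {
      s <- random_state()
      d <- deviation_angle(s$r, s$v_P)
      expect_lte(abs(d), pi)
      cosd <- sum(s$r * s$v_P) / sqrt(sum(s$r^2) * sum(s$v_P^2))
      expect_equal(abs(d), acos(pmin(pmax(cosd, -1), 1)), tolerance = 1e-7)
    }
  })
  expect_error(deviation_angle(c(0, 0), c(1, 0)), "degenerate")
})

test_that("line-of-sight rates match their closed forms", {
  expect_equal(los_rate_inertial(c(1, 0), c(0, 1), c(0, 0)), 1.0)
  expect_equal(los_rate_inertial(c(3, -2), c(4, 5), c(4, 5)), 0)
  expect_equal(los_rate_inertial(c(2, 0), c(0, 0), c(0, 1)), -0.5)
  expect_equal(los_rate_background(c(1, 0), c(0, 2)), 2.0)
  expect_equal(los_rate_background(c(-3, 7), c(0, 0)), 0)
  expect_error(los_rate_background(c(0, 0), c(1, 1)), "degenerate")
})

test_that("inertial and background rates differ by the self-motion term", {
  # identity over 1e4 random states, to machine precision
  withr::with_seed(7, {
    for (i in 1:10000) {
      s <- random_state()
      lhs <- los_rate_inertial(s$r, s$v_T, s$v_P) -
        los_rate_background(s$r, s$v_T)
      rhs <- -(s$r[1] * s$v_P[2] - s$r[2] * s$v_P[1]) / sum(s$r^2)
      expect_true(abs(lhs - rhs) <= 1e-12 * max(1, abs(rhs)))
    }
  })
})

test_that("commanded acceleration is the turn rate times the rotated velocity", {
  a <- commanded_acceleration(guidance_params("inertial_pn", N = 1),
                              los_rate = 0.5, delta = 0.3, v_P = c(10, 0))
  expect_equal(a, c(0, 5))  # K ignored for PN
  a <- commanded_acceleration(guidance_params("pp", K = 5),
                              los_rate = 2, delta = 0, v_P = c(3, 4))
  expect_equal(a, c(0, 0))  # N ignored for PP, delta = 0
  a <- commanded_acceleration(guidance_params("inertial_pnp", N = 0.8, K = 2.4),
                              los_rate = 1.0, delta = 0.1, v_P = c(8, 0))
  expect_equal(a, c(0, 4.48), tolerance = 1e-12)
  # perpendicularity to v_P for all laws on random states
  withr::with_seed(11, {
    for (i in 1:200) {
      s <- random_state()
      law <- sample(guidance_laws, 1)
      p <- guidance_params(law, N = runif(1, -2, 2), K = runif(1, -5, 5))
      a <- commanded_acceleration(p, runif(1, -3, 3), runif(1, -1, 1), s$v_P)
      expect_lt(abs(sum(a * s$v_P)), 1e-10 * max(1, sum(a^2)))
    }
  })
})

test_that("simulated speed matches the measured speed profile exactly", {
  fl <- fx_flight_pn()
  sim <- simulate_pursuit(fl, guidance_params("inertial_pn", N = 1,
                                              tau = 0.055))
  sp <- sqrt(sim$vx^2 + sim$vy^2)
  i0 <- as.integer(round(fl$tau_max / fl$dt))
  meas <- fl$dense$hawk_speed[(i0 + 1):nrow(fl$dense)]
  # normalisation uses the measured speed at the step being advanced from
  expect_true(all(abs(sp[-1] - meas[-length(meas)]) <=
                    1e-12 * meas[-length(meas)]))
  # on the constant-speed cruise the two indexings coincide
  cruise <- which(meas == max(meas))
  cruise <- cruise[cruise > min(cruise)]
  expect_true(all(abs(sp[cruise] - meas[cruise]) <= 1e-12 * meas[cruise]))
})

test_that("simulation aimed at a stationary target conserves zero deviation", {
  # inertial-PN, N = 1, tau = 0, initial velocity on the line-of-sight:
  # the trajectory is a straight line and delta stays 0
  dt <- test_dt
  M <- as.integer(1.5 / dt)
  times <- (0:M) * dt
  tpos <- c(12, 3); p0 <- c(0.5, 3)
  u <- (tpos - p0) / sqrt(sum((tpos - p0)^2))
  dense <- tibble::tibble(
    time_s = times, lure_x = tpos[1], lure_y = tpos[2],
    lure_vx = 0, lure_vy = 0,
    hawk_x = p0[1] + 6 * u[1] * times, hawk_y = p0[2] + 6 * u[2] * times,
    hawk_vx = 6 * u[1], hawk_vy = 6 * u[2], hawk_speed = 6)
  fidx <- seq(1, M + 1, by = as.integer(round(1 / (200 * dt))))
  frames <- tibble::tibble(time_s = times[fidx],
                           hawk_x = dense$hawk_x[fidx],
                           hawk_y = dense$hawk_y[fidx],
                           lure_x = tpos[1], lure_y = tpos[2])
  fl <- as_flight("aimed", frames, dense, dt, intercept_time = 1.5)
  sim <- simulate_pursuit(fl, guidance_params("inertial_pn", N = 1, tau = 0))
  expect_lt(max(abs(sim$delta)), 1e-9)
})

test_that("PNP with a zero gain reduces bit-identically to PN and PP", {
  fl <- fx_flight_pnp()
  pn <- simulate_pursuit(fl, guidance_params("inertial_pn", N = 0.9,
                                             tau = 0.05))
  pnp0 <- simulate_pursuit(fl, guidance_params("inertial_pnp", N = 0.9, K = 0,
                                               tau = 0.05))
  expect_identical(pn$x, pnp0$x)
  expect_identical(pn$y, pnp0$y)
  expect_identical(pn$vx, pnp0$vx)
  pp <- simulate_pursuit(fl, guidance_params("pp", K = 3, tau = 0.05))
  pnp_pp <- simulate_pursuit(fl, guidance_params("inertial_pnp", N = 0,
                                                 K = 3, tau = 0.05))
  expect_identical(pp$x, pnp_pp$x)
  expect_identical(pp$y, pnp_pp$y)
  bg <- simulate_pursuit(fl, guidance_params("background_pn", N = 0.7,
                                             tau = 0.05))
  bgp0 <- simulate_pursuit(fl, guidance_params("background_pnp", N = 0.7,
                                               K = 0, tau = 0.05))
  expect_identical(bg$x, bgp0$x)
})

test_that("halving the integration step changes the endpoint at first order", {
  dts <- test_dt / c(1, 2, 4)
  finals <- lapply(dts, function(dt) {
    M <- as.integer(round(2 / dt))
    target <- weave_target(M, dt)
    p0 <- c(0.5, 3)
    aim <- (target[1, 1:2] - p0) / sqrt(sum((target[1, 1:2] - p0)^2))
    hawk <- matrix(c(p0, 6 * aim), M + 1, 4, byrow = TRUE)
    sim <- hawkpursuit:::pursuit_sim_cpp(target, hawk, rep(6, M + 1), 0L, dt,
                                         4L, 0.8, 2.4, 0L)
    c(sim$x[M + 1], sim$y[M + 1])
  })
  d1 <- sqrt(sum((finals[[1]] - finals[[2]])^2))
  d2 <- sqrt(sum((finals[[2]] - finals[[3]])^2))
  expect_gt(d1 / d2, 1.5)  # O(dt): halving dt roughly halves the change
  expect_lt(d1 / d2, 3)
})

test_that("degenerate and ill-covered inputs raise errors", {
  fl <- fx_flight_pn()
  fl$dense$hawk_speed[10] <- NA
  expect_error(simulate_pursuit(fl, guidance_params("pp", K = 1)),
               "coverage")
  expect_error(guidance_params("pp", K = 1, tau = -0.01), "non-negative")
})
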