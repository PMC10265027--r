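#' Synthetic pursuit specification
#'
#' Defines the study conditions the generator emulates: an indoor arena with
#' a 20.2 x 6.1 m floor, a lure towed along an unpredictable zigzag course at
#' a constant speed drawn from 6-8 m/s, a hawk released from one of three
#' start positions at one end of the arena and steered by a chosen guidance
#' law, 200 Hz sampling of both tracks, and additive isotropic Gaussian
#' measurement noise on the observed frames.
#'
#' @param law,N,K,tau Guidance law and parameters steering the synthetic hawk
#'   (see [guidance_params()]).
#' @param arena Floor dimensions (m), default `c(20.2, 6.1)`.
#' @param lure_speed_range Lure speed is drawn uniformly from this range
#'   (m/s), default `c(6, 8)`.
#' @param n_turns Minimum number of course turns laid out; the course is
#'   extended with further turns until it outlasts `t_cap`.
#' @param corner_radius Radius of the circular arcs rounding the course
#'   corners (m), default 0.2, so lure velocity is defined everywhere.
#' @param hawk_start Start position index 1-3 (left, middle, right perch at
#'   the near end of the arena).
#' @param hawk_cruise Hawk cruise speed (m/s), default 8.
#' @param hawk_v0,hawk_accel Initial speed (m/s) and acceleration (m/s^2) of
#'   the trapezoidal speed ramp, defaults 3 and 6.
#' @param noise_sigma Standard deviation of the per-axis Gaussian measurement
#'   noise on 200 Hz frames (m), default 0.001 (1 mm, typical of indoor
#'   motion capture).
#' @param occlusion_rate Per-marker, per-frame dropout probability in
#'   generated marker clouds, default 0.05.
#' @param spike_rate Expected number of spurious marker points per frame,
#'   default 0.02.
#' @param dt Integration step of the generated truth trajectory (s).
#' @param t_cap Time cap (s): generation fails if no intercept occurs by
#'   then.
#' @param intercept_radius Intercept criterion (m), default 0.03.
#' @param chase_end How a generated flight ends: `"intercept"` (default, at
#'   the first frame within `intercept_radius`) or `"duration"` (a fixed-time
#'   chase of `duration` seconds, for guidance laws — background-PN above
#'   all — that cannot reliably close an intercept).
#' @param duration Fixed chase length (s) when `chase_end = "duration"`.
#' @param seed Integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(law = "inertial_pn", N = 1.0, K = 0, tau = 0.055,
                           arena = c(20.2, 6.1), lure_speed_range = c(6, 8),
                           n_turns = 4, corner_radius = 0.2,
                           hawk_start = 2, hawk_cruise = 8,
                           hawk_v0 = 3, hawk_accel = 6,
                           noise_sigma = 0.001, occlusion_rate = 0.05,
                           spike_rate = 0.02, dt = 5e-5, t_cap = 8,
                           intercept_radius = 0.03,
                           chase_end = c("intercept", "duration"),
                           duration = 2.5, seed = 1L) {
  law <- match.arg(law, guidance_laws)
  chase_end <- match.arg(chase_end)
  stopifnot(length(arena) == 2, all(arena > 2),
            lure_speed_range[1] <= lure_speed_range[2],
            hawk_start %in% 1:3, dt > 0, t_cap > 0)
  structure(
    list(law = law, N = N, K = K, tau = tau, arena = arena,
         lure_speed_range = lure_speed_range, n_turns = n_turns,
         corner_radius = corner_radius, hawk_start = hawk_start,
         hawk_cruise = hawk_cruise, hawk_v0 = hawk_v0,
         hawk_accel = hawk_accel, noise_sigma = noise_sigma,
         occlusion_rate = occlusion_rate, spike_rate = spike_rate,
         dt = dt, t_cap = t_cap, intercept_radius = intercept_radius,
         chase_end = chase_end, duration = duration,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Generate a zigzag lure course
#'
#' Lays out a piecewise-linear waypoint path inside the arena (corners
#' rounded by circular arcs, emulating a tow line guided around pulleys) and
#' traverses it at a constant speed drawn uniformly from the spec's range.
#' The lure sits at the course start until motion onset at `t = 0`. The
#' course is extended with additional zigzag legs until its length outlasts
#' the spec's time cap, bouncing back inside the arena if need be.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `lure_course`: segment table, speed, and start
#'   metadata. Evaluate it at times with [lure_track()].
#' @export
generate_lure_course <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    m <- 0.6                              # wall margin, keeps arcs inside
    L <- spec$arena[1]; W <- spec$arena[2]
    speed <- runif(1, spec$lure_speed_range[1], spec$lure_speed_range[2])
    # corner rounding trims the polyline, so budget generous slack
    need_len <- speed * spec$t_cap + 10
    x <- runif(1, 3.5, 5.5)
    lo_band <- c(m, 0.38 * W); hi_band <- c(0.62 * W, W - m)
    low <- runif(1) < 0.5
    y <- if (low) runif(1, lo_band[1], lo_band[2]) else
      runif(1, hi_band[1], hi_band[2])
    wp <- matrix(c(x, y), ncol = 2)
    dir <- 1
    total <- 0
    while (total < need_len || nrow(wp) < spec$n_turns + 2) {
      low <- !low
      step <- runif(1, 2.5, 4)
      x_new <- x + dir * step
      if (x_new > L - m || x_new < m) { dir <- -dir; x_new <- x + dir * step }
      x_new <- min(max(x_new, m), L - m)
      y_new <- if (low) runif(1, lo_band[1], lo_band[2]) else
        runif(1, hi_band[1], hi_band[2])
      total <- total + sqrt((x_new - x)^2 + (y_new - y)^2)
      wp <- rbind(wp, c(x_new, y_new))
      x <- x_new; y <- y_new
    }
    segs <- round_corners(wp, spec$corner_radius)
    structure(list(segments = segs, speed = speed, waypoints = wp,
                   seed = spec$seed),
              class = "lure_course")
  })
}

# Replace each interior waypoint with a tangent circular arc of radius <= rc.
# Returns a tibble of segments: type ("line"/"arc"), geometry columns and
# cumulative arclength.
round_corners <- function(wp, rc) {
  n <- nrow(wp)
  segs <- list()
  cur <- wp[1, ]                     # current pen position
  for (i in seq_len(n - 2) + 1) {
    A <- wp[i - 1, ]; B <- wp[i, ]; C <- wp[i + 1, ]
    u1 <- (B - A) / sqrt(sum((B - A)^2))
    u2 <- (C - B) / sqrt(sum((C - B)^2))
    cosang <- sum(u1 * u2)
    cosang <- min(max(cosang, -1), 1)
    phi <- acos(cosang)                       # exterior turn angle
    if (phi < 1e-8) next
    psi <- pi - phi                           # interior angle at B
    len1 <- sqrt(sum((B - cur)^2)); len2 <- sqrt(sum((C - B)^2))
    r <- rc
    tcut <- r / tan(psi / 2)
    lim <- 0.4 * min(len1, len2)
    if (tcut > lim) { tcut <- lim; r <- tcut * tan(psi / 2) }
    P1 <- B - u1 * tcut                       # arc start
    P2 <- B + u2 * tcut                       # arc end
    segs[[length(segs) + 1]] <- list(type = "line", p0 = cur, p1 = P1)
    s <- sign(u1[1] * u2[2] - u1[2] * u2[1])  # +1 = left turn
    nrm <- s * c(-u1[2], u1[1])               # toward arc centre
    ctr <- P1 + r * nrm
    a0 <- atan2(P1[2] - ctr[2], P1[1] - ctr[1])
    segs[[length(segs) + 1]] <- list(type = "arc", ctr = ctr, r = r,
                                     a0 = a0, da = s * phi)
    cur <- P2
  }
  segs[[length(segs) + 1]] <- list(type = "line", p0 = cur, p1 = wp[n, ])
  lens <- vapply(segs, function(sg)
    if (sg$type == "line") sqrt(sum((sg$p1 - sg$p0)^2)) else sg$r * abs(sg$da),
    numeric(1))
  keep <- lens > 1e-12
  list(segs = segs[keep], lens = lens[keep], cum = cumsum(lens[keep]))
}

#' Evaluate a lure course at given times
#'
#' @param course A [generate_lure_course()] result.
#' @param times Numeric vector of times (s); the lure is stationary at the
#'   course start for `t < 0` and holds its final position past the course
#'   end.
#' @return A tibble `time_s`, `x`, `y`, `vx`, `vy`.
#' @export
lure_track <- function(course, times) {
  stopifnot(inherits(course, "lure_course"))
  s <- pmax(course$speed * times, 0)
  g <- course$segments
  total <- g$cum[length(g$cum)]
  moving <- s < total
  s <- pmin(s, total - 1e-12)
  seg_i <- findInterval(s, c(0, g$cum), rightmost.closed = TRUE,
                        left.open = TRUE)
  seg_i <- pmin(pmax(seg_i, 1L), length(g$segs))
  s_in <- s - c(0, g$cum)[seg_i]
  n <- length(times)
  x <- y <- vx <- vy <- numeric(n)
  for (k in seq_len(n)) {
    sg <- g$segs[[seg_i[k]]]
    if (sg$type == "line") {
      u <- (sg$p1 - sg$p0) / sqrt(sum((sg$p1 - sg$p0)^2))
      p <- sg$p0 + u * s_in[k]
      tang <- u
    } else {
      a <- sg$a0 + sign(sg$da) * s_in[k] / sg$r
      p <- sg$ctr + sg$r * c(cos(a), sin(a))
      tang <- sign(sg$da) * c(-sin(a), cos(a))
    }
    x[k] <- p[1]; y[k] <- p[2]
    sp <- if (times[k] > 0 && moving[k]) course$speed else 0
    vx[k] <- sp * tang[1]; vy[k] <- sp * tang[2]
  }
  tibble::tibble(time_s = times, x = x, y = y, vx = vx, vy = vy)
}

hawk_start_position <- function(spec) {
  W <- spec$arena[2]
  y <- c(0.17 * W, 0.5 * W, 0.83 * W)[spec$hawk_start]
  c(0.5, y)
}

#' Generate a guided hawk flight against a lure course
#'
#' Simulates the hawk under the spec's guidance law from its start position,
#' with a trapezoidal speed ramp to cruise speed, until it first comes within
#' the intercept radius of the lure. The truth trajectory is retained in the
#' flight's dense tracks; the observed 200 Hz frames are the truth sampled at
#' the frame times plus isotropic Gaussian noise of sd `noise_sigma`.
#'
#' @param course A [generate_lure_course()] result (defaults to generating
#'   one from `spec`).
#' @param spec A [synthetic_spec()].
#' @param id Flight identifier.
#' @return A `hawk_flight` object ([as_flight()]); `meta` records the
#'   generating law, parameters and seed.
#' @export
generate_hawk_flight <- function(spec, course = NULL, id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(course)) course <- generate_lure_course(spec)
  dt <- spec$dt
  M <- as.integer(ceiling(spec$t_cap / dt))
  times <- (0:M) * dt
  lure <- lure_track(course, times)
  target <- cbind(lure$x, lure$y, lure$vx, lure$vy)

  p0 <- hawk_start_position(spec)
  aim <- c(lure$x[1], lure$y[1]) - p0
  aim <- aim / sqrt(sum(aim^2))
  v0 <- spec$hawk_v0 * aim
  speed <- pmin(spec$hawk_v0 + spec$hawk_accel * times, spec$hawk_cruise)
  hawk0 <- matrix(c(p0[1], p0[2], v0[1], v0[2]), nrow = M + 1, ncol = 4,
                  byrow = TRUE)
  dlag <- as.integer(round(spec$tau / dt))
  sim <- pursuit_sim_cpp(target, hawk0, speed, 0L, dt, law_code(spec$law),
                         spec$N, spec$K, dlag)

  dist <- sqrt((sim$x - lure$x)^2 + (sim$y - lure$y)^2)
  fper <- round(1 / (200 * dt))
  if (abs(fper - 1 / (200 * dt)) > 1e-9)
    abort("dt must divide the 200 Hz frame interval")
  frame_idx <- seq(1L, M + 1L, by = as.integer(fper))
  if (identical(spec$chase_end, "duration")) {
    ifr <- max(which(times[frame_idx] <= spec$duration + 1e-9))
  } else {
    hit <- which(dist[frame_idx] <= spec$intercept_radius)
    hit <- hit[frame_idx[hit] > 1]
    if (length(hit) == 0)
      abort(sprintf("no intercept within the %g s time cap", spec$t_cap))
    ifr <- hit[1]
  }
  intercept_time <- times[frame_idx[ifr]]
  keep <- seq_len(frame_idx[ifr])

  dense <- tibble::tibble(
    time_s = times[keep],
    lure_x = lure$x[keep], lure_y = lure$y[keep],
    lure_vx = lure$vx[keep], lure_vy = lure$vy[keep],
    hawk_x = sim$x[keep], hawk_y = sim$y[keep],
    hawk_vx = sim$vx[keep], hawk_vy = sim$vy[keep],
    hawk_speed = speed[keep])

  fidx <- frame_idx[seq_len(ifr)]
  nfr <- length(fidx)
  frames <- withr::with_seed(spec$seed + 1L, tibble::tibble(
    time_s = times[fidx],
    hawk_x = sim$x[fidx] + rnorm(nfr, 0, spec$noise_sigma),
    hawk_y = sim$y[fidx] + rnorm(nfr, 0, spec$noise_sigma),
    lure_x = lure$x[fidx] + rnorm(nfr, 0, spec$noise_sigma),
    lure_y = lure$y[fidx] + rnorm(nfr, 0, spec$noise_sigma)))

  as_flight(id = id, frames = frames, dense = dense, dt = dt,
            intercept_time = intercept_time,
            meta = list(law = spec$law, N = spec$N, K = spec$K,
                        tau = spec$tau, seed = spec$seed,
                        lure_speed = course$speed,
                        truth_frames = tibble::tibble(
                          time_s = times[fidx],
                          hawk_x = sim$x[fidx], hawk_y = sim$y[fidx],
                          lure_x = lure$x[fidx], lure_y = lure$y[fidx])))
}

#' Generate a cohort of synthetic flights
#'
#' Each flight gets its own lure course and measurement-noise stream, derived
#' deterministically from `seed`. Courses on which the hawk fails to
#' intercept within the time cap are discarded and replaced (deterministic
#' retry sequence) — only successful intercepts enter the analysis, matching
#' the study's inclusion criterion.
#'
#' @param n Number of flights.
#' @param spec Base [synthetic_spec()]; per-flight seeds and hawk start
#'   positions are varied deterministically.
#' @param seed Cohort seed.
#' @param max_attempts Attempts allowed per flight before giving up.
#' @return A list of `hawk_flight` objects.
#' @export
generate_cohort <- function(n, spec, seed = spec$seed, max_attempts = 20L) {
  purrr::map(seq_len(n), function(i) {
    for (a in seq_len(max_attempts)) {
      sp <- spec
      sp$seed <- as.integer(seed + 101L * i + 7919L * (a - 1L))
      sp$hawk_start <- 1L + ((i + a) %% 3L)
      fl <- tryCatch(generate_hawk_flight(sp, id = sprintf("synth%03d", i)),
                     error = function(e) NULL)
      if (!is.null(fl)) return(fl)
    }
    abort(sprintf("no intercepting course found for flight %d after %d attempts",
                  i, max_attempts))
  })
}

#' Default marker templates
#'
#' Rigid templates emulating the mocap hardware: a backpack plate with four
#' asymmetrically arranged markers and a tail mount with three symmetrically
#' arranged markers. Offsets are in the body frame (x forward, m), mean-zero
#' so the full-template centroid coincides with the carried position.
#'
#' @return A list of two `marker_template` objects (`backpack`, `tailmount`),
#'   each with `name`, `offsets` (n x 3 matrix) and `dist` (sorted pairwise
#'   distances, m).
#' @export
default_templates <- function() {
  bp <- rbind(c(0.050, 0.000, 0.000),
              c(-0.045, 0.030, 0.012),
              c(-0.025, -0.040, 0.022),
              c(0.020, 0.010, -0.034))
  tm <- rbind(c(0.040, 0.000, 0.000),
              c(-0.020, 0.026, 0.000),
              c(-0.020, -0.026, 0.000))
  make_template <- function(name, off) {
    structure(list(name = name, offsets = off,
                   dist = sort(as.numeric(stats::dist(off)))),
              class = "marker_template")
  }
  list(backpack = make_template("backpack", bp),
       tailmount = make_template("tailmount", tm))
}

#' Generate a raw marker cloud for a flight
#'
#' Places rigid marker sets along the truth trajectories (orientation from
#' the velocity heading), emits three lure markers per long face, adds
#' stationary pulley markers, then applies per-marker Bernoulli dropout and
#' injects spurious spike points. Ground-truth labels are retained in the
#' `label_true` column for test assertions.
#'
#' @param flight A `hawk_flight` from [generate_hawk_flight()].
#' @param spec The [synthetic_spec()] used to generate it.
#' @param templates Templates from [default_templates()].
#' @param hawk_z Hawk flight altitude (m), default 0.9.
#' @return A tibble `frame`, `time_s`, `x`, `y`, `z`, `label_true` — one row
#'   per detected marker point, unlabelled as far as the pipeline is
#'   concerned.
#' @export
generate_marker_cloud <- function(flight, spec, templates = default_templates(),
                                  hawk_z = 0.9) {
  stopifnot(inherits(flight, "hawk_flight"))
  tf <- flight$meta$truth_frames
  if (is.null(tf)) abort("flight carries no truth frames (not synthetic?)")
  d <- flight$dense
  fidx <- match(round(tf$time_s / flight$dt), round(d$time_s / flight$dt))
  hawk_head <- atan2(d$hawk_vy[fidx], d$hawk_vx[fidx])
  lv <- cbind(d$lure_vx[fidx], d$lure_vy[fidx])
  lure_head <- atan2(lv[, 2], lv[, 1])
  lure_head[rowSums(lv^2) == 0] <- 0

  place <- function(cx, cy, cz, head, off, label) {
    n <- length(cx); m <- nrow(off)
    co <- cos(head); si <- sin(head)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      R <- matrix(c(co[i], si[i], -si[i], co[i]), 2)
      xy <- off[, 1:2, drop = FALSE] %*% t(R)
      out[[i]] <- cbind(frame = i, x = cx[i] + xy[, 1], y = cy[i] + xy[, 2],
                        z = cz + off[, 3])
    }
    res <- do.call(rbind, out)
    tibble::tibble(frame = as.integer(res[, "frame"]), x = res[, "x"],
                   y = res[, "y"], z = res[, "z"], label_true = label)
  }

  lure_off <- as.matrix(expand.grid(ax = c(-0.05, 0, 0.05),
                                    side = c(-0.02, 0.02)))
  lure_off <- cbind(lure_off[, 1], lure_off[, 2], 0)

  pts <- dplyr::bind_rows(
    place(tf$hawk_x, tf$hawk_y, hawk_z, hawk_head,
          templates$backpack$offsets, "backpack"),
    place(tf$hawk_x, tf$hawk_y, hawk_z + 0.12, hawk_head,
          templates$tailmount$offsets, "tailmount"),
    place(tf$lure_x, tf$lure_y, 0.05, lure_head, lure_off, "lure"))

  nfr <- nrow(tf)
  pulleys <- cbind(
    x = c(1, 1, spec$arena[1] / 2, spec$arena[1] / 2,
          spec$arena[1] - 1, spec$arena[1] - 1),
    y = c(0.3, spec$arena[2] - 0.3, 0.3, spec$arena[2] - 0.3, 0.3,
          spec$arena[2] - 0.3),
    z = 0.25)
  stat <- tibble::tibble(
    frame = rep(seq_len(nfr), each = nrow(pulleys)),
    x = rep(pulleys[, "x"], nfr), y = rep(pulleys[, "y"], nfr),
    z = rep(pulleys[, "z"], nfr), label_true = "stationary")
  pts <- dplyr::bind_rows(pts, stat)

  withr::with_seed(spec$seed + 2L, {
    keep <- runif(nrow(pts)) >= spec$occlusion_rate
    pts <- pts[keep, , drop = FALSE]
    nsp <- stats::rpois(1, spec$spike_rate * nfr)
    if (nsp > 0) {
      spikes <- tibble::tibble(
        frame = sample.int(nfr, nsp, replace = TRUE),
        x = runif(nsp, 0, spec$arena[1]), y = runif(nsp, 0, spec$arena[2]),
        z = runif(nsp, 0, 1.5), label_true = "spike")
      pts <- dplyr::bind_rows(pts, spikes)
    }
  })
  pts$time_s <- tf$time_s[pts$frame]
  dplyr::arrange(pts[, c("frame", "time_s", "x", "y", "z", "label_true")],
                 .data$frame)
}
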