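#' Label raw marker-cloud points
#'
#' Reproduces the marker-labelling stage: points are tracked frame-to-frame
#' by nearest-neighbour gating; tracks that stay within the same 10 mm
#' per-axis range for at least 60% of their visible frames are labelled
#' stationary (pulleys, tunnel); of the remainder, points within 150 mm of
#' the floor plane are lure markers and the rest are bird markers. Within
#' each frame, bird-marker subsets whose pairwise distances match a rigid
#' template within 5 mm receive that template's label; ambiguous multiple
#' matches leave the frame unassigned for that template (conservative).
#'
#' @param cloud Tibble `frame`, `time_s`, `x`, `y`, `z` (m) — one row per
#'   detected point, unlabelled.
#' @param templates Marker templates, see [default_templates()].
#' @param floor_z Height of the floor plane (m), default 0.
#' @param lure_height Lure threshold above the floor plane (m), default 0.15.
#' @param stationary_range Half-range for the stationary box (m), default
#'   0.005 (a 10 mm range per axis).
#' @param stationary_frac Minimum fraction of visible frames in the box,
#'   default 0.6.
#' @param stationary_frac_of Denominator convention: `"visible"` (frames
#'   where the track is detected, the default) or `"all"` frames.
#' @param min_track_frames Tracks seen in fewer frames than this are never
#'   classed stationary (guards against single spurious detections).
#' @param template_tol Pairwise-distance tolerance for template matching (m),
#'   default 0.005.
#' @param gate Nearest-neighbour tracking gate (m), default 0.06.
#' @return The cloud with columns `track` and `label` added; `label` is one
#'   of `stationary`, `lure`, `backpack`, `tailmount`, `bird_other`,
#'   `unassigned`.
#' @export
label_markers <- function(cloud, templates = default_templates(),
                          floor_z = 0, lure_height = 0.15,
                          stationary_range = 0.005, stationary_frac = 0.6,
                          stationary_frac_of = c("visible", "all"),
                          min_track_frames = 10, template_tol = 0.005,
                          gate = 0.06) {
  if (nrow(cloud) == 0) abort("empty marker cloud")
  stationary_frac_of <- match.arg(stationary_frac_of)
  cloud <- dplyr::arrange(tibble::as_tibble(cloud), .data$frame)
  n_frames <- length(unique(cloud$frame))

  cloud$track <- track_points(cloud, gate)

  # stationary classification per track
  stat_tracks <- integer(0)
  for (tr in unique(cloud$track)) {
    sel <- cloud$track == tr
    nf <- sum(sel)
    if (nf < min_track_frames) next
    mx <- median(cloud$x[sel]); my <- median(cloud$y[sel])
    mz <- median(cloud$z[sel])
    inbox <- abs(cloud$x[sel] - mx) <= stationary_range &
      abs(cloud$y[sel] - my) <= stationary_range &
      abs(cloud$z[sel] - mz) <= stationary_range
    denom <- if (stationary_frac_of == "visible") nf else n_frames
    if (sum(inbox) / denom >= stationary_frac)
      stat_tracks <- c(stat_tracks, tr)
  }

  lab <- rep("unassigned", nrow(cloud))
  lab[cloud$track %in% stat_tracks] <- "stationary"
  free <- lab != "stationary"
  is_lure <- free & (cloud$z - floor_z) <= lure_height
  lab[is_lure] <- "lure"
  is_bird <- free & !is_lure
  lab[is_bird] <- "bird_other"

  # template matching within each frame
  for (fr in unique(cloud$frame)) {
    idx <- which(cloud$frame == fr & lab == "bird_other")
    if (length(idx) < 3) next
    pts <- as.matrix(cloud[idx, c("x", "y", "z")])
    bp <- match_template(pts, templates$backpack, template_tol)
    if (bp$status == "match") lab[idx[bp$subset]] <- "backpack"
    remaining <- which(lab[idx] == "bird_other")
    if (length(remaining) >= 3) {
      tm <- match_template(pts[remaining, , drop = FALSE],
                           templates$tailmount, template_tol)
      if (tm$status == "match")
        lab[idx[remaining[tm$subset]]] <- "tailmount"
    }
  }
  cloud$label <- lab
  cloud
}

# Greedy frame-to-frame nearest-neighbour tracking. Returns a track id per
# point; unmatched points start new tracks.
track_points <- function(cloud, gate) {
  frames <- unique(cloud$frame)
  track <- integer(nrow(cloud))
  next_id <- 1L
  prev_idx <- integer(0)
  for (fr in frames) {
    cur_idx <- which(cloud$frame == fr)
    if (length(prev_idx) > 0) {
      dmat <- outer(cloud$x[cur_idx], cloud$x[prev_idx], "-")^2 +
        outer(cloud$y[cur_idx], cloud$y[prev_idx], "-")^2 +
        outer(cloud$z[cur_idx], cloud$z[prev_idx], "-")^2
      dmat <- sqrt(dmat)
      taken_prev <- rep(FALSE, length(prev_idx))
      ord <- order(dmat)
      assigned <- rep(FALSE, length(cur_idx))
      for (o in ord) {
        if (dmat[o] > gate) break
        i <- (o - 1L) %% length(cur_idx) + 1L
        j <- (o - 1L) %/% length(cur_idx) + 1L
        if (assigned[i] || taken_prev[j]) next
        track[cur_idx[i]] <- track[prev_idx[j]]
        assigned[i] <- TRUE; taken_prev[j] <- TRUE
      }
      for (i in which(!assigned)) {
        track[cur_idx[i]] <- next_id; next_id <- next_id + 1L
      }
    } else {
      for (i in seq_along(cur_idx)) {
        track[cur_idx[i]] <- next_id; next_id <- next_id + 1L
      }
    }
    prev_idx <- cur_idx
  }
  track
}

# Find a subset of points whose sorted pairwise distances match the
# template's within tol; tries full template size first, then one fewer
# (partial occlusion). Returns list(status = "match"/"none"/"ambiguous",
# subset = indices).
match_template <- function(pts, template, tol) {
  full <- nrow(template$offsets)
  for (size in c(full, full - 1L)) {
    if (size < 3 || nrow(pts) < size) next
    tdists <- if (size == full) list(template$dist) else {
      purrr::map(seq_len(full), function(drop_i)
        sort(as.numeric(stats::dist(template$offsets[-drop_i, , drop = FALSE]))))
    }
    combs <- utils::combn(nrow(pts), size)
    hits <- list()
    for (ci in seq_len(ncol(combs))) {
      sub <- combs[, ci]
      dd <- sort(as.numeric(stats::dist(pts[sub, , drop = FALSE])))
      ok <- any(vapply(tdists, function(td)
        length(td) == length(dd) && all(abs(dd - td) <= tol), logical(1)))
      if (ok) hits[[length(hits) + 1]] <- sub
    }
    if (length(hits) == 1) return(list(status = "match", subset = hits[[1]]))
    if (length(hits) > 1) return(list(status = "ambiguous", subset = NULL))
  }
  list(status = "none", subset = NULL)
}

#' Per-frame centroids of labelled markers
#'
#' The bird position is the centroid of the identified backpack and
#' tail-mount markers combined (configurable to backpack only); the lure
#' position is the centroid of the lure markers. A centroid is missing in
#' frames where fewer than `min_markers` markers were identified for a
#' template (or the lure).
#'
#' @param labelled Output of [label_markers()].
#' @param min_markers Minimum identified markers per template / lure,
#'   default 3.
#' @param combine If `TRUE` (default) the bird centroid combines backpack and
#'   tail-mount markers; otherwise backpack only.
#' @return A tibble `frame`, `time_s`, `bird_x`, `bird_y`, `lure_x`,
#'   `lure_y` (m, `NA` = missing), with attribute `reconstruction_fraction`:
#'   the fraction of frames in which the back template was reconstructed.
#' @export
labelled_centroids <- function(labelled, min_markers = 3, combine = TRUE) {
  frames <- sort(unique(labelled$frame))
  times <- labelled$time_s[match(frames, labelled$frame)]
  cent <- function(sel) {
    if (sum(sel) == 0) c(NA_real_, NA_real_) else
      c(mean(labelled$x[sel]), mean(labelled$y[sel]))
  }
  out <- purrr::map_dfr(frames, function(fr) {
    in_fr <- labelled$frame == fr
    nbp <- sum(in_fr & labelled$label == "backpack")
    ntm <- sum(in_fr & labelled$label == "tailmount")
    nlu <- sum(in_fr & labelled$label == "lure")
    bird_ok <- nbp >= min_markers && (!combine || ntm >= min_markers)
    bird_sel <- in_fr & labelled$label %in%
      (if (combine) c("backpack", "tailmount") else "backpack")
    b <- if (bird_ok) cent(bird_sel) else c(NA_real_, NA_real_)
    l <- if (nlu >= min_markers) cent(in_fr & labelled$label == "lure") else
      c(NA_real_, NA_real_)
    tibble::tibble(frame = fr, bird_x = b[1], bird_y = b[2],
                   lure_x = l[1], lure_y = l[2], backpack_n = nbp)
  })
  out$time_s <- times
  out <- out[, c("frame", "time_s", "bird_x", "bird_y", "lure_x", "lure_y",
                 "backpack_n")]
  attr(out, "reconstruction_fraction") <-
    mean(out$backpack_n >= min_markers)
  out
}

#' Two-pass sliding-window outlier elimination
#'
#' Removes misidentified points from a centroid series by comparing each
#' point with the series smoothed by a centered mean sliding window (0.05 s,
#' 11 frames at 200 Hz, mean over non-missing neighbours): a first pass
#' removes extreme outliers beyond 500 mm, a second pass — windows recomputed
#' — removes moderate outliers beyond 75 mm. Removed points become missing.
#'
#' @param track Tibble with columns `x` and `y` (m; `NA` = missing), one row
#'   per 200 Hz frame.
#' @param window Window length (s), default 0.05.
#' @param thresholds Distance thresholds per pass (m), default
#'   `c(0.5, 0.075)`.
#' @param frame_rate Frame rate (Hz), default 200.
#' @return The track with outliers set to `NA`.
#' @export
clean_trajectory <- function(track, window = 0.05, thresholds = c(0.5, 0.075),
                             frame_rate = 200) {
  half <- floor(window * frame_rate / 2)
  x <- track$x; y <- track$y
  for (thr in thresholds) {
    sx <- running_mean(x, half); sy <- running_mean(y, half)
    d <- sqrt((x - sx)^2 + (y - sy)^2)
    out <- !is.na(d) & d > thr
    x[out] <- NA; y[out] <- NA
  }
  track$x <- x; track$y <- y
  track
}

# Centered running mean over +/- half frames, ignoring NA. Near the series
# ends the window shrinks symmetrically (stays centered) so the mean does not
# lag a fast-moving track and flag legitimate end frames as outliers.
running_mean <- function(v, half) {
  n <- length(v)
  ok <- !is.na(v)
  vv <- ifelse(ok, v, 0)
  cs <- c(0, cumsum(vv)); cn <- c(0, cumsum(ok))
  i <- seq_len(n)
  hw <- pmin(half, i - 1L, n - i)
  lo <- i - hw; hi <- i + hw
  s <- cs[hi + 1] - cs[lo]
  m <- cn[hi + 1] - cn[lo]
  ifelse(m > 0, s / m, NA_real_)
}

#' Smooth a track with a quintic spline and differentiate analytically
#'
#' Fills gaps by cubic interpolation, fits a degree-5 smoothing spline —
#' chosen by bisection on the roughness penalty as the smoothest quintic
#' spline whose root-sum-of-squares residual over the frames does not exceed
#' the tolerance — and evaluates position, velocity and acceleration
#' analytically on a dense output grid.
#'
#' @param track Tibble `time_s`, `x`, `y` (m; `NA` = missing).
#' @param tolerance Residual tolerance (m): root-sum-of-squares of the 2D
#'   residuals at the frames. 0.03 m is used for bird tracks, 0.01 m for
#'   lure tracks.
#' @param out_rate Output evaluation rate (Hz), default 20000.
#' @return A tibble of class `smoothed_track`: `time_s`, `x`, `y`, `vx`,
#'   `vy`, `ax`, `ay` on the uniform output grid, with attributes
#'   `residual` (achieved root-sum-of-squares, m) and `tolerance`.
#' @export
smooth_and_differentiate <- function(track, tolerance, out_rate = 20000) {
  ok <- !is.na(track$x) & !is.na(track$y)
  if (sum(ok) < 6) abort("insufficient data: need at least 6 non-missing frames")
  first <- which(ok)[1]; last <- which(ok)[sum(ok)]
  tr <- track[first:last, , drop = FALSE]
  t <- tr$time_s
  fill <- function(v) {
    miss <- is.na(v)
    if (any(miss))
      v[miss] <- spline(t[!miss], v[!miss], xout = t[miss])$y
    v
  }
  Y <- cbind(fill(tr$x), fill(tr$y))
  fit <- qspline_fit(t, Y, tolerance)
  dt_out <- 1 / out_rate
  tout <- seq(t[1], t[length(t)] + 1e-12, by = dt_out)
  P <- qspline_eval(fit, tout, 0)
  V <- qspline_eval(fit, tout, 1)
  A <- qspline_eval(fit, tout, 2)
  out <- tibble::tibble(time_s = tout, x = P[, 1], y = P[, 2],
                        vx = V[, 1], vy = V[, 2], ax = A[, 1], ay = A[, 2])
  attr(out, "residual") <- fit$residual
  attr(out, "tolerance") <- tolerance
  attr(out, "lambda") <- fit$lambda
  class(out) <- c("smoothed_track", class(out))
  out
}

# Penalised quintic B-spline fit: minimises ||Y - B c||^2 + lambda c' G c
# where G is the Gram matrix of 3rd derivatives (3-point Gauss per knot
# interval, exact for the piecewise-quadratic third derivatives). Bisection
# on log-lambda finds the smoothest fit with residual <= tol.
qspline_fit <- function(t, Y, tol) {
  ord <- 6L
  n <- length(t)
  # de-trend: remove the per-axis least-squares straight line (zero
  # roughness, so it does not interact with the penalty) for conditioning
  X <- cbind(1, t)
  trend <- qr.solve(X, Y)
  Yr <- Y - X %*% trend
  knots <- c(rep(t[1], ord), t[seq(2, n - 1)], rep(t[n], ord))
  B <- splines::splineDesign(knots, t, ord = ord)
  G <- qspline_penalty(knots, ord)
  BtB <- crossprod(B)
  BtY <- crossprod(B, Yr)
  ridge <- 1e-10 * mean(diag(BtB))
  solve_c <- function(lam) {
    A <- BtB + lam * G
    diag(A) <- diag(A) + ridge
    solve(A, BtY)
  }
  rss <- function(C) sqrt(sum((Yr - B %*% C)^2))
  scale <- sum(diag(BtB)) / max(sum(diag(G)), .Machine$double.eps)
  lo <- 1e-14 * scale; hi <- 1e8 * scale
  C_hi <- solve_c(hi)
  if (rss(C_hi) <= tol) {
    lam <- hi; C <- C_hi
  } else {
    C_lo <- solve_c(lo)
    if (rss(C_lo) > tol)
      warn("spline tolerance not attainable; returning least-smoothed fit")
    for (it in 1:60) {
      mid <- sqrt(lo * hi)
      C_mid <- solve_c(mid)
      if (rss(C_mid) <= tol) lo <- mid else hi <- mid
    }
    lam <- lo; C <- solve_c(lo)
  }
  list(knots = knots, ord = ord, coef = C, trend = trend, lambda = lam,
       residual = rss(C))
}

qspline_penalty <- function(knots, ord) {
  u <- unique(knots)
  # 3-point Gauss-Legendre on each interval
  gx <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)); gw <- c(5, 8, 5) / 9
  a <- u[-length(u)]; b <- u[-1]
  mid <- (a + b) / 2; hw <- (b - a) / 2
  nodes <- as.numeric(outer(gx, mid, function(g, m) m) + outer(gx, hw, "*"))
  wts <- as.numeric(outer(gw, hw, "*"))
  Bg <- splines::splineDesign(knots, nodes, ord = ord,
                              derivs = rep(3L, length(nodes)))
  crossprod(Bg * sqrt(wts))
}

qspline_eval <- function(fit, xout, deriv) {
  k <- length(xout)
  lo_k <- fit$knots[1]; hi_k <- fit$knots[length(fit$knots)]
  xout <- pmin(pmax(xout, lo_k), hi_k)
  out <- matrix(0, k, ncol(fit$coef))
  chunk <- 4096L
  for (s in seq(1, k, by = chunk)) {
    e <- min(s + chunk - 1L, k)
    D <- splines::splineDesign(fit$knots, xout[s:e], ord = fit$ord,
                               derivs = rep(as.integer(deriv), e - s + 1L))
    out[s:e, ] <- D %*% fit$coef
  }
  # add back the removed linear trend (position) or its slope (velocity)
  if (deriv == 0) out <- out + cbind(1, xout) %*% fit$trend
  if (deriv == 1)
    out <- out + matrix(fit$trend[2, ], k, ncol(out), byrow = TRUE)
  out
}

#' Quality control and cropping of a flight
#'
#' Rejects flights whose back template was reconstructed in at most half of
#' the recorded frames, crops the sequences to begin at the first frame in
#' which both bird and lure are visible, accepts the flight as a successful
#' intercept only if the bird comes within the intercept radius of the lure,
#' and truncates at the intercept time (the first frame within the radius).
#'
#' @param bird,lure Tibbles `time_s`, `x`, `y` (m; `NA` = missing) on a
#'   common 200 Hz clock.
#' @param reconstruction_fraction Fraction of recorded frames in which the
#'   back template was reconstructed (attribute of [labelled_centroids()]).
#' @param min_fraction Required reconstruction fraction (exclusive), default
#'   0.5.
#' @param intercept_radius Intercept criterion (m), default 0.03.
#' @return A list of class `qc_flight` (`bird`, `lure`, `intercept_time`,
#'   `t0`), or of class `flight_rejection` with a `reason`.
#' @export
qc_and_crop <- function(bird, lure, reconstruction_fraction,
                        min_fraction = 0.5, intercept_radius = 0.03) {
  if (reconstruction_fraction <= min_fraction)
    return(reject(sprintf(
      "back template reconstructed in %.0f%% of frames (need > %.0f%%)",
      100 * reconstruction_fraction, 100 * min_fraction)))
  both <- !is.na(bird$x) & !is.na(lure$x)
  if (!any(both)) return(reject("no frame with both bird and lure visible"))
  start <- which(both)[1]
  bird <- bird[start:nrow(bird), , drop = FALSE]
  lure <- lure[start:nrow(lure), , drop = FALSE]
  d <- sqrt((bird$x - lure$x)^2 + (bird$y - lure$y)^2)
  hit <- which(!is.na(d) & d <= intercept_radius)
  if (length(hit) == 0)
    return(reject(sprintf("no intercept: minimum distance %.0f mm > %.0f mm",
                          1000 * min(d, na.rm = TRUE),
                          1000 * intercept_radius)))
  end <- hit[1]
  structure(list(bird = bird[1:end, , drop = FALSE],
                 lure = lure[1:end, , drop = FALSE],
                 intercept_time = bird$time_s[end] - bird$time_s[1],
                 t0 = bird$time_s[1]),
            class = "qc_flight")
}

reject <- function(reason) {
  structure(list(reason = reason), class = "flight_rejection")
}

#' @export
print.flight_rejection <- function(x, ...) {
  cat("<flight_rejection>", x$reason, "\n")
  invisible(x)
}

#' Full preprocessing chain: marker cloud to flight
#'
#' Runs labelling, centroid extraction, two-pass outlier elimination,
#' quality control/cropping and quintic-spline smoothing, and assembles a
#' `hawk_flight` whose dense tracks are the spline evaluations at the
#' integration rate. Times are re-zeroed at the first mutually visible
#' frame.
#'
#' @param cloud Marker cloud tibble (`frame`, `time_s`, `x`, `y`, `z`).
#' @param templates Marker templates.
#' @param dt Integration step of the assembled dense tracks (s).
#' @param bird_tolerance,lure_tolerance Spline tolerances (m).
#' @param id Flight identifier.
#' @param ... Passed to [label_markers()].
#' @return A `hawk_flight`, or a `flight_rejection`.
#' @export
process_marker_cloud <- function(cloud, templates = default_templates(),
                                 dt = 5e-5, bird_tolerance = 0.03,
                                 lure_tolerance = 0.01, id = "flight",
                                 ...) {
  lab <- label_markers(cloud, templates, ...)
  cent <- labelled_centroids(lab)
  bird <- tibble::tibble(time_s = cent$time_s, x = cent$bird_x,
                         y = cent$bird_y)
  lure <- tibble::tibble(time_s = cent$time_s, x = cent$lure_x,
                         y = cent$lure_y)
  bird <- clean_trajectory(bird)
  lure <- clean_trajectory(lure)
  qc <- qc_and_crop(bird, lure, attr(cent, "reconstruction_fraction"))
  if (inherits(qc, "flight_rejection")) return(qc)

  out_rate <- 1 / dt
  sb <- smooth_and_differentiate(qc$bird, bird_tolerance, out_rate)
  sl <- smooth_and_differentiate(qc$lure, lure_tolerance, out_rate)
  n <- min(nrow(sb), nrow(sl))
  t0 <- qc$t0
  dense <- tibble::tibble(
    time_s = sb$time_s[1:n] - t0,
    lure_x = sl$x[1:n], lure_y = sl$y[1:n],
    lure_vx = sl$vx[1:n], lure_vy = sl$vy[1:n],
    hawk_x = sb$x[1:n], hawk_y = sb$y[1:n],
    hawk_vx = sb$vx[1:n], hawk_vy = sb$vy[1:n],
    hawk_speed = sqrt(sb$vx[1:n]^2 + sb$vy[1:n]^2))
  frames <- tibble::tibble(
    time_s = qc$bird$time_s - t0,
    hawk_x = qc$bird$x, hawk_y = qc$bird$y,
    lure_x = qc$lure$x, lure_y = qc$lure$y)
  as_flight(id = id, frames = frames, dense = dense, dt = dt,
            intercept_time = qc$intercept_time,
            meta = list(source = "marker_cloud",
                        bird_residual = attr(sb, "residual"),
                        lure_residual = attr(sl, "residual")))
}
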