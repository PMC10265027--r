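#' Flight objects
#'
#' A flight is the unit the whole pipeline operates on: paired pursuer (hawk)
#' and target (lure) tracks on a common time base, with time `t = 0` at the
#' onset of target motion and the record ending at the intercept.
#'
#' Two representations are carried together:
#' * `frames` — the measured 200 Hz frames (`time_s`, `hawk_x`, `hawk_y`,
#'   `lure_x`, `lure_y`, metres; `NA` marks missing frames). These are the
#'   frames against which the RMS fitting error is evaluated.
#' * `dense` — tracks on the uniform integration grid `dt` covering
#'   `[0, intercept_time]`: target position and velocity, and the measured
#'   hawk position, velocity and speed (`hawk_speed`). The simulator consumes
#'   these directly; no interpolation happens inside the simulator.
#'
#' @param id Flight identifier.
#' @param frames Tibble of measured frames (see above).
#' @param dense Tibble of dense tracks (see above).
#' @param dt Integration step of `dense` (s).
#' @param intercept_time Time of intercept (s): first frame at which the hawk
#'   comes within the intercept radius of the lure.
#' @param frame_rate Measurement frame rate (Hz), default 200.
#' @param tau_max Largest admissible delay (s), default 0.15; simulations of
#'   this flight start at `t = tau_max`.
#' @param meta Named list of provenance metadata (seed, generating law, ...).
#' @return An object of class `hawk_flight`.
#' @export
as_flight <- function(id, frames, dense, dt, intercept_time,
                      frame_rate = 200, tau_max = 0.15, meta = list()) {
  need_f <- c("time_s", "hawk_x", "hawk_y", "lure_x", "lure_y")
  need_d <- c("time_s", "lure_x", "lure_y", "lure_vx", "lure_vy",
              "hawk_x", "hawk_y", "hawk_vx", "hawk_vy", "hawk_speed")
  if (!all(need_f %in% names(frames)))
    abort(paste("frames must have columns:", paste(need_f, collapse = ", ")))
  if (!all(need_d %in% names(dense)))
    abort(paste("dense must have columns:", paste(need_d, collapse = ", ")))
  if (intercept_time <= tau_max)
    abort("flight too short: intercept_time must exceed tau_max")
  structure(
    list(id = id, frames = tibble::as_tibble(frames),
         dense = tibble::as_tibble(dense), dt = dt,
         intercept_time = intercept_time, frame_rate = frame_rate,
         tau_max = tau_max, meta = meta),
    class = "hawk_flight")
}

#' @export
print.hawk_flight <- function(x, ...) {
  cat(sprintf("<hawk_flight '%s'>  %d frames @ %g Hz, intercept at %.3f s, dt = %g s\n",
              x$id, nrow(x$frames), x$frame_rate, x$intercept_time, x$dt))
  if (!is.null(x$meta$law))
    cat(sprintf("  generated under %s (N = %g, K = %g, tau = %g s)\n",
                x$meta$law, x$meta$N %||% NA, x$meta$K %||% NA,
                x$meta$tau %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Measurement frames used for RMS evaluation: 200 Hz frames on
# [tau_max, intercept_time] with a non-missing hawk position, mapped to
# 0-based indices on the dense dt grid (frame times must sit on the grid).
eval_frames <- function(flight) {
  f <- flight$frames
  keep <- f$time_s >= flight$tau_max - 1e-9 &
    f$time_s <= flight$intercept_time + 1e-9 &
    !is.na(f$hawk_x) & !is.na(f$hawk_y)
  f <- f[keep, , drop = FALSE]
  if (nrow(f) == 0) abort("no usable evaluation frames on [tau_max, intercept]")
  idx <- f$time_s / flight$dt
  if (max(abs(idx - round(idx))) > 1e-6)
    abort("frame times do not lie on the dense dt grid")
  list(idx = as.integer(round(idx)), x = f$hawk_x, y = f$hawk_y,
       time_s = f$time_s)
}

#' Plot a flight's measured tracks
#'
#' @param object A `hawk_flight`.
#' @param sim Optional simulated trajectory (output of [simulate_pursuit()])
#'   overlaid in black.
#' @param ... Unused.
#' @return A ggplot object: hawk track in blue, lure track in red.
#' @method autoplot hawk_flight
#' @export
autoplot.hawk_flight <- function(object, sim = NULL, ...) {
  f <- object$frames
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = f, ggplot2::aes(.data$lure_x, .data$lure_y),
                       colour = "firebrick", na.rm = TRUE) +
    ggplot2::geom_path(data = f, ggplot2::aes(.data$hawk_x, .data$hawk_y),
                       colour = "steelblue", na.rm = TRUE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = paste0("flight ", object$id)) +
    ggplot2::theme_minimal()
  if (!is.null(sim))
    p <- p + ggplot2::geom_path(data = sim, ggplot2::aes(.data$x, .data$y),
                                colour = "black", linetype = 2)
  p
}
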