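#' Write a flight's measured frames to CSV
#'
#' Plain-text flight format: `#`-prefixed header lines carrying metadata
#' (id, sample rate, units, seed/provenance), then one row per 200 Hz frame
#' with columns `time_s, hawk_x_m, hawk_y_m, hawk_z_m, lure_x_m, lure_y_m,
#' lure_z_m`. Missing values are written as empty fields. Numeric fields are
#' written at full double precision so the file round-trips losslessly.
#'
#' @param flight A `hawk_flight`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flight <- function(flight, path) {
  f <- flight$frames
  hz <- if ("hawk_z" %in% names(f)) f$hawk_z else rep(0, nrow(f))
  lz <- if ("lure_z" %in% names(f)) f$lure_z else rep(0, nrow(f))
  meta <- c(
    id = flight$id,
    sample_rate_hz = format(flight$frame_rate),
    dt_s = num17(flight$dt),
    intercept_time_s = num17(flight$intercept_time),
    tau_max_s = num17(flight$tau_max),
    units = "m,s")
  for (k in c("law", "N", "K", "tau", "seed")) {
    v <- flight$meta[[k]]
    if (!is.null(v) && length(v) == 1)
      meta[k] <- if (is.numeric(v)) num17(v) else as.character(v)
  }
  hdr <- c("# hawkpursuit flight v1",
           paste0("# ", names(meta), ": ", unname(meta)))
  cols <- cbind(num17(f$time_s), num17(f$hawk_x), num17(f$hawk_y),
                num17(hz), num17(f$lure_x), num17(f$lure_y), num17(lz))
  cols[is.na(cols) | cols == "NA"] <- ""
  body <- apply(cols, 1, paste, collapse = ",")
  writeLines(c(hdr,
               "time_s,hawk_x_m,hawk_y_m,hawk_z_m,lure_x_m,lure_y_m,lure_z_m",
               body), path)
  invisible(path)
}

num17 <- function(x) sprintf("%.17g", x)

#' Read a flight frames file
#'
#' Parses the format written by [write_flight()]. Validates that time is
#' strictly increasing, naming the offending row otherwise; empty fields
#' become missing values. Unknown header keys and extra columns are kept in
#' the metadata.
#'
#' @param path Input file path.
#' @return A list of class `flight_frames`: `frames` tibble, `meta` named
#'   list. Rebuild a full `hawk_flight` (dense tracks via spline smoothing)
#'   with [flight_from_frames()].
#' @export
read_flight <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  n_hdr <- which(!hdr)[1] - 1
  meta <- list()
  for (ln in lines[seq_len(n_hdr)][-1]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[-(seq_len(n_hdr))]
  if (length(body) < 2) abort("malformed flight file: no data rows")
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE,
                        colClasses = "numeric")
  need <- c("time_s", "hawk_x_m", "hawk_y_m", "lure_x_m", "lure_y_m")
  if (!all(need %in% names(df)))
    abort(paste("malformed header: expected columns",
                paste(need, collapse = ", ")))
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad) > 0)
    abort(sprintf("non-monotonic time at row %d", bad[1] + 1L))
  frames <- tibble::tibble(
    time_s = df$time_s,
    hawk_x = df$hawk_x_m, hawk_y = df$hawk_y_m,
    lure_x = df$lure_x_m, lure_y = df$lure_y_m)
  extra <- setdiff(names(df), c(need, "hawk_z_m", "lure_z_m"))
  if (length(extra) > 0) meta$extra_columns <- df[extra]
  structure(list(frames = frames, meta = meta), class = "flight_frames")
}

#' Rebuild a flight from measured frames
#'
#' Reconstructs the dense tracks of a flight read with [read_flight()] by
#' quintic-spline smoothing of the measured frames (the same smoothing used
#' by the preprocessing chain), so the flight can be fed to the simulator
#' and fitting functions.
#'
#' @param ff A `flight_frames` object from [read_flight()].
#' @param dt Integration step (s); defaults to the file's `dt_s` header or
#'   5e-5.
#' @param bird_tolerance,lure_tolerance Spline tolerances (m).
#' @return A `hawk_flight`.
#' @export
flight_from_frames <- function(ff, dt = NULL, bird_tolerance = 0.03,
                               lure_tolerance = 0.01) {
  stopifnot(inherits(ff, "flight_frames"))
  if (is.null(dt)) dt <- ff$meta$dt_s %||% 5e-5
  f <- ff$frames
  out_rate <- 1 / dt
  sb <- smooth_and_differentiate(
    tibble::tibble(time_s = f$time_s, x = f$hawk_x, y = f$hawk_y),
    bird_tolerance, out_rate)
  sl <- smooth_and_differentiate(
    tibble::tibble(time_s = f$time_s, x = f$lure_x, y = f$lure_y),
    lure_tolerance, out_rate)
  n <- min(nrow(sb), nrow(sl))
  dense <- tibble::tibble(
    time_s = sb$time_s[1:n],
    lure_x = sl$x[1:n], lure_y = sl$y[1:n],
    lure_vx = sl$vx[1:n], lure_vy = sl$vy[1:n],
    hawk_x = sb$x[1:n], hawk_y = sb$y[1:n],
    hawk_vx = sb$vx[1:n], hawk_vy = sb$vy[1:n],
    hawk_speed = sqrt(sb$vx[1:n]^2 + sb$vy[1:n]^2))
  it <- ff$meta$intercept_time_s %||% max(f$time_s)
  as_flight(id = as.character(ff$meta$id %||% "flight"), frames = f,
            dense = dense, dt = dt, intercept_time = it,
            tau_max = ff$meta$tau_max_s %||% 0.15, meta = ff$meta)
}

#' Write / read a marker cloud CSV
#'
#' Long-format plain CSV: one row per detected point, columns `frame`,
#' `time_s`, `x_m`, `y_m`, `z_m` (plus `label_true` when present, for
#' synthetic clouds).
#'
#' @param cloud Marker cloud tibble.
#' @param path File path.
#' @return `path` invisibly (write); the cloud tibble (read).
#' @export
write_marker_cloud <- function(cloud, path) {
  df <- data.frame(frame = cloud$frame, time_s = num17(cloud$time_s),
                   x_m = num17(cloud$x), y_m = num17(cloud$y),
                   z_m = num17(cloud$z))
  if (!is.null(cloud$label_true)) df$label_true <- cloud$label_true
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_marker_cloud
#' @export
read_marker_cloud <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::tibble(frame = as.integer(df$frame),
                        time_s = as.numeric(df$time_s),
                        x = as.numeric(df$x_m), y = as.numeric(df$y_m),
                        z = as.numeric(df$z_m))
  if (!is.null(df$label_true)) out$label_true <- df$label_true
  out
}
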