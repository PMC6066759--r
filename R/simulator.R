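# Simulation-session state machine. A session holds the per-plane
# calibrations and pre-loaded radiographs, and maintains the counters
# behind three of the five objective metrics: exposure count, guide-wire
# retry count (hysteresis on insertion depth) and procedural time.
# Sessions are environment-backed so counters mutate in place.

#' Construct an annotated radiograph
#'
#' @param pixels H x W grayscale matrix, values in `[0, 255]`.
#' @param plane `"AP"` or `"CTL"`.
#' @param mm_per_px physical scale of the image (> 0).
#' @param apex annotated femoral-head apex, `c(x, y)` pixels.
#' @param entry annotated lateral-cortex entry point, `c(x, y)` pixels.
#' @return A `radiograph` object.
#' @export
radiograph <- function(pixels, plane = c("AP", "CTL"), mm_per_px,
                       apex, entry) {
  plane <- match.arg(plane)
  pixels <- as.matrix(pixels)
  if (!is.finite(mm_per_px) || mm_per_px <= 0)
    ft_stop("mm_per_px must be finite and > 0", "fluorotrack_invalid_input")
  for (p in list(apex = apex, entry = entry)) ft_assert_finite(p, "annotation")
  if (!in_bounds(apex, pixels) || !in_bounds(entry, pixels))
    ft_stop("apex and entry annotations must lie inside the image",
            "fluorotrack_invalid_input")
  structure(list(pixels = pixels, plane = plane,
                 mm_per_px = as.numeric(mm_per_px),
                 apex = as.numeric(apex), entry = as.numeric(entry)),
            class = "radiograph")
}

in_bounds <- function(p, pixels) {
  p[1] >= 0 && p[1] <= ncol(pixels) - 1 && p[2] >= 0 && p[2] <= nrow(pixels) - 1
}

#' Open a simulation session
#'
#' @param radiographs named list with `AP` and `CTL` [radiograph()]s.
#' @param calibrations named list with `AP` and `CTL` [affine2d()]
#'   camera-to-radiograph transforms (either may be omitted; taking a
#'   radiograph in an uncalibrated plane fails).
#' @param start_time session opening time in seconds.
#' @param depth_on,depth_off insertion-hysteresis thresholds in AP-plane
#'   pixels along the entry-to-apex axis: the wire counts as inserted
#'   once its signed depth exceeds `depth_on`, and as withdrawn (one
#'   retry) once the depth falls below `depth_off`. `depth_off <
#'   depth_on` debounces jitter at the cortex.
#' @return A `fluoro_session` object (environment).
#' @export
new_session <- function(radiographs, calibrations = list(),
                        start_time = 0, depth_on = 5, depth_off = 0) {
  if (depth_off >= depth_on)
    ft_stop("depth_off must be below depth_on", "fluorotrack_invalid_input")
  s <- new.env(parent = emptyenv())
  s$radiographs <- radiographs
  s$calibrations <- calibrations
  s$exposure_count <- 0L
  s$retry_count <- 0L
  s$start_time <- as.numeric(start_time)
  s$end_time <- NA_real_
  s$last_time <- as.numeric(start_time)
  s$open <- TRUE
  s$wire_inserted <- FALSE
  s$depth_on <- depth_on
  s$depth_off <- depth_off
  s$final_tip <- list(AP = NULL, CTL = NULL)  # radiograph coords
  s$events <- list()
  class(s) <- "fluoro_session"
  s
}

log_event <- function(s, t, event, payload = NULL) {
  s$events[[length(s$events) + 1L]] <- list(t = t, event = event,
                                            payload = payload)
  invisible(s)
}

check_open <- function(s) {
  if (!s$open)
    ft_stop("session is closed", "fluorotrack_session_closed")
}

check_time <- function(s, timestamp) {
  if (!is.finite(timestamp) || timestamp < s$last_time)
    ft_stop("timestamps must be non-decreasing",
            "fluorotrack_nonmonotone_time")
}

#' Take a simulated radiograph
#'
#' Maps the tracked camera-space wire pose into the requested plane via
#' its affine calibration, rasterizes the wire as an anti-aliased white
#' segment ending at the tip onto a copy of the pre-loaded radiograph,
#' increments the exposure counter by exactly one, and logs the event.
#'
#' @param s a [new_session()] session.
#' @param plane `"AP"` or `"CTL"`.
#' @param pose_camera a [wire_pose_from_markers()] pose in camera pixels.
#' @param timestamp exposure time in seconds (defaults to the session's
#'   last event time).
#' @param shaft_px drawn shaft length in radiograph pixels (cosmetic).
#' @param width_px drawn wire width in pixels (cosmetic).
#' @return A `simulated_screen` list: `image` (grayscale matrix),
#'   `plane`, `exposure_index`, `tip` (radiograph coords).
#' @export
take_radiograph <- function(s, plane = c("AP", "CTL"), pose_camera,
                            timestamp = NULL, shaft_px = 200, width_px = 2) {
  plane <- match.arg(plane)
  check_open(s)
  tr <- s$calibrations[[plane]]
  if (is.null(tr))
    ft_stop(sprintf("no calibration for %s plane", plane),
            "fluorotrack_missing_calibration")
  if (is.null(timestamp)) timestamp <- s$last_time
  check_time(s, timestamp)
  rad <- s$radiographs[[plane]]
  tip_r <- apply_affine(tr, pose_camera$tip)
  # wire axis mapped into radiograph space (affine maps are not
  # conformal, so the direction must be transformed, not copied)
  back_r <- apply_affine(tr, pose_camera$tip - pose_camera$direction)
  axis <- tip_r - back_r
  axis <- axis / sqrt(sum(axis^2))
  img <- draw_segment(rad$pixels, tip_r - shaft_px * axis, tip_r,
                      width = width_px, value = 255)
  s$exposure_count <- s$exposure_count + 1L
  s$final_tip[[plane]] <- tip_r
  s$last_time <- timestamp
  log_event(s, timestamp, "expose", list(plane = plane, tip = tip_r))
  structure(list(image = img, plane = plane,
                 exposure_index = s$exposure_count, tip = tip_r),
            class = "simulated_screen")
}

#' Rasterize an anti-aliased segment onto a grayscale image
#'
#' Pixel coverage falls off linearly (over half a pixel) with
#' perpendicular distance from the centerline, giving a `width`-px
#' stroke, and is cut with a butt cap at each end so the painted stroke
#' terminates at the endpoints to sub-pixel accuracy.
#'
#' @param pixels grayscale matrix in `[0, 255]`.
#' @param p0,p1 segment endpoints, `c(x, y)` image coordinates.
#' @param width stroke width in pixels.
#' @param value stroke intensity.
#' @return The painted matrix.
#' @export
draw_segment <- function(pixels, p0, p1, width = 2, value = 255) {
  H <- nrow(pixels); W <- ncol(pixels)
  pad <- ceiling(width / 2 + 1)
  cmin <- max(1L, floor(min(p0[1], p1[1])) + 1L - pad)
  cmax <- min(W, ceiling(max(p0[1], p1[1])) + 1L + pad)
  rmin <- max(1L, floor(min(p0[2], p1[2])) + 1L - pad)
  rmax <- min(H, ceiling(max(p0[2], p1[2])) + 1L + pad)
  if (cmin > cmax || rmin > rmax) return(pixels)
  cols <- cmin:cmax; rows <- rmin:rmax
  x <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE)
  y <- matrix(rows - 1, length(rows), length(cols))
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  if (len == 0) {
    d <- sqrt((x - p0[1])^2 + (y - p0[2])^2)
    cov <- pmin(1, pmax(0, width / 2 + 0.5 - d))
  } else {
    u <- ((x - p0[1]) * v[1] + (y - p0[2]) * v[2]) / len  # px along axis
    d_perp <- abs((x - p0[1]) * (-v[2]) + (y - p0[2]) * v[1]) / len
    cov <- pmin(1, pmax(0, width / 2 + 0.5 - d_perp)) *
      pmin(1, pmax(0, 0.5 + pmin(u, len - u)))
  }
  pixels[rows, cols] <- pixels[rows, cols] * (1 - cov) + value * cov
  pixels
}

#' Update the wire insertion state and count retries
#'
#' Signed insertion depth is the projection of `tip - entry` onto the
#' unit entry-to-apex axis of the AP radiograph. The wire latches
#' "inserted" when depth exceeds `depth_on`; each subsequent drop below
#' `depth_off` counts one retry (a complete withdrawal) and unlatches.
#'
#' @param s a session.
#' @param tip_radiograph current wire tip in AP radiograph pixels.
#' @param timestamp event time in seconds; must be non-decreasing.
#' @return The session, invisibly (mutated in place).
#' @export
update_wire_state <- function(s, tip_radiograph, timestamp) {
  check_open(s)
  check_time(s, timestamp)
  ft_assert_finite(tip_radiograph, "tip")
  rad <- s$radiographs$AP
  axis <- rad$apex - rad$entry
  axis <- axis / sqrt(sum(axis^2))
  depth <- sum((as.numeric(tip_radiograph) - rad$entry) * axis)
  if (!s$wire_inserted && depth > s$depth_on) {
    s$wire_inserted <- TRUE
    log_event(s, timestamp, "insert", list(depth = depth))
  } else if (s$wire_inserted && depth < s$depth_off) {
    s$wire_inserted <- FALSE
    s$retry_count <- s$retry_count + 1L
    log_event(s, timestamp, "withdraw", list(depth = depth))
  }
  s$last_time <- timestamp
  log_event(s, timestamp, "move",
            list(tip = as.numeric(tip_radiograph), depth = depth))
  invisible(s)
}

#' Close a session
#'
#' Called when the participant declares their final wire placement.
#' The session becomes immutable; a second close (or any later mutation)
#' raises `fluorotrack_session_closed`.
#'
#' @param s a session.
#' @param timestamp closing time in seconds (>= all prior events).
#' @return The session, invisibly.
#' @export
close_session <- function(s, timestamp) {
  check_open(s)
  check_time(s, timestamp)
  s$end_time <- as.numeric(timestamp)
  s$open <- FALSE
  log_event(s, timestamp, "close", NULL)
  invisible(s)
}

#' Assemble the five objective session metrics
#'
#' TAD comes from the final exposed tip position and apex annotation in
#' each plane (magnification via each radiograph's `mm_per_px` unless
#' apparent wire diameters are given), COR from the cut-out curve, time
#' from the open-to-close interval, and the two counters from the event
#' log.
#'
#' @param s a closed session.
#' @param curve a cut-out curve (default [default_cutout_curve()]).
#' @param d_app_ap,d_app_lat,d_true_mm optional apparent/true wire
#'   diameters for the diameter-based magnification correction.
#' @return A `session_metrics` list: `tad_mm`, `cor_pct`, `time_s`,
#'   `n_radiographs`, `n_retries`.
#' @details Raises `fluorotrack_incomplete_session` if either plane was
#'   never exposed (no final pose), and `fluorotrack_session_open` if
#'   the session has not been closed.
#' @export
session_report <- function(s, curve = default_cutout_curve(),
                           d_app_ap = NULL, d_app_lat = NULL,
                           d_true_mm = NULL) {
  if (s$open)
    ft_stop("session must be closed before reporting",
            "fluorotrack_session_open")
  if (is.null(s$final_tip$AP) || is.null(s$final_tip$CTL))
    ft_stop("no final wire pose in both planes (no exposures?)",
            "fluorotrack_incomplete_session")
  tad <- compute_tad(
    tip_ap = s$final_tip$AP, apex_ap = s$radiographs$AP$apex,
    tip_lat = s$final_tip$CTL, apex_lat = s$radiographs$CTL$apex,
    d_app_ap = d_app_ap, d_app_lat = d_app_lat, d_true_mm = d_true_mm,
    mm_per_px_ap = s$radiographs$AP$mm_per_px,
    mm_per_px_lat = s$radiographs$CTL$mm_per_px)
  structure(list(tad_mm = tad$tad_mm,
                 cor_pct = cor_from_tad(curve, tad$tad_mm),
                 time_s = s$end_time - s$start_time,
                 n_radiographs = s$exposure_count,
                 n_retries = s$retry_count),
            class = "session_metrics")
}

#' Replay a scripted trajectory through a session
#'
#' Drives the full pipeline from a trajectory table (see
#' [make_trajectory()] / [read_trajectory()]): `move` rows update the
#' insertion state from the AP-plane tip, `expose` rows map the tip back
#' into camera space through the inverse calibration and take a
#' simulated radiograph, and the `close` row ends the session.
#'
#' @param s a fresh session whose planes are calibrated.
#' @param traj data frame with columns `t_s`, `event`
#'   (`move`/`expose`/`close`), `plane`, `tip_x`, `tip_y` (radiograph
#'   coordinates).
#' @return The session, invisibly.
#' @export
replay_trajectory <- function(s, traj) {
  for (i in seq_len(nrow(traj))) {
    row <- traj[i, ]
    if (row$event == "move") {
      update_wire_state(s, c(row$tip_x, row$tip_y), row$t_s)
    } else if (row$event == "expose") {
      plane <- as.character(row$plane)
      tr <- s$calibrations[[plane]]
      if (is.null(tr))
        ft_stop(sprintf("no calibration for %s plane", plane),
                "fluorotrack_missing_calibration")
      inv <- invert_affine(tr)
      rad <- s$radiographs[[plane]]
      axis_r <- rad$apex - rad$entry
      axis_r <- axis_r / sqrt(sum(axis_r^2))
      tip_r <- c(row$tip_x, row$tip_y)
      tip_cam <- apply_affine(inv, tip_r)
      back_cam <- apply_affine(inv, tip_r - axis_r)
      dir_cam <- (tip_cam - back_cam) / sqrt(sum((tip_cam - back_cam)^2))
      pose <- structure(list(tip = tip_cam, direction = dir_cam),
                        class = "wire_pose")
      take_radiograph(s, plane, pose, timestamp = row$t_s)
    } else if (row$event == "close") {
      close_session(s, row$t_s)
    } else {
      ft_stop(sprintf("unknown trajectory event '%s'", row$event),
              "fluorotrack_invalid_input")
    }
  }
  invisible(s)
}

#' Write the session event log as JSON lines
#'
#' One event per line: `{"t": ..., "event": "...", "payload": {...}}`.
#'
#' @param s a session.
#' @param path output file.
#' @export
write_session_log <- function(s, path) {
  lines <- vapply(s$events, function(e)
    jsonlite::toJSON(e, digits = NA, auto_unbox = TRUE, null = "null"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf(paste0("Session metrics:\n  TAD         %.1f mm\n",
                     "  COR         %.1f %%\n  time        %.0f s\n",
                     "  radiographs %d\n  retries     %d\n"),
              x$tad_mm, x$cor_pct, x$time_s, x$n_radiographs, x$n_retries))
  invisible(x)
}

#' @export
print.fluoro_session <- function(x, ...) {
  cat(sprintf("<fluoro_session> %s | exposures %d | retries %d | events %d\n",
              if (x$open) "open" else "closed",
              x$exposure_count, x$retry_count, length(x$events)))
  invisible(x)
}
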