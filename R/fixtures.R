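# Deterministic synthetic-data generators: camera frames with colored
# disk markers, annotated hip radiographs, scripted wire trajectories,
# and participant cohorts. Every generator is a pure function of its
# arguments and seed -- global RNG state is saved and restored.

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Pixels whose centers fall inside the disk (center-of-pixel inclusion):
# pixel (row r, col c) is in the disk iff the distance from (c-1, r-1)
# to the center is <= radius. Makes ground-truth counts and centroids
# exactly computable.
disk_pixels <- function(center, radius, H, W) {
  cols <- max(1L, floor(center[1] - radius) + 1L):
          min(W, ceiling(center[1] + radius) + 1L)
  rows <- max(1L, floor(center[2] - radius) + 1L):
          min(H, ceiling(center[2] + radius) + 1L)
  x <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE)
  y <- matrix(rows - 1, length(rows), length(cols))
  inside <- (x - center[1])^2 + (y - center[2])^2 <= radius^2
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

#' Generate a synthetic camera frame with two disk markers
#'
#' Rasterizes two solid circular markers (no anti-aliasing; a pixel
#' belongs to a disk iff its center is within the radius) on a uniform
#' background, then adds clipped Gaussian channel noise.
#'
#' @param size `c(H, W)` frame dimensions.
#' @param centers 2x2 matrix of marker centers, rows = (proximal,
#'   distal), columns = `(x, y)`.
#' @param radius marker radius in px (>= 2).
#' @param colors list of two RGB triples (proximal, distal).
#' @param background background RGB triple.
#' @param noise_sigma Gaussian channel noise SD (clipped to `[0, 255]`).
#' @param seed RNG seed for the noise.
#' @return A list: `frame` (a [camera_frame()]) and `truth` (exact
#'   `centers`, exact rasterized `pixel_counts`, and the analytic
#'   `centroids` of the rasterized disks).
#' @details A marker extending outside the frame raises
#'   `fluorotrack_marker_out_of_frame`.
#' @export
make_frame <- function(size = c(120, 160),
                       centers = rbind(c(50, 60), c(120, 80)),
                       radius = 6,
                       colors = list(c(220, 40, 40), c(40, 40, 220)),
                       background = c(20, 20, 20),
                       noise_sigma = 0, seed = 0L) {
  H <- size[1]; W <- size[2]
  centers <- as.matrix(centers)
  if (radius < 2)
    ft_stop("marker radius must be >= 2", "fluorotrack_invalid_spec")
  for (i in 1:2) {
    c_i <- centers[i, ]
    if (c_i[1] - radius < 0 || c_i[1] + radius > W - 1 ||
        c_i[2] - radius < 0 || c_i[2] + radius > H - 1)
      ft_stop("marker disk extends outside the frame",
              "fluorotrack_marker_out_of_frame")
  }
  px <- array(rep(background, each = H * W), c(H, W, 3))
  counts <- integer(2); centroids <- matrix(NA_real_, 2, 2)
  for (i in 1:2) {
    idx <- disk_pixels(centers[i, ], radius, H, W)
    counts[i] <- nrow(idx)
    centroids[i, ] <- c(mean(idx[, "col"]) - 1, mean(idx[, "row"]) - 1)
    for (ch in 1:3) px[cbind(idx, ch)] <- colors[[i]][ch]
  }
  if (noise_sigma > 0) {
    px <- with_seed(seed, px + rnorm(length(px), 0, noise_sigma))
    px[] <- pmin(255, pmax(0, px))
  }
  list(frame = camera_frame(px),
       truth = list(centers = centers, pixel_counts = counts,
                    centroids = centroids))
}

#' Generate a synthetic annotated hip radiograph
#'
#' A schematic AP or CTL view: dark background, a brighter band for the
#' femoral neck/shaft along the entry-to-head axis, and a brighter disk
#' for the femoral head. The apex annotation is placed on the head
#' boundary along the neck axis (the ideal wire target); the entry
#' annotation is the lateral-cortex entry point.
#'
#' @param plane `"AP"` or `"CTL"`.
#' @param size `c(H, W)`.
#' @param head_center femoral head center, `c(x, y)`.
#' @param head_radius head disk radius in px.
#' @param entry lateral-cortex entry point, `c(x, y)`.
#' @param mm_per_px physical scale (> 0).
#' @param noise_sigma Gaussian intensity noise SD.
#' @param seed RNG seed.
#' @return A [radiograph()] whose `apex` lies on the head boundary.
#' @details `entry` coinciding with `head_center`, or annotations out of
#'   bounds, raise `fluorotrack_geometry_error`.
#' @export
make_radiograph <- function(plane = c("AP", "CTL"), size = c(240, 320),
                            head_center = c(230, 80), head_radius = 40,
                            entry = c(60, 170), mm_per_px = 0.5,
                            noise_sigma = 0, seed = 0L) {
  plane <- match.arg(plane)
  H <- size[1]; W <- size[2]
  axis <- head_center - entry
  len <- sqrt(sum(axis^2))
  if (len < head_radius)
    ft_stop("entry point must lie outside the femoral head",
            "fluorotrack_geometry_error")
  axis <- axis / len
  apex <- head_center + head_radius * axis
  for (p in list(apex, entry, head_center))
    if (p[1] < 0 || p[1] > W - 1 || p[2] < 0 || p[2] > H - 1)
      ft_stop("anatomy extends outside the image",
              "fluorotrack_geometry_error")
  img <- matrix(30, H, W)
  img <- draw_segment(img, entry - 40 * axis, head_center,
                      width = 2 * head_radius * 0.6, value = 90)
  idx <- disk_pixels(head_center, head_radius, H, W)
  img[idx] <- 140
  if (noise_sigma > 0) {
    img <- with_seed(seed, img + rnorm(length(img), 0, noise_sigma))
    img[] <- pmin(255, pmax(0, img))
  }
  radiograph(img, plane = plane, mm_per_px = mm_per_px,
             apex = apex, entry = entry)
}

#' Assemble a scripted trajectory table
#'
#' Interleaves wire `move` waypoints, `expose` events, and the final
#' `close` into one replayable table (see [replay_trajectory()]),
#' ordered by time. Ground-truth counters are attached as the
#' `"expected"` attribute.
#'
#' @param moves data frame with `t_s`, `tip_x`, `tip_y` (AP radiograph
#'   coordinates of the wire tip).
#' @param exposures data frame with `t_s`, `plane`, and optionally
#'   `tip_x`, `tip_y` (defaulting to the last move position).
#' @param close_t closing timestamp (after every other event).
#' @return A data frame `t_s, event, plane, tip_x, tip_y` with
#'   `attr(, "expected")$n_radiographs`.
#' @details Non-strictly-increasing timestamps raise
#'   `fluorotrack_nonmonotone_time`.
#' @export
make_trajectory <- function(moves, exposures, close_t) {
  moves <- as.data.frame(moves); exposures <- as.data.frame(exposures)
  if (is.null(exposures$tip_x)) {
    exposures$tip_x <- NA_real_; exposures$tip_y <- NA_real_
  }
  rows <- rbind(
    data.frame(t_s = moves$t_s, event = "move", plane = "AP",
               tip_x = moves$tip_x, tip_y = moves$tip_y),
    data.frame(t_s = exposures$t_s, event = "expose",
               plane = as.character(exposures$plane),
               tip_x = exposures$tip_x, tip_y = exposures$tip_y),
    data.frame(t_s = close_t, event = "close", plane = "AP",
               tip_x = NA_real_, tip_y = NA_real_))
  rows <- rows[order(rows$t_s), ]
  if (any(diff(rows$t_s) <= 0))
    ft_stop("trajectory timestamps must be strictly increasing",
            "fluorotrack_nonmonotone_time")
  # exposures without a position inherit the preceding move's tip
  last_x <- NA_real_; last_y <- NA_real_
  for (i in seq_len(nrow(rows))) {
    if (rows$event[i] == "move") {
      last_x <- rows$tip_x[i]; last_y <- rows$tip_y[i]
    } else if (rows$event[i] == "expose" && is.na(rows$tip_x[i])) {
      rows$tip_x[i] <- last_x; rows$tip_y[i] <- last_y
    }
  }
  rownames(rows) <- NULL
  attr(rows, "expected") <- list(n_radiographs = nrow(exposures))
  rows
}

#' Scripted insertion attempt with known ground truth
#'
#' Builds a trajectory that performs `n_retries` full
#' withdraw-reinsert cycles along the entry-to-apex axis of an AP
#' radiograph, ends with the tip exactly on the apex, and then takes
#' `n_exposures` radiographs (alternating AP/CTL) before closing. The
#' `"expected"` attribute carries `n_radiographs`, `n_retries`,
#' `tad_mm = 0` and `time_s`.
#'
#' @param rad_ap the AP [radiograph()] whose entry/apex axis drives the
#'   insertion-depth script.
#' @param rad_ctl the CTL [radiograph()]; CTL exposures place the tip at
#'   the equivalent depth fraction along its entry/apex axis (the two
#'   planes view the same wire). Defaults to `rad_ap`.
#' @param n_retries number of complete withdraw-reinsert cycles.
#' @param n_exposures number of simulated radiographs.
#' @param time_s total scripted procedure duration in seconds.
#' @param depth_on,depth_off the session hysteresis thresholds the
#'   script must cross (defaults match [new_session()]).
#' @return A trajectory table as from [make_trajectory()].
#' @export
make_insertion_trajectory <- function(rad_ap, rad_ctl = rad_ap,
                                      n_retries = 0,
                                      n_exposures = 16, time_s = 190,
                                      depth_on = 5, depth_off = 0) {
  axes <- lapply(list(AP = rad_ap, CTL = rad_ctl), function(r) {
    v <- r$apex - r$entry
    len <- sqrt(sum(v^2))
    list(entry = r$entry, axis = v / len, len = len)
  })
  len <- axes$AP$len
  at_frac <- function(f, plane)  # same depth fraction in either plane
    axes[[plane]]$entry + f * axes[[plane]]$len * axes[[plane]]$axis
  deep <- max(2 * depth_on, 0.6 * len)
  depths <- c(-5)  # start outside the cortex
  for (i in seq_len(n_retries)) depths <- c(depths, deep, depth_off - 5)
  depths <- c(depths, len)  # final insertion: tip on the apex
  tips <- t(vapply(depths / len, at_frac, numeric(2), plane = "AP"))
  move_t <- seq(1, time_s * 0.6, length.out = length(depths))
  moves <- data.frame(t_s = move_t, tip_x = tips[, 1], tip_y = tips[, 2])
  exp_t <- seq(time_s * 0.6 + 1, time_s - 1, length.out = n_exposures)
  planes <- rep(c("AP", "CTL"), length.out = n_exposures)
  exp_tip <- t(vapply(planes, at_frac, numeric(2), f = 1))
  exposures <- data.frame(t_s = exp_t, plane = planes,
                          tip_x = exp_tip[, 1], tip_y = exp_tip[, 2])
  traj <- make_trajectory(moves, exposures, close_t = time_s)
  attr(traj, "expected") <- list(n_radiographs = n_exposures,
                                 n_retries = n_retries,
                                 tad_mm = 0, time_s = time_s)
  traj
}

#' Read / write trajectory CSV
#'
#' Header: `t_s,event,plane,tip_x,tip_y`, tip coordinates in radiograph
#' space (0-based, x = column, y = row, origin top-left).
#'
#' @param path CSV file.
#' @return `read_trajectory`: the trajectory data frame.
#' @export
read_trajectory <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_trajectory
#' @param traj trajectory data frame.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' Published-study cohort medians
#'
#' The per-cohort median values of the five objective metrics for
#' novices/intermediates/experts: TAD 47/28/24 mm, COR 55/4.7/2.6 %,
#' procedural time 190/206/222 s, radiographs 16/26/28, retries 0/1/2.
#' These are the generator's median targets and the inputs to the
#' percent-difference analysis; in generation COR is never sampled --
#' it is derived deterministically from TAD through the cut-out curve
#' (whose default anchors are the extreme (TAD, COR) pairs here).
#'
#' @return A data frame with columns `cohort`, `tad_mm`, `cor_pct`,
#'   `time_s`, `n_radiographs`, `n_retries`.
#' @export
study_cohort_medians <- function() {
  data.frame(cohort = cohort_levels(),
             tad_mm = c(47, 28, 24),
             cor_pct = c(55, 4.7, 2.6),
             time_s = c(190, 206, 222),
             n_radiographs = c(16, 26, 28),
             n_retries = c(0, 1, 2))
}

#' Generate a synthetic participant cohort
#'
#' Per cohort: TAD is drawn log-normally with the target median
#' (`meanlog = log(median)`, `sdlog = dispersion`); COR is computed
#' deterministically from each TAD through `curve` (preserving the
#' functional coupling of the two metrics, so cohort median COR equals
#' the curve at the cohort median TAD); procedural time is normal about
#' its median (SD `dispersion * median`, clamped at 0); radiograph and
#' retry counts are Poisson at their medians; `dhs_count` is uniform
#' inside the cohort's defining range; each Likert response is agreeing
#' (uniform on 5..7) with probability `likert_p`, else uniform on 1..4.
#' With `dispersion = 0` every metric equals its cohort median exactly.
#'
#' @param n named integer vector: participants per cohort (default the
#'   study's 8/7/11).
#' @param medians per-cohort metric targets, as [study_cohort_medians()].
#' @param dispersion multiplicative spread (log-normal sdlog for TAD).
#' @param likert_p probability a Likert response is an agreement.
#' @param curve cut-out curve coupling COR to TAD.
#' @param seed RNG seed.
#' @return A data frame with the cohort-CSV columns (`id`, `dhs_count`,
#'   `pgy`, the 5 metrics, `q1`..`q4`) plus a `cohort` factor.
#' @export
make_cohort <- function(n = c(novice = 8, intermediate = 7, expert = 11),
                        medians = study_cohort_medians(),
                        dispersion = 0.3, likert_p = 0.85,
                        curve = default_cutout_curve(), seed = 1L) {
  if (any(n < 1))
    ft_stop("need at least one participant per cohort",
            "fluorotrack_invalid_spec")
  if (dispersion < 0 || likert_p < 0 || likert_p > 1)
    ft_stop("dispersion must be >= 0 and likert_p in [0, 1]",
            "fluorotrack_invalid_spec")
  if (any(medians$tad_mm <= 0) || any(medians$time_s <= 0))
    ft_stop("median targets for positive metrics must be positive",
            "fluorotrack_invalid_spec")
  dhs_range <- list(novice = c(0, 9), intermediate = c(10, 39),
                    expert = c(40, 80))
  pgy_range <- list(novice = c(2, 5), intermediate = c(4, 9),
                    expert = c(7, 15))
  with_seed(seed, {
    rows <- lapply(cohort_levels(), function(g) {
      ng <- n[[g]]
      med <- medians[medians$cohort == g, ]
      tad <- if (dispersion == 0) rep(med$tad_mm, ng) else
        rlnorm(ng, meanlog = log(med$tad_mm), sdlog = dispersion)
      time_s <- if (dispersion == 0) rep(med$time_s, ng) else
        pmax(0, rnorm(ng, med$time_s, dispersion * med$time_s))
      nrad <- if (dispersion == 0) rep(med$n_radiographs, ng) else
        rpois(ng, med$n_radiographs)
      nret <- if (dispersion == 0) rep(med$n_retries, ng) else
        rpois(ng, med$n_retries)
      agree <- matrix(runif(ng * 4) < likert_p, ng, 4)
      likert <- matrix(0L, ng, 4)
      likert[agree] <- sample(5:7, sum(agree), replace = TRUE)
      likert[!agree] <- sample(1:4, sum(!agree), replace = TRUE)
      df <- data.frame(
        id = sprintf("%s_%02d", substr(g, 1, 3), seq_len(ng)),
        dhs_count = sample(dhs_range[[g]][1]:dhs_range[[g]][2], ng,
                           replace = TRUE),
        pgy = sample(pgy_range[[g]][1]:pgy_range[[g]][2], ng,
                     replace = TRUE),
        tad_mm = tad,
        cor_pct = cor_from_tad(curve, tad),
        time_s = time_s,
        n_radiographs = nrad,
        n_retries = nret)
      df[paste0("q", 1:4)] <- likert
      df
    })
    out <- do.call(rbind, rows)
    out$cohort <- assign_cohort(out$dhs_count)
    rownames(out) <- NULL
    out
  })
}

#' Write a complete demo fixture bundle
#'
#' Produces, under `dir`: AP/CTL camera frames (PNG) with markers,
#' AP/CTL radiographs (PNG), calibration JSONs, a scripted trajectory
#' CSV, a participant cohort CSV, and a `manifest.json` with all ground
#' truth.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed for all generators.
#' @return The manifest list, invisibly.
#' @export
write_fixture_bundle <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rads <- list(AP = make_radiograph("AP"),
               CTL = make_radiograph("CTL", entry = c(60, 60),
                                     head_center = c(230, 160)))
  # camera sits at a modest zoom/offset from the radiograph plane
  cam2rad <- list(
    AP = fit_affine(rbind(c(20, 20), c(140, 30), c(40, 110)),
                    rbind(c(50, 60), c(280, 75), c(90, 230))),
    CTL = fit_affine(rbind(c(25, 15), c(130, 25), c(35, 105)),
                     rbind(c(60, 40), c(270, 60), c(80, 220))))
  manifest <- list(seed = seed,
                   coords = "0-based, x=column, y=row, origin top-left")
  for (plane in c("AP", "CTL")) {
    fr <- make_frame(noise_sigma = 4, seed = seed + match(plane, c("AP", "CTL")))
    write_frame_png(fr$frame, file.path(dir, paste0("frame_", plane, ".png")))
    png::writePNG(rads[[plane]]$pixels / 255,
                  file.path(dir, paste0("radiograph_", plane, ".png")))
    rad <- rads[[plane]]
    tr <- cam2rad[[plane]]
    write_calibration(
      list(plane = plane,
           src = rbind(c(20, 20), c(140, 30), c(40, 110)),
           dst = apply_affine(tr, rbind(c(20, 20), c(140, 30), c(40, 110)))),
      file.path(dir, paste0("calibration_", plane, ".json")))
    manifest[[plane]] <- list(
      marker_centers = fr$truth$centers,
      marker_pixel_counts = fr$truth$pixel_counts,
      apex = rad$apex, entry = rad$entry, mm_per_px = rad$mm_per_px,
      matrix = unclass(tr))
  }
  traj <- make_insertion_trajectory(rads$AP, rads$CTL, n_retries = 2,
                                    n_exposures = 16)
  write_trajectory(traj, file.path(dir, "trajectory.csv"))
  manifest$trajectory_expected <- attr(traj, "expected")
  cohort <- make_cohort(seed = seed)
  write.csv(cohort[setdiff(names(cohort), "cohort")],
            file.path(dir, "cohort.csv"), row.names = FALSE)
  manifest$cohort_n <- as.list(table(cohort$cohort))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(manifest)
}
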