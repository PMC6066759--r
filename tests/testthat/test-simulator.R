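test_that("each simulated radiograph increments the exposure counter once", {
  sc <- default_scene()
  s <- new_session(sc$rads, sc$cals)
  pose <- wire_pose_from_markers(c(50, 60), c(120, 80), tip_offset = 10)
  scr <- take_radiograph(s, "AP", pose, timestamp = 1)
  expect_equal(s$exposure_count, 1L)
  expect_s3_class(scr, "simulated_screen")
  expect_equal(dim(scr$image), dim(sc$rads$AP$pixels))

  for (i in 2:25) take_radiograph(s, sample(c("AP", "CTL"), 1), pose,
                                  timestamp = i)
  expect_equal(s$exposure_count, 25L)
  expect_equal(sum(vapply(s$events, function(e) e$event == "expose",
                          logical(1))), 25L)
})

test_that("the drawn tip lands where the calibration maps it", {
  sc <- default_scene()
  cam <- fit_affine(rbind(c(20, 20), c(140, 30), c(40, 110)),
                    rbind(c(50, 60), c(280, 75), c(90, 230)))
  s <- new_session(sc$rads, list(AP = cam, CTL = cam))
  set.seed(13)
  for (i in 1:20) {
    tip_cam <- c(runif(1, 40, 120), runif(1, 40, 100))
    pose <- wire_pose_from_markers(tip_cam - c(30, 10), tip_cam, 0)
    scr <- take_radiograph(s, "AP", pose, timestamp = i)
    expected <- apply_affine(cam, tip_cam)
    # locate the overlay endpoint: the painted pixel farthest along the
    # drawn wire axis
    diffpix <- which(scr$image != sc$rads$AP$pixels, arr.ind = TRUE)
    xy <- cbind(diffpix[, "col"] - 1, diffpix[, "row"] - 1)
    axis <- expected - apply_affine(cam, tip_cam - pose$direction)
    axis <- axis / sqrt(sum(axis^2))
    proj <- xy %*% axis
    # farthest painted extent along the wire axis vs the mapped tip
    expect_lt(abs(max(proj) - sum(expected * axis)), 1)
  }
})

test_that("uncalibrated or closed sessions refuse exposures", {
  sc <- default_scene()
  s <- new_session(sc$rads, list(AP = identity_affine()))
  pose <- wire_pose_from_markers(c(0, 0), c(10, 0), 0)
  expect_error(take_radiograph(s, "CTL", pose),
               class = "fluorotrack_missing_calibration")
  close_session(s, 10)
  expect_error(take_radiograph(s, "AP", pose),
               class = "fluorotrack_session_closed")
})

test_that("retries follow the insertion-depth hysteresis", {
  sc <- default_scene()
  rad <- sc$rads$AP
  axis <- (rad$apex - rad$entry) / sqrt(sum((rad$apex - rad$entry)^2))
  run_depths <- function(depths) {
    s <- new_session(sc$rads, sc$cals)
    for (i in seq_along(depths))
      update_wire_state(s, rad$entry + depths[i] * axis, i)
    s
  }
  shallow <- c(-5, 1, 4, 4.9, 2, -1)        # never crosses depth_on
  expect_equal(run_depths(shallow)$retry_count, 0L)
  expect_equal(oracle_retries(shallow), 0L)

  one <- c(-5, 20, 40, -2, 30)              # insert, withdraw, re-insert
  expect_equal(run_depths(one)$retry_count, 1L)
  expect_equal(oracle_retries(one), 1L)

  two <- c(-5, 30, -3, 25, -4, 40)          # two full cycles
  expect_equal(run_depths(two)$retry_count, 2L)
  expect_equal(oracle_retries(two), 2L)

  # jitter inside the hysteresis band (0 < depth < 5) is debounced
  jitter <- c(-5, 30, 3, 1, 4, 30, -2)
  expect_equal(run_depths(jitter)$retry_count, oracle_retries(jitter))
  expect_equal(run_depths(jitter)$retry_count, 1L)
})

test_that("retry counts match the depth-scan oracle on random walks", {
  sc <- default_scene()
  rad <- sc$rads$AP
  axis <- (rad$apex - rad$entry) / sqrt(sum((rad$apex - rad$entry)^2))
  set.seed(21)
  for (rep in 1:25) {
    depths <- cumsum(rnorm(60, 0, 8))
    s <- new_session(sc$rads, sc$cals)
    for (i in seq_along(depths))
      update_wire_state(s, rad$entry + depths[i] * axis, i)
    expect_equal(s$retry_count, oracle_retries(depths))
    # counters equal an independent tally of the event log
    expect_equal(s$retry_count,
                 sum(vapply(s$events, function(e) e$event == "withdraw",
                            logical(1))))
  }
})

test_that("sessions close once, keep time, and enforce monotone timestamps", {
  sc <- default_scene()
  s <- new_session(sc$rads, sc$cals, start_time = 0)
  expect_error(update_wire_state(s, c(0, 0), -1),
               class = "fluorotrack_nonmonotone_time")
  close_session(s, 190)
  expect_equal(s$end_time - s$start_time, 190)
  expect_error(close_session(s, 200), class = "fluorotrack_session_closed")

  s2 <- new_session(sc$rads, sc$cals, start_time = 100)
  expect_error(close_session(s2, 50),
               class = "fluorotrack_nonmonotone_time")
})

test_that("the session report assembles the five metrics", {
  sc <- default_scene()
  s <- new_session(sc$rads, sc$cals, start_time = 0)
  traj <- make_insertion_trajectory(sc$rads$AP, sc$rads$CTL,
                                    n_retries = 0, n_exposures = 16,
                                    time_s = 190)
  replay_trajectory(s, traj)
  rep <- session_report(s)
  expect_equal(rep$n_radiographs, 16L)
  expect_equal(rep$n_retries, 0L)
  expect_equal(rep$time_s, 190)
  # final tip sits on the apex in both planes
  expect_equal(rep$tad_mm, 0, tolerance = 1e-9)
  expect_equal(rep$cor_pct, cor_from_tad(default_cutout_curve(), rep$tad_mm))

  # open or exposure-free sessions cannot be reported
  s3 <- new_session(sc$rads, sc$cals)
  expect_error(session_report(s3), class = "fluorotrack_session_open")
  close_session(s3, 5)
  expect_error(session_report(s3),
               class = "fluorotrack_incomplete_session")
})

test_that("the event log serializes as JSON lines", {
  sc <- default_scene()
  s <- new_session(sc$rads, sc$cals)
  pose <- wire_pose_from_markers(c(50, 60), c(120, 80), 10)
  take_radiograph(s, "AP", pose, timestamp = 2)
  update_wire_state(s, sc$rads$AP$apex, 3)
  close_session(s, 4)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(s, path)
  lines <- readLines(path)
  expect_equal(length(lines), length(s$events))
  parsed <- lapply(lines, jsonlite::fromJSON)
  expect_equal(parsed[[1]]$event, "expose")
  expect_equal(parsed[[length(parsed)]]$event, "close")
})
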