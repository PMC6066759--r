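test_that("generators are pure functions of spec and seed", {
  f1 <- make_frame(noise_sigma = 7, seed = 42)
  f2 <- make_frame(noise_sigma = 7, seed = 42)
  expect_identical(f1$frame$pixels, f2$frame$pixels)
  f3 <- make_frame(noise_sigma = 7, seed = 43)
  expect_false(identical(f1$frame$pixels, f3$frame$pixels))

  r1 <- make_radiograph(noise_sigma = 3, seed = 5)
  r2 <- make_radiograph(noise_sigma = 3, seed = 5)
  expect_identical(r1$pixels, r2$pixels)

  c1 <- make_cohort(seed = 3)
  c2 <- make_cohort(seed = 3)
  expect_identical(c1, c2)

  # the global RNG stream is left untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(make_cohort(seed = 3)); after <- runif(3)
  expect_identical(before, after)
})

test_that("marker geometry is validated", {
  expect_error(make_frame(centers = rbind(c(-5, 0), c(50, 50))),
               class = "fluorotrack_marker_out_of_frame")
  expect_error(make_frame(centers = rbind(c(50, 50), c(158, 50))),
               class = "fluorotrack_marker_out_of_frame")
  expect_error(make_frame(radius = 1),
               class = "fluorotrack_invalid_spec")
})

test_that("synthetic radiographs carry a consistent apex annotation", {
  rad <- make_radiograph()
  # apex sits on the femoral-head boundary along the neck axis
  expect_equal(sqrt(sum((rad$apex - c(230, 80))^2)), 40, tolerance = 0.5)
  # head disk is brighter than the background at its center
  expect_gt(rad$pixels[81, 231], rad$pixels[5, 5])
  # a wire tip placed exactly on the apex scores a TAD of zero
  rad2 <- make_radiograph("CTL", entry = c(60, 60), head_center = c(230, 160))
  z <- compute_tad(rad$apex, rad$apex, rad2$apex, rad2$apex,
                   mm_per_px_ap = rad$mm_per_px,
                   mm_per_px_lat = rad2$mm_per_px)
  expect_equal(z$tad_mm, 0)

  expect_error(make_radiograph(entry = c(230, 80)),
               class = "fluorotrack_geometry_error")
  expect_error(make_radiograph(head_center = c(500, 80)),
               class = "fluorotrack_geometry_error")
})

test_that("trajectory tables interleave events and carry ground truth", {
  moves <- data.frame(t_s = c(1, 5, 9), tip_x = c(0, 10, 20),
                      tip_y = c(0, 0, 0))
  exposures <- data.frame(t_s = c(3, 7), plane = c("AP", "CTL"))
  traj <- make_trajectory(moves, exposures, close_t = 12)
  expect_equal(nrow(traj), 6L)
  expect_equal(traj$event, c("move", "expose", "move", "expose", "move",
                             "close"))
  expect_equal(attr(traj, "expected")$n_radiographs, 2L)
  # exposures inherit the preceding move's tip
  expect_equal(traj$tip_x[traj$event == "expose"], c(0, 10))

  expect_error(make_trajectory(moves,
                               data.frame(t_s = c(5, 7), plane = "AP"), 12),
               class = "fluorotrack_nonmonotone_time")
})

test_that("scripted attempts replay to their ground-truth counters", {
  sc <- default_scene()
  for (want in list(c(0, 16), c(1, 7), c(2, 26))) {
    s <- new_session(sc$rads, sc$cals)
    traj <- make_insertion_trajectory(sc$rads$AP, sc$rads$CTL,
                                      n_retries = want[1],
                                      n_exposures = want[2], time_s = 190)
    replay_trajectory(s, traj)
    rep <- session_report(s)
    expect_equal(rep$n_retries, as.integer(want[1]))
    expect_equal(rep$n_radiographs, as.integer(want[2]))
    expect_equal(rep$tad_mm, attr(traj, "expected")$tad_mm,
                 tolerance = 1e-9)
    # counters equal an independent event-log tally
    evs <- vapply(s$events, `[[`, character(1), "event")
    expect_equal(rep$n_radiographs, sum(evs == "expose"))
    expect_equal(rep$n_retries, sum(evs == "withdraw"))
  }
})

test_that("trajectory CSV round-trips and replays identically", {
  sc <- default_scene()
  traj <- make_insertion_trajectory(sc$rads$AP, sc$rads$CTL,
                                    n_retries = 2, n_exposures = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  s <- new_session(sc$rads, sc$cals)
  replay_trajectory(s, back)
  close_ok <- session_report(s)
  expect_equal(close_ok$n_retries, 2L)
  expect_equal(close_ok$n_radiographs, 8L)
})

test_that("cohort generation hits its median targets and couples COR to TAD", {
  # degenerate dispersion: every member sits exactly on the median
  flat <- make_cohort(dispersion = 0, seed = 1)
  meds <- study_cohort_medians()
  for (g in meds$cohort) {
    sub <- flat[flat$cohort == g, ]
    expect_true(all(sub$tad_mm == meds$tad_mm[meds$cohort == g]))
    expect_true(all(sub$time_s == meds$time_s[meds$cohort == g]))
    expect_true(all(sub$n_radiographs == meds$n_radiographs[meds$cohort == g]))
    expect_true(all(sub$n_retries == meds$n_retries[meds$cohort == g]))
  }

  # parameter recovery at n = 201 per cohort, sigma = 0.3
  big <- make_cohort(n = c(novice = 201, intermediate = 201, expert = 201),
                     dispersion = 0.3, seed = 1)
  m <- cohort_medians(big, "tad_mm")
  expect_lt(abs(m["novice"] - 47) / 47, 0.05)
  expect_lt(abs(m["intermediate"] - 28) / 28, 0.05)
  expect_lt(abs(m["expert"] - 24) / 24, 0.05)

  # COR is a deterministic monotone map of TAD, so it commutes with the
  # median within each cohort
  curve <- default_cutout_curve()
  mc <- cohort_medians(big, "cor_pct")
  expect_equal(unname(mc), unname(cor_from_tad(curve, m)), tolerance = 1e-9)

  # ordering property: cohort TAD medians honor the target ordering
  for (seed in 1:5) {
    co <- make_cohort(n = c(novice = 100, intermediate = 100, expert = 100),
                      seed = seed)
    mm <- cohort_medians(co, "tad_mm")
    expect_true(mm["novice"] > mm["intermediate"])
    expect_true(mm["intermediate"] > mm["expert"])
  }

  expect_error(make_cohort(n = c(novice = 0, intermediate = 2, expert = 2)),
               class = "fluorotrack_invalid_spec")
  expect_error(make_cohort(dispersion = -1),
               class = "fluorotrack_invalid_spec")
})

test_that("dhs counts and Likert responses respect their cohort ranges", {
  co <- make_cohort(seed = 11)
  expect_true(all(co$dhs_count[co$cohort == "novice"] <= 9))
  expect_true(all(co$dhs_count[co$cohort == "intermediate"] %in% 10:39))
  expect_true(all(co$dhs_count[co$cohort == "expert"] >= 40))
  lik <- as.matrix(co[paste0("q", 1:4)])
  expect_true(all(lik %in% 1:7))
  # high agreement probability should dominate the tallies
  expect_gt(mean(lik >= 5), 0.6)
})

test_that("the demo bundle writes every artifact with a truthful manifest", {
  dir <- withr::local_tempdir()
  manifest <- write_fixture_bundle(dir, seed = 2)
  files <- c("frame_AP.png", "frame_CTL.png", "radiograph_AP.png",
             "radiograph_CTL.png", "calibration_AP.json",
             "calibration_CTL.json", "trajectory.csv", "cohort.csv",
             "manifest.json")
  expect_true(all(file.exists(file.path(dir, files))))

  # marker ground truth in the manifest matches what the tracker finds
  fr <- read_frame_png(file.path(dir, "frame_AP.png"))
  det <- locate_markers(fr, default_marker_specs())
  expect_lt(max(abs(det[[1]]$centroid - manifest$AP$marker_centers[1, ])),
            0.5)

  cal <- read_calibration(file.path(dir, "calibration_AP.json"))
  expect_lt(max(abs(apply_affine(cal$matrix, cal$src) - cal$dst)), 1e-6)

  cohort <- read_cohort_csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(cohort), 26L)  # 8 + 7 + 11
})
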