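test_that("linearized inverse is exact for translations, close for rotations", {
  arr <- default_array()
  expect_equal(linearized_pose(rep(0, 6), arr)$t, c(0, 0, 0))
  p <- rigid_pose(0, 0, 10)
  est <- linearized_pose(forward_readings(p, arr), arr)
  expect_equal(est$t, c(0, 0, 10), tolerance = 1e-9)
  expect_equal(est$R, diag(3), tolerance = 1e-12)
  ## 0.5 deg transverse rotation: linearized within 1%, refined exact
  R <- rotation_from_projected_angles(0, 0, 0.5)
  readings <- forward_readings(rigid_pose(0, 0, 0, R), arr)
  lin <- projected_angles_from_rotation(linearized_pose(readings, arr)$R)
  expect_lt(abs(lin[["transverse_deg"]] - 0.5) / 0.5, 0.01)
  sol <- recover_pose(readings, arr)
  expect_true(sol$converged)
  ang <- projected_angles_from_rotation(sol$pose$R)
  expect_equal(ang[["transverse_deg"]], 0.5, tolerance = 1e-8)
})

test_that("recovery round-trips poses across the study motion envelope", {
  arr <- default_array()
  set.seed(21)
  for (i in 1:100) {
    rp <- random_small_pose()
    sol <- recover_pose(forward_readings(rp$pose, arr), arr)
    expect_true(sol$converged)
    expect_lt(max(abs(sol$pose$t - rp$pose$t)), 0.01)
    ang <- projected_angles_from_rotation(sol$pose$R)
    expect_lt(max(abs(unname(ang) - rp$angles)), 1e-5)
  }
})

test_that("zero readings recover the identity immediately", {
  sol <- recover_pose(rep(0, 6), default_array())
  expect_true(sol$converged)
  expect_lte(sol$iterations, 1)
  expect_equal(sol$pose$t, c(0, 0, 0))
})

test_that("linearized and refined solutions agree to first order", {
  arr <- default_array()
  ## halving the pose should quarter the linearized-vs-refined gap
  gap <- function(s) {
    ang <- c(0.4, 0.3, -0.5) * s
    readings <- forward_readings(rigid_pose(
      0, 0, 0, rotation_from_projected_angles(ang[1], ang[2], ang[3])), arr)
    lin <- projected_angles_from_rotation(linearized_pose(readings, arr)$R)
    full <- projected_angles_from_rotation(recover_pose(readings, arr)$pose$R)
    sqrt(sum((lin - full)^2))
  }
  expect_gt(gap(1) / gap(0.5), 3.5)   # ~4 for an O(|pose|^2) difference
})

test_that("sensor noise at the resolution bound propagates to a few um", {
  arr <- default_array()
  set.seed(31)
  noise <- matrix(rnorm(6000, 0, 0.7), 1000, 6)
  df <- data.frame(time_s = seq_len(1000), noise)
  names(df) <- c("time_s", paste0("s", 1:6))
  rec <- recover_pose_series(df, arr)
  terr <- as.matrix(rec[, c("t_med_um", "t_ant_um", "t_dist_um")])
  expect_lt(max(abs(terr)), 3)
  expect_lt(stats::sd(terr), 1)
})

test_that("degenerate sensor geometry is reported with its null space", {
  bad <- sensor_array(list(
    sensor_spec(c(0, 0, 0), c(1, 0, 0), "a"),
    sensor_spec(c(0, 5, 0), c(1, 0, 0), "b"),
    sensor_spec(c(0, 0, 5), c(1, 0, 0), "c"),
    sensor_spec(c(0, 5, 5), c(1, 0, 0), "d"),
    sensor_spec(c(0, 2, 1), c(1, 0, 0), "e"),
    sensor_spec(c(0, 1, 2), c(1, 0, 0), "f")))
  expect_error(linearized_pose(rep(1, 6), bad), "singular")
  expect_error(worst_case_rotation_error(bad, 1), "singular")
})

test_that("worst-case rotation error is linear in e and vertex-attained", {
  arr <- default_array()
  expect_equal(worst_case_rotation_error(arr, 0), 0)
  w1 <- worst_case_rotation_error(arr, 1)
  expect_equal(worst_case_rotation_error(arr, 2), 2 * w1,
               tolerance = 1e-12)
  ## order of magnitude of a millidegree-scale analytic bound at the
  ## single-sensor accuracy of the emulated system
  w <- worst_case_rotation_error(arr, 1.7)
  expect_gt(w, 1e-3)
  expect_lt(w, 1e-1)
})

test_that("sensor/pose CSV round trip preserves the series", {
  arr <- default_array()
  set.seed(41)
  df <- data.frame(time_s = (0:31) / 32,
                   matrix(rnorm(32 * 6, 0, 5), 32, 6))
  names(df) <- c("time_s", paste0("s", 1:6))
  f <- tempfile(fileext = ".csv")
  data.table::fwrite(df, f)
  back <- read_sensor_csv(f)
  expect_equal(back$s3, df$s3)
  pose <- recover_pose_series(back, arr)
  f2 <- tempfile(fileext = ".csv")
  write_pose_csv(pose, f2)
  again <- as.data.frame(data.table::fread(f2))
  expect_equal(again$t_dist_um, pose$t_dist_um)
  expect_error(read_sensor_csv(f2), "columns")  # pose CSV lacks s1..s6
  unlink(c(f, f2))
})

test_that("series recovery equals per-sample recovery", {
  arr <- default_array()
  set.seed(51)
  poses <- lapply(1:10, function(i) random_small_pose())
  Y <- t(vapply(poses, function(p) forward_readings(p$pose, arr),
                numeric(6)))
  df <- data.frame(time_s = seq_len(10), Y)
  names(df) <- c("time_s", paste0("s", 1:6))
  rec <- recover_pose_series(df, arr)
  for (i in 1:10) {
    one <- recover_pose(Y[i, ], arr)$pose
    expect_equal(c(rec$t_med_um[i], rec$t_ant_um[i], rec$t_dist_um[i]),
                 one$t, tolerance = 1e-7)
    ang <- projected_angles_from_rotation(one$R) * 1e3
    expect_equal(c(rec$rot_front_mdeg[i], rec$rot_sag_mdeg[i],
                   rec$rot_trans_mdeg[i]), unname(ang), tolerance = 1e-6)
  }
})
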