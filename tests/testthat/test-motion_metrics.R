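make_pose_df <- function(ncycles, spc = 32, f = 1, distal = NULL,
                         fcc = TRUE) {
  n <- ncycles * spc
  t <- (seq_len(n) - 1) / (spc * f)
  df <- data.frame(time_s = t, t_med_um = 0, t_ant_um = 0,
                   t_dist_um = if (is.null(distal)) 0 else distal,
                   rot_front_mdeg = 0, rot_sag_mdeg = 0, rot_trans_mdeg = 0)
  if (fcc) df$Fcc_BW <- 0.4 + 1.9 * (1 + sin(2 * pi * t - pi / 2)) / 2
  df
}

test_that("cycle segmentation recovers means and cyclic excursions", {
  ## constant pose: every summary equals the pose, zero excursion
  df <- make_pose_df(5)
  df$t_dist_um <- 42
  s <- segment_cycles(df)
  expect_equal(nrow(s), 5)
  expect_equal(s$mean_t_dist_um, rep(42, 5))
  expect_equal(s$exc_t_dist_um, rep(0, 5))
  ## sinusoid in phase with the load: excursion is the full 2A swing
  A <- 7.5
  df <- make_pose_df(10)
  df$t_dist_um <- A * sin(2 * pi * df$time_s - pi / 2)
  s <- segment_cycles(df)
  expect_equal(s$mean_t_dist_um, rep(0, 10), tolerance = 1e-9)
  expect_equal(s$exc_t_dist_um, rep(2 * A, 10), tolerance = 1e-6)
  ## 3000-cycle series yields 3000 summaries
  expect_equal(nrow(segment_cycles(make_pose_df(30))), 30)
  expect_error(segment_cycles(make_pose_df(1)[1:10, ]), "incomplete")
})

test_that("migration integrates drift between cycle 100 and the step end", {
  ## drift-free series
  df <- make_pose_df(1000, spc = 8)
  s <- segment_cycles(df)
  expect_equal(max(abs(migration(s, 1000))), 0)
  ## 0.1 um/cycle linear distal drift: 90 um between cycles 100 and 1000
  df$t_dist_um <- 0.1 * df$time_s
  s <- segment_cycles(df)
  m <- migration(s, 1000)
  expect_equal(m[["distal_um"]], 90, tolerance = 1)
  expect_equal(m[["lateral_um"]], 0)
  expect_error(migration(s, 2000), "missing")
})

test_that("migration is additive over consecutive steps", {
  set.seed(13)
  df <- make_pose_df(300, spc = 8)
  df$t_dist_um <- cumsum(rnorm(nrow(df), 0.01, 0.02))
  df$rot_trans_mdeg <- cumsum(rnorm(nrow(df), -0.005, 0.01))
  s <- segment_cycles(df)
  m13 <- migration(s, 300, 100)
  m12 <- migration(s, 200, 100)
  m23 <- migration(s, 300, 200)
  expect_equal(m13, m12 + m23, tolerance = 1e-9)
})

test_that("micromotion is the detrended cyclic excursion, drift-invariant", {
  A <- 4
  base <- make_pose_df(300, spc = 16)
  base$t_dist_um <- A * sin(2 * pi * base$time_s - pi / 2)
  s0 <- segment_cycles(base)
  mm0 <- micromotion(s0, 300)
  expect_equal(mm0[["distal_um"]], 2 * A, tolerance = 1e-6)
  ## adding a strong linear drift leaves micromotion unchanged
  drifted <- base
  drifted$t_dist_um <- drifted$t_dist_um + 0.5 * drifted$time_s
  mm1 <- micromotion(segment_cycles(drifted), 300)
  expect_equal(mm1[["distal_um"]], mm0[["distal_um"]], tolerance = 0.005 * 2 * A)
  ## constant offset: no effect at all
  shifted <- base
  shifted$t_dist_um <- shifted$t_dist_um + 123
  expect_equal(micromotion(segment_cycles(shifted), 300), mm0,
               tolerance = 1e-9)
  ## half-amplitude convention
  expect_equal(micromotion(s0, 300, mode = "half-amplitude")[["distal_um"]],
               A, tolerance = 1e-6)
  expect_error(micromotion(s0, 100, n_cycles = 200), "window")
})

test_that("micromotion sign follows the peak-minus-trough convention", {
  df <- make_pose_df(300, spc = 16)
  ## anterior motion opposing the load: negative excursion
  df$t_ant_um <- -3 * sin(2 * pi * df$time_s - pi / 2)
  mm <- micromotion(segment_cycles(df), 300)
  expect_equal(mm[["anterior_um"]], -6, tolerance = 1e-6)
})

test_that("sensor-level noise leaves micromotion below a 2 um floor", {
  set.seed(17)
  reps <- vapply(1:20, function(i) {
    df <- make_pose_df(250, spc = 16)
    for (cc in c("t_med_um", "t_ant_um", "t_dist_um"))
      df[[cc]] <- rnorm(nrow(df), 0, 0.5)
    mm <- micromotion(segment_cycles(df), 250)
    max(abs(mm[c("lateral_um", "anterior_um", "distal_um")]))
  }, numeric(1))
  expect_lt(max(reps), 2)
})

test_that("resultants combine components as norms and helical angles", {
  r <- resultants(62, 39, 385, 0, 0, 0)
  expect_equal(r[["total_trans_um"]], sqrt(62^2 + 39^2 + 385^2))
  expect_equal(round(r[["total_trans_um"]], 1), 391.9)
  expect_equal(resultants(0, -17, 0, 0, 0, 0)[["total_trans_um"]], 17)
  ## pure transverse rotation: helical resultant equals |angle|
  expect_equal(resultants(0, 0, 0, 0, 0, -1175)[["total_rot_mdeg"]], 1175,
               tolerance = 1e-6)
})

test_that("step metrics assemble table-layout rows per loading phase", {
  df <- make_pose_df(900, spc = 8)
  df$phase <- rep(c("fap0.0", "fap0.3", "fap0.6"), each = 2400)
  df$t_dist_um <- 0.05 * df$time_s +
    3 * sin(2 * pi * df$time_s - pi / 2)
  sm <- step_metrics(df, reference_cycle = 100, micromotion_cycles = 100)
  expect_equal(nrow(sm), 3)
  expect_equal(sm$phase, c("fap0.0", "fap0.3", "fap0.6"))
  expect_equal(sm$migration_distal_um, c(10, 25, 40), tolerance = 0.5)
  expect_equal(sm$micromotion_distal_um, rep(6, 3), tolerance = 0.01)
  expect_equal(sm$total_trans_migration_um, abs(sm$migration_distal_um),
               tolerance = 1e-9)
})
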