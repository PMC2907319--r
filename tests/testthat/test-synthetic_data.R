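elastic_only_model <- function(compliance, noise = 0) {
  specimen_model(compliance = compliance, noise_sd_um = noise)
}

test_that("elastic-only specimens return compliance * delta-load micromotion", {
  C <- matrix(c(2, 1, 0,
                -1, 3, 0,
                5, 2, 0,
                4, 6, 0,
                0.5, 8, 0,
                0, -12, 0), 6, 3, byrow = TRUE)
  m <- elastic_only_model(C)
  sch <- reference_schedule(FALSE, 300)
  sim <- simulate_specimen(m, sch, reference_geometry(FALSE), default_array(),
                           16, seed = 1)
  pose <- recover_pose_series(sim, default_array())
  sm <- step_metrics(pose, reference_cycle = 100, micromotion_cycles = 200)
  dF <- list(c(1.9, 0), c(1.9, 0.4), c(1.9, 0.7))
  for (p in 1:3) {
    want <- C[, 1] * dF[[p]][1] + C[, 2] * dF[[p]][2]
    got <- c(-sm$micromotion_lateral_um[p], sm$micromotion_anterior_um[p],
             sm$micromotion_distal_um[p], sm$micromotion_frontal_mdeg[p],
             sm$micromotion_sagittal_mdeg[p],
             sm$micromotion_transverse_mdeg[p])
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("simulation is deterministic for a fixed seed", {
  pre <- reference_preset(8, 300)
  a <- simulate_specimen(pre$model_no_abductor, reference_schedule(FALSE, 300),
                         reference_geometry(FALSE), default_array(), 8, seed = 77)
  b <- simulate_specimen(pre$model_no_abductor, reference_schedule(FALSE, 300),
                         reference_geometry(FALSE), default_array(), 8, seed = 77)
  expect_identical(a, b)
  c_ <- simulate_specimen(pre$model_no_abductor, reference_schedule(FALSE, 300),
                          reference_geometry(FALSE), default_array(), 8,
                          seed = 78)
  expect_false(identical(a$s1, c_$s1))
})

test_that("pipeline recovers programmed drift and micromotion", {
  pre <- reference_preset(16, 300)
  m <- pre$model_no_abductor
  m$noise_sd_um <- 0
  sch <- reference_schedule(FALSE, 300)
  g <- reference_geometry(FALSE)
  sim <- simulate_specimen(m, sch, g, default_array(), 16, seed = 1)
  pose <- recover_pose_series(sim, default_array())
  sm <- step_metrics(pose, reference_cycle = 100, micromotion_cycles = 200)
  truth <- programmed_step_metrics(m, sch, g, 16)
  mig_cols <- grep("^migration_", names(truth), value = TRUE)
  mic_cols <- grep("^micromotion_", names(truth), value = TRUE)
  expect_lt(max(abs(as.matrix(sm[mig_cols]) - as.matrix(truth[mig_cols]))),
            2)
  expect_lt(max(abs(as.matrix(sm[mic_cols]) - as.matrix(truth[mic_cols]))),
            0.5)
})

test_that("cohort generation writes 12 specimens with a truthful manifest", {
  cfg <- mini_config(noise_sd_um = 0, n_per_group = 6)
  d <- file.path(tempdir(), "cohort_test")
  unlink(d, recursive = TRUE)
  man <- generate_cohort(cfg, d)
  files <- list.files(d, pattern = "_sensors\\.csv$")
  expect_length(files, 12)
  expect_length(man$specimens, 12)
  expect_equal(sum(vapply(man$specimens, function(s)
    s$group == "abductor", logical(1))), 6)
  expect_true(file.exists(file.path(d, "manifest.json")))
  ## manifest seeds are reproducible derivations of the master seed
  expect_equal(man$specimens[[3]]$noise_seed,
               (cfg$master_seed + 7919 * 3) %% 2147483647)
  unlink(d, recursive = TRUE)
})

test_that("zero inter-specimen variability gives identical group members", {
  cfg <- mini_config(noise_sd_um = 0)
  cfg$sdlog_compliance <- 0
  cfg$sdlog_ratchet <- 0
  tab <- sample_cohort_metrics(cfg, seed = 5, noise_floor_trans_um = 0,
                               noise_floor_rot_mdeg = 0)
  sp <- split(tab, list(tab$group, tab$metric, tab$fap_level), drop = TRUE)
  for (cell in sp) expect_lt(diff(range(cell$value)), 1e-9)
})

test_that("transverse micromotion magnitude grows with the F_ap peak", {
  pre <- reference_preset()
  for (m in list(pre$model_no_abductor, pre$model_abductor)) {
    for (g in list(reference_geometry(FALSE), reference_geometry(TRUE))) {
      sm <- programmed_step_metrics(m, reference_schedule(g$abductor_enabled),
                                    g, 32)
      expect_true(all(diff(abs(sm$micromotion_transverse_mdeg)) > -1e-9))
    }
  }
})

test_that("abductor attenuation separates groups only beyond the threshold", {
  pre <- reference_preset()
  template <- pre$model_no_abductor
  template$noise_sd_um <- 0
  attenuated <- template
  attenuated$abductor_attenuation <- 0.2
  base <- programmed_step_metrics(template, reference_schedule(FALSE),
                                  reference_geometry(FALSE), 32)
  att <- programmed_step_metrics(attenuated, reference_schedule(TRUE),
                                 reference_geometry(TRUE), 32)
  d <- abs(att$migration_distal_um - base$migration_distal_um)
  ## identical at F_ap peaks 0 and 0.3 BW (excess zero), separated at 0.6
  expect_lt(d[1], 1e-9)
  expect_lt(d[2], 1e-9)
  expect_gt(d[3], 50)
})

test_that("compliance is recoverable from micromotion at working noise", {
  pre <- reference_preset(16, 300)
  m <- pre$model_no_abductor
  m$noise_sd_um <- 0.5
  sch <- reference_schedule(FALSE, 300)
  sim <- simulate_specimen(m, sch, reference_geometry(FALSE), default_array(),
                           16, seed = 3)
  pose <- recover_pose_series(sim, default_array())
  sm <- step_metrics(pose, reference_cycle = 100, micromotion_cycles = 200)
  ## distal F_cc compliance from the no-torque phase: micromotion / 1.9
  expect_equal(sm$micromotion_distal_um[1] / 1.9, m$compliance[3, 1],
               tolerance = 0.05 * abs(m$compliance[3, 1]))
})

test_that("calibrated preset means sit inside the reference intervals", {
  pre <- reference_preset()
  tabs <- reference_tables()
  for (grp in c("group1", "group2")) {
    model <- if (grp == "group1") pre$model_no_abductor else
      pre$model_abductor
    sm <- programmed_step_metrics(model, reference_schedule(grp == "group2"),
                                  reference_geometry(grp == "group2"), 32)
    for (kind in c("migration", "micromotion")) {
      tab <- tabs[[kind]]
      for (comp in c("distal_um", "transverse_mdeg")) {
        rows <- tab[tab$component == comp, ]
        vals <- sm[[paste0(kind, "_", comp)]]
        for (k in 1:3) {
          mu <- rows[[paste0(grp, "_mean")]][k]
          ci <- rows[[paste0(grp, "_ci")]][k]
          expect_gte(vals[k], mu - ci)
          expect_lte(vals[k], mu + ci)
        }
      }
    }
  }
})
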