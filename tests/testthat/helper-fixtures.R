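## Shared fixtures and independent oracles used across the test files.

## Independent axis-angle rotation constructor (Rodrigues form written
## out directly; deliberately not the package's rotvec helper).
oracle_axis_angle <- function(axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Quaternion product oracle for rotation composition / angle.
quat_from_matrix <- function(R) {
  w <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
  if (w > 1e-8) {
    c(w, (R[3, 2] - R[2, 3]) / (4 * w), (R[1, 3] - R[3, 1]) / (4 * w),
      (R[2, 1] - R[1, 2]) / (4 * w))
  } else stop("quaternion oracle needs angle < 180 deg")
}
quat_angle_deg <- function(q) 2 * acos(min(1, abs(q[1]))) * 180 / pi

random_small_pose <- function(t_range = 300, ang_range = 1.2) {
  ang <- stats::runif(3, -ang_range, ang_range)
  list(pose = rigid_pose(stats::runif(1, -t_range, t_range),
                         stats::runif(1, -t_range, t_range),
                         stats::runif(1, -t_range, t_range),
                         rotation_from_projected_angles(ang[1], ang[2],
                                                        ang[3])),
       angles = ang)
}

## Small, fast cohort configuration used by pipeline-level tests:
## 2 specimens per group, 300-cycle phases, 8 samples per cycle.
mini_config <- function(noise_sd_um = 0.5, n_per_group = 2,
                        seed = 101) {
  pre <- reference_preset(samples_per_cycle = 8, cycles_per_phase = 300)
  pre$n_per_group <- as.integer(n_per_group)
  pre$master_seed <- as.integer(seed)
  pre$model_no_abductor$noise_sd_um <- noise_sd_um
  pre$model_abductor$noise_sd_um <- noise_sd_um
  pre
}

## Null cohort template: no F_ap effect on the elastic response and no
## load-dependent ratchet, identical in both groups, so the group x
## F_ap interaction is null for micromotion metrics.
null_cohort_config <- function(seed = 1) {
  pre <- reference_preset()
  m <- pre$model_no_abductor
  m$compliance[, 2] <- 0
  m$ap_excess_compliance[] <- 0
  m$ratchet_gain[] <- 0
  cohort_config(6, m, m, sdlog_compliance = 0.3, sdlog_ratchet = 0.3,
                master_seed = seed)
}

## Long-format cohort table builder for ANOVA tests.
long_table <- function(values, groups, metric = "m",
                       fap_levels = c(0, 0.3, 0.6)) {
  ## values: matrix subjects x levels
  n <- nrow(values)
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(specimen_id = sprintf("s%02d", i), group = groups[i],
               fap_level = fap_levels, metric = metric,
               value = as.numeric(values[i, ]))))
}
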