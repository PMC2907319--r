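## Synthetic specimen and cohort generator.
##
## A virtual specimen responds to the applied loads with (i) a
## quasi-static elastic pose, linear in (F_cc, F_ap, F_abd) through a
## 6x3 compliance matrix plus a threshold term proportional to
## max(F_ap - F0, 0) (torsional load exceeding the interface friction
## threshold engages extra compliance - a purely linear law cannot
## reproduce the strongly nonlinear transverse response seen between
## walking and stair-climbing torque levels); and (ii) a cumulative
## ratcheting drift: each cycle adds a per-component increment
## (base + gain * attenuation * max(F_ap_peak - F0, 0)^exponent) *
## exp(-k / saturation_cycles), with k the cycle index within the phase,
## so the drift settles exponentially within each loading phase. The
## abductor attenuation multiplies only the load-excess gain, so groups
## differ only once F_ap exceeds the threshold. Sensor noise is i.i.d.
## Gaussian per sample (default sd 0.5 um, below the 0.7 um resolution
## of the measurement system being emulated).
##
## Component order of all 6-vectors and compliance rows: medial um,
## anterior um, distal um, frontal mdeg, sagittal mdeg, transverse mdeg
## (the core frame; reporting flips medial to lateral).

#' Synthetic specimen model
#'
#' @param compliance 6x3 matrix: pose components (um or mdeg, rows in
#'   the order medial, anterior, distal, frontal, sagittal, transverse)
#'   per unit (F_cc, F_ap, F_abd) in xBW.
#' @param ap_excess_compliance Length-6: extra compliance per unit
#'   `max(F_ap - ap_threshold_BW, 0)`.
#' @param ap_threshold_BW Torque engagement threshold, xBW (0.3).
#' @param ratchet_base Length-6 per-cycle drift increment at reference
#'   load (um or mdeg per cycle before settling).
#' @param ratchet_gain Length-6 additional increment per
#'   `(F_ap_peak - threshold)^exponent`.
#' @param ratchet_load_exponent Dose exponent on the F_ap excess.
#' @param saturation_cycles Exponential settling constant, cycles.
#' @param abductor_attenuation Factor in (0, 1] applied to
#'   `ratchet_gain` when the abductor load is present.
#' @param noise_sd_um Sensor noise standard deviation, um.
#' @return Object of class `specimen_model`.
#' @export
specimen_model <- function(compliance,
                           ap_excess_compliance = numeric(6),
                           ap_threshold_BW = 0.3,
                           ratchet_base = numeric(6),
                           ratchet_gain = numeric(6),
                           ratchet_load_exponent = 1,
                           saturation_cycles = 300,
                           abductor_attenuation = 1,
                           noise_sd_um = 0.5) {
  compliance <- as.matrix(compliance)
  if (!all(dim(compliance) == c(6L, 3L)))
    stop("compliance must be a 6x3 matrix")
  if (!is.finite(noise_sd_um) || noise_sd_um < 0)
    stop("noise_sd_um must be >= 0")
  if (!is.finite(saturation_cycles) || saturation_cycles <= 0)
    stop("saturation_cycles must be > 0")
  if (abductor_attenuation <= 0 || abductor_attenuation > 1)
    stop("abductor_attenuation must lie in (0, 1]")
  structure(list(compliance = unname(compliance),
                 ap_excess_compliance = as.numeric(ap_excess_compliance),
                 ap_threshold_BW = ap_threshold_BW,
                 ratchet_base = as.numeric(ratchet_base),
                 ratchet_gain = as.numeric(ratchet_gain),
                 ratchet_load_exponent = ratchet_load_exponent,
                 saturation_cycles = saturation_cycles,
                 abductor_attenuation = abductor_attenuation,
                 noise_sd_um = noise_sd_um),
            class = "specimen_model")
}

scale_specimen <- function(model, compliance_mult = 1, ratchet_mult = 1) {
  model$compliance <- model$compliance * compliance_mult
  model$ap_excess_compliance <- model$ap_excess_compliance * compliance_mult
  model$ratchet_base <- model$ratchet_base * ratchet_mult
  model$ratchet_gain <- model$ratchet_gain * ratchet_mult
  model
}

## True pose components (n x 6, um / mdeg) for every sample of a
## waveform: elastic response + per-cycle ratcheting drift (linear
## within a cycle so that cycle means sit at D(k-1) + inc_k / 2).
pose_components <- function(model, waveform, samples_per_cycle) {
  spc <- as.integer(samples_per_cycle)
  loads <- cbind(waveform$Fcc_BW, waveform$Fap_BW, waveform$Fabd_BW)
  X <- loads %*% t(model$compliance)
  excess <- pmax(waveform$Fap_BW - model$ap_threshold_BW, 0)
  X <- X + outer(excess, model$ap_excess_compliance)
  ## per-cycle increments
  ncyc <- max(waveform$cycle)
  cyc1 <- match(seq_len(ncyc), waveform$cycle)       # first sample of cycle
  fap_peak <- vapply(seq_len(ncyc), function(k)
    max(waveform$Fap_BW[waveform$cycle == k][1:spc]), numeric(1))
  ## (identical within a phase; computed per cycle for generality)
  ph <- as.integer(waveform$phase[cyc1])
  kin <- stats::ave(seq_len(ncyc), ph, FUN = seq_along)  # cycle within phase
  abd <- waveform$Fabd_BW[cyc1] > 0
  att <- ifelse(abd, model$abductor_attenuation, 1)
  ex_pk <- pmax(fap_peak - model$ap_threshold_BW, 0)^model$ratchet_load_exponent
  settle <- exp(-kin / model$saturation_cycles)
  frac <- (rep(seq_len(spc), ncyc) - 0.5) / spc
  for (c in seq_len(6)) {
    inc <- (model$ratchet_base[c] + model$ratchet_gain[c] * att * ex_pk) *
      settle
    D_before <- c(0, cumsum(inc))[seq_len(ncyc)]
    X[, c] <- X[, c] + rep(D_before, each = spc) + rep(inc, each = spc) * frac
  }
  colnames(X) <- c("t_med_um", "t_ant_um", "t_dist_um",
                   "rot_front_mdeg", "rot_sag_mdeg", "rot_trans_mdeg")
  X
}

## Exact rotation vectors (radians, n x 3) for projected plane angles
## given as an n x 3 matrix (frontal, sagittal, transverse; degrees).
rotvec_rows_from_angles <- function(A) {
  b <- A[, 1] * DEG2RAD; a <- A[, 2] * DEG2RAD; g <- A[, 3] * DEG2RAD
  cb <- cos(b); sb <- sin(b); ca <- cos(a); sa <- sin(a)
  cg <- cos(g); sg <- sin(g)
  ## R = Rz(g) Rx(a) Ry(b)
  R11 <- cg * cb - sg * sa * sb; R12 <- -sg * ca; R13 <- cg * sb + sg * sa * cb
  R21 <- sg * cb + cg * sa * sb; R22 <- cg * ca; R23 <- sg * sb - cg * sa * cb
  R31 <- -ca * sb; R32 <- sa; R33 <- ca * cb
  tr <- R11 + R22 + R33
  th <- acos(pmax(-1, pmin(1, (tr - 1) / 2)))
  ax1 <- R32 - R23; ax2 <- R13 - R31; ax3 <- R21 - R12
  f <- ifelse(th < 1e-8, 0.5 + th^2 / 12,
              th / (2 * pmax(sin(th), 1e-300)))
  cbind(f * ax1, f * ax2, f * ax3)
}

#' Simulate one specimen's sensor time series
#'
#' Forward chain: load waveform -> true pose (elastic + ratchet) ->
#' six LVDT readings through the sensor forward model -> additive
#' Gaussian sensor noise. Deterministic for a fixed seed. The output
#' carries the applied loads alongside the readings so downstream stages
#' can locate load peaks.
#'
#' @param model A [specimen_model()].
#' @param schedule A [load_schedule()].
#' @param geometry A [rig_geometry()].
#' @param array A [sensor_array()].
#' @param samples_per_cycle Samples per load cycle.
#' @param seed Integer seed for the sensor noise.
#' @param path Optional CSV destination; when given, the data frame is
#'   written there and the path returned invisibly.
#' @return Data frame `time_s, s1..s6, cycle, phase, Fcc_BW, Fap_BW,
#'   Fabd_BW` (or the path).
#' @export
simulate_specimen <- function(model, schedule, geometry, array,
                              samples_per_cycle = 32, seed = 1,
                              path = NULL) {
  stopifnot(inherits(model, "specimen_model"))
  wf <- load_waveform(schedule, geometry, samples_per_cycle)
  P <- pose_components(model, wf, samples_per_cycle)
  W <- rotvec_rows_from_angles(P[, c("rot_front_mdeg", "rot_sag_mdeg",
                                     "rot_trans_mdeg")] * 1e-3)
  X <- cbind(P[, 1:3], W * 1e3)     # t um, w mrad
  Y <- forward_readings_matrix(X, array)
  if (model$noise_sd_um > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
    Y <- Y + matrix(stats::rnorm(length(Y), 0, model$noise_sd_um),
                    nrow(Y), 6)
  }
  colnames(Y) <- paste0("s", 1:6)
  out <- data.frame(time_s = wf$time_s, Y, cycle = wf$cycle,
                    phase = wf$phase, Fcc_BW = wf$Fcc_BW,
                    Fap_BW = wf$Fap_BW, Fabd_BW = wf$Fabd_BW)
  if (!is.null(path)) {
    data.table::fwrite(out, path)
    return(invisible(path))
  }
  out
}

## Discrete one-cycle statistics of a phase's waveform, matching
## load_waveform's sampling exactly.
phase_cycle_stats <- function(phase, samples_per_cycle, threshold) {
  shape <- (1 + sin(2 * pi * (seq_len(samples_per_cycle) - 1) /
                      samples_per_cycle - pi / 2)) / 2
  fcc <- phase$F_cc_min + (phase$F_cc_max - phase$F_cc_min) * shape
  fap <- phase$F_ap_min + (phase$F_ap_max - phase$F_ap_min) * shape
  ex <- pmax(fap - threshold, 0)
  pk <- which.max(fcc); tr <- which.min(fcc)
  list(mean = c(mean(fcc), mean(fap), phase$F_abd), mean_ex = mean(ex),
       delta = c(fcc[pk] - fcc[tr], fap[pk] - fap[tr], 0),
       delta_ex = ex[pk] - ex[tr],
       fap_peak = max(fap))
}

settle_sum <- function(a, b, tau) {
  q <- exp(-1 / tau)
  (q^a - q^(b + 1)) / (1 - q)
}

#' Programmed (ground-truth) step metrics of a specimen model
#'
#' Computes analytically, without simulating sensors, the migration and
#' micromotion a noise-free pipeline run would extract from the model:
#' migration combines the cumulative ratchet drift (closed-form
#' geometric sums of the settling increments, including the half-cycle
#' offset of a cycle mean) with the elastic shift due to phase-to-phase
#' changes in cycle-mean load; micromotion is the elastic peak-to-trough
#' excursion at the load extrema. Serves both as the oracle for the
#' simulate -> recover -> metrics round trip and as the fast path for
#' cohort-level statistical simulation.
#'
#' @inheritParams simulate_specimen
#' @param reference_cycle Pre-conditioning boundary (100).
#' @return Data frame in the layout of [step_metrics()].
#' @export
programmed_step_metrics <- function(model, schedule, geometry,
                                    samples_per_cycle = 32,
                                    reference_cycle = 100) {
  stopifnot(inherits(model, "specimen_model"),
            inherits(schedule, "load_schedule"))
  phases <- schedule$phases
  tau <- model$saturation_cycles
  st <- lapply(phases, phase_cycle_stats, samples_per_cycle,
               model$ap_threshold_BW)
  ## drift rate per phase per component
  rate <- vapply(seq_along(phases), function(p) {
    att <- if (phases[[p]]$F_abd > 0) model$abductor_attenuation else 1
    ex <- max(st[[p]]$fap_peak - model$ap_threshold_BW, 0)^
      model$ratchet_load_exponent
    model$ratchet_base + model$ratchet_gain * att * ex
  }, numeric(6))                                     # 6 x nphase
  rows <- vector("list", length(phases))
  drift_at_end <- matrix(0, 6, length(phases))       # cycle-mean drift
  carried <- numeric(6)                              # drift at phase starts
  for (p in seq_along(phases)) {
    nc <- phases[[p]]$cycles
    within <- settle_sum(1, nc - 1, tau) + exp(-nc / tau) / 2
    drift_at_end[, p] <- carried + rate[, p] * within
    carried <- carried + rate[, p] * settle_sum(1, nc, tau)
  }
  ## reference: cycle-mean drift at reference_cycle (in phase 1)
  nr <- reference_cycle
  ref_drift <- rate[, 1] * (settle_sum(1, nr - 1, tau) + exp(-nr / tau) / 2)
  ref_elastic <- model$compliance %*% st[[1]]$mean +
    model$ap_excess_compliance * st[[1]]$mean_ex
  for (p in seq_along(phases)) {
    el <- model$compliance %*% st[[p]]$mean +
      model$ap_excess_compliance * st[[p]]$mean_ex
    mig <- as.numeric(el - ref_elastic) + drift_at_end[, p] - ref_drift
    mic <- as.numeric(model$compliance %*% st[[p]]$delta) +
      model$ap_excess_compliance * st[[p]]$delta_ex
    ## net rotations for the resultants
    ang_ref <- (model$compliance[4:6, ] %*% st[[1]]$mean +
                model$ap_excess_compliance[4:6] * st[[1]]$mean_ex +
                ref_drift[4:6]) * 1e-3
    ang_last <- ang_ref + mig[4:6] * 1e-3
    R_ref <- rotation_from_projected_angles(ang_ref[1], ang_ref[2], ang_ref[3])
    R_last <- rotation_from_projected_angles(ang_last[1], ang_last[2],
                                             ang_last[3])
    R_mic <- rotation_from_projected_angles(mic[4] * 1e-3, mic[5] * 1e-3,
                                            mic[6] * 1e-3)
    rows[[p]] <- data.frame(
      phase = phases[[p]]$name,
      migration_lateral_um = -mig[1],
      migration_anterior_um = mig[2],
      migration_distal_um = mig[3],
      migration_sagittal_mdeg = mig[5],
      migration_frontal_mdeg = mig[4],
      migration_transverse_mdeg = mig[6],
      micromotion_lateral_um = -mic[1],
      micromotion_anterior_um = mic[2],
      micromotion_distal_um = mic[3],
      micromotion_sagittal_mdeg = mic[5],
      micromotion_frontal_mdeg = mic[4],
      micromotion_transverse_mdeg = mic[6],
      total_trans_migration_um = sqrt(sum(mig[1:3]^2)),
      total_rot_migration_mdeg =
        helical_rotation_angle(R_last %*% t(R_ref)) * 1e3,
      total_trans_micromotion_um = sqrt(sum(mic[1:3]^2)),
      total_rot_micromotion_mdeg = helical_rotation_angle(R_mic) * 1e3)
  }
  do.call(rbind, rows)
}

#' Cohort configuration
#'
#' @param n_per_group Specimens per group (6).
#' @param model_no_abductor,model_abductor Group [specimen_model()]
#'   templates.
#' @param sdlog_compliance,sdlog_ratchet Between-specimen lognormal
#'   variability (sd of log multiplier) on the elastic and ratchet
#'   parameters; multipliers are mean-one (`meanlog = -sdlog^2 / 2`).
#' @param master_seed Master seed; per-specimen seeds are derived as
#'   `(master_seed + 7919 * index) mod (2^31 - 1)`.
#' @param samples_per_cycle Samples per cycle.
#' @param cycles_per_phase Cycles per loading phase.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 6,
                          model_no_abductor, model_abductor,
                          sdlog_compliance = 0.3, sdlog_ratchet = 0.3,
                          master_seed = 20100624,
                          samples_per_cycle = 32,
                          cycles_per_phase = 1000) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  structure(list(n_per_group = as.integer(n_per_group),
                 model_no_abductor = model_no_abductor,
                 model_abductor = model_abductor,
                 sdlog_compliance = sdlog_compliance,
                 sdlog_ratchet = sdlog_ratchet,
                 master_seed = as.integer(master_seed),
                 samples_per_cycle = as.integer(samples_per_cycle),
                 cycles_per_phase = as.integer(cycles_per_phase)),
            class = "cohort_config")
}

specimen_seed <- function(master_seed, index)
  as.integer((as.double(master_seed) + 7919 * index) %% 2147483647)

cohort_plan <- function(config, seed = config$master_seed) {
  ## deterministic per-specimen multipliers and seeds
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- config$n_per_group
  plan <- data.frame(
    specimen_id = sprintf("sp%02d", seq_len(2 * n)),
    group = rep(c("no_abductor", "abductor"), each = n),
    compliance_mult = stats::rlnorm(2 * n,
                                    -config$sdlog_compliance^2 / 2,
                                    config$sdlog_compliance),
    ratchet_mult = stats::rlnorm(2 * n, -config$sdlog_ratchet^2 / 2,
                                 config$sdlog_ratchet))
  plan$noise_seed <- specimen_seed(seed, seq_len(2 * n))
  plan
}

cohort_member <- function(config, plan_row) {
  template <- if (plan_row$group == "abductor") config$model_abductor
              else config$model_no_abductor
  scale_specimen(template, plan_row$compliance_mult, plan_row$ratchet_mult)
}

#' Generate a full synthetic cohort
#'
#' Writes one sensor CSV per specimen (two groups of `n_per_group`,
#' each an independently perturbed copy of its group template) plus a
#' `manifest.json` recording the configuration, per-specimen seeds,
#' multipliers and the programmed (ground-truth) step metrics that a
#' noise-free analysis should recover.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$master_seed` when given.
#' @return The manifest, invisibly (a list).
#' @export
generate_cohort <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) seed <- config$master_seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plan <- cohort_plan(config, seed)
  sched <- list(no_abductor = reference_schedule(FALSE, config$cycles_per_phase),
                abductor = reference_schedule(TRUE, config$cycles_per_phase))
  geom <- list(no_abductor = reference_geometry(FALSE),
               abductor = reference_geometry(TRUE))
  array <- default_array()
  specimens <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    g <- plan$group[i]
    model <- cohort_member(config, plan[i, ])
    f <- file.path(out_dir, paste0(plan$specimen_id[i], "_sensors.csv"))
    simulate_specimen(model, sched[[g]], geom[[g]], array,
                      config$samples_per_cycle, plan$noise_seed[i], path = f)
    truth <- programmed_step_metrics(model, sched[[g]], geom[[g]],
                                     config$samples_per_cycle)
    specimens[[i]] <- list(specimen_id = plan$specimen_id[i], group = g,
                           file = basename(f),
                           noise_seed = plan$noise_seed[i],
                           compliance_mult = plan$compliance_mult[i],
                           ratchet_mult = plan$ratchet_mult[i],
                           programmed_metrics = truth)
  }
  manifest <- list(master_seed = seed,
                   n_per_group = config$n_per_group,
                   samples_per_cycle = config$samples_per_cycle,
                   cycles_per_phase = config$cycles_per_phase,
                   sdlog_compliance = config$sdlog_compliance,
                   sdlog_ratchet = config$sdlog_ratchet,
                   variability_model = paste(
                     "independent mean-one lognormal multipliers per",
                     "specimen on compliance and ratchet (true",
                     "between-specimen covariance is unknowable from",
                     "summary tables)"),
                   specimens = specimens)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Fast metric-level cohort sampler
#'
#' Draws a cohort's per-specimen step metrics directly from the
#' generator's analytic ground truth ([programmed_step_metrics()] under
#' the per-specimen lognormal multipliers) plus a small metric-level
#' noise floor emulating propagated sensor noise (sd
#' `noise_floor_trans_um` on translations and migration resultants,
#' `noise_floor_rot_mdeg` on rotations). Used for simulation studies
#' (type-I error, seed sweeps) where running the full sensor pipeline
#' hundreds of times would add nothing but the already-validated
#' recovery step.
#'
#' @param config A [cohort_config()].
#' @param seed Cohort seed.
#' @param noise_floor_trans_um,noise_floor_rot_mdeg Metric-level noise.
#' @return Long-format cohort table: `specimen_id, group, phase,
#'   fap_level, metric, value`.
#' @export
sample_cohort_metrics <- function(config, seed = config$master_seed,
                                  noise_floor_trans_um = 0.8,
                                  noise_floor_rot_mdeg = 2) {
  stopifnot(inherits(config, "cohort_config"))
  plan <- cohort_plan(config, seed)
  sched <- list(no_abductor = reference_schedule(FALSE, config$cycles_per_phase),
                abductor = reference_schedule(TRUE, config$cycles_per_phase))
  geom <- list(no_abductor = reference_geometry(FALSE),
               abductor = reference_geometry(TRUE))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(specimen_seed(seed, 424243L))
  out <- vector("list", nrow(plan))
  fap_levels <- c(0, 0.3, 0.6)
  for (i in seq_len(nrow(plan))) {
    g <- plan$group[i]
    model <- cohort_member(config, plan[i, ])
    sm <- programmed_step_metrics(model, sched[[g]], geom[[g]],
                                  config$samples_per_cycle)
    long <- metrics_to_long(sm, plan$specimen_id[i], g,
                            fap_levels[seq_len(nrow(sm))])
    trans <- grepl("_um$", long$metric)
    long$value <- long$value + stats::rnorm(nrow(long)) *
      ifelse(trans, noise_floor_trans_um, noise_floor_rot_mdeg)
    out[[i]] <- long
  }
  do.call(rbind, out)
}

metrics_to_long <- function(step_df, specimen_id, group, fap_levels) {
  metric_cols <- setdiff(names(step_df), "phase")
  do.call(rbind, lapply(seq_len(nrow(step_df)), function(k) {
    data.frame(specimen_id = specimen_id, group = group,
               phase = step_df$phase[k], fap_level = fap_levels[k],
               metric = metric_cols,
               value = as.numeric(step_df[k, metric_cols]),
               row.names = NULL)
  }))
}

#' Reference cohort summary tables
#'
#' The published group means and 95% confidence half-widths (two groups
#' of six specimens, three F_ap levels, six migration and six
#' micromotion components) that the synthetic preset is calibrated to.
#'
#' @return List with data frames `migration` and `micromotion`.
#' @export
reference_tables <- function() {
  read1 <- function(f) as.data.frame(data.table::fread(
    system.file("extdata", f, package = "stemstab", mustWork = TRUE)))
  list(migration = read1("reference_migration.csv"),
       micromotion = read1("reference_micromotion.csv"))
}

## Solve one group's model parameters from the reference tables.
## Micromotion rows give the compliance columns (F_cc from the F_ap = 0
## excursion, F_ap from the walking-phase change, threshold column from
## the stair-climb change); migration rows give the ratchet base (from
## the first phase) and gain (from the stair-climb increment), after
## removing the elastic cycle-mean shifts.
calibrate_group_model <- function(mig, mic, group, tau = 300,
                                  samples_per_cycle = 32,
                                  noise_sd_um = 0.5) {
  mcol <- paste0(group, "_mean")
  comp_order <- c("lateral_um", "anterior_um", "distal_um",
                  "frontal_mdeg", "sagittal_mdeg", "transverse_mdeg")
  sgn <- c(-1, 1, 1, 1, 1, 1)        # table lateral -> core medial
  get6 <- function(tab, fap) {
    v <- vapply(comp_order, function(cc)
      tab[[mcol]][tab$component == cc & tab$fap_BW == fap], numeric(1))
    v * sgn
  }
  sched <- reference_schedule(abductor = group == "group2")
  st <- lapply(sched$phases, phase_cycle_stats, samples_per_cycle, 0.3)
  mm <- cbind(get6(mic, 0), get6(mic, 0.3), get6(mic, 0.6))
  C_cc <- mm[, 1] / st[[1]]$delta[1]
  C_ap <- (mm[, 2] - mm[, 1]) / st[[2]]$delta[2]
  C_x <- (mm[, 3] - C_cc * st[[3]]$delta[1] - C_ap * st[[3]]$delta[2]) /
    st[[3]]$delta_ex
  compliance <- cbind(C_cc, C_ap, c(0.5, -0.2, 1.5, 0.3, 0.1, 0.2))
  ## elastic migration contribution per phase (cycle-mean load shifts)
  el <- vapply(1:3, function(p)
    C_cc * (st[[p]]$mean[1] - st[[1]]$mean[1]) +
    C_ap * (st[[p]]$mean[2] - st[[1]]$mean[2]) +
    C_x * (st[[p]]$mean_ex - st[[1]]$mean_ex), numeric(6))
  mg <- cbind(get6(mig, 0), get6(mig, 0.3), get6(mig, 0.6)) - el
  nc <- 1000
  W1 <- settle_sum(100, nc - 1, tau) + (exp(-nc / tau) - exp(-100 / tau)) / 2
  Wfull <- settle_sum(1, nc - 1, tau) + exp(-nc / tau) / 2
  Wcarry <- settle_sum(1, nc, tau)
  base <- mg[, 1] / W1
  ## base-only cumulative (cycle-mean) drift at the end of phase 3,
  ## relative to the cycle-100 reference; the stair-climb gain then
  ## supplies the remainder of the phase-3 target.
  ref <- base * (settle_sum(1, 99, tau) + exp(-100 / tau) / 2)
  base_end3 <- base * (2 * Wcarry + Wfull)
  ex3 <- st[[3]]$fap_peak - 0.3
  gain <- (mg[, 3] - (base_end3 - ref)) / (ex3 * Wfull)
  specimen_model(compliance = compliance,
                 ap_excess_compliance = C_x,
                 ap_threshold_BW = 0.3,
                 ratchet_base = base,
                 ratchet_gain = gain,
                 ratchet_load_exponent = 1,
                 saturation_cycles = tau,
                 abductor_attenuation = 1,
                 noise_sd_um = noise_sd_um)
}

#' Calibrated cohort preset
#'
#' Cohort configuration whose group templates are calibrated, in closed
#' form, against the reference summary tables ([reference_tables()]):
#' compliance columns from the micromotion rows, ratchet base and gain
#' from the migration rows (after removing elastic cycle-mean shifts),
#' settling constant 300 cycles, mean-one lognormal between-specimen
#' variability (sdlog 0.3) sized to the reported confidence intervals,
#' sensor noise sd 0.5 um, frozen master seed 20100624. The calibration
#' places the analytic group means of distal translation and transverse
#' rotation (both migration and micromotion) inside the reference 95%
#' confidence intervals at all three F_ap levels in both groups.
#'
#' Because the two groups genuinely differ in ratchet direction
#' (opposite transverse migration), each group gets its own calibrated
#' template; the `abductor_attenuation` mechanism remains available for
#' experiments that perturb a single template.
#'
#' @param samples_per_cycle Samples per cycle (32).
#' @param cycles_per_phase Cycles per phase (1000).
#' @return A [cohort_config()].
#' @export
reference_preset <- function(samples_per_cycle = 32,
                              cycles_per_phase = 1000) {
  tabs <- reference_tables()
  m1 <- calibrate_group_model(tabs$migration, tabs$micromotion, "group1",
                              samples_per_cycle = samples_per_cycle)
  m2 <- calibrate_group_model(tabs$migration, tabs$micromotion, "group2",
                              samples_per_cycle = samples_per_cycle)
  cohort_config(n_per_group = 6, model_no_abductor = m1,
                model_abductor = m2, sdlog_compliance = 0.3,
                sdlog_ratchet = 0.3, master_seed = 20100624,
                samples_per_cycle = samples_per_cycle,
                cycles_per_phase = cycles_per_phase)
}
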