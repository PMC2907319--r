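## Migration and micromotion extraction from a pose time series.
##
## Migration: difference in stem mean position (translations and
## projected rotations) between cycle 100 and the last cycle of each
## loading step (cycles 1-100 are pre-conditioning and excluded).
## Micromotion: average reversible motion over the last 200 cycles of
## each step - per cycle, the peak-minus-trough excursion (at the samples
## of maximum and minimum F_cc) after removing the cycle's linear drift;
## signed per component. Resultants: Euclidean norm of the three
## translations; rotation angle about the helical axis of the net
## rotation operator.
##
## Reporting convention: the component tables list "lateral" translation,
## i.e. the negative of the core frame's +medial component; rotations are
## reported in millidegrees.

POSE_COLS <- c("t_med_um", "t_ant_um", "t_dist_um",
               "rot_front_mdeg", "rot_sag_mdeg", "rot_trans_mdeg")

#' Per-cycle pose summaries
#'
#' Splits a uniformly sampled pose series into whole load cycles and
#' returns, per cycle: the mean of each pose component, the detrended
#' peak-minus-trough excursion of each component, and the detrended
#' helical rotation angle between the peak and trough poses. Peak and
#' trough samples are those of maximum and minimum applied `Fcc_BW` when
#' that column is present, otherwise of the distal translation.
#' Detrending subtracts the cycle's linear drift, whose rate is
#' estimated from the change in adjacent cycle means (a full-period
#' sinusoid sums to zero over a cycle, so cycle means carry the drift
#' alone and the cyclic component is untouched - a within-cycle
#' least-squares line would instead absorb part of the sampled sinusoid
#' and bias the excursion).
#'
#' @param pose_df Pose series (columns `time_s` and the six pose
#'   components; optional `Fcc_BW`, `phase`).
#' @param frequency_Hz Load frequency.
#' @return Data frame with one row per complete cycle: `cycle`,
#'   `mean_<comp>`, `exc_<comp>`, `exc_helical_mdeg` (and `phase` when
#'   present in the input).
#' @export
segment_cycles <- function(pose_df, frequency_Hz = 1) {
  if (!all(c("time_s", POSE_COLS) %in% names(pose_df)))
    stop("pose series must have columns time_s, ",
         paste(POSE_COLS, collapse = ", "))
  n <- nrow(pose_df)
  dt <- stats::median(diff(pose_df$time_s))
  spc <- as.integer(round(1 / (frequency_Hz * dt)))
  if (n < spc) stop("incomplete cycle: series shorter than one load cycle")
  ncyc <- n %/% spc
  m <- ncyc * spc
  idx <- function(col) matrix(pose_df[[col]][seq_len(m)], nrow = spc)
  ## peak/trough sample index within the cycle
  drv <- if ("Fcc_BW" %in% names(pose_df)) idx("Fcc_BW") else idx("t_dist_um")
  pk <- max.col(t(drv))
  tr <- max.col(t(-drv))
  s <- seq_len(spc)
  sbar <- mean(s)
  comp_mats <- lapply(POSE_COLS, idx)
  names(comp_mats) <- POSE_COLS
  out <- data.frame(cycle = seq_len(ncyc))
  ci <- seq_len(ncyc)
  ## cycle-level phase labels; drift-rate estimation never straddles a
  ## phase boundary (the elastic cycle-mean jumps there, which would
  ## masquerade as drift)
  cyc_phase <- if ("phase" %in% names(pose_df))
    as.character(pose_df$phase[seq(1, m, by = spc)]) else rep("all", ncyc)
  prev_ok <- c(FALSE, cyc_phase[-1] == cyc_phase[-ncyc])
  next_ok <- c(cyc_phase[-1] == cyc_phase[-ncyc], FALSE)
  detr_at <- function(X) {
    mean_ <- colMeans(X)
    ## drift rate per cycle from differences of adjacent within-phase
    ## cycle means (centred where possible); per-sample rate = rate/spc
    rate <- numeric(ncyc)
    if (ncyc > 1) {
      fwd <- c(mean_[-1] - mean_[-ncyc], 0)       # mean[k+1] - mean[k]
      bwd <- c(0, mean_[-1] - mean_[-ncyc])       # mean[k] - mean[k-1]
      both <- prev_ok & next_ok
      rate[both] <- (fwd[both] + bwd[both]) / 2
      only_f <- next_ok & !prev_ok
      rate[only_f] <- fwd[only_f]
      only_b <- prev_ok & !next_ok
      rate[only_b] <- bwd[only_b]
    }
    at <- function(ii) X[cbind(ii, ci)] - rate * (ii - sbar) / spc
    list(mean = mean_, pk = at(pk), tr = at(tr))
  }
  det <- lapply(comp_mats, detr_at)
  for (cc in POSE_COLS) {
    out[[paste0("mean_", cc)]] <- det[[cc]]$mean
    out[[paste0("exc_", cc)]] <- det[[cc]]$pk - det[[cc]]$tr
  }
  ## helical angle of R(peak) R(trough)^-1 from detrended projected angles
  hel <- numeric(ncyc)
  apk <- cbind(det$rot_front_mdeg$pk, det$rot_sag_mdeg$pk,
               det$rot_trans_mdeg$pk) * 1e-3
  atr <- cbind(det$rot_front_mdeg$tr, det$rot_sag_mdeg$tr,
               det$rot_trans_mdeg$tr) * 1e-3
  for (i in seq_len(ncyc)) {
    Rp <- rotation_from_projected_angles(apk[i, 1], apk[i, 2], apk[i, 3])
    Rt <- rotation_from_projected_angles(atr[i, 1], atr[i, 2], atr[i, 3])
    hel[i] <- helical_rotation_angle(Rp %*% t(Rt))
  }
  out$exc_helical_mdeg <- hel * 1e3
  if ("phase" %in% names(pose_df)) out$phase <- cyc_phase
  out
}

summary_row <- function(summaries, cycle) {
  i <- match(cycle, summaries$cycle)
  if (is.na(i)) stop("cycle ", cycle, " missing from the pose summaries")
  summaries[i, ]
}

#' Migration between a reference cycle and a step's last cycle
#'
#' Component-wise difference of the cycle-mean pose,
#' `mean_pose(last_cycle) - mean_pose(reference_cycle)`; rotations are
#' differenced as projected angles (small-angle regime).
#'
#' @param summaries Output of [segment_cycles()].
#' @param last_cycle Last cycle of the loading step (e.g. 1000).
#' @param reference_cycle Pre-conditioning boundary, default 100.
#' @return Named numeric: `lateral_um, anterior_um, distal_um,
#'   sagittal_mdeg, frontal_mdeg, transverse_mdeg`.
#' @export
migration <- function(summaries, last_cycle, reference_cycle = 100) {
  a <- summary_row(summaries, last_cycle)
  b <- summary_row(summaries, reference_cycle)
  d <- vapply(POSE_COLS, function(cc)
    a[[paste0("mean_", cc)]] - b[[paste0("mean_", cc)]], numeric(1))
  c(lateral_um = -d[["t_med_um"]],
    anterior_um = d[["t_ant_um"]],
    distal_um = d[["t_dist_um"]],
    sagittal_mdeg = d[["rot_sag_mdeg"]],
    frontal_mdeg = d[["rot_front_mdeg"]],
    transverse_mdeg = d[["rot_trans_mdeg"]])
}

#' Micromotion over a step's last cycles
#'
#' Mean signed detrended peak-minus-trough excursion per component over
#' the step's last `n_cycles` cycles. `mode = "half-amplitude"` halves
#' the excursion (amplitude rather than full excursion reading of the
#' cyclic motion).
#'
#' @param summaries Output of [segment_cycles()].
#' @param last_cycle Last cycle of the step.
#' @param n_cycles Averaging window, default 200.
#' @param mode `"peak-to-trough"` (default) or `"half-amplitude"`.
#' @return Named numeric as in [migration()] plus `helical_mdeg`, the
#'   cycle-averaged helical angle between peak and trough poses.
#' @export
micromotion <- function(summaries, last_cycle, n_cycles = 200,
                        mode = c("peak-to-trough", "half-amplitude")) {
  mode <- match.arg(mode)
  first <- last_cycle - n_cycles + 1
  rows <- summaries$cycle >= first & summaries$cycle <= last_cycle
  if (sum(rows) != n_cycles)
    stop("micromotion window ", first, "-", last_cycle,
         " not fully present in the pose summaries")
  scale <- if (mode == "half-amplitude") 0.5 else 1
  m <- vapply(POSE_COLS, function(cc)
    mean(summaries[[paste0("exc_", cc)]][rows]), numeric(1)) * scale
  c(lateral_um = -m[["t_med_um"]],
    anterior_um = m[["t_ant_um"]],
    distal_um = m[["t_dist_um"]],
    sagittal_mdeg = m[["rot_sag_mdeg"]],
    frontal_mdeg = m[["rot_front_mdeg"]],
    transverse_mdeg = m[["rot_trans_mdeg"]],
    helical_mdeg = mean(summaries$exc_helical_mdeg[rows]) * scale)
}

rotation_from_mdeg <- function(front, sag, trans)
  rotation_from_projected_angles(front * 1e-3, sag * 1e-3, trans * 1e-3)

#' Step metrics for every loading phase
#'
#' Runs [migration()] and [micromotion()] at each step boundary and
#' attaches the four resultants: total translational migration and
#' micromotion (Euclidean norm of the three translation components) and
#' total rotational migration and micromotion (helical-axis rotation
#' angle: for migration, of `R(last) R(reference)^-1`; for micromotion,
#' the cycle-averaged peak-trough helical angle).
#'
#' @param pose_df Pose series (see [segment_cycles()]).
#' @param phase_ends Integer vector of step-final cycles, default
#'   `c(1000, 2000, 3000)`; derived from the `phase` column when present.
#' @param frequency_Hz Load frequency.
#' @param reference_cycle Pre-conditioning boundary (100).
#' @param micromotion_cycles Averaging window (200).
#' @param micromotion_mode Passed to [micromotion()].
#' @param phase_labels Optional labels; default from `phase` column or
#'   `"step<k>"`.
#' @return Data frame, one row per step: `phase`, `fap_level` (when the
#'   labels carry it), six `migration_*`, six `micromotion_*`,
#'   `total_trans_migration_um`, `total_rot_migration_mdeg`,
#'   `total_trans_micromotion_um`, `total_rot_micromotion_mdeg`.
#' @export
step_metrics <- function(pose_df, phase_ends = NULL, frequency_Hz = 1,
                         reference_cycle = 100, micromotion_cycles = 200,
                         micromotion_mode = "peak-to-trough",
                         phase_labels = NULL) {
  summaries <- segment_cycles(pose_df, frequency_Hz)
  if (is.null(phase_ends)) {
    if ("phase" %in% names(summaries)) {
      r <- rle(summaries$phase)
      phase_ends <- cumsum(r$lengths)
      if (is.null(phase_labels)) phase_labels <- r$values
    } else phase_ends <- c(1000, 2000, 3000)
  }
  if (is.null(phase_labels)) phase_labels <- paste0("step", seq_along(phase_ends))
  rows <- vector("list", length(phase_ends))
  ref <- summary_row(summaries, reference_cycle)
  R_ref <- rotation_from_mdeg(ref$mean_rot_front_mdeg, ref$mean_rot_sag_mdeg,
                              ref$mean_rot_trans_mdeg)
  for (k in seq_along(phase_ends)) {
    lc <- phase_ends[k]
    mig <- migration(summaries, lc, reference_cycle)
    mic <- micromotion(summaries, lc, micromotion_cycles, micromotion_mode)
    last <- summary_row(summaries, lc)
    R_last <- rotation_from_mdeg(last$mean_rot_front_mdeg,
                                 last$mean_rot_sag_mdeg,
                                 last$mean_rot_trans_mdeg)
    rows[[k]] <- data.frame(
      phase = phase_labels[k],
      migration_lateral_um = mig[["lateral_um"]],
      migration_anterior_um = mig[["anterior_um"]],
      migration_distal_um = mig[["distal_um"]],
      migration_sagittal_mdeg = mig[["sagittal_mdeg"]],
      migration_frontal_mdeg = mig[["frontal_mdeg"]],
      migration_transverse_mdeg = mig[["transverse_mdeg"]],
      micromotion_lateral_um = mic[["lateral_um"]],
      micromotion_anterior_um = mic[["anterior_um"]],
      micromotion_distal_um = mic[["distal_um"]],
      micromotion_sagittal_mdeg = mic[["sagittal_mdeg"]],
      micromotion_frontal_mdeg = mic[["frontal_mdeg"]],
      micromotion_transverse_mdeg = mic[["transverse_mdeg"]],
      total_trans_migration_um = sqrt(mig[["lateral_um"]]^2 +
        mig[["anterior_um"]]^2 + mig[["distal_um"]]^2),
      total_rot_migration_mdeg =
        helical_rotation_angle(R_last %*% t(R_ref)) * 1e3,
      total_trans_micromotion_um = sqrt(mic[["lateral_um"]]^2 +
        mic[["anterior_um"]]^2 + mic[["distal_um"]]^2),
      total_rot_micromotion_mdeg = mic[["helical_mdeg"]])
  }
  do.call(rbind, rows)
}

#' Translational and rotational resultants of six components
#'
#' Helper mirroring the resultant definitions: the translational total is
#' the Euclidean norm of the three translation components; the rotational
#' total is the helical-axis angle of the rotation built from the three
#' projected angles.
#'
#' @param lateral_um,anterior_um,distal_um Translations, um.
#' @param sagittal_mdeg,frontal_mdeg,transverse_mdeg Projected rotations,
#'   millidegrees.
#' @return `c(total_trans_um, total_rot_mdeg)`.
#' @export
resultants <- function(lateral_um, anterior_um, distal_um,
                       sagittal_mdeg, frontal_mdeg, transverse_mdeg) {
  R <- rotation_from_mdeg(frontal_mdeg, sagittal_mdeg, transverse_mdeg)
  c(total_trans_um = sqrt(lateral_um^2 + anterior_um^2 + distal_um^2),
    total_rot_mdeg = helical_rotation_angle(R) * 1e3)
}
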