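## Static model of the loading rig and the three-phase sinusoidal load
## program.
##
## Two set-ups are modelled. Without the abductor, the machine's linear
## actuator loads the femoral head directly (femur potted at 13 deg of
## adduction, so the vertical hip contact force runs at 13 deg to the
## femur axis). With the abductor, the actuator loads a hinged lever that
## presses on the femoral head at offset d_off from the actuator axis and
## is pulled down by the abductor cable attached at lever arm d_m on the
## other side of the head; the femur is potted at 4 deg of abduction and
## the distal pot rides on a linear guide, so the frontal-plane horizontal
## force on the femur is zero. The anterior-posterior head load F_ap is
## applied by the rotary actuator as a torque M = F_ap * d_off.

GRAVITY <- 9.81
#' @rdname rig_geometry
#' @export
body_weight_newtons <- function(mass_kg = 75) mass_kg * GRAVITY

#' Rig geometry
#'
#' @param d_off_mm Frontal-plane offset between the actuator axis and the
#'   femoral head (mm); 32 mm without the abductor, `0.83 * d_m` with it.
#' @param d_m_mm Abductor-cable-to-head lever arm (mm); measured values
#'   ranged 46-50 mm.
#' @param potting_angle_deg Angle between femur axis and vertical (deg):
#'   13 (adduction) without the abductor, 4 (abduction) with it.
#' @param body_weight_N Body weight in Newtons (75 kg default).
#' @param abductor_enabled Logical; is the abductor cable present?
#' @param cable_angle_deg Abductor-cable angle from vertical (deg). The
#'   default 19.25 makes the hip contact force run at 13 deg to the femur
#'   axis in the abductor set-up (see [lever_equilibrium()]).
#' @param cable_perturbation_deg Optional perturbation of the cable angle
#'   emulating the ~1 deg actuator rotation seen during the stair-climb
#'   phase; default 0 (off).
#' @return Object of class `rig_geometry`.
#' @export
rig_geometry <- function(d_off_mm, d_m_mm = NA_real_, potting_angle_deg,
                         body_weight_N = body_weight_newtons(),
                         abductor_enabled = FALSE,
                         cable_angle_deg = 19.25,
                         cable_perturbation_deg = 0) {
  if (!is.finite(d_off_mm) || d_off_mm <= 0) stop("d_off_mm must be > 0")
  if (abductor_enabled && (!is.finite(d_m_mm) || d_m_mm <= 0))
    stop("d_m_mm must be > 0 when the abductor is enabled")
  if (!is.finite(body_weight_N) || body_weight_N <= 0)
    stop("body_weight_N must be > 0")
  structure(list(d_off_mm = d_off_mm, d_m_mm = d_m_mm,
                 potting_angle_deg = potting_angle_deg,
                 body_weight_N = body_weight_N,
                 abductor_enabled = abductor_enabled,
                 cable_angle_deg = cable_angle_deg,
                 cable_perturbation_deg = cable_perturbation_deg),
            class = "rig_geometry")
}

#' Reference rig geometries
#'
#' `reference_geometry(abductor = FALSE)` is the direct-loading set-up
#' (d_off = 32 mm, 13 deg adduction); `reference_geometry(abductor = TRUE)`
#' is the lever set-up with d_m = 48 mm, d_off = 0.83 * d_m, 4 deg
#' abduction.
#'
#' @param abductor Logical.
#' @return A [rig_geometry()].
#' @export
reference_geometry <- function(abductor = FALSE) {
  if (abductor)
    rig_geometry(d_off_mm = abductor_offset(48), d_m_mm = 48,
                 potting_angle_deg = 4, abductor_enabled = TRUE)
  else
    rig_geometry(d_off_mm = 32, potting_angle_deg = 13,
                 abductor_enabled = FALSE)
}

#' Decompose a frontal-plane force along and across the femur axis
#'
#' @param F_magnitude_xBW Force magnitude (multiples of body weight).
#' @param angle_deg Angle between force and femur axis, degrees.
#' @return `c(axial_xBW, medial_lateral_xBW)`:
#'   `(F cos(angle), F sin(angle))`.
#' @examples
#' decompose_frontal(2.3, 13)  # ~ (2.24, 0.52): rounds to 2.2 / 0.5 BW
#' @export
decompose_frontal <- function(F_magnitude_xBW, angle_deg) {
  if (!is.finite(F_magnitude_xBW) || F_magnitude_xBW < 0)
    stop("force magnitude must be >= 0")
  if (!is.finite(angle_deg) || abs(angle_deg) >= 90)
    stop("|angle| must be < 90 deg")
  a <- angle_deg * DEG2RAD
  c(axial_xBW = F_magnitude_xBW * cos(a),
    medial_lateral_xBW = F_magnitude_xBW * sin(a))
}

#' Actuator-to-head offset from the abductor lever arm
#'
#' The abductor set-up fixes `d_off = 0.83 * d_m` so that the same hip
#' contact and abductor forces are obtained for every specimen despite
#' specimen-to-specimen variation in d_m (46-50 mm, giving d_off between
#' 38 and 41 mm to the nearest mm).
#'
#' @param d_m_mm Lever arm, mm.
#' @return d_off in mm.
#' @export
abductor_offset <- function(d_m_mm) {
  if (!is.finite(d_m_mm) || d_m_mm <= 0) stop("d_m_mm must be > 0")
  0.83 * d_m_mm
}

#' Torque applied by the rotary actuator for a given F_ap
#'
#' `M = F_ap * d_off` with F_ap in multiples of body weight: the returned
#' torque is `F_ap_xBW * body_weight_N * d_off_m` in Newton-metres.
#'
#' @param F_ap_xBW Anterior-posterior head load, xBW (may be negative).
#' @param d_off_mm Offset, mm.
#' @param body_weight_N Body weight, N.
#' @return Torque, N m.
#' @export
fap_torque <- function(F_ap_xBW, d_off_mm,
                       body_weight_N = body_weight_newtons()) {
  if (!is.finite(d_off_mm) || d_off_mm <= 0) stop("d_off_mm must be > 0")
  F_ap_xBW * body_weight_N * d_off_mm * 1e-3
}

#' Planar static equilibrium of the abductor lever
#'
#' Free bodies: (i) the lever, hinged on the actuator rod (vertical force
#' `A`), pressing on the femoral head at `d_off` medial of the hinge and
#' pulled by the abductor cable at `d_m` lateral of the head, the cable
#' running at `cable_angle_deg` from vertical; (ii) the femur, whose
#' distal pot rides a linear guide so its frontal-plane horizontal force
#' balance closes through the head and cable forces alone. The three
#' equations (lever vertical force, lever moment about the head contact,
#' femur horizontal force) determine the cable tension, the head force
#' magnitude and its direction. With the reference abductor geometry
#' (`reference_geometry(TRUE)`) an actuator force of ~1.24 BW yields
#' F_cc = 2.3 BW at 13 deg to the femur axis and F_abd = 1.1 BW
#' (F_abd / F_cc = 0.475).
#'
#' With `abductor_enabled = FALSE` (cable tension constrained to zero)
#' the lever degenerates and the head force equals the actuator force.
#'
#' @param geometry A [rig_geometry()].
#' @param actuator_force_N Actuator axial force, N (positive down).
#' @return List of class `load_vector`: `F_head_N`, `F_head_xBW`,
#'   `head_angle_from_vertical_deg`, `head_angle_to_femur_deg`,
#'   `F_abd_N`, `F_abd_xBW`, `residual` (max force/moment imbalance,
#'   N and N m), plus the head-force frontal components.
#' @export
lever_equilibrium <- function(geometry, actuator_force_N) {
  stopifnot(inherits(geometry, "rig_geometry"))
  if (!is.finite(actuator_force_N)) stop("actuator force must be finite")
  BW <- geometry$body_weight_N
  A <- actuator_force_N
  if (!geometry$abductor_enabled) {
    out <- list(F_head_N = A, F_head_xBW = A / BW,
                head_angle_from_vertical_deg = 0,
                head_angle_to_femur_deg = geometry$potting_angle_deg,
                F_abd_N = 0, F_abd_xBW = 0,
                F_head_vertical_N = A, F_head_horizontal_N = 0,
                residual = 0)
    class(out) <- "load_vector"
    return(out)
  }
  d_off <- geometry$d_off_mm
  d_m <- geometry$d_m_mm
  psi <- (geometry$cable_angle_deg + geometry$cable_perturbation_deg) *
    DEG2RAD
  if (abs(cos(psi)) < 1e-9)
    stop("equilibrium error: abductor cable cannot be horizontal")
  ## lever moment about the head contact: A * d_off = (T cos psi) * d_m
  T_vert <- A * d_off / d_m
  T_cable <- T_vert / cos(psi)
  if (T_cable < 0)
    stop("equilibrium error: negative cable tension for this geometry")
  T_horiz <- T_cable * sin(psi)
  ## lever vertical balance: head reaction carries actuator + cable pull
  F_vert <- A + T_vert
  ## femur horizontal balance (linear guide): head horizontal matches cable
  F_horiz <- T_horiz
  F_head <- sqrt(F_vert^2 + F_horiz^2)
  phi <- atan2(F_horiz, F_vert)
  ## self-consistency: reinsert into the three balance equations
  res <- max(abs(F_vert - A - T_cable * cos(psi)),
             abs(A * d_off - T_cable * cos(psi) * d_m) * 1e-3,
             abs(F_head * sin(phi) - T_cable * sin(psi)))
  if (res > 1e-9 * max(1, abs(A)))
    stop("equilibrium error: residual ", signif(res, 3))
  out <- list(F_head_N = F_head, F_head_xBW = F_head / BW,
              head_angle_from_vertical_deg = phi * RAD2DEG,
              head_angle_to_femur_deg = phi * RAD2DEG +
                geometry$potting_angle_deg,
              F_abd_N = T_cable, F_abd_xBW = T_cable / BW,
              F_head_vertical_N = F_vert, F_head_horizontal_N = F_horiz,
              residual = res)
  class(out) <- "load_vector"
  out
}

#' Three-phase load schedule
#'
#' @param name Phase label.
#' @param cycles Number of cycles in the phase.
#' @param F_cc_min,F_cc_max Cranial-caudal hip contact force range, xBW.
#' @param F_ap_min,F_ap_max Anterior-posterior range, xBW.
#' @param F_abd Constant abductor force, xBW (0 when absent).
#' @return Object of class `load_phase`.
#' @export
load_phase <- function(name, cycles, F_cc_min, F_cc_max,
                       F_ap_min = 0, F_ap_max = 0, F_abd = 0) {
  if (cycles <= 0) stop("cycles must be > 0")
  if (F_cc_max < F_cc_min) stop("F_cc_max must be >= F_cc_min")
  structure(list(name = name, cycles = as.integer(cycles),
                 F_cc_min = F_cc_min, F_cc_max = F_cc_max,
                 F_ap_min = F_ap_min, F_ap_max = F_ap_max, F_abd = F_abd),
            class = "load_phase")
}

#' @param phases List of [load_phase()] objects, applied in order.
#' @param frequency_Hz Loading frequency (1 Hz).
#' @rdname load_phase
#' @export
load_schedule <- function(phases, frequency_Hz = 1) {
  if (!length(phases) || !all(vapply(phases, inherits, TRUE, "load_phase")))
    stop("phases must be a list of load_phase objects")
  structure(list(phases = phases, frequency_Hz = frequency_Hz,
                 in_phase = TRUE),
            class = "load_schedule")
}

#' The reference three-phase schedule
#'
#' Three sequential 1000-cycle phases at 1 Hz with in-phase sinusoidal
#' peaks: F_cc 0.4-2.3 xBW throughout; F_ap 0, then -0.1 to +0.3
#' (walking), then -0.1 to +0.6 (stair climbing); the abductor force,
#' when present, is constant at 1.1 xBW.
#'
#' @param abductor Logical: include the 1.1 xBW abductor load?
#' @param cycles_per_phase Cycles per phase (1000).
#' @return A [load_schedule()].
#' @export
reference_schedule <- function(abductor = FALSE, cycles_per_phase = 1000) {
  fab <- if (abductor) 1.1 else 0
  load_schedule(list(
    load_phase("fap0.0", cycles_per_phase, 0.4, 2.3, 0, 0, fab),
    load_phase("fap0.3", cycles_per_phase, 0.4, 2.3, -0.1, 0.3, fab),
    load_phase("fap0.6", cycles_per_phase, 0.4, 2.3, -0.1, 0.6, fab)))
}

#' Sampled load waveform
#'
#' Each load traces `min + (max - min) * (1 + sin(2 pi f t - pi/2)) / 2`
#' so that all loads peak simultaneously mid-cycle (in-phase peaks) and
#' start each cycle at their minimum. The abductor force is constant
#' within a phase. With an even `samples_per_cycle` the analytic extrema
#' are sampled exactly.
#'
#' @param schedule A [load_schedule()].
#' @param geometry A [rig_geometry()] (for the F_ap torque).
#' @param samples_per_cycle Samples per load cycle, >= 8.
#' @return Data frame `time_s, cycle, phase, Fcc_BW, Fap_BW, Fabd_BW,
#'   torque_Nm`.
#' @export
load_waveform <- function(schedule, geometry, samples_per_cycle = 32) {
  stopifnot(inherits(schedule, "load_schedule"),
            inherits(geometry, "rig_geometry"))
  if (samples_per_cycle < 8) stop("samples_per_cycle must be >= 8")
  f <- schedule$frequency_Hz
  spc <- as.integer(samples_per_cycle)
  total_cycles <- sum(vapply(schedule$phases, `[[`, integer(1), "cycles"))
  n <- total_cycles * spc
  k <- seq_len(n) - 1L
  t <- k / (spc * f)
  cycle <- k %/% spc + 1L
  shape <- (1 + sin(2 * pi * f * t - pi / 2)) / 2   # 0 at cycle start, 1 mid
  phase_id <- integer(n)
  Fcc <- Fap <- Fabd <- numeric(n)
  phase_names <- character(length(schedule$phases))
  start <- 0L
  for (p in seq_along(schedule$phases)) {
    ph <- schedule$phases[[p]]
    phase_names[p] <- ph$name
    idx <- cycle > start & cycle <= start + ph$cycles
    phase_id[idx] <- p
    Fcc[idx] <- ph$F_cc_min + (ph$F_cc_max - ph$F_cc_min) * shape[idx]
    Fap[idx] <- ph$F_ap_min + (ph$F_ap_max - ph$F_ap_min) * shape[idx]
    Fabd[idx] <- ph$F_abd
    start <- start + ph$cycles
  }
  data.frame(time_s = t, cycle = cycle,
             phase = factor(phase_names[phase_id], levels = phase_names),
             Fcc_BW = Fcc, Fap_BW = Fap, Fabd_BW = Fabd,
             torque_Nm = fap_torque(Fap, geometry$d_off_mm,
                                    geometry$body_weight_N))
}
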