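## Forward model of the six-LVDT measurement system: six single-axis
## displacement sensors contact a rigid triangular target plate fixed to
## the lateral aspect of the stem; the sensor frame is fixed to the bone.
## Each sensor reports the projection of its contact point's displacement
## onto a fixed measurement axis (the axis does not rotate with the plate;
## for rotations below 1.2 deg the cosine error of this assumption is
## below 2e-4).

#' Single displacement-sensor specification
#'
#' @param contact_point Length-3 point (mm, femur frame at rest) where the
#'   sensor tip touches the target plate.
#' @param direction Length-3 measurement axis; normalised internally and
#'   must be within 1e-6 of unit length on input.
#' @param label Sensor name.
#' @return Object of class `sensor_spec`.
#' @export
sensor_spec <- function(contact_point, direction, label = "") {
  if (!all(is.finite(contact_point)) || length(contact_point) != 3L)
    stop("contact_point must be a finite length-3 vector")
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || abs(n - 1) > 1e-6)
    stop("direction must be a unit vector (|direction| = 1)")
  structure(list(contact_point = unname(as.numeric(contact_point)),
                 direction = unname(as.numeric(direction) / n),
                 label = as.character(label)),
            class = "sensor_spec")
}

#' Six-sensor array
#'
#' @param sensors List of exactly six [sensor_spec()] objects.
#' @param reference_point Length-3 point (mm): the stem reference point
#'   about which poses rotate.
#' @return Object of class `sensor_array`.
#' @export
sensor_array <- function(sensors, reference_point = c(0, 0, 0)) {
  if (length(sensors) != 6L || !all(vapply(sensors, inherits, TRUE, "sensor_spec")))
    stop("a sensor_array needs exactly six sensor_spec objects")
  if (!all(is.finite(reference_point)) || length(reference_point) != 3L)
    stop("reference_point must be a finite length-3 vector")
  structure(list(sensors = sensors,
                 reference_point = unname(as.numeric(reference_point))),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("sensor_array: 6 LVDTs, reference point (",
      paste(x$reference_point, collapse = ", "), ") mm\n", sep = "")
  for (s in x$sensors)
    cat("  ", s$label, ": contact (", paste(round(s$contact_point, 2),
        collapse = ", "), ") mm, axis (", paste(round(s$direction, 3),
        collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Default 3-2-1 sensor layout
#'
#' A documented stand-in geometry for the triangular target plate: an
#' equilateral triangle of 25 mm side centred on the stem reference point,
#' lying in the anterior-distal (lateral-facing) plane. Three sensors bear
#' on the plate face along the medial axis (one per corner), two bear on
#' edge flats along the distal axis, and one along the anterior axis - the
#' classic 3-2-1 exact-constraint layout, which makes the 6x6
#' small-displacement Jacobian well conditioned (condition number below
#' 100 with rotations scaled in millradians).
#'
#' @param side_mm Triangle side length, mm.
#' @param reference_point Length-3 point (mm).
#' @return A [sensor_array()].
#' @export
default_array <- function(side_mm = 25, reference_point = c(0, 0, 0)) {
  h <- side_mm / sqrt(3)           # circumradius of the equilateral triangle
  ## corners in the plate plane (x = 0): (anterior, distal) offsets
  A <- reference_point + c(0,  0,          -h)        # proximal corner
  B <- reference_point + c(0, -side_mm / 2, h / 2)    # posterior-distal
  C <- reference_point + c(0,  side_mm / 2, h / 2)    # anterior-distal
  sensor_array(list(
    sensor_spec(A, c(1, 0, 0), "s1_medial_A"),
    sensor_spec(B, c(1, 0, 0), "s2_medial_B"),
    sensor_spec(C, c(1, 0, 0), "s3_medial_C"),
    sensor_spec(B, c(0, 0, 1), "s4_distal_B"),
    sensor_spec(C, c(0, 0, 1), "s5_distal_C"),
    sensor_spec(A, c(0, 1, 0), "s6_anterior_A")),
    reference_point = reference_point)
}

#' Predicted sensor readings for a pose
#'
#' Forward measurement model: each reading is the projection of its
#' contact point's displacement onto the sensor axis,
#' `direction . (transform_point(pose, contact, ref) - contact)`, in
#' micrometres. The identity pose yields six zeros.
#'
#' @param pose A [rigid_pose()].
#' @param array A [sensor_array()].
#' @return Numeric vector of six readings (micrometres), named by sensor
#'   label.
#' @export
forward_readings <- function(pose, array) {
  stopifnot(inherits(pose, "rigid_pose"), inherits(array, "sensor_array"))
  r <- vapply(array$sensors, function(s) {
    d <- transform_point(pose, s$contact_point, array$reference_point) -
      s$contact_point
    sum(s$direction * d) * 1e3    # mm -> um
  }, numeric(1))
  names(r) <- vapply(array$sensors, `[[`, character(1), "label")
  r
}

#' Small-displacement Jacobian of the sensor array
#'
#' Row i is the gradient of reading i with respect to the pose parameters
#' `(t_medial, t_anterior, t_distal, w_frontal, w_sagittal, w_transverse)`
#' evaluated at the identity, with translations in micrometres and the
#' rotation vector in milliradians (so all columns carry micrometre-scale
#' entries: 1 mrad about a lever of v mm displaces by v um).
#'
#' @param array A [sensor_array()].
#' @return 6x6 numeric matrix.
#' @export
array_jacobian <- function(array) {
  stopifnot(inherits(array, "sensor_array"))
  J <- matrix(0, 6, 6)
  for (i in seq_len(6)) {
    s <- array$sensors[[i]]
    v <- s$contact_point - array$reference_point   # mm lever arm
    J[i, 1:3] <- s$direction
    ## d(reading)/dw = direction . (w x v) per unit w => v x direction
    J[i, 4:6] <- c(v[2] * s$direction[3] - v[3] * s$direction[2],
                   v[3] * s$direction[1] - v[1] * s$direction[3],
                   v[1] * s$direction[2] - v[2] * s$direction[1])
  }
  rownames(J) <- vapply(array$sensors, `[[`, character(1), "label")
  colnames(J) <- c("t_med_um", "t_ant_um", "t_dist_um",
                   "w_med_mrad", "w_ant_mrad", "w_dist_mrad")
  J
}
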