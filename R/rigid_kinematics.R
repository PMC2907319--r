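## Rigid-body kinematics for implant-bone motion.
##
## Coordinate frame (femur-fixed, right-handed): +x medial, +y anterior,
## +z distal; origin at the stem reference point on the lateral aspect of
## the stem, 113 mm proximal from the stem tip. All poses express implant
## motion relative to the bone. Translations are stored in micrometres,
## rotations as proper orthogonal 3x3 matrices; reporting layers convert
## rotations to the three anatomical-plane projections in degrees (tables
## use millidegrees).

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Rigid implant-bone pose
#'
#' A 6-DOF pose: translation of the stem reference point (micrometres,
#' medial/anterior/distal components) plus a proper rotation of the
#' femur-fixed frame.
#'
#' @param t_medial,t_anterior,t_distal Translation components in
#'   micrometres along the medial, anterior and distal axes.
#' @param rotation 3x3 proper orthogonal matrix (determinant +1). Defaults
#'   to the identity.
#' @return An object of class `rigid_pose` with fields `t` (length-3
#'   numeric, micrometres) and `R` (3x3 rotation matrix).
#' @examples
#' rigid_pose(5, 0, -2)
#' rigid_pose(0, 0, 0, rotation_from_projected_angles(0, 0, 0.5))
#' @export
rigid_pose <- function(t_medial = 0, t_anterior = 0, t_distal = 0,
                       rotation = diag(3)) {
  t <- c(t_medial, t_anterior, t_distal)
  if (!all(is.finite(t))) stop("pose translations must be finite")
  check_rotation(rotation)
  structure(list(t = unname(t), R = unname(rotation)), class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  ang <- tryCatch(projected_angles_from_rotation(x$R),
                  error = function(e) c(NA_real_, NA_real_, NA_real_))
  cat("rigid_pose: t = (", paste(signif(x$t, 6), collapse = ", "),
      ") um; projected angles (frontal, sagittal, transverse) = (",
      paste(signif(ang, 6), collapse = ", "), ") deg\n", sep = "")
  invisible(x)
}

check_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)) || !all(is.finite(R)))
    stop("rotation must be a finite 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("rotation is not orthogonal within tolerance ", tol)
  if (abs(det(R) - 1) > tol)
    stop("rotation must be proper (determinant +1)")
  invisible(R)
}

rot_x <- function(a) { # about medial axis (sagittal-plane rotation)
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) { # about anterior axis (frontal-plane rotation)
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) { # about distal axis (transverse-plane rotation)
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Build a rotation from anatomical-plane projected angles
#'
#' Composes the three plane rotations in the fixed extrinsic order
#' frontal (about the anterior axis), then sagittal (about the medial
#' axis), then transverse (about the distal axis):
#' `R = Rz(transverse) %*% Rx(sagittal) %*% Ry(frontal)`.
#' At the sub-degree magnitudes of stem motion the composition order
#' affects the result by less than 1e-5 degrees; the order is fixed and
#' documented so that [projected_angles_from_rotation()] is its exact
#' inverse. Positive transverse rotation is anteversion (the anterior
#' axis swings medially); negative is retroversion.
#'
#' @param frontal_deg,sagittal_deg,transverse_deg Projected angles in
#'   degrees; each must be finite and below 90 in magnitude.
#' @return 3x3 proper rotation matrix.
#' @seealso [projected_angles_from_rotation()], [helical_rotation_angle()]
#' @export
rotation_from_projected_angles <- function(frontal_deg, sagittal_deg,
                                           transverse_deg) {
  a <- c(frontal_deg, sagittal_deg, transverse_deg)
  if (!all(is.finite(a))) stop("projected angles must be finite")
  if (any(abs(a) >= 90)) stop("projected angles must satisfy |angle| < 90 deg")
  r <- a * DEG2RAD
  rot_z(r[3]) %*% rot_x(r[2]) %*% rot_y(r[1])
}

#' Extract anatomical-plane projected angles from a rotation
#'
#' Exact inverse of [rotation_from_projected_angles()] for its fixed
#' composition order. For the small rotations of a stability test each
#' returned angle equals the rotation of the corresponding axis pair
#' projected into its anatomical plane.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @return Numeric vector `c(frontal_deg, sagittal_deg, transverse_deg)`.
#' @export
projected_angles_from_rotation <- function(rotation) {
  check_rotation(rotation)
  R <- rotation
  ## R = Rz(g) Rx(a) Ry(b): R[3,2] = sin(a); R[3,] = (-cos(a)sin(b), sin(a),
  ## cos(a)cos(b)); R[,2] = (-sin(g)cos(a), cos(g)cos(a), sin(a)).
  if (sqrt(R[3, 1]^2 + R[3, 3]^2) < 1e-12 ||
      sqrt(R[1, 2]^2 + R[2, 2]^2) < 1e-12)
    stop("degenerate geometry: sagittal rotation too close to 90 deg for ",
         "plane projection")
  sag <- asin(max(-1, min(1, R[3, 2])))
  fro <- atan2(-R[3, 1], R[3, 3])
  tra <- atan2(-R[1, 2], R[2, 2])
  c(frontal_deg = fro, sagittal_deg = sag, transverse_deg = tra) * RAD2DEG
}

#' Rotation angle about the helical (screw) axis
#'
#' Any rigid rotation is a single rotation about one axis (the helical
#' axis of the displacement); its angle, `acos((trace(R) - 1) / 2)`, is
#' the resultant used for "total rotational" migration and micromotion.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
helical_rotation_angle <- function(rotation) {
  check_rotation(rotation)
  x <- (sum(diag(rotation)) - 1) / 2
  if (x > 1 + 1e-9 || x < -1 - 1e-9)
    stop("invalid rotation: trace outside [-1, 3]")
  acos(max(-1, min(1, x))) * RAD2DEG
}

#' Displace a point by a rigid pose
#'
#' Applies the pose rotation about the pivot (the stem reference point)
#' and then the translation: `pivot + R (point - pivot) + t`. Point and
#' pivot are in millimetres; the returned point includes the pose
#' translation converted from micrometres.
#'
#' @param pose A [rigid_pose()].
#' @param point Length-3 point, mm, femur frame.
#' @param pivot Length-3 pivot, mm; the pose's reference point.
#' @return Displaced point in mm.
#' @export
transform_point <- function(pose, point, pivot = c(0, 0, 0)) {
  stopifnot(inherits(pose, "rigid_pose"))
  if (!all(is.finite(point)) || !all(is.finite(pivot)))
    stop("point and pivot must be finite")
  as.numeric(pivot + pose$R %*% (point - pivot) + pose$t * 1e-3)
}

## Rotation-vector (axis-angle) helpers used by the pose solver. The
## rotation vector w (radians) maps to exp([w]x) via Rodrigues' formula.
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  if (th < 1e-12) return(diag(3) + K + 0.5 * K %*% K)
  diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * K %*% K
}

matrix_to_rotvec <- function(R) {
  check_rotation(R)
  x <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  th <- acos(x)
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (th < 1e-8) return(0.5 * ax)          # first-order: axis*angle ~ ax/2
  if (abs(pi - th) < 1e-6) {               # near 180 deg: use diagonal
    v <- sqrt(pmax(0, (diag(R) + 1) / 2))
    v[which.max(abs(ax))] <- v[which.max(abs(ax))] * sign(ax[which.max(abs(ax))])
    return(th * v / sqrt(sum(v^2)))
  }
  th / (2 * sin(th)) * ax
}
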