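## Inversion of six LVDT readings into a 6-DOF implant pose.
##
## The inverse problem is nearly linear over the motion envelope of a
## stability test (translations below a few hundred micrometres, rotations
## below ~1.2 deg), so a linearized solve gives an excellent starting
## point and Gauss-Newton refinement converges in two or three iterations.
## The solver parameterizes rotation as a rotation vector (axis-angle) to
## avoid projection degeneracies; projected plane angles are a reporting
## conversion only. No smoothing or filtering happens here - the inverse
## map is deterministic and noise handling belongs to the metrics stage.

pose_from_x <- function(x) {
  ## x = (t_um[3], w_mrad[3])
  rigid_pose(x[1], x[2], x[3], rotation = rotvec_to_matrix(x[4:6] * 1e-3))
}

solve_array <- function(J, readings) {
  ## Solve J x = readings, failing loudly with the null-space direction
  ## when the geometry does not constrain all six degrees of freedom.
  sv <- svd(J)
  if (min(sv$d) < 1e-9 * max(sv$d)) {
    ns <- sv$v[, which.min(sv$d)]
    stop("singular sensor geometry: unconstrained pose direction (",
         paste(signif(ns, 3), collapse = ", "),
         ") [t_um x3, w_mrad x3]")
  }
  as.numeric(sv$v %*% ((crossprod(sv$u, readings)) / sv$d))
}

#' First-order pose estimate from six readings
#'
#' Solves the linear system `J x = readings` where `J` is the array's
#' small-displacement Jacobian ([array_jacobian()]). Exact for pure
#' translations; for rotations the error is second order in the angle.
#'
#' @param readings Six sensor readings, micrometres.
#' @param array A [sensor_array()].
#' @return A [rigid_pose()].
#' @export
linearized_pose <- function(readings, array) {
  if (length(readings) != 6L || !all(is.finite(readings)))
    stop("readings must be six finite values")
  pose_from_x(solve_array(array_jacobian(array), readings))
}

#' Recover a 6-DOF pose from six sensor readings
#'
#' Gauss-Newton minimisation of `||forward_readings(pose) - readings||`,
#' started from [linearized_pose()]. On noise-free readings generated by
#' the forward model the recovered pose matches the generating pose to
#' better than 0.01 um and 1e-5 deg across the study motion envelope.
#'
#' @param readings Six readings, micrometres.
#' @param array A [sensor_array()].
#' @param max_iterations Iteration cap.
#' @param tol Convergence tolerance on the residual norm, micrometres.
#' @return A `recovery_solution`: list with `pose` ([rigid_pose()]),
#'   `residual_norm` (um), `iterations`, `converged`. Non-convergence
#'   returns the best iterate with `converged = FALSE` and a warning.
#' @export
recover_pose <- function(readings, array, max_iterations = 50, tol = 1e-9) {
  if (length(readings) != 6L || !all(is.finite(readings)))
    stop("readings must be six finite values")
  J <- array_jacobian(array)
  sv <- svd(J)
  if (min(sv$d) < 1e-9 * max(sv$d))
    return(linearized_pose(readings, array))  # raises the singular error
  x <- solve_array(J, readings)
  best_x <- x
  best_res <- Inf
  it <- 0L
  converged <- FALSE
  repeat {
    r <- readings - forward_readings(pose_from_x(x), array)
    rn <- sqrt(sum(r^2))
    if (rn < best_res) { best_res <- rn; best_x <- x }
    if (rn < tol) { converged <- TRUE; break }
    if (it >= max_iterations) break
    ## J at identity is an excellent Jacobian everywhere in the envelope
    ## (Gauss-Newton with a frozen Jacobian; contraction factor ~|w|^2).
    x <- x + solve_array(J, r)
    it <- it + 1L
  }
  if (!converged)
    warning("pose recovery did not converge: residual ",
            signif(best_res, 4), " um after ", it, " iterations")
  structure(list(pose = pose_from_x(best_x), residual_norm = best_res,
                 iterations = it, converged = converged),
            class = "recovery_solution")
}

#' @export
print.recovery_solution <- function(x, ...) {
  cat("recovery_solution: converged =", x$converged, "in", x$iterations,
      "iterations, residual", signif(x$residual_norm, 4), "um\n")
  print(x$pose)
  invisible(x)
}

#' Analytic worst-case rotation error of an array
#'
#' Propagates a per-sensor maximum reading error through the linearized
#' inverse: every one of the 64 sign patterns of +/-e on the six readings
#' is mapped to a pose and the largest helical rotation angle is returned.
#' Because the linearized inverse is a linear map, the maximum over the
#' error hypercube is attained at a vertex, so the enumeration is exact;
#' it also scales linearly in `e`.
#'
#' @param array A [sensor_array()].
#' @param per_sensor_max_error Maximum absolute single-sensor error, um.
#' @return Worst-case rotation angle, degrees.
#' @export
worst_case_rotation_error <- function(array, per_sensor_max_error) {
  if (!is.finite(per_sensor_max_error) || per_sensor_max_error < 0)
    stop("per_sensor_max_error must be a non-negative finite value")
  Jinv <- {
    J <- array_jacobian(array)
    sv <- svd(J)
    if (min(sv$d) < 1e-9 * max(sv$d))
      solve_array(J, rep(0, 6))    # raises the singular error
    sv$v %*% diag(1 / sv$d) %*% t(sv$u)
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  worst <- 0
  for (i in seq_len(nrow(signs))) {
    x <- Jinv %*% (per_sensor_max_error * signs[i, ])
    ang <- sqrt(sum(x[4:6]^2)) * 1e-3 * RAD2DEG  # |rotvec| in degrees
    if (ang > worst) worst <- ang
  }
  worst
}

## ---- vectorized series recovery ------------------------------------------

## Apply Rodrigues' rotation to each row of V (n x 3) given rotation
## vectors W (n x 3, radians): R v = v cos(th) + (k x v) sin(th)
## + k (k.v)(1 - cos(th)).
rotate_rows <- function(W, v) {
  th <- sqrt(rowSums(W^2))
  safe <- pmax(th, 1e-300)
  K <- W / safe
  kv <- K[, 1] * v[1] + K[, 2] * v[2] + K[, 3] * v[3]
  cx <- K[, 2] * v[3] - K[, 3] * v[2]
  cy <- K[, 3] * v[1] - K[, 1] * v[3]
  cz <- K[, 1] * v[2] - K[, 2] * v[1]
  ct <- cos(th); st <- sin(th)
  out <- cbind(v[1] * ct + cx * st + K[, 1] * kv * (1 - ct),
               v[2] * ct + cy * st + K[, 2] * kv * (1 - ct),
               v[3] * ct + cz * st + K[, 3] * kv * (1 - ct))
  zero <- th < 1e-14
  if (any(zero)) out[zero, ] <- matrix(v, sum(zero), 3, byrow = TRUE)
  out
}

## Forward readings for n poses at once. X is n x 6 (t um, w mrad);
## returns n x 6 readings (um).
forward_readings_matrix <- function(X, array) {
  n <- nrow(X)
  W <- X[, 4:6, drop = FALSE] * 1e-3
  out <- matrix(0, n, 6)
  for (i in seq_len(6)) {
    s <- array$sensors[[i]]
    v <- s$contact_point - array$reference_point
    disp_mm <- rotate_rows(W, v)
    disp_mm[, 1] <- disp_mm[, 1] - v[1]
    disp_mm[, 2] <- disp_mm[, 2] - v[2]
    disp_mm[, 3] <- disp_mm[, 3] - v[3]
    out[, i] <- 1e3 * (disp_mm[, 1] * s$direction[1] +
                       disp_mm[, 2] * s$direction[2] +
                       disp_mm[, 3] * s$direction[3]) +
      X[, 1] * s$direction[1] + X[, 2] * s$direction[2] +
      X[, 3] * s$direction[3]
  }
  out
}

## Vectorised rotation-vector (radians) -> projected plane angles (deg).
## Uses the closed-form Rodrigues entries R = I + a K + b K^2 with
## a = sin(th)/th, b = (1-cos(th))/th^2, K = [w]x, K^2 = w w' - th^2 I,
## then the same extraction as projected_angles_from_rotation.
projected_angles_from_rotvec_rows <- function(W) {
  th2 <- rowSums(W^2)
  th <- sqrt(th2)
  small <- th < 1e-7
  a <- ifelse(small, 1 - th2 / 6, sin(th) / pmax(th, 1e-300))
  b <- ifelse(small, 0.5 - th2 / 24, (1 - cos(th)) / pmax(th2, 1e-300))
  w1 <- W[, 1]; w2 <- W[, 2]; w3 <- W[, 3]
  R32 <- a * w1 + b * w3 * w2
  R31 <- -a * w2 + b * w3 * w1
  R33 <- 1 + b * (w3^2 - th2)
  R12 <- -a * w3 + b * w1 * w2
  R22 <- 1 + b * (w2^2 - th2)
  cbind(frontal_deg = atan2(-R31, R33),
        sagittal_deg = asin(pmax(-1, pmin(1, R32))),
        transverse_deg = atan2(-R12, R22)) * RAD2DEG
}

#' Recover a pose time series from a sensor time series
#'
#' Vectorised Gauss-Newton over all samples at once: the linearized solve
#' seeds every sample, then the shared identity Jacobian is used to
#' correct the full batch until the worst residual passes `tol` (the
#' problem is near-linear, so 2-4 sweeps suffice). Equivalent to calling
#' [recover_pose()] per row but orders of magnitude faster in R.
#'
#' @param sensor_df Data frame with columns `time_s, s1..s6` (um); extra
#'   columns (e.g. applied loads) are carried through to the output.
#' @param array A [sensor_array()].
#' @param max_iterations,tol As in [recover_pose()]; `tol` applies to the
#'   worst per-sample residual norm.
#' @return Data frame `time_s, t_med_um, t_ant_um, t_dist_um,
#'   rot_front_mdeg, rot_sag_mdeg, rot_trans_mdeg, residual_um` plus any
#'   carried columns.
#' @export
recover_pose_series <- function(sensor_df, array, max_iterations = 50,
                                tol = 1e-9) {
  need <- c("time_s", paste0("s", 1:6))
  if (!all(need %in% names(sensor_df)))
    stop("sensor series must have columns ", paste(need, collapse = ", "))
  Yobs <- as.matrix(sensor_df[, paste0("s", 1:6)])
  if (!all(is.finite(Yobs))) stop("sensor readings must be finite")
  J <- array_jacobian(array)
  sv <- svd(J)
  if (min(sv$d) < 1e-9 * max(sv$d))
    solve_array(J, rep(0, 6))      # raises the singular error
  Jinv <- sv$v %*% diag(1 / sv$d) %*% t(sv$u)
  X <- Yobs %*% t(Jinv)
  for (it in seq_len(max_iterations)) {
    Rres <- Yobs - forward_readings_matrix(X, array)
    if (sqrt(max(rowSums(Rres^2))) < tol) break
    X <- X + Rres %*% t(Jinv)
  }
  Rres <- Yobs - forward_readings_matrix(X, array)
  ang <- projected_angles_from_rotvec_rows(X[, 4:6, drop = FALSE] * 1e-3)
  out <- data.frame(time_s = sensor_df$time_s,
                    t_med_um = X[, 1], t_ant_um = X[, 2], t_dist_um = X[, 3],
                    rot_front_mdeg = ang[, 1] * 1e3,
                    rot_sag_mdeg = ang[, 2] * 1e3,
                    rot_trans_mdeg = ang[, 3] * 1e3,
                    residual_um = sqrt(rowSums(Rres^2)))
  extra <- setdiff(names(sensor_df), need)
  if (length(extra)) out <- cbind(out, sensor_df[, extra, drop = FALSE])
  out
}

#' Read a sensor time-series CSV
#'
#' Expects a header `time_s,s1,...,s6` (micrometres, "." decimal, UTF-8);
#' extra columns are preserved.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_sensor_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("time_s", paste0("s", 1:6))
  if (!all(need %in% names(df)))
    stop("sensor CSV ", path, " must have columns ",
         paste(need, collapse = ", "))
  df
}

#' Write a pose time-series CSV
#'
#' @param pose_df Output of [recover_pose_series()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(pose_df, path) {
  data.table::fwrite(pose_df, path)
  invisible(path)
}
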