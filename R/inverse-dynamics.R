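# Newton-Euler computation of the total external wrench acting on the body.
# With ground contact as the only significant external load, the internal
# joint forces cancel over the closed chain, so the total external moment
# about a reference point O reduces to the sum of each segment's rotational
# Euler terms plus the gravito-inertial moment of its CoM about O.

#' Per-segment CoM positions and accelerations in the global frame
#' @noRd
segment_com_state <- function(body, kin) {
  n <- length(kin$time)
  out <- list()
  for (nm in names(body$segments)) {
    seg <- body$segments[[nm]]
    k <- kin$segments[[nm]]
    if (is.null(k))
      stopf("inverse dynamics: kinematics lack segment '%s' of the body model", nm)
    Rs <- quat_to_matrix(k$quat)
    r <- rotate_local_vector(Rs, seg$com_offset_local)
    if (is.null(k$angacc))
      stopf("inverse dynamics: segment '%s' lacks angular acceleration; run differentiate_angular_velocity()", nm)
    out[[nm]] <- list(
      com = k$pos + r,
      acc = translate_acceleration_to_com(k$acc, k$angvel, k$angacc, r),
      Rs = Rs
    )
  }
  out
}

#' Total external force from the Newton equation
#'
#' `F_ext(t) = sum_i m_i (a_i(t) - g)` over all body segments, with `a_i`
#' the linear acceleration of each segment's centre of mass (obtained from
#' the origin acceleration via [translate_acceleration_to_com()]). For a
#' static pose this is the body weight pointing up.
#'
#' @param body a [body_model()].
#' @param kin a [segment_kinematics()] with `angacc` present (see
#'   [differentiate_angular_velocity()]).
#' @return A [wrench_series()] carrying the force (moment zero).
#' @export
total_external_force <- function(body, kin) {
  if (!setequal(names(body$segments), names(kin$segments)))
    stopf("total_external_force: body and kinematics segment sets differ")
  st <- segment_com_state(body, kin)
  n <- length(kin$time)
  F <- matrix(0, n, 3)
  g <- matrix(body$gravity, n, 3, byrow = TRUE)
  for (nm in names(body$segments))
    F <- F + body$segments[[nm]]$mass * (st[[nm]]$acc - g)
  wrench_series(kin$time, F, frame = "global")
}

#' Total external moment from the Euler equation
#'
#' About the (possibly moving) reference point `O(t)`:
#' `M_ext = sum_i [ R_i J_i R_i' wdot_i + w_i x (R_i J_i R_i' w_i)
#'                  + (c_i - O) x m_i (a_i - g) ]`
#' where `c_i` is the segment CoM position and `R_i` its orientation.
#' Segment-frame inertia tensors are rotated to the global frame per
#' sample.
#'
#' @param body a [body_model()].
#' @param kin a [segment_kinematics()] with `angacc` present.
#' @param ref_point length-3 vector or n x 3 matrix: the moment reference
#'   point per sample (m). Defaults to the global origin.
#' @return A [wrench_series()] with both force and moment about `ref_point`.
#' @export
total_external_moment <- function(body, kin, ref_point = c(0, 0, 0)) {
  if (!setequal(names(body$segments), names(kin$segments)))
    stopf("total_external_moment: body and kinematics segment sets differ")
  st <- segment_com_state(body, kin)
  n <- length(kin$time)
  if (is.null(dim(ref_point)))
    ref_point <- matrix(ref_point, n, 3, byrow = TRUE)
  M <- matrix(0, n, 3)
  F <- matrix(0, n, 3)
  g <- matrix(body$gravity, n, 3, byrow = TRUE)
  for (nm in names(body$segments)) {
    seg <- body$segments[[nm]]
    k <- kin$segments[[nm]]
    s <- st[[nm]]
    J <- seg$inertia_com_local
    euler <- t(vapply(seq_len(n), function(i) {
      Jw <- s$Rs[[i]] %*% J %*% t(s$Rs[[i]])
      as.numeric(Jw %*% k$angacc[i, ]) +
        as.numeric(crossprod_vec(k$angvel[i, ], as.numeric(Jw %*% k$angvel[i, ])))
    }, numeric(3)))
    f_i <- seg$mass * (s$acc - g)
    M <- M + euler + cross3(s$com - ref_point, f_i)
    F <- F + f_i
  }
  wrench_series(kin$time, F, M, ref_point, frame = "global")
}

#' Single 3-vector cross product
#' @noRd
crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
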