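# Rotation algebra for dual-body relative-orientation analysis.
#
# Conventions (degrees everywhere in the public API; radians only inside):
#   * Refinement Euler angles (rot, tilt, psi) follow the z-y-z sequence of
#     the refinement package that writes the STAR files:
#       R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)
#     with right-handed, counter-clockwise-positive elementary rotations.
#   * Relative orientations are reported as z-y-x (Tait-Bryan) angles
#     (alpha, beta, gamma) with R = Rz(alpha) %*% Ry(beta) %*% Rx(gamma),
#     alpha in (-180, 180], beta in [-90, 90], gamma in (-180, 180].
#
# Worked example of the z-y-z convention (rot = 90, tilt = 0, psi = 0):
#   R = Rz(90) = | 0 -1  0 |
#                | 1  0  0 |   so R %*% c(1,0,0) = c(0,1,0).
#                | 0  0  1 |

.ORTHO_TOL <- 1e-9
.DUP_TOL <- 1e-9
.GIMBAL_TOL_DEG <- 1e-7

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to the half-open interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped so that every value lies in `(-180, 180]`
#'   (`-180` maps to `180`).
#' @export
wrap180 <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w <= -180] <- 180
  w
}

# Smallest signed angular difference a - b on the circle, in (-180, 180].
angle_diff <- function(a, b) wrap180(a - b)

.Rz <- function(deg) {
  t <- deg2rad(deg); c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
.Ry <- function(deg) {
  t <- deg2rad(deg); c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
.Rx <- function(deg) {
  t <- deg2rad(deg); c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' Validate a rotation matrix
#'
#' Checks orthonormality (`||M'M - I||_F < tol`) and `det(M) = +1` within
#' `tol`.
#'
#' @param m 3x3 numeric matrix.
#' @param tol tolerance (default `1e-9`).
#' @param name label used in error messages.
#' @return `m`, invisibly, if valid; otherwise an error naming the offence.
#' @export
validate_rotation <- function(m, tol = .ORTHO_TOL, name = "matrix") {
  if (!is.matrix(m) || !all(dim(m) == c(3, 3)) || !all(is.finite(m)))
    stop(sprintf("%s is not a finite 3x3 matrix", name))
  ortho <- sqrt(sum((crossprod(m) - diag(3))^2))
  if (ortho >= tol)
    stop(sprintf("%s is not orthonormal (||M'M - I||_F = %.3g >= %.3g)",
                 name, ortho, tol))
  if (abs(det(m) - 1) >= tol)
    stop(sprintf("%s has det %.6f, not +1: improper rotation", name, det(m)))
  invisible(m)
}

#' Build a rotation matrix from refinement (z-y-z) Euler angles
#'
#' Composes `R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)` under the right-handed,
#' counter-clockwise-positive convention of the refinement package whose STAR
#' files are consumed (see the worked example in the package vignette).
#'
#' @param rot,tilt,psi Euler angles in degrees (scalars).
#' @return a 3x3 rotation matrix.
#' @export
euler_zyz_to_matrix <- function(rot, tilt, psi) {
  if (!all(is.finite(c(rot, tilt, psi))))
    stop("non-finite Euler angle")
  .Rz(psi) %*% .Ry(tilt) %*% .Rz(rot)
}

#' Build a rotation matrix from z-y-x (alpha, beta, gamma) angles
#'
#' Composes `R = Rz(alpha) %*% Ry(beta) %*% Rx(gamma)`, the inverse of
#' [matrix_to_euler_zyx()].
#'
#' @param alpha,beta,gamma angles in degrees (scalars).
#' @return a 3x3 rotation matrix.
#' @export
euler_zyx_to_matrix <- function(alpha, beta, gamma) {
  if (!all(is.finite(c(alpha, beta, gamma))))
    stop("non-finite Euler angle")
  .Rz(alpha) %*% .Ry(beta) %*% .Rx(gamma)
}

#' Relative rotation of the condensing body in the modifying-body frame
#'
#' The relative orientation between the two rigid bodies is the product of
#' the inverse (here: transpose) rotation matrix of the reference body and
#' the rotation matrix of the other body: `t(r_mod) %*% r_cond`. The result
#' is invariant to any common pre-rotation (the particle's viewing
#' direction).
#'
#' @param r_mod rotation matrix of the reference (modifying) body.
#' @param r_cond rotation matrix of the other (condensing) body.
#' @return a 3x3 rotation matrix.
#' @export
relative_rotation <- function(r_mod, r_cond) {
  validate_rotation(r_mod, name = "r_mod")
  validate_rotation(r_cond, name = "r_cond")
  crossprod(r_mod, r_cond)
}

#' Decompose a rotation matrix into z-y-x Euler angles
#'
#' Returns `(alpha, beta, gamma)` in degrees such that
#' `R = Rz(alpha) %*% Ry(beta) %*% Rx(gamma)`, with `alpha, gamma` in
#' `(-180, 180]` and `beta` in `[-90, 90]`. At gimbal lock
#' (`|beta| = 90` within `1e-7` degrees) the decomposition is degenerate:
#' `gamma` is set to 0 and `alpha` absorbs the free degree of freedom, so the
#' rebuilt matrix still reproduces the input.
#'
#' @param r 3x3 rotation matrix.
#' @return named numeric vector `c(alpha, beta, gamma)` in degrees.
#' @export
matrix_to_euler_zyx <- function(r) {
  validate_rotation(r, name = "r")
  sb <- max(-1, min(1, -r[3, 1]))
  cb <- sqrt(r[3, 2]^2 + r[3, 3]^2)
  if (cb < sin(deg2rad(.GIMBAL_TOL_DEG))) {
    beta <- if (sb > 0) 90 else -90
    gamma <- 0
    alpha <- rad2deg(atan2(-r[1, 2], sign(sb) * r[1, 3]))
  } else {
    beta <- rad2deg(atan2(sb, cb))
    alpha <- rad2deg(atan2(r[2, 1], r[1, 1]))
    gamma <- rad2deg(atan2(r[3, 2], r[3, 3]))
  }
  c(alpha = wrap180(alpha), beta = beta, gamma = wrap180(gamma))
}

# 180-degree rotation about an arbitrary unit axis.
.C2 <- function(axis) {
  u <- axis / sqrt(sum(axis^2))
  2 * tcrossprod(u) - diag(3)
}

#' C2-equivalent relative orientations
#'
#' Symmetry expansion applies the internal C2 operator of each body's
#' reference map independently, so one physical particle can appear under up
#' to four equivalent relative orientations:
#' `t(S_mod) %*% R %*% S_cond` with `S` ranging over `{I, C2(axis)}` per
#' body. Duplicates are collapsed at Frobenius distance `1e-9`.
#'
#' @param orientation numeric `(alpha, beta, gamma)` in degrees.
#' @param axis_mod,axis_cond unit C2 axes of the modifying and condensing
#'   reference maps (default `c(0, 0, 1)`).
#' @return data.frame with columns `alpha`, `beta`, `gamma`, one row per
#'   distinct equivalent (at most 4).
#' @export
c2_equivalents <- function(orientation, axis_mod = c(0, 0, 1),
                           axis_cond = c(0, 0, 1)) {
  for (ax in list(axis_mod, axis_cond))
    if (abs(sqrt(sum(ax^2)) - 1) >= 1e-9)
      stop("C2 axis must be a unit vector")
  r <- euler_zyx_to_matrix(orientation[[1]], orientation[[2]], orientation[[3]])
  sm <- .C2(axis_mod); sc <- .C2(axis_cond)
  mats <- list(r, t(sm) %*% r, r %*% sc, t(sm) %*% r %*% sc)
  keep <- list()
  for (m in mats) {
    dup <- any(vapply(keep, function(k) sqrt(sum((k - m)^2)) < .DUP_TOL,
                      logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- m
  }
  ang <- t(vapply(keep, matrix_to_euler_zyx, numeric(3)))
  data.frame(alpha = ang[, 1], beta = ang[, 2], gamma = ang[, 3])
}

#' Canonical representative of a C2 equivalence class
#'
#' Deterministically picks, among [c2_equivalents()], the orientation that is
#' lexicographically minimal in `(|beta|, |alpha|, |gamma|)` (ties broken by
#' the signed values). Idempotent: canonicalizing a canonical orientation
#' returns it unchanged.
#'
#' @inheritParams c2_equivalents
#' @return named numeric vector `c(alpha, beta, gamma)`.
#' @export
canonicalize_orientation <- function(orientation, axis_mod = c(0, 0, 1),
                                     axis_cond = c(0, 0, 1)) {
  eq <- c2_equivalents(orientation, axis_mod, axis_cond)
  key <- cbind(round(abs(eq$beta) / .DUP_TOL), round(abs(eq$alpha) / .DUP_TOL),
               round(abs(eq$gamma) / .DUP_TOL),
               round(eq$beta / .DUP_TOL), round(eq$alpha / .DUP_TOL),
               round(eq$gamma / .DUP_TOL))
  i <- do.call(order, as.data.frame(key))[1]
  c(alpha = eq$alpha[i], beta = eq$beta[i], gamma = eq$gamma[i])
}

#' Draw rotation matrices uniformly over SO(3)
#'
#' Uses the unit-quaternion construction (three uniform variates per draw),
#' consuming the current RNG stream.
#'
#' @param n number of rotations.
#' @return a list of `n` 3x3 rotation matrices.
#' @export
random_rotations <- function(n) {
  e <- .random_rotation_elems(n)
  lapply(seq_len(n), function(i) .elems_matrix(e, i))
}

# ---- vectorised element kernels ------------------------------------------
# A rotation batch is stored as a list of 9 numeric vectors r11..r33 so that
# whole-table pipelines stay O(n) vector arithmetic.

.zyz_elems <- function(rot, tilt, psi) {
  cr <- cos(deg2rad(rot)); sr <- sin(deg2rad(rot))
  ct <- cos(deg2rad(tilt)); st <- sin(deg2rad(tilt))
  cp <- cos(deg2rad(psi)); sp <- sin(deg2rad(psi))
  list(r11 = cp * ct * cr - sp * sr, r12 = -cp * ct * sr - sp * cr, r13 = cp * st,
       r21 = sp * ct * cr + cp * sr, r22 = -sp * ct * sr + cp * cr, r23 = sp * st,
       r31 = -st * cr,               r32 = st * sr,                 r33 = ct)
}

.zyx_elems <- function(alpha, beta, gamma) {
  ca <- cos(deg2rad(alpha)); sa <- sin(deg2rad(alpha))
  cb <- cos(deg2rad(beta));  sb <- sin(deg2rad(beta))
  cg <- cos(deg2rad(gamma)); sg <- sin(deg2rad(gamma))
  list(r11 = ca * cb, r12 = ca * sb * sg - sa * cg, r13 = ca * sb * cg + sa * sg,
       r21 = sa * cb, r22 = sa * sb * sg + ca * cg, r23 = sa * sb * cg - ca * sg,
       r31 = -sb,     r32 = cb * sg,                r33 = cb * cg)
}

.elems_t <- function(e) {
  list(r11 = e$r11, r12 = e$r21, r13 = e$r31,
       r21 = e$r12, r22 = e$r22, r23 = e$r32,
       r31 = e$r13, r32 = e$r23, r33 = e$r33)
}

.elems_mult <- function(a, b) {
  list(r11 = a$r11 * b$r11 + a$r12 * b$r21 + a$r13 * b$r31,
       r12 = a$r11 * b$r12 + a$r12 * b$r22 + a$r13 * b$r32,
       r13 = a$r11 * b$r13 + a$r12 * b$r23 + a$r13 * b$r33,
       r21 = a$r21 * b$r11 + a$r22 * b$r21 + a$r23 * b$r31,
       r22 = a$r21 * b$r12 + a$r22 * b$r22 + a$r23 * b$r32,
       r23 = a$r21 * b$r13 + a$r22 * b$r23 + a$r23 * b$r33,
       r31 = a$r31 * b$r11 + a$r32 * b$r21 + a$r33 * b$r31,
       r32 = a$r31 * b$r12 + a$r32 * b$r22 + a$r33 * b$r32,
       r33 = a$r31 * b$r13 + a$r32 * b$r23 + a$r33 * b$r33)
}

.elems_matrix <- function(e, i) {
  matrix(c(e$r11[i], e$r21[i], e$r31[i],
           e$r12[i], e$r22[i], e$r32[i],
           e$r13[i], e$r23[i], e$r33[i]), 3, 3)
}

# Vectorised z-y-x decomposition; gimbal rows get gamma = 0.
.elems_to_zyx <- function(e) {
  sb <- pmax(-1, pmin(1, -e$r31))
  cb <- sqrt(e$r32^2 + e$r33^2)
  gimbal <- cb < sin(deg2rad(.GIMBAL_TOL_DEG))
  beta <- rad2deg(atan2(sb, cb))
  alpha <- rad2deg(atan2(e$r21, e$r11))
  gamma <- rad2deg(atan2(e$r32, e$r33))
  if (any(gimbal)) {
    beta[gimbal] <- ifelse(sb[gimbal] > 0, 90, -90)
    alpha[gimbal] <- rad2deg(atan2(-e$r12[gimbal],
                                   sign(sb[gimbal]) * e$r13[gimbal]))
    gamma[gimbal] <- 0
  }
  data.frame(alpha = wrap180(alpha), beta = beta, gamma = wrap180(gamma))
}

# Vectorised z-y-z decomposition (for writing refinement angles back out).
.elems_to_zyz <- function(e) {
  ct <- pmax(-1, pmin(1, e$r33))
  st <- sqrt(pmin(1, e$r13^2 + e$r23^2))
  tilt <- rad2deg(atan2(st, ct))
  degen <- st < 1e-12
  rot <- rad2deg(atan2(e$r32, -e$r31))
  psi <- rad2deg(atan2(e$r23, e$r13))
  if (any(degen)) {
    rot[degen] <- 0
    up <- degen & ct > 0
    dn <- degen & ct <= 0
    psi[up] <- rad2deg(atan2(e$r21[up], e$r11[up]))
    psi[dn] <- rad2deg(atan2(-e$r21[dn], -e$r11[dn]))
  }
  data.frame(rot = wrap180(rot), tilt = tilt, psi = wrap180(psi))
}

# Rotation batch from axis-angle: axes is an n x 3 matrix of unit axes,
# angle_deg a vector (Rodrigues formula, element-wise).
.axis_angle_elems <- function(axes, angle_deg) {
  t <- deg2rad(angle_deg); c <- cos(t); s <- sin(t); v <- 1 - c
  x <- axes[, 1]; y <- axes[, 2]; z <- axes[, 3]
  list(r11 = c + x * x * v,     r12 = x * y * v - z * s, r13 = x * z * v + y * s,
       r21 = y * x * v + z * s, r22 = c + y * y * v,     r23 = y * z * v - x * s,
       r31 = z * x * v - y * s, r32 = z * y * v + x * s, r33 = c + z * z * v)
}

# Uniform SO(3) batch via random unit quaternions.
.random_rotation_elems <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  qx <- sqrt(1 - u1) * sin(2 * pi * u2)
  qy <- sqrt(1 - u1) * cos(2 * pi * u2)
  qz <- sqrt(u1) * sin(2 * pi * u3)
  qw <- sqrt(u1) * cos(2 * pi * u3)
  list(r11 = 1 - 2 * (qy^2 + qz^2), r12 = 2 * (qx * qy - qz * qw), r13 = 2 * (qx * qz + qy * qw),
       r21 = 2 * (qx * qy + qz * qw), r22 = 1 - 2 * (qx^2 + qz^2), r23 = 2 * (qy * qz - qx * qw),
       r31 = 2 * (qx * qz - qy * qw), r32 = 2 * (qy * qz + qx * qw), r33 = 1 - 2 * (qx^2 + qy^2))
}
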