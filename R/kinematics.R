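# Global frame convention: x = craniocaudal, y = proximodistal (the femur's
# long axis points along -y at neutral), z = mediolateral. At neutral the
# FE axis is z, the ABD axis is x and the LAR axis is y.

.deg2rad <- function(d) d * pi / 180

# Rodrigues rotation about unit axis u by angle (radians), right-hand rule.
rotation_about <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(u)
}

#' Femur orientation at a posture
#'
#' Builds the rotation that carries femur-local neutral coordinates into the
#' global frame, as the intrinsic cascade: flexion-extension about the
#' pelvis-fixed mediolateral axis (z), then abduction-adduction about the
#' FE-rotated craniocaudal axis, then long-axis rotation about the FE- and
#' ABD-rotated proximodistal axis. Each anatomical angle is multiplied by the
#' joint's per-degree-of-freedom sense before the right-handed rotation is
#' applied.
#'
#' @param q A [posture()] (degrees, anatomical signs).
#' @param joint A [hip_joint()].
#' @return A 3x3 rotation matrix (orthonormal, determinant +1).
#' @export
#' @examples
#' femur_orientation(posture(0, 0, 0))            # identity
#' femur_orientation(posture(-45, -10, 25))       # 45 flex, 10 abd, 25 lat
femur_orientation <- function(q, joint = hip_joint()) {
  q <- .as_posture(q)
  s <- joint$dof_senses
  ang <- .deg2rad(c(s["FE"] * q[1], s["ABD"] * q[2], s["LAR"] * q[3]))
  rotation_about(c(0, 0, 1), ang[1]) %*%
    rotation_about(c(1, 0, 0), ang[2]) %*%
    rotation_about(c(0, 1, 0), ang[3])
}

#' Instantaneous hip joint axes at a posture
#'
#' Under the corrected convention the flexion-extension axis stays parallel
#' to the pelvis z axis for every femoral posture; the abduction-adduction
#' axis is the FE-rotated x axis (it does not move with abduction or
#' long-axis rotation); and the long-axis rotation axis is the FE- and
#' ABD-rotated y axis (it does not move with long-axis rotation itself).
#' Under the legacy convention -- the error of the original published models
#' -- all three axes stay in their neutral, pelvis-fixed orientations
#' (z, x, y) at every posture.
#'
#' @param q A [posture()].
#' @param joint A [hip_joint()].
#' @param mode `"corrected"` or `"legacy"`.
#' @return An `axis_set`: list with `axes` (3x3 matrix whose columns `FE`,
#'   `ABD`, `LAR` are unit vectors in the global frame), `mode` and the
#'   posture.
#' @export
#' @examples
#' axis_set(posture(90, 0, 0))            # ABD axis rotated 90 deg about z
#' axis_set(posture(-45, -10, 25), mode = "legacy")  # always (z, x, y)
axis_set <- function(q, joint = hip_joint(),
                     mode = c("corrected", "legacy")) {
  mode <- match.arg(mode)
  q <- .as_posture(q)
  s <- joint$dof_senses
  axes <- cbind(FE = c(0, 0, 1), ABD = c(1, 0, 0), LAR = c(0, 1, 0))
  if (mode == "corrected") {
    Rfe <- rotation_about(c(0, 0, 1), .deg2rad(s["FE"] * q[1]))
    axes[, "ABD"] <- Rfe %*% c(1, 0, 0)
    axes[, "LAR"] <- Rfe %*%
      rotation_about(c(1, 0, 0), .deg2rad(s["ABD"] * q[2])) %*% c(0, 1, 0)
  }
  structure(list(axes = axes, mode = mode, posture = q), class = "axis_set")
}

#' @export
print.axis_set <- function(x, ...) {
  cat("<axis_set> mode=", x$mode, " at (",
      paste(format(x$posture), collapse = ", "), ")\n", sep = "")
  print(round(x$axes, 6))
  invisible(x)
}

#' Transform femur-local points to the global frame
#'
#' Femur-local coordinates are expressed relative to the joint centre at
#' neutral, so a posture acts as a pure rotation about the joint centre:
#' `global = center + R %*% p`. Pelvis-owned points need no transform (the
#' pelvis frame is the global frame).
#'
#' @param p Numeric length 3, or an n x 3 matrix of femur-local points.
#' @param q A [posture()].
#' @param joint A [hip_joint()].
#' @return Global coordinates with the same shape as `p`.
#' @export
transform_femur_point <- function(p, q, joint = hip_joint()) {
  R <- femur_orientation(q, joint)
  if (is.matrix(p)) {
    t(joint$center + R %*% t(p))
  } else {
    as.numeric(joint$center + R %*% as.numeric(p))
  }
}

#' Per-posture axis triads over a sweep grid
#'
#' Tabulates the instantaneous joint axes at every posture of a sweep
#' protocol, one row per posture x axis, for export and animation.
#'
#' @param protocol A [sweep_protocol()].
#' @param joint A [hip_joint()].
#' @param mode `"corrected"` or `"legacy"`.
#' @return A tibble with columns `fe_deg, abd_deg, lar_deg, mode, axis,
#'   ux, uy, uz`.
#' @export
axis_frames <- function(protocol = sweep_protocol(), joint = hip_joint(),
                        mode = c("corrected", "legacy")) {
  mode <- match.arg(mode)
  fe <- seq(protocol$fe_min, protocol$fe_max, by = protocol$fe_step)
  rows <- lapply(fe, function(f) {
    q <- posture(f, protocol$abd_deg, protocol$lar_deg)
    ax <- axis_set(q, joint, mode)$axes
    tibble(fe_deg = f, abd_deg = q[[2]], lar_deg = q[[3]], mode = mode,
           axis = DOFS, ux = unname(ax[1, ]), uy = unname(ax[2, ]),
           uz = unname(ax[3, ]))
  })
  dplyr::bind_rows(rows)
}
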