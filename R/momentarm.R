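# Vectorised geometry engine. A compiled model caches the path points as a
# 3 x N matrix (pelvis points already global; femur points local to the joint
# centre), the consecutive-pair segment index, and which segments mix the two
# owners -- only mixed segments change length with posture, so only they
# contribute to moment arms.

.compile_model <- function(model) {
  validate_limb_model(model)
  m <- model$muscles
  P <- t(as.matrix(m[, c("x", "y", "z")]))
  fem <- m$segment == "femur"
  muscles <- unique(m$muscle)
  mu_idx <- match(m$muscle, muscles)
  same <- mu_idx[-1] == mu_idx[-length(mu_idx)]
  seg_a <- which(same)
  seg_b <- seg_a + 1L
  list(P = P, fem = fem, seg_a = seg_a, seg_b = seg_b,
       seg_muscle = mu_idx[seg_a],
       mixed = fem[seg_a] != fem[seg_b],
       muscles = muscles, center = model$joint$center,
       senses = model$joint$dof_senses,
       femur_length = model$femur_length)
}

.points_global <- function(cache, R) {
  G <- cache$P
  if (any(cache$fem)) {
    G[, cache$fem] <- cache$center + R %*% cache$P[, cache$fem, drop = FALSE]
  }
  G
}

# muscle-tendon lengths for all muscles given a femur orientation
.lengths_at <- function(cache, R) {
  G <- .points_global(cache, R)
  d <- G[, cache$seg_b, drop = FALSE] - G[, cache$seg_a, drop = FALSE]
  len <- sqrt(colSums(d^2))
  tol <- 1e-12 * cache$femur_length
  if (any(len < tol)) {
    bad <- cache$muscles[cache$seg_muscle[len < tol][1]]
    stop("degenerate geometry: zero-length path segment in muscle ", bad,
         call. = FALSE)
  }
  as.numeric(rowsum(len, cache$seg_muscle, reorder = TRUE))
}

# tendon-excursion moment arms, all muscles x requested dofs, one posture
.arms_excursion <- function(cache, q, mode, h_deg, dofs = DOFS) {
  R0 <- .femur_R(cache, q)
  ax <- .axes_at(cache, q, mode)
  hr <- .deg2rad(h_deg)
  out <- matrix(NA_real_, length(cache$muscles), length(dofs),
                dimnames = list(cache$muscles, dofs))
  for (d in dofs) {
    u <- ax[, d]
    s <- cache$senses[d]
    Lp <- .lengths_at(cache, rotation_about(u, s * hr) %*% R0)
    Lm <- .lengths_at(cache, rotation_about(u, -s * hr) %*% R0)
    out[, d] <- -(Lp - Lm) / (2 * hr)
  }
  out
}

# exact cross-product moment arms, all muscles x requested dofs, one posture
.arms_geometric <- function(cache, q, mode, dofs = DOFS) {
  R0 <- .femur_R(cache, q)
  ax <- .axes_at(cache, q, mode)
  G <- .points_global(cache, R0)
  out <- matrix(0, length(cache$muscles), length(dofs),
                dimnames = list(cache$muscles, dofs))
  mix <- which(cache$mixed)
  if (length(mix) == 0) return(out)
  ia <- cache$seg_a[mix]; ib <- cache$seg_b[mix]
  fem_first <- cache$fem[ia]
  # b = femur-owned endpoint, a = pelvis-owned endpoint of each mixed segment
  bi <- ifelse(fem_first, ia, ib)
  ai <- ifelse(fem_first, ib, ia)
  B <- G[, bi, drop = FALSE]; A <- G[, ai, drop = FALSE]
  V <- B - A
  len <- sqrt(colSums(V^2))
  tol <- 1e-12 * cache$femur_length
  if (any(len < tol)) {
    bad <- cache$muscles[cache$seg_muscle[mix][len < tol][1]]
    stop("degenerate geometry: zero-length path segment in muscle ", bad,
         call. = FALSE)
  }
  E <- sweep(V, 2, len, "/")
  Rv <- B - cache$center
  # W = (b - c) x e, columnwise
  W <- rbind(Rv[2, ] * E[3, ] - Rv[3, ] * E[2, ],
             Rv[3, ] * E[1, ] - Rv[1, ] * E[3, ],
             Rv[1, ] * E[2, ] - Rv[2, ] * E[1, ])
  grp <- factor(cache$seg_muscle[mix], levels = seq_along(cache$muscles))
  for (d in dofs) {
    contrib <- -cache$senses[d] * colSums(ax[, d] * W)
    out[, d] <- as.numeric(rowsum(contrib, grp))
  }
  out
}

.femur_R <- function(cache, q) {
  q <- .as_posture(q)
  s <- cache$senses
  rotation_about(c(0, 0, 1), .deg2rad(s["FE"] * q[1])) %*%
    rotation_about(c(1, 0, 0), .deg2rad(s["ABD"] * q[2])) %*%
    rotation_about(c(0, 1, 0), .deg2rad(s["LAR"] * q[3]))
}

.axes_at <- function(cache, q, mode) {
  q <- .as_posture(q)
  s <- cache$senses
  axes <- cbind(FE = c(0, 0, 1), ABD = c(1, 0, 0), LAR = c(0, 1, 0))
  if (mode == "corrected") {
    Rfe <- rotation_about(c(0, 0, 1), .deg2rad(s["FE"] * q[1]))
    axes[, "ABD"] <- Rfe %*% c(1, 0, 0)
    axes[, "LAR"] <- Rfe %*%
      rotation_about(c(1, 0, 0), .deg2rad(s["ABD"] * q[2])) %*% c(0, 1, 0)
  } else if (mode != "legacy") {
    stop("unknown mode: ", mode, call. = FALSE)
  }
  axes
}

.check_h <- function(h_deg) {
  if (!is.numeric(h_deg) || length(h_deg) != 1 || !is.finite(h_deg) ||
      h_deg <= 0 || h_deg > 2) {
    stop("finite-difference half-step `h_deg` must be in (0, 2] degrees",
         call. = FALSE)
  }
  h_deg
}

.check_muscle <- function(cache, muscle) {
  if (!muscle %in% cache$muscles) {
    stop("unknown muscle: ", muscle, call. = FALSE)
  }
  match(muscle, cache$muscles)
}

#' Muscle-tendon length at a posture
#'
#' Sum of Euclidean segment lengths of the muscle's path polyline after
#' transforming its femur-owned points to the global frame at the given
#' posture.
#'
#' @param model A `limb_model`.
#' @param muscle Muscle name.
#' @param q A [posture()].
#' @return Length in model units (strictly positive).
#' @export
#' @examples
#' toy <- make_hinge_toy()
#' muscle_length(toy, "TOY", posture(60, 0, 0))  # sqrt(3) by law of cosines
muscle_length <- function(model, muscle, q) {
  cache <- .compile_model(model)
  i <- .check_muscle(cache, muscle)
  .lengths_at(cache, .femur_R(cache, q))[i]
}

#' Moment arm by the tendon-excursion method
#'
#' Estimates the moment arm as `r = -dL/dtheta` by central differencing:
#' the femur (and every femur-owned path point) is rotated by plus and minus
#' a half-step about the instantaneous axis of the requested degree of
#' freedom -- a pure hinge rotation through the joint centre, holding the
#' other two angles fixed -- and the length change is divided by the angle
#' change in radians. Positive values are moment arms for extension /
#' adduction / lateral rotation; negative for flexion / abduction / medial
#' rotation.
#'
#' @param model A `limb_model`.
#' @param muscle Muscle name.
#' @param dof `"FE"`, `"ABD"` or `"LAR"`.
#' @param q A [posture()].
#' @param mode `"corrected"` (axes rotate with the femur) or `"legacy"`
#'   (pelvis-fixed axes, the historical error).
#' @param h_deg Central-difference half-step in degrees, in (0, 2].
#' @return Moment arm in model length units.
#' @seealso [geometric_moment_arm()] for the exact cross-product value.
#' @export
#' @examples
#' toy <- make_hinge_toy(a = 1, b = 1)
#' excursion_moment_arm(toy, "TOY", "FE", posture(60, 0, 0))  # ~0.5
excursion_moment_arm <- function(model, muscle, dof, q,
                                 mode = c("corrected", "legacy"),
                                 h_deg = 0.25) {
  mode <- match.arg(mode)
  dof <- match.arg(dof, DOFS)
  .check_h(h_deg)
  cache <- .compile_model(model)
  i <- .check_muscle(cache, muscle)
  .arms_excursion(cache, q, mode, h_deg, dofs = dof)[i, dof]
}

#' Moment arm by the exact geometric (cross-product) method
#'
#' For each path segment joining a pelvis-owned point `a` to a femur-owned
#' point `b`, the instantaneous length rate under a unit hinge rotation about
#' axis `u` through the joint centre `c` is `u . ((b - c) x e)` with `e` the
#' unit vector from `a` to `b`; the moment arm is minus the sense-weighted
#' sum over mixed-ownership segments. Segments owned entirely by one segment
#' are posture-invariant in length and contribute nothing. This is the exact
#' derivative the tendon-excursion method approximates, and serves as its
#' independent oracle.
#'
#' @inheritParams excursion_moment_arm
#' @return Moment arm in model length units.
#' @export
#' @examples
#' toy <- make_hinge_toy(a = 1, b = 1)
#' geometric_moment_arm(toy, "TOY", "FE", posture(60, 0, 0))  # exactly 0.5
geometric_moment_arm <- function(model, muscle, dof, q,
                                 mode = c("corrected", "legacy")) {
  mode <- match.arg(mode)
  dof <- match.arg(dof, DOFS)
  cache <- .compile_model(model)
  i <- .check_muscle(cache, muscle)
  .arms_geometric(cache, q, mode, dofs = dof)[i, dof]
}

#' Moment arms of every muscle at one posture
#'
#' Vectorised evaluation over all muscles and the requested degrees of
#' freedom.
#'
#' @inheritParams excursion_moment_arm
#' @param dofs Subset of `c("FE", "ABD", "LAR")`.
#' @param method `"excursion"` (tendon excursion, central differencing) or
#'   `"geometric"` (exact).
#' @return A tibble with columns `muscle, dof, moment_arm, moment_arm_norm`.
#' @export
moment_arms <- function(model, q, dofs = DOFS,
                        mode = c("corrected", "legacy"),
                        method = c("excursion", "geometric"), h_deg = 0.25) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  dofs <- match.arg(dofs, DOFS, several.ok = TRUE)
  cache <- .compile_model(model)
  arms <- if (method == "excursion") {
    .arms_excursion(cache, q, mode, .check_h(h_deg), dofs)
  } else {
    .arms_geometric(cache, q, mode, dofs)
  }
  tibble(muscle = rep(cache$muscles, times = length(dofs)),
         dof = rep(dofs, each = length(cache$muscles)),
         moment_arm = as.numeric(arms[, dofs]),
         moment_arm_norm = as.numeric(arms[, dofs]) / cache$femur_length)
}
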