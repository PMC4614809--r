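# The 19 hip muscles of the comparative archosaur models.
HIP_MUSCLES <- c("IF", "CFB", "CFL", "PIFE1", "PIFE2", "PIFI1", "PIFI2",
                 "ADD1", "ADD2", "ISTR", "ITBa", "ITBp", "FTE", "FTI3",
                 "AMB", "IFB", "IFMa", "IFMp", "PIT")

# run code with a private RNG stream, leaving the caller's stream untouched
.with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Analytic hinge-toy model with a closed-form moment arm
#'
#' A single straight-line muscle lying in the plane normal to the tested
#' degree of freedom's neutral axis: the origin sits on the pelvis at
#' distance `a` from the joint centre and the insertion on the femur at
#' distance `b`, collinear through the centre at neutral. Rotating the tested
#' dof by an angle `theta` gives the exact moment arm
#' `a * b * sin(theta) / sqrt(a^2 + b^2 + 2 * a * b * cos(theta))`
#' (and muscle length `sqrt(a^2 + b^2 + 2ab cos(theta))` by the law of
#' cosines), the validation yardstick for both moment-arm methods.
#'
#' @param a,b Positive origin and insertion offsets from the joint centre.
#' @param dof Degree of freedom the toy exercises (`"FE"`, `"ABD"`,
#'   `"LAR"`).
#' @param femur_length Normalization length (default 1).
#' @return A `limb_model` with one muscle named `"TOY"`.
#' @export
#' @examples
#' toy <- make_hinge_toy(a = 1, b = 1)
#' geometric_moment_arm(toy, "TOY", "FE", posture(60, 0, 0))  # 0.5
#' hinge_toy_moment_arm(1, 1, 60)                             # 0.5
make_hinge_toy <- function(a = 1, b = 1, dof = c("FE", "ABD", "LAR"),
                           femur_length = 1) {
  dof <- match.arg(dof)
  if (!is.finite(a) || a <= 0 || !is.finite(b) || b <= 0) {
    stop("`a` and `b` must be positive", call. = FALSE)
  }
  pts <- switch(dof,
    FE  = rbind(c(0, a, 0), c(0, -b, 0)),   # x-y plane, normal to z
    ABD = rbind(c(0, a, 0), c(0, -b, 0)),   # y-z plane, normal to x
    LAR = rbind(c(a, 0, 0), c(-b, 0, 0)))   # x-z plane, normal to y
  limb_model(
    name = paste0("hinge_toy_", dof),
    muscles = tibble(muscle = "TOY", segment = c("pelvis", "femur"),
                     x = pts[, 1], y = pts[, 2], z = pts[, 3]),
    femur_length = femur_length,
    metadata = list(kind = "hinge_toy", dof = dof, a = a, b = b))
}

#' Closed-form hinge-toy moment arm
#'
#' @param a,b Origin and insertion offsets of [make_hinge_toy()].
#' @param theta_deg Hinge angle in degrees.
#' @return `a * b * sin(theta) / sqrt(a^2 + b^2 + 2ab cos(theta))`.
#' @export
hinge_toy_moment_arm <- function(a, b, theta_deg) {
  th <- .deg2rad(theta_deg)
  a * b * sin(th) / sqrt(a^2 + b^2 + 2 * a * b * cos(th))
}

# anatomically flavoured sampling boxes (units of `scale`); x caudal
# (positive flexion-extension rotation retracts the femur toward +x),
# y dorsal (femur long axis along -y), z lateral; ventral-girdle
# origins (pubis, ischium) sit medially, iliac origins laterally
.synth_regions <- function() {
  box <- function(x, y, z) rbind(x = x, y = y, z = z)
  dorsal_origin <- box(c(-0.50, -0.10), c(0.15, 0.45), c(-0.10, 0.20))
  ischium_origin <- box(c(0.15, 0.55), c(-0.45, -0.10), c(-0.25, 0.05))
  pubis_origin <- box(c(-0.40, -0.05), c(-0.60, -0.25), c(-0.25, 0.05))
  prox_insert <- box(c(-0.10, 0.10), c(-0.40, -0.15), c(-0.12, 0.12))
  dist_insert <- box(c(-0.10, 0.10), c(-0.75, -0.45), c(-0.12, 0.12))
  reg <- list()
  for (mu in c("IF", "IFB", "IFMa", "IFMp", "PIFI1", "PIFI2")) {
    reg[[mu]] <- list(origin = dorsal_origin, insertion = prox_insert)
  }
  for (mu in c("ITBa", "AMB")) {
    reg[[mu]] <- list(origin = dorsal_origin, insertion = dist_insert)
  }
  reg$ITBp <- list(origin = box(c(0.10, 0.40), c(0.15, 0.40),
                                c(-0.10, 0.20)),
                   insertion = dist_insert)
  reg$CFB <- list(origin = box(c(0.30, 0.60), c(-0.15, 0.15),
                               c(-0.10, 0.20)),
                  insertion = prox_insert)
  reg$CFL <- list(origin = box(c(0.55, 1.00), c(-0.15, 0.10),
                               c(-0.10, 0.20)),
                  insertion = box(c(-0.10, 0.10), c(-0.60, -0.35),
                                  c(-0.12, 0.12)))
  for (mu in c("ISTR", "PIT")) {
    reg[[mu]] <- list(origin = ischium_origin, insertion = prox_insert)
  }
  for (mu in c("FTE", "FTI3")) {
    reg[[mu]] <- list(origin = ischium_origin, insertion = dist_insert)
  }
  via_pube <- box(c(-0.20, 0.00), c(-0.65, -0.45), c(-0.20, 0.05))
  for (mu in c("PIFE1", "PIFE2")) {
    reg[[mu]] <- list(origin = pubis_origin, via = via_pube,
                      insertion = prox_insert)
  }
  for (mu in c("ADD1", "ADD2")) {
    reg[[mu]] <- list(origin = pubis_origin, insertion = prox_insert)
  }
  reg[HIP_MUSCLES]
}

.sample_box <- function(box, scale) {
  round(scale * stats::runif(3, box[, 1], box[, 2]), 6)
}

.sample_muscle_rows <- function(mu, reg, scale) {
  o <- .sample_box(reg$origin, scale)
  i <- .sample_box(reg$insertion, scale)
  if (!is.null(reg$via)) {
    v <- .sample_box(reg$via, scale)
    tibble(muscle = mu, segment = c("pelvis", "pelvis", "femur"),
           x = c(o[1], v[1], i[1]), y = c(o[2], v[2], i[2]),
           z = c(o[3], v[3], i[3]))
  } else {
    tibble(muscle = mu, segment = c("pelvis", "femur"),
           x = c(o[1], i[1]), y = c(o[2], i[2]), z = c(o[3], i[3]))
  }
}

# plausibility / conditioning: the joint-spanning path segment must keep a
# span of at least 0.4 femur lengths over the default posture range. Shorter
# spans would place an attachment essentially on the joint capsule, and the
# curvature of the length-angle curve (which grows like rho^3 / span^2 for
# insertion radius rho) would make the path ill-conditioned for
# finite-difference excursion analysis.
.length_ok <- function(rows, scale, min_span = 0.4) {
  cand <- limb_model("cand", rows, scale)
  cache <- .compile_model(cand)
  proto <- sweep_protocol()
  fe <- seq(proto$fe_min, proto$fe_max, by = proto$fe_step)
  mix <- which(cache$mixed)
  for (f in fe) {
    R <- .femur_R(cache, posture(f, proto$abd_deg, 0))
    G <- .points_global(cache, R)
    d <- G[, cache$seg_b[mix], drop = FALSE] -
      G[, cache$seg_a[mix], drop = FALSE]
    if (any(colSums(d^2) < (min_span * scale)^2)) return(FALSE)
  }
  TRUE
}

# signs of one candidate muscle's normalized geometric moment arms across
# the default sweep grid
.polarity_ok <- function(rows, femur_length, targets, margin) {
  cand <- limb_model("cand", rows, femur_length)
  rec <- run_sweep(cand, sweep_protocol(dofs = names(targets)),
                   method = "geometric")
  for (d in names(targets)) {
    r <- rec$moment_arm_norm[rec$dof == d]
    if (!all(sign(targets[[d]]) * r >= margin)) return(d)
  }
  NULL
}

#' Generate a randomized archosaur-hip-like model
#'
#' Draws muscle attachment points in anatomically plausible regions (e.g.
#' caudofemoralis origins caudal to the hip, iliofemoralis origins on the
#' dorsal ilium, insertions on the femoral shaft) for the standard set of 19
#' hip muscles of the comparative archosaur models. Generation is
#' deterministic: the same seed yields a byte-identical model file
#' (coordinates are rounded to 6 decimals). The caller's RNG stream is left
#' untouched. Candidate geometries are resampled until the joint-spanning
#' path segment keeps a span of at least 0.4 femur lengths over the default
#' posture sweep: shorter spans would put an attachment essentially on the
#' joint capsule and make the length-angle curve ill-conditioned for
#' excursion analysis.
#'
#' Optional polarity targets force a muscle's moment arm sign for a degree of
#' freedom: the muscle's attachments are resampled until its normalized
#' geometric moment arm keeps the required sign, with a margin of 0.01 femur
#' lengths, across the default flexion-extension sweep grid (so an
#' "obligatory adductor" target really is obligatory over the sweep, not just
#' at neutral).
#'
#' @param seed Integer seed (default 0).
#' @param n_muscles Number of muscles, up to 19 (taken in canonical order).
#' @param scale Coordinate scale; the femur length equals `scale`.
#' @param posture_class `"biped"` or `"quadruped"` (stored in metadata; used
#'   by cohort contrasts).
#' @param polarity_targets Named list, e.g. `list(PIT = c(ABD = 1))`:
#'   for each named muscle, a named vector of required moment-arm signs per
#'   dof (+1 or -1). Unsatisfiable targets raise an error naming the muscle
#'   and dof.
#' @param name Model name (default derived from the seed).
#' @return A validated `limb_model`.
#' @export
#' @examples
#' m <- make_hip_model(seed = 1)
#' m
make_hip_model <- function(seed = 0, n_muscles = 19, scale = 1,
                           posture_class = c("biped", "quadruped"),
                           polarity_targets = NULL, name = NULL) {
  posture_class <- match.arg(posture_class)
  if (n_muscles < 1 || n_muscles > length(HIP_MUSCLES)) {
    stop("`n_muscles` must be between 1 and ", length(HIP_MUSCLES),
         call. = FALSE)
  }
  if (!is.finite(scale) || scale <= 0) {
    stop("`scale` must be positive", call. = FALSE)
  }
  regions <- .synth_regions()
  muscles <- HIP_MUSCLES[seq_len(n_muscles)]
  bad_target <- setdiff(names(polarity_targets), muscles)
  if (length(bad_target)) {
    stop("polarity target for unknown muscle: ",
         paste(bad_target, collapse = ", "), call. = FALSE)
  }
  rows <- .with_private_seed(seed, {
    out <- vector("list", length(muscles))
    for (k in seq_along(muscles)) {
      mu <- muscles[k]
      targets <- polarity_targets[[mu]]
      ok <- FALSE
      last_bad <- NULL
      for (try in seq_len(400)) {
        cand <- .sample_muscle_rows(mu, regions[[mu]], scale)
        if (!.length_ok(cand, scale)) next
        if (!is.null(targets)) {
          last_bad <- .polarity_ok(cand, scale, as.list(targets),
                                   margin = 0.01)
          if (!is.null(last_bad)) next
        }
        out[[k]] <- cand; ok <- TRUE; break
      }
      if (!ok) {
        if (!is.null(last_bad)) {
          stop("unsatisfiable polarity target for muscle ", mu, ", dof ",
               last_bad, call. = FALSE)
        }
        stop("could not draw a plausible geometry for muscle ", mu,
             call. = FALSE)
      }
    }
    dplyr::bind_rows(out)
  })
  if (is.null(name)) name <- sprintf("synthetic_hip_seed%d", seed)
  limb_model(
    name = name, muscles = rows, femur_length = scale,
    metadata = list(taxon = name, posture_class = posture_class,
                    generator = "hiparm-synth-1", seed = seed))
}

#' Uniformly scale a limb model
#'
#' Multiplies every coordinate, the joint centre and the femur length by
#' `k`. Raw moment arms scale by `k`; normalized moment arms are invariant.
#'
#' @param model A `limb_model`.
#' @param k Positive scale factor.
#' @return The scaled `limb_model`.
#' @export
scale_model <- function(model, k) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0) {
    stop("`k` must be a single positive number", call. = FALSE)
  }
  m <- model$muscles
  m$x <- m$x * k; m$y <- m$y * k; m$z <- m$z * k
  limb_model(name = model$name, muscles = m,
             femur_length = model$femur_length * k,
             joint = hip_joint(center = model$joint$center * k,
                               dof_senses = model$joint$dof_senses),
             metadata = model$metadata)
}
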