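# shared fixtures, all built in code

# minimal straight-line model: origin (0,1,0) on the pelvis, insertion
# (0,-1,0) femur-local; neutral length 2
straight_model <- function(femur_length = 1) {
  limb_model(
    "straight",
    muscles = tibble::tibble(muscle = "M1",
                             segment = c("pelvis", "femur"),
                             x = 0, y = c(1, -1), z = 0),
    femur_length = femur_length)
}

# reflect a model across the x-y plane, optionally flipping dof senses
mirror_model <- function(model, flip = character()) {
  m <- model$muscles
  m$z <- -m$z
  senses <- model$joint$dof_senses
  senses[flip] <- -senses[flip]
  limb_model(model$name, m, model$femur_length,
             joint = hip_joint(center = model$joint$center * c(1, 1, -1),
                               dof_senses = senses),
             metadata = model$metadata)
}

# hand-built record table with prescribed normalized moment arms on a grid
fake_records <- function(r_norm_by_dof, fe = seq(-90, 90, 15),
                         model = "fake", muscle = "MU",
                         mode = "corrected", femur_length = 1) {
  rows <- lapply(names(r_norm_by_dof), function(d) {
    r <- r_norm_by_dof[[d]](fe)
    tibble::tibble(model = model, muscle = muscle, dof = d, fe_deg = fe,
                   abd_deg = -10, lar_deg = 0, mode = mode,
                   moment_arm = r * femur_length, moment_arm_norm = r)
  })
  hiparm:::new_marm_records(dplyr::bind_rows(rows))
}

expect_rotation <- function(R, tol = 1e-12) {
  expect_lt(max(abs(crossprod(R) - diag(3))), tol)
  expect_lt(abs(det(R) - 1), tol)
}

random_postures <- function(n, range = 150) {
  matrix(stats::runif(3 * n, -range, range), ncol = 3)
}
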