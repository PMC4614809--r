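test_that("muscle length follows the law of cosines on the straight toy", {
  m <- straight_model()
  expect_equal(muscle_length(m, "M1", posture(0, 0, 0)), 2)
  expect_equal(muscle_length(m, "M1", posture(60, 0, 0)), sqrt(3),
               tolerance = 1e-12)
  for (th in c(-120, -37.5, 45, 150)) {
    expect_equal(muscle_length(m, "M1", posture(th, 0, 0)),
                 sqrt(2 + 2 * cos(th * pi / 180)), tolerance = 1e-12)
  }
  expect_error(muscle_length(m, "NOPE", posture(0, 0, 0)), "unknown muscle")
})

test_that("a collinear via point leaves length and moment arms unchanged", {
  plain <- straight_model()
  with_via <- limb_model(
    "straight_via",
    muscles = tibble::tibble(muscle = "M1",
                             segment = c("pelvis", "pelvis", "femur"),
                             x = 0, y = c(1, 0.5, -1), z = 0),
    femur_length = 1)
  # the insertion lies on the long-axis line, so the path stays straight
  # through the via point under any long-axis rotation
  for (q in list(posture(0, 0, 0), posture(0, 0, 77))) {
    expect_equal(muscle_length(with_via, "M1", q),
                 muscle_length(plain, "M1", q), tolerance = 1e-12)
    for (d in c("FE", "ABD", "LAR")) {
      expect_equal(geometric_moment_arm(with_via, "M1", d, q),
                   geometric_moment_arm(plain, "M1", d, q),
                   tolerance = 1e-12)
    }
  }
})

test_that("hinge toys recover the closed-form moment arm for each dof", {
  cases <- list(list(a = 1, b = 1, dof = "FE"),
                list(a = 1, b = 1, dof = "ABD"),
                list(a = 2, b = 1, dof = "LAR"))
  for (cs in cases) {
    toy <- make_hinge_toy(cs$a, cs$b, cs$dof)
    for (th in seq(-150, 150, by = 10)) {
      q <- posture(ifelse(cs$dof == "FE", th, 0),
                   ifelse(cs$dof == "ABD", th, 0),
                   ifelse(cs$dof == "LAR", th, 0))
      expect_equal(geometric_moment_arm(toy, "TOY", cs$dof, q),
                   hinge_toy_moment_arm(cs$a, cs$b, th), tolerance = 1e-9)
    }
  }
  # spot values: ab sin(60)/sqrt(3) = 1/2 and 2 sin(90)/sqrt(5)
  expect_equal(geometric_moment_arm(make_hinge_toy(), "TOY", "FE",
                                    posture(60, 0, 0)), 0.5,
               tolerance = 1e-12)
  expect_equal(geometric_moment_arm(make_hinge_toy(2, 1, "LAR"), "TOY",
                                    "LAR", posture(0, 0, 90)), 2 / sqrt(5),
               tolerance = 1e-12)
  expect_equal(excursion_moment_arm(make_hinge_toy(), "TOY", "FE",
                                    posture(60, 0, 0)), 0.5,
               tolerance = 1e-6)
})

test_that("zero-lever geometries give zero moment arms", {
  # straight line through the joint center: zero for all three dofs
  m <- straight_model()
  for (d in c("FE", "ABD", "LAR")) {
    expect_equal(geometric_moment_arm(m, "M1", d, posture(0, 0, 0)), 0,
                 tolerance = 1e-14)
    expect_equal(excursion_moment_arm(m, "M1", d, posture(0, 0, 0)), 0,
                 tolerance = 1e-10)
  }
  # all points on the long-axis line: zero LAR moment arm at any posture
  on_axis <- limb_model(
    "on_axis",
    muscles = tibble::tibble(muscle = "M1",
                             segment = c("pelvis", "femur"),
                             x = 0, y = c(0.8, -0.9), z = 0),
    femur_length = 1)
  for (lar in c(0, 35, -120)) {
    expect_equal(geometric_moment_arm(on_axis, "M1", "LAR",
                                      posture(0, 0, lar)), 0,
                 tolerance = 1e-12)
  }
})

test_that("excursion and geometric methods agree on seeded random models", {
  proto <- sweep_protocol(modes = c("corrected", "legacy"))
  for (s in c(5, 23)) {
    m <- make_hip_model(seed = s)
    re <- run_sweep(m, proto, method = "excursion", h_deg = 0.25)
    rg <- run_sweep(m, proto, method = "geometric")
    expect_lt(max(abs(re$moment_arm - rg$moment_arm)),
              1e-5 * m$femur_length)
  }
})

test_that("central differencing is second order: halving h shrinks the
           residual about fourfold", {
  m <- make_hip_model(seed = 8)
  proto <- sweep_protocol()
  rg <- run_sweep(m, proto, method = "geometric")
  r1 <- max(abs(run_sweep(m, proto, h_deg = 0.5)$moment_arm -
                rg$moment_arm))
  r2 <- max(abs(run_sweep(m, proto, h_deg = 0.25)$moment_arm -
                rg$moment_arm))
  expect_gt(r1 / r2, 3.2)
  expect_lt(r1 / r2, 4.8)
})

test_that("corrected and legacy modes agree exactly at neutral", {
  m <- make_hip_model(seed = 4)
  q0 <- posture(0, 0, 0)
  for (mu in c("IF", "CFB", "PIT")) {
    for (d in c("FE", "ABD", "LAR")) {
      expect_equal(excursion_moment_arm(m, mu, d, q0, mode = "corrected"),
                   excursion_moment_arm(m, mu, d, q0, mode = "legacy"),
                   tolerance = 1e-10)
      expect_equal(geometric_moment_arm(m, mu, d, q0, mode = "corrected"),
                   geometric_moment_arm(m, mu, d, q0, mode = "legacy"),
                   tolerance = 1e-14)
    }
  }
})

test_that("mirroring across the x-y plane behaves as a limb-side swap", {
  m <- make_hip_model(seed = 9, n_muscles = 6)
  # left-limb construction: mirrored geometry + flipped ABD/LAR senses
  # preserves every anatomical moment arm at every posture
  left <- mirror_model(m, flip = c("ABD", "LAR"))
  rec_r <- run_sweep(m, sweep_protocol(), method = "geometric")
  rec_l <- run_sweep(left, sweep_protocol(), method = "geometric")
  expect_equal(rec_l$moment_arm, rec_r$moment_arm, tolerance = 1e-12)
  # mirrored geometry alone negates ABD/LAR and preserves FE at postures
  # with zero abduction and long-axis rotation
  mir <- mirror_model(m, flip = character())
  proto0 <- sweep_protocol(abd_offset = 0)
  a <- run_sweep(m, proto0, method = "geometric")
  b <- run_sweep(mir, proto0, method = "geometric")
  fe <- a$dof == "FE"
  expect_equal(b$moment_arm[fe], a$moment_arm[fe], tolerance = 1e-12)
  expect_equal(b$moment_arm[!fe], -a$moment_arm[!fe], tolerance = 1e-12)
})

test_that("isometric scaling multiplies raw arms by k and leaves normalized
           arms unchanged", {
  m <- make_hip_model(seed = 14, n_muscles = 8)
  base <- run_sweep(m, sweep_protocol(), method = "geometric")
  for (k in c(0.5, 2, 10)) {
    sc <- run_sweep(scale_model(m, k), sweep_protocol(),
                    method = "geometric")
    expect_equal(sc$moment_arm, k * base$moment_arm, tolerance = 1e-12)
    expect_equal(sc$moment_arm_norm, base$moment_arm_norm,
                 tolerance = 1e-12)
  }
})

test_that("degenerate and invalid inputs are rejected", {
  # valid at neutral, but the insertion rotates onto the origin at 90 deg
  degen <- limb_model(
    "degen",
    muscles = tibble::tibble(muscle = "M1",
                             segment = c("pelvis", "femur"),
                             x = c(0, 1), y = c(1, 0), z = 0),
    femur_length = 1)
  expect_equal(muscle_length(degen, "M1", posture(0, 0, 0)), sqrt(2))
  expect_error(muscle_length(degen, "M1", posture(90, 0, 0)),
               "degenerate|zero-length")
  # the +h perturbation lands exactly on the degenerate posture
  expect_error(excursion_moment_arm(degen, "M1", "FE",
                                    posture(89.75, 0, 0), h_deg = 0.25),
               "degenerate|zero-length")
  # coincident consecutive points are rejected at construction
  expect_error(limb_model(
    "coin",
    muscles = tibble::tibble(muscle = "M1",
                             segment = c("pelvis", "femur"),
                             x = 0, y = c(1, 1), z = 0),
    femur_length = 1), "coincident")
  expect_error(excursion_moment_arm(straight_model(), "M1", "FE",
                                    posture(0, 0, 0), h_deg = 0),
               "h_deg")
  expect_error(excursion_moment_arm(straight_model(), "M1", "FE",
                                    posture(0, 0, 0), h_deg = 3),
               "h_deg")
  expect_error(moment_arms(straight_model(), posture(0, 0, 0),
                           mode = "sideways"), "arg")
})
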