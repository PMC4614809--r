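test_that("classification recovers constructed functional profiles", {
  fe <- seq(-90, 90, 15)
  rec <- fake_records(list(
    FE = function(th) 0.01 * sin(th * pi / 180),   # switching, zero at 0
    ABD = function(th) rep(0.1, length(th)),       # obligatory adductor
    LAR = function(th) rep(0.001, length(th))),    # below epsilon
    fe = fe)
  labs <- classify_function(rec)
  lab <- function(d) labs[labs$dof == d, ]
  expect_equal(lab("FE")$label, "switching")
  expect_lt(abs(lab("FE")$crossing_angle_deg - 0), 1)
  expect_equal(lab("ABD")$label, "obligatory-positive")
  expect_true(is.na(lab("ABD")$crossing_angle_deg))
  expect_equal(lab("LAR")$label, "negligible")
  expect_equal(lab("ABD")$min_norm, 0.1)
  expect_equal(lab("ABD")$max_norm, 0.1)
})

test_that("classification handles offset crossings, pure negatives and
           epsilon overrides", {
  rec <- fake_records(list(
    FE = function(th) 0.02 * sin((th - 40) * pi / 180),  # zero at +40
    ABD = function(th) rep(-0.3, length(th)),
    LAR = function(th) rep(0.05, length(th))))
  labs <- classify_function(rec)
  fe_row <- labs[labs$dof == "FE", ]
  expect_equal(fe_row$label, "switching")
  # linear interpolation of sin() between 30 and 45 crosses near 40
  expect_lt(abs(fe_row$crossing_angle_deg - 40), 1)
  expect_equal(labs$label[labs$dof == "ABD"], "obligatory-negative")
  # raising epsilon above 0.05 makes the LAR profile negligible
  labs2 <- classify_function(rec, epsilon = 0.06)
  expect_equal(labs2$label[labs2$dof == "LAR"], "negligible")
})

test_that("classification refuses single-posture and mixed-mode input", {
  one <- fake_records(list(FE = function(th) th * 0 + 0.1), fe = 0)
  expect_error(classify_function(one), ">= 2 postures")
  both <- dplyr::bind_rows(
    fake_records(list(FE = function(th) th * 0 + 0.1)),
    fake_records(list(FE = function(th) th * 0 + 0.1), mode = "legacy"))
  expect_error(classify_function(both), "single axis mode")
})

test_that("classification labels are invariant under uniform model scaling", {
  m <- make_hip_model(seed = 21, n_muscles = 8)
  l1 <- classify_function(run_sweep(m, method = "geometric"))
  l2 <- classify_function(run_sweep(scale_model(m, 10),
                                    method = "geometric"))
  expect_equal(l1$label, l2$label)
  expect_equal(l1$crossing_angle_deg, l2$crossing_angle_deg,
               tolerance = 1e-9)
})

test_that("group summaries split sums by sign and conserve the net total", {
  # two muscles, +0.1 and -0.2 at one posture
  rec <- dplyr::bind_rows(
    fake_records(list(ABD = function(th) th * 0 + 0.1), muscle = "A"),
    fake_records(list(ABD = function(th) th * 0 - 0.2), muscle = "B"))
  s <- summarize_groups(rec)
  expect_true(all(s$summed_positive == 0.1))
  expect_true(all(s$summed_negative_magnitude == 0.2))
  expect_equal(unique(s$mean_positive), 0.05)  # mean over the two muscles

  # one all-positive muscle: zero negative magnitude everywhere
  s1 <- summarize_groups(fake_records(list(FE = function(th) th * 0 + 0.3)))
  expect_true(all(s1$summed_negative_magnitude == 0))

  # recount oracle on a random model: independent brute-force pass over the
  # record table, plus the conservation identity
  m <- make_hip_model(seed = 17)
  rec2 <- run_sweep(m)
  s2 <- summarize_groups(rec2)
  for (i in sample(nrow(s2), 10)) {
    cell <- rec2[rec2$dof == s2$dof[i] & rec2$fe_deg == s2$fe_deg[i], ]
    expect_equal(s2$summed_positive[i],
                 sum(cell$moment_arm_norm[cell$moment_arm_norm > 0]))
    expect_equal(s2$summed_negative_magnitude[i],
                 -sum(cell$moment_arm_norm[cell$moment_arm_norm < 0]))
  }
  net <- tapply(rec2$moment_arm_norm,
                paste(rec2$dof, rec2$fe_deg), sum)
  expect_equal(as.numeric(net[paste(s2$dof, s2$fe_deg)]),
               s2$summed_positive - s2$summed_negative_magnitude,
               tolerance = 1e-12)
})

test_that("cohort contrasts recover constructed differences", {
  mkrec <- function(model, value) {
    fake_records(list(LAR = function(th) th * 0 + value), model = model)
  }
  s <- lapply(list(c("q1", 0.30), c("q2", 0.40), c("b1", 0.10),
                   c("b2", 0.20)),
              function(x) summarize_groups(mkrec(x[1], as.numeric(x[2]))))
  summaries <- dplyr::bind_rows(s)
  cohorts <- tibble::tibble(model = c("q1", "q2", "b1", "b2"),
                            cohort = c("quadruped", "quadruped",
                                       "biped", "biped"))
  ct <- compare_cohorts(summaries, cohorts)
  ov <- glance(ct)
  # lateral-rotator means differ by the constructed offset of 0.20
  delta <- ov$mean_positive[ov$cohort == "quadruped"] -
    ov$mean_positive[ov$cohort == "biped"]
  expect_equal(delta, 0.20)
  byp <- tidy(ct)
  expect_true(all(byp$mean_summed_positive[byp$cohort == "quadruped"] ==
                    0.35))

  # two identical models in opposite cohorts: zero contrast everywhere
  same <- dplyr::bind_rows(summarize_groups(mkrec("x1", 0.25)),
                           summarize_groups(mkrec("x2", 0.25)))
  ct0 <- compare_cohorts(same, tibble::tibble(model = c("x1", "x2"),
                                              cohort = c("A", "B")))
  ov0 <- glance(ct0)
  expect_equal(diff(ov0$mean_positive), 0)

  # a single-model cohort reports that model's own summary
  expect_equal(ov0$mean_positive[ov0$cohort == "A"], 0.25)
  expect_equal(ov0$n_models, c(1, 1))

  # missing cohort assignment names the model
  expect_error(compare_cohorts(summaries,
                               cohorts[cohorts$model != "b2", ]), "b2")
})

test_that("mode differences vanish where the axes coincide and match an
           independent oracle elsewhere", {
  m <- make_hip_model(seed = 12, n_muscles = 6)
  rec <- run_sweep(m, sweep_protocol(modes = c("corrected", "legacy")),
                   method = "geometric")
  d <- diff_modes(rec)
  diffs <- tidy(d)
  # FE axis was never wrong: zero difference at every posture
  expect_lt(max(abs(diffs$delta[diffs$dof == "FE"])), 1e-10)
  # independent recomputation of the LAR difference at FE = 60
  for (mu in c("IF", "CFL")) {
    expected <- geometric_moment_arm(m, mu, "LAR", posture(60, -10, 0),
                                     mode = "corrected") -
      geometric_moment_arm(m, mu, "LAR", posture(60, -10, 0),
                           mode = "legacy")
    got <- diffs$delta[diffs$muscle == mu & diffs$dof == "LAR" &
                         diffs$fe_deg == 60]
    expect_equal(got, expected, tolerance = 1e-12)
  }
  g <- glance(d)
  expect_equal(g$max_abs_delta_fe, 0, tolerance = 1e-10)
  expect_gt(g$max_abs_delta, 0)

  # neutral posture: all dofs agree between modes
  rec0 <- run_sweep(m, sweep_protocol(fe_min = 0, fe_max = 0,
                                      abd_offset = 0,
                                      modes = c("corrected", "legacy")),
                    method = "geometric")
  expect_lt(max(abs(tidy(diff_modes(rec0))$delta)), 1e-10)

  # mismatched grids are an error
  trimmed <- rec[!(rec$mode == "legacy" & rec$fe_deg == 60), ]
  expect_error(diff_modes(trimmed), "mismatched")
  expect_error(diff_modes(rec[rec$mode == "corrected", ]), "both")
})
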