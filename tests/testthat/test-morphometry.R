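test_that("cap measurement maps long/short to D1/H and passes the tilt through", {
  r <- rotated_rect(50, 50, 60, 30, 0)
  cap <- measure_cap(r)
  expect_equal(cap$D1, 60)
  expect_equal(cap$H, 30)
  expect_equal(cap$tilt_deg, 0)

  r25 <- rotated_rect(50, 50, 60, 30, 25)
  expect_equal(measure_cap(r25)$tilt_deg, 25)

  # near-square cap: values still returned, ambiguity warned
  rsq <- rotated_rect(50, 50, 40, 39.5, 10)
  expect_warning(cap_sq <- measure_cap(rsq, tie_tol = 1),
                 class = "mushgrade_ambiguity")
  expect_equal(cap_sq$D1, 40)
  expect_true(cap_sq$ambiguous)
})

test_that("stalk measurement follows the vertical-side rule, not magnitude", {
  near_vertical <- rotated_rect(0, 0, 80, 20, 88)
  s <- measure_stalk(near_vertical)
  expect_equal(s$L, 80)
  expect_equal(s$D2, 20)

  horizontal <- rotated_rect(0, 0, 80, 20, 0)   # squat, lying stalk
  s2 <- measure_stalk(horizontal)
  expect_equal(s2$L, 20)
  expect_equal(s2$D2, 80)

  at45 <- rotated_rect(0, 0, 80, 20, 45)
  expect_warning(s3 <- measure_stalk(at45), class = "mushgrade_ambiguity")
  expect_equal(s3$L, 80)                        # tie breaks to the long side
})

test_that("rotate_upright is identity at zero tilt and undoes a known tilt", {
  mask <- demo_mask(rotation_deg = 0)
  expect_identical(unclass(rotate_upright(mask, 0)), unclass(mask))

  tilted <- demo_mask(rotation_deg = 30)
  n_before <- sum(unclass(tilted) > 0)
  cap_rect <- min_bounding_rect(extract_component_mask(tilted, 1L))
  up <- rotate_upright(tilted, cap_rect$angle_deg)
  refit <- min_bounding_rect(extract_component_mask(up, 1L))
  expect_equal(refit$angle_deg, 0, tolerance = 2)
  # nearest-neighbour labels: foreground conserved within 5%
  n_after <- sum(unclass(up) > 0)
  expect_lt(abs(n_after / n_before - 1), 0.05)
  expect_true(all(unclass(up) %in% 0:2))
})

test_that("ratios follow their definitions", {
  r <- compute_ratios(list(D1 = 60, H = 30), list(L = 40, D2 = 20))
  expect_equal(r$RDHP, 2)
  expect_equal(r$RLDS, 2)
  expect_equal(compute_ratios(list(D1 = 40, H = 40),
                              list(L = 10, D2 = 20))$RDHP, 1)
  expect_error(compute_ratios(list(D1 = 60, H = 0), list(L = 40, D2 = 20)))
})

test_that("full measurement recovers rendering parameters across rotations", {
  for (ang in seq(0, 345, by = 30)) {
    fx <- render_mushroom(fixture_spec(
      D1 = 90, H = 45, L = 70, D2 = 30, rotation_deg = ang,
      canvas = c(256, 256)
    ))
    m <- measure_mushroom(fx$mask)
    expect_lt(abs(m$D1_px - 90), 3)
    expect_lt(abs(m$H_px - 45), 3)
    expect_lt(abs(m$L_px - 70), 3)
    expect_lt(abs(m$D2_px - 30), 3)
    expect_lt(abs(m$RDHP / 2 - 1), 0.05)
    expect_lt(abs(m$RLDS / (70 / 30) - 1), 0.05)
  }
})

test_that("measurements scale with resolution while ratios stay put", {
  f1 <- measure_mushroom(render_mushroom(fixture_spec(
    D1 = 60, H = 30, L = 40, D2 = 20, rotation_deg = 20, canvas = c(192, 192)
  ))$mask)
  f2 <- measure_mushroom(render_mushroom(fixture_spec(
    D1 = 120, H = 60, L = 80, D2 = 40, rotation_deg = 20, canvas = c(384, 384)
  ))$mask)
  for (col in c("D1_px", "H_px", "L_px", "D2_px")) {
    expect_lt(abs(f2[[col]] - 2 * f1[[col]]), 2.5)
  }
  expect_lt(abs(f2$RDHP / f1$RDHP - 1), 0.02)
  expect_lt(abs(f2$RLDS / f1$RLDS - 1), 0.02)
})

test_that("a square cap falls back to the stalk axis for orientation", {
  fx <- render_mushroom(fixture_spec(
    D1 = 40, H = 40, L = 60, D2 = 20, rotation_deg = 15, canvas = c(224, 224)
  ))
  m <- measure_mushroom(fx$mask)
  expect_match(m$warnings, "stalk long axis")
  # the fallback still yields a sound stalk measurement
  expect_lt(abs(m$L_px - 60), 3.5)
  expect_lt(abs(m$D2_px - 20), 3.5)
})
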