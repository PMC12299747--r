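test_that("blow force and break-even mass reproduce the worked constants", {
  f <- blow_force(P = 0.80e6, r = 4e-3, pi_const = 3.14)
  expect_equal(f$S_tube * 1e6, 50.24)                       # mm2
  expect_equal(round_half_up(f$F, 2), 40.19)                # N
  m_star <- break_even_mass(P = 0.80e6, r = 4e-3, mu = 0.10, g = 9.80,
                            pi_const = 3.14)
  expect_equal(round_half_up(m_star, 2), 41.01)             # kg

  # full-precision pi differs in the third significant figure
  expect_equal(blow_force(0.80e6, 4e-3, "exact")$S_tube * 1e6, pi * 16)
  expect_error(blow_force(0.80e6, 0))

  # a 30 g mushroom is far below break-even: always displaceable
  expect_true(can_displace(air_blow_params(m = 0.030)))
  # exact force balance must NOT displace (strict inequality)
  p_bal <- air_blow_params(m = break_even_mass(0.80e6, 4e-3, 0.10, 9.80))
  expect_false(can_displace(p_bal))
})

test_that("impulse formula: dimensional limits hold", {
  expect_equal(post_blow_velocity(F = 40.19, dt0 = 0, m = 0.03, Vy0 = 0), 0)
  expect_equal(post_blow_velocity(F = 0, dt0 = 1, m = 0.03, Vy0 = 1.7), 1.7)
  # N * s / kg = m/s: 40.192 N for 1 ms on 30 g
  expect_equal(post_blow_velocity(40.192, 1e-3, 0.030), 40.192 * 1e-3 / 0.030)
})

test_that("crossing kinematics match the closed form and the stepwise integrator", {
  params <- air_blow_params()                      # mu=.10 g=9.80 W=.20 Vx=.10
  Vy1 <- post_blow_velocity(blow_force(params$P, params$r)$F,
                            params$dt0, params$m)
  k <- crossing_kinematics(params, Vy1)
  expect_equal(k$a, 0.98)
  expect_equal(k$Vy2, sqrt(Vy1^2 - 2 * 0.98 * 0.10))
  expect_equal(k$dt1, (Vy1 - k$Vy2) / 0.98)
  expect_equal(k$X, k$dt1 * 0.10)

  o <- integrate_crossing(Vy1, params$mu, params$g, params$W, params$Vx)
  expect_lt(abs(k$Vy2 / o$Vy2 - 1), 1e-3)
  expect_lt(abs(k$dt1 / o$dt1 - 1), 1e-3)
  expect_lt(abs(k$X / o$X - 1), 1e-3)

  # literal published sign convention: friction term enters with a plus
  kp <- crossing_kinematics(params, Vy1, mode = "as_printed")
  expect_equal(kp$Vy2, sqrt(2 * 0.98 * 0.10 + Vy1^2))
  expect_gt(kp$Vy2, Vy1)

  # Vx = 0 gives zero displacement in both modes
  p0 <- air_blow_params(Vx = 0)
  expect_equal(crossing_kinematics(p0, Vy1)$X, 0)
  expect_equal(crossing_kinematics(p0, Vy1, mode = "as_printed")$X, 0)

  # near-frictionless limit approaches the closed form d / Vy1
  pf <- air_blow_params(mu = 1e-6)
  kf <- crossing_kinematics(pf, Vy1)
  expect_equal(kf$dt1, (pf$W / 2) / Vy1, tolerance = 1e-4)
})

test_that("too weak a blow stalls on the belt with a warning", {
  params <- air_blow_params()
  expect_warning(k <- crossing_kinematics(params, Vy1 = 0.05),
                 class = "mushgrade_stall")
  expect_true(k$stalled)
  expect_equal(k$Vy2, 0)
})

test_that("closed form tracks the integrator across a 100-point sweep", {
  set.seed(4)
  worst <- 0
  for (i in 1:100) {
    mu <- runif(1, 0.05, 0.5)
    W <- runif(1, 0.1, 0.5)
    Vx <- runif(1, 0.05, 0.5)
    p <- air_blow_params(mu = mu, W = W, Vx = Vx)
    Vy1 <- runif(1, 1.05 * sqrt(2 * mu * 9.80 * W / 2), 4)  # no stall
    k <- crossing_kinematics(p, Vy1)
    o <- integrate_crossing(Vy1, mu, 9.80, W, Vx)
    worst <- max(worst,
                 abs(k$Vy2 / o$Vy2 - 1), abs(k$dt1 / o$dt1 - 1),
                 abs(k$X / o$X - 1))
  }
  expect_lt(worst, 1e-3)
})

test_that("displacement is monotone in Vx, Vy1 and friction", {
  p <- air_blow_params()
  Vy1 <- 1.4
  x1 <- crossing_kinematics(p, Vy1)$X
  # more belt speed: proportionally more downstream drift
  expect_gt(crossing_kinematics(air_blow_params(Vx = 0.2), Vy1)$X, x1)
  # a harder ejection crosses the belt faster, so it drifts LESS downstream
  expect_lt(crossing_kinematics(p, 1.8)$X, crossing_kinematics(p, 1.4)$X)
  # more friction slows the crossing and lengthens the drift
  expect_gt(crossing_kinematics(air_blow_params(mu = 0.2), Vy1)$X, x1)
})

test_that("the displacement envelope brackets masses and scales with Vx", {
  p <- air_blow_params()
  env <- displacement_envelope(p, 0.020, 0.045)
  expect_lte(env$X_min, env$X_max)
  # heavier specimens eject slower, cross slower, drift farther downstream
  expect_equal(env$m_at_max, 0.045)
  env_eq <- displacement_envelope(p, 0.030, 0.030)
  expect_equal(env_eq$X_min, env_eq$X_max)

  p2 <- air_blow_params(Vx = 0.20)
  env2 <- displacement_envelope(p2, 0.020, 0.045)
  expect_equal(env2$X_min / env$X_min, 2)
  expect_equal(env2$X_max / env$X_max, 2)
})

test_that("the full trajectory object tidies and summarises", {
  tr <- blow_trajectory(air_blow_params())
  td <- tidy(tr)
  expect_equal(nrow(td), 7)
  expect_true(all(c("term", "value", "unit") %in% names(td)))
  gl <- glance(tr)
  expect_equal(gl$X, tr$X)
  expect_true(gl$displaceable)
})
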