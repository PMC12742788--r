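test_that("swing derivatives vanish in the upright zero configuration and isolate the spring term", {
  u <- actuation_input(P = 0.1, k1 = 1.3, k2 = 0.4)
  d0 <- swing_derivatives(walker_state(0, -0.7, 0, 0), u)
  expect_identical(unname(d0[["theta_ddot"]]), 0)
  expect_identical(unname(d0[["phi_ddot"]]), 0)

  # with otherwise identical states, phi = +h engages k1 and phi = -h
  # engages k2; subtracting the two accelerations cancels every term of the
  # swing equation except the spring torque, which is odd in phi
  h <- 0.1
  sp <- walker_state(0.2, -0.3, +h, -0.1)
  sm <- walker_state(0.2, -0.3, -h, -0.1)
  dp <- swing_derivatives(sp, u)[["phi_ddot"]]
  dm <- swing_derivatives(sm, u)[["phi_ddot"]]
  gravity_odd <- 2 * (0.3^2 * sin(h) - cos(0.2) * sin(h))
  expect_equal(dp - dm, gravity_odd - u[["k1"]] * h - u[["k2"]] * h,
               tolerance = 1e-12)
})

test_that("swing derivatives match an independent term-by-term evaluation", {
  st <- walker_state(0.2, -0.3, 0.25, -0.1)
  u <- actuation_input(P = 0, k1 = 0.5, k2 = 0.5)
  d <- swing_derivatives(st, u)
  # oracle: each term written out separately
  theta_ddot <- sin(0.2)
  centrifugal <- (-0.3)^2 * sin(0.25)
  gravity <- cos(0.2) * sin(0.25)
  spring <- 0.5 * 0.25
  expect_equal(unname(d[["theta_dot"]]), -0.3)
  expect_equal(unname(d[["theta_ddot"]]), theta_ddot, tolerance = 1e-15)
  expect_equal(unname(d[["phi_dot"]]), -0.1)
  expect_equal(unname(d[["phi_ddot"]]),
               theta_ddot + centrifugal - gravity - spring,
               tolerance = 1e-15)
})

test_that("heel-strike map reduces to identity-with-zeroed-swing at theta = 0, P = 0", {
  post <- heelstrike_map(walker_state(0, -0.5, 0, 0.2), P = 0)
  expect_equal(unname(unclass(post)), c(0, -0.5, 0, 0), tolerance = 1e-15)
})

test_that("heel-strike rows for theta and phi are push-off independent", {
  set.seed(42)
  for (i in 1:20) {
    th <- runif(1, -0.6, 0.6); thd <- runif(1, -1.5, 0.5)
    P <- runif(1, 0, 1)
    post <- heelstrike_map(walker_state(th, thd, 2 * th, 0.3), P)
    expect_equal(post[["theta"]], -th, tolerance = 1e-15)
    expect_equal(post[["phi"]], -2 * th, tolerance = 1e-15)
  }
})

test_that("heel-strike map agrees with the explicit transition-matrix evaluation", {
  th <- -0.3; thd <- -0.4; P <- 0.05
  pre <- c(th, thd, 2 * th, -0.2)
  c2 <- cos(2 * th); s2 <- sin(2 * th)
  M <- rbind(c(-1, 0, 0, 0),
             c(0, c2, 0, 0),
             c(-2, 0, 0, 0),
             c(0, c2 * (1 - c2), 0, 0))
  v <- c(0, s2, 0, s2 * (1 - c2))
  oracle <- as.numeric(M %*% pre + v * P)
  post <- heelstrike_map(walker_state(pre[1], pre[2], pre[3], pre[4]), P)
  expect_equal(unname(unclass(post)), oracle, tolerance = 1e-15)
  expect_error(heelstrike_map(walker_state(th, thd, 2 * th, 0), -0.1),
               "non-negative|>= 0")
})

test_that("swing-foot height vanishes at scuff and contact configurations", {
  for (th in c(-0.4, 0.1, 0.3)) {
    expect_equal(swing_foot_height(walker_state(th, 0, 0, 0)), 0,
                 tolerance = 1e-15)
    expect_equal(swing_foot_height(walker_state(th, 0, 2 * th, 0)), 0,
                 tolerance = 1e-14)
  }
  expect_equal(swing_foot_height(walker_state(0.25, 0, 0.1, 0)),
               cos(0.25) - cos(0.15), tolerance = 1e-15)
  # between the scuff (phi = 0) and contact (phi = 2 theta) configurations
  # the point foot is below ground level; outside, above it
  expect_lt(swing_foot_height(walker_state(0.25, 0, 0.1, 0)), 0)
  expect_gt(swing_foot_height(walker_state(0.25, 0, -0.1, 0)), 0)
  expect_gt(swing_foot_height(walker_state(0.25, 0, 0.6, 0)), 0)
})

test_that("a step from the limit cycle returns to its starting state", {
  g <- centre_gait()
  start <- expand_stance_state(g$x_star[[1]], g$x_star[[2]])
  res <- simulate_step(start, g$u_nominal)
  expect_identical(res$outcome, "completed")
  expect_equal(unname(unclass(res$start_state_next)),
               unname(unclass(start)), tolerance = 1e-10)
  expect_equal(res$step_length, 2 * abs(sin(res$end_state_pre_collision[["theta"]])),
               tolerance = 1e-14)
  expect_equal(res$step_frequency * res$step_time, 1, tolerance = 1e-14)
})

test_that("event consistency holds at the accepted contact", {
  g <- centre_gait()
  res <- simulate_step(expand_stance_state(g$x_star[[1]], g$x_star[[2]]),
                       g$u_nominal)
  pre <- res$end_state_pre_collision
  expect_lt(abs(pre[["phi"]] - 2 * pre[["theta"]]), 1e-10)
  expect_lt(abs(swing_foot_height(pre)), 1e-10)
})

test_that("a walker tilted past horizontal falls immediately", {
  res <- simulate_step(walker_state(1.6, -0.1, 0.2, 0), actuation_input(0, 1))
  expect_identical(res$outcome, "fell")
})

test_that("the simulated swing phase matches an independent reference integration", {
  g <- centre_gait()
  start <- expand_stance_state(g$x_star[[1]], g$x_star[[2]])
  res <- simulate_step(start, g$u_nominal)
  ref <- reference_swing_integrate(start, g$u_nominal, res$step_time)
  expect_equal(unname(unclass(res$end_state_pre_collision)), ref,
               tolerance = 1e-8)
})

test_that("equal stiffnesses reproduce a single-spring walker", {
  g <- centre_gait()
  start <- expand_stance_state(g$x_star[[1]], g$x_star[[2]])
  res <- simulate_step(start, g$u_nominal)
  # oracle: constant-stiffness (no switching) reference integration
  u_const <- actuation_input(g$u_nominal[["P"]], g$u_nominal[["k1"]],
                             g$u_nominal[["k1"]])
  ref <- reference_swing_integrate(start, u_const, res$step_time)
  expect_equal(unname(unclass(res$end_state_pre_collision)), ref,
               tolerance = 1e-8)
})

test_that("the impulsive transition conserves and dissipates energy as bookkept", {
  g <- centre_gait()
  res <- simulate_step(expand_stance_state(g$x_star[[1]], g$x_star[[2]]),
                       g$u_nominal)
  thd_pre <- res$end_state_pre_collision[["theta_dot"]]
  th_pre <- res$end_state_pre_collision[["theta"]]
  P <- g$u_nominal[["P"]]
  thd_post <- res$start_state_next[["theta_dot"]]
  # Cartesian oracle for the hip point mass: pre-collision velocity is
  # perpendicular to the old stance leg with magnitude |theta_dot|; the
  # push-off impulse adds a component along the old stance leg; the
  # collision projects onto the direction perpendicular to the new stance
  # leg (inter-leg angle 2 theta)
  v_perp <- thd_pre            # signed, in the old stance frame
  v_after_pushoff_sq <- v_perp^2 + P^2
  proj <- cos(2 * th_pre) * v_perp + sin(2 * th_pre) * P
  expect_equal(thd_post, proj, tolerance = 1e-12)
  ke_before <- 0.5 * thd_pre^2
  ke_pushed <- 0.5 * v_after_pushoff_sq
  ke_after <- 0.5 * thd_post^2
  expect_equal(ke_pushed - ke_before, 0.5 * P^2, tolerance = 1e-12)
  expect_gte(ke_pushed - ke_after, 0)   # the inelastic collision only removes energy
})

test_that("trajectories can be recorded and exported as delimited text", {
  g <- centre_gait()
  res <- simulate_step(expand_stance_state(g$x_star[[1]], g$x_star[[2]]),
                       g$u_nominal, record = TRUE)
  expect_true(is.matrix(res$trajectory))
  expect_identical(colnames(res$trajectory),
                   c("time", "theta", "theta_dot", "phi", "phi_dot",
                     "active_spring"))
  f <- tempfile(fileext = ".csv")
  write_trajectory(res, f)
  back <- read.csv(f)
  expect_identical(nrow(back), nrow(res$trajectory))
  unlink(f)
})

test_that("scaling constants derive the stated time, frequency and velocity scales", {
  sc <- scaling_constants(l = 1, g = 9.81, M = 70)
  expect_equal(sc$time_scale, sqrt(1 / 9.81))
  expect_equal(sc$frequency_scale, sqrt(9.81))
  expect_equal(sc$velocity_scale, sqrt(9.81))
  expect_error(scaling_constants(l = -1), "positive")
})
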