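test_that("deadbeat synthesis zeroes the closed-loop spectrum", {
  lm <- centre_maps()
  K <- deadbeat_gains(lm)
  expect_identical(dim(K), c(3L, 2L))
  cl <- lm$A - lm$B %*% K
  expect_lt(max(Mod(eigen(cl, only.values = TRUE)$values)), 1e-8)
})

test_that("an already-deadbeat system gets the zero minimum-norm gain", {
  lm <- centre_maps()
  fake <- lm
  fake$A <- matrix(0, 2, 2)
  K <- deadbeat_gains(fake)
  expect_equal(max(abs(K)), 0, tolerance = 1e-12)
})

test_that("synthesis refuses an uncontrollable pair and names the gait", {
  fake <- structure(list(A = diag(2), B = matrix(0, 2, 2),
                         mode = "single", SL_target = 0.5, SF_target = 0.5),
                    class = "linearized_maps")
  expect_error(deadbeat_gains(fake), "0\\.500.*uncontrollable")
})

test_that("the control law is exact at the nominal point and linear in the error", {
  ctrl <- centre_ctrl()
  u0 <- control_step(ctrl$x_nominal, ctrl)
  expect_equal(as.numeric(u0), as.numeric(ctrl$u_nominal),
               tolerance = 1e-15)

  dx <- c(2e-3, -1e-3)
  u1 <- unclass(control_step(ctrl$x_nominal + dx, ctrl))
  u2 <- unclass(control_step(ctrl$x_nominal + 2 * dx, ctrl))
  un <- unclass(ctrl$u_nominal)
  expect_equal(u2 - un, 2 * (u1 - un), tolerance = 1e-10)

  # matrix-vector oracle
  expect_equal(as.numeric(u1 - un), as.numeric(-ctrl$K_gain %*% dx),
               tolerance = 1e-12)
})

test_that("negative push-off requests are clamped and flagged", {
  ctrl <- centre_ctrl()
  # drive the error along the direction that reduces push-off the most
  dir <- ctrl$K_gain[1, ] / sqrt(sum(ctrl$K_gain[1, ]^2))
  u <- control_step(ctrl$x_nominal + dir * 1, ctrl)
  expect_identical(u[["P"]], 0)
  expect_true(attr(u, "clamped"))
})

test_that("one controlled step eliminates a small perturbation", {
  g <- centre_gait()
  ctrl <- centre_ctrl()
  dx <- c(1e-6, -1e-6) / sqrt(2)
  run <- run_walker(g$x_star + dx, 3, controller = ctrl,
                    x_ref = g$x_star, settle_tol = 1e-9)
  expect_identical(run$settled_at, 1L)
})

test_that("controlled steps reduce larger perturbations by orders of magnitude", {
  g <- centre_gait()
  ctrl <- centre_ctrl()
  for (mag in c(1e-6, 1e-5)) {
    dx <- mag * c(0.8, -0.6)
    fm <- return_map(g$x_star + dx, control_step(g$x_star + dx, ctrl))
    err <- sqrt(sum((fm$x_next - g$x_star)^2))
    expect_lt(err, mag / 1e3)
  }
})

test_that("settling time follows the remain-below-threshold semantics", {
  # immediate crossing: interpolates to just under one step
  st <- settling_time(c(0.04, 0.01, 0.005), initial_error = 1)
  expect_identical(st$steps, 1L)
  expect_lt(abs(st$steps_interp - 1), 0.05)
  expect_true(st$settled)

  # a dip below 5% followed by a re-excursion counts from the final crossing
  st2 <- settling_time(c(0.04, 0.08, 0.6, 0.02, 0.01), initial_error = 1)
  expect_identical(st2$steps, 4L)
  expect_gt(st2$steps_interp, 3)

  # never settles
  st3 <- settling_time(c(0.5, 0.4, 0.3), initial_error = 1)
  expect_false(st3$settled)
  expect_true(is.na(st3$steps))

  # an error already below threshold from the first step settles at step one
  st4 <- settling_time(c(0.004, 0.001), initial_error = 0.1)
  expect_identical(st4$steps, 1L)
})

test_that("the gait cache warm-starts and bridges to nearby targets", {
  cache <- new_gait_cache()
  g1 <- solve_cached(cache, 0.6, 0.6)
  expect_true(g1$converged)
  g2 <- solve_cached(cache, 0.61, 0.6)
  expect_true(g2$converged)
  expect_lt(abs(g2$u_nominal[["k1"]] - g1$u_nominal[["k1"]]), 0.2)
  # cache hit returns the identical object
  expect_identical(solve_cached(cache, 0.6, 0.6), g1)
})

test_that("controlled MTP dominates open loop at the centre gait", {
  g <- centre_gait()
  cache <- new_gait_cache()
  open <- mtp_search(g, controller = NULL, cache = cache, max_layers = 3L)
  ctrl <- mtp_search(g, controller = centre_ctrl(), cache = cache,
                     max_layers = 3L)
  expect_gte(ctrl$mtp_radius, open$mtp_radius)
  expect_gte(ctrl$mtp_radius, 0.02)
  expect_true(all(ctrl$neighbors$distance[!ctrl$neighbors$converged] >
                    ctrl$mtp_radius))
})

test_that("perturbation response settles and counts the arrival step", {
  g <- centre_gait()
  pr <- perturbation_response(g, centre_ctrl(), axis = "SL", size = 0.02,
                              n_steps = 20L)
  expect_true(pr$settling$settled)
  expect_gt(pr$settling$steps_interp, 1)   # arrival step is step one
  expect_lt(pr$settling$steps_interp, 10)
})
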