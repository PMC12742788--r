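test_that("policy interpolation is exact at grid nodes and averages at cell centers", {
  gg <- small_gain_grid()
  pol <- interpolate_policy(0.6, 0.6, gg)
  i <- match(0.6, gg$SL_axis); j <- match(0.6, gg$SF_axis)
  expect_identical(unname(pol$K_gain), unname(gg$K[i, j, , ]))
  expect_identical(pol$x_nominal, gg$x_nom[i, j, ])
  expect_identical(unname(unclass(pol$u_nominal)), unname(gg$u_nom[i, j, ]))

  # midpoint of a cell: every quantity is the mean of the four corners
  pc <- interpolate_policy(0.605, 0.605, gg)
  Kc <- (gg$K[i, j, , ] + gg$K[i + 1, j, , ] + gg$K[i, j + 1, , ] +
           gg$K[i + 1, j + 1, , ]) / 4
  expect_equal(unname(pc$K_gain), Kc, tolerance = 1e-14)
  xc <- (gg$x_nom[i, j, ] + gg$x_nom[i + 1, j, ] + gg$x_nom[i, j + 1, ] +
           gg$x_nom[i + 1, j + 1, ]) / 4
  expect_equal(pc$x_nominal, xc, tolerance = 1e-14)

  expect_error(interpolate_policy(0.9, 0.6, gg), "hull")
})

test_that("exponential references honor their time constant and limits", {
  r <- exponential_reference(1, 0, n_steps = 10, tau = 2)
  expect_equal(r[1], 1)
  expect_equal(r[3], exp(-1), tolerance = 1e-12)  # s = tau
  # tau -> 0+: jump to the target from the first step
  r0 <- exponential_reference(1, 0, 5, tau = 1e-6)
  expect_equal(r0[-1], rep(0, 5), tolerance = 1e-12)
  # tau -> Inf: stays at the start
  rI <- exponential_reference(1, 0, 5, tau = 1e9)
  expect_equal(rI, rep(1, 6), tolerance = 1e-6)
  expect_error(exponential_reference(1, 0, 5, tau = 0), "positive")
})

test_that("sine paths close after full periods with a 2:1 frequency ratio", {
  g <- centre_gait()
  p <- sine_path(g, amplitude = 0.05, n_steps = 40)
  expect_equal(p$SL_target[40], g$SL_target, tolerance = 1e-12)
  expect_equal(p$SF_target[40], g$SF_target, tolerance = 1e-12)
  # odd length avoids samples landing exactly on the mean: step length
  # (two cycles) has three interior mean crossings, step frequency (one
  # cycle) has one
  p41 <- sine_path(g, amplitude = 0.05, n_steps = 41)
  crossings <- function(x, mid) sum(diff(sign(x - mid)) != 0)
  expect_identical(crossings(p41$SL_target[-41], g$SL_target), 3L)
  expect_identical(crossings(p41$SF_target[-41], g$SF_target), 1L)

  p0 <- sine_path(g, amplitude = 0, n_steps = 10)
  expect_true(all(p0$SL_target == g$SL_target))

  expect_error(sine_path(g, 0.5, 20, hull = c(0.5, 0.7, 0.5, 0.7)), "hull")
})

test_that("tracking a constant path at the start gait stays on the limit cycle", {
  g <- centre_gait()
  gg <- small_gain_grid()
  p <- sine_path(g, 0, 10)
  run <- track_path(p, g, gg)
  expect_identical(run$outcome, "completed")
  expect_lt(max(run$rms_pct), 1e-6)
})

test_that("the policy holds an off-grid constant target for many steps", {
  g <- centre_gait()
  gg <- small_gain_grid()
  tgt <- c(0.604, 0.596)   # strictly between grid nodes
  p <- data.frame(step = 1:50, SL_target = tgt[1], SF_target = tgt[2])
  class(p) <- c("target_path", "data.frame")
  run <- track_path(p, g, gg)
  expect_identical(run$outcome, "completed")
  expect_lt(max(abs(run$SL[10:50] - tgt[1])), 1e-3)
  expect_lt(max(abs(run$SF[10:50] - tgt[2])), 1e-3)
})

test_that("tracking with the interpolated policy at a node equals the local controller", {
  g <- centre_gait()
  gg <- small_gain_grid()
  pg <- solve_limit_cycle(gait_spec(0.61, 0.61))
  p <- data.frame(step = 1:5, SL_target = 0.6, SF_target = 0.6)
  class(p) <- c("target_path", "data.frame")
  run_pol <- track_path(p, pg, gg)
  run_loc <- run_walker(pg$x_star, 5, controller = centre_ctrl())
  # the node controller in the gain grid is synthesized from the grid's own
  # solve of the same gait; agreement is to solver precision
  expect_equal(run_pol$SL, run_loc$SL, tolerance = 1e-6)
  expect_equal(run_pol$SF, run_loc$SF, tolerance = 1e-6)
})

test_that("a zero-amplitude sine path has minimum length one", {
  g <- centre_gait()
  gg <- small_gain_grid()
  ml <- min_path_length(g, 0, gg)
  expect_identical(ml$n_steps, 1L)
  expect_identical(ml$run$outcome, "completed")
})

test_that("tracking runs export with targets, actuals and actuations", {
  g <- centre_gait()
  gg <- small_gain_grid()
  run <- track_path(sine_path(g, 0.005, 8), g, gg)
  f <- tempfile(fileext = ".csv")
  write_tracking(run, f)
  back <- read.csv(f)
  unlink(f)
  expect_identical(names(back),
                   c("step", "SL_target", "SF_target", "SL_actual",
                     "SF_actual", "P", "k1", "k2", "fell"))
  expect_identical(nrow(back), 8L)
  expect_false(any(back$fell))
})
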