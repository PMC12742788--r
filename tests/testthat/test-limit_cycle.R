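test_that("the residual at a converged gait is at solver tolerance and target terms are linear", {
  g <- centre_gait()
  cand <- c(g$x_star[[1]], g$x_star[[2]], g$u_nominal[["P"]],
            g$u_nominal[["k1"]])
  r <- gait_residual(cand, gait_spec(0.6, 0.6))
  expect_true(attr(r, "ok"))
  expect_lt(max(abs(r)), 1e-11)

  r2 <- gait_residual(cand, gait_spec(1.2, 0.6))
  expect_equal(r2[3] - r[3], -0.6, tolerance = 1e-14)  # SL target doubled
  expect_equal(r2[c(1, 2, 4)], r[c(1, 2, 4)], tolerance = 1e-14)
})

test_that("residual entries for a perturbed candidate match direct return-map differences", {
  g <- centre_gait()
  cand <- c(g$x_star[[1]] + 1e-3, g$x_star[[2]], g$u_nominal[["P"]],
            g$u_nominal[["k1"]])
  r <- gait_residual(cand, gait_spec(0.6, 0.6))
  fm <- return_map(cand[1:2], g$u_nominal)
  expect_equal(unname(r[1]), fm$x_next[1] - cand[1], tolerance = 1e-13)
  expect_equal(unname(r[2]), fm$x_next[2] - cand[2], tolerance = 1e-13)
  expect_gt(max(abs(r[1:2])), 1e-5)  # periodicity genuinely broken
})

test_that("infeasible candidates are reported as evaluation failures, not residuals", {
  r <- gait_residual(c(0.3, +0.5, 0.1, 2), gait_spec(0.6, 0.6))
  expect_false(attr(r, "ok"))
  expect_true(all(is.na(r)))
})

test_that("a solved gait is periodic over ten open-loop steps", {
  g <- centre_gait()
  expect_true(g$converged)
  expect_lt(g$residual_norm, 1e-11)
  expect_gt(g$u_nominal[["P"]], 0)
  x <- g$x_star
  for (s in 1:10) {
    fm <- return_map(x, g$u_nominal)
    expect_identical(fm$outcome, "completed")
    x <- fm$x_next
    expect_lt(max(abs(x - g$x_star)), 1e-8)
  }
  expect_equal(g$SL, 0.6, tolerance = 1e-9)
  expect_equal(g$SF, 0.6, tolerance = 1e-9)
})

test_that("single- and double-spring solves agree with equal stiffnesses", {
  gs <- centre_gait()
  gd <- centre_gait_double()
  expect_true(gd$converged)
  expect_equal(unname(gd$x_star), unname(gs$x_star), tolerance = 1e-9)
  expect_equal(gd$u_nominal[["k1"]], gd$u_nominal[["k2"]], tolerance = 1e-11)
  expect_equal(gd$u_nominal[["k1"]], gs$u_nominal[["k1"]], tolerance = 1e-8)
})

test_that("resolving from a solution converges immediately", {
  g <- centre_gait()
  cand <- c(g$x_star[[1]], g$x_star[[2]], g$u_nominal[["P"]],
            g$u_nominal[["k1"]])
  g2 <- solve_limit_cycle(gait_spec(0.6, 0.6), guess = cand)
  expect_true(g2$converged)
  expect_lte(g2$iterations, 1L)
})

test_that("a small continuation patch converges everywhere with smooth parameters", {
  grid <- small_grid()
  expect_identical(nrow(grid), 9L)
  expect_true(all(grid$converged))
  expect_true(all(grid$P > 0))
  jumps <- audit_smoothness(grid)
  # adjacent cells are 0.01 apart; parameters vary by O(d(param)/d(gait) * 0.01)
  expect_lt(jumps[["theta"]], 0.02)
  expect_lt(jumps[["k1"]], 0.2)  # dk/dSF is ~11 per unit SF at the centre
  expect_lt(jumps[["P"]], 0.05)
})

test_that("every stored grid gait re-verifies its periodicity", {
  grid <- small_grid()
  for (i in seq_len(nrow(grid))) {
    g <- row_to_gait(grid[i, ], "single")
    fm <- return_map(g$x_star, g$u_nominal)
    expect_lt(max(abs(fm$x_next - g$x_star)), 1e-10)
    expect_equal(fm$SL, grid$SL_target[i], tolerance = 1e-9)
    expect_equal(fm$SF, grid$SF_target[i], tolerance = 1e-9)
  }
})

test_that("physical-unit conversion reproduces the stated frequency range", {
  grid <- data.frame(SL_target = c(0.1, 1.1), SF_target = c(0.1, 1.1))
  attr(grid, "increment") <- 0.01; attr(grid, "mode") <- "single"
  class(grid) <- c("gait_grid", "data.frame")
  phys <- to_physical_units(grid, scaling_constants(l = 1, g = 9.81))
  expect_lt(max(abs(phys$SF_Hz - c(0.31, 3.44))), 0.01)
  expect_equal(phys$SL_m, c(0.1, 1.1))
  # unit scales collapse when l = g = 1
  phys1 <- to_physical_units(grid, scaling_constants(l = 1, g = 1))
  expect_equal(phys1$SF_Hz, phys1$SF_target)
})

test_that("a gait grid round-trips through CSV at full precision", {
  grid <- small_grid()
  f <- tempfile(fileext = ".csv")
  write_gait_grid(grid, f)
  back <- read_gait_grid(f)
  unlink(f)
  for (col in c("theta", "theta_dot", "P", "k1", "k2", "step_time"))
    expect_equal(back[[col]], grid[[col]], tolerance = 1e-15)
  expect_identical(attr(back, "increment"), attr(grid, "increment"))
  expect_identical(attr(back, "mode"), attr(grid, "mode"))
  expect_equal(attr(back, "SL_axis"), attr(grid, "SL_axis"))
})

test_that("gait_at retrieves the requested cell and rejects far queries", {
  grid <- small_grid()
  g <- gait_at(grid, 0.6, 0.6)
  expect_s3_class(g, "limit_cycle_gait")
  expect_identical(g$SL_target, 0.6)
  expect_error(gait_at(grid, 0.9, 0.9), "no grid cell")
})

test_that("high-stiffness multi-swing branches are rejected by the family bound", {
  # a distinct solution branch with k near 72 exists at these targets (the
  # swing leg oscillates several times before contact); the solver must not
  # return it
  g <- solve_limit_cycle(gait_spec(1.0, 0.9),
                         guess = c(0.5236, -1.035, 0.5976, 71.88))
  if (g$converged) {
    expect_lt(abs(g$u_nominal[["k1"]]), 30)
  } else {
    expect_identical(g$failure_reason, "wrong_family")
  }
})

test_that("the family walk is path-independent at a gait with a nearby twin root", {
  # two periodic solutions exist at the centre with stiffness about 0.12
  # apart; the canonical path continuation must land on the same one
  # regardless of what was solved before
  c1 <- new_gait_cache()
  g1 <- solve_family_gait(0.6, 0.6, cache = c1)
  c2 <- new_gait_cache()
  invisible(solve_family_gait(0.85, 0.35, cache = c2))
  g2 <- solve_family_gait(0.6, 0.6, cache = c2)
  expect_true(g1$converged && g2$converged)
  expect_equal(g1$u_nominal[["k1"]], g2$u_nominal[["k1"]], tolerance = 1e-9)
  # the centre gait of the family is open-loop stable
  eig <- max(Mod(eigen(finite_difference_A(g1), only.values = TRUE)$values))
  expect_lt(eig, 1)
})
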