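# Shared, lazily computed fixtures. Everything is generated in code at test
# time; the memo environment avoids re-solving the same gaits across files.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

centre_gait <- function() memo("centre_gait",
  solve_family_gait(0.6, 0.6))

centre_gait_double <- function() memo("centre_gait_double", {
  g <- centre_gait()
  solve_limit_cycle(gait_spec(0.6, 0.6),
                    guess = c(unname(g$x_star), g$u_nominal[["P"]],
                              g$u_nominal[["k1"]], g$u_nominal[["k2"]]),
                    mode = "double")
})

centre_maps <- function() memo("centre_maps",
  linearize_gait(centre_gait(), mode = "double"))

centre_maps_single <- function() memo("centre_maps_single",
  linearize_gait(centre_gait(), mode = "single"))

centre_ctrl <- function() memo("centre_ctrl",
  local_controller(centre_gait(), centre_maps()))

# 3x3 grid around the centre gait, used by several invariant tests
small_grid <- function() memo("small_grid",
  continuation_sweep(c(0.59, 0.61), c(0.59, 0.61), increment = 0.01))

small_gain_grid <- function() memo("small_gain_grid",
  gain_grid(small_grid()))

# 7x7 fixture grid (the desk-scale acceptance fixture)
fixture_grid_7 <- function() memo("fixture_grid_7",
  make_fixture_grid(c(0.6, 0.6), half_width = 0.03, increment = 0.01))

# plain-R reference integration of the swing dynamics (independent of the
# package's event-driven compiled path): integrates the continuous swing
# ODEs over a fixed time span with a sign-switched stiffness
reference_swing_integrate <- function(state0, u, t_end, n = NULL) {
  rhs <- function(t, y, p) {
    thdd <- sin(y[1])
    k <- if (y[3] > 0) u[["k1"]] else u[["k2"]]
    list(c(y[2], thdd,
           y[4], thdd + y[2]^2 * sin(y[3]) - cos(y[1]) * sin(y[3]) - k * y[3]))
  }
  out <- deSolve::ode(unname(state0)[1:4], c(0, t_end), rhs, NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-12)
  unname(out[nrow(out), 2:5])
}
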