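#' Build a gain grid: deadbeat controllers over a patch of gait space
#'
#' Synthesizes the deadbeat local controller at every converged cell of a
#' solved gait grid and stores, per cell, the six feedback gains, the
#' nominal stance states and the nominal actuations, in a form suitable for
#' bilinear interpolation between cells.
#'
#' @param grid a \code{gait_grid} (double-spring controllers are always
#'   synthesized; the grid may have been solved in either mode since the
#'   nominal stiffnesses agree).
#' @param delta finite-difference step for the linearizations.
#' @param int_tol integration tolerance.
#' @return A list of class \code{gain_grid}: axes, arrays \code{K}
#'   (nSL x nSF x 3 x 2), \code{x_nom} (nSL x nSF x 2), \code{u_nom}
#'   (nSL x nSF x 3), and logical matrix \code{ok}.
#' @export
gain_grid <- function(grid, delta = 1e-7, int_tol = 1e-13) {
  SLs <- attr(grid, "SL_axis"); SFs <- attr(grid, "SF_axis")
  nSL <- length(SLs); nSF <- length(SFs)
  K <- array(NA_real_, c(nSL, nSF, 3, 2))
  x_nom <- array(NA_real_, c(nSL, nSF, 2))
  u_nom <- array(NA_real_, c(nSL, nSF, 3))
  ok <- matrix(FALSE, nSL, nSF)
  for (r in seq_len(nrow(grid))) {
    if (!grid$converged[r]) next
    i <- match(grid$SL_target[r], SLs); j <- match(grid$SF_target[r], SFs)
    g <- row_to_gait(grid[r, ], "double")
    lm <- try(linearize_gait(g, delta = delta, mode = "double",
                             int_tol = int_tol), silent = TRUE)
    if (inherits(lm, "try-error")) next
    Kg <- try(deadbeat_gains(lm), silent = TRUE)
    if (inherits(Kg, "try-error")) next
    K[i, j, , ] <- Kg
    x_nom[i, j, ] <- unname(g$x_star)
    u_nom[i, j, ] <- unclass(g$u_nominal)
    ok[i, j] <- TRUE
  }
  structure(list(SL_axis = SLs, SF_axis = SFs, K = K, x_nom = x_nom,
                 u_nom = u_nom, ok = ok),
            class = "gain_grid")
}

#' Interpolate the feedback policy at an arbitrary target gait
#'
#' Piece-wise (bi)linear interpolation of the six feedback gains, the two
#' nominal stance states and the three nominal actuations from the four
#' corners of the enclosing grid cell. Queries exactly at a grid node
#' return that node's stored values.
#'
#' @param SL_t,SF_t target gait (must lie inside the grid hull, on cells
#'   whose corners all hold synthesized controllers).
#' @param gg a \code{gain_grid}.
#' @return A list of class \code{local_controller} (\code{K_gain},
#'   \code{x_nominal}, \code{u_nominal}, gait key).
#' @export
interpolate_policy <- function(SL_t, SF_t, gg) {
  nSL <- length(gg$SL_axis); nSF <- length(gg$SF_axis)
  if (SL_t < gg$SL_axis[1] || SL_t > gg$SL_axis[nSL] ||
      SF_t < gg$SF_axis[1] || SF_t > gg$SF_axis[nSF])
    stop(sprintf("target (%.4f, %.4f) outside the gain grid hull: refusing to extrapolate",
                 SL_t, SF_t))
  i <- min(max(findInterval(SL_t, gg$SL_axis), 1L), nSL - 1L)
  j <- min(max(findInterval(SF_t, gg$SF_axis), 1L), nSF - 1L)
  wx <- (SL_t - gg$SL_axis[i]) / (gg$SL_axis[i + 1] - gg$SL_axis[i])
  wy <- (SF_t - gg$SF_axis[j]) / (gg$SF_axis[j + 1] - gg$SF_axis[j])
  if (!all(gg$ok[i + 0:1, j + 0:1]))
    stop("gain grid cell has unsolved corners at the query point")
  w <- c((1 - wx) * (1 - wy), wx * (1 - wy), (1 - wx) * wy, wx * wy)
  corner <- function(arr) {
    d <- dim(arr)
    if (length(d) == 4) {
      w[1] * arr[i, j, , ] + w[2] * arr[i + 1, j, , ] +
        w[3] * arr[i, j + 1, , ] + w[4] * arr[i + 1, j + 1, , ]
    } else if (d[3] == 2) {
      w[1] * arr[i, j, ] + w[2] * arr[i + 1, j, ] +
        w[3] * arr[i, j + 1, ] + w[4] * arr[i + 1, j + 1, ]
    } else {
      w[1] * arr[i, j, ] + w[2] * arr[i + 1, j, ] +
        w[3] * arr[i, j + 1, ] + w[4] * arr[i + 1, j + 1, ]
    }
  }
  Kq <- corner(gg$K)
  dimnames(Kq) <- list(c("P", "k1", "k2"), c("theta", "theta_dot"))
  un <- corner(gg$u_nom)
  structure(list(K_gain = Kq, x_nominal = corner(gg$x_nom),
                 u_nominal = actuation_input(max(un[1], 0), un[2], un[3]),
                 SL_target = SL_t, SF_target = SF_t),
            class = "local_controller")
}

#' Exponential reference path for one gait variable
#'
#' \code{ref(s) = target + (start - target) exp(-s / tau)} for
#' \code{s = 0, ..., n_steps}.
#'
#' @param start_value,target_value endpoints of the reference.
#' @param n_steps number of steps.
#' @param tau time constant in steps (> 0).
#' @return Numeric vector of length \code{n_steps + 1}.
#' @export
exponential_reference <- function(start_value, target_value, n_steps, tau) {
  if (tau <= 0) stop("tau must be positive")
  s <- 0:n_steps
  target_value + (start_value - target_value) * exp(-s / tau)
}

#' Sinusoidal target path in gait space
#'
#' Step length completes two full cycles while step frequency completes
#' one, with equal amplitudes and zero starting phase:
#' \code{SL(s) = SL0 + a sin(4 pi s / n)}, \code{SF(s) = SF0 +
#' a sin(2 pi s / n)}, \code{s = 1, ..., n}.
#'
#' @param start a \code{limit_cycle_gait} providing \code{(SL0, SF0)}.
#' @param amplitude dimensionless amplitude \code{a}.
#' @param n_steps path length in steps.
#' @param hull optional length-4 \code{c(SL_min, SL_max, SF_min, SF_max)};
#'   a path leaving it is rejected.
#' @return A data frame of class \code{target_path} with columns
#'   \code{step, SL_target, SF_target}.
#' @export
sine_path <- function(start, amplitude, n_steps, hull = NULL) {
  s <- seq_len(n_steps)
  path <- data.frame(step = s,
                     SL_target = start$SL_target +
                       amplitude * sin(4 * pi * s / n_steps),
                     SF_target = start$SF_target +
                       amplitude * sin(2 * pi * s / n_steps))
  if (!is.null(hull)) {
    if (any(path$SL_target < hull[1] | path$SL_target > hull[2] |
            path$SF_target < hull[3] | path$SF_target > hull[4]))
      stop("sine path leaves the gait-space hull")
  }
  class(path) <- c("target_path", "data.frame")
  path
}

#' Track a target path with the interpolated feedback policy
#'
#' Starting from the limit-cycle state of the initial gait, each step
#' interpolates the policy at the next target on the path, applies the
#' once-per-step control law with the current stance states, and simulates
#' one step. Falls are recorded with their step index.
#'
#' @param path a \code{target_path} (columns \code{SL_target, SF_target}).
#' @param start a converged \code{limit_cycle_gait} (the walker starts on
#'   its limit cycle).
#' @param gg a \code{gain_grid}.
#' @param int_tol integration tolerance.
#' @return A list of class \code{tracking_run}: \code{outcome}
#'   (\code{"completed"} or \code{"fell"}), \code{fell_at} (step or NA),
#'   per-step realized \code{SL}, \code{SF}, applied \code{u} matrix, the
#'   targets, and \code{rms_pct}: RMS tracking errors as a percentage of
#'   the starting gait's step length and frequency.
#' @export
track_path <- function(path, start, gg, int_tol = 1e-13) {
  n <- nrow(path)
  x <- unname(start$x_star)
  SL <- SF <- rep(NA_real_, n)
  um <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("P", "k1", "k2")))
  fell_at <- NA_integer_
  for (s in seq_len(n)) {
    ctrl <- try(interpolate_policy(path$SL_target[s], path$SF_target[s], gg),
                silent = TRUE)
    if (inherits(ctrl, "try-error")) {
      # no controller available at this target (outside the hull or on
      # unsolved cells): the path cannot be tracked from here
      fell_at <- s
      attr(fell_at, "policy_unavailable") <- TRUE
      break
    }
    u <- control_step(x, ctrl)
    fm <- try(return_map(x, u, tol = int_tol), silent = TRUE)
    if (inherits(fm, "try-error") || fm$outcome != "completed") {
      fell_at <- s; break
    }
    x <- fm$x_next
    SL[s] <- fm$SL; SF[s] <- fm$SF; um[s, ] <- unclass(u)
  }
  done <- is.na(fell_at)
  rms <- function(e) sqrt(mean(e^2))
  rms_pct <- if (done) c(
    SL = 100 * rms(SL - path$SL_target) / start$SL_target,
    SF = 100 * rms(SF - path$SF_target) / start$SF_target)
  else c(SL = NA_real_, SF = NA_real_)
  structure(list(outcome = if (done) "completed" else "fell",
                 fell_at = fell_at, SL = SL, SF = SF, u = um,
                 SL_target = path$SL_target, SF_target = path$SF_target,
                 rms_pct = rms_pct, start = c(start$SL_target,
                                              start$SF_target)),
            class = "tracking_run")
}

# Track an exponential reference on one axis (the other axis held at the
# target gait) and return the realized series plus RMS cost vs the
# reference over the path steps.
.track_reference <- function(ref, axis, target, gg, extra_steps, int_tol,
                             start_gait) {
  n <- length(ref) - 1L
  tgt_SL <- target$SL_target; tgt_SF <- target$SF_target
  SLs <- if (axis == "SL") c(ref[-1], rep(tgt_SL, extra_steps))
         else rep(tgt_SL, n + extra_steps)
  SFs <- if (axis == "SF") c(ref[-1], rep(tgt_SF, extra_steps))
         else rep(tgt_SF, n + extra_steps)
  path <- data.frame(step = seq_along(SLs), SL_target = SLs, SF_target = SFs)
  class(path) <- c("target_path", "data.frame")
  run <- track_path(path, start_gait, gg, int_tol = int_tol)
  series <- if (axis == "SL") run$SL else run$SF
  tgt <- if (axis == "SL") tgt_SL else tgt_SF
  fell <- run$outcome != "completed"
  list(run = run, series = series,
       cost_ref = if (fell) Inf else
         sqrt(mean((series[seq_len(n)] - ref[-1])^2)),
       cost_target = if (fell) Inf else
         sqrt(mean((series[seq_len(n)] - tgt)^2)))
}

#' Optimal response time of the feedback policy to a 15% perturbation
#'
#' Reproduces the adaptation experiment: the walker starts on the limit
#' cycles of two gaits whose step length (or frequency) lies 15% above and
#' below the target gait, and follows exponential reference paths sharing
#' one time constant toward the target while the other axis is held at the
#' target value. The shared time constant is chosen by bounded scalar
#' minimization of the summed RMS deviation of the two tracked trajectories
#' from the target value over the reference length (a run that falls costs
#' infinity). This makes the optimization well posed: a too-aggressive
#' reference overshoots or topples the walker, a too-slow one leaves it far
#' from the target, and the optimum is the fastest reference the policy can
#' actually follow. The response time is the 5% settling time of the
#' optimal reference, \code{tau * log(20)}; the settling times of the
#' tracked series themselves are also reported.
#'
#' @param target a converged \code{limit_cycle_gait}.
#' @param axis \code{"SL"} or \code{"SF"}.
#' @param gg a \code{gain_grid} covering the perturbed range.
#' @param max_steps reference path length in steps (10 in most regions).
#' @param perturb_frac perturbation fraction (default 0.15).
#' @param cache optional gait cache for the perturbed-gait solves.
#' @param extra_steps steps appended at the target to confirm settling.
#' @param int_tol integration tolerance.
#' @return A list with \code{tau} (optimal time constant),
#'   \code{response_time} (\code{tau * log(20)}),
#'   \code{response_times_tracked} (per-run interpolated settling of the
#'   realized series), \code{cost} and the optimal runs' costs.
#' @export
optimize_response_time <- function(target, axis = c("SL", "SF"), gg,
                                   max_steps = 10L, perturb_frac = 0.15,
                                   cache = NULL, extra_steps = 5L,
                                   int_tol = 1e-13) {
  axis <- match.arg(axis)
  if (is.null(cache)) cache <- new_gait_cache(int_tol = int_tol)
  v0 <- if (axis == "SL") target$SL_target else target$SF_target
  starts <- lapply(c(1 + perturb_frac, 1 - perturb_frac), function(f) {
    SL <- if (axis == "SL") v0 * f else target$SL_target
    SF <- if (axis == "SF") v0 * f else target$SF_target
    pg <- solve_cached(cache, SL, SF, seed = target)
    if (!pg$converged) stop("perturbed start gait did not converge")
    pg
  })
  cost_of <- function(tau) {
    tot <- 0
    for (pg in starts) {
      v_start <- if (axis == "SL") pg$SL_target else pg$SF_target
      ref <- exponential_reference(v_start, v0, max_steps, tau)
      tot <- tot + .track_reference(ref, axis, target, gg, extra_steps,
                                    int_tol, pg)$cost_target
    }
    # falls are penalized with a large finite cost so the scalar optimizer
    # steers away from them without warnings
    if (!is.finite(tot)) 1e6 else tot
  }
  opt <- optimize(cost_of, lower = 0.1, upper = max_steps)
  tau <- opt$minimum
  if (opt$objective >= 1e6)
    stop("both perturbed runs fell for every time constant in bounds")
  rts <- vapply(starts, function(pg) {
    v_start <- if (axis == "SL") pg$SL_target else pg$SF_target
    ref <- exponential_reference(v_start, v0, max_steps, tau)
    tr <- .track_reference(ref, axis, target, gg, extra_steps, int_tol, pg)
    if (!is.finite(tr$cost_target)) return(NA_real_)
    # the arrival step on the perturbed limit cycle counts as step one
    settling_time(c(v_start - v0, tr$series - v0), v_start - v0)$steps_interp
  }, 0)
  list(tau = tau, response_time = tau * log(20),
       response_times_tracked = rts, cost = opt$objective)
}

#' Minimum sine-path length completed without falling
#'
#' Increasing (doubling) search over the path length followed by bisection:
#' the shortest number of steps for which the walker tracks the full
#' sinusoidal path without falling.
#'
#' @param start a converged \code{limit_cycle_gait} at the path center.
#' @param amplitude sine amplitude.
#' @param gg a \code{gain_grid} covering the path.
#' @param n_min,n_cap search bounds on the path length.
#' @param int_tol integration tolerance.
#' @return A list with \code{n_steps} (NA if none found below the cap) and
#'   the completing \code{run}.
#' @export
min_path_length <- function(start, amplitude, gg, n_min = 2L, n_cap = 400L,
                            int_tol = 1e-13) {
  if (amplitude == 0) {
    run <- track_path(sine_path(start, 0, 1L), start, gg, int_tol = int_tol)
    return(list(n_steps = 1L, run = run))
  }
  try_n <- function(n) track_path(sine_path(start, amplitude, n), start, gg,
                                  int_tol = int_tol)
  lo <- n_min; n <- max(4L, n_min); run <- NULL
  while (n <= n_cap) {
    r <- try_n(n)
    if (r$outcome == "completed") { run <- r; break }
    lo <- n; n <- n * 2L
  }
  if (is.null(run)) return(list(n_steps = NA_integer_, run = NULL))
  hi <- n
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    r <- try_n(mid)
    if (r$outcome == "completed") { hi <- mid; run <- r } else lo <- mid
  }
  list(n_steps = hi, run = run)
}

#' Write a target path or tracking run as CSV
#'
#' @param x a \code{target_path} or \code{tracking_run}.
#' @param file path.
#' @return The path, invisibly.
#' @export
write_tracking <- function(x, file) {
  df <- if (inherits(x, "tracking_run")) {
    data.frame(step = seq_along(x$SL_target), SL_target = x$SL_target,
               SF_target = x$SF_target, SL_actual = x$SL, SF_actual = x$SF,
               P = x$u[, "P"], k1 = x$u[, "k1"], k2 = x$u[, "k2"],
               fell = !is.na(x$fell_at) & seq_along(x$SL_target) == x$fell_at)
  } else as.data.frame(x)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
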