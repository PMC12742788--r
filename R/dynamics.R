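#' Construct a walker state
#'
#' The continuous state of the simplest walker at an instant: stance angle
#' \code{theta} (rad, measured from vertical), stance angular rate
#' \code{theta_dot}, swing angle \code{phi} (rad, measured from the stance
#' leg) and swing angular rate \code{phi_dot}. All rates are dimensionless
#' (time scaled by \code{sqrt(l/g)}).
#'
#' @param theta,theta_dot,phi,phi_dot finite numeric scalars.
#' @return A named numeric vector of class \code{walker_state}.
#' @export
walker_state <- function(theta, theta_dot, phi, phi_dot) {
  x <- c(theta = unname(theta), theta_dot = unname(theta_dot),
         phi = unname(phi), phi_dot = unname(phi_dot))
  if (!all(is.finite(x))) stop("walker_state fields must be finite")
  class(x) <- "walker_state"
  x
}

#' Construct a once-per-step actuation input
#'
#' \code{P} is the push-off impulse applied along the stance leg just before
#' foot-ground contact; \code{k1} and \code{k2} are the hip spring stiffnesses
#' active while \code{phi > 0} (first half of swing) and \code{phi <= 0}
#' (second half), respectively. The single-spring walker is the special case
#' \code{k1 == k2}.
#'
#' @param P push-off impulse, must be non-negative.
#' @param k1 stiffness of the early-swing hip spring.
#' @param k2 stiffness of the late-swing hip spring; defaults to \code{k1}.
#' @return A named numeric vector of class \code{actuation_input}.
#' @export
actuation_input <- function(P, k1, k2 = k1) {
  if (!is.finite(P) || P < 0) stop("push-off impulse P must be finite and >= 0")
  u <- c(P = unname(P), k1 = unname(k1), k2 = unname(k2))
  if (!all(is.finite(u))) stop("actuation fields must be finite")
  class(u) <- "actuation_input"
  u
}

#' Swing-phase equations of motion
#'
#' Time derivatives of the walker state during the swing phase. The stance
#' leg is an inverted pendulum, \code{theta'' = sin(theta)}; the swing leg
#' obeys
#' \deqn{\ddot\phi = \ddot\theta + \dot\theta^2 \sin\phi - \cos\theta
#'       \sin\phi - k\,\phi,}
#' with \code{k = k1} while \code{phi > 0} and \code{k = k2} while
#' \code{phi <= 0}. Because the feet are massless relative to the hip, swing
#' dynamics do not feed back into stance dynamics.
#'
#' @param state a \code{\link{walker_state}} (or named numeric vector).
#' @param u an \code{\link{actuation_input}}; only \code{k1}/\code{k2} enter.
#' @return Named numeric vector of derivatives
#'   \code{(theta_dot, theta_ddot, phi_dot, phi_ddot)}.
#' @export
swing_derivatives <- function(state, u) {
  th <- state[["theta"]]; thd <- state[["theta_dot"]]
  ph <- state[["phi"]];   phd <- state[["phi_dot"]]
  k <- if (ph > 0) u[["k1"]] else u[["k2"]]
  thdd <- sin(th)
  phdd <- thdd + thd^2 * sin(ph) - cos(th) * sin(ph) - k * ph
  c(theta_dot = thd, theta_ddot = thdd, phi_dot = phd, phi_ddot = phdd)
}

#' Push-off plus heel-strike transition map
#'
#' The composite impulsive transition at the end of a step: the push-off
#' impulse \code{P} acts along the (old) stance leg just before contact, the
#' swing foot then strikes the ground in a perfectly inelastic collision and
#' the legs swap roles. With \code{s = sin(2 theta)} and
#' \code{c = cos(2 theta)} evaluated at the pre-collision stance angle:
#' \deqn{\theta^+ = -\theta^-, \quad
#'       \dot\theta^+ = c\,\dot\theta^- + s\,P, \quad
#'       \phi^+ = -2\theta^-, \quad
#'       \dot\phi^+ = (1 - c)\,(c\,\dot\theta^- + s\,P).}
#'
#' @param pre pre-collision \code{\link{walker_state}} (a contact state,
#'   \code{phi = 2 theta}).
#' @param P push-off impulse, non-negative.
#' @return Post-collision \code{\link{walker_state}}.
#' @export
heelstrike_map <- function(pre, P) {
  if (!is.finite(P) || P < 0) stop("push-off impulse P must be finite and >= 0")
  th <- pre[["theta"]]; thd <- pre[["theta_dot"]]
  c2 <- cos(2 * th); s2 <- sin(2 * th)
  thd_post <- c2 * thd + s2 * P
  walker_state(theta     = -th,
               theta_dot = thd_post,
               phi       = -2 * th,
               phi_dot   = (1 - c2) * thd_post)
}

#' Swing-foot height above the ground
#'
#' Vertical position of the swing foot, \code{cos(theta) - cos(theta - phi)}
#' (dimensionless, leg length = 1). Zero both in the scuffing configuration
#' \code{phi = 0} and in the contact configuration \code{phi = 2 theta}.
#'
#' @param state a \code{\link{walker_state}}.
#' @return Dimensionless height (scalar).
#' @export
swing_foot_height <- function(state) {
  cos(state[["theta"]]) - cos(state[["theta"]] - state[["phi"]])
}

#' Expand stance states to a full step-start state
#'
#' The walker has two independent degrees of freedom at the start of a step,
#' \code{(theta, theta_dot)}; the swing states are fixed by the transition
#' map: \code{phi = 2 theta} (the trailing foot is still on the ground) and
#' \code{phi_dot = (1 - cos(2 theta)) theta_dot}.
#'
#' @param theta,theta_dot stance angle and rate at the start of the step.
#' @return A full \code{\link{walker_state}}.
#' @export
expand_stance_state <- function(theta, theta_dot) {
  walker_state(theta, theta_dot, 2 * theta, (1 - cos(2 * theta)) * theta_dot)
}

# One classical RK4 step of the swing dynamics, used to nudge the integrator
# just past an event so the stopped root is not immediately re-detected.
# h ~ 1e-8 keeps the local error (O(h^5)) far below integration tolerance.
.rk4_nudge <- function(y, u, h) {
  f <- function(s) unname(swing_derivatives(
    c(theta = s[1], theta_dot = s[2], phi = s[3], phi_dot = s[4]), u))
  k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
  k4 <- f(y + h * k3)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate one walking step
#'
#' Integrates the swing-phase equations of motion from a post-collision
#' step-start state until the swing foot contacts the ground, then applies
#' the push-off + heel-strike transition with the commanded impulse. Event
#' handling:
#' \itemize{
#'   \item contact is a zero of \code{phi - 2 theta}; because that function is
#'     also zero at the step start and the point foot scuffs at \code{phi = 0},
#'     only crossings with \code{phi < -event_guard} and a descending foot
#'     are accepted (ascending crossings exit a mid-stance scuff);
#'   \item the active hip spring switches at \code{phi = 0}; the integration
#'     is restarted there so the discontinuous stiffness never degrades the
#'     solver's error control;
#'   \item the walker falls if \code{|theta| >= pi/2}, or if
#'     \code{theta_dot} changes sign while \code{theta > 0} (rocking
#'     backward before mid-stance);
#'   \item if no contact occurs before \code{t_max} the outcome is
#'     \code{"no_contact"}.
#' }
#'
#' @param start step-start \code{\link{walker_state}} (post-collision).
#' @param u \code{\link{actuation_input}} held fixed for the whole step;
#'   \code{u["P"]} is applied at the accepted contact.
#' @param tol absolute and relative integration tolerance (default 1e-13).
#' @param t_max dimensionless time limit for one step.
#' @param record if \code{TRUE}, return a sampled trajectory.
#' @param event_guard contact acceptance guard on \code{-phi}.
#' @return A list of class \code{step_result} with elements
#'   \code{outcome} (\code{"completed"}, \code{"fell"} or
#'   \code{"no_contact"}), \code{end_state_pre_collision},
#'   \code{start_state_next}, \code{step_time}, \code{step_length}
#'   (\code{2 |sin(theta)|} at contact), \code{step_frequency}
#'   (\code{1 / step_time}) and (optionally) \code{trajectory}.
#' @export
simulate_step <- function(start, u, tol = 1e-13, t_max = 50,
                          record = FALSE, event_guard = 1e-6) {
  y <- unname(start[c("theta", "theta_dot", "phi", "phi_dot")])
  if (abs(y[1]) >= pi / 2) {
    res <- list(outcome = "fell",
                end_state_pre_collision = walker_state(y[1], y[2], y[3], y[4]),
                start_state_next = NULL, step_time = NA_real_,
                step_length = NA_real_, step_frequency = NA_real_,
                n_spring_switches = 0L, n_skipped_contacts = 0L,
                trajectory = NULL)
    class(res) <- "step_result"
    return(res)
  }
  parms <- c(u[["k1"]], u[["k2"]])
  t_now <- 0
  traj <- if (record) list() else NULL
  nudge_h <- 1e-8
  outcome <- "no_contact"
  pre <- NULL
  n_switches <- 0L
  n_skipped <- 0L
  theta0 <- y[1]

  for (ev in seq_len(100L)) {
    times <- if (record) {
      n <- max(2L, ceiling((t_max - t_now) * 50))
      seq(t_now, t_max, length.out = n)
    } else c(t_now, t_max)
    seg <- try(deSolve::lsodar(
      y = y, times = times, func = "walker_derivs", parms = parms,
      dllname = "gaitscape", initfunc = "walker_init",
      rootfunc = "walker_root", nroot = 5L,
      rtol = tol, atol = tol, maxsteps = 20000L), silent = TRUE)
    if (inherits(seg, "try-error")) {
      stop("integration failure during step simulation: ",
           attr(seg, "condition")$message)
    }
    istate <- attr(seg, "istate")[1]
    if (!istate %in% c(2, 3)) {
      stop("integration failure during step simulation (istate = ", istate, ")")
    }
    if (record) {
      m <- unname(seg[, 1:5, drop = FALSE])
      traj[[length(traj) + 1L]] <- cbind(m, if (y[3] > 0) parms[1] else parms[2])
    }
    last <- unname(seg[nrow(seg), ])
    t_now <- last[1]
    y <- last[2:5]
    iroot <- which(attr(seg, "iroot") == 1L)

    if (length(iroot) == 0L) break # reached t_max: no contact

    if (any(iroot %in% c(3L, 4L))) { outcome <- "fell"; break }
    # genuine heel strike: swing leg past the stance leg (phi < 0) and the
    # foot descending (a phi - 2 theta crossing with the foot ascending is
    # the exit of a mid-stance scuff and is ignored for the point foot)
    hdot <- -sin(y[1]) * y[2] + sin(y[1] - y[3]) * (y[2] - y[4])
    if (2L %in% iroot && y[3] < -event_guard && hdot < 0) {
      pre <- walker_state(y[1], y[2], y[3], y[4])
      outcome <- "completed"
      break
    }
    if (5L %in% iroot && y[1] > 1e-8) { outcome <- "fell"; break } # rocks back
    if (1L %in% iroot) n_switches <- n_switches + 1L
    # a contact crossing rejected deep in the landing zone (stance angle
    # past half its final value) means the foot grazed the ground away from
    # the benign mid-stance scuff; such crossings are counted so that gait
    # solutions relying on them can be screened out
    if (2L %in% iroot && y[1] < -0.5 * theta0) n_skipped <- n_skipped + 1L
    # spring switch (phi = 0), step-start shadow of the contact function, or a
    # benign theta_dot zero: nudge past the stopped root and continue
    y <- .rk4_nudge(y, u, nudge_h)
    t_now <- t_now + nudge_h
    if (t_now >= t_max) break
  }

  res <- list(
    outcome = outcome,
    end_state_pre_collision = if (outcome == "completed") pre else
      walker_state(y[1], y[2], y[3], y[4]),
    start_state_next = NULL, step_time = NA_real_,
    step_length = NA_real_, step_frequency = NA_real_,
    n_spring_switches = n_switches,
    n_skipped_contacts = n_skipped,
    trajectory = NULL)
  if (outcome == "completed") {
    res$start_state_next <- heelstrike_map(pre, u[["P"]])
    res$step_time <- t_now
    res$step_length <- 2 * abs(sin(pre[["theta"]]))
    res$step_frequency <- 1 / t_now
  }
  if (record) {
    tr <- do.call(rbind, traj)
    colnames(tr) <- c("time", "theta", "theta_dot", "phi", "phi_dot",
                      "active_spring")
    res$trajectory <- tr
  }
  class(res) <- "step_result"
  res
}

#' @export
print.step_result <- function(x, ...) {
  cat("<step_result> outcome:", x$outcome, "\n")
  if (x$outcome == "completed") {
    cat(sprintf("  step_time = %.6f  step_length = %.6f  step_frequency = %.6f\n",
                x$step_time, x$step_length, x$step_frequency))
  }
  invisible(x)
}

#' Scaling constants between dimensionless and physical units
#'
#' @param l leg length in meters.
#' @param g gravitational acceleration in m/s^2.
#' @param M total mass in kg.
#' @return A list of class \code{scaling_constants} with the base constants
#'   and the derived scales: \code{time_scale = sqrt(l/g)},
#'   \code{frequency_scale = sqrt(g/l)}, \code{velocity_scale = sqrt(g l)}.
#' @export
scaling_constants <- function(l = 1, g = 9.81, M = 1) {
  if (l <= 0 || g <= 0 || M <= 0) stop("scaling constants must be positive")
  structure(list(l = l, g = g, M = M,
                 time_scale = sqrt(l / g),
                 frequency_scale = sqrt(g / l),
                 velocity_scale = sqrt(g * l)),
            class = "scaling_constants")
}

#' Export a simulated trajectory as delimited text
#'
#' @param result a \code{step_result} simulated with \code{record = TRUE}.
#' @param file path of the output file.
#' @return The file path, invisibly.
#' @export
write_trajectory <- function(result, file) {
  if (is.null(result$trajectory)) stop("simulate the step with record = TRUE")
  write.csv(as.data.frame(result$trajectory), file, row.names = FALSE)
  invisible(file)
}
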