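#' Deadbeat gain matrix for a linearized gait
#'
#' Places all eigenvalues of the closed-loop return map at zero. With the
#' control law \code{u = u_n - K (x - x_n)} the closed loop is
#' \code{A - B K}; choosing \code{K = pinv(B) A} (Moore-Penrose) makes it
#' exactly zero whenever B has full row rank, and among the many exact
#' solutions of the underdetermined double-spring case (3 inputs, 2 states)
#' it is the minimum-norm one, so the synthesis is deterministic.
#'
#' @param maps a \code{linearized_maps} for the gait.
#' @param sv_tol rank tolerance forwarded to the controllability check.
#' @return The m x 2 gain matrix K (m inputs).
#' @export
deadbeat_gains <- function(maps, sv_tol = 1e-8) {
  ct <- controllability_test(maps, sv_tol = sv_tol)
  if (!ct$controllable)
    stop(sprintf("gait (%.3f, %.3f) is uncontrollable (rank %d): cannot place poles",
                 maps$SL_target, maps$SF_target, ct$rank))
  s <- svd(maps$B)
  pos <- s$d > sv_tol * s$d[1]
  Binv <- s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  K <- Binv %*% maps$A
  dimnames(K) <- list(colnames(maps$B), c("theta", "theta_dot"))
  K
}

#' Build a local once-per-step feedback controller for one gait
#'
#' @param gait a converged \code{limit_cycle_gait}.
#' @param maps optional precomputed \code{linearized_maps}; computed
#'   (double-spring) if missing.
#' @param ... passed to \code{\link{linearize_gait}}.
#' @return A list of class \code{local_controller} with \code{K_gain},
#'   \code{x_nominal}, \code{u_nominal} and the gait key.
#' @export
local_controller <- function(gait, maps = NULL, ...) {
  if (is.null(maps)) maps <- linearize_gait(gait, mode = "double", ...)
  structure(list(K_gain = deadbeat_gains(maps),
                 x_nominal = unname(gait$x_star),
                 u_nominal = gait$u_nominal,
                 SL_target = gait$SL_target, SF_target = gait$SF_target),
            class = "local_controller")
}

#' Once-per-step control law
#'
#' \code{u = u_nominal - K_gain (x - x_nominal)}, evaluated at the start of
#' a step from the current stance states. A negative requested push-off is
#' clamped to zero (attribute \code{clamped}).
#'
#' @param x current stance states \code{(theta, theta_dot)} (a length-2
#'   vector or a full \code{walker_state}).
#' @param ctrl a \code{local_controller} (or any list with \code{K_gain},
#'   \code{x_nominal}, \code{u_nominal}).
#' @return An \code{\link{actuation_input}}.
#' @export
control_step <- function(x, ctrl) {
  if (length(x) == 4L) x <- x[c("theta", "theta_dot")]
  du <- -ctrl$K_gain %*% (unname(x)[1:2] - ctrl$x_nominal)
  u <- unclass(ctrl$u_nominal) + as.numeric(du)
  clamped <- u[["P"]] < 0
  out <- actuation_input(max(u[["P"]], 0), u[["k1"]], u[["k2"]])
  attr(out, "clamped") <- clamped
  out
}

#' Run the walker for several steps under fixed or feedback actuation
#'
#' @param x0 starting stance states \code{(theta, theta_dot)}.
#' @param n_steps maximum number of steps.
#' @param controller a \code{local_controller}, or \code{NULL} for open
#'   loop with \code{u_fixed}.
#' @param u_fixed actuation used when \code{controller} is \code{NULL}.
#' @param x_ref reference stance state; when supplied, the run stops early
#'   once \code{||x - x_ref|| < settle_tol} (the controller would hold it
#'   there) or diverges beyond \code{diverge_tol}.
#' @param settle_tol,diverge_tol early-exit thresholds on the Euclidean
#'   state error.
#' @param int_tol integration tolerance.
#' @return A list of class \code{walk_run}: \code{outcome}
#'   (\code{"completed"}, \code{"fell"}, \code{"no_contact"}),
#'   \code{steps_taken}, \code{settled_at} (step index or NA), and per-step
#'   vectors \code{SL}, \code{SF}, \code{step_time}, matrix \code{x}
#'   (stance states at each step start, row 1 = x0) and matrix \code{u}
#'   (actuations applied on each step).
#' @export
run_walker <- function(x0, n_steps, controller = NULL, u_fixed = NULL,
                       x_ref = NULL, settle_tol = 1e-8, diverge_tol = 10,
                       int_tol = 1e-13) {
  if (is.null(controller) && is.null(u_fixed))
    stop("need a controller or a fixed actuation")
  x <- unname(x0)[1:2]
  SL <- SF <- st <- rep(NA_real_, n_steps)
  um <- matrix(NA_real_, n_steps, 3, dimnames = list(NULL, c("P", "k1", "k2")))
  xm <- matrix(NA_real_, n_steps + 1L, 2,
               dimnames = list(NULL, c("theta", "theta_dot")))
  xm[1, ] <- x
  outcome <- "completed"
  settled <- NA_integer_
  taken <- 0L
  for (s in seq_len(n_steps)) {
    u <- if (is.null(controller)) u_fixed else control_step(x, controller)
    fm <- try(return_map(x, u, tol = int_tol), silent = TRUE)
    if (inherits(fm, "try-error")) { outcome <- "integration_failure"; break }
    if (fm$outcome != "completed") { outcome <- fm$outcome; break }
    taken <- s
    x <- fm$x_next
    xm[s + 1L, ] <- x
    SL[s] <- fm$SL; SF[s] <- fm$SF; st[s] <- fm$step_time
    um[s, ] <- unclass(u)
    if (!is.null(x_ref)) {
      err <- sqrt(sum((x - unname(x_ref)[1:2])^2))
      if (err < settle_tol) { settled <- s; break }
      if (err > diverge_tol) break
    }
  }
  structure(list(outcome = outcome, steps_taken = taken,
                 settled_at = settled,
                 SL = SL[seq_len(taken)], SF = SF[seq_len(taken)],
                 step_time = st[seq_len(taken)],
                 x = xm[seq_len(taken + 1L), , drop = FALSE],
                 u = um[seq_len(taken), , drop = FALSE]),
            class = "walk_run")
}

# Cache of solved gaits keyed by rounded (SL, SF) targets, with warm starts
# from the nearest cached solution. Used by neighbor-layer searches and
# perturbation experiments, where many nearby gaits are solved.
#' Create a gait solution cache
#'
#' @param mode actuation mode for the cached solves.
#' @param tol,int_tol solver and integration tolerances.
#' @return An environment used by \code{\link{solve_cached}}.
#' @export
new_gait_cache <- function(mode = "single", tol = 1e-11, int_tol = 1e-13) {
  e <- new.env(parent = emptyenv())
  e$gaits <- list()
  e$keys <- matrix(numeric(0), 0, 2)
  e$mode <- mode; e$tol <- tol; e$int_tol <- int_tol
  e
}

#' Solve a gait through a cache with nearest-neighbor warm starts
#'
#' @param cache from \code{\link{new_gait_cache}}.
#' @param SL,SF target gait.
#' @param seed optional \code{limit_cycle_gait} used as warm start when the
#'   cache is empty.
#' @return A \code{limit_cycle_gait} (possibly unconverged; cached either
#'   way only when converged).
#' @export
solve_cached <- function(cache, SL, SF, seed = NULL) {
  key <- sprintf("%.9f_%.9f", SL, SF)
  hit <- cache$gaits[[key]]
  if (!is.null(hit)) return(hit)
  guess <- NULL
  ord <- integer(0)
  if (nrow(cache$keys) > 0) {
    d <- (cache$keys[, 1] - SL)^2 + (cache$keys[, 2] - SF)^2
    ord <- order(d)[seq_len(min(4L, length(d)))]
  }
  fit <- NULL
  for (i in ord) {
    nb <- cache$gaits[[i]]
    guess <- .gait_to_candidate(nb, cache$mode)
    fit <- solve_limit_cycle(gait_spec(SL, SF), guess, mode = cache$mode,
                             tol = cache$tol, int_tol = cache$int_tol,
                             J0 = nb$jacobian)
    if (fit$converged) break
  }
  if (is.null(fit) || !fit$converged) {
    guess <- if (!is.null(seed)) .gait_to_candidate(seed, cache$mode) else NULL
    fit2 <- solve_limit_cycle(gait_spec(SL, SF), guess, mode = cache$mode,
                              tol = cache$tol, int_tol = cache$int_tol,
                              J0 = if (!is.null(seed)) seed$jacobian)
    if (is.null(fit) || fit2$converged) fit <- fit2
  }
  if (!fit$converged && !is.null(seed)) {
    # pendulum-estimate multi-start (the seeded guess may sit in the wrong
    # basin when the seed is far away)
    fit3 <- solve_limit_cycle(gait_spec(SL, SF), NULL, mode = cache$mode,
                              tol = cache$tol, int_tol = cache$int_tol)
    if (fit3$converged) fit <- fit3
  }
  if (!fit$converged) {
    # bridge by short continuation from the nearest available solution
    from <- if (nrow(cache$keys) > 0) {
      d <- (cache$keys[, 1] - SL)^2 + (cache$keys[, 2] - SF)^2
      cache$gaits[[order(d)[1]]]
    } else seed
    if (!is.null(from) && isTRUE(from$converged)) {
      dist <- sqrt((from$SL_target - SL)^2 + (from$SF_target - SF)^2)
      nsub <- max(2L, ceiling(dist / 0.025))
      cur <- from
      ok <- TRUE
      for (f in seq_len(nsub) / nsub) {
        sp <- gait_spec(from$SL_target + f * (SL - from$SL_target),
                        from$SF_target + f * (SF - from$SF_target))
        cur <- solve_limit_cycle(sp, .gait_to_candidate(cur, cache$mode),
                                 mode = cache$mode, tol = cache$tol,
                                 int_tol = cache$int_tol, J0 = cur$jacobian)
        if (!cur$converged) { ok <- FALSE; break }
      }
      if (ok) fit <- cur
    }
  }
  if (fit$converged) {
    cache$gaits[[key]] <- fit
    cache$keys <- rbind(cache$keys, c(SL, SF))
  }
  fit
}

#' Maximum tolerable perturbation of a target gait
#'
#' Layered neighbor search in gait space: the walker is started from the
#' limit-cycle state of each neighboring gait on concentric grid layers
#' around the target (increment-spaced), actuated either by the target's
#' nominal actuations (open loop) or its deadbeat local controller, and
#' must complete \code{n_steps} steps without falling and return to the
#' target's fixed point within \code{conv_tol}. Layers expand until a
#' failure bounds the radius; the maximum tolerable perturbation is the
#' largest radius within which every neighbor converged.
#'
#' @param target a converged \code{limit_cycle_gait}.
#' @param controller a \code{local_controller} for the target, or
#'   \code{NULL} for the open-loop analysis.
#' @param cache a gait cache (created if missing) used to solve neighbor
#'   gaits; pass a shared cache when sweeping many targets.
#' @param increment neighbor spacing in gait space (default 0.01).
#' @param max_layers maximum number of layers explored.
#' @param n_steps steps of the survival test.
#' @param conv_tol state-error tolerance defining "returned to the target".
#' @param int_tol integration tolerance.
#' @return A list of class \code{perturbation_result}: \code{mtp_radius}
#'   (reported at the increment resolution of the neighbor lattice: the
#'   largest increment-multiple circle containing only converged
#'   neighbors), \code{max_converged_distance}, \code{controlled}, and a
#'   data frame \code{neighbors} with per-neighbor
#'   \code{dSL, dSF, distance, solved, converged}.
#' @export
mtp_search <- function(target, controller = NULL, cache = NULL,
                       increment = 0.01, max_layers = 12L, n_steps = 100L,
                       conv_tol = 1e-6, int_tol = 1e-13) {
  if (is.null(cache)) cache <- new_gait_cache(int_tol = int_tol)
  u_n <- target$u_nominal
  res <- list()
  min_fail <- Inf
  for (L in seq_len(max_layers)) {
    # stop once no unexplored cell can lie inside the current failure radius
    if ((L - 1) * increment >= min_fail) break
    offs <- .layer_offsets(L)
    for (r in seq_len(nrow(offs))) {
      dSL <- offs[r, 1] * increment; dSF <- offs[r, 2] * increment
      d <- sqrt(dSL^2 + dSF^2)
      if (d >= min_fail) next
      nb <- solve_cached(cache, target$SL_target + dSL,
                         target$SF_target + dSF, seed = target)
      ok <- FALSE
      if (nb$converged) {
        run <- run_walker(nb$x_star, n_steps, controller = controller,
                          u_fixed = if (is.null(controller)) u_n,
                          x_ref = target$x_star, settle_tol = 1e-8,
                          int_tol = int_tol)
        ok <- run$outcome == "completed" &&
          (!is.na(run$settled_at) ||
             (run$steps_taken == n_steps &&
                sqrt(sum((run$x[n_steps + 1, ] -
                            unname(target$x_star))^2)) <= conv_tol))
      }
      res[[length(res) + 1L]] <- data.frame(
        dSL = dSL, dSF = dSF, distance = d, solved = nb$converged,
        converged = ok)
      if (!ok) min_fail <- min(min_fail, d)
    }
  }
  nbrs <- do.call(rbind, res)
  max_conv <- if (is.finite(min_fail)) {
    okd <- nbrs$distance[nbrs$converged & nbrs$distance < min_fail]
    if (length(okd)) max(okd) else 0
  } else max_layers * increment
  # largest increment-multiple radius whose circle contains only converged
  # neighbors (the neighbor lattice has increment resolution, so the radius
  # is reported at that resolution)
  mtp <- if (is.finite(min_fail)) {
    m <- 0L
    while ((m + 1L) * increment < min_fail &&
           (m + 1L) * increment <= max_conv + 1e-12) m <- m + 1L
    m * increment
  } else max_layers * increment
  structure(list(mtp_radius = mtp, max_converged_distance = max_conv,
                 controlled = !is.null(controller),
                 SL_target = target$SL_target, SF_target = target$SF_target,
                 neighbors = nbrs),
            class = "perturbation_result")
}

.layer_offsets <- function(L) {
  o <- expand.grid(di = -L:L, dj = -L:L)
  as.matrix(o[pmax(abs(o$di), abs(o$dj)) == L, ])
}

#' Settling time of an error series
#'
#' The number of steps needed for an error to remain below a fraction
#' (default 5%) of its initial value for all subsequent recorded steps.
#' Since the error is sampled once per step, a fractional refinement by
#' linear interpolation between the last step at or above threshold and the
#' first step of the final sub-threshold run is also reported.
#'
#' @param error_series per-step errors (step 1, 2, ...), signed or absolute.
#' @param initial_error the error at step 0 (before the first controlled
#'   step).
#' @param frac threshold fraction of \code{|initial_error|}.
#' @return A list with \code{steps} (integer index of the first step of the
#'   final sub-threshold run), \code{steps_interp} (fractional), and
#'   \code{settled} (FALSE when the series ends at or above threshold).
#' @export
settling_time <- function(error_series, initial_error, frac = 0.05) {
  e <- c(abs(initial_error), abs(error_series))
  thr <- frac * abs(initial_error)
  n <- length(e) - 1L
  above <- which(e >= thr) - 1L   # step indices, 0-based
  if (length(above) == 0L)
    return(list(steps = 0L, steps_interp = 0, settled = TRUE))
  last_above <- max(above)
  if (last_above >= n)
    return(list(steps = NA_integer_, steps_interp = NA_real_,
                settled = FALSE))
  i <- last_above + 1L            # first step of the final sub-threshold run
  e_hi <- e[last_above + 1L]; e_lo <- e[i + 1L]
  fracstep <- if (e_hi > e_lo) (e_hi - thr) / (e_hi - e_lo) else 1
  list(steps = i, steps_interp = last_above + fracstep, settled = TRUE)
}

#' Response of a local controller to a gait-space perturbation
#'
#' Starts the walker at the limit-cycle state of a gait perturbed from the
#' target in step length or step frequency, runs the target's local
#' controller, and measures the settling time of the perturbed quantity
#' (realized per-step SL or SF against the target's value, 5% criterion).
#' Step counting: the walker arrives on the perturbed limit cycle, so the
#' arrival step is step one of the error series (its error equals the
#' initial difference); the controller's adjustments first show in the
#' realized gait from step two onward.
#'
#' @param target a converged \code{limit_cycle_gait}.
#' @param ctrl the target's \code{local_controller}.
#' @param axis \code{"SL"} or \code{"SF"}.
#' @param size signed perturbation (dimensionless).
#' @param cache optional gait cache for the perturbed gait solve.
#' @param n_steps steps simulated.
#' @param int_tol integration tolerance.
#' @return A list with the \code{settling} result, the perturbed gait and
#'   the \code{run}.
#' @export
perturbation_response <- function(target, ctrl, axis = c("SL", "SF"), size,
                                  cache = NULL, n_steps = 40L,
                                  int_tol = 1e-13) {
  axis <- match.arg(axis)
  if (is.null(cache)) cache <- new_gait_cache(int_tol = int_tol)
  SLp <- target$SL_target + if (axis == "SL") size else 0
  SFp <- target$SF_target + if (axis == "SF") size else 0
  pg <- solve_cached(cache, SLp, SFp, seed = target)
  if (!pg$converged) stop("perturbed gait did not converge; cannot start run")
  run <- run_walker(pg$x_star, n_steps, controller = ctrl, int_tol = int_tol)
  if (run$outcome != "completed")
    return(list(settling = list(steps = NA_integer_,
                                steps_interp = NA_real_, settled = FALSE),
                perturbed_gait = pg, run = run))
  series <- if (axis == "SL") run$SL else run$SF
  tgt <- if (axis == "SL") target$SL_target else target$SF_target
  v_pert <- if (axis == "SL") pg$SL_target else pg$SF_target
  st <- settling_time(c(v_pert - tgt, series - tgt), size)
  list(settling = st, perturbed_gait = pg, run = run)
}
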