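#' Linearize the return map around a periodic gait
#'
#' Builds the discrete linear step-to-step model around a limit cycle by
#' finite differences on the full nonlinear step simulation:
#' \deqn{\Delta x_{i+1} = A \Delta x_i + B \Delta u_i, \qquad
#'       \Delta y_{i+1} = C \Delta x_i + D \Delta u_i,}
#' with state deviations \code{dx = (dtheta, dtheta_dot)}, input deviations
#' \code{du = (dP, dk)} (single-spring) or \code{(dP, dk1, dk2)}
#' (double-spring), and outputs \code{dy = (dSL, dSF)} of the ensuing step.
#'
#' @param gait a converged \code{limit_cycle_gait}.
#' @param delta finite-difference perturbation size (default 1e-7, large
#'   relative to the 1e-13 integration tolerance yet inside the linear
#'   regime of the return map).
#' @param mode \code{"single"} (inputs P, k) or \code{"double"}
#'   (inputs P, k1, k2); defaults to the gait's own mode.
#' @param method \code{"forward"} one-sided differences (default) or
#'   \code{"central"}.
#' @param int_tol integration tolerance.
#' @return A list of class \code{linearized_maps} with matrices \code{A}
#'   (2x2), \code{B} (2xm), \code{C} (2x2), \code{D} (2xm), the
#'   \code{eigenvalues} of A, \code{fd_step}, \code{mode} and the gait key.
#' @export
linearize_gait <- function(gait, delta = 1e-7,
                           mode = NULL, method = c("forward", "central"),
                           int_tol = 1e-13) {
  method <- match.arg(method)
  if (is.null(mode)) mode <- gait$mode
  if (!isTRUE(gait$converged)) stop("gait must be converged to linearize")
  u0 <- gait$u_nominal
  x0 <- unname(gait$x_star)
  f0 <- return_map(x0, u0, tol = int_tol)
  if (f0$outcome != "completed") stop("nominal step did not complete")

  eval_x <- function(x) {
    fm <- return_map(x, u0, tol = int_tol)
    if (fm$outcome != "completed")
      stop("perturbed step did not complete; gait not evaluable at delta = ",
           delta)
    c(fm$x_next, fm$SL, fm$SF)
  }
  eval_u <- function(du) {
    uu <- unclass(u0) + du
    if (uu[["P"]] < 0) uu[["P"]] <- 0
    fm <- return_map(x0, actuation_input(uu[["P"]], uu[["k1"]], uu[["k2"]]),
                     tol = int_tol)
    if (fm$outcome != "completed")
      stop("perturbed step did not complete; gait not evaluable at delta = ",
           delta)
    c(fm$x_next, fm$SL, fm$SF)
  }

  base <- c(f0$x_next, f0$SL, f0$SF)
  AC <- matrix(NA_real_, 4, 2)
  for (j in 1:2) {
    xp <- x0; xp[j] <- xp[j] + delta
    if (method == "forward") {
      AC[, j] <- (eval_x(xp) - base) / delta
    } else {
      xm <- x0; xm[j] <- xm[j] - delta
      AC[, j] <- (eval_x(xp) - eval_x(xm)) / (2 * delta)
    }
  }

  cols <- if (mode == "single") list(P = c(delta, 0, 0),
                                     k = c(0, delta, delta))
          else list(P = c(delta, 0, 0), k1 = c(0, delta, 0),
                    k2 = c(0, 0, delta))
  BD <- matrix(NA_real_, 4, length(cols))
  for (j in seq_along(cols)) {
    if (method == "forward") {
      BD[, j] <- (eval_u(cols[[j]]) - base) / delta
    } else {
      BD[, j] <- (eval_u(cols[[j]]) - eval_u(-cols[[j]])) / (2 * delta)
    }
  }

  A <- AC[1:2, , drop = FALSE]
  C <- AC[3:4, , drop = FALSE]
  B <- BD[1:2, , drop = FALSE]
  D <- BD[3:4, , drop = FALSE]
  dimnames(A) <- list(c("theta", "theta_dot"), c("theta", "theta_dot"))
  dimnames(C) <- list(c("SL", "SF"), c("theta", "theta_dot"))
  dimnames(B) <- list(c("theta", "theta_dot"), names(cols))
  dimnames(D) <- list(c("SL", "SF"), names(cols))
  structure(list(A = A, B = B, C = C, D = D,
                 eigenvalues = eigen(A, only.values = TRUE)$values,
                 fd_step = delta, mode = mode, method = method,
                 SL_target = gait$SL_target, SF_target = gait$SF_target),
            class = "linearized_maps")
}

#' @export
print.linearized_maps <- function(x, ...) {
  cat(sprintf("<linearized_maps> gait (%.3f, %.3f), %s-spring, fd = %g\n",
              x$SL_target, x$SF_target, x$mode, x$fd_step))
  cat("  max |eigenvalue(A)| =", max(Mod(x$eigenvalues)), "\n")
  invisible(x)
}

#' State-transition sensitivity matrix of the return map
#'
#' Convenience wrapper around \code{\link{linearize_gait}} returning only
#' the 2x2 Jacobian A of the stance-state return map.
#'
#' @inheritParams linearize_gait
#' @return A 2x2 matrix.
#' @export
finite_difference_A <- function(gait, delta = 1e-7,
                                method = c("forward", "central"),
                                int_tol = 1e-13) {
  linearize_gait(gait, delta = delta, method = match.arg(method),
                 int_tol = int_tol)$A
}

#' Input, output and feedthrough sensitivity matrices
#'
#' @inheritParams linearize_gait
#' @return A list with matrices \code{B}, \code{C}, \code{D}.
#' @export
finite_difference_BCD <- function(gait, delta = 1e-7,
                                  mode = c("single", "double"),
                                  method = c("forward", "central"),
                                  int_tol = 1e-13) {
  lm <- linearize_gait(gait, delta = delta, mode = match.arg(mode),
                       method = match.arg(method), int_tol = int_tol)
  lm[c("B", "C", "D")]
}

#' Classify open-loop stability over a gait grid
#'
#' Computes the return-map Jacobian at every converged cell of a grid,
#' flags cells with both eigenvalue magnitudes below one as stable, and
#' labels the unstable cells by which side of the stable band they fall on
#' along the step-frequency axis: the gait space has a low-frequency
#' unstable region (left), a central stable region, and an unstable region
#' at combinations of high step frequency and long step length (right).
#'
#' @param grid a \code{gait_grid}.
#' @param delta finite-difference step.
#' @param int_tol integration tolerance.
#' @return A data frame of class \code{stability_report} keyed by
#'   \code{(SL_target, SF_target)} with \code{max_eig}, \code{stable} and
#'   \code{region} in \code{"left-unstable"}, \code{"center-stable"},
#'   \code{"right-unstable"} (NA where not evaluable).
#' @export
classify_stability <- function(grid, delta = 1e-7, int_tol = 1e-13) {
  mode <- attr(grid, "mode")
  max_eig <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (!grid$converged[i]) next
    g <- row_to_gait(grid[i, ], mode)
    A <- try(finite_difference_A(g, delta = delta, int_tol = int_tol),
             silent = TRUE)
    if (!inherits(A, "try-error"))
      max_eig[i] <- max(Mod(eigen(A, only.values = TRUE)$values))
  }
  rep <- data.frame(SL_target = grid$SL_target, SF_target = grid$SF_target,
                    max_eig = max_eig, stable = !is.na(max_eig) & max_eig < 1,
                    region = NA_character_)
  # per-SL-row labeling relative to the stable band along SF
  for (sl in unique(rep$SL_target)) {
    sel <- rep$SL_target == sl
    sub <- rep[sel, ]
    st <- sub$stable & !is.na(sub$max_eig)
    lab <- rep(NA_character_, nrow(sub))
    if (any(st)) {
      lo <- min(sub$SF_target[st]); hi <- max(sub$SF_target[st])
      lab[st] <- "center-stable"
      lab[!st & sub$SF_target < lo] <- "left-unstable"
      lab[!st & sub$SF_target > hi] <- "right-unstable"
      lab[!st & sub$SF_target >= lo & sub$SF_target <= hi] <- "center-stable"
    } else {
      lab[sub$SF_target < 0.3] <- "left-unstable"
      lab[sub$SF_target >= 0.3] <- "right-unstable"
    }
    lab[is.na(sub$max_eig)] <- NA_character_
    rep$region[sel] <- lab
  }
  class(rep) <- c("stability_report", "data.frame")
  rep
}

#' Controllability of a linearized gait
#'
#' Builds the controllability matrix \code{[B, AB]} and evaluates its
#' numerical rank by the singular-value ratio. For the single-spring walker
#' a zero-boundary proximity score is reported:
#' \code{max(|A12|, |B12|, |B22|)} (state convention: row 1 = theta,
#' column 2 = the stiffness input), the three sensitivities that vanish
#' simultaneously along the uncontrollable locus.
#'
#' @param maps a \code{linearized_maps}.
#' @param sv_tol singular-value ratio threshold for rank decisions.
#' @return A list of class \code{controllability_report} with
#'   \code{ctrb} (the controllability matrix), \code{singular_values},
#'   \code{rank}, \code{controllable} and \code{zero_boundary_score}
#'   (NA in double-spring mode).
#' @export
controllability_test <- function(maps, sv_tol = 1e-8) {
  ctrb <- cbind(maps$B, maps$A %*% maps$B)
  sv <- svd(ctrb, nu = 0, nv = 0)$d
  rank <- sum(sv > sv_tol * sv[1])
  zb <- if (maps$mode == "single")
    max(abs(maps$A[1, 2]), abs(maps$B[1, 2]), abs(maps$B[2, 2]))
  else NA_real_
  structure(list(ctrb = ctrb, singular_values = sv, rank = rank,
                 controllable = rank == 2L, zero_boundary_score = zb,
                 SL_target = maps$SL_target, SF_target = maps$SF_target,
                 mode = maps$mode),
            class = "controllability_report")
}

#' Locate the single-spring zero-boundary along a step-frequency sweep
#'
#' At fixed step length, finds the step frequency at which the stiffness
#' column of B loses its effect on the next stance angle (the B12 = 0
#' crossing), by sign change between grid samples refined with bisection.
#' Gaits on this locus are uncontrollable in single-spring mode.
#'
#' @param SL fixed step length.
#' @param SF_range length-2 search interval.
#' @param n_coarse number of coarse samples.
#' @param tol_SF bisection tolerance on SF.
#' @param ... passed to \code{\link{solve_limit_cycle}}.
#' @return A list with \code{SF_boundary}, the bracketing samples, and the
#'   \code{linearized_maps} at the refined boundary gait.
#' @export
locate_zero_boundary <- function(SL, SF_range, n_coarse = 9L,
                                 tol_SF = 1e-3, ...) {
  # a private cache: the localization always uses a fresh canonical walk so
  # the refined boundary does not depend on what was solved earlier
  cache <- new_gait_cache()
  b12_at <- function(SF) {
    g <- solve_family_gait(SL, SF, cache = cache, ...)
    if (!g$converged) return(list(val = NA_real_, gait = g))
    lm <- linearize_gait(g, mode = "single")
    list(val = lm$B[1, 2], gait = g, maps = lm)
  }
  SFs <- seq(SF_range[1], SF_range[2], length.out = n_coarse)
  vals <- rep(NA_real_, n_coarse)
  for (i in seq_along(SFs)) vals[i] <- b12_at(SFs[i])$val
  cross <- which(diff(sign(vals)) != 0 & !is.na(head(vals, -1)) &
                 !is.na(tail(vals, -1)))
  if (length(cross) == 0L) stop("no B12 sign change in SF_range")
  lo <- SFs[cross[1]]; hi <- SFs[cross[1] + 1]
  vlo <- vals[cross[1]]
  last <- NULL
  while (hi - lo > tol_SF) {
    mid <- (lo + hi) / 2
    r <- b12_at(mid)
    if (is.na(r$val)) break
    last <- r
    if (sign(r$val) == sign(vlo)) { lo <- mid; vlo <- r$val } else hi <- mid
  }
  list(SF_boundary = (lo + hi) / 2, SF_bracket = c(lo, hi),
       maps = last$maps, gait = last$gait)
}

#' Export a stability or controllability report as CSV
#'
#' @param report a data frame report.
#' @param file path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, file) {
  write.csv(as.data.frame(report), file, row.names = FALSE)
  invisible(file)
}
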