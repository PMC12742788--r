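#' The five representative gaits of the gait space
#'
#' One gait per region: centre, top right (long, fast), top left (long,
#' slow), bottom right (short, fast), bottom left (short, slow).
#'
#' @return A data frame with columns \code{region, SL, SF}.
#' @export
representative_gaits <- function() {
  data.frame(
    region = c("centre", "top_right", "top_left", "bottom_right",
               "bottom_left"),
    SL = c(0.60, 0.85, 0.85, 0.35, 0.35),
    SF = c(0.60, 0.85, 0.35, 0.85, 0.35))
}

#' Experiment configuration
#'
#' Bundles the tunable numerical parameters of the workbench experiments.
#' Defaults: gait space \code{[0.1, 1.1]^2} at 0.01 increment, integration
#' tolerance 1e-13, solver tolerance 1e-11, finite-difference perturbation
#' 1e-7, the five representative gaits, seed 1.
#'
#' @param SL_range,SF_range gait-space extent.
#' @param increment grid increment.
#' @param int_tol,tol,fd_delta integration / solver / finite-difference
#'   parameters.
#' @param representative data frame of representative gaits.
#' @param seed integer seed for any randomized choices.
#' @param out_dir output directory for exports.
#' @return A list of class \code{experiment_config}.
#' @export
experiment_config <- function(SL_range = c(0.1, 1.1),
                              SF_range = c(0.1, 1.1),
                              increment = 0.01,
                              int_tol = 1e-13, tol = 1e-11,
                              fd_delta = 1e-7,
                              representative = representative_gaits(),
                              seed = 1L, out_dir = ".") {
  stopifnot(int_tol > 0, tol > 0, fd_delta > 0, increment > 0)
  if (any(representative$SL < SL_range[1] | representative$SL > SL_range[2] |
          representative$SF < SF_range[1] | representative$SF > SF_range[2]))
    stop("representative gaits must lie inside the gait space")
  structure(list(SL_range = SL_range, SF_range = SF_range,
                 increment = increment, int_tol = int_tol, tol = tol,
                 fd_delta = fd_delta, representative = representative,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Solve a small fixture grid
#'
#' A fully converged square sub-grid around a center gait, solved by
#' warm-start continuation; fails loudly if any cell does not converge, so
#' a fixture is always a valid grid.
#'
#' @param center length-2 \code{c(SL, SF)}.
#' @param half_width half extent of the square patch.
#' @param increment grid increment.
#' @param ... passed to \code{\link{continuation_sweep}}.
#' @return A \code{gait_grid}.
#' @export
make_fixture_grid <- function(center = c(0.6, 0.6), half_width = 0.03,
                              increment = 0.01, ...) {
  grid <- continuation_sweep(center[1] + c(-1, 1) * half_width,
                             center[2] + c(-1, 1) * half_width,
                             increment = increment, ...)
  if (!all(grid$converged))
    stop(sum(!grid$converged), " fixture cells failed to converge")
  grid
}

#' Open-loop stability structure of the gait space
#'
#' Solves a sub-sampled grid over the gait space by continuation,
#' classifies per-cell stability from the return-map eigenvalues, and
#' summarizes the mean largest eigenvalue magnitude per region.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param stride sub-sampling increment (default 0.05: every 5th cell of
#'   the reference 0.01 grid).
#' @return A list with the solved \code{grid}, the per-cell \code{report}
#'   and \code{region_means} (named mean max-eigenvalue magnitudes).
#' @export
stability_experiment <- function(config = experiment_config(),
                                 stride = 0.05) {
  # Solve stride-spaced step-length rows, each densely (0.01) in step
  # frequency: small warm-start steps keep the continuation on the single
  # gait family (coarser jumps can slip onto a neighboring solution branch
  # with different stability), and each row is seeded at the fast-frequency
  # end where the solution is unique.
  SLs <- seq(config$SL_range[1], config$SL_range[2], by = stride)
  eig_SFs <- seq(config$SF_range[1], config$SF_range[2], by = stride)
  nSL <- length(SLs); nSF <- length(eig_SFs)
  G <- vector("list", nSL * nSF)
  idx <- function(i, j) (i - 1L) * nSF + j
  for (i in seq_len(nSL)) for (j in seq_len(nSF)) {
    G[[idx(i, j)]] <- solve_family_gait(SLs[i], eig_SFs[j],
                                        step = config$increment,
                                        tol = config$tol,
                                        int_tol = config$int_tol)
  }
  # coherence repair: the family's stiffness varies only weakly with step
  # length, so a cell whose k deviates strongly from two mutually coherent
  # step-length neighbors has hopped onto a crossing branch during its
  # column walk; re-approach it by bridging from a neighbor
  k_of <- function(g) if (g$converged) g$u_nominal[["k1"]] else NA_real_
  for (pass in 1:2) {
    for (i in seq_len(nSL)) for (j in seq_len(nSF)) {
      if (i == 1L || i == nSL) next
      g <- G[[idx(i, j)]]
      n1 <- G[[idx(i - 1L, j)]]; n2 <- G[[idx(i + 1L, j)]]
      k1 <- k_of(n1); k2 <- k_of(n2)
      if (is.na(k1) || is.na(k2) || abs(k1 - k2) > 0.04) next
      pred <- (k1 + k2) / 2
      if (!is.na(k_of(g)) && abs(k_of(g) - pred) <= 0.08) next
      gb <- .bridge_walk(n1, SLs[i], eig_SFs[j], "single",
                         config$tol, config$int_tol, n_sub = 8L)
      if (gb$converged && abs(k_of(gb) - pred) < 0.08) {
        G[[idx(i, j)]] <- gb
        fc <- .family_cache(config$tol, config$int_tol)
        fc$gaits[[sprintf("%.9f_%.9f", SLs[i], eig_SFs[j])]] <- gb
      }
    }
  }
  rows <- lapply(seq_along(G), function(r) {
    g <- G[[r]]
    i <- (r - 1L) %/% nSF + 1L; j <- (r - 1L) %% nSF + 1L
    data.frame(SL_target = SLs[i], SF_target = eig_SFs[j],
               theta = g$x_star[[1]], theta_dot = g$x_star[[2]],
               P = g$u_nominal[["P"]], k1 = g$u_nominal[["k1"]],
               k2 = g$u_nominal[["k2"]], step_time = g$step_time,
               SL = g$SL, SF = g$SF, converged = g$converged,
               residual_norm = g$residual_norm)
  })
  grid <- do.call(rbind, rows)
  attr(grid, "SL_axis") <- SLs
  attr(grid, "SF_axis") <- sort(unique(grid$SF_target))
  attr(grid, "increment") <- stride
  attr(grid, "mode") <- "single"
  attr(grid, "tol") <- config$tol
  attr(grid, "int_tol") <- config$int_tol
  class(grid) <- c("gait_grid", "data.frame")
  rep <- classify_stability(grid, delta = config$fd_delta,
                            int_tol = config$int_tol)
  means <- tapply(rep$max_eig[!is.na(rep$region)],
                  rep$region[!is.na(rep$region)],
                  mean, na.rm = TRUE)
  list(grid = grid, report = rep, region_means = means)
}

#' Maximum-tolerable-perturbation sweep over a gait sample
#'
#' Runs \code{\link{mtp_search}} (open loop and/or controlled) at each
#' gait of a sub-sampled lattice of the gait space.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param stride lattice spacing of target gaits (default 0.1: every 10th
#'   cell of the reference grid).
#' @param controlled logical vector: which of open-loop (\code{FALSE}) and
#'   controlled (\code{TRUE}) sweeps to run.
#' @param n_steps survival-test length.
#' @param max_layers cap on neighbor layers per target.
#' @return A data frame with one row per (gait, mode): \code{SL, SF,
#'   controlled, solved, mtp}.
#' @export
mtp_experiment <- function(config = experiment_config(), stride = 0.1,
                           controlled = c(FALSE, TRUE), n_steps = 100L,
                           max_layers = 12L) {
  SLs <- seq(config$SL_range[1], config$SL_range[2], by = stride)
  SFs <- seq(config$SF_range[1], config$SF_range[2], by = stride)
  out <- list()
  for (SL in rev(SLs)) {
    for (SF in rev(SFs)) {
    cache <- new_gait_cache(mode = "single", tol = config$tol,
                            int_tol = config$int_tol)
    g <- solve_family_gait(SL, SF, tol = config$tol,
                           int_tol = config$int_tol)
    if (g$converged) {
      # pre-warm the per-target cache so neighbor solves start on-family
      cache$gaits[[sprintf("%.9f_%.9f", g$SL_target, g$SF_target)]] <- g
      cache$keys <- rbind(cache$keys, c(g$SL_target, g$SF_target))
    }
    for (ctl in controlled) {
      mtp <- NA_real_
      if (g$converged) {
        ctrl <- NULL
        if (ctl) {
          lm <- try(linearize_gait(g, delta = config$fd_delta,
                                   mode = "double",
                                   int_tol = config$int_tol), silent = TRUE)
          if (!inherits(lm, "try-error"))
            ctrl <- try(local_controller(g, lm), silent = TRUE)
          if (inherits(ctrl, "try-error")) ctrl <- NULL
          if (is.null(ctrl)) {
            out[[length(out) + 1L]] <- data.frame(
              SL = SL, SF = SF, controlled = ctl, solved = TRUE,
              mtp = NA_real_)
            next
          }
        }
        mtp <- mtp_search(g, controller = ctrl, cache = cache,
                          increment = config$increment,
                          max_layers = max_layers, n_steps = n_steps,
                          int_tol = config$int_tol)$mtp_radius
      }
      out[[length(out) + 1L]] <- data.frame(
        SL = SL, SF = SF, controlled = ctl, solved = g$converged, mtp = mtp)
    }
    }
  }
  do.call(rbind, out)
}

#' Local-controller response times at the representative gaits
#'
#' For each representative gait: the controlled maximum tolerable
#' perturbation, and the four settling times after perturbing step
#' frequency and step length up and down by the MTP magnitude under the
#' gait's own deadbeat controller.
#'
#' @param config an \code{\link{experiment_config}}.
#' @return A data frame with columns \code{region, SL, SF, MTP,
#'   rt_SF_up, rt_SF_down, rt_SL_up, rt_SL_down} (settling times in steps,
#'   interpolated).
#' @export
reproduce_table1 <- function(config = experiment_config()) {
  reps <- config$representative
  rows <- list()
  for (r in seq_len(nrow(reps))) {
    cache <- new_gait_cache(mode = "single", tol = config$tol,
                            int_tol = config$int_tol)
    g <- solve_family_gait(reps$SL[r], reps$SF[r], tol = config$tol,
                           int_tol = config$int_tol)
    if (!g$converged) stop("representative gait did not converge: ",
                           reps$region[r])
    cache$gaits[[sprintf("%.9f_%.9f", g$SL_target, g$SF_target)]] <- g
    cache$keys <- rbind(cache$keys, c(g$SL_target, g$SF_target))
    ctrl <- local_controller(g, linearize_gait(g, delta = config$fd_delta,
                                               mode = "double",
                                               int_tol = config$int_tol))
    mtp <- mtp_search(g, controller = ctrl, cache = cache,
                      increment = config$increment,
                      int_tol = config$int_tol)$mtp_radius
    rt <- function(axis, sgn) {
      pr <- perturbation_response(g, ctrl, axis = axis, size = sgn * mtp,
                                  cache = cache, int_tol = config$int_tol)
      pr$settling$steps_interp
    }
    rows[[r]] <- data.frame(
      region = reps$region[r], SL = reps$SL[r], SF = reps$SF[r], MTP = mtp,
      rt_SF_up = rt("SF", 1), rt_SF_down = rt("SF", -1),
      rt_SL_up = rt("SL", 1), rt_SL_down = rt("SL", -1))
  }
  do.call(rbind, rows)
}

# Gain-grid patch covering an exponential-reference experiment: the
# perturbed axis spans +/- (perturb_frac * value + margin), the other axis
# one increment around the target.
.policy_patch <- function(target, axis, config, perturb_frac = 0.15,
                          margin = 0.03) {
  inc <- config$increment
  span <- function(v) {
    lo <- floor((v * (1 - perturb_frac) - margin) / inc) * inc
    hi <- ceiling((v * (1 + perturb_frac) + margin) / inc) * inc
    c(max(lo, config$SL_range[1]), hi)
  }
  if (axis == "SL") {
    SLr <- span(target$SL_target)
    SFr <- target$SF_target + c(-1, 1) * inc
  } else {
    SLr <- target$SL_target + c(-1, 1) * inc
    SFr <- span(target$SF_target)
  }
  grid <- continuation_sweep(SLr, SFr, increment = inc, mode = "single",
                             tol = config$tol, int_tol = config$int_tol,
                             seed_gait = target)
  gain_grid(grid, delta = config$fd_delta, int_tol = config$int_tol)
}

#' Optimal policy response times at the representative gaits
#'
#' For each representative gait and each perturbed axis, builds a local
#' gain-grid patch, then optimizes the exponential-reference time constant
#' and reports the settling time of the policy-tracked runs for the 15%
#' perturbation experiment. The reference length is 10 steps except for
#' the top-left gait's step-frequency case, which needs 30.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param regions subset of region names to run (default all five).
#' @return A data frame \code{region, SL, SF, axis, tau, response_time}.
#' @export
reproduce_table2 <- function(config = experiment_config(),
                             regions = NULL) {
  reps <- config$representative
  if (!is.null(regions)) reps <- reps[reps$region %in% regions, ]
  rows <- list()
  for (r in seq_len(nrow(reps))) {
    cache <- new_gait_cache(mode = "single", tol = config$tol,
                            int_tol = config$int_tol)
    g <- solve_family_gait(reps$SL[r], reps$SF[r], tol = config$tol,
                           int_tol = config$int_tol)
    if (!g$converged) stop("representative gait did not converge: ",
                           reps$region[r])
    cache$gaits[[sprintf("%.9f_%.9f", g$SL_target, g$SF_target)]] <- g
    cache$keys <- rbind(cache$keys, c(g$SL_target, g$SF_target))
    for (axis in c("SF", "SL")) {
      gg <- .policy_patch(g, axis, config)
      ms <- if (axis == "SF" && reps$region[r] == "top_left") 30L else 10L
      res <- optimize_response_time(g, axis = axis, gg = gg, max_steps = ms,
                                    cache = cache,
                                    int_tol = config$int_tol)
      rows[[length(rows) + 1L]] <- data.frame(
        region = reps$region[r], SL = reps$SL[r], SF = reps$SF[r],
        axis = axis, tau = res$tau, response_time = res$response_time)
    }
  }
  do.call(rbind, rows)
}

#' Summary statistics of controller performance
#'
#' Means and standard deviations: local-controller response times over the
#' representative gaits (step-length and step-frequency perturbations
#' separately, both directions pooled) and, when an MTP sweep is supplied,
#' the open-loop and controlled maximum tolerable perturbations.
#'
#' @param table1 output of \code{\link{reproduce_table1}}.
#' @param mtp output of \code{\link{mtp_experiment}} (optional).
#' @return A list with \code{response_SL}, \code{response_SF} (each
#'   \code{c(mean, sd)}), and when available \code{mtp_open},
#'   \code{mtp_controlled} and \code{mtp_ratio}.
#' @export
reproduce_summary_stats <- function(table1, mtp = NULL) {
  msd <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  out <- list(
    response_SL = msd(c(table1$rt_SL_up, table1$rt_SL_down)),
    response_SF = msd(c(table1$rt_SF_up, table1$rt_SF_down)))
  if (!is.null(mtp)) {
    op <- mtp$mtp[!mtp$controlled & mtp$solved]
    cl <- mtp$mtp[mtp$controlled & mtp$solved]
    out$mtp_open <- msd(op)
    out$mtp_controlled <- msd(cl)
    out$mtp_ratio <- mean(cl, na.rm = TRUE) / mean(op, na.rm = TRUE)
  }
  out
}
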