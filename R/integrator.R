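#' Solver settings
#'
#' @param method time stepping scheme: `"ssprk3"` (default, third-order
#'   strong-stability-preserving Runge-Kutta), `"rk2"` (Heun) or `"euler"`.
#' @param cfl_safety CFL safety factor in `(0, 1]` multiplying the stable
#'   step estimate.
#' @param t_final integration horizon.
#' @param snapshot_times times at which full densities are stored; the step
#'   size is clipped so snapshots are hit exactly (no interpolation).
#' @param steady_tol relative rhs-norm threshold for steady-state detection.
#' @param max_steps hard cap on the number of steps.
#' @param limiter slope limiter for advection (see [make_rhs()]).
#' @param theta generalised minmod parameter.
#' @param split_sinks if `TRUE`, transitions into absorbing states with pure
#'   local (possibly stiff) rates are removed from the explicit right-hand
#'   side and applied after each step by their exact exponential solution;
#'   the stiff rate then no longer restricts the step size.
#' @param record_every record observables (per-state masses) every this many
#'   steps.
#' @param recompute_dt recompute the CFL step every step (needed only for
#'   time-dependent rates).
#' @param progress print a progress line every `progress` steps (0 = quiet).
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(method = c("ssprk3", "rk2", "euler"),
                            cfl_safety = 0.4, t_final = 1,
                            snapshot_times = NULL, steady_tol = 1e-8,
                            max_steps = 1e8, limiter = "minmod", theta = 1,
                            split_sinks = FALSE, record_every = 1L,
                            recompute_dt = FALSE, progress = 0L) {
  method <- match.arg(method)
  stopifnot(cfl_safety > 0, cfl_safety <= 1)
  structure(list(method = method, cfl_safety = cfl_safety, t_final = t_final,
                 snapshot_times = snapshot_times, steady_tol = steady_tol,
                 max_steps = max_steps, limiter = limiter, theta = theta,
                 split_sinks = split_sinks, record_every = as.integer(record_every),
                 recompute_dt = recompute_dt, progress = progress),
            class = "solver_settings")
}

# transitions treatable by the exact-exponential split: non-negative local
# rates into an absorbing state
sink_transition_idx <- function(model) {
  labels <- state_labels(model)
  absorbing <- stats::setNames(state_flag(model, "absorbing"), labels)
  which(vapply(model$transitions, function(tr)
    isTRUE(absorbing[[tr$to]]) && !isTRUE(absorbing[[tr$from]]),
    logical(1)))
}

#' Stable explicit time step
#'
#' Conservative CFL bound combining the advective limit `dx / max |rate|`,
#' the diffusive limit `omega dx^2 / max(rate * |e|^2)`, and the local-rate
#' limit `1 / max(total outgoing rate)` (jump losses and transition rates,
#' including stiff absorption unless it is being split).  The bound is
#' multiplied by `cfl_safety` and clipped to the remaining time.
#'
#' @param model an [acme_model()].
#' @param p current density (unused by the bound itself; kept for signature
#'   stability with state-dependent extensions).
#' @param t current time.
#' @param settings a [solver_settings()].
#' @return positive time step.
#' @export
compute_dt <- function(model, p, t, settings) {
  grid <- acme_grid(model)
  coords <- grid_coords(grid)
  N <- grid$n_total
  labels <- state_labels(model)
  absorbing <- stats::setNames(state_flag(model, "absorbing"), labels)
  excl <- if (isTRUE(settings$split_sinks)) sink_transition_idx(model) else integer(0)

  vmax <- 0
  dmax <- 0
  out_rate <- matrix(0, N, length(labels))
  colnames(out_rate) <- labels
  for (rx in model$reactions) {
    e2 <- sum(rx$displacement^2)
    for (k in labels) {
      f <- rx$rate[[k]]
      if (is.null(f) || absorbing[[k]]) next
      v <- abs(rate_values(f, coords, t, N, rx$name))
      vmax <- max(vmax, v)
      if (model$diffusion) dmax <- max(dmax, max(v) * e2)
    }
  }
  for (jp in model$jumps) {
    for (k in labels) {
      f <- jp$rate[[k]]
      if (is.null(f) || absorbing[[k]]) next
      out_rate[, k] <- out_rate[, k] + pmax(rate_values(f, coords, t, N, jp$name), 0)
    }
  }
  for (i in seq_along(model$transitions)) {
    if (i %in% excl) next
    tr <- model$transitions[[i]]
    if (absorbing[[tr$from]]) next
    g <- rate_values(tr$rate, coords, t, N, "transition")
    out_rate[, tr$from] <- out_rate[, tr$from] + abs(g)
  }

  cand <- c(if (vmax > 0) grid$dx / vmax,
            if (dmax > 0) model$omega * grid$dx^2 / dmax,
            if (max(out_rate) > 0) 1 / max(out_rate))
  remaining <- settings$t_final - t
  if (!length(cand)) return(remaining)
  min(settings$cfl_safety * min(cand), remaining)
}

#' Integrate the hybrid system
#'
#' Explicit time integration of the semi-discrete system from `p0` to
#' `settings$t_final` under CFL control.  Fully deterministic: repeated runs
#' with identical inputs are bit-identical.
#'
#' @param model a validated [acme_model()].
#' @param p0 initial [grid_density()] on the model's grid.
#' @param settings a [solver_settings()].
#' @return object of class `acme_trajectory`: list with `times` and
#'   `snapshots` (densities at the requested snapshot times plus the final
#'   time), `observables` (data.frame of step times and per-state masses),
#'   `model` and `settings`.
#' @export
acme_integrate <- function(model, p0, settings = solver_settings()) {
  grid <- attr(p0, "grid")
  labels <- colnames(p0)
  validate_model(model, strict = TRUE)
  excl <- if (isTRUE(settings$split_sinks)) sink_transition_idx(model) else integer(0)
  rhs <- make_rhs(model, limiter = settings$limiter, theta = settings$theta,
                  exclude_transitions = excl)
  sinks <- lapply(excl, function(i) model$transitions[[i]])
  coords <- grid_coords(grid)
  dxd <- grid$dx^grid$d

  p <- unclass_density(p0)
  t <- 0
  dt0 <- compute_dt(model, p0, 0, settings)
  snap_times <- sort(unique(c(settings$snapshot_times, settings$t_final)))
  snap_times <- snap_times[snap_times > 1e-14]
  snapshots <- list()
  snap_at <- numeric(0)
  if (!is.null(settings$snapshot_times) && any(settings$snapshot_times <= 1e-14)) {
    snapshots[[1]] <- p0
    snap_at <- 0
  }

  est <- min(ceiling(settings$t_final / max(dt0, 1e-300)) + length(snap_times) + 2L,
             settings$max_steps + 1L, 5e7)
  nrec <- as.integer(est %/% settings$record_every + 2L)
  rec_t <- numeric(nrec)
  rec_m <- matrix(NA_real_, nrec, length(labels))
  rec_t[1] <- 0
  rec_m[1, ] <- colSums(p) * dxd
  irec <- 1L

  step <- 0L
  next_snap <- 1L
  while (t < settings$t_final - 1e-14 && step < settings$max_steps) {
    dt <- if (settings$recompute_dt) {
      compute_dt(model, NULL, t, settings)
    } else min(dt0, settings$t_final - t)
    if (next_snap <= length(snap_times))
      dt <- min(dt, snap_times[next_snap] - t)
    p <- rk_step(rhs, p, t, dt, settings$method)
    if (length(sinks))
      p <- apply_sinks(p, sinks, coords, t, dt)
    t <- t + dt
    step <- step + 1L
    if (step %% settings$record_every == 0L) {
      irec <- irec + 1L
      if (irec > nrec) {  # grow if the estimate was short
        rec_t <- c(rec_t, numeric(nrec))
        rec_m <- rbind(rec_m, matrix(NA_real_, nrec, length(labels)))
        nrec <- length(rec_t)
      }
      rec_t[irec] <- t
      rec_m[irec, ] <- colSums(p) * dxd
    }
    if (step %% 200L == 0L && any(!is.finite(p))) {
      bad <- which(!is.finite(p), arr.ind = TRUE)[1, ]
      stop(sprintf("non-finite density at t = %g (cell %d, state %s)",
                   t, bad[1], labels[bad[2]]))
    }
    if (next_snap <= length(snap_times) &&
        abs(t - snap_times[next_snap]) < 1e-12 * max(1, t)) {
      snapshots[[length(snapshots) + 1L]] <- grid_density(grid, labels, p)
      snap_at <- c(snap_at, t)
      next_snap <- next_snap + 1L
    }
    if (settings$progress > 0 && step %% settings$progress == 0L)
      message(sprintf("step %d  t=%.6g  dt=%.3g  mass=%s", step, t, dt,
                      paste(signif(colSums(p) * dxd, 6), collapse = " ")))
  }
  if (any(!is.finite(p)))
    stop(sprintf("non-finite density at t = %g", t))
  if (!length(snap_at) || abs(snap_at[length(snap_at)] - t) > 1e-12) {
    snapshots[[length(snapshots) + 1L]] <- grid_density(grid, labels, p)
    snap_at <- c(snap_at, t)
  }
  obs <- data.frame(t = rec_t[seq_len(irec)])
  for (j in seq_along(labels))
    obs[[paste0("mass_", labels[j])]] <- rec_m[seq_len(irec), j]
  structure(list(times = snap_at, snapshots = snapshots, observables = obs,
                 model = model, settings = settings, steps = step),
            class = "acme_trajectory")
}

rk_step <- function(rhs, p, t, dt, method) {
  switch(method,
    euler = p + dt * rhs(p, t),
    rk2 = {
      p1 <- p + dt * rhs(p, t)
      0.5 * (p + p1 + dt * rhs(p1, t + dt))
    },
    ssprk3 = {
      p1 <- p + dt * rhs(p, t)
      p2 <- 0.75 * p + 0.25 * (p1 + dt * rhs(p1, t + dt))
      (p + 2 * (p2 + dt * rhs(p2, t + 0.5 * dt))) / 3
    },
    stop("unknown method '", method, "'"))
}

apply_sinks <- function(p, sinks, coords, t, dt) {
  for (tr in sinks) {
    r <- tr$rate(coords, t)
    if (length(r) == 1L) r <- rep.int(r, nrow(p))
    decay <- exp(-r * dt)
    moved <- p[, tr$from] * (1 - decay)
    p[, tr$from] <- p[, tr$from] * decay
    p[, tr$to] <- p[, tr$to] + moved
  }
  p
}

#' @export
print.acme_trajectory <- function(x, ...) {
  cat("<acme_trajectory> ", length(x$snapshots), " snapshots, ",
      x$steps, " steps, t in [0, ", format(max(x$times)), "]\n", sep = "")
  invisible(x)
}

#' Stationary density
#'
#' Two methods.  `"direct"` (default) assembles the linearised semi-discrete
#' operator ([operator_matrix()], unlimited central slopes) and solves its
#' null space with one row replaced by the unit-mass constraint -- fast and
#' exact to solver precision for autonomous models.  `"march"` integrates in
#' time until the relative rhs norm `||dp/dt||_1 / ||p||_1` drops below
#' `settings$steady_tol`, which also works for limited slopes.
#'
#' Non-convergence of the march is reported through the `converged`
#' attribute, not as an error.
#'
#' @param model an autonomous [acme_model()].
#' @param p0 initial density; required for `"march"`, used by `"direct"`
#'   only to set the total mass (default mass 1).
#' @param settings a [solver_settings()]; `t_final` bounds the march.
#' @param method `"direct"` or `"march"`.
#' @return a [grid_density()] with attributes `converged` (logical) and
#'   `residual` (relative rhs norm at the returned density).
#' @export
steady_state <- function(model, p0 = NULL, settings = solver_settings(),
                         method = c("direct", "march")) {
  method <- match.arg(method)
  grid <- acme_grid(model)
  labels <- state_labels(model)
  if (method == "direct") {
    A <- operator_matrix(model, t = 0)
    n <- nrow(A)
    mass0 <- if (is.null(p0)) 1 else total_mass(p0)
    pin <- if (is.null(p0)) (n %/% 2L + 1L) else which.max(abs(as.numeric(unclass_density(p0))))
    A2 <- A
    A2[pin, ] <- grid$dx^grid$d
    b <- numeric(n)
    b[pin] <- mass0
    q <- tryCatch(as.numeric(Matrix::solve(A2, b)),
                  error = function(e) rep(NA_real_, n))
    vals <- matrix(q, grid$n_total, length(labels))
    p <- grid_density(grid, labels, vals)
    res <- if (any(!is.finite(q))) Inf else
      sum(abs(A %*% q)) / max(sum(abs(q)), 1e-300)
    attr(p, "converged") <- is.finite(res) && res < max(settings$steady_tol, 1e-6)
    attr(p, "residual") <- res
    return(p)
  }
  stopifnot(!is.null(p0))
  rhs <- make_rhs(model, limiter = settings$limiter, theta = settings$theta)
  p <- unclass_density(p0)
  t <- 0
  dt <- compute_dt(model, p0, 0, settings)
  check_every <- 20L
  converged <- FALSE
  res <- sum(abs(rhs(p, 0))) / max(sum(abs(p)), 1e-300)
  if (res < settings$steady_tol) {
    attr(p0, "converged") <- TRUE
    attr(p0, "residual") <- res
    return(p0)
  }
  for (step in seq_len(settings$max_steps)) {
    p <- rk_step(rhs, p, t, min(dt, settings$t_final - t), settings$method)
    t <- t + min(dt, settings$t_final - t)
    if (step %% check_every == 0L) {
      r <- rhs(p, t)
      res <- sum(abs(r)) / max(sum(abs(p)), 1e-300)
      if (!is.finite(res)) stop("non-finite density during steady-state march")
      if (res < settings$steady_tol) {
        converged <- TRUE
        break
      }
    }
    if (t >= settings$t_final - 1e-14) break
  }
  out <- grid_density(grid, labels, p)
  attr(out, "converged") <- converged
  attr(out, "residual") <- res
  out
}
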