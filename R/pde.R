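#' Discretization grid for the length-structured transport equations
#'
#' Builds the shared (x, l) grid and time step for the deterministic solver.
#' Minus-end position `x` and length `l` use the same resolution `dx = dl`, so
#' plus-end positions `x + l` land on grid nodes and the advection terms can be
#' applied as exact integer-cell shifts (no numerical diffusion in the
#' transport). The time step is chosen commensurate: `vg*dt/dx` and `vs*dt/dx`
#' are integers, obtained from the smallest integer ratio approximating
#' `vg : vs` within 1% (a rational approximation for awkward ratios; the
#' effective shrink speed is then `vg * b / a`, within 1% of `vs`).
#'
#' The state-exchange terms are integrated by forward Euler, so the commensurate
#' `dt` must also satisfy `max(fcat, fres) * dt < 0.1`; `dx` is halved (and a
#' message emitted) until it does.
#'
#' @param params A [dynamics_params()] object (fixes the commensurate ratio and
#'   the stability guard).
#' @param dx Requested spatial/length resolution, um. May be refined downward.
#' @param x_max Domain size in minus-end position, um.
#' @param l_max Domain size in length, um; defaults to 10 times the mean
#'   microtubule length in the bounded regime (a warning is issued below that).
#' @return An object of class `sim_grid`: list with `dx`, `dt`, `nx`, `nl`,
#'   `x`, `l` (cell centers), `shift_g`, `shift_s`, `x_max`, `l_max`.
#' @examples
#' g <- sim_grid(dynamics_params(30, 40, 3, 1), dx = 0.5, x_max = 100)
#' g$dt; g$shift_g; g$shift_s
#' @export
sim_grid <- function(params, dx = 0.5, x_max = 200, l_max = NULL) {
  p <- as_dynamics_params(params)
  stopifnot(dx > 0, x_max > dx)

  ab <- commensurate_ratio(p$vg, p$vs)
  a <- ab[1]; b <- ab[2]

  dt <- a * dx / p$vg
  guard <- max(p$fcat, p$fres)
  n_ref <- 0L
  while (guard * dt >= 0.1 && n_ref < 8L) {
    dx <- dx / 2
    dt <- a * dx / p$vg
    n_ref <- n_ref + 1L
  }
  if (guard * dt >= 0.1) {
    stop("could not find a stable commensurate time step; reduce dx",
         call. = FALSE)
  }
  if (n_ref > 0L) {
    message(sprintf("grid refined to dx = %g um (dt = %g min) for stability",
                    dx, dt))
  }

  lbar <- if (net_drift(p) < 0) mean_mt_length(p) else NA_real_
  if (is.null(l_max)) {
    l_max <- if (is.finite(lbar)) 10 * lbar else x_max
  }
  if (is.finite(lbar) && l_max < 10 * lbar) {
    warning(sprintf("l_max = %g um is below 10 x mean length (%.3g um); %s",
                    l_max, lbar, "length-domain truncation may bias results"),
            call. = FALSE)
  }

  nx <- as.integer(ceiling(x_max / dx))
  nl <- as.integer(ceiling(l_max / dx))
  structure(list(
    dx = dx, dt = dt, nx = nx, nl = nl,
    x = (seq_len(nx) - 0.5) * dx, l = (seq_len(nl) - 0.5) * dx,
    shift_g = a, shift_s = b, x_max = nx * dx, l_max = nl * dx
  ), class = "sim_grid")
}

# smallest integer pair (a, b) with a/b within 1% of vg/vs
commensurate_ratio <- function(vg, vs) {
  target <- vg / vs
  for (b in 1:128) {
    a <- round(target * b)
    if (a >= 1 && abs(a / b - target) / target < 0.01) return(c(a, b))
  }
  stop("no commensurate integer ratio for vg:vs within 1%; rescale speeds",
       call. = FALSE)
}

#' Simulation configuration
#'
#' @param t_end Total simulated time, min.
#' @param snapshot_every Interval between recorded snapshots, min.
#' @param init_width Width of the initial pulse of zero-length growing
#'   microtubules at the origin, um.
#' @param init_amplitude Plus-end density of the initial pulse (same units as
#'   the nucleation carrying capacity). Must stay below the carrying capacity.
#' @param centrosome_renucleation If `TRUE`, shrinking microtubules reaching
#'   zero length in the cell at `x = 0` re-enter the growing state (centrosomal
#'   re-nucleation); elsewhere they disappear. Off by default: front dynamics
#'   are autonomous of the seed.
#' @param clamp_nucleation If `TRUE` the logistic nucleation term is clamped at
#'   zero from below where the local density overshoots the carrying capacity.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(t_end, snapshot_every = 1, init_width = 2,
                       init_amplitude = 0.01, centrosome_renucleation = FALSE,
                       clamp_nucleation = TRUE) {
  stopifnot(t_end > 0, snapshot_every > 0, init_width >= 0,
            init_amplitude > 0)
  structure(list(t_end = t_end, snapshot_every = snapshot_every,
                 init_width = init_width, init_amplitude = init_amplitude,
                 centrosome_renucleation = isTRUE(centrosome_renucleation),
                 clamp_nucleation = isTRUE(clamp_nucleation)),
            class = "sim_config")
}

#' Initialize the PDE state
#'
#' Seeds a localized pulse of zero-length growing microtubules at the origin
#' (the first length cell, minus ends within `init_width` of `x = 0`), with
#' no shrinking microtubules. The pulse amplitude is the plus-end density it
#' contributes and must not exceed the nucleation carrying capacity.
#'
#' @param grid A [sim_grid()].
#' @param config A [sim_config()].
#' @param carrying_capacity Carrying capacity against which the pulse
#'   amplitude is validated (default `Inf`: no check).
#' @return An `aster_field` object: list with `t`, matrices `rho_g`, `rho_s`
#'   (rows = minus-end position, columns = length; densities per um per um),
#'   and the grid.
#' @export
initialize_state <- function(grid, config, carrying_capacity = Inf) {
  stopifnot(inherits(grid, "sim_grid"), inherits(config, "sim_config"))
  if (config$init_amplitude > carrying_capacity) {
    stop("initial pulse amplitude exceeds the carrying capacity",
         call. = FALSE)
  }
  rho_g <- matrix(0, grid$nx, grid$nl)
  rho_s <- matrix(0, grid$nx, grid$nl)
  n_cells <- max(1L, as.integer(round(config$init_width / grid$dx)))
  rho_g[seq_len(n_cells), 1L] <- config$init_amplitude / grid$dx
  structure(list(t = 0, rho_g = rho_g, rho_s = rho_s, grid = grid),
            class = "aster_field")
}

#' Growing plus-end density profile
#'
#' A microtubule with minus end at `x'` and length `l` carries its plus end at
#' `x' + l`; the plus-end density is the diagonal sum (convolution)
#' \eqn{C_g(x) = \sum_l \rho_g(x - l, l)\, dl}. Plus ends beyond the domain
#' edge are not counted.
#'
#' @param state An `aster_field`.
#' @return A tibble with columns `x` (um) and `density` (plus ends per um).
#' @export
plus_end_density <- function(state) {
  stopifnot(inherits(state, "aster_field"))
  tibble::tibble(x = state$grid$x, density = cg_profile(state$rho_g, state$grid))
}

cg_profile <- function(rho_g, grid) {
  nx <- grid$nx; nl <- grid$nl
  cg <- numeric(nx)
  for (il in seq_len(min(nl, nx))) {  # plus ends beyond x_max are not counted
    col <- rho_g[, il]
    if (il == 1L) cg <- cg + col * grid$dx
    else cg[il:nx] <- cg[il:nx] + col[seq_len(nx - il + 1L)] * grid$dx
  }
  cg
}

#' Polymer mass density profile
#'
#' Micrometres of microtubule polymer per micrometre of axis: each microtubule
#' (growing or shrinking) contributes its overlap with every cell it spans,
#' so the profile integrates to the total polymer length in the system.
#'
#' @param state An `aster_field`.
#' @return A tibble with columns `x` (um) and `density` (um polymer per um).
#' @export
polymer_density <- function(state) {
  stopifnot(inherits(state, "aster_field"))
  tibble::tibble(x = state$grid$x,
                 density = m_profile(state$rho_g + state$rho_s, state$grid))
}

m_profile <- function(rho, grid) {
  nx <- grid$nx; nl <- grid$nl
  m <- numeric(nx)
  for (il in seq_len(nl)) {
    col <- rho[, il]
    if (!any(col != 0)) next
    s <- cumsum(col)
    lo <- pmax(seq_len(nx) - il, 0L)
    w <- s - c(0, s)[lo + 1L]
    m <- m + w * grid$dx^2  # il cells of width dx each, density col * dx
  }
  m
}

#' Nucleation rate profile
#'
#' The local rate of appearance of new (zero-length) microtubules,
#' \eqn{Q(x) = r\, C_g (1 - C_g/K)} in plus-end mode or
#' \eqn{Q(x) = p\, M (1 - C_g/K)} in polymer mode, where the logistic factor
#' uses the local growing plus-end density in both modes.
#'
#' @param state An `aster_field`.
#' @param nucleation A [nucleation_spec()].
#' @param clamp If `TRUE`, negative values (density above carrying capacity)
#'   are clamped to zero.
#' @return A tibble with columns `x` (um) and `rate` (new microtubules per um
#'   per min).
#' @export
nucleation_profile <- function(state, nucleation, clamp = TRUE) {
  stopifnot(inherits(state, "aster_field"),
            inherits(nucleation, "nucleation_spec"))
  cg <- cg_profile(state$rho_g, state$grid)
  q <- q_profile(cg, state$rho_g, state$rho_s, state$grid, nucleation, clamp)
  tibble::tibble(x = state$grid$x, rate = q)
}

q_profile <- function(cg, rho_g, rho_s, grid, nucleation, clamp) {
  logistic <- 1 - cg / nucleation$carrying_capacity
  q <- if (nucleation$mode == "plus_end") {
    nucleation$rate * cg * logistic
  } else {
    nucleation$rate * m_profile(rho_g + rho_s, grid) * logistic
  }
  if (clamp) q <- pmax(q, 0)
  q
}

#' Advance the PDE state by one time step
#'
#' Operator-split update mirroring the transport equations:
#' 1. advect: growing microtubules lengthen by `vg*dt` (integer-cell shift in
#'    `l`), shrinking ones shorten by `vs*dt`;
#' 2. shrinking mass crossing `l = 0` disappears — except, with centrosomal
#'    re-nucleation on, mass in the `x = 0` cell re-enters the growing state
#'    at zero length;
#' 3. forward-Euler state exchange at rates `fcat` (growing to shrinking) and
#'    `fres` (shrinking to growing);
#' 4. nucleation deposits `Q(x)*dt` of zero-length growing microtubules at the
#'    plus-end position where they were induced.
#'
#' @param state An `aster_field`.
#' @param params A [dynamics_params()]; must match the grid's commensurate
#'   shifts.
#' @param nucleation A [nucleation_spec()].
#' @param config A [sim_config()].
#' @return The updated `aster_field`.
#' @export
step_state <- function(state, params, nucleation, config) {
  p <- as_dynamics_params(params)
  g <- state$grid
  stopifnot(inherits(state, "aster_field"), inherits(config, "sim_config"))
  if (abs(p$vg * g$dt / g$dx - g$shift_g) > 1e-8) {
    stop("grid was built for different dynamics parameters", call. = FALSE)
  }
  rho_g <- state$rho_g
  rho_s <- state$rho_s
  nl <- g$nl
  a <- g$shift_g; b <- g$shift_s

  # exact two-state switching kernel over a half step (matrix exponential of
  # the catastrophe/rescue generator; positivity-preserving, and removes the
  # leading reaction-step error, which matters because the net growth rate is
  # a small difference of the large opposing exchange fluxes)
  tot <- p$fcat + p$fres
  E <- exp(-tot * g$dt / 2)
  k_gg <- (p$fres + p$fcat * E) / tot
  k_sg <- (p$fres - p$fres * E) / tot
  k_gs <- (p$fcat - p$fcat * E) / tot
  k_ss <- (p$fcat + p$fres * E) / tot
  exchange <- function() {
    new_g <- k_gg * rho_g + k_sg * rho_s
    rho_s <<- k_gs * rho_g + k_ss * rho_s
    rho_g <<- new_g
  }

  # Strang splitting: half exchange, exact advection shifts (with absorption
  # at l = 0), half exchange, then nucleation
  exchange()

  # advection by exact integer-cell shifts; shrinking mass crossing l = 0
  # disappears, except (with centrosomal re-nucleation on) in the x = 0 cell,
  # where it re-enters the growing state at zero length
  rho_g <- cbind(matrix(0, g$nx, a), rho_g[, seq_len(nl - a), drop = FALSE])
  lost <- rowSums(rho_s[, seq_len(min(b, nl)), drop = FALSE]) * g$dx
  rho_s <- cbind(rho_s[, -seq_len(min(b, nl)), drop = FALSE],
                 matrix(0, g$nx, min(b, nl)))
  if (config$centrosome_renucleation) {
    rho_g[1L, 1L] <- rho_g[1L, 1L] + lost[1L] / g$dx
  }

  exchange()

  # nucleation at the plus-end position: newborn mass is compounded over the
  # step (daughters born early keep nucleating, expm1 of the local effective
  # rate; exact for the rescue-free subsystem) and spread over the first
  # shift_g length cells, the growth accumulated between a uniform-in-time
  # birth and the end of the step
  if (nucleation$rate > 0) {
    cg <- cg_profile(rho_g, g)
    q <- q_profile(cg, rho_g, rho_s, g, nucleation, config$clamp_nucleation)
    born <- if (nucleation$mode == "plus_end") {
      # compounding only applies in plus-end mode, where the local effective
      # per-plus-end rate q/Cg is bounded by r; in polymer mode births come
      # from the lattice, not the plus ends, and the plain q*dt is used
      ifelse(cg > 0, cg * expm1(ifelse(cg > 0, q / cg, 0) * g$dt), q * g$dt)
    } else {
      q * g$dt
    }
    dep <- born / g$dx / a
    for (j in seq_len(a)) rho_g[, j] <- rho_g[, j] + dep
  }

  if (min(rho_g) < 0 || min(rho_s) < 0) {
    stop("negative density after step: dt too large for the exchange rates",
         call. = FALSE)
  }
  state$rho_g <- rho_g
  state$rho_s <- rho_s
  state$t <- state$t + g$dt
  state
}

#' Run the deterministic aster simulation
#'
#' Iterates [step_state()] to `t_end`, recording plus-end density snapshots,
#' the front position, and the total microtubule number at every snapshot
#' interval, then fits the front velocity over the last half of the trajectory
#' and classifies the outcome as `stationary` (late-time front speed below
#' 0.5 um/min) or `traveling_wave`.
#'
#' @inheritParams step_state
#' @param grid A [sim_grid()] built for `params`.
#' @return An object of class `aster_sim`: list with `snapshots` (tibble
#'   `t, x, density`), `front` (tibble `t, x_front`), `mass` (tibble
#'   `t, n_microtubules`), `velocity` (tibble from
#'   [estimate_front_velocity()]), `regime`, plus the inputs.
#' @examples
#' \donttest{
#' p <- dynamics_params(30, 40, 3, 1)
#' g <- sim_grid(p, dx = 0.5, x_max = 60, l_max = 60)
#' s <- simulate_aster(p, nucleation_spec("plus_end", 1.0, 0.1), g,
#'                     sim_config(t_end = 5))
#' s$regime
#' }
#' @export
simulate_aster <- function(params, nucleation, grid, config) {
  p <- as_dynamics_params(params)
  stopifnot(inherits(grid, "sim_grid"), inherits(config, "sim_config"),
            inherits(nucleation, "nucleation_spec"))
  state <- initialize_state(grid, config, nucleation$carrying_capacity)
  steps_per_snap <- max(1L, as.integer(round(config$snapshot_every / grid$dt)))
  n_snaps <- as.integer(floor(config$t_end / (steps_per_snap * grid$dt)))

  snap_t <- numeric(n_snaps + 1L)
  snap_cg <- matrix(0, grid$nx, n_snaps + 1L)
  mass <- numeric(n_snaps + 1L)
  snap_cg[, 1L] <- cg_profile(state$rho_g, grid)
  mass[1L] <- sum(state$rho_g + state$rho_s) * grid$dx^2

  # inner loop runs in compiled code (identical algorithm to step_state();
  # their agreement is asserted in the test suite)
  for (i in seq_len(n_snaps)) {
    res <- .run_steps_cpp(
      state$rho_g, state$rho_s, steps_per_snap, grid$dt, grid$dx,
      grid$shift_g, grid$shift_s, p$fcat, p$fres,
      as.integer(nucleation$mode == "plus_end"), nucleation$rate,
      nucleation$carrying_capacity, as.integer(config$clamp_nucleation),
      as.integer(config$centrosome_renucleation)
    )
    state$rho_g <- res$rho_g
    state$rho_s <- res$rho_s
    state$t <- state$t + steps_per_snap * grid$dt
    snap_t[i + 1L] <- state$t
    snap_cg[, i + 1L] <- .cg_profile_cpp(state$rho_g, grid$dx)
    mass[i + 1L] <- sum(state$rho_g + state$rho_s) * grid$dx^2
  }
  if (min(state$rho_g) < -1e-12 || min(state$rho_s) < -1e-12) {
    stop("negative density in simulation: unstable configuration",
         call. = FALSE)
  }

  # one fixed threshold for the whole trace: half the final-profile plateau,
  # falling back to 1% of the carrying capacity when no plateau developed;
  # the centrosomal boundary layer is excluded from the plateau estimate
  # (with re-nucleation on, mass piles up at the origin cell)
  fallback <- 0.01 * nucleation$carrying_capacity
  inner <- grid$x > min(15, 0.2 * grid$x_max)
  plateau <- max(snap_cg[inner, n_snaps + 1L])
  thr <- if (is.finite(fallback) && fallback > 0 && plateau < 2 * fallback) {
    fallback
  } else {
    plateau / 2
  }
  x_front <- vapply(seq_len(n_snaps + 1L), function(i) {
    front_position(grid$x, snap_cg[, i], threshold = thr)
  }, numeric(1))
  front <- tibble::tibble(t = snap_t, x_front = x_front)

  fit <- estimate_front_velocity(front)
  if (any(is.finite(x_front)) &&
      max(x_front, na.rm = TRUE) > 0.95 * grid$x_max) {
    stop("front reached the domain edge inside the fit window; enlarge x_max",
         call. = FALSE)
  }
  regime <- if (is.na(fit$velocity) || abs(fit$velocity) < 0.5) {
    "stationary"
  } else {
    "traveling_wave"
  }

  snapshots <- tibble::tibble(
    t = rep(snap_t, each = grid$nx),
    x = rep(grid$x, n_snaps + 1L),
    density = as.vector(snap_cg)
  )
  structure(list(
    snapshots = snapshots, front = front,
    mass = tibble::tibble(t = snap_t, n_microtubules = mass),
    velocity = fit, regime = regime,
    params = p, nucleation = nucleation, grid = grid, config = config,
    final_state = state
  ), class = "aster_sim")
}

#' @export
print.aster_sim <- function(x, ...) {
  cat("<aster_sim>\n")
  cat(sprintf("  %s regime; fitted front velocity %.3g um/min (RMSE %.3g um)\n",
              x$regime, x$velocity$velocity, x$velocity$rmse))
  cat(sprintf("  grid: dx = %g um, dt = %g min, domain %g x %g um\n",
              x$grid$dx, x$grid$dt, x$grid$x_max, x$grid$l_max))
  cat(sprintf("  final microtubule number: %.4g\n",
              utils::tail(x$mass$n_microtubules, 1)))
  invisible(x)
}

#' Front position of a density profile
#'
#' The outermost position where the profile crosses a threshold, linearly
#' interpolated between grid nodes. The default threshold is half the bulk
#' plateau value (taken as the profile maximum); when the profile has no
#' plateau above `fallback`, `fallback` is used instead (0.01 times the
#' carrying capacity in [simulate_aster()]).
#'
#' @param x Positions, um.
#' @param density Profile values at `x`.
#' @param threshold Crossing threshold; default half the profile maximum.
#' @param fallback Threshold used when the profile maximum is below
#'   `2 * fallback` (no plateau).
#' @return Front position in um, or `NA` if the profile never reaches the
#'   threshold.
#' @export
front_position <- function(x, density, threshold = NULL, fallback = 0) {
  stopifnot(length(x) == length(density))
  peak <- max(density)
  if (is.null(threshold)) {
    threshold <- if (is.finite(fallback) && fallback > 0 &&
                     peak < 2 * fallback) fallback else peak / 2
  }
  if (peak < threshold || threshold <= 0) return(NA_real_)
  above <- which(density >= threshold)
  i <- above[length(above)]
  if (i == length(x)) return(x[i])
  # interpolate down-crossing between node i and i+1
  frac <- (density[i] - threshold) / (density[i] - density[i + 1L])
  x[i] + frac * (x[i + 1L] - x[i])
}

#' Fit the front velocity from a position trace
#'
#' Least-squares slope of front position against time over the last half of
#' the trajectory (the early transient is excluded), with the residual RMSE as
#' a diagnostic. A warning is issued when the trace is non-monotone beyond the
#' fit RMSE.
#'
#' @param trace A data frame with columns `t` (min) and `x_front` (um); `NA`
#'   front positions are dropped.
#' @param fit_fraction Fraction of the trajectory (from the end) used in the
#'   fit.
#' @return A one-row tibble: `velocity` (um/min), `rmse` (um), `t_start`,
#'   `t_end`, `n_points`.
#' @export
estimate_front_velocity <- function(trace, fit_fraction = 0.5) {
  stopifnot(is.data.frame(trace), all(c("t", "x_front") %in% names(trace)))
  tr <- trace[stats::complete.cases(trace[, c("t", "x_front")]), ]
  t0 <- max(tr$t, -Inf) - fit_fraction * (max(tr$t) - min(tr$t))
  tr <- tr[tr$t >= t0, , drop = FALSE]
  if (nrow(tr) < 5L) {
    return(tibble::tibble(velocity = NA_real_, rmse = NA_real_,
                          t_start = NA_real_, t_end = NA_real_,
                          n_points = nrow(tr)))
  }
  fit <- stats::lm(x_front ~ t, data = tr)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  if (any(diff(tr$x_front) < -max(3 * rmse, 1e-9))) {
    warning("front trace is non-monotone beyond the fit residual scale",
            call. = FALSE)
  }
  tibble::tibble(velocity = unname(stats::coef(fit)[2]), rmse = rmse,
                 t_start = min(tr$t), t_end = max(tr$t),
                 n_points = nrow(tr))
}
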