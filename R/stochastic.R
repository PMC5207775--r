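#' Simulate single-microtubule lifetimes
#'
#' Event-driven (exact exponential waiting times) simulation of the two-state
#' model for microtubules born growing at zero length and absorbed when they
#' shrink back to zero length. The sampler is the package's brute-force oracle:
#' the mean `time_growing` must equal `1/rc` and the mean `integrated_length`
#' must equal `1/pc`, the reciprocals of the two critical nucleation rates.
#'
#' Trajectories are piecewise linear, so per-segment statistics (time in state,
#' integrated length) are accumulated exactly; there is no time discretization.
#' In the unbounded regime (`J >= 0`) a finite `max_time` is required and
#' trajectories still alive at the cap are returned with `censored = TRUE`.
#'
#' @param params A [dynamics_params()] object.
#' @param n Number of independent lifetimes.
#' @param seed Integer seed; the same seed reproduces the sample exactly.
#' @param max_time Censoring time in min (`Inf` allowed only when `J < 0`).
#' @return A tibble with one row per microtubule: `lifetime` (min),
#'   `time_growing` (min), `integrated_length` (um*min), `max_plus_end` (um),
#'   `n_catastrophes`, `censored`.
#' @examples
#' x <- simulate_lifetimes(dynamics_params(30, 40, 3, 1), n = 1000, seed = 1)
#' mean(x$time_growing) # about 1/rc = 0.444 min
#' @export
simulate_lifetimes <- function(params, n, seed = NULL, max_time = Inf) {
  p <- as_dynamics_params(params)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (!is.finite(max_time) && net_drift(p) >= 0) {
    stop("J >= 0: absorption is not guaranteed, supply a finite `max_time`",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  # all trajectories advance in lock-step through growth/shrink rounds;
  # each round is fully vectorized over the still-alive subset
  len <- numeric(n)           # current length, um
  lifetime <- numeric(n)
  time_growing <- numeric(n)
  int_len <- numeric(n)
  max_pe <- numeric(n)
  n_cat <- integer(n)
  alive <- rep(TRUE, n)
  censored <- rep(FALSE, n)

  while (any(alive)) {
    idx <- which(alive)
    m <- length(idx)

    # growing segment: Exp(fcat) until catastrophe
    tau <- stats::rexp(m, p$fcat)
    over <- lifetime[idx] + tau > max_time
    tau[over] <- max_time - lifetime[idx][over]
    int_len[idx] <- int_len[idx] + len[idx] * tau + p$vg * tau^2 / 2
    len[idx] <- len[idx] + p$vg * tau
    lifetime[idx] <- lifetime[idx] + tau
    time_growing[idx] <- time_growing[idx] + tau
    max_pe[idx] <- pmax(max_pe[idx], len[idx])
    if (any(over)) {
      censored[idx[over]] <- TRUE
      alive[idx[over]] <- FALSE
      idx <- idx[!over]
      if (!length(idx)) break
    }
    n_cat[idx] <- n_cat[idx] + 1L

    # shrinking segment: Exp(fres) rescue vs first passage to zero length
    m <- length(idx)
    tau_res <- if (p$fres > 0) stats::rexp(m, p$fres) else rep(Inf, m)
    t_hit <- len[idx] / p$vs
    tau <- pmin(tau_res, t_hit)
    over <- lifetime[idx] + tau > max_time
    tau[over] <- max_time - lifetime[idx][over]
    int_len[idx] <- int_len[idx] + len[idx] * tau - p$vs * tau^2 / 2
    len[idx] <- len[idx] - p$vs * tau
    lifetime[idx] <- lifetime[idx] + tau
    if (any(over)) {
      censored[idx[over]] <- TRUE
      alive[idx[over]] <- FALSE
    }
    absorbed <- !over & t_hit <= tau_res
    alive[idx[absorbed]] <- FALSE
    len[idx[absorbed]] <- 0
  }

  tibble::tibble(
    lifetime = lifetime, time_growing = time_growing,
    integrated_length = int_len, max_plus_end = max_pe,
    n_catastrophes = n_cat, censored = censored
  )
}

mc_summary <- function(x, quantity) {
  tibble::tibble(quantity = quantity, mean = mean(x),
                 se = stats::sd(x) / sqrt(length(x)), n = length(x))
}

#' Monte-Carlo mean time in the growing state
#'
#' Estimates the mean total time a microtubule spends growing over its
#' lifetime; the analytic prediction is `1 / critical_nucleation_rate(params)`.
#'
#' @inheritParams simulate_lifetimes
#' @return A one-row tibble: `quantity`, `mean`, `se`, `n`.
#' @export
estimate_growing_time <- function(params, n = 1e5, seed = NULL) {
  s <- simulate_lifetimes(params, n = n, seed = seed)
  mc_summary(s$time_growing, "time_growing")
}

#' Monte-Carlo mean time-integrated length
#'
#' Estimates `E[int l dt]` over one lifetime; the analytic prediction is
#' [expected_integrated_length()], the reciprocal of the critical
#' polymer-stimulated nucleation rate.
#'
#' @inheritParams simulate_lifetimes
#' @return A one-row tibble: `quantity`, `mean`, `se`, `n`.
#' @export
estimate_integrated_length <- function(params, n = 1e5, seed = NULL) {
  s <- simulate_lifetimes(params, n = n, seed = seed)
  mc_summary(s$integrated_length, "integrated_length")
}

# sample event times of an inhomogeneous Poisson process with rate
# rate_per_um * l(t), l(t) = l0 + v*t on [0, tau], by inverting the
# cumulative hazard (quadratic in t; exact, no discretization)
segment_nucleation_times <- function(l0, v, tau, rate_per_um) {
  total <- rate_per_um * (l0 * tau + v * tau^2 / 2)
  if (total <= 0) return(numeric(0))
  k <- stats::rpois(1L, total)
  if (k == 0L) return(numeric(0))
  u <- sort(stats::runif(k)) * (l0 * tau + v * tau^2 / 2)
  if (abs(v) < 1e-12) return(u / l0)
  # solve l0*s + v*s^2/2 = u for s in [0, tau]
  disc <- pmax(l0^2 + 2 * v * u, 0)
  (-l0 + sqrt(disc)) / v
}

#' Simulate a branching microtubule population
#'
#' Event-driven simulation of the autocatalytic branching process: a single
#' founder microtubule is born growing at the origin, and every microtubule
#' nucleates daughters — at rate `r` per growing plus end (plus-end mode) or
#' at rate `p * l(t)` along its length (polymer mode, exact time-inhomogeneous
#' sampling). Daughters are born growing, at zero length, at the mother's
#' current plus-end position, and mother and daughter live and die
#' independently. Saturation is ignored (`K = Inf` behaviour), which makes the
#' population a true branching process whose extinction threshold is the
#' critical nucleation rate.
#'
#' @inheritParams simulate_lifetimes
#' @param nucleation A [nucleation_spec()]; `carrying_capacity` is ignored.
#' @param max_time Simulation horizon, min.
#' @param max_population Cap on the number of microtubules ever created; runs
#'   hitting the cap are flagged `censored = TRUE` (supercritical explosion).
#' @param n_replicates Number of independent replicates.
#' @param sample_every Spacing of the recorded population/rightmost-end time
#'   grid, min.
#' @param seed Integer seed; replicate `i` uses stream `seed + i`.
#' @return A tibble with one row per replicate: `replicate`, `extinct`,
#'   `censored`, `n_created`, `extinction_time` (NA if not extinct) and a
#'   list-column `trace` of tibbles `(t, population, rightmost)` where
#'   `rightmost` is the largest plus-end position among microtubules alive at
#'   `t` (NA when none).
#' @examples
#' p <- dynamics_params(30, 40, 3, 1)
#' b <- simulate_branching(p, nucleation_spec("plus_end", 1.0), max_time = 20,
#'                         n_replicates = 5, seed = 1)
#' b$extinct
#' @export
simulate_branching <- function(params, nucleation, max_time = 50,
                               max_population = 1000, n_replicates = 1,
                               sample_every = 0.5, seed = NULL) {
  p <- as_dynamics_params(params)
  stopifnot(inherits(nucleation, "nucleation_spec"),
            max_time > 0, max_population >= 1, n_replicates >= 1)
  base_seed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1L) else seed

  purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
    set.seed((base_seed + rep_i) %% .Machine$integer.max)
    one_branching_replicate(p, nucleation, max_time, max_population,
                            sample_every, rep_i)
  })
}

one_branching_replicate <- function(p, nucleation, max_time, max_population,
                                    sample_every, rep_i) {
  t_grid <- seq(0, max_time, by = sample_every)
  ng <- length(t_grid)
  pop <- integer(ng)
  rightmost <- rep(-Inf, ng)

  # stack of microtubules awaiting simulation: birth time, minus-end position
  stack_t <- 0
  stack_x <- 0
  n_created <- 1L
  censored <- FALSE
  last_death <- 0

  plus_end_mode <- nucleation$mode == "plus_end"
  rate <- nucleation$rate

  while (length(stack_t) > 0) {
    t0 <- stack_t[1]; x0 <- stack_x[1]
    stack_t <- stack_t[-1]; stack_x <- stack_x[-1]

    # simulate this microtubule's full piecewise-linear path from birth
    t_cur <- t0; len <- 0; growing <- TRUE
    seg_t0 <- numeric(0); seg_l0 <- numeric(0); seg_v <- numeric(0)
    seg_tau <- numeric(0)
    repeat {
      if (t_cur >= max_time) break
      if (growing) {
        tau <- stats::rexp(1L, p$fcat)
      } else {
        tau_res <- if (p$fres > 0) stats::rexp(1L, p$fres) else Inf
        t_hit <- len / p$vs
        tau <- min(tau_res, t_hit)
      }
      tau <- min(tau, max_time - t_cur)
      v <- if (growing) p$vg else -p$vs
      seg_t0 <- c(seg_t0, t_cur); seg_l0 <- c(seg_l0, len)
      seg_v <- c(seg_v, v); seg_tau <- c(seg_tau, tau)

      # nucleation events along this segment
      if (rate > 0) {
        times <- if (plus_end_mode) {
          if (growing) {
            k <- stats::rpois(1L, rate * tau)
            if (k > 0) sort(stats::runif(k)) * tau else numeric(0)
          } else numeric(0)
        } else {
          segment_nucleation_times(len, v, tau, rate)
        }
        if (length(times) > 0) {
          keep <- seq_len(min(length(times), max_population - n_created))
          if (length(keep) < length(times)) censored <- TRUE
          if (length(keep) > 0) {
            times <- times[keep]
            stack_t <- c(stack_t, t_cur + times)
            stack_x <- c(stack_x, x0 + len + v * times)
            n_created <- n_created + length(times)
          }
        }
      }

      len <- len + v * tau
      t_cur <- t_cur + tau
      if (!growing && len <= 1e-12) { len <- 0; break }  # absorbed
      growing <- !growing
    }
    death <- t_cur
    last_death <- max(last_death, death)

    # fold this microtubule into the sampled population / rightmost traces
    in_life <- t_grid >= t0 & t_grid <= death
    if (any(in_life)) {
      pop[in_life] <- pop[in_life] + 1L
      tg <- t_grid[in_life]
      plus_end <- x0 + vapply(tg, function(tt) {
        i <- findInterval(tt, seg_t0)
        if (i == 0L) 0 else seg_l0[i] + seg_v[i] * min(tt - seg_t0[i], seg_tau[i])
      }, numeric(1))
      rightmost[in_life] <- pmax(rightmost[in_life], plus_end)
    }
    if (censored && n_created >= max_population && length(stack_t) == 0) break
  }

  extinct <- !censored && last_death < max_time
  tibble::tibble(
    replicate = rep_i, extinct = extinct, censored = censored,
    n_created = n_created,
    extinction_time = if (extinct) last_death else NA_real_,
    trace = list(tibble::tibble(
      t = t_grid, population = pop,
      rightmost = ifelse(is.finite(rightmost), rightmost, NA_real_)
    ))
  )
}

#' Survival probability of the branching process
#'
#' Fraction of replicates whose microtubule population has not gone extinct by
#' `max_time`, with a binomial (Wilson) confidence interval. As `max_time`
#' grows this crosses zero exactly at the critical nucleation rate, providing
#' a simulation-based locator of the growth threshold.
#'
#' @inheritParams simulate_branching
#' @param r Plus-end nucleation rate, 1/min.
#' @param conf_level Confidence level of the interval.
#' @return A one-row tibble: `r`, `estimate`, `lower`, `upper`,
#'   `n_replicates`, `n_censored`.
#' @export
survival_probability <- function(params, r, max_time = 50,
                                 max_population = 1000, n_replicates = 100,
                                 seed = NULL, conf_level = 0.95) {
  stopifnot(is.numeric(r), length(r) == 1L, r >= 0)
  if (r == 0) {
    return(tibble::tibble(r = 0, estimate = 0, lower = 0, upper = 0,
                          n_replicates = as.integer(n_replicates),
                          n_censored = 0L))
  }
  b <- simulate_branching(params, nucleation_spec("plus_end", r),
                          max_time = max_time,
                          max_population = max_population,
                          n_replicates = n_replicates,
                          sample_every = max_time, seed = seed)
  k <- sum(!b$extinct)
  n <- nrow(b)
  ci <- stats::prop.test(k, n, conf.level = conf_level, correct = TRUE)$conf.int
  tibble::tibble(r = r, estimate = k / n, lower = ci[1], upper = ci[2],
                 n_replicates = n, n_censored = sum(b$censored))
}
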