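#' Synthetic plus-end comet lifetimes
#'
#' Generates exponential comet (growing plus-end) lifetimes at catastrophe
#' rate `fcat` and quantizes them to the imaging frame interval, emulating
#' tracked fluorescent plus-end marker data (default 2 s frames). Tracks must
#' span at least one frame, so durations are rounded up to a multiple of the
#' interval.
#'
#' @param fcat Catastrophe rate, 1/min.
#' @param n Number of tracks.
#' @param frame_interval Imaging interval, seconds.
#' @param seed Integer seed for reproducibility.
#' @return A tibble with columns `track` and `duration` (seconds, quantized),
#'   carrying the frame interval as attribute `frame_interval`.
#' @examples
#' x <- synth_comet_lifetimes(3.3, n = 1000, seed = 1)
#' mean(x$duration) # about 60/3.3 s plus half-frame quantization
#' @export
synth_comet_lifetimes <- function(fcat, n, frame_interval = 2, seed = NULL) {
  stopifnot(fcat > 0, n >= 0, frame_interval > 0)
  if (!is.null(seed)) set.seed(seed)
  raw <- stats::rexp(n, rate = fcat / 60)  # seconds
  out <- tibble::tibble(
    track = seq_len(n),
    duration = ceiling(raw / frame_interval) * frame_interval
  )
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Fit the catastrophe rate from comet lifetimes
#'
#' Estimates the catastrophe rate as the decay rate of the comet-lifetime
#' distribution. The default `"semilog"` method bins durations at the frame
#' interval and fits a straight line to the log of the counts inside the fit
#' window (default 5-60 s), so early tracking artefacts and the censored tail
#' are excluded; the standard error comes from bootstrap resampling of tracks.
#' The `"mle"` alternative is the discretization-aware maximum-likelihood
#' estimate for frame-quantized exponential data,
#' `lambda = log(mean(d) / (mean(d) - delta)) / delta`; on clean exponential
#' data the two agree within their standard errors.
#'
#' @param lifetimes A data frame with a `duration` column in seconds (e.g.
#'   from [synth_comet_lifetimes()]).
#' @param window Fit window in seconds, default `c(5, 60)`.
#' @param method `"semilog"` (binned log-linear fit) or `"mle"`.
#' @param n_boot Bootstrap replicates for the standard error.
#' @param frame_interval Bin width in seconds; defaults to the attribute set
#'   by the generator, else 2 s.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `catastrophe_fit`; [tidy()] returns the
#'   estimate, [glance()] the fit summary.
#' @examples
#' x <- synth_comet_lifetimes(3.3, n = 3000, seed = 1)
#' fit <- fit_catastrophe_rate(x, seed = 2)
#' glance(fit)
#' @export
fit_catastrophe_rate <- function(lifetimes, window = c(5, 60),
                                 method = c("semilog", "mle"), n_boot = 200,
                                 frame_interval = NULL, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(lifetimes), "duration" %in% names(lifetimes),
            length(window) == 2L, window[1] < window[2])
  d <- lifetimes$duration
  if (is.null(frame_interval)) {
    frame_interval <- attr(lifetimes, "frame_interval") %||% 2
  }
  in_window <- d >= window[1] & d <= window[2]
  if (sum(in_window) < 50L) {
    stop("fewer than 50 tracks inside the fit window", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  est_fun <- if (method == "semilog") {
    function(x) semilog_rate(x, window, frame_interval)
  } else {
    function(x) mle_rate(x, frame_interval)
  }
  fcat <- est_fun(d)
  boot <- vapply(seq_len(n_boot), function(i) {
    est_fun(d[sample.int(length(d), replace = TRUE)])
  }, numeric(1))
  se <- stats::sd(boot, na.rm = TRUE)

  structure(list(
    fcat = fcat, se = se, method = method, window = window,
    n_tracks = length(d), n_in_window = sum(in_window),
    frame_interval = frame_interval, n_boot = n_boot
  ), class = "catastrophe_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# slope of log-counts vs bin center inside the window, converted to 1/min
semilog_rate <- function(d, window, delta) {
  breaks <- seq(0, max(d) + delta, by = delta)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  keep <- h$mids >= window[1] & h$mids <= window[2] & h$counts > 0
  if (sum(keep) < 3L) return(NA_real_)
  fit <- stats::lm(log(h$counts[keep]) ~ h$mids[keep])
  -unname(stats::coef(fit)[2]) * 60
}

# MLE for exponential durations quantized upward to multiples of delta
# (geometric in the frame count): lambda = log(mean/(mean - delta))/delta
mle_rate <- function(d, delta) {
  m <- mean(d)
  if (m <= delta) return(NA_real_)
  log(m / (m - delta)) / delta * 60
}

#' @export
print.catastrophe_fit <- function(x, ...) {
  cat(sprintf(
    "<catastrophe_fit> fcat = %.3g +/- %.2g /min (%s, window %g-%g s, n = %d)\n",
    x$fcat, x$se, x$method, x$window[1], x$window[2], x$n_tracks))
  invisible(x)
}

#' @rdname fit_catastrophe_rate
#' @param x A `catastrophe_fit` object.
#' @param ... Unused.
#' @method tidy catastrophe_fit
#' @export
tidy.catastrophe_fit <- function(x, ...) {
  tibble::tibble(term = "fcat", estimate = x$fcat, std.error = x$se,
                 units = "1/min")
}

#' @rdname fit_catastrophe_rate
#' @method glance catastrophe_fit
#' @export
glance.catastrophe_fit <- function(x, ...) {
  tibble::tibble(fcat = x$fcat, se = x$se, method = x$method,
                 window_lo = x$window[1], window_hi = x$window[2],
                 n_tracks = x$n_tracks, n_in_window = x$n_in_window)
}

#' Polymerization speed from plus-end track displacements
#'
#' Per-track speeds (displacement over duration) and their summary; the mean
#' is the `vg` input of the inference pipeline.
#'
#' @param tracks A data frame with columns `displacement` (um) and `duration`
#'   (seconds); zero- or negative-duration tracks are rejected.
#' @return A list with `tracks` (tibble with per-track `speed`, um/min) and
#'   `summary` (one-row tibble: `vg`, `sd`, `se`, `n`).
#' @examples
#' tr <- tibble::tibble(displacement = c(1, 1, 1), duration = c(2, 2, 2))
#' estimate_polymerization_rate(tr)$summary$vg # 30 um/min
#' @export
estimate_polymerization_rate <- function(tracks) {
  stopifnot(is.data.frame(tracks),
            all(c("displacement", "duration") %in% names(tracks)))
  if (nrow(tracks) == 0L) stop("no tracks supplied", call. = FALSE)
  if (any(tracks$duration <= 0)) {
    stop("zero-duration tracks are not allowed", call. = FALSE)
  }
  speed <- tracks$displacement / tracks$duration * 60
  list(
    tracks = tibble::tibble(speed = speed),
    summary = tibble::tibble(
      vg = mean(speed), sd = stats::sd(speed),
      se = stats::sd(speed) / sqrt(length(speed)), n = length(speed)
    )
  )
}

#' Synthetic aster intensity-profile time series
#'
#' Emulates 1-D fluorescence intensity profiles of a growing aster: a
#' sigmoidal edge of width `edge_width` on a plateau, translating outward at
#' constant speed `v`, sampled on a fixed spatial axis at the stated times
#' (default every 2 min) with additive Gaussian noise.
#'
#' @param v True front velocity, um/min (>= 0).
#' @param times Sampling times, min.
#' @param plateau Plateau intensity (arbitrary units).
#' @param edge_width Sigmoid width parameter, um.
#' @param noise_sd Additive noise standard deviation (intensity units).
#' @param r0 Edge position at `t = 0`, um.
#' @param x_max,dx Spatial axis extent and sampling, um.
#' @param seed Integer seed.
#' @return A tibble with columns `t` (min), `x` (um), `intensity`.
#' @export
synth_aster_profiles <- function(v, times = seq(0, 20, by = 2), plateau = 1,
                                 edge_width = 10, noise_sd = 0.05, r0 = 50,
                                 x_max = NULL, dx = 1, seed = NULL) {
  stopifnot(v >= 0, length(times) >= 2L, plateau > 0, edge_width > 0,
            noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x_max)) x_max <- r0 + v * max(times) + 10 * edge_width
  x <- seq(0, x_max, by = dx)
  purrr::map_dfr(times, function(tt) {
    edge <- r0 + v * tt
    tibble::tibble(
      t = tt, x = x,
      intensity = plateau / (1 + exp((x - edge) / edge_width)) +
        stats::rnorm(length(x), sd = noise_sd)
    )
  })
}

#' Aster radius from one intensity profile
#'
#' The imaging analogue of [front_position()]: the profile is low-pass
#' filtered (centered moving average of configurable width) and the outermost
#' half-maximum crossing, linearly interpolated, is reported as the aster
#' edge.
#'
#' @param profile A data frame with columns `x` (um) and `intensity`, one time
#'   point.
#' @param smooth_width Moving-average window, in number of samples (odd;
#'   even values are incremented).
#' @param background Baseline intensity subtracted before the half-max rule.
#' @return Radius in um, or `NA` if the profile never rises above background
#'   (no edge).
#' @export
extract_radius <- function(profile, smooth_width = 9, background = 0) {
  stopifnot(is.data.frame(profile), all(c("x", "intensity") %in% names(profile)))
  raw <- profile$intensity - background
  y <- raw
  k <- 1L
  if (smooth_width > 1) {
    k <- as.integer(smooth_width)
    if (k %% 2L == 0L) k <- k + 1L
    kern <- rep(1 / k, k)
    y <- as.vector(stats::filter(y, kern, sides = 2))
    # shrink the window at the edges instead of dropping them
    n <- length(y)
    half <- (k - 1L) %/% 2L
    for (i in which(is.na(y))) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      y[i] <- mean(raw[lo:hi])
    }
  }
  peak <- max(y)
  # flat / all-background detection: compare the smoothed peak to the
  # smoothed noise scale (robust sd of raw first differences, reduced by the
  # averaging window)
  noise <- stats::mad(diff(raw)) / sqrt(2) / sqrt(k)
  if (peak <= max(4 * noise, 1e-12)) return(NA_real_)
  front_position(profile$x, y, threshold = peak / 2)
}

#' Aster radius time series from profile stacks
#'
#' Applies [extract_radius()] to each time point of an intensity-profile
#' series.
#'
#' @param profiles A data frame with columns `t`, `x`, `intensity` (e.g. from
#'   [synth_aster_profiles()]).
#' @inheritParams extract_radius
#' @return A tibble with columns `t` (min) and `radius` (um).
#' @export
aster_radius_series <- function(profiles, smooth_width = 9, background = 0) {
  stopifnot(is.data.frame(profiles),
            all(c("t", "x", "intensity") %in% names(profiles)))
  profiles |>
    dplyr::group_by(.data$t) |>
    dplyr::group_modify(~ tibble::tibble(
      radius = extract_radius(.x, smooth_width, background)
    )) |>
    dplyr::ungroup()
}

#' Aster velocity from a radius time series
#'
#' Least-squares slope of radius against time, the operational definition of
#' the aster velocity `V = dR/dt`. Series whose fitted slope magnitude falls
#' below `zero_threshold` are scored as non-growing (`velocity = 0`), matching
#' how stationary or shrinking asters are scored as zero growth velocity.
#'
#' @param radii A data frame with columns `t` (min) and `radius` (um); at
#'   least 3 valid points.
#' @param zero_threshold Speed below which the aster is scored stationary,
#'   um/min.
#' @return An object of class `front_fit`; [tidy()]/[glance()] return the
#'   fitted velocity (um/min), its standard error, and the fit RMSE (um).
#' @examples
#' r <- tibble::tibble(t = 0:5, radius = 50 + 20.3 * (0:5))
#' glance(velocity_from_radii(r))$velocity # 20.3
#' @export
velocity_from_radii <- function(radii, zero_threshold = 0.5) {
  stopifnot(is.data.frame(radii), all(c("t", "radius") %in% names(radii)))
  ok <- stats::complete.cases(radii[, c("t", "radius")])
  if (sum(ok) < 3L) stop("need at least 3 valid radii", call. = FALSE)
  d <- radii[ok, ]
  fit <- stats::lm(radius ~ t, data = d)
  slope <- unname(stats::coef(fit)[2])
  # vcov warns on exactly collinear (noise-free) input; the SE is still valid
  se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  scored <- if (abs(slope) < zero_threshold) 0 else slope
  structure(list(
    velocity = scored, slope = slope, se = se, rmse = rmse,
    n = nrow(d), zero_threshold = zero_threshold, data = tibble::as_tibble(d)
  ), class = "front_fit")
}

#' @export
print.front_fit <- function(x, ...) {
  cat(sprintf("<front_fit> V = %.3g um/min (raw slope %.3g +/- %.2g, RMSE %.3g um, n = %d)\n",
              x$velocity, x$slope, x$se, x$rmse, x$n))
  invisible(x)
}

#' @rdname velocity_from_radii
#' @param x A `front_fit` object.
#' @param ... Unused.
#' @method tidy front_fit
#' @export
tidy.front_fit <- function(x, ...) {
  tibble::tibble(term = "velocity", estimate = x$velocity,
                 std.error = x$se, units = "um/min")
}

#' @rdname velocity_from_radii
#' @method glance front_fit
#' @export
glance.front_fit <- function(x, ...) {
  tibble::tibble(velocity = x$velocity, slope = x$slope, se = x$se,
                 rmse = x$rmse, n = x$n)
}
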