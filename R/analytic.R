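#' Net drift of a long microtubule
#'
#' Time-weighted average of the polymerization and depolymerization speeds,
#' \deqn{J = \frac{v_g f_{res} - v_s f_{cat}}{f_{res} + f_{cat}},}
#' the mean elongation rate of a microtubule that persists over many
#' catastrophe/rescue cycles. `J < 0` is the bounded regime (every microtubule
#' eventually shrinks to zero length and disappears); `J > 0` is unbounded.
#'
#' @param params A [dynamics_params()] object.
#' @return Net drift in um/min.
#' @examples
#' net_drift(dynamics_params(30, 42, 3.3, 2.0))
#' @export
net_drift <- function(params) {
  p <- as_dynamics_params(params)
  (p$vg * p$fres - p$vs * p$fcat) / (p$fres + p$fcat)
}

#' Critical plus-end nucleation rate
#'
#' The minimum plus-end-stimulated nucleation rate that sustains collective
#' aster growth in the bounded regime,
#' \deqn{r_c = f_{cat} - \frac{v_g}{v_s} f_{res},}
#' whose reciprocal is the mean time a microtubule spends in the growing state
#' over its lifetime: growth requires each microtubule to nucleate on average
#' at least one daughter before it disappears. Returns 0 when the drift
#' `J >= 0` (no threshold in the unbounded regime).
#'
#' @inheritParams net_drift
#' @return Critical rate in 1/min.
#' @examples
#' critical_nucleation_rate(dynamics_params(30, 40, 3, 1)) # 2.25
#' @export
critical_nucleation_rate <- function(params) {
  p <- as_dynamics_params(params)
  rc <- p$fcat - (p$vg / p$vs) * p$fres
  max(rc, 0)
}

#' Aster growth velocity under collective growth
#'
#' Closed-form front speed of the growing aster for plus-end-stimulated
#' nucleation rate `r` in the validity window `rc < r < fcat`:
#' \deqn{V = \frac{v_g (v_g f_{res} - v_s f_{cat})^2}{
#'   v_g (v_g f_{res} - v_s f_{cat})(f_{res}+f_{cat})
#'   + (v_g+v_s)(v_g f_{res} + v_s f_{cat})\, r
#'   - 2 (v_g+v_s)\sqrt{v_g f_{cat} f_{res}\, r\,
#'       (v_g f_{res} - v_s f_{cat} + v_s r)}}.}
#' Outside the window the formula is not extrapolated: values are `NA` with a
#' warning (`"below critical nucleation"` for `r <= rc`, `"outside analytic
#' validity"` for `r >= fcat`); callers needing those regimes fall back on the
#' numerical solver [simulate_aster()].
#'
#' @inheritParams net_drift
#' @param r Plus-end nucleation rate(s), 1/min. Vectorized.
#' @return Velocity in um/min, `NA` where `r` lies outside `(rc, fcat)`.
#' @seealso [gap_velocity()] for the limit `r -> rc`; [classify_regime()].
#' @examples
#' p <- dynamics_params(30, 42, 3.3, 2.0)
#' aster_velocity(p, 2.1)
#' @export
aster_velocity <- function(params, r) {
  p <- as_dynamics_params(params)
  stopifnot(is.numeric(r), all(is.finite(r)))
  rc <- critical_nucleation_rate(p)
  out <- rep(NA_real_, length(r))
  # at fres = 0 the validity window (rc, fcat) is empty (rc = fcat); the
  # boundary point r = fcat is kept by continuity, where V = vg exactly
  ok <- (r > rc & r < p$fcat) | (p$fres == 0 & r == p$fcat)
  if (any(r <= rc & !ok)) {
    warning("below critical nucleation: r <= rc, returning NA", call. = FALSE)
  }
  if (any(r >= p$fcat & !ok)) {
    warning("outside analytic validity: r >= fcat, returning NA", call. = FALSE)
  }
  if (any(ok)) {
    rr <- r[ok]
    a <- p$vg * p$fres - p$vs * p$fcat
    num <- p$vg * a^2
    den <- p$vg * a * (p$fres + p$fcat) +
      (p$vg + p$vs) * (p$vg * p$fres + p$vs * p$fcat) * rr -
      2 * (p$vg + p$vs) * sqrt(p$vg * p$fcat * p$fres * rr * (a + p$vs * rr))
    out[ok] <- num / den
  }
  out
}

#' Gap velocity at the growth transition
#'
#' The limit of the aster velocity as the nucleation rate approaches the
#' critical rate from above,
#' \deqn{V_{gap} = -\frac{v_g v_s (v_g f_{res} - v_s f_{cat})}{
#'   v_g^2 f_{res} + v_s^2 f_{cat}},}
#' a strictly positive speed in `(0, vg]`: the transition from stationary to
#' growing asters is explosive, with no velocities between 0 and `Vgap`.
#' Equals `vg` when `fres = 0`. Defined only in the bounded regime (`J < 0`);
#' otherwise `NA` with a warning.
#'
#' @inheritParams net_drift
#' @return Gap velocity in um/min.
#' @examples
#' gap_velocity(dynamics_params(30, 42, 3.3, 2.0))
#' @export
gap_velocity <- function(params) {
  p <- as_dynamics_params(params)
  if (net_drift(p) >= 0) {
    warning("gap velocity is defined only for J < 0 (bounded regime)",
            call. = FALSE)
    return(NA_real_)
  }
  -p$vg * p$vs * (p$vg * p$fres - p$vs * p$fcat) /
    (p$vg^2 * p$fres + p$vs^2 * p$fcat)
}

#' Mean steady-state microtubule length
#'
#' Mean of the exponential steady-state length distribution of the two-state
#' model in the bounded regime,
#' \deqn{\langle l \rangle = \frac{v_g v_s}{v_s f_{cat} - v_g f_{res}}
#'   = v_g / r_c.}
#' Diverges as `J -> 0` from below; `Inf` with a warning when
#' `vs*fcat <= vg*fres`.
#'
#' @inheritParams net_drift
#' @return Mean length in um.
#' @examples
#' mean_mt_length(dynamics_params(30, 42, 3.3, 2.0)) # about 16 um
#' @export
mean_mt_length <- function(params) {
  p <- as_dynamics_params(params)
  den <- p$vs * p$fcat - p$vg * p$fres
  if (den <= 0) {
    warning("mean length diverges: vs*fcat <= vg*fres (unbounded regime)",
            call. = FALSE)
    return(Inf)
  }
  p$vg * p$vs / den
}

#' Expected time-integrated length over one microtubule lifetime
#'
#' For a microtubule born growing at zero length and absorbed when it shrinks
#' back to zero length, the expectation of \eqn{\int l(t)\,dt} over its
#' lifetime. From the quadratic-ansatz solution of the coupled backward
#' equations,
#' \deqn{E\!\left[\int l\,dt\right] =
#'   \frac{v_g v_s (v_g + v_s)}{(v_s f_{cat} - v_g f_{res})^2}.}
#' This is the first-passage quantity underlying the polymer-stimulated
#' critical nucleation rate: at rate `p` per um per min, a microtubule
#' nucleates on average `p * E[int l dt]` daughters over its lifetime.
#'
#' @inheritParams net_drift
#' @return Expected integrated length in um*min; `Inf` with a warning in the
#'   unbounded regime.
#' @seealso [polymer_critical_rate()], [estimate_integrated_length()] for the
#'   Monte-Carlo cross-check.
#' @examples
#' expected_integrated_length(dynamics_params(30, 40, 3, 1)) # 10.37
#' @export
expected_integrated_length <- function(params) {
  p <- as_dynamics_params(params)
  den <- p$vs * p$fcat - p$vg * p$fres
  if (den <= 0) {
    warning("integrated length diverges: vs*fcat <= vg*fres", call. = FALSE)
    return(Inf)
  }
  p$vg * p$vs * (p$vg + p$vs) / den^2
}

#' Critical polymer-stimulated nucleation rate
#'
#' The threshold rate per micrometre of polymer at which each microtubule,
#' nucleating along its whole length, produces on average exactly one daughter
#' per lifetime:
#' \deqn{p_c = \frac{1}{E[\int l\,dt]} =
#'   \frac{(v_s f_{cat} - v_g f_{res})^2}{v_g v_s (v_g + v_s)}.}
#' Returns 0 (with a warning) when `J >= 0`: no threshold in the unbounded
#' regime.
#'
#' @inheritParams net_drift
#' @return Critical rate in 1/(um min).
#' @examples
#' polymer_critical_rate(dynamics_params(30, 40, 3, 1)) # 0.0964
#' @export
polymer_critical_rate <- function(params) {
  p <- as_dynamics_params(params)
  den <- p$vs * p$fcat - p$vg * p$fres
  if (den <= 0) {
    warning("no polymer nucleation threshold in the unbounded regime",
            call. = FALSE)
    return(0)
  }
  den^2 / (p$vg * p$vs * (p$vg + p$vs))
}

#' Bulk growing plus-end density inside the aster
#'
#' Fixed point of the logistic nucleation term at which each microtubule
#' produces exactly one daughter per lifetime:
#' \deqn{C_g^{bulk} = K (1 - r_c / r),}
#' proportional to `r - rc` near the transition, approaching the carrying
#' capacity `K` as `r` grows. Returns 0 for `r <= rc`.
#'
#' @inheritParams net_drift
#' @param r Plus-end nucleation rate, 1/min.
#' @param K Carrying capacity; the result is in the same density units as `K`.
#' @return Bulk density in units of `K`.
#' @examples
#' bulk_plus_end_density(dynamics_params(30, 42, 3.3, 2.0), r = 2.1, K = 0.4)
#' @export
bulk_plus_end_density <- function(params, r, K) {
  p <- as_dynamics_params(params)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(K), length(K) == 1L, K > 0)
  rc <- critical_nucleation_rate(p)
  if (r <= rc) return(0)
  K * (1 - rc / r)
}

#' Classify the aster growth regime
#'
#' Places a parameter set on the phase diagram spanned by the net drift `J`
#' and the nucleation rate, and reports the predicted aster velocity:
#' * `stationary` — `J < 0` and nucleation below the critical rate; `V = 0`.
#' * `collective_growth` — nucleation above the critical rate; aster expands
#'   as a traveling wave of short microtubules (`V` from the analytic formula
#'   when `rate < fcat`, otherwise flagged for simulation fallback).
#' * `individual_growth` — `J > 0` with no nucleation; the aster dilutes as it
#'   expands at `V = J`.
#'
#' With `J > 0` and nucleation on, growth is reported as collective-type with
#' `V > J`. A rate exactly at the critical value is flagged `"at_transition"`
#' with `V = Vgap`.
#'
#' @inheritParams net_drift
#' @param nucleation A [nucleation_spec()].
#' @return A one-row tibble (class `regime_report`) with columns `regime`,
#'   `J`, `critical_rate`, `rate`, `mode`, `v_gap`, `V`, `note`.
#' @examples
#' p <- dynamics_params(30, 40, 3, 1)
#' classify_regime(p, nucleation_spec("plus_end", 2.5, 0.1))
#' @export
classify_regime <- function(params, nucleation) {
  p <- as_dynamics_params(params)
  stopifnot(inherits(nucleation, "nucleation_spec"))
  J <- net_drift(p)
  crit <- if (nucleation$mode == "plus_end") {
    critical_nucleation_rate(p)
  } else {
    if (J < 0) polymer_critical_rate(p) else 0
  }
  vgap <- if (J < 0) gap_velocity(p) else NA_real_
  rate <- nucleation$rate
  note <- ""

  if (rate == 0) {
    if (J > 0) {
      regime <- "individual_growth"; V <- J
    } else {
      regime <- "stationary"; V <- 0
    }
  } else if (J >= 0) {
    regime <- "collective_growth"; V <- NA_real_
    note <- "J >= 0 with nucleation: V > J, outside analytic validity; use simulate_aster()"
  } else if (rate < crit) {
    regime <- "stationary"; V <- 0
  } else if (rate == crit) {
    regime <- "collective_growth"; V <- vgap
    note <- "at_transition: rate equals critical rate, V = Vgap"
  } else {
    regime <- "collective_growth"
    if (nucleation$mode == "plus_end" && rate < p$fcat) {
      V <- aster_velocity(p, rate)
    } else {
      V <- NA_real_
      note <- if (nucleation$mode == "plus_end") {
        "rate >= fcat: outside analytic validity; use simulate_aster()"
      } else {
        "polymer mode: no closed-form V; use simulate_aster()"
      }
    }
  }

  out <- tibble::tibble(
    regime = regime, J = J, critical_rate = crit, rate = rate,
    mode = nucleation$mode, v_gap = vgap, V = V, note = note
  )
  class(out) <- c("regime_report", class(out))
  out
}
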