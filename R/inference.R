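#' Rescue rate from the measured gap velocity
#'
#' Inverts the gap-velocity formula for `fres` given the directly measurable
#' plus-end parameters and the gap velocity (the slowest observed growth speed
#' at the transition):
#' \deqn{f_{res} = \frac{v_s^2 f_{cat} (v_g - V_{gap})}{v_g^2 (v_s + V_{gap})}.}
#' The inversion is exact (linear in `fres`) and round-trips through
#' [gap_velocity()] to machine precision. Feasible only for
#' `0 < Vgap < vg`: the gap velocity is capped at `vg` (reached at `fres = 0`).
#'
#' @param vg,vs Polymerization and depolymerization speeds, um/min.
#' @param fcat Catastrophe rate, 1/min.
#' @param v_gap Measured gap velocity, um/min.
#' @return Rescue rate in 1/min.
#' @examples
#' infer_rescue_from_gap(30, 42, 3.3, 12.8) # about 2.0
#' @export
infer_rescue_from_gap <- function(vg, vs, fcat, v_gap) {
  check_number(vg, "vg", strict = TRUE)
  check_number(vs, "vs", strict = TRUE)
  check_number(fcat, "fcat", strict = TRUE)
  if (!is.numeric(v_gap) || length(v_gap) != 1L || !is.finite(v_gap) ||
      v_gap <= 0) {
    stop("`v_gap` must be a single number > 0", call. = FALSE)
  }
  if (v_gap >= vg) {
    if (v_gap == vg) return(0)
    stop("infeasible measurement: v_gap exceeds vg (gap velocity is capped at vg)",
         call. = FALSE)
  }
  vs^2 * fcat * (vg - v_gap) / (vg^2 * (vs + v_gap))
}

#' Nucleation rate from the measured aster velocity
#'
#' Solves the analytic aster-velocity formula for the plus-end nucleation rate
#' `r` given a measured velocity `V`, by bisection on `(rc, fcat)` — valid
#' because `V` is strictly increasing in `r` there, and robust against the
#' square-root singularity at `r = rc`. Velocities below the gap velocity are
#' refused: the model admits no asters growing at speeds between 0 and `Vgap`.
#'
#' @param params A [dynamics_params()] object (with the inferred or measured
#'   rescue rate).
#' @param v Measured aster velocity, um/min.
#' @param tol Absolute tolerance on `r`, 1/min.
#' @return Nucleation rate in 1/min.
#' @examples
#' fres <- infer_rescue_from_gap(30, 42, 3.3, 12.8)
#' p <- dynamics_params(30, 42, 3.3, fres)
#' infer_nucleation_from_velocity(p, 22.3) # about 2.1
#' @export
infer_nucleation_from_velocity <- function(params, v, tol = 1e-8) {
  p <- as_dynamics_params(params)
  if (net_drift(p) >= 0) {
    stop("inversion requires the bounded regime (J < 0)", call. = FALSE)
  }
  vgap <- gap_velocity(p)
  if (v < vgap) {
    stop(sprintf(
      "no growing solution: V = %.4g um/min is below the gap velocity %.4g um/min",
      v, vgap), call. = FALSE)
  }
  rc <- critical_nucleation_rate(p)
  if (v == vgap) return(rc)
  lo <- rc * (1 + 1e-9)
  hi <- p$fcat * (1 - 1e-9)
  v_hi <- suppressWarnings(aster_velocity(p, hi))
  if (v > v_hi) {
    stop(sprintf(
      "V = %.4g um/min exceeds the analytic-formula maximum %.4g um/min at r -> fcat (outside validity)",
      v, v_hi), call. = FALSE)
  }
  stats::uniroot(function(r) aster_velocity(p, r) - v, c(lo, hi),
                 tol = tol)$root
}

#' Carrying capacity from the measured bulk plus-end density
#'
#' Algebraic inverse of [bulk_plus_end_density()]:
#' \deqn{K = C_g^{bulk} \frac{r}{r - r_c}.}
#' Marked approximate: the logistic fixed point reproduces the measured bulk
#' density only to tens of percent, so the recovered `K` is an
#' order-of-magnitude estimate.
#'
#' @inheritParams infer_nucleation_from_velocity
#' @param r Nucleation rate, 1/min; must exceed the critical rate.
#' @param cg_bulk Measured bulk growing plus-end density (e.g. per um^2).
#' @return Carrying capacity in the units of `cg_bulk`.
#' @export
infer_carrying_capacity <- function(params, r, cg_bulk) {
  p <- as_dynamics_params(params)
  rc <- critical_nucleation_rate(p)
  if (r <= rc) {
    stop("infeasible: r must exceed the critical nucleation rate", call. = FALSE)
  }
  if (cg_bulk < 0) stop("`cg_bulk` must be >= 0", call. = FALSE)
  cg_bulk * r / (r - rc)
}

#' Recover unmeasurable rates from measured aster dynamics
#'
#' Chains the closed-form and root-finding inversions to recover the rescue
#' rate `fres` (from the gap velocity), the autocatalytic nucleation rate `r`
#' (from the aster velocity) and optionally the carrying capacity `K` (from
#' the bulk plus-end density), and derives the net drift, critical nucleation
#' rate and mean microtubule length. Forward-consistency residuals
#' (re-predicted `Vgap` and `V` minus their inputs) are reported as
#' diagnostics; both are at solver precision by construction.
#'
#' @param measured A one-row data frame (or named list) with columns `vg`,
#'   `vs`, `fcat`, `v` (aster velocity), `v_gap` (gap velocity) and optionally
#'   `cg_bulk`; speeds in um/min, rates in 1/min.
#' @return An object of class `aster_inference`. Use [tidy()] for the
#'   parameter table and [glance()] for the one-row summary.
#' @examples
#' m <- tibble::tibble(vg = 30, vs = 42, fcat = 3.3,
#'                     v = 22.3, v_gap = 12.8, cg_bulk = 0.053)
#' fit <- infer_aster_dynamics(m)
#' tidy(fit)
#' @export
infer_aster_dynamics <- function(measured) {
  m <- as.list(measured)
  need <- c("vg", "vs", "fcat", "v", "v_gap")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("measured input lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.data.frame(measured) && nrow(measured) != 1L) {
    stop("`measured` must have exactly one row", call. = FALSE)
  }
  m <- lapply(m, function(v) if (is.list(v)) v[[1]] else v[[1]])
  if (m$v_gap > m$vg) {
    stop("infeasible measurement `v_gap`: exceeds vg (the gap velocity is capped at vg)",
         call. = FALSE)
  }
  if (m$v < m$v_gap) {
    stop("infeasible measurement `v`: below the measured gap velocity",
         call. = FALSE)
  }

  fres <- infer_rescue_from_gap(m$vg, m$vs, m$fcat, m$v_gap)
  p <- dynamics_params(m$vg, m$vs, m$fcat, fres)
  r <- infer_nucleation_from_velocity(p, m$v)
  K <- if (!is.null(m$cg_bulk) && is.finite(m$cg_bulk)) {
    infer_carrying_capacity(p, r, m$cg_bulk)
  } else {
    NA_real_
  }

  structure(list(
    measured = tibble::as_tibble(m[c(need, intersect("cg_bulk", names(m)))]),
    params = p,
    estimates = tibble::tibble(
      fres = fres, r = r, K = K,
      rc = critical_nucleation_rate(p),
      J = net_drift(p),
      mean_length = mean_mt_length(p)
    ),
    residuals = tibble::tibble(
      v_gap = gap_velocity(p) - m$v_gap,
      v = aster_velocity(p, r) - m$v
    )
  ), class = "aster_inference")
}

#' @export
print.aster_inference <- function(x, ...) {
  e <- x$estimates
  cat("<aster_inference>\n")
  cat(sprintf("  fres = %.3g /min, r = %.3g /min (rc = %.3g /min)\n",
              e$fres, e$r, e$rc))
  cat(sprintf("  J = %.3g um/min, mean length = %.3g um", e$J, e$mean_length))
  if (is.finite(e$K)) cat(sprintf(", K = %.3g (approximate)", e$K))
  cat("\n")
  cat(sprintf("  forward residuals: Vgap %.2e, V %.2e um/min\n",
              x$residuals$v_gap, x$residuals$v))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an aster-dynamics inference
#'
#' @param x An `aster_inference` object.
#' @param ... Unused.
#' @return A tibble with one row per recovered or derived parameter:
#'   `term`, `estimate`, `units`, `kind` (`"inferred"` or `"derived"`).
#' @method tidy aster_inference
#' @export
tidy.aster_inference <- function(x, ...) {
  e <- x$estimates
  out <- tibble::tibble(
    term = c("fres", "r", "K", "rc", "J", "mean_length"),
    estimate = c(e$fres, e$r, e$K, e$rc, e$J, e$mean_length),
    units = c("1/min", "1/min", "density", "1/min", "um/min", "um"),
    kind = c("inferred", "inferred", "inferred", "derived", "derived",
             "derived")
  )
  out[is.finite(out$estimate), ]
}

#' Summarise an aster-dynamics inference
#'
#' @param x An `aster_inference` object.
#' @param ... Unused.
#' @return A one-row tibble: the recovered rates, derived quantities and the
#'   forward-consistency residuals (`resid_v_gap`, `resid_v`, um/min).
#' @method glance aster_inference
#' @export
glance.aster_inference <- function(x, ...) {
  dplyr::bind_cols(
    x$estimates,
    tibble::tibble(resid_v_gap = x$residuals$v_gap, resid_v = x$residuals$v)
  )
}
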