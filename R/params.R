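#' Single-microtubule dynamics parameters
#'
#' Bundle the four rates of the two-state (growing/shrinking) model of
#' microtubule dynamic instability. All speeds are in micrometres per minute,
#' all frequencies in events per minute; no unit conversion happens inside the
#' model functions.
#'
#' @param vg Polymerization (growth) speed of the plus end, um/min. Must be > 0.
#' @param vs Depolymerization (shrinkage) speed, um/min. Must be > 0.
#' @param fcat Catastrophe frequency (growing to shrinking), 1/min. Must be > 0.
#' @param fres Rescue frequency (shrinking to growing), 1/min. Must be >= 0.
#'
#' @return An object of class `dynamics_params`: a named list with elements
#'   `vg`, `vs`, `fcat`, `fres`.
#'
#' @details The sign of the time-weighted net drift
#'   \eqn{J = (v_g f_{res} - v_s f_{cat}) / (f_{res} + f_{cat})}
#'   separates the bounded regime (J < 0, every microtubule eventually shrinks
#'   away) from the unbounded regime (J > 0).
#'
#' @examples
#' p <- dynamics_params(vg = 30, vs = 42, fcat = 3.3, fres = 2.0)
#' net_drift(p)
#' @export
dynamics_params <- function(vg, vs, fcat, fres) {
  check_number(vg, "vg", strict = TRUE)
  check_number(vs, "vs", strict = TRUE)
  check_number(fcat, "fcat", strict = TRUE)
  check_number(fres, "fres", strict = FALSE)
  structure(list(vg = vg, vs = vs, fcat = fcat, fres = fres),
            class = "dynamics_params")
}

check_number <- function(x, name, strict) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (!strict && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat("<dynamics_params>\n")
  cat(sprintf("  vg = %g um/min, vs = %g um/min, fcat = %g /min, fres = %g /min\n",
              x$vg, x$vs, x$fcat, x$fres))
  cat(sprintf("  net drift J = %.4g um/min (%s regime)\n", net_drift(x),
              if (net_drift(x) < 0) "bounded" else "unbounded"))
  invisible(x)
}

as_dynamics_params <- function(x) {
  if (inherits(x, "dynamics_params")) return(x)
  if (is.list(x) && all(c("vg", "vs", "fcat", "fres") %in% names(x))) {
    return(dynamics_params(x$vg, x$vs, x$fcat, x$fres))
  }
  stop("expected a `dynamics_params` object or a list with vg, vs, fcat, fres",
       call. = FALSE)
}

#' Autocatalytic nucleation specification
#'
#' Describes how new microtubules are nucleated by existing ones: either at
#' growing plus ends (rate `r` per plus end per minute) or along the polymer
#' lattice (rate `p` per micrometre of polymer per minute). Nucleation
#' saturates logistically at a carrying capacity `K` of the local growing
#' plus-end density, \eqn{Q = r C_g (1 - C_g/K)}.
#'
#' @param mode `"plus_end"` or `"polymer"`.
#' @param rate Nucleation rate: 1/min (plus-end mode) or 1/(um min) (polymer
#'   mode). Must be >= 0.
#' @param carrying_capacity Plus-end density scale `K` at which nucleation
#'   shuts off. Units follow the caller's density convention (the model only
#'   uses the ratio `Cg/K`); `Inf` disables saturation, as used for
#'   branching-process criticality checks.
#'
#' @return An object of class `nucleation_spec`.
#' @examples
#' nucleation_spec("plus_end", rate = 2.1, carrying_capacity = 0.4)
#' @export
nucleation_spec <- function(mode = c("plus_end", "polymer"), rate,
                            carrying_capacity = Inf) {
  mode <- match.arg(mode)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0) {
    stop("`rate` must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(carrying_capacity) || length(carrying_capacity) != 1L ||
      is.na(carrying_capacity) || carrying_capacity <= 0) {
    stop("`carrying_capacity` must be > 0 (Inf allowed)", call. = FALSE)
  }
  structure(list(mode = mode, rate = rate,
                 carrying_capacity = carrying_capacity),
            class = "nucleation_spec")
}

#' @export
print.nucleation_spec <- function(x, ...) {
  unit <- if (x$mode == "plus_end") "/min" else "/(um min)"
  cat(sprintf("<nucleation_spec> mode = %s, rate = %g %s, K = %g\n",
              x$mode, x$rate, unit, x$carrying_capacity))
  invisible(x)
}
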