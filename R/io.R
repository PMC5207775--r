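#' Load and validate a run configuration
#'
#' Reads a YAML or JSON key-value document describing a run (dynamics rates,
#' nucleation, grid, oracle caps, analysis options), validates every physical
#' parameter against the type invariants, fills defaults, and rejects unknown
#' keys by name.
#'
#' Recognized top-level keys: `dynamics` (vg, vs, fcat, fres), `nucleation`
#' (mode, rate, carrying_capacity), `grid` (dx, x_max, l_max), `sim` (t_end,
#' snapshot_every, init_width, init_amplitude, centrosome_renucleation,
#' clamp_nucleation), `oracle` (n, max_time, max_population, n_replicates),
#' `measured` (vg, vs, fcat, v, v_gap, cg_bulk), `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated named list of class `run_config` with constructed
#'   `dynamics_params` / `nucleation_spec` objects where given.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("dynamics", "nucleation", "grid", "sim", "oracle", "measured",
             "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_fields <- function(block, allowed, name) {
    extra <- setdiff(names(block), allowed)
    if (length(extra)) {
      stop(sprintf("unknown key(s) in `%s`: %s", name,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    block
  }
  out <- list(seed = raw$seed %||% 1L)
  if (!is.null(raw$dynamics)) {
    d <- check_fields(raw$dynamics, c("vg", "vs", "fcat", "fres"), "dynamics")
    out$dynamics <- dynamics_params(d$vg, d$vs, d$fcat, d$fres %||% 0)
  }
  if (!is.null(raw$nucleation)) {
    nu <- check_fields(raw$nucleation, c("mode", "rate", "carrying_capacity"),
                       "nucleation")
    out$nucleation <- nucleation_spec(nu$mode %||% "plus_end", nu$rate,
                                      nu$carrying_capacity %||% Inf)
  }
  if (!is.null(raw$grid)) {
    out$grid <- check_fields(raw$grid, c("dx", "x_max", "l_max"), "grid")
  }
  if (!is.null(raw$sim)) {
    out$sim <- check_fields(
      raw$sim, c("t_end", "snapshot_every", "init_width", "init_amplitude",
                 "centrosome_renucleation", "clamp_nucleation"), "sim")
  }
  if (!is.null(raw$oracle)) {
    out$oracle <- check_fields(
      raw$oracle, c("n", "max_time", "max_population", "n_replicates"),
      "oracle")
  }
  if (!is.null(raw$measured)) {
    out$measured <- check_fields(
      raw$measured, c("vg", "vs", "fcat", "v", "v_gap", "cg_bulk"), "measured")
  }
  structure(out, class = "run_config")
}

#' Write a result bundle to disk
#'
#' Serializes a summary list as `summary.json`, each named table as a CSV, and
#' a `provenance.json` (package version, seed, config echo, timestamp) into
#' `outdir`. Deterministic paths re-written with the same inputs are
#' bit-identical (the timestamp lives only in the provenance file).
#'
#' @param bundle A list with elements `summary` (named list), `tables` (named
#'   list of data frames) and optionally `config`, `seed`.
#' @param outdir Output directory, created if needed.
#' @return Invisibly, the character vector of written paths.
#' @export
write_bundle <- function(bundle, outdir) {
  stopifnot(is.list(bundle))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  sp <- file.path(outdir, "summary.json")
  jsonlite::write_json(bundle$summary %||% list(), sp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, sp)
  for (nm in names(bundle$tables %||% list())) {
    tp <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(bundle$tables[[nm]], tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  pv <- file.path(outdir, "provenance.json")
  jsonlite::write_json(list(
    package = "asterwave",
    version = as.character(utils::packageVersion("asterwave")),
    seed = bundle$seed %||% NA,
    config = bundle$config %||% list(),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), pv, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, pv))
}

#' Generate the bundled example/fixture files
#'
#' Writes the small plain-text inputs used in examples and tests: the measured
#' summary values of the reference aster-dynamics data set, the stationary and
#' traveling-wave simulation configurations (plus-end nucleation r = 1.0 and
#' 2.5 at vg = 30, vs = 40, fcat = 3, fres = 1), the matching polymer-mode
#' configurations (p = 0.07 and 0.18), a synthetic comet-lifetime CSV and a
#' synthetic intensity-profile CSV.
#'
#' @param dir Target directory.
#' @param seed Seed for the synthetic data sets.
#' @return Invisibly, the written paths.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(name, obj) {
    p <- file.path(dir, name)
    yaml::write_yaml(obj, p)
    paths <<- c(paths, p)
  }
  w("measured_table.yaml", list(
    measured = list(vg = 30, vs = 42, fcat = 3.3, v = 22.3, v_gap = 12.8,
                    cg_bulk = 0.053)
  ))
  base <- list(vg = 30, vs = 40, fcat = 3, fres = 1)
  w("stationary_plus_end.yaml", list(
    dynamics = base,
    nucleation = list(mode = "plus_end", rate = 1.0, carrying_capacity = 0.1),
    grid = list(dx = 0.25, x_max = 100, l_max = 135),
    sim = list(t_end = 15, snapshot_every = 1, init_amplitude = 0.05,
               init_width = 5, centrosome_renucleation = TRUE)
  ))
  w("traveling_plus_end.yaml", list(
    dynamics = base,
    nucleation = list(mode = "plus_end", rate = 2.5, carrying_capacity = 0.1),
    grid = list(dx = 0.25, x_max = 700, l_max = 135),
    sim = list(t_end = 22, snapshot_every = 2, init_amplitude = 0.05,
               init_width = 5, centrosome_renucleation = TRUE)
  ))
  w("stationary_polymer.yaml", list(
    dynamics = base,
    nucleation = list(mode = "polymer", rate = 0.07, carrying_capacity = 0.1),
    grid = list(dx = 0.25, x_max = 100, l_max = 135),
    sim = list(t_end = 15, snapshot_every = 1, init_amplitude = 0.05,
               init_width = 5, centrosome_renucleation = TRUE)
  ))
  w("growing_polymer.yaml", list(
    dynamics = base,
    nucleation = list(mode = "polymer", rate = 0.18, carrying_capacity = 0.1),
    grid = list(dx = 0.25, x_max = 500, l_max = 135),
    sim = list(t_end = 20, snapshot_every = 1, init_amplitude = 0.05,
               init_width = 5, centrosome_renucleation = TRUE)
  ))

  comets <- synth_comet_lifetimes(3.3, n = 3000, seed = seed)
  cp <- file.path(dir, "synthetic_comet_lifetimes.csv")
  utils::write.csv(comets, cp, row.names = FALSE)
  profiles <- synth_aster_profiles(22.3, seed = seed + 1L)
  pp <- file.path(dir, "synthetic_aster_profiles.csv")
  utils::write.csv(profiles, pp, row.names = FALSE)
  invisible(c(paths, cp, pp))
}

#' Analytic summary of a parameter set
#'
#' Convenience wrapper producing the full closed-form report for one dynamics
#' parameter set and nucleation specification: net drift, critical rates, gap
#' velocity, analytic aster velocity, mean length, bulk density and regime.
#'
#' @param params A [dynamics_params()].
#' @param nucleation A [nucleation_spec()].
#' @return A one-row tibble.
#' @examples
#' analytic_summary(dynamics_params(30, 42, 3.3, 2.0),
#'                  nucleation_spec("plus_end", 2.1, 0.4))
#' @export
analytic_summary <- function(params, nucleation) {
  p <- as_dynamics_params(params)
  rep <- classify_regime(p, nucleation)
  bounded <- net_drift(p) < 0
  tibble::tibble(
    J = net_drift(p),
    rc = critical_nucleation_rate(p),
    pc = if (bounded) polymer_critical_rate(p) else 0,
    v_gap = rep$v_gap,
    V = rep$V,
    mean_length = if (bounded) mean_mt_length(p) else Inf,
    bulk_density = if (nucleation$mode == "plus_end" &&
                       is.finite(nucleation$carrying_capacity)) {
      bulk_plus_end_density(p, nucleation$rate, nucleation$carrying_capacity)
    } else {
      NA_real_
    },
    regime = rep$regime
  )
}
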