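test_that("net drift is the time-weighted mean elongation rate", {
  expect_equal(net_drift(table_params()), -14.83019, tolerance = 1e-6)
  expect_equal(net_drift(dynamics_params(25, 25, 2, 2)), 0)
  expect_equal(net_drift(dynamics_params(30, 15, 3, 3)), 7.5)
})

test_that("parameter containers validate their invariants", {
  expect_error(dynamics_params(-1, 40, 3, 1), "vg")
  expect_error(dynamics_params(30, 40, 0, 1), "fcat")
  expect_error(dynamics_params(30, 40, 3, -0.1), "fres")
  expect_silent(dynamics_params(30, 40, 3, 0))
  expect_error(nucleation_spec("plus_end", -1), "rate")
  expect_error(nucleation_spec("plus_end", 1, carrying_capacity = 0),
               "carrying_capacity")
})

test_that("critical nucleation rate and its limits", {
  expect_equal(critical_nucleation_rate(dynamics_params(30, 40, 3, 1)), 2.25)
  # no rescues: the critical rate equals the catastrophe rate, exactly
  expect_identical(critical_nucleation_rate(dynamics_params(30, 40, 3, 0)), 3)
  # J = 0 exactly: no threshold
  expect_equal(critical_nucleation_rate(dynamics_params(30, 30, 2, 2)), 0)
  # J > 0: clamped at zero
  expect_equal(critical_nucleation_rate(dynamics_params(30, 15, 3, 3)), 0)
})

test_that("aster velocity matches frozen values and flags out-of-range rates", {
  expect_equal(aster_velocity(table_params(), 2.1), 21.97771, tolerance = 1e-6)
  expect_equal(aster_velocity(fig_params(), 2.5), 27.58474, tolerance = 1e-6)
  expect_warning(v <- aster_velocity(fig_params(), 1.0), "below critical")
  expect_true(is.na(v))
  expect_warning(v2 <- aster_velocity(fig_params(), 3.5), "outside analytic")
  expect_true(is.na(v2))
})

test_that("velocity limits pin the formula: V(rc+) = Vgap, V(fcat) = vg at fres = 0", {
  for (p in random_bounded_params(20, seed = 42)) {
    rc <- critical_nucleation_rate(p)
    if (rc <= 0 || rc >= p$fcat) next
    v_near <- aster_velocity(p, rc * (1 + 1e-13))  # sqrt singularity: V - Vgap ~ sqrt(r - rc)
    expect_equal(v_near, gap_velocity(p), tolerance = 1e-6)
  }
  # rescue-free limit: V(r = fcat) = vg and Vgap = vg, exactly
  p0 <- dynamics_params(30, 40, 3, 0)
  expect_equal(aster_velocity(p0, 3), 30, tolerance = 1e-12)
  expect_equal(gap_velocity(p0), 30)
})

test_that("velocity is monotone: up in r, fres, vg; down in fcat, vs", {
  ps <- random_bounded_params(15, seed = 7)
  h <- 1e-4
  for (p in ps) {
    rc <- critical_nucleation_rate(p)
    if (rc <= 0 || rc >= p$fcat) next
    r <- rc + 0.6 * (p$fcat - rc)
    v0 <- aster_velocity(p, r)
    expect_gt(aster_velocity(p, r + h * (p$fcat - r)), v0)
    up <- function(field, sgn) {
      q <- unclass(p)
      q[[field]] <- q[[field]] * (1 + sgn * h)
      q <- dynamics_params(q$vg, q$vs, q$fcat, q$fres)
      # keep r inside the perturbed validity window
      if (critical_nucleation_rate(q) < r && r < q$fcat) {
        aster_velocity(q, r)
      } else {
        NA_real_
      }
    }
    for (f in c("fres", "vg")) {
      v1 <- up(f, +1)
      if (!is.na(v1)) expect_gt(v1, v0, label = paste("V after increasing", f))
    }
    for (f in c("fcat", "vs")) {
      v1 <- up(f, +1)
      if (!is.na(v1)) expect_lt(v1, v0, label = paste("V after increasing", f))
    }
  }
})

test_that("gap velocity: frozen values, range, and the mean-length identity", {
  expect_equal(gap_velocity(table_params()), 12.9948, tolerance = 1e-5)
  expect_equal(gap_velocity(fig_params()), 108000 / 5700)
  expect_warning(v <- gap_velocity(dynamics_params(30, 15, 3, 3)), "J < 0")
  expect_true(is.na(v))
  for (p in random_bounded_params(20, seed = 3)) {
    if (net_drift(p) >= 0) next
    vgap <- gap_velocity(p)
    expect_true(vgap > 0 && vgap <= p$vg)
    # Vgap * <l> * (vg^2 fres + vs^2 fcat) = (vg vs)^2, exactly
    lhs <- vgap * mean_mt_length(p) * (p$vg^2 * p$fres + p$vs^2 * p$fcat)
    expect_equal(lhs, (p$vg * p$vs)^2, tolerance = 1e-12)
  }
})

test_that("mean microtubule length: values and divergence at J = 0", {
  expect_equal(mean_mt_length(table_params()), 16.03053, tolerance = 1e-6)
  expect_equal(mean_mt_length(fig_params()), 40 / 3)
  expect_warning(l <- mean_mt_length(dynamics_params(30, 30, 2, 2)), "diverges")
  expect_identical(l, Inf)
  # equals vg / rc
  p <- fig_params()
  expect_equal(mean_mt_length(p), p$vg / critical_nucleation_rate(p))
})

test_that("expected integrated length: closed form, limits, reciprocity", {
  p <- fig_params()
  expect_equal(expected_integrated_length(p), 84000 / 8100, tolerance = 1e-12)
  # rescue-free special case
  expect_equal(expected_integrated_length(dynamics_params(30, 40, 3, 0)),
               30 * 40 * 70 / (40 * 3)^2, tolerance = 1e-12)
  # instantaneous-collapse limit: vg/fcat^2 (triangle path integral)
  big <- expected_integrated_length(dynamics_params(30, 1e7, 3, 0))
  expect_equal(big, 30 / 9, tolerance = 1e-5)
  # reciprocity with the polymer critical rate
  for (q in random_bounded_params(10, seed = 5)) {
    if (net_drift(q) >= 0) next
    expect_equal(polymer_critical_rate(q) * expected_integrated_length(q), 1,
                 tolerance = 1e-12)
  }
  expect_warning(expected_integrated_length(dynamics_params(30, 15, 3, 3)),
                 "diverges")
})

test_that("polymer critical rate reproduces the reference value", {
  expect_equal(polymer_critical_rate(fig_params()), 0.0964286,
               tolerance = 1e-6)
  expect_equal(polymer_critical_rate(dynamics_params(30, 40, 3, 0)),
               14400 / 84000, tolerance = 1e-12)
  expect_warning(pc <- polymer_critical_rate(dynamics_params(30, 15, 3, 3)),
                 "unbounded")
  expect_identical(pc, 0)
})

test_that("bulk plus-end density: fixed point, limits, local linearity", {
  p <- table_params()
  rc <- critical_nucleation_rate(p)
  expect_equal(bulk_plus_end_density(p, 2.1, 0.4), 0.4 * (1 - rc / 2.1))
  expect_identical(bulk_plus_end_density(p, rc, 0.4), 0)
  expect_equal(bulk_plus_end_density(p, 1e9, 0.4), 0.4, tolerance = 1e-6)
  # linear in (r - rc) near the transition: the second difference vanishes
  # relative to the first as the probe spacing shrinks
  h <- 1e-4
  d1 <- bulk_plus_end_density(p, rc + h, 0.4)
  d2 <- bulk_plus_end_density(p, rc + 2 * h, 0.4)
  d3 <- bulk_plus_end_density(p, rc + 3 * h, 0.4)
  expect_lt(abs(d3 - 2 * d2 + d1), 1e-3 * (d2 - d1))
  expect_equal((d2 - d1) / (d3 - d2), 1, tolerance = 1e-3)
})

test_that("regime classification covers the phase diagram", {
  p <- fig_params()
  expect_equal(classify_regime(p, nucleation_spec("plus_end", 1.0))$regime,
               "stationary")
  rep2 <- classify_regime(p, nucleation_spec("plus_end", 2.5))
  expect_equal(rep2$regime, "collective_growth")
  expect_equal(rep2$V, aster_velocity(p, 2.5))
  rep3 <- classify_regime(dynamics_params(30, 15, 3, 3),
                          nucleation_spec("plus_end", 0))
  expect_equal(rep3$regime, "individual_growth")
  expect_equal(rep3$V, 7.5)
  # exactly at the transition: boundary flag with V = Vgap
  rc <- critical_nucleation_rate(p)
  rep4 <- classify_regime(p, nucleation_spec("plus_end", rc))
  expect_match(rep4$note, "at_transition")
  expect_equal(rep4$V, gap_velocity(p))
  # polymer mode uses the polymer critical rate
  rep5 <- classify_regime(p, nucleation_spec("polymer", 0.07))
  expect_equal(rep5$regime, "stationary")
  rep6 <- classify_regime(p, nucleation_spec("polymer", 0.18))
  expect_equal(rep6$regime, "collective_growth")
})

test_that("analytic summary assembles the full report", {
  s <- analytic_summary(table_params(), nucleation_spec("plus_end", 2.1, 0.4))
  expect_equal(s$J, net_drift(table_params()))
  expect_equal(s$V, 21.97771, tolerance = 1e-6)
  expect_equal(s$mean_length, 16.03053, tolerance = 1e-6)
  expect_equal(s$regime, "collective_growth")
})
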