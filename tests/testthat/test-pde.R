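test_that("grid construction: commensurate shifts, stability refinement, l_max rule", {
  p <- fig_params()
  expect_message(g <- sim_grid(p, dx = 0.5, x_max = 100), "refined")
  expect_equal(g$dx, 0.25)
  expect_equal(g$shift_g, 3)
  expect_equal(g$shift_s, 4)
  expect_equal(g$shift_g * g$dx / g$dt, p$vg)
  expect_lt(max(p$fcat, p$fres) * g$dt, 0.1)
  expect_equal(g$l_max, 10 * mean_mt_length(p), tolerance = 0.01)
  expect_warning(sim_grid(p, dx = 0.25, x_max = 50, l_max = 30), "l_max")
})

test_that("initialization seeds zero-length growing microtubules and checks K", {
  g <- suppressMessages(sim_grid(fig_params(), dx = 0.5, x_max = 50, l_max = 140))
  cfg <- sim_config(t_end = 1, init_width = 2, init_amplitude = 0.05)
  st <- initialize_state(g, cfg, carrying_capacity = 0.1)
  # total number equals the pulse mass; all growing, zero length
  expect_equal(sum(st$rho_g) * g$dx^2, 0.05 * 2, tolerance = 1e-12)
  expect_true(all(st$rho_s == 0))
  expect_true(all(st$rho_g[, -1] == 0))
  expect_error(initialize_state(g, sim_config(t_end = 1, init_amplitude = 0.15),
                                carrying_capacity = 0.1), "carrying capacity")
  # width below one cell still seeds a single-cell delta
  st1 <- initialize_state(g, sim_config(t_end = 1, init_width = 0,
                                        init_amplitude = 0.01))
  expect_equal(sum(st1$rho_g > 0), 1L)
})

test_that("plus-end density is the diagonal convolution of the growing field", {
  g <- suppressMessages(sim_grid(fig_params(), dx = 0.5, x_max = 50, l_max = 140))
  st <- initialize_state(g, sim_config(t_end = 1, init_amplitude = 0.01))
  st$rho_g[] <- 0
  # one cell of growing microtubules: minus end cell 10, length cell 21
  st$rho_g[10, 21] <- 1
  cg <- plus_end_density(st)
  expect_equal(which(cg$density > 0), 30L) # plus end at cell 10 + 21 - 1
  expect_equal(sum(cg$density) * g$dx, sum(st$rho_g) * g$dx^2)
  # uniform in l at one x: flat plus-end density over [x0, x0 + L]
  st$rho_g[] <- 0
  st$rho_g[5, 1:20] <- 1
  cg2 <- plus_end_density(st)$density
  expect_true(all(abs(cg2[5:24] - cg2[5]) < 1e-12))
  expect_true(all(cg2[-(5:24)] == 0))
})

test_that("polymer density integrates to total polymer length", {
  g <- suppressMessages(sim_grid(fig_params(), dx = 0.5, x_max = 50, l_max = 140))
  st <- initialize_state(g, sim_config(t_end = 1, init_amplitude = 0.01))
  st$rho_g[] <- 0
  # one microtubule (number 1) of length 10 um: density 1/dx^2 in the cell
  # whose coverage spans 10/dx cells
  st$rho_g[10, as.integer(round(10 / g$dx))] <- 1 / g$dx^2
  m <- polymer_density(st)
  expect_true(all(m$density >= 0))
  expect_equal(sum(m$density) * g$dx, 10, tolerance = 1e-12)
  # linearity: doubling the field doubles the profile
  st2 <- st
  st2$rho_g <- st$rho_g * 2
  expect_equal(polymer_density(st2)$density, 2 * m$density, tolerance = 1e-12)
})

test_that("nucleation profile follows the logistic law", {
  g <- suppressMessages(sim_grid(fig_params(), dx = 0.5, x_max = 50, l_max = 140))
  st <- initialize_state(g, sim_config(t_end = 1, init_amplitude = 0.01))
  K <- 0.1
  nu <- nucleation_spec("plus_end", 2, K)
  # construct Cg = K/2 at one position: rho_g[x, 1] = (K/2)/dx
  st$rho_g[] <- 0
  st$rho_g[10, 1] <- (K / 2) / g$dx
  q <- nucleation_profile(st, nu)
  expect_equal(q$rate[10], 2 * K / 4, tolerance = 1e-12) # logistic maximum
  st$rho_g[10, 1] <- K / g$dx
  expect_equal(nucleation_profile(st, nu)$rate[10], 0, tolerance = 1e-12)
  st$rho_g[10, 1] <- 0
  expect_true(all(nucleation_profile(st, nu)$rate == 0))
  # above K: clamped at zero when requested, negative otherwise
  st$rho_g[10, 1] <- 1.5 * K / g$dx
  expect_equal(nucleation_profile(st, nu, clamp = TRUE)$rate[10], 0)
  expect_lt(nucleation_profile(st, nu, clamp = FALSE)$rate[10], 0)
})

test_that("pure growing seed advects exactly with exponential catastrophe loss", {
  p <- dynamics_params(30, 40, 3, 0)
  g <- suppressMessages(sim_grid(p, dx = 0.5, x_max = 30, l_max = 140))
  cfg <- sim_config(t_end = 1, init_amplitude = 0.01, init_width = 0)
  nu <- nucleation_spec("plus_end", 0)
  st <- initialize_state(g, cfg)
  m0 <- sum(st$rho_g)
  n <- 10
  for (i in seq_len(n)) st <- step_state(st, p, nu, cfg)
  # growing mass sits exactly n * shift_g cells up in l with factor e^(-fcat t)
  expect_equal(sum(st$rho_g[, 1 + n * g$shift_g]),
               m0 * exp(-p$fcat * n * g$dt), tolerance = 1e-12)
  expect_equal(sum(st$rho_g), m0 * exp(-p$fcat * n * g$dt), tolerance = 1e-12)
})

test_that("transport conserves mass away from the absorbing boundary", {
  p <- fig_params()
  g <- suppressMessages(sim_grid(p, dx = 0.5, x_max = 30, l_max = 140))
  cfg <- sim_config(t_end = 1, init_amplitude = 0.01)
  nu <- nucleation_spec("plus_end", 0)
  st <- initialize_state(g, cfg)
  st$rho_g[] <- 0
  st$rho_g[5, 200] <- 1 # seed far from both l boundaries
  m0 <- sum(st$rho_g + st$rho_s)
  for (i in 1:10) {
    st <- step_state(st, p, nu, cfg)
    expect_true(all(st$rho_g >= 0), label = "non-negative growing density")
    expect_true(all(st$rho_s >= 0), label = "non-negative shrinking density")
  }
  # shrinking mass has moved at most 10*4 cells down from cell 200: no
  # absorption yet, so total microtubule number is exactly conserved
  expect_equal(sum(st$rho_g + st$rho_s), m0, tolerance = 1e-12)
})

test_that("without nucleation the bounded population decays to zero", {
  p <- fig_params()
  g <- suppressWarnings(suppressMessages(
    sim_grid(p, dx = 0.5, x_max = 30, l_max = 60)))
  cfg <- sim_config(t_end = 1, init_amplitude = 0.01)
  nu <- nucleation_spec("plus_end", 0)
  st <- initialize_state(g, cfg)
  masses <- numeric(3)
  for (k in 1:3) {
    for (i in 1:80) st <- step_state(st, p, nu, cfg)
    masses[k] <- sum(st$rho_g + st$rho_s)
  }
  expect_true(all(diff(masses) < 0))
  expect_lt(masses[3] / (0.01 * 2 / g$dx^2), 0.01)
})

test_that("compiled fast path reproduces the reference R stepper exactly", {
  p <- fig_params()
  g <- suppressMessages(suppressWarnings(
    sim_grid(p, dx = 0.5, x_max = 40, l_max = 40)))
  cfg <- sim_config(t_end = 1, init_amplitude = 0.05,
                    centrosome_renucleation = TRUE)
  st <- initialize_state(g, cfg, 0.1)
  for (mode in c("plus_end", "polymer")) {
    nu <- nucleation_spec(mode, if (mode == "polymer") 0.15 else 2.5, 0.1)
    stR <- st
    for (i in 1:20) stR <- step_state(stR, p, nu, cfg)
    res <- asterwave:::.run_steps_cpp(st$rho_g, st$rho_s, 20L, g$dt, g$dx, g$shift_g,
                          g$shift_s, p$fcat, p$fres,
                          as.integer(mode == "plus_end"), nu$rate,
                          nu$carrying_capacity, 1L, 1L)
    expect_equal(res$rho_g, stR$rho_g, tolerance = 1e-14)
    expect_equal(res$rho_s, stR$rho_s, tolerance = 1e-14)
  }
})

test_that("subcritical runs are stationary, supercritical ones travel near the analytic speed", {
  p <- fig_params()
  # stationary: nucleation below the critical rate, centrosome maintains a
  # confined population
  g1 <- sim_grid(p, dx = 0.25, x_max = 100, l_max = 135)
  s1 <- simulate_aster(p, nucleation_spec("plus_end", 1.0, 0.1), g1,
                       sim_config(t_end = 25, snapshot_every = 1,
                                  init_amplitude = 0.05, init_width = 5,
                                  centrosome_renucleation = TRUE))
  expect_equal(s1$regime, "stationary")
  expect_lt(abs(s1$velocity$velocity), 0.5)
  prof <- function(s, tt) s$snapshots$density[s$snapshots$t == tt]
  # without the centrosomal source the subcritical population decays and the
  # late-time L2 change per min goes to zero
  s1d <- simulate_aster(p, nucleation_spec("plus_end", 1.0, 0.1), g1,
                        sim_config(t_end = 25, snapshot_every = 1,
                                   init_amplitude = 0.05, init_width = 5,
                                   centrosome_renucleation = FALSE))
  expect_equal(s1d$regime, "stationary")
  l2 <- sqrt(mean((prof(s1d, 25) - prof(s1d, 24))^2))
  l2_early <- sqrt(mean((prof(s1d, 6) - prof(s1d, 5))^2))
  expect_lt(l2, 0.01 * l2_early)

  # traveling wave at r = 2.5: speed within 5% of the analytic value
  g2 <- sim_grid(p, dx = 0.25, x_max = 700, l_max = 135)
  s2 <- simulate_aster(p, nucleation_spec("plus_end", 2.5, 0.1), g2,
                       sim_config(t_end = 22, snapshot_every = 2,
                                  init_amplitude = 0.05, init_width = 5,
                                  centrosome_renucleation = TRUE))
  v_pred <- aster_velocity(p, 2.5)
  expect_equal(s2$regime, "traveling_wave")
  expect_lt(abs(s2$velocity$velocity - v_pred) / v_pred, 0.05)

  # shape invariance: the front region of the last two profiles collapses
  # after translation (the wake further back is still relaxing toward the
  # bulk fixed point and is compared against that fixed point instead)
  d1 <- prof(s2, 20); d2 <- prof(s2, 22)
  x <- unique(s2$snapshots$x)
  fr <- s2$front$x_front[s2$front$t == 22]
  shift <- fr - s2$front$x_front[s2$front$t == 20]
  d1s <- stats::approx(x + shift, d1, xout = x)$y
  keep <- !is.na(d1s) & x > fr - 60 & x < fr + 120
  plateau <- max(d2[keep])
  expect_lt(sqrt(mean((d2[keep] - d1s[keep])^2)), 0.02 * plateau)

  # bulk plateau close to the logistic fixed point (band behind the front)
  fr <- max(s2$front$x_front, na.rm = TRUE)
  band <- x > 0.6 * fr & x < 0.85 * fr
  expect_equal(stats::median(d2[band]), bulk_plus_end_density(p, 2.5, 0.1),
               tolerance = 0.1)
})

test_that("front speed approaches the analytic value for other parameter sets", {
  cases <- list(
    list(p = dynamics_params(30, 30, 3, 1), r = 2.5, xm = 700, te = 22),
    list(p = dynamics_params(30, 15, 3, 1), r = 2.0, xm = 650, te = 22)
  )
  for (cs in cases) {
    v_pred <- aster_velocity(cs$p, cs$r)
    g <- sim_grid(cs$p, dx = 0.25, x_max = cs$xm, l_max = NULL)
    s <- simulate_aster(cs$p, nucleation_spec("plus_end", cs$r, 0.1), g,
                        sim_config(t_end = cs$te, snapshot_every = 2,
                                   init_amplitude = 0.05, init_width = 5,
                                   centrosome_renucleation = TRUE))
    expect_lt(abs(s$velocity$velocity - v_pred) / v_pred, 0.05,
              label = sprintf("front speed at vg=%g vs=%g", cs$p$vg, cs$p$vs))
  }
})

test_that("polymer-stimulated nucleation is stationary below pc and grows above", {
  p <- fig_params() # pc = 0.0964 per um per min
  g1 <- sim_grid(p, dx = 0.25, x_max = 100, l_max = 135)
  s_lo <- simulate_aster(p, nucleation_spec("polymer", 0.07, 0.1), g1,
                         sim_config(t_end = 15, snapshot_every = 1,
                                    init_amplitude = 0.05, init_width = 5,
                                    centrosome_renucleation = TRUE))
  expect_equal(s_lo$regime, "stationary")
  g2 <- sim_grid(p, dx = 0.25, x_max = 500, l_max = 135)
  s_hi <- simulate_aster(p, nucleation_spec("polymer", 0.18, 0.1), g2,
                         sim_config(t_end = 20, snapshot_every = 1,
                                    init_amplitude = 0.05, init_width = 5,
                                    centrosome_renucleation = TRUE))
  expect_equal(s_hi$regime, "traveling_wave")
  expect_gt(s_hi$velocity$velocity, gap_velocity(p) * 0.5)
})

test_that("front position: interpolated crossing, sentinels, exit guard", {
  x <- seq(0.5, 200, by = 1)
  dens <- ifelse(x < 120, 1, ifelse(x == 120.5, 0.5, 0))
  dens[x == 120.5] <- 0.5
  expect_equal(front_position(x, dens, threshold = 0.5), 120.5)
  expect_true(is.na(front_position(x, rep(0, length(x)), threshold = 0.5)))
  # default threshold: half the profile maximum
  expect_equal(front_position(x, dens), 120.5)
  # a run whose front would leave the domain raises a structured error
  p <- fig_params()
  g <- sim_grid(p, dx = 0.25, x_max = 80, l_max = 135)
  expect_error(
    simulate_aster(p, nucleation_spec("plus_end", 2.5, 0.1), g,
                   sim_config(t_end = 8, snapshot_every = 0.5,
                              init_amplitude = 0.05, init_width = 5,
                              centrosome_renucleation = TRUE)),
    "x_max")
})

test_that("front velocity estimation: exact line, noise, short traces", {
  tr <- tibble::tibble(t = seq(0, 10, by = 1), x_front = 5 + 20 * seq(0, 10, 1))
  fit <- estimate_front_velocity(tr)
  expect_equal(fit$velocity, 20, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  set.seed(21)
  tr2 <- tr
  tr2$x_front <- tr2$x_front + stats::rnorm(11, sd = 0.5)
  fit2 <- estimate_front_velocity(tr2)
  expect_equal(fit2$velocity, 20, tolerance = 0.05)
  expect_equal(nrow(tr2[tr2$t >= 5, ]), fit2$n_points)
  short <- estimate_front_velocity(tr[1:4, ])
  expect_true(is.na(short$velocity))
})
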