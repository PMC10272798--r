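# The two-compartment circulation: driving waveforms, venous collapse law,
# the integrator, and its conservation / convergence properties.

test_that("systemic sinusoid hits SBP, DBP and MAP", {
  inp <- systemic_input(120, 40, 60)
  t <- seq(0, 1, 1e-4)
  p <- systemic_pressure(t, inp)
  expect_equal(max(p), 120, tolerance = 1e-6)
  expect_equal(min(p), 80, tolerance = 1e-6)
  expect_equal(mean(p[-1]), 100, tolerance = 1e-3)
})

test_that("cuff pressure ramps linearly and holds at the maximum", {
  pr <- cuff_protocol(rate = 6, start = 5, max_pressure = 170, hold = 10)
  expect_identical(cuff_pressure(c(0, 4.9), pr), c(0, 0))
  expect_equal(cuff_pressure(15, pr), 60)
  expect_equal(cuff_pressure(100, pr), 170)
})

test_that("venous resistance transitions from open to occluded at threshold", {
  cp <- circuit_params()
  expect_equal(venous_resistance(0, cp), cp$r_ven_open, tolerance = 0.01)
  expect_gt(venous_resistance(60, cp), 1e6)
  # at the threshold the sigmoid sits at the log-scale midpoint
  expect_equal(venous_resistance(cp$collapse_threshold, cp),
               sqrt(cp$r_ven_open * 1e9), tolerance = 1e-6)
  expect_true(all(diff(venous_resistance(seq(0, 100, 0.5), cp)) >= 0))
})

test_that("closed-form equilibrium pressure is the compliance-weighted mean", {
  cp <- circuit_params()
  expect_identical(equilibrium_pressure(70, 70, cp), 70)
  expect_equal(equilibrium_pressure(100, 40, cp),
               (0.03 * 100 + 0.9 * 40) / 0.93, tolerance = 1e-12)
  big <- circuit_params(c_ven = 9000)
  expect_equal(equilibrium_pressure(100, 40, big), 40, tolerance = 0.1)
})

test_that("without inflation the distal pressures settle at the linear steady state", {
  sim <- simulate_arm(protocol = cuff_protocol(rate = 6, max_pressure = 0,
                                               hold = 24),
                      dt = 1e-3)
  tail_i <- sim$time > 20
  # analytic steady state of the two-node circuit at the mean resistance
  inp <- sim$input
  r_art <- mean(poiseuille_resistance(systemic_pressure(seq(0, 1, 1e-3),
                                                        inp)))
  expected <- (inp$map / r_art + inp$venous / 100) / (1 / r_art + 1 / 100)
  expect_equal(mean(sim$p_art_distal[tail_i]), expected, tolerance = 0.5)
  # open-vein distal venous level: divider between arterial inflow via
  # R_systemic and the systemic venous source via R_ven_open
  pv_exp <- (expected / 100 + inp$venous / 10) / (1 / 100 + 1 / 10)
  expect_equal(mean(sim$p_ven_distal[tail_i]), pv_exp, tolerance = 0.5)
})

test_that("venous pressure builds up distally once the vein collapses", {
  sim <- ref_sim()
  pv_rest <- mean(sim$p_ven_distal[sim$time < sim$protocol$start])
  i50 <- which(sim$p_cuff >= 50)[1]
  expect_gt(sim$p_ven_distal[i50], sim$input$venous + 5)
  expect_gt(sim$p_ven_distal[i50], pv_rest + 2)
  # and little buildup before the collapse threshold is approached
  i15 <- which(sim$p_cuff >= 15)[1]
  expect_lt(sim$p_ven_distal[i15], pv_rest + 1)
})

test_that("after full occlusion the stored charge is conserved", {
  sim <- ref_sim()
  cp <- sim$circuit
  late <- sim$time > occlusion_time(sim) + 5
  q <- cp$c_art * sim$p_art_distal[late] + cp$c_ven * sim$p_ven_distal[late]
  expect_lt(diff(range(q)) / mean(q), 0.005)
})

test_that("halving the step changes no pressure sample appreciably", {
  s1 <- simulate_arm(dt = 5e-4)
  s2 <- simulate_arm(dt = 2.5e-4)
  i2 <- seq(1, length(s2$time), by = 2)
  m <- min(length(s1$time), length(i2))  # t_end rounding can differ by one
  i1 <- seq_len(m); i2 <- i2[i1]
  expect_lt(max(abs(s1$p_art_distal[i1] - s2$p_art_distal[i2])), 0.1)
  expect_lt(max(abs(s1$p_ven_distal[i1] - s2$p_ven_distal[i2])), 0.1)
})

test_that("Euler and RK4 agree on the reference run", {
  s1 <- ref_sim()
  s2 <- simulate_arm(method = "rk4")
  expect_lt(max(abs(s1$p_art_distal - s2$p_art_distal)), 0.1)
})

test_that("the simulator rejects invalid steps and inputs", {
  expect_error(simulate_arm(dt = 2e-3), "dt")
  expect_error(systemic_input(100, 110), "SBP > PP")
  expect_error(systemic_input(100, 95, venous = 10), "venous")
  expect_error(cuff_protocol(rate = -1), "rate")
  expect_error(circuit_params(c_art = -0.01), "positive")
})

test_that("simulated equilibrium matches the conservation closed form", {
  sim <- ref_sim()
  io <- which.min(abs(sim$time - occlusion_time(sim)))
  pe <- equilibrium_pressure(sim$p_art_distal[io], sim$p_ven_distal[io],
                             sim$circuit)
  expect_equal(sim$p_end, pe, tolerance = 0.5)
})

test_that("simulation output satisfies the container invariants", {
  sim <- ref_sim()
  n <- length(sim$time)
  expect_true(all(lengths(list(sim$p_art_sys, sim$p_cuff, sim$p_art_distal,
                               sim$p_ven_distal)) == n))
  expect_true(all(diff(sim$time) > 0))
  vals <- c(sim$p_art_sys, sim$p_cuff, sim$p_art_distal, sim$p_ven_distal)
  expect_true(all(is.finite(vals) & vals >= 0 & vals <= 400))
  df <- as.data.frame(sim)
  expect_equal(nrow(df), n)
})
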