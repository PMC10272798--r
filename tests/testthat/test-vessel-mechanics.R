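# Static arterial mechanics: tube law, compliance, Poiseuille resistance,
# wave speed, transit times. Frozen scalar expectations were computed by
# hand evaluation of the constitutive relations at reference parameters.

test_that("tube law reproduces hand-computed areas and clamps under collapse", {
  tl <- tube_law()
  # A(0) = d exactly: the normalized log argument is 1 at zero transmural
  expect_identical(luminal_area(0, tl), 0.08)
  # A(100) = 0.08 * (ln 6.3 / ln 3.3)^(1 + e^-10); exponent ~ 1
  expect_equal(luminal_area(100, tl), 0.1233303, tolerance = 1e-6)
  # deep collapse clamps at the area floor
  expect_identical(luminal_area(-80, tl), 1e-6)
  expect_identical(luminal_area(-200, tl), 1e-6)  # log argument <= 1
  # vectorised and finite
  A <- luminal_area(seq(-150, 250, 1), tl)
  expect_true(all(is.finite(A) & A >= 1e-6))
})

test_that("tube law is monotone non-decreasing over the working range", {
  for (tl in list(tube_law(), tube_law(0.017, 0.14), tube_law(0.035, 0.08))) {
    A <- luminal_area(seq(-150, 250, 1), tl)
    expect_true(all(diff(A) >= 0))
  }
})

test_that("area compliance matches the symbolic derivative and clamps flat", {
  tl <- tube_law()
  # symbolic total derivative of the normalized law (independent oracle)
  sym <- function(p, tl) {
    u <- tl$a * p + 3.3
    w <- log(u) / log(3.3)
    E <- 1 + exp(-tl$c * p)
    A <- tl$d * w^E
    A * (-tl$c * exp(-tl$c * p) * log(w) + E * tl$a / (u * log(u)))
  }
  grid <- seq(-25, 250, 2.5)
  expect_equal(area_compliance(grid, tl), sym(grid, tl), tolerance = 1e-3)
  expect_equal(area_compliance(100, tl), 3.19e-4, tolerance = 1e-2)
  # zero across the collapsed plateau, non-negative everywhere
  expect_identical(area_compliance(c(-80, -120), tl), c(0, 0))
  expect_true(all(area_compliance(seq(-150, 250, 1), tl) >= 0))
  # near-collapse lumen is far more compliant than the stiffened one
  expect_gt(area_compliance(0, tl), area_compliance(150, tl))
})

test_that("Poiseuille resistance follows the quartic radius law", {
  expect_equal(poiseuille_resistance(100), 0.6084, tolerance = 1e-3)
  # doubling the radius (area x4 via d) divides resistance by 16
  r1 <- poiseuille_resistance(100, tube = tube_law(d = 0.08))
  r2 <- poiseuille_resistance(100, tube = tube_law(d = 0.32))
  expect_equal(r1 / r2, 16, tolerance = 1e-9)
  # proportional to cuff length
  ra <- poiseuille_resistance(100, arm_geometry(cuff_length = 0.07))
  rb <- poiseuille_resistance(100, arm_geometry(cuff_length = 0.14))
  expect_equal(rb / ra, 2, tolerance = 1e-9)
  expect_lt(poiseuille_resistance(100, arm_geometry(cuff_length = 1e-6)),
            1e-4)
  # monotone non-increasing in transmural pressure, capped when clamped
  R <- poiseuille_resistance(seq(-150, 250, 1))
  expect_true(all(diff(R) <= 1e-9))
  expect_identical(poiseuille_resistance(-100), 1e9)
})

test_that("wave speed is ~7 m/s at MAP, increases with distension, floors", {
  expect_equal(pulse_wave_velocity(100), 6.975, tolerance = 1e-3)
  expect_gt(pulse_wave_velocity(120), pulse_wave_velocity(60))
  pwv <- pulse_wave_velocity(seq(0, 250, 1))
  expect_true(all(diff(pwv) > 0))
  # below buckling the speed is held at the knee minimum until full clamp
  expect_equal(pulse_wave_velocity(-20), pulse_wave_velocity(0))
  expect_true(is.na(pulse_wave_velocity(-80)))
  # without the floor the distension-branch speed keeps falling sub-knee
  expect_lt(pulse_wave_velocity(-20, collapse_floor = FALSE),
            pulse_wave_velocity(0))
})

test_that("segment transit time is linear and additive in length", {
  expect_equal(segment_transit_time(100, 0.86), 123.3, tolerance = 1e-3)
  t1 <- segment_transit_time(80, 0.3)
  t2 <- segment_transit_time(80, 0.56)
  expect_identical(segment_transit_time(80, 0.86), t1 + t2)
  expect_identical(segment_transit_time(80, 0), 0)
  # halving the length halves the transit time
  expect_equal(segment_transit_time(80, 0.43), (t1 + t2) / 2,
               tolerance = 1e-12)
  expect_true(is.na(segment_transit_time(-90, 0.5)))
})

test_that("parameter constructors validate their invariants", {
  expect_error(tube_law(a = -1), "positive")
  expect_error(blood_properties(viscosity = 0), "positive")
  expect_error(arm_geometry(1, 1.2), "cuff_length")
  tab <- mechanics_table(c(-50, 0, 100))
  expect_named(tab, c("ptm_mmHg", "area_cm2", "dA_dP", "R_art", "pwv_m_s"))
  expect_equal(nrow(tab), 3)
})
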