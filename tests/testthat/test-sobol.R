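# Quasi-random sequence, Saltelli design and the Sobol index estimators,
# benchmarked against analytic sensitivity test functions.

test_that("the Sobol' sequence reproduces reference low-discrepancy points", {
  # first points of the unscrambled sequence (independently verified
  # against a reference quasi-Monte-Carlo implementation)
  pts <- sobol_points(5, 12)
  expect_identical(pts[1, ], rep(0, 12))
  expect_identical(pts[2, ], rep(0.5, 12))
  expect_identical(pts[3, ], c(0.75, 0.25, 0.25, 0.25, 0.75, 0.75, 0.25,
                               0.75, 0.75, 0.75, 0.75, 0.75))
  expect_identical(pts[5, ], c(0.375, 0.375, 0.625, 0.875, 0.375, 0.125,
                               0.375, 0.875, 0.875, 0.625, 0.875, 0.375))
  # dyadic balance: each half contains exactly half the points
  p <- sobol_points(256, 6, skip = 256)
  expect_true(all(colSums(p < 0.5) == 128))
  # a seeded digital shift is deterministic and stays in the unit cube
  s1 <- sobol_points(64, 4, skip = 64, seed = 9)
  s2 <- sobol_points(64, 4, skip = 64, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 < 1))
  expect_false(identical(s1, sobol_points(64, 4, skip = 64)))
})

test_that("the Saltelli design has the radial block structure and margins", {
  specs <- table2_specs()
  d <- sobol_design(specs, n = 64, seed = 1)
  expect_equal(nrow(d$physical), 64 * 8)
  expect_identical(colnames(d$physical),
                   c("a", "c", "sbp", "pp", "rate", "cuff_length"))
  # AB_i blocks differ from A only in column i
  A <- d$unit[1:64, ]
  B <- d$unit[64 + 1:64, ]
  for (i in 1:6) {
    ABi <- d$unit[(i + 1) * 64 + 1:64, ]
    expect_identical(ABi[, i], B[, i])
    expect_identical(ABi[, -i], A[, -i])
  }
  expect_true(all(d$physical[, "rate"] >= 4 & d$physical[, "rate"] <= 8))
  expect_true(all(d$physical[, "cuff_length"] >= 0.10 &
                    d$physical[, "cuff_length"] <= 0.18))
  d2 <- sobol_design(specs, n = 512, seed = 1)
  expect_equal(mean(d2$physical[, "sbp"]), 125, tolerance = 1.5 / 125)
  expect_equal(sd(d2$physical[, "pp"]), 5, tolerance = 0.1)
})

saltelli_eval <- function(design, f) {
  apply(design$physical, 1, f)
}

test_that("estimators recover the analytic Ishigami indices", {
  specs <- lapply(paste0("x", 1:3), parameter_spec, dist = "uniform",
                  min = -pi, max = pi)
  d <- sobol_design(specs, n = 2^12, seed = 5)
  y <- with(as.data.frame(d$physical),
            sin(x1) + 7 * sin(x2)^2 + 0.1 * x3^4 * sin(x1))
  r <- sobol_indices(d, y, n_boot = 50, seed = 5)
  expect_equal(unname(r$S1[, 1]), c(0.3139, 0.4424, 0), tolerance = 0.03)
  expect_true(all(r$ST_raw[, 1] + 0.02 >= r$S1_raw[, 1]))
  # x3 acts only through its interaction with x1
  expect_gt(r$ST[3, 1], 0.2)
})

test_that("estimators recover the analytic g-function indices", {
  a <- c(0, 1, 4.5, 9, 99, 99)
  specs <- lapply(paste0("x", 1:6), parameter_spec, dist = "uniform",
                  min = 0, max = 1)
  d <- sobol_design(specs, n = 2^12, seed = 3)
  y <- apply(d$physical, 1,
             function(x) prod((abs(4 * x - 2) + a) / (1 + a)))
  vi <- (1 / 3) / (1 + a)^2
  s1_true <- vi / (prod(1 + vi) - 1)
  r <- sobol_indices(d, y, n_boot = 50, seed = 3)
  expect_equal(unname(r$S1[, 1]), s1_true, tolerance = 0.03)
})

test_that("an additive symmetric model splits variance equally", {
  specs <- lapply(paste0("x", 1:4), parameter_spec, dist = "uniform",
                  min = 0, max = 1)
  d <- sobol_design(specs, n = 2^11, seed = 2)
  y <- rowSums(d$physical)
  r <- sobol_indices(d, y, n_boot = 50, seed = 2)
  expect_equal(unname(r$S1[, 1]), rep(0.25, 4), tolerance = 0.02)
  expect_lte(sum(r$S1_raw[, 1]), 1.05)
})

test_that("a degenerate (fixed) parameter gets a null index", {
  specs <- list(parameter_spec("x1", "uniform", min = 0, max = 1),
                parameter_spec("x2", "uniform", min = 0.5, max = 0.5),
                parameter_spec("x3", "normal", mean = 0, sd = 1))
  d <- sobol_design(specs, n = 2^10, seed = 7)
  y <- d$physical[, 1] + d$physical[, 2] + d$physical[, 3]
  r <- sobol_indices(d, y, n_boot = 50, seed = 7)
  expect_lt(abs(r$S1_raw[2, 1]), 0.02)
  expect_lt(r$ST[2, 1], 0.02)
})

test_that("constant outputs are rejected", {
  specs <- list(parameter_spec("x1", "uniform", min = 0, max = 1))
  d <- sobol_design(specs, n = 64, seed = 1)
  expect_error(sobol_indices(d, rep(3, nrow(d$physical))), "variance")
})

test_that("the model batch is deterministic and consistent with single runs", {
  ref_row <- c(a = 0.03, c = 0.1, sbp = 120, pp = 40, rate = 6,
               cuff_length = 0.14)
  X <- rbind(ref_row, ref_row, c(a = 0.02, c = 0.12, sbp = 135, pp = 45,
                                 rate = 5, cuff_length = 0.12))
  rownames(X) <- NULL
  out <- run_model_batch(list(physical = X), fail_frac = 1)
  # identical rows give identical outputs
  expect_identical(out[1, ], out[2, ])
  # the all-reference row equals the single-run reference metrics
  m <- ref_parts()$metrics
  expect_equal(unname(out[1, ]), unname(unlist(m[cuffsim:::.METRIC_COLS])),
               tolerance = 1e-6)
  expect_true(all(is.finite(out[3, ])))
})

test_that("invalid draws are flagged and batch failure aborts over threshold", {
  bad <- c(a = 0.03, c = 0.1, sbp = 40, pp = 38, rate = 6,
           cuff_length = 0.14)   # DBP barely above venous pressure
  good <- c(a = 0.03, c = 0.1, sbp = 120, pp = 40, rate = 6,
            cuff_length = 0.14)
  X <- rbind(bad, good)
  rownames(X) <- NULL
  expect_error(run_model_batch(list(physical = X), fail_frac = 0.01),
               "failed")
  out <- suppressMessages(run_model_batch(list(physical = X),
                                          fail_frac = 0.6))
  expect_identical(attr(out, "failed"), 1L)
  expect_true(anyNA(out[1, ]) && !anyNA(out[2, ]))
})
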